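test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_sites = 5), "n_sites")
  expect_error(simulation_config(n_replicates = 1), "n_replicates")
  expect_error(simulation_config(group_times_min = c(0, 30, 30, 240)),
               "increasing")
  expect_error(simulation_config(effect_size = 0.99), "0.95")
  expect_error(simulation_config(frac_cis = 0.3, frac_time_trend = 0.1),
               "frac_cis")
  expect_error(simulation_config(category_mix = c("3'UTR" = 1)), "sum|named")
})

test_that("a null configuration carries no DRE flags", {
  sim <- generate_dataset(simulation_config(n_sites = 30, frac_dre = 0,
                                            frac_time_trend = 0, frac_cis = 0,
                                            effect_size = 0, seed = 3))
  expect_equal(sum(sim$truth$is_dre), 0)
  expect_equal(sum(sim$truth$is_time_trend), 0)
})

test_that("the same config and seed give byte-identical files", {
  cfg <- simulation_config(n_sites = 40, frac_dre = 0.1, frac_time_trend = 0.1,
                           frac_cis = 0.05, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_dataset(cfg); s2 <- generate_dataset(cfg)
  p1 <- write_dataset(s1$dataset, d1, truth = s1$truth)
  p2 <- write_dataset(s2$dataset, d2, truth = s2$truth)
  expect_equal(basename(p1), basename(p2))
  for (f in names(p1))
    expect_equal(unname(tools::md5sum(p1[[f]])), unname(tools::md5sum(p2[[f]])),
                 info = f)
})

test_that("truth flags respect the configured structure", {
  cfg <- simulation_config(n_sites = 200, frac_dre = 0.1, frac_time_trend = 0.1,
                           frac_cis = 0.05, seed = 7)
  sim <- generate_dataset(cfg)
  tr <- sim$truth
  expect_equal(sum(tr$is_dre), 20)
  expect_equal(sum(tr$is_time_trend), 20)
  expect_equal(sum(tr$is_cis), 10)
  expect_equal(sum(tr$is_decoy), 20)
  # decoys never carry A-to-I truth flags, and cis implies trend
  expect_false(any(tr$is_decoy & (tr$is_dre | tr$is_time_trend | tr$is_cis)))
  expect_true(all(tr$is_time_trend[tr$is_cis]))
  # DRE spread equals the configured effect size
  levcols <- grep("^level_", names(tr))
  spread <- apply(tr[levcols], 1, function(x) max(x) - min(x))
  expect_true(all(spread[tr$is_dre] >= cfg$effect_size - 1e-9))
  expect_true(all(spread[!tr$is_dre & !tr$is_time_trend] < 1e-12))
  # trend trajectories are monotone in the trend direction
  for (i in which(tr$is_time_trend)) {
    d <- diff(as.numeric(tr[i, levcols]))
    expect_true(all(sign(d) == tr$trend_sign[i]))
  }
  # decoy mismatches are never A>G in transcript orientation
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  dk <- tr[tr$is_decoy, ]
  ref_t <- ifelse(dk$strand == "-", comp[dk$ref], dk$ref)
  alt_t <- ifelse(dk$strand == "-", comp[dk$alt], dk$alt)
  expect_false(any(ref_t == "A" & alt_t == "G"))
  # known sites are a subset of true A-to-I sites
  expect_false(any(tr$is_known & tr$is_decoy))
})

test_that("baseline levels match the Beta moment and counts stay bounded", {
  cfg <- simulation_config(n_sites = 1000, frac_dre = 0.1, seed = 7)
  sim <- generate_dataset(cfg)
  tr <- sim$truth
  base_mean <- 2 / (2 + 18)
  nondre <- !tr$is_dre & !tr$is_time_trend & !tr$is_decoy
  x <- tr$level_PBS[nondre]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - base_mean), 3 * se)
  ac <- sim$dataset$allele_counts
  expect_true(all(ac$alt_count <= ac$ref_count + ac$alt_count + ac$other_count))
  expect_true(all(ac$alt_count >= 0 & ac$ref_count >= 0))
  # every site has a row for every sample
  expect_equal(nrow(ac), 1000 * 12)
})

test_that("truth-null sites are exchangeable across groups", {
  cfg <- simulation_config(n_sites = 2000, frac_dre = 0, frac_time_trend = 0,
                           frac_cis = 0, decoy_mismatch_frac = 0, seed = 42)
  sim <- generate_dataset(cfg)
  ac <- sim$dataset$allele_counts
  lev <- ac$alt_count / pmax(ac$ref_count + ac$alt_count, 1)
  des <- as.data.frame(sim$dataset$design)
  g <- factor(des$group_label[match(ac$sample_id, des$sample_id)])
  kwp <- vapply(split(seq_len(nrow(ac)), ac$pos), function(ix) {
    if (length(unique(lev[ix])) < 2) return(NA_real_)
    suppressWarnings(kruskal.test(lev[ix], g[ix])$p.value)
  }, numeric(1))
  frac <- mean(kwp < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("cis sites couple true editing to simulated expression", {
  cfg <- simulation_config(n_sites = 100, frac_time_trend = 0.3,
                           frac_cis = 0.2, seed = 23)
  sim <- generate_dataset(cfg)
  tr <- sim$truth
  cnt <- sim$dataset$gene_counts$counts
  des <- as.data.frame(sim$dataset$design)
  levcols <- grep("^level_", names(tr))
  for (i in which(tr$is_cis)) {
    ge <- cnt[tr$gene_id[i], ]
    gmean <- tapply(ge, des$group_label[match(colnames(cnt), des$sample_id)],
                    mean)
    gmean <- gmean[sub("^level_", "", names(tr)[levcols])]
    r <- suppressWarnings(cor(as.numeric(tr[i, levcols]), gmean,
                              method = "spearman"))
    expect_gt(r, 0)
  }
})

test_that("written datasets are complete and round-trip faithfully", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  paths <- write_dataset(sim$dataset, dir, truth = sim$truth)
  expect_true(all(file.exists(paths)))
  expect_setequal(basename(paths),
                  c("allele_counts.tsv", "gene_counts.tsv",
                    "transcript_models.tsv", "cds_sequences.fa",
                    "known_sites.tsv", "design.tsv", "truth.tsv"))
  back <- read_allele_counts(paths[["allele_counts"]])
  expect_equal(back, sim$dataset$allele_counts)
  expect_equal(nrow(read.delim(paths[["truth"]])), 80)
  gc <- read_gene_counts(paths[["gene_counts"]])
  expect_equal(gc$counts, sim$dataset$gene_counts$counts)
  des <- read_design(paths[["design"]])
  expect_equal(des$sample_id, sim$dataset$design$sample_id)
  # refuses to overwrite without force
  expect_error(write_dataset(sim$dataset, dir, truth = sim$truth),
               "overwrite")
  expect_silent(write_dataset(sim$dataset, dir, truth = sim$truth,
                              force = TRUE))
})
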