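grp4 <- factor(rep(paste0("g", 1:4), each = 3), levels = paste0("g", 1:4))

test_that("identical groups give a zero LRT statistic and p = 1", {
  alt <- rep(5, 12); ref <- rep(45, 12)
  r <- glm_lrt_test(alt, ref, grp4)
  expect_equal(r$stat, 0, tolerance = 1e-8)
  expect_equal(r$p, 1, tolerance = 1e-8)
})

test_that("a large group effect is detected and matches permutation mode", {
  set.seed(3)
  lev <- rep(c(0.05, 0.05, 0.05, 0.40), each = 3)
  d <- rep(200L, 12)
  a <- rbinom(12, d, lev)
  r <- glm_lrt_test(a, d - a, grp4)
  expect_lt(r$p, 1e-6)
  rp <- glm_lrt_test(a, d - a, grp4,
                     dre_config(empirical_p_mode = "permutation",
                                n_perm = 500, seed = 9))
  # shuffles can reproduce the observed partition (any relabeling ties the
  # statistic), so the empirical p sits near its 1/(n_perm+1) floor
  expect_lt(rp$p, 0.03)
})

test_that("the LRT handles degenerate groups without crashing", {
  alt <- c(0, 0, 0, 8, 9, 7, 5, 6, 4, 5, 5, 5)
  ref <- c(50, 60, 40, 42, 41, 43, 45, 44, 46, 45, 45, 45)
  r <- glm_lrt_test(alt, ref, grp4)
  expect_true(r$separation_adjusted)
  expect_true(is.finite(r$p) && r$p > 0 && r$p <= 1)
})

test_that("the null LRT is approximately calibrated", {
  set.seed(21)
  ps <- replicate(400, {
    d <- rnbinom(12, mu = 100, size = 5)
    a <- rbinom(12, d, 0.1)
    glm_lrt_test(a, pmax(d - a, 0), grp4)$p
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("the R x 2 exact test matches brute-force enumeration", {
  expect_equal(as.numeric(fisher_rx2_test(cbind(c(10, 0), c(0, 10)))),
               fisher_oracle(cbind(c(10, 0), c(0, 10)))$p, tolerance = 1e-9)
  # proportional rows are exactly independent
  prop <- cbind(c(2, 4, 6, 8), c(3, 6, 9, 12))
  expect_equal(as.numeric(fisher_rx2_test(prop)), 1, tolerance = 1e-9)
  set.seed(17)
  for (i in 1:40) {
    R <- sample(2:4, 1)
    tab <- matrix(sample(0:10, 2 * R, replace = TRUE), R, 2)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) next
    got <- fisher_rx2_test(tab)
    orc <- fisher_oracle(tab)
    expect_equal(as.numeric(got), orc$p, tolerance = 1e-9)
    expect_equal(attr(got, "prob_total"), 1, tolerance = 1e-9)
    # independent reference implementation
    expect_equal(as.numeric(got), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-6)
  }
})

test_that("the Monte-Carlo fallback approximates the exact p", {
  tab <- cbind(c(40, 55, 38, 60), c(160, 145, 162, 140))
  exact <- as.numeric(fisher_rx2_test(tab, budget = 1e7))
  mc <- fisher_rx2_test(tab, budget = 10, n_mc = 20000, seed = 4)
  expect_equal(attr(mc, "method"), "monte-carlo")
  expect_equal(as.numeric(mc), exact, tolerance = 0.03)
  expect_warning(p1 <- fisher_rx2_test(cbind(c(0, 0), c(5, 5))), "degenerate")
  expect_equal(as.numeric(p1), 1)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(2)
  p <- runif(1000)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in rank
})

test_that("Tukey HSD matches a direct studentized-range computation", {
  set.seed(6)
  for (i in 1:10) {
    y <- rnorm(12, mean = rep(c(0, 0.5, 0, 1), each = 3), sd = 0.4)
    got <- tukey_hsd(y, grp4)
    # independent path: studentized range distribution from first principles
    gm <- tapply(y, grp4, mean)
    mse <- sum((y - ave(y, grp4))^2) / (12 - 4)
    for (j in seq_len(nrow(got))) {
      gs <- strsplit(got$pair[j], "-", fixed = TRUE)[[1]]
      q <- abs(gm[[gs[1]]] - gm[[gs[2]]]) / sqrt(mse / 3)
      expect_equal(got$p[j], stats::ptukey(q, 4, 8, lower.tail = FALSE),
                   tolerance = 1e-6)
    }
  }
})

test_that("Tukey HSD behaves at the extremes", {
  y_eq <- rep(c(0.1, 0.12, 0.11), 4)
  got <- tukey_hsd(y_eq, grp4)
  expect_true(all(got$p > 0.95))
  y_shift <- c(rnorm(9, 0.1, 0.01), rnorm(3, 0.6, 0.01))
  got2 <- tukey_hsd(y_shift, grp4)
  worst <- got2[order(got2$p), ]
  expect_true(all(grepl("g4", worst$pair[1:3])))
  y_const <- rep(c(0.1, 0.1, 0.1, 0.3), each = 3)
  got3 <- tukey_hsd(y_const, grp4)
  expect_true(attr(got3, "zero_variance"))
  expect_equal(sort(unique(got3$p)), c(0, 1))
})

test_that("the dual decision rule gates on GLM p and either FDR", {
  cfg <- dre_config()
  expect_true(decide_dre(0.04, 0.20, 0.01, cfg))
  expect_false(decide_dre(0.06, 0.001, 0.001, cfg))
  expect_false(decide_dre(0.01, 0.10, 0.10, cfg))
  expect_true(decide_dre(0.01, 0.01, NA, cfg))
  expect_false(decide_dre(0.01, 0.10, NA, cfg))
})

test_that("missense flag needs DRE, missense category and >5% spread", {
  cfg <- dre_config()
  # group means like the documented Azin1-style event: 17.3/9/6.6/19.1%
  expect_true(flag_missense_diff(TRUE, "missense", 0.191 - 0.066, cfg))
  expect_false(flag_missense_diff(TRUE, "missense", 0.03, cfg))
  expect_false(flag_missense_diff(TRUE, "3'UTR", 0.20, cfg))
  expect_false(flag_missense_diff(FALSE, "missense", 0.20, cfg))
})

test_that("dre_test recovers designated DRE sites on synthetic data", {
  cfg <- simulation_config(n_sites = 150, frac_dre = 0.2, frac_time_trend = 0,
                           frac_cis = 0, effect_size = 0.2,
                           depth_nb_params = c(mean = 100, dispersion = 5),
                           seed = 11)
  sim <- generate_dataset(cfg)
  ev <- events_from_sim(sim)
  res <- dre_test(ev, sim$dataset$design)
  truth <- sim$truth
  res$true_dre <- truth$is_dre[match(res$site_id, truth$site_id)]
  sens <- mean(res$is_dre[res$true_dre], na.rm = TRUE)
  expect_gt(sens, 0.8)
  flagged <- sum(res$is_dre, na.rm = TRUE)
  fdr <- 1 - sum(res$is_dre & res$true_dre, na.rm = TRUE) / max(flagged, 1)
  expect_lt(fdr, 0.15)
  # result invariants
  expect_true(all(res$max_intergroup_diff >= 0, na.rm = TRUE))
  expect_true(all(res$glm_p > 0 & res$glm_p <= 1, na.rm = TRUE))
  expect_true(all(res$is_dre == (res$glm_p < 0.05 &
                    (res$glm_fdr < 0.05 |
                       (!is.na(res$fisher_fdr) & res$fisher_fdr < 0.05))),
                  na.rm = TRUE))
  # Fisher p only computed below the GLM gate
  expect_true(all(is.na(res$fisher_p[res$glm_p >= 0.05])))
  # Tukey columns exist and are probabilities
  tk <- as.matrix(res[, grep("^tukey_", names(res))])
  expect_true(all(tk >= 0 & tk <= 1, na.rm = TRUE))
})
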