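#' Simulation configuration for the LPS time-course generator
#'
#' Defines the study conditions the generator emulates: four time-point
#' groups of three replicates (control at 0 min), beta-distributed per-site
#' baseline editing levels, negative-binomial sequencing depth, designated
#' differential / time-trend / cis-correlated sites, a mixture of
#' functional categories, and a fraction of non-A>G decoy mismatches.
#'
#' @param n_groups number of time-point groups (default 4).
#' @param n_replicates samples per group (default 3).
#' @param group_times_min strictly increasing minutes post-treatment, the
#'   control at 0 (default `c(0, 15, 30, 240)`, a vessels-like design; use
#'   `c(0, 30, 60, 120)` for a CEC/microglia-like design).
#' @param n_sites number of editing sites (>= 10).
#' @param frac_dre proportion of sites with a group effect.
#' @param frac_time_trend proportion with a monotone-in-time effect.
#' @param frac_cis proportion whose host-gene expression tracks editing;
#'   cis sites are a subset of trend sites, so `frac_cis <=
#'   frac_time_trend`.
#' @param baseline_beta_params `c(a, b)` of the baseline editing-level
#'   Beta distribution (default `c(2, 18)`, mean 10%).
#' @param effect_size additive shift in editing proportion for the
#'   affected group of a DRE site.
#' @param trend_amplitude total editing-level change from first to last
#'   time point for trend sites (default `effect_size`).
#' @param depth_nb_params `c(mean, dispersion)` of the negative-binomial
#'   per-site per-sample depth (default `c(50, 5)`).
#' @param decoy_mismatch_frac fraction of sites that are non-A>G decoys.
#' @param category_mix named proportions over the functional categories
#'   `3'UTR`, `missense`, `intronic`, `lincRNA`, `synonymous`, `5'UTR`;
#'   must sum to 1.
#' @param known_site_frac fraction of true A-to-I sites included in the
#'   known-site (REDIportal-style) list (default 0.3).
#' @param adar_coupling strength of the global coupling between editing
#'   levels and the ADAR2-like enzyme trajectory (default 0, which keeps
#'   truth-null sites exchangeable across groups).
#' @param n_background_genes extra expressed genes without editing sites.
#' @param tissue tissue label stamped on the design.
#' @param seed RNG seed; fixing it fixes every emitted byte.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_groups = 4L, n_replicates = 3L,
                              group_times_min = c(0, 15, 30, 240),
                              n_sites = 300L,
                              frac_dre = 0.05, frac_time_trend = 0.05,
                              frac_cis = 0.02,
                              baseline_beta_params = c(2, 18),
                              effect_size = 0.15,
                              trend_amplitude = effect_size,
                              depth_nb_params = c(mean = 50, dispersion = 5),
                              decoy_mismatch_frac = 0.10,
                              category_mix = c("3'UTR" = 0.35,
                                               missense = 0.10,
                                               intronic = 0.20,
                                               lincRNA = 0.10,
                                               synonymous = 0.10,
                                               "5'UTR" = 0.15),
                              known_site_frac = 0.30,
                              adar_coupling = 0,
                              n_background_genes = 40L,
                              tissue = "vessels", seed = 1L) {
  props <- c(frac_dre, frac_time_trend, frac_cis, decoy_mismatch_frac,
             known_site_frac)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (abs(sum(category_mix) - 1) > 1e-8) stop("category_mix must sum to 1")
  if (any(category_mix < 0)) stop("category_mix proportions must be >= 0")
  need_cat <- c("3'UTR", "missense", "intronic", "lincRNA", "synonymous",
                "5'UTR")
  if (!setequal(names(category_mix), need_cat))
    stop("category_mix must be named over: ", paste(need_cat, collapse = ", "))
  if (any(diff(group_times_min) <= 0))
    stop("group_times_min must be strictly increasing")
  if (length(group_times_min) != n_groups)
    stop("group_times_min must have one entry per group")
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (n_sites < 10L) stop("n_sites must be >= 10")
  if (frac_cis > frac_time_trend)
    stop("frac_cis must not exceed frac_time_trend (cis sites are trend sites)")
  if (effect_size < 0 || effect_size > 0.95 ||
      trend_amplitude < 0 || trend_amplitude > 0.95)
    stop("effect sizes above 0.95 push editing levels outside [0, 1] for ",
         "any attainable baseline")
  stopifnot(length(baseline_beta_params) == 2, all(baseline_beta_params > 0),
            length(depth_nb_params) == 2, all(depth_nb_params > 0))
  structure(list(n_groups = as.integer(n_groups),
                 n_replicates = as.integer(n_replicates),
                 group_times_min = as.numeric(group_times_min),
                 n_sites = as.integer(n_sites), frac_dre = frac_dre,
                 frac_time_trend = frac_time_trend, frac_cis = frac_cis,
                 baseline_beta_params = unname(baseline_beta_params),
                 effect_size = effect_size,
                 trend_amplitude = trend_amplitude,
                 depth_nb_params = unname(depth_nb_params),
                 decoy_mismatch_frac = decoy_mismatch_frac,
                 category_mix = category_mix[need_cat],
                 known_site_frac = known_site_frac,
                 adar_coupling = adar_coupling,
                 n_background_genes = as.integer(n_background_genes),
                 tissue = tissue, seed = as.integer(seed)),
            class = "simulation_config")
}

time_group_label <- function(t) {
  if (t == 0) "PBS" else if (t %% 60 == 0) paste0(t / 60, "h")
  else paste0(t, "min")
}

# enzyme expression trajectories (fold change vs control), interpolated to
# the number of groups; shapes emulate a fast ADAR2-like rise with late
# decline and a late ADAR1-like rise
enzyme_trajectories <- function(n_groups) {
  base_adar <- c(1.0, 0.9, 0.8, 1.8)
  base_adarb1 <- c(1.0, 1.8, 1.4, 0.8)
  ix <- seq(1, 4, length.out = n_groups)
  list(Adar = stats::approx(1:4, base_adar, ix)$y,
       Adarb1 = stats::approx(1:4, base_adarb1, ix)$y)
}

NON_AG_PAIRS <- {
  b <- c("A", "C", "G", "T")
  p <- expand.grid(ref = b, alt = b, stringsAsFactors = FALSE)
  p <- p[p$ref != p$alt, ]
  p[!(p$ref == "A" & p$alt == "G"), ]
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

# build one host gene (transcript model + optional CDS sequence) and the
# genomic coordinates of its designed site
build_host_gene <- function(i, g0, strand, category, config) {
  gid <- sprintf("gene%04d", i)
  tid <- sprintf("tx%04d", i)
  if (category == "lincRNA") {
    m <- transcript_model(gid, tid, "chr1", strand,
                          exons = cbind(g0, g0 + 999L), cds = NULL,
                          biotype = "lincRNA")
    pos <- g0 + sample.int(1000L, 1) - 1L
    return(list(model = m, cds_seq = NULL, pos = pos, cds_pos = NA_integer_))
  }
  exons <- cbind(c(g0, g0 + 700L), c(g0 + 499L, g0 + 1699L))
  cds <- if (strand == "+")
    cbind(c(g0 + 150L, g0 + 700L), c(g0 + 499L, g0 + 1249L))
  else
    cbind(c(g0 + 450L, g0 + 700L), c(g0 + 499L, g0 + 1549L))
  m <- transcript_model(gid, tid, "chr1", strand, exons, cds,
                        biotype = "protein_coding")
  codons <- sample(sense_codons(), 300, replace = TRUE)
  codons[1] <- "ATG"
  cds_pos <- NA_integer_
  if (category %in% c("missense", "synonymous")) {
    ci <- sample(10:290, 1)
    if (category == "missense") {           # AGC(S) -> GGC(G), offset 1
      codons[ci] <- "AGC"
      cds_pos <- (ci - 1L) * 3L + 1L
    } else {                                # GCA(A) -> GCG(A), offset 3
      codons[ci] <- "GCA"
      cds_pos <- ci * 3L
    }
    pos <- cds_to_genomic(cds_pos, m)
  } else {
    pos <- switch(category,
      "5'UTR" = if (strand == "+") g0 + sample.int(150L, 1) - 1L
                else g0 + 1550L + sample.int(150L, 1) - 1L,
      "3'UTR" = if (strand == "+") g0 + 1250L + sample.int(450L, 1) - 1L
                else g0 + sample.int(450L, 1) - 1L,
      intronic = g0 + 500L + sample.int(200L, 1) - 1L,
      stop("unhandled category ", category))
  }
  list(model = m, cds_seq = paste(codons, collapse = ""), pos = pos,
       cds_pos = cds_pos)
}

#' Generate a synthetic editing dataset with ground truth
#'
#' Draws per-site baseline editing levels from the configured Beta
#' distribution, applies additive group effects to DRE sites and
#' equal-increment monotone trajectories (random sign) to time-trend
#' sites, then samples per-site per-sample alternative counts as
#' Binomial(depth, level) with negative-binomial depth. Each site is
#' hosted by its own toy gene (two-exon protein-coding template or
#' single-exon lincRNA) so categories, strand resolution and coding
#' consequences are all exercised; cis sites get host-gene expression
#' whose group means increase with the true group-mean editing level;
#' decoy sites emit a non-A>G mismatch. Deterministic for a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (a `simulated_dataset`: `allele_counts`,
#'   `gene_counts`, `models`, `cds_seqs`, `known_sites`, `design`) and
#'   `truth` (the ground-truth table).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  local_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  G <- config$n_groups; R <- config$n_replicates
  ns <- config$n_sites
  groups <- vapply(config$group_times_min, time_group_label, character(1))
  design <- study_design(
    sample_id = sprintf("s%02d", seq_len(G * R)),
    group_label = rep(groups, each = R),
    time_min = rep(config$group_times_min, each = R),
    tissue = config$tissue)
  samples <- design$sample_id
  grp_of <- factor(design_group_of(design, samples), levels = groups)

  # --- site roles -----------------------------------------------------
  n_dre <- round(config$frac_dre * ns)
  n_trend <- round(config$frac_time_trend * ns)
  n_cis <- round(config$frac_cis * ns)
  n_decoy <- round(config$decoy_mismatch_frac * ns)
  if (n_dre + n_trend + n_decoy > ns)
    stop("frac_dre + frac_time_trend + decoy_mismatch_frac exceed n_sites")
  role <- rep("null", ns)
  role[seq_len(n_dre)] <- "dre"
  role[n_dre + seq_len(n_trend)] <- "trend"
  is_cis <- rep(FALSE, ns)
  if (n_cis > 0) is_cis[n_dre + seq_len(n_cis)] <- TRUE   # cis subset of trend
  if (n_decoy > 0) role[n_dre + n_trend + seq_len(n_decoy)] <- "decoy"
  role <- role[sample.int(ns)]            # shuffle roles over site indices
  is_cis <- rep(FALSE, ns)                # cis flags follow the shuffled trend sites

  if (n_cis > 0) is_cis[which(role == "trend")[seq_len(n_cis)]] <- TRUE

  # --- categories, strands, host genes --------------------------------
  mix <- config$category_mix
  cats <- sample(names(mix), ns, replace = TRUE, prob = mix)
  decoy_ok <- c("3'UTR", "intronic", "lincRNA", "5'UTR")
  dmix <- mix[decoy_ok] / sum(mix[decoy_ok])
  redo <- role == "decoy" & !(cats %in% decoy_ok)
  cats[redo] <- sample(decoy_ok, sum(redo), replace = TRUE, prob = dmix)
  strands <- sample(c("+", "-"), ns, replace = TRUE)

  models <- vector("list", ns)
  cds_seqs <- character(0)
  pos <- integer(ns); cds_pos <- integer(ns)
  for (i in seq_len(ns)) {
    hg <- build_host_gene(i, g0 = 1000L + (i - 1L) * 5000L,
                          strand = strands[i], category = cats[i], config)
    models[[i]] <- hg$model
    if (!is.null(hg$cds_seq)) cds_seqs[hg$model$transcript_id] <- hg$cds_seq
    pos[i] <- hg$pos; cds_pos[i] <- hg$cds_pos
  }
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")

  # genomic ref/alt: A>G in transcript orientation for true sites, a
  # non-A>G transcript-orientation pair for decoys
  ref_t <- rep("A", ns); alt_t <- rep("G", ns)
  if (any(role == "decoy")) {
    di <- which(role == "decoy")
    pick <- sample.int(nrow(NON_AG_PAIRS), length(di), replace = TRUE)
    ref_t[di] <- NON_AG_PAIRS$ref[pick]
    alt_t[di] <- NON_AG_PAIRS$alt[pick]
  }
  minus <- strands == "-"
  ref_g <- ifelse(minus, COMPLEMENT[ref_t], ref_t)
  alt_g <- ifelse(minus, COMPLEMENT[alt_t], alt_t)

  # --- true editing levels per group ----------------------------------
  a <- config$baseline_beta_params[1]; b <- config$baseline_beta_params[2]
  eff <- config$effect_size; amp <- config$trend_amplitude
  base <- pmin(pmax(rbeta(ns, a, b), 0.005), 0.98)
  lev <- matrix(rep(base, G), ns, G, dimnames = list(NULL, groups))
  dre_group <- rep(NA_character_, ns)
  trend_sign <- rep(NA_integer_, ns)
  ramp <- (seq_len(G) - 1) / (G - 1)      # equal increments across time points
  for (i in seq_len(ns)) {
    if (role[i] == "dre") {
      base[i] <- min(base[i], 1 - eff - 0.01)
      g <- sample.int(G, 1)
      lev[i, ] <- base[i]; lev[i, g] <- base[i] + eff
      dre_group[i] <- groups[g]
    } else if (role[i] == "trend") {
      s <- sample(c(1L, -1L), 1)
      if (s > 0) base[i] <- min(base[i], 1 - amp - 0.01)
      else base[i] <- max(base[i], amp + 0.005)
      lev[i, ] <- base[i] + s * amp * ramp
      trend_sign[i] <- s
    }
  }
  traj <- enzyme_trajectories(G)
  if (config$adar_coupling != 0) {
    mult <- 1 + config$adar_coupling * (traj$Adarb1 - 1)
    keep <- role != "decoy"
    lev[keep, ] <- pmin(pmax(sweep(lev[keep, , drop = FALSE], 2, mult, "*"),
                             0), 1)
  }

  # --- allele counts --------------------------------------------------
  mu <- config$depth_nb_params[1]; disp <- config$depth_nb_params[2]
  nsmp <- length(samples)
  depth <- matrix(rnbinom(ns * nsmp, mu = mu, size = disp), ns, nsmp)
  lev_s <- lev[, as.integer(grp_of), drop = FALSE]
  altc <- matrix(rbinom(ns * nsmp, depth, lev_s), ns, nsmp)
  refc <- depth - altc
  allele_counts <- data.frame(
    chrom = "chr1",
    pos = rep(pos, times = nsmp),
    ref = rep(ref_g, times = nsmp),
    alt = rep(alt_g, times = nsmp),
    sample_id = rep(samples, each = ns),
    ref_count = as.integer(refc),
    alt_count = as.integer(altc),
    other_count = 0L, stringsAsFactors = FALSE)
  allele_counts <- allele_counts[order(allele_counts$pos,
                                       allele_counts$sample_id), ]
  rownames(allele_counts) <- NULL

  # --- expression -----------------------------------------------------
  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  exonic_len <- vapply(models, function(m)
    sum(m$exons[, 2] - m$exons[, 1] + 1L), integer(1))
  bg_ids <- sprintf("bg%03d", seq_len(config$n_background_genes))
  all_genes <- c(unname(gene_ids), bg_ids, "Adar", "Adarb1")
  lengths <- c(unname(exonic_len),
               sample(800:3000, config$n_background_genes, replace = TRUE),
               2000L, 2200L)
  names(lengths) <- all_genes
  base_expr <- rlnorm(length(all_genes), log(300), 0.6)
  mult <- matrix(1, length(all_genes), G, dimnames = list(all_genes, groups))
  ci <- which(is_cis)
  if (length(ci)) mult[gene_ids[ci], ] <- 1 + 5 * lev[ci, , drop = FALSE]
  mult["Adar", ] <- traj$Adar
  mult["Adarb1", ] <- traj$Adarb1
  mu_expr <- base_expr * mult[, as.integer(grp_of), drop = FALSE]
  counts <- matrix(rnbinom(length(mu_expr), mu = mu_expr, size = 50),
                   length(all_genes), nsmp,
                   dimnames = list(all_genes, samples))

  # --- known sites, truth ---------------------------------------------
  true_ix <- which(role != "decoy")
  n_known <- round(config$known_site_frac * length(true_ix))
  known_ix <- sort(sample(true_ix, n_known))
  known_sites <- data.frame(chrom = "chr1", pos = pos[known_ix],
                            ref = ref_g[known_ix], alt = "A-to-I",
                            strand = strands[known_ix],
                            stringsAsFactors = FALSE)
  truth <- data.frame(
    site_id = paste0("chr1:", pos), chrom = "chr1", pos = pos,
    strand = strands, ref = ref_g, alt = alt_g,
    gene_id = unname(gene_ids), category = cats, cds_pos = cds_pos,
    is_dre = role == "dre", dre_group = dre_group,
    is_time_trend = role == "trend", trend_sign = trend_sign,
    is_cis = is_cis, is_decoy = role == "decoy",
    is_known = seq_len(ns) %in% known_ix, stringsAsFactors = FALSE)
  truth <- cbind(truth, setNames(as.data.frame(lev),
                                 paste0("level_", groups)))

  dataset <- structure(list(allele_counts = allele_counts,
                            gene_counts = list(counts = counts,
                                               lengths = lengths),
                            models = models, cds_seqs = cds_seqs,
                            known_sites = known_sites, design = design),
                       class = "simulated_dataset")
  list(dataset = dataset, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits `allele_counts.tsv`, `gene_counts.tsv`, `transcript_models.tsv`,
#' `cds_sequences.fa`, `known_sites.tsv`, `design.tsv` and `truth.tsv` in
#' the formats the analysis readers consume. Refuses to overwrite existing
#' files unless `force = TRUE`.
#'
#' @param dataset the `dataset` element of [generate_dataset()] output.
#' @param truth the matching truth table (omit to skip `truth.tsv`).
#' @param out_dir target directory, created if missing.
#' @param force overwrite existing files.
#' @return invisibly, the named vector of paths written.
#' @export
write_dataset <- function(dataset, out_dir, truth = NULL, force = FALSE) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c(
    allele_counts = "allele_counts.tsv", gene_counts = "gene_counts.tsv",
    models = "transcript_models.tsv", cds = "cds_sequences.fa",
    known = "known_sites.tsv", design = "design.tsv", truth = "truth.tsv"))
  names(paths) <- c("allele_counts", "gene_counts", "models", "cds", "known",
                    "design", "truth")
  if (is.null(truth)) paths <- paths[names(paths) != "truth"]
  if (!force && any(file.exists(paths)))
    stop("refusing to overwrite existing files in ", out_dir,
         " (use force = TRUE)")
  wt <- function(d, p) write.table(d, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(dataset$allele_counts, paths[["allele_counts"]])
  gc_df <- data.frame(gene_id = rownames(dataset$gene_counts$counts),
                      length = unname(dataset$gene_counts$lengths[
                        rownames(dataset$gene_counts$counts)]),
                      dataset$gene_counts$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
  wt(gc_df, paths[["gene_counts"]])
  wt(models_to_table(dataset$models), paths[["models"]])
  fa <- Biostrings::DNAStringSet(dataset$cds_seqs)
  Biostrings::writeXStringSet(fa, paths[["cds"]])
  wt(dataset$known_sites, paths[["known"]])
  wt(as.data.frame(dataset$design), paths[["design"]])
  if (!is.null(truth)) wt(truth, paths[["truth"]])
  invisible(paths)
}
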