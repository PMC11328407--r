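#' Run the full editing-analysis pipeline from a config
#'
#' Executes simulate (or load) -> call -> filter -> annotate -> dre ->
#' time/cis/enzyme correlation -> expression -> report, writing every
#' stage's table under `out_dir` plus a JSON run manifest with input/output
#' MD5 checksums, the config snapshot, the seed and per-stage row counts.
#' With a fixed seed the whole run is byte-deterministic.
#'
#' The config is a YAML file (or an equivalent named list) with keys:
#' \describe{
#'   \item{seed}{integer, required.}
#'   \item{out_dir}{output directory (may instead be passed as the
#'     `out_dir` argument).}
#'   \item{simulate}{optional block of [simulation_config()] fields; when
#'     present the inputs are generated and also written to
#'     `out_dir/inputs`.}
#'   \item{inputs}{otherwise required: paths `allele_counts`, `design`,
#'     `transcript_models`, `cds_sequences`, `known_sites`, `gene_counts`.}
#'   \item{thresholds}{optional [calling_thresholds()] fields.}
#'   \item{dre}{optional [dre_config()] fields.}
#'   \item{alpha}{significance level for time-dependence (default 0.05).}
#' }
#'
#' @param config path to a YAML file or a named list.
#' @param out_dir output directory (overrides the config key).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (key in c("seed"))
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config is missing required key: out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage, ...) message("[", stage, "] ", ...)
  counts <- list()
  inputs <- character(0)

  set.seed(config$seed)
  thr <- do.call(calling_thresholds, config$thresholds %||% list())
  dcfg <- do.call(dre_config,
                  modifyList(list(seed = config$seed), config$dre %||% list()))
  alpha <- config$alpha %||% 0.05

  # --- stage: inputs ---------------------------------------------------
  if (!is.null(config$simulate)) {
    log_msg("simulate", "generating synthetic dataset")
    sim_cfg <- do.call(simulation_config,
                       modifyList(list(seed = config$seed), config$simulate))
    sim <- generate_dataset(sim_cfg)
    in_dir <- file.path(out_dir, "inputs")
    inputs <- write_dataset(sim$dataset, in_dir, truth = sim$truth,
                            force = TRUE)
    allele <- sim$dataset$allele_counts
    design <- sim$dataset$design
    models <- sim$dataset$models
    cds_seqs <- sim$dataset$cds_seqs
    known <- sim$dataset$known_sites
    gc <- sim$dataset$gene_counts
  } else {
    if (is.null(config$inputs)) stop("config is missing required key: inputs")
    need <- c("allele_counts", "design", "transcript_models",
              "cds_sequences", "known_sites", "gene_counts")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) stop("config inputs missing key(s): ",
                           paste(miss, collapse = ", "))
    log_msg("load", "reading inputs")
    allele <- read_allele_counts(config$inputs$allele_counts)
    design <- read_design(config$inputs$design)
    models <- read_transcript_models(config$inputs$transcript_models)
    cds_seqs <- read_cds_sequences(config$inputs$cds_sequences)
    known <- read_known_sites(config$inputs$known_sites)
    gc <- read_gene_counts(config$inputs$gene_counts)
    inputs <- unlist(config$inputs)
  }
  known$site_id <- paste0(known$chrom, ":", known$pos)
  counts$allele_records <- nrow(allele)

  # --- stage: call -----------------------------------------------------
  calls <- call_variants(allele, thr)
  log_msg("call", nrow(calls), " passing site x sample calls")
  counts$passing_calls <- nrow(calls)
  if (!nrow(calls)) stop("stage call produced no passing variant calls")
  write_variant_calls(calls, file.path(out_dir, "variants.tsv"),
                      file.path(out_dir, "variants.vcf"))

  # --- stage: annotate + A-to-I typing --------------------------------
  events <- events_from_calls(calls, design, counts = allele)
  events <- annotate_events(events, models, cds_seqs)
  n0 <- nrow(events$info)
  ambiguous <- sum(events$info$strand_ambiguous)
  events <- subset_events(events, !events$info$strand_ambiguous &
                            !is.na(events$info$is_a_to_i) &
                            events$info$is_a_to_i)
  log_msg("annotate", nrow(events$info), " A-to-I sites (",
          n0 - nrow(events$info) - ambiguous, " non-A-to-I, ", ambiguous,
          " strand-ambiguous dropped)")
  counts$a_to_i_sites <- nrow(events$info)

  # --- stage: filter ---------------------------------------------------
  events <- retain_high_confidence(events, known)
  log_msg("filter", nrow(events$info), " high-confidence events")
  counts$high_confidence_events <- nrow(events$info)
  if (!nrow(events$info)) stop("stage filter retained no events")
  ev_tab <- cbind(events$info, as.data.frame(events$levels))
  write.table(ev_tab, file.path(out_dir, "annotated_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  act <- summarize_activity(events, design)
  write.table(act$per_sample, file.path(out_dir, "activity_per_sample.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(act$per_group, file.path(out_dir, "activity_per_group.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pres <- group_presence(events, design)
  venn_df <- data.frame(region = names(pres$venn), n = as.integer(pres$venn))
  venn_df <- rbind(venn_df, data.frame(region = "shared_fraction",
                                       n = pres$shared_fraction))
  write.table(venn_df, file.path(out_dir, "group_presence_venn.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: dre -------------------------------------------------------
  dre <- dre_test(events, design, dcfg)
  dre_out <- cbind(events$info[, c("site_id", "chrom", "pos", "strand",
                                   "gene_id", "category", "hgvs_c", "hgvs_p")],
                   dre[, setdiff(names(dre), "site_id")])
  write.table(dre_out, file.path(out_dir, "dre_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manhattan <- data.frame(chrom = events$info$chrom, pos = events$info$pos,
                          neg_log10_p = -log10(pmax(dre$glm_p, 1e-300)))
  write.table(manhattan, file.path(out_dir, "manhattan.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_msg("dre", sum(dre$is_dre, na.rm = TRUE), " differentially edited of ",
          sum(!is.na(dre$glm_p)), " tested")
  counts$dre_events <- sum(dre$is_dre, na.rm = TRUE)

  # --- stage: expression ------------------------------------------------
  tpm_mat <- tpm(gc$counts, gc$lengths)
  tpm_df <- data.frame(gene_id = rownames(tpm_mat), tpm_mat,
                       check.names = FALSE)
  write.table(tpm_df, file.path(out_dir, "tpm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  de <- de_glm(tpm_mat, design)
  write.table(de, file.path(out_dir, "de_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts$de_genes <- sum(de$fdr < dcfg$fdr_threshold, na.rm = TRUE)
  log_msg("expression", counts$de_genes, " differentially expressed genes")

  # --- stage: timecorr --------------------------------------------------
  tc <- time_dependent_sites(events, design, alpha = alpha)
  write.table(tc, file.path(out_dir, "time_correlation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts$time_dependent <- sum(tc$time_dependent, na.rm = TRUE)
  cis <- suppressMessages(
    cis_expression_correlation(events, tpm_mat, design = design))
  write.table(cis, file.path(out_dir, "cis_correlation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  enz <- enzyme_correlation(act, tpm_mat)
  if (!is.null(enz))
    write.table(enz, file.path(out_dir, "enzyme_correlation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  log_msg("timecorr", counts$time_dependent, " time-dependent sites")

  # --- stage: report ----------------------------------------------------
  dre_ids <- dre$site_id[!is.na(dre$is_dre) & dre$is_dre]
  if (length(dre_ids) >= 2) {
    pc <- tryCatch(
      pca_on_dre(events$levels[events$info$site_id %in% dre_ids, ,
                               drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(pc)) {
      sc <- data.frame(sample_id = rownames(pc$scores), pc$scores,
                       check.names = FALSE)
      write.table(sc, file.path(out_dir, "pca_scores.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(data.frame(component = seq_along(pc$var_explained),
                             var_explained = pc$var_explained),
                  file.path(out_dir, "pca_variance.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  cd <- category_distribution(events$info$category)
  write.table(cd, file.path(out_dir, "category_distribution.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cd_dre <- tryCatch(
    category_distribution(events$info$category,
                          restrict = events$info$site_id %in% dre_ids),
    error = function(e) NULL)
  if (!is.null(cd_dre))
    write.table(cd_dre, file.path(out_dir, "category_distribution_dre.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  # --- manifest ---------------------------------------------------------
  outs <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                  file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "editscan",
    version = as.character(utils::packageVersion("editscan")),
    seed = config$seed,
    config = config,
    stage_counts = counts,
    files = setNames(as.list(unname(md5sum(outs))),
                     sub(paste0("^", out_dir, "/?"), "", outs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("report", "manifest written with ", length(outs), " files")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
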