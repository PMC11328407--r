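#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes the tie-corrected Spearman coefficient (Pearson correlation of
#' average ranks) after pairwise removal of missing values, with a
#' two-sided p-value from the t-approximation on n - 2 degrees of freedom.
#' A permutation p-value (fixed seed, add-one smoothing) is available for
#' small n. Constant input in either variable gives an undefined (NA)
#' result with a reason.
#'
#' @param x,y numeric vectors of equal length.
#' @param method "t" (default) or "permutation".
#' @param n_perm,seed permutation settings.
#' @return list with `r`, `p`, `n`, and `reason` (NA unless undefined).
#' @export
spearman_cor <- function(x, y, method = c("t", "permutation"),
                         n_perm = 2000L, seed = 1L) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "fewer than 3 pairs"))
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "constant input"))
  r <- cor(rank(x), rank(y))
  if (method == "t") {
    p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)),
                                        df = n - 2)
  } else {
    robs <- abs(r)
    perm <- local_seed(seed, vapply(seq_len(n_perm), function(i)
      abs(cor(rank(x), rank(sample(y)))), numeric(1)))
    p <- (1 + sum(perm >= robs - 1e-12)) / (n_perm + 1)
  }
  list(r = r, p = p, n = n, reason = NA_character_)
}

#' Time-dependent editing sites
#'
#' Spearman correlation of per-sample editing levels against minutes
#' post-treatment (the untreated control contributes time 0); sites with
#' p < `alpha` are flagged time-dependent. With `use_group_means = TRUE`
#' the correlation is computed on per-group mean levels against group
#' times instead of per-sample values.
#'
#' @param events an `editing_events` object.
#' @param design a [study_design()].
#' @param alpha significance level for the flag (default 0.05).
#' @param use_group_means correlate group means (n = number of groups)
#'   instead of samples.
#' @param method passed to [spearman_cor()].
#' @return data frame: `site_id`, `kind` = "time", `r`, `p`, `n`,
#'   `time_dependent`. Sites observed in fewer than 3 samples yield no row.
#' @export
time_dependent_sites <- function(events, design, alpha = 0.05,
                                 use_group_means = FALSE, method = "t") {
  lev <- events$levels[, design$sample_id, drop = FALSE]
  if (use_group_means) {
    groups <- design_groups(design)
    grp <- factor(design_group_of(design, design$sample_id), levels = groups)
    lev <- t(apply(lev, 1, function(v) tapply(v, grp, mean, na.rm = TRUE)))
    lev[is.nan(lev)] <- NA
    times <- vapply(groups, function(g)
      design$time_min[design$group_label == g][1], numeric(1))
  } else {
    times <- design$time_min
  }
  rows <- lapply(seq_len(nrow(lev)), function(i) {
    s <- spearman_cor(times, lev[i, ], method = method)
    if (s$n < 3L) return(NULL)
    data.frame(site_id = events$info$site_id[i], kind = "time",
               r = s$r, p = s$p, n = s$n,
               time_dependent = !is.na(s$p) & s$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site_id = character(0), kind = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0),
                      time_dependent = logical(0))
  out
}

#' Cis correlation of editing level with edited-gene expression
#'
#' For each site mapped to its host gene, the Spearman correlation between
#' per-sample editing levels and per-sample TPM of that gene. Sites whose
#' gene is absent from the expression matrix are skipped with a message;
#' constant expression gives an undefined record.
#'
#' @param events an `editing_events` object.
#' @param tpm gene x sample TPM matrix.
#' @param gene_map named character vector: site_id -> gene_id (defaults to
#'   the `gene_id` column of annotated events).
#' @param design a [study_design()] giving the sample order.
#' @return data frame: `site_id`, `gene_id`, `kind` = "cis_expression",
#'   `r`, `p`, `n`.
#' @export
cis_expression_correlation <- function(events, tpm, gene_map = NULL,
                                       design = NULL) {
  if (is.null(gene_map)) {
    if (is.null(events$info$gene_id))
      stop("no gene_map given and events are not annotated with gene_id")
    gene_map <- setNames(events$info$gene_id, events$info$site_id)
  }
  samples <- if (is.null(design)) colnames(events$levels) else design$sample_id
  lev <- events$levels[, samples, drop = FALSE]
  rows <- lapply(seq_len(nrow(lev)), function(i) {
    sid <- events$info$site_id[i]
    gid <- unname(gene_map[sid])
    if (is.na(gid) || !gid %in% rownames(tpm)) {
      if (!is.na(gid)) message("gene ", gid, " absent from expression matrix; ",
                               "skipping site ", sid)
      return(NULL)
    }
    s <- spearman_cor(lev[i, ], tpm[gid, samples])
    data.frame(site_id = sid, gene_id = gid, kind = "cis_expression",
               r = s$r, p = s$p, n = s$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site_id = character(0), gene_id = character(0),
                      kind = character(0), r = numeric(0), p = numeric(0),
                      n = integer(0))
  out
}

#' Correlation of overall editing activity with editing-enzyme expression
#'
#' Spearman correlation between the per-sample mean editing level and the
#' per-sample TPM of each editing enzyme gene (ADAR family). Records from
#' fewer than 4 paired samples are flagged `low_n`.
#'
#' @param activity per-sample activity, either the list returned by
#'   [summarize_activity()] or a data frame with `sample_id` and
#'   `mean_level`.
#' @param tpm gene x sample TPM matrix.
#' @param enzyme_genes gene identifiers of the editing enzymes.
#' @return data frame: `gene_id`, `kind` = "enzyme_expression", `r`, `p`,
#'   `n`, `low_n`.
#' @export
enzyme_correlation <- function(activity, tpm,
                               enzyme_genes = c("Adar", "Adarb1")) {
  if (is.list(activity) && !is.data.frame(activity))
    activity <- activity$per_sample
  stopifnot(all(c("sample_id", "mean_level") %in% names(activity)))
  do.call(rbind, lapply(enzyme_genes, function(g) {
    if (!g %in% rownames(tpm)) {
      message("enzyme gene ", g, " absent from expression matrix; skipped")
      return(NULL)
    }
    e <- tpm[g, activity$sample_id]
    s <- spearman_cor(activity$mean_level, e)
    data.frame(gene_id = g, kind = "enzyme_expression", r = s$r, p = s$p,
               n = s$n, low_n = s$n < 4L, stringsAsFactors = FALSE)
  }))
}

#' Top-k correlation records by absolute coefficient
#'
#' Convenience sorting mirroring a "top 25 time-dependent events" listing.
#' @param records a correlation data frame with an `r` column.
#' @param k number of records to keep.
#' @return the k records with largest |r| (defined r only), sorted.
#' @export
top_correlated <- function(records, k = 25L) {
  records <- records[!is.na(records$r), , drop = FALSE]
  records[order(-abs(records$r)), , drop = FALSE][seq_len(min(k, nrow(records))), ,
                                                  drop = FALSE]
}
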