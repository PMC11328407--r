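#' TPM normalization
#'
#' Transcripts per million: per gene, the count is divided by gene length
#' to a rate; per sample, rates are scaled to sum to one million. A sample
#' with zero total counts yields an all-NA column with a warning.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param lengths gene lengths in bases, recycled by gene name when named.
#' @return TPM matrix with the same dimnames.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0),
            all(counts >= 0, na.rm = TRUE))
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom == 0)) {
    warning("sample(s) with zero total counts: ",
            paste(colnames(counts)[denom == 0], collapse = ", "),
            "; TPM set to NA")
    denom[denom == 0] <- NA
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Read a gene-count TSV with gene lengths
#'
#' Columns: `gene_id`, `length`, then one column per sample.
#' @param path path to the TSV.
#' @return list with `counts` (matrix) and `lengths` (named vector).
#' @export
read_gene_counts <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "length") %in% names(d)))
    stop("gene-count file missing columns: gene_id, length")
  counts <- as.matrix(d[, setdiff(names(d), c("gene_id", "length")),
                        drop = FALSE])
  rownames(counts) <- d$gene_id
  list(counts = counts, lengths = setNames(d$length, d$gene_id))
}

#' Group-wise differential expression on log TPM
#'
#' One-way comparison of log2(TPM + 1) across groups per gene; the F test
#' of the group model against the intercept-only model (the Gaussian
#' likelihood-ratio test in its exact small-sample form) gives the
#' p-value, BH-adjusted across genes. A gene constant across all samples
#' gets p = 1.
#'
#' @param tpm_mat gene x sample TPM matrix.
#' @param design a [study_design()].
#' @return data frame: `gene_id`, `p`, `fdr`, per-group mean log2(TPM+1)
#'   columns.
#' @export
de_glm <- function(tpm_mat, design) {
  samples <- design$sample_id
  stopifnot(all(samples %in% colnames(tpm_mat)))
  groups <- design_groups(design)
  grp <- factor(design_group_of(design, samples), levels = groups)
  if (nlevels(grp) < 2L || any(table(grp) < 2L))
    stop("de_glm needs >= 2 groups with >= 2 samples each")
  y <- log2(tpm_mat[, samples, drop = FALSE] + 1)
  p <- apply(y, 1, function(v) {
    if (anyNA(v) || max(v) - min(v) < 1e-12) return(1)
    anova(lm(v ~ grp))[["Pr(>F)"]][1]
  })
  gm <- t(apply(y, 1, function(v) tapply(v, grp, mean)))
  colnames(gm) <- paste0("mean_log2_", groups)
  data.frame(gene_id = rownames(y), p = unname(p), fdr = bh_adjust(unname(p)),
             gm, row.names = NULL, stringsAsFactors = FALSE)
}
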