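#' PCA of a site x sample editing-level matrix
#'
#' Missing levels are imputed by the site mean, sites are centered, and
#' the singular-value decomposition yields sample scores and the fraction
#' of variance explained by each component.
#'
#' @param levels site x sample numeric matrix (e.g. the `levels` of DRE
#'   events).
#' @return list with `scores` (samples x components), `var_explained`
#'   (fractions summing to 1), and `sdev`.
#' @export
pca_on_dre <- function(levels) {
  x <- as.matrix(levels)
  if (ncol(x) < 3L) stop("PCA needs at least 3 samples")
  all_na <- rowSums(!is.na(x)) == 0
  x <- x[!all_na, , drop = FALSE]
  for (i in seq_len(nrow(x))) {
    na <- is.na(x[i, ])
    if (any(na)) x[i, na] <- mean(x[i, !na])
  }
  keep <- apply(x, 1, function(v) max(v) - min(v) > 0)
  if (sum(keep) < 2L)
    stop("PCA needs at least 2 non-constant sites after imputation")
  x <- x[keep, , drop = FALSE]
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, var_explained = ve, sdev = pc$sdev)
}

#' Venn region counts over named sets
#'
#' Counts every non-empty-membership region of the Venn diagram over k
#' sets, keyed by the set names joined with `&` (e.g. `"A&C"` for elements
#' in A and C but no other set). Region counts sum to the union size.
#'
#' @param x either a named list of vectors (sets of identifiers) or a
#'   logical membership matrix (elements x sets).
#' @return named integer vector over all 2^k - 1 regions.
#' @export
venn_regions <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    ids <- unique(unlist(x))
    memb <- sapply(x, function(s) ids %in% s)
    memb <- matrix(memb, nrow = length(ids),
                   dimnames = list(ids, names(x)))
  } else {
    memb <- as.matrix(x)
    stopifnot(is.logical(memb))
  }
  k <- ncol(memb)
  sets <- colnames(memb)
  if (is.null(sets)) sets <- LETTERS[seq_len(k)]
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  keys <- apply(combos, 1, function(m) paste(sets[unlist(m)], collapse = "&"))
  counts <- apply(combos, 1, function(m)
    sum(apply(memb, 1, function(row) all(row == unlist(m)))))
  setNames(as.integer(counts), keys)
}

#' Venn region counts of differentially edited genes across tissues
#'
#' @param gene_sets named list of gene-identifier vectors, one per tissue
#'   or cell type (at least two).
#' @return named region counts, see [venn_regions()].
#' @export
cross_tissue_intersection <- function(gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 2,
            !is.null(names(gene_sets)))
  venn_regions(gene_sets)
}

#' Functional-category distribution of editing events
#'
#' Proportion of events per functional category, optionally restricted to
#' a subset (e.g. the DRE events).
#'
#' @param categories character vector of category labels (NA dropped).
#' @param restrict optional logical vector selecting a subset.
#' @return data frame with `category`, `n`, `proportion` (summing to 1).
#' @export
category_distribution <- function(categories, restrict = NULL) {
  if (!is.null(restrict)) categories <- categories[restrict]
  categories <- categories[!is.na(categories)]
  if (!length(categories)) stop("no categorized events")
  tab <- sort(table(categories), decreasing = TRUE)
  data.frame(category = names(tab), n = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
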