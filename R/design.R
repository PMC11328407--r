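#' Study design: sample-to-group-to-time mapping
#'
#' Encodes the time-course layout of one tissue or cell type: each sample
#' belongs to exactly one treatment group, and each group has a time
#' coordinate in minutes post-treatment (the untreated/PBS control sits at
#' time 0).
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group_label character vector, same length, group of each sample.
#' @param time_min numeric vector, same length, minutes post-treatment of
#'   each sample's group (identical within a group).
#' @param tissue single string naming the tissue or cell type.
#' @return A `study_design` data frame with columns `sample_id`, `tissue`,
#'   `group_label`, `time_min`, ordered by time then sample.
#' @examples
#' study_design(paste0("s", 1:12), rep(c("PBS", "15min", "30min", "4h"), each = 3),
#'              rep(c(0, 15, 30, 240), each = 3))
#' @export
study_design <- function(sample_id, group_label, time_min, tissue = "tissue") {
  stopifnot(length(sample_id) == length(group_label),
            length(sample_id) == length(time_min))
  if (anyDuplicated(sample_id))
    stop("duplicated sample_id in study design")
  d <- data.frame(sample_id = as.character(sample_id),
                  tissue = as.character(tissue),
                  group_label = as.character(group_label),
                  time_min = as.numeric(time_min),
                  stringsAsFactors = FALSE)
  tpg <- tapply(d$time_min, d$group_label, function(x) length(unique(x)))
  if (any(tpg != 1L))
    stop("each group must map to a single time_min")
  npg <- table(d$group_label)
  if (any(npg < 2L))
    stop("each group needs at least 2 samples: ",
         paste(names(npg)[npg < 2], collapse = ", "))
  d <- d[order(d$time_min, d$sample_id), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("study_design", "data.frame")
  d
}

#' Ordered group labels of a design
#'
#' Groups sorted by their time coordinate (control first).
#' @param design a `study_design`.
#' @return character vector of group labels.
#' @export
design_groups <- function(design) {
  u <- unique(design[, c("group_label", "time_min")])
  u$group_label[order(u$time_min)]
}

#' Read a study design TSV
#'
#' Expects columns `sample_id`, `tissue`, `group_label`, `time_min`.
#' @param path path to the TSV file.
#' @return a `study_design`.
#' @export
read_design <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "group_label", "time_min")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design file missing columns: ", paste(miss, collapse = ", "))
  study_design(d$sample_id, d$group_label, d$time_min, tissue = d$tissue)
}

# times of each sample, in design order of `samples`
design_times <- function(design, samples) {
  design$time_min[match(samples, design$sample_id)]
}

# group of each sample
design_group_of <- function(design, samples) {
  design$group_label[match(samples, design$sample_id)]
}
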