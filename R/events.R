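#' Editing-event container
#'
#' An `editing_events` object bundles, for a set of strand-resolved A-to-I
#' sites, the per-sample editing levels and the underlying reference /
#' alternative read counts across the whole design. Missing entries (NA)
#' mean the site had no passing call in that sample.
#'
#' @param info data frame with one row per site: `site_id`, `chrom`, `pos`,
#'   `strand` (may be NA before annotation), `ref`, `alt`, and optionally
#'   `is_known`.
#' @param levels,ref_counts,alt_counts numeric matrices, sites x samples,
#'   with rownames `site_id` and identical dimnames. Levels quantify every
#'   covered sample, whether or not the site was detected there.
#' @param detected logical matrix of the same shape: TRUE where the sample
#'   had a passing per-sample variant call. Defaults to coverage
#'   (`!is.na(levels)`).
#' @return an `editing_events` object.
#' @export
editing_events <- function(info, levels, ref_counts, alt_counts,
                           detected = NULL) {
  stopifnot(is.data.frame(info), is.matrix(levels),
            nrow(info) == nrow(levels),
            identical(dim(levels), dim(ref_counts)),
            identical(dim(levels), dim(alt_counts)))
  if (is.null(rownames(levels))) rownames(levels) <- info$site_id
  stopifnot(identical(rownames(levels), info$site_id))
  bad <- levels[!is.na(levels)]
  stopifnot(all(bad >= 0 & bad <= 1))
  if (is.null(detected)) detected <- !is.na(levels)
  stopifnot(identical(dim(detected), dim(levels)), is.logical(detected))
  if (is.null(info$is_known)) info$is_known <- FALSE
  structure(list(info = info, levels = levels,
                 ref_counts = ref_counts, alt_counts = alt_counts,
                 detected = detected),
            class = "editing_events")
}

#' @export
print.editing_events <- function(x, ...) {
  cat("editing_events:", nrow(x$info), "sites x", ncol(x$levels), "samples\n")
  cat("  known sites:", sum(x$info$is_known), "\n")
  invisible(x)
}

#' @export
dim.editing_events <- function(x) dim(x$levels)

# subset sites by logical/integer index
subset_events <- function(events, idx) {
  editing_events(events$info[idx, , drop = FALSE],
                 events$levels[idx, , drop = FALSE],
                 events$ref_counts[idx, , drop = FALSE],
                 events$alt_counts[idx, , drop = FALSE],
                 events$detected[idx, , drop = FALSE])
}

#' Assemble editing events from per-sample variant calls
#'
#' Pivots a long table of passing variant calls into site x sample matrices
#' of editing levels and allele counts. All calls for one site must agree on
#' ref/alt (multi-allelic resolution happens upstream, in the caller).
#'
#' Detection and quantification are kept separate: a site enters the event
#' set through its passing calls, but when the full allele-count table is
#' supplied via `counts`, the level and count matrices quantify *every*
#' covered sample at those sites, including samples where the per-sample
#' call failed the screening thresholds. Without this, downstream group
#' comparisons would see counts truncated at the calling thresholds
#' (e.g. alternative depth >= 2), a selection bias that inflates apparent
#' group differences at weakly edited sites.
#'
#' @param calls passing calls from [call_variants()].
#' @param design a [study_design()]; its samples define the columns.
#' @param counts optional full allele-count table (all records, passing or
#'   not) used to quantify all covered samples at the called sites.
#' @param strand optional named vector (by `site_id`) of site strands.
#' @return an `editing_events` object.
#' @export
events_from_calls <- function(calls, design, counts = NULL, strand = NULL) {
  if (!nrow(calls)) stop("no passing calls to assemble")
  calls$site_id <- paste0(calls$chrom, ":", calls$pos)
  key <- unique(calls[, c("site_id", "chrom", "pos", "ref", "alt")])
  if (anyDuplicated(key$site_id))
    stop("conflicting ref/alt for one site across samples")
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  samples <- design$sample_id
  mk <- function(what = NA_real_) matrix(what, nrow(key), length(samples),
                                         dimnames = list(key$site_id, samples))
  lev <- mk(); rc <- mk(); ac <- mk(); det <- mk(FALSE)
  fill <- function(d) {
    ri <- match(paste0(d$chrom, ":", d$pos), key$site_id)
    ci <- match(d$sample_id, samples)
    keep <- !is.na(ri) & !is.na(ci) & (d$ref_count + d$alt_count) > 0
    idx <- cbind(ri[keep], ci[keep])
    lev[idx] <<- editing_level(d$ref_count[keep], d$alt_count[keep])
    rc[idx] <<- d$ref_count[keep]
    ac[idx] <<- d$alt_count[keep]
    idx
  }
  if (!is.null(counts)) fill(counts)
  det_idx <- fill(calls)
  det[det_idx] <- TRUE
  info <- data.frame(site_id = key$site_id, chrom = key$chrom, pos = key$pos,
                     strand = if (is.null(strand)) NA_character_
                              else unname(strand[key$site_id]),
                     ref = key$ref, alt = key$alt, is_known = FALSE,
                     stringsAsFactors = FALSE)
  editing_events(info, lev, rc, ac, det)
}

#' Retain high-confidence editing events
#'
#' An event is retained if its editing level reaches `min_level` in at
#' least `min_samples` samples, or if the site is annotated as a known RNA
#' editing variant (REDIportal-style list). The known-site rescue waives
#' only this retention rule: a rescued site still needs at least one
#' passing per-sample call to be present in `events` at all.
#'
#' @param events an `editing_events` object.
#' @param known_sites data frame with `chrom` and `pos` (or a `site_id`
#'   column), e.g. from [read_known_sites()]; NULL for no rescue.
#' @param min_level retention level threshold (default 0.01).
#' @param min_samples number of samples required at `min_level` (default 2).
#' @return the retained `editing_events`, with `is_known` filled in.
#' @export
retain_high_confidence <- function(events, known_sites = NULL,
                                   min_level = 0.01, min_samples = 2L) {
  lev <- events$levels
  n_ok <- rowSums(events$detected & !is.na(lev) & lev >= min_level,
                  na.rm = TRUE)
  known_ids <- character(0)
  if (!is.null(known_sites)) {
    known_ids <- if (!is.null(known_sites$site_id)) known_sites$site_id
                 else paste0(known_sites$chrom, ":", known_sites$pos)
  }
  is_known <- events$info$site_id %in% known_ids
  keep <- n_ok >= min_samples | is_known
  out <- subset_events(events, keep)
  out$info$is_known <- is_known[keep]
  out
}

#' Per-sample and per-group editing activity summaries
#'
#' The per-sample mean editing level averages over the sites called in that
#' sample (no zero-imputation of undetected sites). The per-group mean is
#' the mean of its sample means (`mean_level`); a pooled alternative that
#' averages all site x sample values of the group is also reported
#' (`mean_level_pooled`). The per-group event count is the number of sites
#' with a passing call in at least one sample of the group.
#'
#' @param events an `editing_events` object.
#' @param design a [study_design()].
#' @return list with `per_sample` and `per_group` data frames.
#' @export
summarize_activity <- function(events, design) {
  if (!nrow(events$info)) stop("no events to summarize")
  lev <- events$levels[, design$sample_id, drop = FALSE]
  lev[!events$detected[, design$sample_id, drop = FALSE]] <- NA  # called sites only
  per_sample <- data.frame(
    sample_id = design$sample_id,
    group_label = design$group_label,
    time_min = design$time_min,
    n_sites = colSums(!is.na(lev)),
    mean_level = colMeans(lev, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  per_sample$mean_level[per_sample$n_sites == 0] <- NA_real_
  groups <- design_groups(design)
  per_group <- do.call(rbind, lapply(groups, function(g) {
    sm <- design$sample_id[design$group_label == g]
    gl <- lev[, sm, drop = FALSE]
    ml <- per_sample$mean_level[match(sm, per_sample$sample_id)]
    if (all(is.na(gl)))
      warning("group ", g, " has no called levels; summary is NA")
    data.frame(group_label = g,
               time_min = design$time_min[design$group_label == g][1],
               mean_level = if (all(is.na(ml))) NA_real_ else mean(ml, na.rm = TRUE),
               mean_level_pooled = if (all(is.na(gl))) NA_real_
                                   else mean(gl, na.rm = TRUE),
               n_events = sum(rowSums(!is.na(gl)) > 0),
               stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, per_group = per_group)
}

#' Presence of events across groups and the shared fraction
#'
#' An event is present in a group if it has a passing call in at least one
#' sample of that group. Returns the site x group presence matrix, the
#' fraction of events present in every group, and the full Venn region
#' counts over groups.
#'
#' @param events an `editing_events` object.
#' @param design a [study_design()].
#' @return list with `presence` (logical matrix), `shared_fraction`, and
#'   `venn` (named region counts, see [venn_regions()]).
#' @export
group_presence <- function(events, design) {
  if (!nrow(events$info)) stop("no events")
  groups <- design_groups(design)
  pres <- sapply(groups, function(g) {
    sm <- design$sample_id[design$group_label == g]
    rowSums(events$detected[, sm, drop = FALSE]) > 0
  })
  pres <- matrix(pres, nrow = nrow(events$info),
                 dimnames = list(events$info$site_id, groups))
  list(presence = pres,
       shared_fraction = mean(rowSums(pres) == length(groups)),
       venn = venn_regions(pres))
}
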