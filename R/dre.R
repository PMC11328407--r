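#' Differential RNA editing configuration
#'
#' Thresholds and modes for the dual DRE criterion: a site is differentially
#' edited iff its GLM likelihood-ratio p-value is below `glm_p_threshold`
#' AND its GLM FDR or its Fisher FDR is below `fdr_threshold`.
#'
#' @param glm_p_threshold gate (1) on the raw GLM p (default 0.05).
#' @param fdr_threshold gate (2) on the BH-adjusted p-values (default 0.05).
#' @param missense_diff_threshold minimum max-min spread of group mean
#'   editing levels for the missense highlight flag (default 0.05, i.e. 5
#'   percentage points).
#' @param family "binomial" (default) or "quasibinomial" for the GLM.
#' @param empirical_p_mode "lrt" (chi-square likelihood-ratio p, default)
#'   or "permutation" (group labels shuffled `n_perm` times; empirical
#'   tail proportion with add-one smoothing).
#' @param n_perm,seed permutation count and RNG seed for permutation mode
#'   and for the Monte-Carlo Fisher fallback.
#' @param fisher_budget maximum number of margin-fixed tables enumerated
#'   exactly before falling back to Monte-Carlo.
#' @param fisher_mc number of Monte-Carlo tables in the fallback.
#' @return a `dre_config` list.
#' @export
dre_config <- function(glm_p_threshold = 0.05, fdr_threshold = 0.05,
                       missense_diff_threshold = 0.05,
                       family = c("binomial", "quasibinomial"),
                       empirical_p_mode = c("lrt", "permutation"),
                       n_perm = 1000L, seed = 1L,
                       fisher_budget = 2e5, fisher_mc = 10000L) {
  stopifnot(glm_p_threshold > 0, glm_p_threshold < 1,
            fdr_threshold > 0, fdr_threshold < 1,
            missense_diff_threshold > 0, missense_diff_threshold < 1)
  structure(list(glm_p_threshold = glm_p_threshold,
                 fdr_threshold = fdr_threshold,
                 missense_diff_threshold = missense_diff_threshold,
                 family = match.arg(family),
                 empirical_p_mode = match.arg(empirical_p_mode),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 fisher_budget = fisher_budget,
                 fisher_mc = as.integer(fisher_mc)),
            class = "dre_config")
}

#' Binomial GLM likelihood-ratio test for group differences in editing
#'
#' Fits edited-vs-unedited per-sample counts against the group factor with
#' a logit-link binomial GLM and compares it to the intercept-only null by
#' the deviance difference (chi-square with k-1 df). Counts, not level
#' proportions, enter the fit, so sequencing depth weights the evidence.
#' When any group is degenerate (all its samples fully unedited or fully
#' edited) 0.5 is added to every ref and alt cell of the site
#' (Haldane-Anscombe style) to avoid complete separation; the result is
#' flagged. In permutation mode the LRT statistic is recomputed under
#' `n_perm` group-label shuffles and the p-value is the add-one-smoothed
#' tail proportion.
#'
#' @param alt,ref per-sample edited / unedited read counts.
#' @param group group label per sample (factor or character).
#' @param config a [dre_config()].
#' @return list with `p`, `stat`, `df`, `separation_adjusted`, `method`.
#' @export
glm_lrt_test <- function(alt, ref, group, config = dre_config()) {
  keep <- !is.na(alt) & !is.na(ref) & (alt + ref) > 0
  alt <- alt[keep]; ref <- ref[keep]; group <- factor(as.character(group[keep]))
  tab <- table(group)
  if (length(tab) < 2L || any(tab < 2L))
    return(list(p = NA_real_, stat = NA_real_, df = NA_integer_,
                separation_adjusted = FALSE, method = config$empirical_p_mode))
  degen <- tapply(seq_along(alt), group, function(ix)
    all(alt[ix] == 0) || all(ref[ix] == 0))
  adjusted <- any(degen)
  if (adjusted) { alt <- alt + 0.5; ref <- ref + 0.5 }
  stat_fun <- function(g) {
    fit1 <- suppressWarnings(glm(cbind(alt, ref) ~ g, family = config$family))
    fit0 <- suppressWarnings(glm(cbind(alt, ref) ~ 1, family = config$family))
    max(0, fit0$deviance - fit1$deviance)
  }
  stat <- stat_fun(group)
  df <- nlevels(group) - 1L
  if (config$empirical_p_mode == "lrt") {
    p <- pchisq(stat, df = df, lower.tail = FALSE)
  } else {
    perm <- local_seed(config$seed, {
      vapply(seq_len(config$n_perm),
             function(i) stat_fun(sample(group)), numeric(1))
    })
    p <- (1 + sum(perm >= stat - 1e-12)) / (config$n_perm + 1)
  }
  list(p = p, stat = stat, df = df, separation_adjusted = adjusted,
       method = config$empirical_p_mode)
}

# run expr under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Exact R x 2 Fisher test on pooled allele counts
#'
#' Two-sided exact test of independence for an R x 2 table (rows = groups,
#' columns = pooled alternative / reference allele counts) with all margins
#' fixed: the p-value is the total null probability of every margin-fixed
#' table whose point (multivariate hypergeometric) probability does not
#' exceed that of the observed table, within a relative tolerance of 1e-7.
#' Tables are enumerated by descent over per-row first-column allocations;
#' when the enumeration bound exceeds `budget`, a Monte-Carlo estimate over
#' `n_mc` tables drawn from the null (via [stats::r2dtable()]) is returned
#' instead, with add-one smoothing and a fixed seed, and the result is
#' flagged accordingly.
#'
#' @param tab matrix with R rows and 2 columns of non-negative counts.
#' @param budget enumeration budget (number of candidate tables).
#' @param n_mc Monte-Carlo sample size for the fallback.
#' @param seed RNG seed for the fallback.
#' @return p-value with attributes `method` ("enumeration" or
#'   "monte-carlo") and, for enumeration, `prob_total` (the summed point
#'   probabilities over all enumerated tables, equal to 1 up to rounding).
#' @export
fisher_rx2_test <- function(tab, budget = 2e5, n_mc = 10000L, seed = 1L) {
  tab <- as.matrix(tab)
  stopifnot(ncol(tab) == 2L, all(tab >= 0))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L)
    return(structure(NA_real_, method = "degenerate"))
  if (any(colSums(tab) == 0)) {
    warning("degenerate table: one allele column is empty; p = 1")
    return(structure(1, method = "degenerate"))
  }
  rs <- rowSums(tab)
  A <- sum(tab[, 1])
  N <- sum(rs)
  lp_obs <- sum(lchoose(rs, tab[, 1])) - lchoose(N, A)
  bound <- prod(pmin(rs[-length(rs)], A) + 1)
  if (bound <= budget) {
    grid <- as.matrix(expand.grid(lapply(rs[-length(rs)],
                                         function(r) 0:min(r, A))))
    last <- A - rowSums(grid)
    ok <- last >= 0 & last <= rs[length(rs)]
    grid <- cbind(grid[ok, , drop = FALSE], last[ok])
    lp <- rowSums(lchoose(matrix(rs, nrow(grid), length(rs), byrow = TRUE),
                          grid)) - lchoose(N, A)
    p <- sum(exp(lp)[lp <= lp_obs + 1e-7 * abs(lp_obs) + 1e-12])
    structure(min(1, p), method = "enumeration", prob_total = sum(exp(lp)))
  } else {
    sim <- local_seed(seed, r2dtable(n_mc, rs, c(A, N - A)))
    lps <- vapply(sim, function(m) sum(lchoose(rs, m[, 1])) - lchoose(N, A),
                  numeric(1))
    p <- (1 + sum(lps <= lp_obs + 1e-7 * abs(lp_obs) + 1e-12)) / (n_mc + 1)
    structure(p, method = "monte-carlo")
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1; input
#' order is preserved and NAs pass through untouched (they do not count
#' toward the family size).
#'
#' @param p numeric vector of p-values in \[0, 1\], NAs allowed.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Tukey HSD post-hoc comparisons of group editing levels
#'
#' One-way ANOVA on the per-sample editing levels feeds the studentized
#' range statistic for every group pair. When the within-group variance is
#' exactly zero everywhere, the limiting convention is applied: p = 0 for
#' pairs with unequal means, p = 1 for equal means, flagged in the result.
#'
#' @param levels per-sample editing levels.
#' @param group group label per sample.
#' @return data frame with `pair`, `diff`, `p`, and attribute
#'   `zero_variance` when the limit convention was used.
#' @export
tukey_hsd <- function(levels, group) {
  keep <- !is.na(levels)
  levels <- levels[keep]
  group <- if (is.factor(group)) droplevels(group[keep])
           else factor(as.character(group[keep]))
  tab <- table(group)
  if (nlevels(group) < 2L || any(tab < 2L))
    stop("tukey_hsd needs >= 2 groups with >= 2 non-missing samples each")
  gm <- tapply(levels, group, mean)
  wss <- sum(tapply(levels, group, function(x) sum((x - mean(x))^2)))
  pairs <- utils::combn(levels(group), 2)
  pair_names <- paste(pairs[2, ], pairs[1, ], sep = "-")
  diffs <- gm[pairs[2, ]] - gm[pairs[1, ]]
  if (wss <= 0) {
    p <- ifelse(abs(diffs) > 0, 0, 1)
    out <- data.frame(pair = pair_names, diff = as.numeric(diffs), p = p,
                      stringsAsFactors = FALSE)
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  fit <- aov(levels ~ group)
  tk <- TukeyHSD(fit)$group
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    p = tk[, "p adj"], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "zero_variance") <- FALSE
  out
}

#' The dual DRE decision rule
#'
#' A site is differentially edited iff (1) its GLM p-value is below the
#' `glm_p_threshold` and (2) its GLM FDR or its Fisher FDR is below the
#' `fdr_threshold`. A missing Fisher FDR (the Fisher test is only run for
#' sites passing gate 1) never satisfies gate 2 on its own.
#'
#' @param glm_p,glm_fdr,fisher_fdr numeric vectors.
#' @param config a [dre_config()].
#' @return logical vector.
#' @export
decide_dre <- function(glm_p, glm_fdr, fisher_fdr, config = dre_config()) {
  gate1 <- !is.na(glm_p) & glm_p < config$glm_p_threshold
  g_ok <- !is.na(glm_fdr) & glm_fdr < config$fdr_threshold
  f_ok <- !is.na(fisher_fdr) & fisher_fdr < config$fdr_threshold
  gate1 & (g_ok | f_ok)
}

#' Flag missense DRE events with a large intergroup spread
#'
#' TRUE for differentially edited missense events whose group mean editing
#' levels span more than `missense_diff_threshold` (default 5 percentage
#' points) between the extreme groups.
#'
#' @param is_dre logical DRE decision.
#' @param category functional category per site.
#' @param max_intergroup_diff max - min of group mean editing levels
#'   (proportion scale).
#' @param config a [dre_config()].
#' @return logical vector.
#' @export
flag_missense_diff <- function(is_dre, category, max_intergroup_diff,
                               config = dre_config()) {
  !is.na(is_dre) & is_dre &
    !is.na(category) & category == "missense" &
    !is.na(max_intergroup_diff) &
    max_intergroup_diff > config$missense_diff_threshold
}

#' Differential RNA editing across time-point groups
#'
#' Runs, per site: the binomial GLM likelihood-ratio test on per-sample
#' allele counts; BH adjustment of the GLM p-values across all tested
#' sites; for sites passing the GLM p gate, the exact R x 2 Fisher test on
#' counts pooled within groups, BH-adjusted over the family of all tested
#' sites (unselected sites enter the family as p = 1, so selection on the
#' correlated GLM gate cannot break FDR control); group mean
#' editing levels and their max - min spread; optionally Tukey HSD
#' pairwise p-values; and the dual DRE decision. If `events` carries
#' category annotation, missense events with > 5 percentage-point spread
#' are flagged.
#'
#' @param events an `editing_events` object (annotated or not).
#' @param design a [study_design()].
#' @param config a [dre_config()].
#' @param tukey compute Tukey HSD pairwise columns (default TRUE).
#' @return data frame (`dre_result`), one row per site: `site_id`,
#'   `glm_p`, `glm_fdr`, `fisher_p`, `fisher_fdr`, `is_dre`, per-group mean
#'   level columns (`mean_<group>`), `max_intergroup_diff`, Tukey columns
#'   (`tukey_<pair>`), `separation_adjusted`, and `missense_flag` when
#'   categories are available.
#' @export
dre_test <- function(events, design, config = dre_config(), tukey = TRUE) {
  info <- events$info
  samples <- design$sample_id
  groups <- design_groups(design)
  grp <- factor(design_group_of(design, samples), levels = groups)
  alt <- events$alt_counts[, samples, drop = FALSE]
  ref <- events$ref_counts[, samples, drop = FALSE]
  lev <- events$levels[, samples, drop = FALSE]
  n <- nrow(info)

  glm_p <- rep(NA_real_, n); sep_adj <- rep(FALSE, n)
  for (i in seq_len(n)) {
    r <- glm_lrt_test(alt[i, ], ref[i, ], grp, config)
    glm_p[i] <- r$p; sep_adj[i] <- r$separation_adjusted
  }
  glm_fdr <- bh_adjust(glm_p)

  fisher_p <- rep(NA_real_, n)
  todo <- which(!is.na(glm_p) & glm_p < config$glm_p_threshold)
  for (i in todo) {
    pooled <- cbind(alt = tapply(alt[i, ], grp, sum, na.rm = TRUE),
                    ref = tapply(ref[i, ], grp, sum, na.rm = TRUE))
    pooled[is.na(pooled)] <- 0
    fisher_p[i] <- suppressWarnings(
      as.numeric(fisher_rx2_test(pooled, budget = config$fisher_budget,
                                 n_mc = config$fisher_mc,
                                 seed = config$seed)))
  }
  # BH family for the Fisher p-values is all tested sites: sites not
  # reaching the GLM gate enter as p = 1 (they were not tested further and
  # can never be significant). Adjusting within the selected subset alone
  # would be anticonservative: selection on the correlated GLM test leaves
  # the subset's null Fisher p-values far from uniform, and gate 2 would
  # then no longer control the false-discovery rate.
  pvec <- fisher_p
  pvec[is.na(pvec) & !is.na(glm_p)] <- 1
  fisher_fdr <- bh_adjust(pvec)
  fisher_fdr[is.na(fisher_p)] <- NA_real_

  gm <- t(apply(lev, 1, function(x) tapply(x, grp, mean, na.rm = TRUE)))
  gm[is.nan(gm)] <- NA
  colnames(gm) <- paste0("mean_", groups)
  max_diff <- apply(gm, 1, function(x)
    if (all(is.na(x))) NA_real_ else diff(range(x, na.rm = TRUE)))

  res <- data.frame(site_id = info$site_id, glm_p = glm_p, glm_fdr = glm_fdr,
                    fisher_p = fisher_p, fisher_fdr = fisher_fdr,
                    is_dre = decide_dre(glm_p, glm_fdr, fisher_fdr, config),
                    stringsAsFactors = FALSE)
  res <- cbind(res, gm, max_intergroup_diff = max_diff,
               separation_adjusted = sep_adj)

  if (tukey) {
    pair_labels <- apply(utils::combn(groups, 2), 2,
                         function(x) paste(x[2], x[1], sep = "-"))
    tkm <- matrix(NA_real_, n, length(pair_labels),
                  dimnames = list(NULL, paste0("tukey_", pair_labels)))
    for (i in seq_len(n)) {
      li <- lev[i, ]
      keep <- !is.na(li)
      tb <- table(factor(grp[keep], levels = groups))
      ok_groups <- names(tb)[tb >= 2]        # pairs need >= 2 samples a side
      if (length(ok_groups) < 2) next
      keep <- keep & grp %in% ok_groups
      tk <- suppressWarnings(tukey_hsd(li[keep], grp[keep, drop = TRUE]))
      tkm[i, paste0("tukey_", tk$pair)] <- tk$p
    }
    res <- cbind(res, tkm)
  }
  if (!is.null(info$category))
    res$missense_flag <- flag_missense_diff(res$is_dre, info$category,
                                            res$max_intergroup_diff, config)
  class(res) <- c("dre_result", "data.frame")
  res
}
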