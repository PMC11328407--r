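# Shared fixtures, all built in code.

# A 3-sample, 4-site hand-designed pileup (one vector of lines per sample)
# with per-line expected counts worked out by hand, character by character.
# Quality characters: 'I' = Phred 40 (passes the >= 25 threshold),
# '5' = Phred 20 (fails).
pileup_fixture <- function() {
  lines <- list(
    s1 = c(
      # 12 ref + 5 G pass, 1 g below quality; '^]' and '$' consume no quality
      paste0("chr1\t100\tA\t18\t^]............GGGGGg$\t",
             strrep("I", 17), "5"),
      # 30 ref + 2 G pass; one read carries a 2-base insertion (no quality)
      paste0("chr1\t200\tA\t32\t..............+2AC................GG\t",
             strrep("I", 32)),
      # 20 ref + 1 G pass: alt depth 1 fails the alt >= 2 threshold
      paste0("chr1\t300\tA\t21\t....................G\t", strrep("I", 21)),
      # depth 8 < 10 fails the depth threshold
      paste0("chr1\t400\tC\t8\t......TT\t", strrep("I", 8))),
    s2 = c(
      # 10 ref + 3 G pass + 1 deletion placeholder (other)
      paste0("chr1\t100\tA\t14\t..........GGG*\t", strrep("I", 14)),
      # 25 ref + 1 G: alt depth 1 fails
      paste0("chr1\t200\tA\t26\t", strrep(".", 25), "G\t", strrep("I", 26)),
      # 9 ref pass, 2 g below quality: counted depth 9 < 10 fails
      paste0("chr1\t300\tA\t11\t.........gg\t", strrep("I", 9), "55"),
      # 11 ref + 1 T: alt depth 1 fails
      paste0("chr1\t400\tC\t12\t...........T\t", strrep("I", 12))),
    s3 = c(
      # 18 ref + 2 G pass; '$' mid-string consumes no quality
      paste0("chr1\t100\tA\t20\t........$..........GG\t", strrep("I", 20)),
      # all reference: no alternative allele at all
      paste0("chr1\t200\tA\t15\t", strrep(".", 15), "\t", strrep("I", 15)),
      # 12 ref + 4 G pass
      paste0("chr1\t300\tA\t16\t............GGGG\t", strrep("I", 16)),
      # 5 ref pass, 3 low-quality ','; '-1A' deletion run consumes no quality
      paste0("chr1\t400\tC\t8\t.....-1A,,,\t", "IIIII555")))
  expected <- data.frame(
    sample_id = rep(c("s1", "s2", "s3"), each = 4),
    pos = rep(c(100L, 200L, 300L, 400L), 3),
    ref = rep(c("A", "A", "A", "C"), 3),
    alt = c("G", "G", "G", "T",  "G", "G", NA, "T",  "G", NA, "G", NA),
    ref_count = c(12L, 30L, 20L, 6L,  10L, 25L, 9L, 11L,  18L, 15L, 12L, 5L),
    alt_count = c(5L, 2L, 1L, 2L,  3L, 1L, 0L, 1L,  2L, 0L, 4L, 0L),
    other_count = c(0L, 0L, 0L, 0L,  1L, 0L, 0L, 0L,  0L, 0L, 0L, 0L),
    n_below_quality = c(1L, 0L, 0L, 0L,  0L, 0L, 2L, 0L,  0L, 0L, 0L, 3L),
    stringsAsFactors = FALSE)
  # the five site x sample calls that pass all screening thresholds
  passing <- data.frame(
    sample_id = c("s1", "s1", "s2", "s3", "s3"),
    pos = c(100L, 200L, 100L, 100L, 300L), stringsAsFactors = FALSE)
  list(lines = lines, expected = expected, passing = passing,
       known = data.frame(chrom = "chr1", pos = 200L, ref = "A",
                          alt = "A-to-I", strand = "+",
                          stringsAsFactors = FALSE),
       design = study_design(c("s1", "s2", "s3"), rep("PBS", 3), rep(0, 3)))
}

parse_pileup_fixture <- function(fx = pileup_fixture(),
                                 thresholds = calling_thresholds()) {
  do.call(rbind, lapply(names(fx$lines), function(s)
    parse_pileup(fx$lines[[s]], sample_id = s, thresholds = thresholds)))
}

# Single-exon plus-strand protein-coding toy transcript whose CDS starts at
# genomic position 1, with chosen codons overridden.
toy_coding_transcript <- function(n_codons, codon_overrides = NULL,
                                  strand = "+", chrom = "chrT",
                                  id = "tx_toy") {
  len <- 3L * n_codons
  m <- transcript_model(paste0(id, "_gene"), id, chrom, strand,
                        exons = cbind(1L, len), cds = cbind(1L, len))
  codons <- rep("GCT", n_codons)
  codons[1] <- "ATG"
  for (ci in names(codon_overrides))
    codons[as.integer(ci)] <- codon_overrides[[ci]]
  list(model = m, cds_seq = paste(codons, collapse = ""))
}

# small default simulated dataset shared across tests
small_sim <- function(seed = 42, ...) {
  generate_dataset(simulation_config(n_sites = 80, frac_dre = 0.1,
                                     frac_time_trend = 0.1, frac_cis = 0.05,
                                     seed = seed, ...))
}

# events assembled from a simulated dataset through the calling path
events_from_sim <- function(sim, thresholds = calling_thresholds(),
                            annotate = TRUE, retain = TRUE) {
  ds <- sim$dataset
  calls <- call_variants(ds$allele_counts, thresholds)
  ev <- events_from_calls(calls, ds$design, counts = ds$allele_counts)
  if (annotate) ev <- annotate_events(ev, ds$models, ds$cds_seqs)
  if (retain) ev <- retain_high_confidence(ev, ds$known_sites)
  ev
}

# independent brute-force oracle for the R x 2 exact test: recursive descent
# over all margin-fixed tables, accumulating point probabilities directly
fisher_oracle <- function(tab) {
  rs <- rowSums(tab); A <- sum(tab[, 1]); N <- sum(rs)
  lp_obs <- sum(lchoose(rs, tab[, 1])) - lchoose(N, A)
  total <- 0; psum <- 0
  recurse <- function(i, left, acc) {
    if (i == length(rs)) {
      if (left <= rs[i]) {
        lp <- sum(lchoose(rs, c(acc, left))) - lchoose(N, A)
        total <<- total + exp(lp)
        if (lp <= lp_obs + 1e-7 * abs(lp_obs) + 1e-12) psum <<- psum + exp(lp)
      }
      return(invisible())
    }
    for (a in 0:min(rs[i], left)) recurse(i + 1, left - a, c(acc, a))
  }
  recurse(1, A, integer(0))
  list(p = psum, total = total)
}
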