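#' Parse samtools-mpileup text into allele counts
#'
#' Reads the 6-column samtools mpileup dialect (chrom, pos, ref, depth,
#' base string, quality string) for a single sample and produces one
#' allele-count record per line. Only bases whose Phred quality (ASCII-33)
#' is at least `thresholds$min_base_quality` contribute to counts; `.` and
#' `,` count as reference; read-start (`^` plus mapping-quality character)
#' and read-end (`$`) markers and indel runs (`+`/`-` followed by a length
#' and the inserted/deleted bases) are consumed without contributing.
#' Deletion placeholders (`*`) and reference skips (`>`/`<`) consume a
#' quality character and are tallied as "other". Among quality-passing
#' non-reference bases the most frequent becomes the alternative allele
#' (ties broken by base order A < C < G < T); remaining non-reference bases
#' are tallied as "other".
#'
#' @param input path to a pileup file, or a character vector of pileup
#'   lines (anything with more than one element, or containing a tab, is
#'   treated as lines).
#' @param sample_id sample identifier stamped on every record.
#' @param thresholds a [calling_thresholds()]; only `min_base_quality` is
#'   used here.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `ref_count`, `alt_count`, `other_count`,
#'   `n_below_quality`, `depth_reported`. `alt` is NA when no
#'   quality-passing non-reference base was seen.
#' @export
parse_pileup <- function(input, sample_id = "sample",
                         thresholds = calling_thresholds()) {
  lines <- if (length(input) == 1L && !grepl("\t", input) && file.exists(input))
    readLines(input) else input
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L)
      stop("pileup parse error at line ", i, ": expected 6 columns, got ",
           length(f))
    ref <- toupper(f[3])
    calls <- decode_pileup_bases(f[5], ref, i)
    quals <- utf8ToInt(f[6]) - 33L
    if (length(calls) != length(quals))
      stop("pileup parse error at line ", i, ": base string encodes ",
           length(calls), " calls but quality string has ", length(quals))
    pass <- quals >= thresholds$min_base_quality
    below <- sum(!pass)
    calls <- calls[pass]
    ref_count <- sum(calls == "ref")
    other <- sum(calls == "*")
    bases <- calls[calls %in% c("A", "C", "G", "T")]
    alt <- NA_character_
    alt_count <- 0L
    if (length(bases)) {
      tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
      alt <- names(tab)[which.max(tab)]  # which.max takes first => A<C<G<T ties
      alt_count <- as.integer(tab[alt])
      other <- other + sum(tab) - alt_count
    }
    out[[i]] <- data.frame(
      chrom = f[1], pos = as.integer(f[2]), ref = ref, alt = alt,
      sample_id = sample_id, ref_count = ref_count, alt_count = alt_count,
      other_count = as.integer(other), n_below_quality = below,
      depth_reported = as.integer(f[4]), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Decode one mpileup base string into a vector of per-read calls, each of
# which consumes one quality character: "ref", "A"/"C"/"G"/"T", or "*"
# (deletion placeholder / reference skip / ambiguous base, tallied as other).
decode_pileup_bases <- function(s, ref, line_no) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  calls <- character(0)
  j <- 1L
  nch <- length(ch)
  while (j <= nch) {
    c0 <- ch[j]
    if (c0 == "^") {
      if (j + 1L > nch)
        stop("pileup parse error at line ", line_no, ": dangling '^'")
      j <- j + 2L                      # '^' + mapping quality, no base call
    } else if (c0 == "$") {
      j <- j + 1L
    } else if (c0 == "+" || c0 == "-") {
      k <- j + 1L
      while (k <= nch && grepl("[0-9]", ch[k])) k <- k + 1L
      if (k == j + 1L)
        stop("pileup parse error at line ", line_no,
             ": indel marker without length")
      len <- as.integer(paste(ch[(j + 1L):(k - 1L)], collapse = ""))
      if (k + len - 1L > nch)
        stop("pileup parse error at line ", line_no,
             ": indel run past end of base string")
      j <- k + len                     # indel sequence carries no qualities
    } else if (c0 == "." || c0 == ",") {
      calls <- c(calls, "ref"); j <- j + 1L
    } else if (toupper(c0) %in% c("A", "C", "G", "T")) {
      calls <- c(calls, toupper(c0)); j <- j + 1L
    } else if (c0 %in% c("*", "#", ">", "<", "N", "n")) {
      calls <- c(calls, "*"); j <- j + 1L
    } else {
      stop("pileup parse error at line ", line_no,
           ": unexpected character '", c0, "' in base string")
    }
  }
  calls
}
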