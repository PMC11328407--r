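#' Variant-screening thresholds
#'
#' The per-site, per-sample screening thresholds applied to allele counts:
#' base quality >= 25, sequencing depth >= 10, alternative allele depth >= 2
#' and alternative allele frequency >= 1% by default.
#'
#' @param min_base_quality minimum Phred base quality for a base to be
#'   counted at all (applied during pileup parsing).
#' @param min_depth minimum sequencing depth (ref + alt + other) at the site.
#' @param min_alt_depth minimum number of alternative-allele reads.
#' @param min_frequency minimum alternative allele frequency,
#'   `alt / (ref + alt)`, in (0, 1].
#' @return A `calling_thresholds` list.
#' @export
calling_thresholds <- function(min_base_quality = 25L, min_depth = 10L,
                               min_alt_depth = 2L, min_frequency = 0.01) {
  stopifnot(min_base_quality >= 0, min_depth >= 0, min_alt_depth >= 0,
            min_frequency > 0, min_frequency <= 1)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_depth = as.integer(min_depth),
                 min_alt_depth = as.integer(min_alt_depth),
                 min_frequency = min_frequency),
            class = "calling_thresholds")
}

#' Editing level of a site in a sample
#'
#' Proportion of edited reads among reference plus edited reads,
#' `alt / (ref + alt)`. Reads carrying other bases are excluded from the
#' denominator as noise. Undefined (NA) when `ref + alt` is zero.
#'
#' @param ref_count,alt_count non-negative integer vectors.
#' @return numeric vector of proportions, NA where undefined.
#' @examples
#' editing_level(80, 20)  # 0.2
#' editing_level(0, 0)    # NA
#' @export
editing_level <- function(ref_count, alt_count) {
  stopifnot(all(ref_count >= 0, na.rm = TRUE), all(alt_count >= 0, na.rm = TRUE))
  tot <- ref_count + alt_count
  ifelse(tot > 0, alt_count / tot, NA_real_)
}

#' Is a mismatch consistent with A-to-I editing?
#'
#' Inosine is read as guanosine by the sequencer, so A-to-I editing appears
#' as A>G on the transcribed (+) strand, or as its reverse complement T>C
#' when the gene lies on the (-) strand.
#'
#' @param ref_base,alt_base single-character base vectors (A/C/G/T).
#' @param strand "+" or "-" per element; NA allowed only with
#'   `strand_agnostic = TRUE`.
#' @param strand_agnostic if TRUE, an unknown strand accepts either A>G or
#'   T>C (the caller should mark such sites strand-unresolved).
#' @return logical vector.
#' @export
resolve_editing_type <- function(ref_base, alt_base, strand,
                                 strand_agnostic = FALSE) {
  n <- max(length(ref_base), length(alt_base), length(strand))
  ref_base <- rep_len(toupper(ref_base), n)
  alt_base <- rep_len(toupper(alt_base), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(ref_base %in% c("A", "C", "G", "T")) ||
      !all(alt_base %in% c("A", "C", "G", "T")))
    stop("bases must be one of A/C/G/T")
  known <- strand %in% c("+", "-")
  if (any(!known) && !strand_agnostic)
    stop("unknown strand; use strand_agnostic = TRUE to accept A>G or T>C")
  ag <- ref_base == "A" & alt_base == "G"
  tc <- ref_base == "T" & alt_base == "C"
  out <- ifelse(strand == "+", ag, ifelse(strand == "-", tc, ag | tc))
  out[is.na(strand)] <- (ag | tc)[is.na(strand)]
  out
}

#' Screen allele-count records into variant calls
#'
#' Applies the depth, alternative-depth and frequency thresholds to a table
#' of per-site per-sample allele counts. Depth is `ref + alt + other`;
#' frequency is `alt / (ref + alt)`.
#'
#' @param records data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `ref_count`, `alt_count`, `other_count` (missing
#'   `other_count` treated as 0).
#' @param thresholds a [calling_thresholds()].
#' @param keep_all if TRUE, return every record with the computed
#'   `frequency` and `passes` columns; if FALSE (default) return only
#'   passing records.
#' @return data frame of variant calls with added `frequency` and `passes`.
#' @export
call_variants <- function(records, thresholds = calling_thresholds(),
                          keep_all = FALSE) {
  need <- c("chrom", "pos", "ref", "alt", "sample_id", "ref_count", "alt_count")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (is.null(records$other_count)) records$other_count <- 0L
  stopifnot(all(records$ref_count >= 0), all(records$alt_count >= 0),
            all(records$other_count >= 0))
  depth <- records$ref_count + records$alt_count + records$other_count
  freq <- editing_level(records$ref_count, records$alt_count)
  passes <- depth >= thresholds$min_depth &
    records$alt_count >= thresholds$min_alt_depth &
    !is.na(freq) & freq >= thresholds$min_frequency
  records$frequency <- freq
  records$passes <- passes
  if (keep_all) records else records[passes, , drop = FALSE]
}

#' Read a pre-counted allele TSV
#'
#' Columns: chrom, pos, ref, alt, sample_id, ref_count, alt_count,
#' other_count.
#' @param path path to the TSV.
#' @return allele-count data frame.
#' @export
read_allele_counts <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character", ref = "character",
                                 alt = "character", sample_id = "character"))
  need <- c("chrom", "pos", "ref", "alt", "sample_id", "ref_count", "alt_count",
            "other_count")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("allele-count file missing columns: ",
                         paste(miss, collapse = ", "))
  d
}

#' Read a known editing-site list
#'
#' REDIportal-style TSV with columns chrom, pos (1-based), ref, alt (or the
#' literal "A-to-I"), strand.
#' @param path path to the TSV.
#' @return data frame with a `site_id` column (`chrom:pos`).
#' @export
read_known_sites <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("known-site file missing columns: ",
                         paste(miss, collapse = ", "))
  d$site_id <- paste0(d$chrom, ":", d$pos)
  d
}

#' Write variant calls as TSV and a VCF-like text file
#'
#' The TSV holds one row per passing site x sample. The VCF-like file is a
#' sites-level interchange format (CHROM, POS, ID, REF, ALT, QUAL, FILTER,
#' INFO) whose INFO field carries per-sample allele depths (`AD`) and
#' frequencies (`AF`).
#'
#' @param calls variant-call data frame from [call_variants()].
#' @param tsv_path output TSV path.
#' @param vcf_path optional output path for the VCF-like file.
#' @return invisibly, the paths written.
#' @export
write_variant_calls <- function(calls, tsv_path, vcf_path = NULL) {
  write.table(calls, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(vcf_path)) {
    key <- paste0(calls$chrom, ":", calls$pos, ":", calls$ref, ">", calls$alt)
    sp <- split(calls, key)
    hdr <- c("##fileformat=VCF-like-sites-v1",
             "##INFO=<ID=AD,Description=\"per-sample sample:ref,alt\">",
             "##INFO=<ID=AF,Description=\"per-sample sample:alt frequency\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    rows <- vapply(sp, function(g) {
      g <- g[order(g$sample_id), , drop = FALSE]
      info <- paste0(
        "AD=", paste0(g$sample_id, ":", g$ref_count, ",", g$alt_count,
                      collapse = "|"),
        ";AF=", paste0(g$sample_id, ":", format(round(g$frequency, 6),
                                                trim = TRUE, scientific = FALSE),
                       collapse = "|"))
      paste(g$chrom[1], g$pos[1], ".", g$ref[1], g$alt[1], ".", "PASS", info,
            sep = "\t")
    }, character(1))
    ord <- order(vapply(sp, function(g) g$chrom[1], character(1)),
                 vapply(sp, function(g) g$pos[1], numeric(1)))
    writeLines(c(hdr, unname(rows[ord])), vcf_path)
  }
  invisible(c(tsv_path, vcf_path))
}
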