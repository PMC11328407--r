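#' Transcript model
#'
#' Minimal exon/CDS representation of one transcript, in 1-based inclusive
#' genomic coordinates. Exons must be sorted and non-overlapping; CDS
#' intervals must lie within exons. A CDS whose total length is not a
#' multiple of 3 is flagged `cds_partial` rather than rejected.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons two-column matrix (start, end) of exon intervals.
#' @param cds optional two-column matrix of CDS intervals.
#' @param biotype "protein_coding", "lincRNA" or "other".
#' @return a `transcript_model` object.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons,
                             cds = NULL, biotype = "protein_coding") {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  stopifnot(all(exons[, 2] >= exons[, 1]))
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  cds_partial <- FALSE
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    stopifnot(all(cds[, 2] >= cds[, 1]))
    within <- vapply(seq_len(nrow(cds)), function(i)
      any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2]), logical(1))
    if (!all(within)) stop("CDS intervals not contained in exons for ",
                           transcript_id)
    if (sum(cds[, 2] - cds[, 1] + 1L) %% 3L != 0L) cds_partial <- TRUE
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 biotype = biotype, cds_partial = cds_partial),
            class = "transcript_model")
}

cds_length <- function(model) {
  if (is.null(model$cds)) 0L else sum(model$cds[, 2] - model$cds[, 1] + 1L)
}

#' Map a genomic position to a 1-based CDS coordinate
#'
#' Accumulates coding bases 5' to 3' in transcript orientation: plus-strand
#' models count left to right, minus-strand models traverse CDS intervals
#' right to left.
#'
#' @param pos genomic 1-based position, inside a CDS interval of `model`.
#' @param model a [transcript_model()] with a CDS.
#' @return integer CDS (c.) coordinate.
#' @export
genomic_to_cds <- function(pos, model) {
  if (is.null(model$cds)) stop("transcript ", model$transcript_id,
                               " has no CDS")
  cds <- model$cds
  hit <- which(pos >= cds[, 1] & pos <= cds[, 2])
  if (!length(hit))
    stop("position ", pos, " is not in the CDS of ", model$transcript_id,
         "; categorize the site first")
  if (model$strand == "+") {
    before <- if (hit > 1) sum(cds[seq_len(hit - 1), 2] -
                               cds[seq_len(hit - 1), 1] + 1L) else 0L
    as.integer(before + (pos - cds[hit, 1] + 1L))
  } else {
    nseg <- nrow(cds)
    after <- if (hit < nseg) sum(cds[(hit + 1):nseg, 2] -
                                 cds[(hit + 1):nseg, 1] + 1L) else 0L
    as.integer(after + (cds[hit, 2] - pos + 1L))
  }
}

# inverse mapping, used by the simulator to place coding sites
cds_to_genomic <- function(cds_pos, model) {
  cds <- model$cds
  lens <- cds[, 2] - cds[, 1] + 1L
  if (cds_pos < 1 || cds_pos > sum(lens)) stop("cds_pos out of range")
  if (model$strand == "+") {
    cum <- cumsum(lens)
    seg <- which(cds_pos <= cum)[1]
    off <- cds_pos - c(0L, cum)[seg]
    as.integer(cds[seg, 1] + off - 1L)
  } else {
    ord <- rev(seq_len(nrow(cds)))
    cum <- cumsum(lens[ord])
    k <- which(cds_pos <= cum)[1]
    seg <- ord[k]
    off <- cds_pos - c(0L, cum)[k]
    as.integer(cds[seg, 2] - off + 1L)
  }
}

#' Functional category of a position within one transcript
#'
#' For protein-coding transcripts, an exonic position is classified as
#' "CDS", "5'UTR" or "3'UTR" in transcript orientation; a position inside
#' the gene span but not exonic is "intronic". lincRNA transcripts yield
#' "lincRNA" for exonic and "intronic" otherwise. Positions outside the
#' transcript span yield "intergenic".
#'
#' @param pos genomic 1-based position.
#' @param model a [transcript_model()].
#' @return a category string.
#' @export
categorize_position <- function(pos, model) {
  ex <- model$exons
  span <- c(min(ex[, 1]), max(ex[, 2]))
  if (pos < span[1] || pos > span[2]) return("intergenic")
  exonic <- any(pos >= ex[, 1] & pos <= ex[, 2])
  if (!exonic) return("intronic")
  if (model$biotype == "lincRNA") return("lincRNA")
  if (model$biotype != "protein_coding" || is.null(model$cds)) return("other")
  cds <- model$cds
  if (any(pos >= cds[, 1] & pos <= cds[, 2])) return("CDS")
  cds_lo <- min(cds[, 1]); cds_hi <- max(cds[, 2])
  upstream <- pos < cds_lo  # genomically left of the CDS
  if (model$strand == "+") {
    if (upstream) "5'UTR" else "3'UTR"
  } else {
    if (upstream) "3'UTR" else "5'UTR"
  }
}

#' Coding consequence of an A-to-G edit at a CDS position
#'
#' Computes the codon index (`ceiling(cds_pos / 3)`), substitutes A with G
#' at the in-codon offset, translates both codons with the standard genetic
#' code, and emits HGVS-style c. and p. strings (e.g. `c.1099A>G`,
#' `p.S367G`).
#'
#' @param model a [transcript_model()] (identifiers used in the output).
#' @param cds_pos 1-based CDS coordinate of the edited base.
#' @param cds_seq transcript-oriented coding sequence (single string); the
#'   base at `cds_pos` must be A, otherwise the model and sequence are
#'   inconsistent and an error is raised.
#' @return data frame with `category` ("missense", "synonymous" or
#'   "stop_related"), `cds_pos`, `codon_index`, `codon_offset`, `ref_aa`,
#'   `alt_aa`, `hgvs_c`, `hgvs_p`.
#' @examples
#' m <- transcript_model("g", "t", "chr1", "+", cbind(1, 3300), cbind(1, 3300))
#' s <- paste(rep("GCT", 1100), collapse = "")
#' substr(s, 3295, 3297) <- "AGC"
#' recode_edit(m, 3295L, s)  # p.S1099G
#' @export
recode_edit <- function(model, cds_pos, cds_seq) {
  cds_seq <- toupper(as.character(cds_seq))
  stopifnot(cds_pos >= 1, cds_pos <= nchar(cds_seq))
  ref_base <- substr(cds_seq, cds_pos, cds_pos)
  if (ref_base != "A")
    stop("transcript base at c.", cds_pos, " of ", model$transcript_id,
         " is ", ref_base, ", not A: transcript model and CDS sequence ",
         "disagree with an A-to-I edit")
  codon_index <- as.integer(ceiling(cds_pos / 3))
  codon_offset <- as.integer((cds_pos - 1L) %% 3L + 1L)
  cstart <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds_seq, cstart, cstart + 2L)
  if (nchar(ref_codon) < 3L)
    stop("CDS sequence truncated before the end of codon ", codon_index)
  alt_codon <- ref_codon
  substr(alt_codon, codon_offset, codon_offset) <- "G"
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  category <- if (ref_aa == "*" || alt_aa == "*") "stop_related"
              else if (ref_aa == alt_aa) "synonymous" else "missense"
  data.frame(category = category, cds_pos = as.integer(cds_pos),
             codon_index = codon_index, codon_offset = codon_offset,
             ref_aa = ref_aa, alt_aa = alt_aa,
             hgvs_c = paste0("c.", cds_pos, "A>G"),
             hgvs_p = paste0("p.", ref_aa, codon_index, alt_aa),
             stringsAsFactors = FALSE)
}

#' Read transcript models from a simplified TSV or a GTF
#'
#' The simplified table has columns `gene_id`, `transcript_id`, `chrom`,
#' `strand`, `biotype`, `feature` ("exon" or "CDS"), `start`, `end`
#' (1-based inclusive). Files ending in `.gtf`/`.gff` are imported with
#' rtracklayer and reduced to the same features.
#'
#' @param path input file.
#' @return list of [transcript_model()] objects, named by transcript_id.
#' @export
read_transcript_models <- function(path) {
  if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    g <- rtracklayer::import(path)
    d <- data.frame(gene_id = g$gene_id, transcript_id = g$transcript_id,
                    chrom = as.character(GenomicRanges::seqnames(g)),
                    strand = as.character(GenomicRanges::strand(g)),
                    biotype = if (!is.null(g$gene_biotype)) g$gene_biotype
                              else "protein_coding",
                    feature = as.character(g$type),
                    start = GenomicRanges::start(g),
                    end = GenomicRanges::end(g), stringsAsFactors = FALSE)
    d <- d[d$feature %in% c("exon", "CDS"), , drop = FALSE]
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "transcript_id", "chrom", "strand", "biotype",
              "feature", "start", "end")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("transcript-model file missing columns: ",
                           paste(miss, collapse = ", "))
  }
  models_from_table(d)
}

# build transcript_model list from the simplified long table
models_from_table <- function(d) {
  sp <- split(d, d$transcript_id)
  out <- lapply(sp, function(t) {
    ex <- t[t$feature == "exon", c("start", "end"), drop = FALSE]
    cd <- t[t$feature == "CDS", c("start", "end"), drop = FALSE]
    transcript_model(t$gene_id[1], t$transcript_id[1], t$chrom[1],
                     t$strand[1], as.matrix(ex),
                     if (nrow(cd)) as.matrix(cd) else NULL,
                     biotype = t$biotype[1])
  })
  out[order(names(out))]
}

# long table from transcript_model list (for writing)
models_to_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    ex <- data.frame(feature = "exon", start = m$exons[, 1], end = m$exons[, 2])
    cd <- if (!is.null(m$cds))
      data.frame(feature = "CDS", start = m$cds[, 1], end = m$cds[, 2])
      else NULL
    f <- rbind(ex, cd)
    data.frame(gene_id = m$gene_id, transcript_id = m$transcript_id,
               chrom = m$chrom, strand = m$strand, biotype = m$biotype,
               f, stringsAsFactors = FALSE)
  }))
}

#' Read CDS sequences from a FASTA keyed by transcript_id
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_cds_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Keep one canonical transcript per gene
#'
#' The transcript with the longest CDS wins (total exonic length breaks
#' ties, then transcript_id lexicographically for determinism).
#' @param models list of [transcript_model()].
#' @return filtered list.
#' @export
select_canonical <- function(models) {
  gene <- vapply(models, `[[`, character(1), "gene_id")
  keep <- tapply(seq_along(models), gene, function(ix) {
    cl <- vapply(models[ix], cds_length, integer(1))
    el <- vapply(models[ix], function(m)
      sum(m$exons[, 2] - m$exons[, 1] + 1L), integer(1))
    id <- vapply(models[ix], `[[`, character(1), "transcript_id")
    ix[order(-cl, -el, id)][1]
  })
  models[sort(unlist(keep))]
}

#' Annotate editing events with strand, category and coding consequence
#'
#' For each site, overlapping canonical transcripts are found; the gene
#' strand resolves the site strand and hence A-to-I identity (A>G on "+",
#' T>C on "-"). Sites overlapped by genes on both strands are marked
#' strand-ambiguous and their category is withheld. Category precedence
#' across overlapping transcripts is CDS > UTR > intronic > lincRNA >
#' intergenic; CDS sites with an available CDS sequence are further
#' resolved to missense / synonymous / stop_related with HGVS c. and p.
#' strings.
#'
#' @param events an `editing_events` object.
#' @param models list of [transcript_model()] (canonicalized internally).
#' @param cds_seqs named character vector of transcript-oriented CDS
#'   sequences (from [read_cds_sequences()]); optional.
#' @return `events` with `info` gaining `strand`, `strand_ambiguous`,
#'   `is_a_to_i`, `gene_id`, `transcript_id`, `category`, `cds_pos`,
#'   `codon_index`, `ref_aa`, `alt_aa`, `hgvs_c`, `hgvs_p`.
#' @export
annotate_events <- function(events, models, cds_seqs = NULL) {
  models <- select_canonical(models)
  info <- events$info
  n <- nrow(info)
  gr_models <- GenomicRanges::GRanges(
    vapply(models, `[[`, character(1), "chrom"),
    IRanges::IRanges(
      vapply(models, function(m) min(m$exons[, 1]), integer(1)),
      vapply(models, function(m) max(m$exons[, 2]), integer(1))))
  gr_sites <- GenomicRanges::GRanges(info$chrom,
                                     IRanges::IRanges(info$pos, info$pos))
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_models)
  hit_list <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))

  prec <- c(missense = 1, stop_related = 1, synonymous = 1, CDS = 1,
            "3'UTR" = 2, "5'UTR" = 2, intronic = 3, lincRNA = 4,
            other = 5, intergenic = 6)
  out <- data.frame(strand = NA_character_, strand_ambiguous = FALSE,
                    is_a_to_i = NA, gene_id = NA_character_,
                    transcript_id = NA_character_,
                    category = "intergenic", cds_pos = NA_integer_,
                    codon_index = NA_integer_, ref_aa = NA_character_,
                    alt_aa = NA_character_, hgvs_c = NA_character_,
                    hgvs_p = NA_character_, stringsAsFactors = FALSE)
  out <- out[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL

  for (i in seq_len(n)) {
    hits <- hit_list[[as.character(i)]]
    if (is.null(hits)) next
    mods <- models[hits]
    strands <- unique(vapply(mods, `[[`, character(1), "strand"))
    if (length(strands) > 1L) {
      out$strand_ambiguous[i] <- TRUE
      out$category[i] <- NA_character_
      next
    }
    out$strand[i] <- strands
    out$is_a_to_i[i] <- resolve_editing_type(info$ref[i], info$alt[i], strands)
    cats <- vapply(mods, function(m) categorize_position(info$pos[i], m),
                   character(1))
    best <- order(prec[cats])[1]
    m <- mods[[best]]
    cat_i <- cats[best]
    out$gene_id[i] <- m$gene_id
    out$transcript_id[i] <- m$transcript_id
    if (cat_i == "CDS") {
      cpos <- genomic_to_cds(info$pos[i], m)
      out$cds_pos[i] <- cpos
      seq <- cds_seqs[[m$transcript_id]]
      if (!is.null(seq) && isTRUE(out$is_a_to_i[i])) {
        rc <- recode_edit(m, cpos, seq)
        out$category[i] <- rc$category
        out$codon_index[i] <- rc$codon_index
        out$ref_aa[i] <- rc$ref_aa
        out$alt_aa[i] <- rc$alt_aa
        out$hgvs_c[i] <- rc$hgvs_c
        out$hgvs_p[i] <- rc$hgvs_p
      } else {
        out$category[i] <- "CDS"
        out$hgvs_c[i] <- paste0("c.", cpos, info$ref[i], ">", info$alt[i])
      }
    } else {
      out$category[i] <- cat_i
    }
  }
  events$info <- cbind(info[, setdiff(names(info), names(out)), drop = FALSE],
                       out)
  events
}
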