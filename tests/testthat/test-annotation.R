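# two-exon plus/minus templates mirroring the simulator's host-gene layout
pc_gene <- function(strand = "+", g0 = 1000L, id = "tx1") {
  exons <- cbind(c(g0, g0 + 700L), c(g0 + 499L, g0 + 1699L))
  cds <- if (strand == "+")
    cbind(c(g0 + 150L, g0 + 700L), c(g0 + 499L, g0 + 1249L))
  else
    cbind(c(g0 + 450L, g0 + 700L), c(g0 + 499L, g0 + 1549L))
  transcript_model(paste0(id, "g"), id, "chr1", strand, exons, cds)
}

test_that("positions are categorized by transcript structure and strand", {
  m <- pc_gene("+")
  expect_equal(categorize_position(1000, m), "5'UTR")
  expect_equal(categorize_position(1200, m), "CDS")
  expect_equal(categorize_position(1600, m), "intronic")
  expect_equal(categorize_position(2500, m), "3'UTR")
  expect_equal(categorize_position(99, m), "intergenic")
  mm <- pc_gene("-")
  expect_equal(categorize_position(1000, mm), "3'UTR")   # genomic left = 3' end
  expect_equal(categorize_position(2600, mm), "5'UTR")
  li <- transcript_model("g", "t", "chr1", "+", cbind(1L, 1000L),
                         biotype = "lincRNA")
  expect_equal(categorize_position(500, li), "lincRNA")
})

test_that("genomic-to-CDS mapping accumulates in transcript orientation", {
  m <- pc_gene("+")
  expect_equal(genomic_to_cds(1150, m), 1L)            # first CDS base
  expect_equal(genomic_to_cds(1499, m), 350L)          # last base of exon 1 CDS
  expect_equal(genomic_to_cds(1700, m), 351L)          # first base of exon 2 CDS
  mm <- pc_gene("-")
  expect_equal(genomic_to_cds(2549, mm), 1L)           # rightmost CDS base
  expect_equal(genomic_to_cds(1450, mm), 900L)

  # toy two-exon CDS of lengths 30 + 15: 3rd base of exon 2 is c.33
  toy <- transcript_model("g", "t", "chr1", "+",
                          exons = cbind(c(1L, 101L), c(30L, 115L)),
                          cds = cbind(c(1L, 101L), c(30L, 115L)))
  expect_equal(genomic_to_cds(103, toy), 33L)
  expect_error(genomic_to_cds(50, toy), "not in the CDS")
})

test_that("mapping is a bijection between CDS and genomic coordinates", {
  for (strand in c("+", "-")) {
    m <- pc_gene(strand)
    for (cp in c(1L, 2L, 349L, 350L, 351L, 899L, 900L))
      expect_equal(genomic_to_cds(editscan:::cds_to_genomic(cp, m), m), cp,
                   info = paste(strand, cp))
  }
})

test_that("recoding reproduces the documented missense calls", {
  # codon 367 = AGC, edit at c.1099 (offset 1): AGC Ser -> GGC Gly
  t1 <- toy_coding_transcript(370, list("367" = "AGC"))
  r1 <- recode_edit(t1$model, 1099L, t1$cds_seq)
  expect_equal(r1$hgvs_p, "p.S367G")
  expect_equal(r1$hgvs_c, "c.1099A>G")
  expect_equal(r1$category, "missense")
  expect_equal(r1$codon_index, 367L)

  # codon 619 = CAA, edit at c.1856 (offset 2): CAA Gln -> CGA Arg
  t2 <- toy_coding_transcript(620, list("619" = "CAA"))
  r2 <- recode_edit(t2$model, 1856L, t2$cds_seq)
  expect_equal(r2$hgvs_p, "p.Q619R")
  expect_equal(r2$category, "missense")

  # wobble position: GCA -> GCG stays Ala
  t3 <- toy_coding_transcript(20, list("10" = "GCA"))
  r3 <- recode_edit(t3$model, 30L, t3$cds_seq)
  expect_equal(r3$category, "synonymous")
  expect_equal(r3$ref_aa, r3$alt_aa)

  # model/sequence inconsistency: base at the edit is not A
  expect_error(recode_edit(t3$model, 29L, t3$cds_seq), "not A")
})

test_that("recoding agrees with a direct codon-table lookup for all contexts", {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  for (off in 1:3) for (b1 in bases) for (b2 in bases) {
    codon <- c(b1, b2, b1)
    codon[off] <- "A"
    codon <- paste(codon, collapse = "")
    tt <- toy_coding_transcript(10, list("5" = codon))
    r <- recode_edit(tt$model, 12L + off, tt$cds_seq)
    alt_codon <- codon
    substr(alt_codon, off, off) <- "G"
    expect_equal(r$ref_aa, unname(code[codon]))
    expect_equal(r$alt_aa, unname(code[alt_codon]))
    expect_equal(r$codon_index, 5L)
    # cross-field consistency: residue number in hgvs_p equals ceil(cds_pos/3)
    expect_true(grepl(paste0(r$ref_aa, ceiling((12 + off) / 3), r$alt_aa),
                      r$hgvs_p, fixed = TRUE))
  }
})

test_that("canonical transcript selection prefers the longest CDS", {
  short <- transcript_model("g1", "txA", "chr1", "+", cbind(1L, 300L),
                            cbind(1L, 150L))
  long <- transcript_model("g1", "txB", "chr1", "+", cbind(1L, 300L),
                           cbind(1L, 300L))
  expect_equal(select_canonical(list(short, long))[[1]]$transcript_id, "txB")
})

test_that("event annotation resolves strand, category and consequences", {
  sim <- small_sim()
  ev <- events_from_sim(sim, annotate = TRUE, retain = FALSE)
  truth <- sim$truth
  ix <- match(ev$info$site_id, truth$site_id)
  expect_true(all(!is.na(ix)))
  expect_equal(ev$info$strand, truth$strand[ix])
  expect_equal(ev$info$is_a_to_i, !truth$is_decoy[ix])
  tr_cat <- truth$category[ix]
  comparable <- ev$info$is_a_to_i       # decoys in CDS are not recoded
  expect_equal(ev$info$category[comparable], tr_cat[comparable])
  mis <- which(ev$info$category == "missense")
  expect_true(length(mis) > 0)
  expect_match(ev$info$hgvs_p[mis], "^p\\.S\\d+G$")  # designed AGC->GGC codon
  expect_equal(ev$info$codon_index[mis], ceiling(ev$info$cds_pos[mis] / 3))
})

test_that("annotation is independent of transcript input order", {
  sim <- small_sim()
  ev <- events_from_sim(sim, annotate = FALSE, retain = FALSE)
  a <- annotate_events(ev, sim$dataset$models, sim$dataset$cds_seqs)
  b <- annotate_events(ev, rev(sim$dataset$models), sim$dataset$cds_seqs)
  expect_equal(a$info, b$info)
})

test_that("genes overlapping on both strands make a site strand-ambiguous", {
  plus <- pc_gene("+", g0 = 1000L, id = "txP")
  minus <- pc_gene("-", g0 = 1200L, id = "txM")
  info <- data.frame(site_id = "chr1:1300", chrom = "chr1", pos = 1300L,
                     strand = NA_character_, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  lev <- matrix(0.1, 1, 2, dimnames = list("chr1:1300", c("s1", "s2")))
  ev <- editing_events(info, lev, lev * 0 + 90, lev * 0 + 10)
  ann <- annotate_events(ev, list(txP = plus, txM = minus))
  expect_true(ann$info$strand_ambiguous)
  expect_true(is.na(ann$info$category))
})

test_that("transcript models round-trip through the simplified TSV", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir, truth = sim$truth)
  models <- read_transcript_models(file.path(dir, "transcript_models.tsv"))
  expect_equal(length(models), length(sim$dataset$models))
  m0 <- sim$dataset$models[[1]]
  m1 <- models[[m0$transcript_id]]
  expect_equal(m1$exons, m0$exons)
  expect_equal(m1$cds, m0$cds)
  expect_equal(m1$strand, m0$strand)
  seqs <- read_cds_sequences(file.path(dir, "cds_sequences.fa"))
  expect_equal(seqs[sort(names(seqs))],
               sim$dataset$cds_seqs[sort(names(sim$dataset$cds_seqs))])
})
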