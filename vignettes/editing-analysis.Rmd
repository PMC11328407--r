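---
title: "Detecting and testing A-to-I RNA editing across an LPS time course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and testing A-to-I RNA editing across an LPS time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

## The problem

ADAR enzymes convert adenosine to inosine in double-stranded RNA; because
inosine pairs like guanosine, editing appears in RNA-seq as A>G mismatches
on the transcribed strand (T>C on the antisense strand). In acute
neuroinflammation models — a PBS control and a handful of time points after
LPS challenge, with N = 3 animals per group — editing activity can shift
within minutes, and the questions are: which sites are edited at all, which
are *differentially* edited between time-point groups, which follow time
monotonically, and whether editing of a site tracks expression of its host
gene (a cis signal) or of the ADAR enzymes themselves.

`editscan` implements that analysis downstream of alignment: its inputs are
per-site per-sample allele counts (a TSV or samtools-mpileup text), a
transcript model, a known-editing-site list and a gene-count matrix.
Alignment, duplicate marking and base-quality recalibration are upstream
concerns and out of scope.

## Site calling and high-confidence filtering

A per-sample record at a site carries reference, alternative and other
base counts (bases under Phred 25 are discarded during pileup parsing;
the most frequent non-reference base becomes the alternative, ties broken
A < C < G < T). A record passes screening iff

* depth (ref + alt + other) ≥ 10,
* alternative depth ≥ 2,
* frequency alt/(ref + alt) ≥ 1%.

The **editing level** is alt/(ref + alt): "other" bases are treated as
sequencing noise and excluded from the denominator, the convention of
REDIportal-style pipelines. Positions are 1-based throughout.

A site becomes a high-confidence editing event if its level reaches 1% in
at least two samples, or if it appears in the known-site list. The rescue
clause waives only the two-sample rule — a rescued site still needs at
least one passing call, otherwise zero-evidence rows would enter the event
set. Strand comes from the transcript model of the overlapping gene; sites
overlapped by genes on both strands are marked strand-ambiguous and
excluded from A-to-I typing rather than guessed.

**Detection vs quantification.** Once a site is retained, its level and
allele counts are taken from *every* covered sample, not only from samples
whose individual call passed screening. Quantifying only passing calls
would truncate counts at the alt ≥ 2 / freq ≥ 1% boundary and
systematically exaggerate group differences at weakly edited sites — in
our recovery benchmark this selection bias alone pushed the realized false
discovery rate of the differential test from ~0.04 to ~0.3. Detection
status is kept separately and drives presence/Venn summaries and per-sample
activity means (a site contributes to a sample's mean level only where it
was actually called, so detection-rate differences are not imputed as
zeros; this is a caveat when comparing groups with very different
coverage).

## Differential RNA editing

For each retained site with at least two groups of two covered samples,
per-sample (alt, ref) counts — the sufficient statistics, so depth weighs
evidence naturally — enter a binomial GLM with logit link,

counts ~ group vs. counts ~ 1,

compared by the likelihood-ratio deviance with a chi-square (k − 1)
reference. If any group is degenerate (all its samples fully edited or
fully unedited), 0.5 is added to every cell of that site's table
(Haldane–Anscombe) and the result flagged; there is no other continuity
handling. A permutation mode (`empirical_p_mode = "permutation"`)
recomputes the statistic under group-label shuffles with add-one smoothing,
as an alternative reading of an "empirical" p-value; the chi-square LRT is
the default and is what the calibration tests exercise (null rejection rate
0.056 at nominal 0.05 in a 2,000-site benchmark).

For sites with GLM p < 0.05 an **R×2 Fisher exact test** is run on allele
counts pooled within groups. The two-sided p sums the null probabilities of
all margin-fixed tables whose point probability does not exceed the
observed one (relative tolerance 1e-7). Enumeration is exact up to a
configurable budget of candidate tables; above it, a Monte-Carlo estimate
over `r2dtable` draws (fixed seed, add-one smoothing) is returned and
flagged. The test is verified against a brute-force recursive enumeration
oracle and against `stats::fisher.test`.

The decision rule is dual: a site is differentially edited iff
GLM p < 0.05 **and** (GLM FDR < 0.05 **or** Fisher FDR < 0.05), both FDRs
Benjamini–Hochberg. The GLM family is all tested sites of a run. For the
Fisher p-values the family is *also* all tested sites, with sites that did
not reach the GLM gate entering as p = 1: adjusting within the selected
subset alone is anticonservative, because selection on the correlated GLM
statistic leaves the subset's null Fisher p-values far from uniform and the
second gate stops controlling the FDR (we measured realized FDR 0.32 under
subset-wise adjustment vs 0.04 under the full family, at identical
sensitivity). Tukey HSD pairwise comparisons (studentized range after
one-way ANOVA on levels) are attached descriptively and never gate the
decision; when within-group variance is exactly zero the limit convention
p = 0 (unequal means) / p = 1 (equal) is used and flagged. Missense events
whose per-group mean levels span more than 5 percentage points get a
highlight flag.

## Coding consequences

One canonical transcript per gene (longest CDS; exonic length, then
transcript id, break ties) resolves multi-transcript ambiguity, mirroring
"most severe consequence" annotators while staying deterministic. Genomic
positions map to 1-based CDS coordinates by accumulating coding bases 5'→3'
in transcript orientation (minus-strand models traverse exons in reverse).
An A>G edit at CDS position c has codon index ceiling(c/3) and in-codon
offset ((c − 1) mod 3) + 1; both codons are translated with the standard
genetic code (no mitochondrial or selenocysteine handling) and HGVS-style
strings are emitted, e.g. codon 367 = AGC edited at c.1099 gives
`c.1099A>G` / `p.S367G`, codon 619 = CAA at c.1856 gives `p.Q619R`. A
transcript base other than A at the edit position is treated as a
model/sequence inconsistency and raises an error rather than a silent skip.

## Correlation analyses

Time-dependence is Spearman correlation of per-sample editing levels
against minutes post-treatment, control at 0 (vessels-like design
0/15/30/240; endothelial/microglia-like 0/30/60/120). Correlations use
per-sample values (n = 12) by default — group means (n = 4) are available
via `use_group_means` but have little power at these sizes. The coefficient
is the tie-corrected rank correlation; p comes from the t-approximation on
n − 2 df, with a seeded permutation option for small n. Constant input is
reported as undefined rather than 0. Cis records correlate a site's levels
with its host gene's TPM; enzyme records correlate per-sample mean editing
with ADAR-family TPM and are flagged when fewer than 4 pairs are available.

TPM is computed as count/length rates scaled to one million per sample.
The accompanying expression test is a one-way F test on log2(TPM + 1)
(the exact small-sample form of the Gaussian likelihood-ratio test);
count-model machinery such as edgeR's dispersion estimation is deliberately
not re-implemented here, because expression testing only supports the
editing analyses — treat its output as descriptive, not as a
state-of-the-art DE method. PCA of DRE editing levels imputes missing
entries by the site mean (the simplest choice that keeps all samples),
centers sites, and reports sample scores and variance fractions from the
SVD.

## The synthetic-data generator

`simulation_config()` encodes the study conditions: 4 groups × 3
replicates at 0/15/30/240 min; baseline levels Beta(2, 18) (mean 10%,
right-skewed, as editing-level distributions are); depth negative binomial
with mean 50 and dispersion 5 (RNA-seq-like overdispersion); group effects
additive on the proportion scale with clipping, matching how levels are
reported (percentages); alternative counts Binomial(depth, level).
Designated DRE sites shift one uniformly chosen group by `effect_size`;
time-trend sites follow an equal-increment monotone trajectory across the
ordered time points with random sign — the sampling times are roughly
log-spaced, so equal per-time-point increments model a saturating
(log-time) response, which is also the shape Spearman against time detects
most efficiently; a separate `trend_amplitude` (default `effect_size`)
controls its total span. Cis sites are a subset of trend sites (editing
must vary for a cis correlation to exist) and their host-gene expression
means scale as 1 + 5 × true group editing. Decoy sites emit one of the 11
non-A>G substitutions, uniformly, in non-coding categories. Each site is
hosted by its own two-exon toy gene (or single-exon lincRNA), with designed
codons (AGC→GGC missense, GCA→GCG synonymous) at coding sites; the
known-site list covers 30% of true sites, mimicking partial database
coverage of mouse sites. An optional `adar_coupling` multiplies all levels
by the ADAR2-like trajectory; it defaults to 0 so that truth-null sites
stay exchangeable across groups (the generator's calibration property).

What the generator does **not** emulate: biological replicate variation
beyond binomial sampling (no per-sample beta noise), library or batch
effects, read-level artifacts (it enters at the allele-count level),
overlapping genes, hyper-edited clusters, and realistic background
mismatch composition (protocol-dependent and left uniform over the 11
non-A>G substitutions here). Passing recovery
benchmarks here therefore demonstrates correctness of the statistics under
the stated model, not performance on arbitrary real data — in particular,
real replicate overdispersion would make the binomial GLM anticonservative,
which is why the quasi-binomial family and the permutation mode are
exposed as configuration.

## Benchmark problem sizes and expected operating points

The packaged acceptance tests run, at fixed seeds:

* GLM calibration: 2,000 null sites (4 × 3, depth ~ NB(100, 5), level
  0.1); null rejection at 0.05 lands near 0.056.
* DRE recovery: 1,000 sites with 100 designated DRE (effect 0.15, depth
  mean 100); the dual rule reaches sensitivity ~0.99 at realized FDR
  ~0.04.
* Time-trend recovery: 2,000 sites, 500 with amplitude 0.10, depth mean
  200 — chosen because Spearman with 12 samples and 4 tied time ranks has
  a hard power ceiling: at depth 50 even a perfectly monotone amplitude-
  0.10 trend is detected at best ~60% of the time regardless of trajectory
  shape, while at depth 200 sensitivity is ~0.96 with the truth-null
  flagged fraction ~0.06. Deeply covered sites are the regime where
  time-trend claims are meaningful.
* Fisher exactness: 200 random R×2 tables (R ≤ 4, totals ≤ 40) against
  brute-force enumeration, agreement to 1e-9, point probabilities summing
  to 1.
* End-to-end determinism: two pipeline runs with one seed produce
  byte-identical outputs (MD5-verified manifests).

## Numerical and degenerate-input conventions

* Zero-coverage level is missing (NA), never 0.
* Empty allele columns in a Fisher table give p = 1 with a warning.
* BH adjustment passes NAs through without counting them in the family.
* Multi-allelic pileup sites keep the majority alternative; ties break
  A < C < G < T.
* Known-site rescue requires ≥ 1 passing call.
* PCA requires ≥ 2 non-constant sites after imputation and errors
  otherwise.
* All simulation, permutation and Monte-Carlo paths take explicit seeds;
  fixing the seed fixes every emitted byte.

## Known limitations

Single canonical transcript per gene (isoform-specific consequences are
not reported); standard genetic code only; no splice-site consequence
calling; no network access to editing databases (file readers only); the
expression test is a convenience, not a replacement for dedicated DE
tools; Spearman-based trend detection is underpowered at shallow depth, as
quantified above.
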