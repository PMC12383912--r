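---
title: "riboscape: models and methods for joint Ribo-seq / RNA-seq analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboscape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

riboscape analyses bulk ribosome-profiling (Ribo-seq) data together with
matched RNA-seq counts at the transcript level. The motivating setting is a
two-group comparison with few biological replicates — for example testis
tissue from a fertile bovid and its sterile hybrid, three animals per group —
where the question is which genes diverge transcriptionally, which diverge
translationally, and how sequence features (CDS length, GC, RNA structure,
upstream open reading frames) relate to translation efficiency. This vignette
explains the models the package implements, the parameters that matter, what
the bundled synthetic-data generator does and does not emulate, and the
numerical choices behind the defaults.

## Coordinate model and data containers

Every transcript is represented in transcript space with 0-based, half-open
spans: the 5'UTR is `[0, cds_start)`, the CDS — stop codon included — is
`[cds_start, cds_end)`, and the 3'UTR is `[cds_end, length)`. The three spans
tile the transcript exactly, the CDS must be a non-empty multiple of 3 and
begin with ATG (a `nonstandard_start` flag admits annotated exceptions).
Conversions from 1-based GTF coordinates happen only inside the GTF reader,
so no other code ever adjusts by one. A ribosome footprint is a
`(sample, transcript, 5'-end position, read length)` record; a quantification
layer (RNA counts, footprint counts, FPKM, TE) is a genes-by-samples matrix
that carries its unit, per-gene effective lengths and per-sample library
sizes. Counts must be integers: tools that emit posterior-mean counts should
round upstream, because the negative-binomial tests below are defined on
integer data.

One canonical transcript per gene is assumed (the generator produces exactly
that). For multi-isoform annotations the intended convention is the
longest-CDS transcript per gene, chosen when building the model table.

## Footprint QC

Footprints are filtered to 20–40 nt, the usual size window for
ribosome-protected fragments. Region occupancy is reported by the aligned
5' end (the conventional assignment rule) with an alternative P-site mode;
under half-open spans an anchor exactly at `cds_start` is CDS. Note that with
5'-end anchoring the CDS fraction is mechanically a little lower than the
true P-site occupancy, because footprints whose P-site sits in the first
codons have 5' ends in the 5'UTR.

The P-site offset per read length is estimated riboWaltz-style: candidate
offsets 10–15 nt are scored by the meta-gene count of 5' ends exactly at
`cds_start − offset`, the argmax wins, and exact ties resolve toward the
canonical mammalian 12 nt. Length classes with fewer than 200 reads fall back
to 12 nt and are flagged — at that depth the argmax is dominated by noise.
Frame periodicity is then computed on CDS-internal P-sites as
`(psite − cds_start) mod 3`; frame 0 is the first codon position, so active
translation shows the familiar high–low–low profile. Sample-level QC uses
Pearson correlation and PCA on `log10(FPKM + 1)`; the pseudocount of 1
handles zeros and matches the conventional display scale for FPKM
distributions.

## Quantification

FPKM is `count · 10^9 / (library size · effective length)`. Effective length
is the mature transcript length for RNA-seq and the CDS length for Ribo-seq,
because footprints are counted over the ORF. Translation efficiency is
`TE = FPKM(Ribo) / FPKM(RNA)`, computed per sample and then averaged per
group; per-sample ratios preserve replicate information, whereas a
ratio-of-group-means discards it (both modes exist; per-sample is the
default). TE is undefined (NA) where the RNA denominator is zero, and 0 where
only the numerator is zero. Genes are binned by group-mean TE into
`log2(TE) ≤ −1`, `(−1, 0]`, `(0, 1]`, `> 1` — upper edges inclusive, so
TE = 0.5 falls in the lowest bin and TE = 1 in the second.

## Differential testing

All three contrasts are count-based NB models with median-of-ratios size
factors (library-size factors when fewer than 10 genes are positive in every
sample):

* **Dispersion.** Per gene, a method-of-moments estimate of φ in
  `Var = μ + φμ²` is computed from size-factor-normalized counts, and a
  mean–dispersion trend `φ(μ) = a/μ + b` is fitted across genes by least
  squares. The per-gene estimate is shrunk toward the trend with an
  empirical-Bayes weight: the sampling variance of the MoM estimator (via NB
  cumulants including the fourth-cumulant term, which is not negligible at
  2 × 3 replicates) against the estimated between-gene spread of true
  dispersions around the trend. When dispersions are homogeneous the weight
  collapses to the trend; genuine dispersion outliers keep most of their own
  estimate.

* **Two-group tests (RNA layer, RIBO layer).** The fold change is the group
  coefficient of the NB GLM `count ~ group` with `log(size factor)` offsets
  and the shrunk dispersion plugged in. P-values come from the exact
  conditional NB test on size-factor-adjusted pseudo-counts: conditional on
  the two group totals' sum, the group-1 total has a distribution free of
  the mean, and the two-sided p-value sums all outcome probabilities not
  exceeding the observed one. We use the exact test rather than the
  asymptotic Wald z because, at three replicates per group, the Wald
  reference is measurably anti-conservative (about 6–7% rejections at
  nominal 5% in our null simulations, versus 4.5–6% for the exact test);
  `method = "wald"` is available for comparison. Significance is the usual
  `|log2FC| ≥ 1` and BH FDR < 0.05.

* **TE contrast (DTEGs).** A joint model over both layers,
  `count ~ layer + group + layer:group`, with per-layer offsets; the
  interaction coefficient is the log fold change of TE and is tested by Wald.
  There is no exact analog for the interaction, so this contrast inherits
  the mild small-sample liberality described above — worth remembering when
  interpreting borderline DTEGs.

* **Five-category classification.** With significance defined per contrast,
  genes partition into Homodirection (both significant, same sign), Opposite
  (both, opposite signs), Transcription (first contrast only), Translation
  or TE (second only), and Unchanged. The same classifier serves the
  RNA-vs-RIBO comparison and the RNA-vs-TE comparison. BH adjustment is
  implemented in the package (step-up with enforced monotonicity) and is
  tested against `stats::p.adjust` as an independent reference.

## CDS sequence features by TE bin

For each gene the package reports CDS length, GC content (N excluded from
the denominator), and normalized minimum free energy, then compares the four
TE bins by Kruskal–Wallis followed by pairwise Mann–Whitney with BH
correction, condensed into a compact letter display at α = 0.05
(insert-and-absorb). Nonparametric tests were chosen because all three
features are strongly skewed.

The default folding backend is an internal Nussinov base-pair maximization
(canonical AU/GC/GU pairs, minimum hairpin loop of 3) scored at −1 per pair,
so "MFE" from this backend is a structure-capacity proxy in pair units, not
a thermodynamic energy; the backend tag is recorded in every output, and an
RNAfold backend can be swapped in where ViennaRNA is installed. "Higher
NMFE" always means closer to zero, i.e. less structure. `fold_nmfe()` guards
folding at 3000 nt; the pipeline folds the 5'-most 400 nt of each CDS
(config `fold_max_len`), since exact O(n³) folding of every full-length CDS
is not a desk-scale computation and the 5'-proximal window is where
structure most directly opposes initiation and early elongation.

## uORF analysis

AUG-initiated ORFs with an in-frame stop entirely inside the 5'UTR and a
length (stop included) of at least 9 nt are candidate uORFs; nested in-frame
AUGs sharing a stop collapse to the most 5' start. ORFs that would read
through into the CDS are not counted as uORFs by default. Four scores assess
translation:

* **ORFscore** — `log2(1 + Σ (F_i − F̄)² / F̄)` over P-site counts per frame
  relative to the uORF start, negated when frame 0 is not the strict
  maximum. Default threshold 6 (≈ 32 perfectly phased P-sites).
* **RRS** — P-site density inside the uORF over density in the 5'UTR gap
  between the uORF stop and the CDS start (pseudocount 1 in the gap count;
  gap < 15 nt leaves it undefined). The classic RRS denominator is the
  3'UTR, which has no analog for a uORF; the downstream UTR gap is the
  closest structural substitute. Default threshold 2.
* **Fickett TESTCODE** — codon-position asymmetry `max/(min+1)` and
  composition per base, mapped through the published lookup tables with the
  published weights. Default threshold 0.74, the classic coding cutoff.
  (Exact self-concatenation invariance does not hold because of the +1
  regularizer; scores converge as counts grow.)
* **Hexamer score** — mean natural-log ratio of in-frame hexamer frequencies
  under a coding model (in-frame hexamers of the annotated CDS set) versus a
  noncoding background built by a seeded dinucleotide-preserving shuffle of
  the same CDS set (Altschul–Erikson), smoothing 1e-6. Positive = coding-like.

A uORF is called potentially translated when all four scores pass and its
mean footprint FPKM is at least 1 (uORF FPKM uses P-site counts over uORF
length with the sample's total mapped footprints as library size). A missing
score fails the call: absence of evidence is treated as untranslated, which
is the conservative direction for a discovery flag. The thresholds are
configuration with the stated defaults; published analyses of this kind do
not state theirs, so counts of "translated" uORFs are comparable only within
one threshold setting.

Kozak contexts use the fixed −6…+4 window (A of AUG at +1), padded with N
when clipped at the transcript start; translated and untranslated sets are
compared per position by 4-category chi-square, and the same machinery
compares uORF starts with mORF starts. Distances use the last (most 3')
uORF per gene: `cds_start − uorf_end`, normalized by 5'UTR length — the
normalization basis is a package choice, made so that genes with long UTRs
do not dominate the comparison. The uORF–mORF relation report combines the
Pearson correlation of uORF and mORF footprint log2 fold changes (uORFs with
group-mean FPKM ≥ 1 in at least one group), linear regressions of log2 TE on
uORF length/GC/NMFE, and Kolmogorov–Smirnov comparisons of TE across genes
with no / untranslated / translated uORFs.

## The synthetic-data generator

`simulate_study()` produces the full study shape end to end: 2 groups × 3
replicates, one canonical transcript per gene (5'UTR 100–500 nt, CDS
300–3000 nt, 3'UTR 100–500 nt), NB counts (`Var = μ + φμ²`, default
φ = 0.1) around lognormal gene baselines (median 500, sdlog 0.5 — counts
deep enough that planted |log2FC| = 2 effects are recoverable at three
replicates, as in a well-powered bulk study), footprints with lengths peaked
at 28 and 30 nt, 90% of footprints in the CDS, 90% of CDS P-sites in frame
0, and a global P-site offset of 12 nt that the QC module must recover.
Planted divergence categories (defaults 19% Transcription, 12% Translation,
24% Homodirection, 1% Opposite, 44% Unchanged, signs random) follow the
category semantics of the classifier: Transcription genes shift RNA only
(translationally buffered), Translation genes shift footprints only (these
are also the TE-shifted genes), Homodirection both with one sign, Opposite
both with opposing signs. The Opposite fraction is kept small, mirroring how
rare genuinely anti-directional regulation is in real joint analyses, while
still leaving ~20 genes for recovery checks at the default size.

uORFs are planted into half of the 5'UTRs (51–198 nt, matching the
empirical 50–200 bp range of real uORFs), always leaving ≥ 20 nt of UTR
downstream so that termination — the RRS denominator region — is observable.
Translated-planted uORFs are shorter (≤ 120 nt) and closer to the CDS
(gap ≤ 60 nt), use the coding sequence model, and divert 15% of the gene's
footprints into the uORF with the same frame bias; untranslated-planted
uORFs get flat-composition codons and only ambient UTR reads. The synthetic
coding model draws codons from strongly asymmetric position-specific base
profiles — more asymmetric than real codon usage — so that coding sequence
carries unambiguous positional signal at uORF length scales; this is what
makes Fickett/hexamer separation learnable from 50–200 nt fragments.

What the generator does **not** emulate: multi-isoform genes, alignment and
mapping artifacts, rRNA contamination, codon-level dwell-time variation,
realistic codon usage or amino-acid content, 3'UTR ORFs, and overlapping
uORFs. Consequently, green recovery tests demonstrate that the estimators
are consistent with their own model assumptions at realistic depths — they
do not certify performance on real libraries, where mapping noise and
isoform mixing add error modes the generator omits.

Determinism: one global seed fans out to fixed per-stage substreams
(`stage_seed`), so stages are individually reproducible and two runs of the
pipeline with one seed are byte-identical.

## Numerical and policy choices

* Exact ties in offset estimation resolve toward 12 nt; ties in nested-uORF
  collapse resolve to the most 5' AUG.
* All-zero genes test at p = 1 with log2FC 0 rather than NA, so they stay in
  the BH family.
* GLM fits that do not converge (e.g. a group of all zeros) are refit with a
  0.5 pseudocount and flagged.
* `|log2FC| ≥ 1` is used (not >): boundary genes count as significant.
* Size factors fall back to library-size factors when fewer than 10 genes
  are observed in every sample.
* The demo pipeline (`run_all`) uses 2000 genes and completes in a few
  minutes on one core; its per-stage sizes are stated in the manifest it
  writes.

## Known limitations

The TE interaction test relies on the asymptotic Wald reference and is
slightly liberal at three replicates. The internal folding backend ranks
structure capacity, not free energy; absolute NMFE values are not comparable
with thermodynamic folders. uORF FPKM is computed from P-sites only, so very
short uORFs near the 5' cap can be undercounted when the P-site offset
pushes anchors off the transcript. The hexamer background is trained on the
same transcriptome being scored; for cross-species scoring, train on the
reference of the species under study.
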