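# riboscape

Joint analysis of ribosome profiling (Ribo-seq) and RNA-seq at the
transcript level, for two-group designs with few replicates — the typical
shape of a tissue comparison such as fertile versus hybrid-sterile bovid
testis, three animals per group. The package answers three questions:

1. **Is the footprint data any good?** Length filtering (20–40 nt), region
   occupancy, P-site offset estimation, 3-nt periodicity, sample
   correlation/PCA.
2. **Which genes diverge, and at which layer?** FPKM and translation
   efficiency (TE = FPKM(Ribo)/FPKM(RNA)); negative-binomial tests at the
   RNA, footprint and TE layers; five-category classification
   (Transcription / Translation or TE / Homodirection / Opposite /
   Unchanged) at |log2FC| ≥ 1 and BH FDR < 0.05.
3. **What sequence features track translation?** CDS length, GC and
   normalized minimum free energy across the four log2(TE) bins
   (≤ −1, (−1,0], (0,1], > 1); uORF detection in 5'UTRs with a four-score
   translatability call (ORFscore, ribosome release score, Fickett TESTCODE,
   hexamer log-likelihood), Kozak context and uORF–mORF relation analyses.

## The statistics at the core

Counts are modeled as NB(μ, φ) with Var = μ + φμ² and median-of-ratios size
factors. Per-gene dispersions are method-of-moments estimates shrunk
empirically (NB-cumulant-weighted) toward a fitted mean–dispersion trend
φ(μ) = a/μ + b. Two-group p-values come from the exact conditional NB test,
which stays calibrated at n = 3 per group; fold changes come from the NB GLM
`count ~ group` with log size-factor offsets. Differential TE is the
`layer × group` interaction of the joint two-layer GLM. uORF translation is
scored by

    ORFscore = ± log2(1 + Σᵢ (Fᵢ − F̄)² / F̄),   i ∈ {frame 0, 1, 2}

(positive only when frame 0 is the strict maximum), the in/downstream
P-site density ratio (RRS), the Fickett TESTCODE statistic, and the mean
in-frame hexamer log-likelihood ratio against a dinucleotide-shuffled
background.

A seeded generator (`simulate_study()`) emulates the full study — NB counts
with planted divergence categories, footprints with 28/30-nt length peaks,
90% frame-0 CDS occupancy, a 12-nt P-site offset, and planted
translated/untranslated uORFs — so every stage can be checked against ground
truth.

## Worked example

```r
library(riboscape)

st <- simulate_study(sim_config(n_genes = 2000, seed = 1))

# QC: recover the planted P-site offset and periodicity
offs <- estimate_psite_offsets(st$footprints, st$models)
round(frame_periodicity(st$footprints, st$models, offs)$pooled, 5)
#>      f0      f1      f2
#> 0.90003 0.04994 0.05004

# differential layers and five-category classification
grp    <- factor(st$groups, levels = c("g1", "g2"))
d_rna  <- nb_two_group_test(st$rna,  grp)
d_ribo <- nb_two_group_test(st$ribo, grp)
cls    <- classify_divergence(d_rna, d_ribo)
divergence_summary(cls)$label
#> [1] "Transcription (19.50%, 390)" "Translation (12.10%, 242)"
#> [3] "Homodirection (23.75%, 475)" "Opposite (1.25%, 25)"
#> [5] "Unchanged (43.40%, 868)"

mean(as.character(cls$category) ==
       st$truth$category[match(cls$gene_id, st$truth$gene_id)])
#> [1] 0.987
```

The pooled frame fractions show the high–low–low periodicity of genuine
translation (the generator plants 90% frame-0 occupancy, and the QC recovers
it); the five-category labels recover 98.7% of the planted assignments, with
Opposite the rarest class — as it is in real joint analyses. The whole
pipeline, including CDS-feature and uORF stages plus all file outputs and a
run manifest, is one call:

```r
run_all("out/", seed = 1)          # ~2 min for the 2000-gene demo
```

A thin CLI wrapper for shell use ships at `inst/cli/riboscape.R`
(`Rscript riboscape.R all --outdir out --seed 1`).

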