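# titinpsi

Exon-level alternative-splicing analysis of titin and decomposition of
muscle passive stress into titin-based and collagen-based components.

## What this is for

Titin is the giant (~4.2 MDa) sarcomeric spring protein; which of its
PEVK and Z-repeat exons a muscle splices into the transcript pool sets the
isoform's contour length and hence the muscle's passive stiffness. In the
*mdm* mouse — a small deletion at titin's N2A–PEVK boundary that causes
severe muscular dystrophy with high passive tension — both altered titin
splicing and increased collagen are in play. This package implements the
computational pipeline for studies of that kind, for people working with
RNA-seq of a single giant transcript and skinned-fiber mechanics:

- **Transcript model / counting bins** — load one transcript from
  GTF/GFF3/TSV, split exons into counting bins at observed junction
  boundaries (with `_hang` bins for read-supported segments outside
  annotated exon edges), query named domain regions (Z-repeats, PEVK I–III,
  M-band exons).
- **PSI quantification** — classify spliced alignments (BAM/SAM or tabular
  counts) into per-bin inclusion/exclusion evidence and compute
  percent-spliced-in, ψ = (I/P_I) / (I/P_I + E/P_E), with
  placement-count normalization and a support threshold.
- **Group comparison** — per-muscle ΔPSI = mean(mdm) − mean(WT) with the
  small-sample pooled SD
  √[((n₁−1)s₁² + (n₂−1)s₂²)/(n₁+n₂−2)], per-bin two-way
  genotype × muscle ANOVA (Type III, sum contrasts), and Holm
  (sequential Bonferroni) correction.
- **PEVK mass estimation** — minimum / maximum / PSI-weighted (Σ mᵢψᵢ)
  mass of an exon range, from sequence-derived or user-supplied per-exon
  masses.
- **Amplicon prediction** — the gel ladder of a splice-variant PCR assay
  (all subset sums of the optional exons plus the flank).
- **Mechanics** — steady-state stress (force / cylindrical
  cross-sectional area) from ramp-and-hold traces (SL 2.6 → 3.0 µm,
  60 s hold), and the serial trypsin / KCl / KI extraction decomposition:
  collagen-based = residual after all treatments, titin-based = control −
  residual, summing to the total exactly.
- **Simulators** — beta-binomial junction counts and ramp-and-hold stress
  traces with known truth, so the whole pipeline is testable without raw
  data.

See the vignette in `vignettes/titin-splicing-mechanics.Rmd` for the
methods, modelling assumptions, and design choices.

## Worked example

Simulate splice counts under the default titin profile (PEVK exons down in
mdm, Z-repeat exons up in mdm fast muscles), quantify PSI, and compare
genotypes:

```r
library(titinpsi)

profile <- default_titin_psi_profile()
sim <- simulate_splice_counts(splice_sim_config(
  profile, junction_coverage = 1000, overdispersion = 0.01,
  n_per_group = 4, seed = 42))

model <- gene_model("demo", data.frame(
  exon_index = 1:400, start0 = (0:399) * 300, end0 = (0:399) * 300 + 150))
model$bins <- model$bins[model$bins$bin_id %in% unique(profile$bin_id), ]

tab <- build_psi_table(sim$counts, model, sim$metadata)
res <- compare_splicing(tab, alpha = 0.05)
head(subset(res, muscle == "EDL"), 8)
#>    bin_id muscle   dpsi sd_pooled n_mut n_ref  p_value p_adjusted significant
#> 1      12    EDL  0.406    0.0278     4     4 6.15e-12   6.77e-11        TRUE
#> 4     124    EDL -0.309    0.0366     4     4 9.96e-12   9.96e-11        TRUE
#> 7     125    EDL -0.337    0.0438     4     4 6.29e-11   5.03e-10        TRUE
#> 10    126    EDL -0.359    0.0262     4     4 2.19e-12   2.84e-11        TRUE
```

Negative ΔPSI means the exon is included more in wild type: the injected
PEVK exclusion in mdm EDL (true ΔPSI −0.35) is recovered with the right
sign and magnitude, and the Z-repeat exon 12 shift (+0.4) likewise;
`p_adjusted` is the Holm-corrected genotype effect from the per-bin ANOVA.

Mechanics — simulate bundles at the study's group sizes and decompose:

```r
mech <- simulate_fiber_bundles(mech_sim_config(seed = 42))
out <- analyze_fiber_bundles(mech$traces, mech$bundles)
group_stress_summary(out$decomposition, mech$bundles)$summary
#>        component genotype  n  mean    sd
#> 1   total_stress      mdm 20 26.96 0.645
#> 2   total_stress       WT 21 12.73 1.420
#> 3   post_trypsin      mdm 20 15.98 0.385
#> 4   post_trypsin       WT 21  8.04 0.899
#> 5 collagen_based      mdm 20  6.59 0.159
#> 6 collagen_based       WT 21  2.45 0.269
#> 7    titin_based      mdm 20 20.37 0.487
#> 8    titin_based       WT 21 10.29 1.151
```

Units are mN/mm². The decomposition conserves stress exactly
(titin_based + collagen_based = total_stress per bundle), and the recovered
group means sit at the configured study-level values (mdm ≈ 27 vs WT ≈ 13
total; ≈ 20.4 vs ≈ 10.5 titin-based).

The Z-repeat PCR assay ladder:

```r
predict_amplicons(amplicon_design(185, c(138, 138, 138)))
#>   included_exons length_bp
#> 1              3       599
#> 2              2       461
#> 3              1       323
#> 4              0       185
```

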