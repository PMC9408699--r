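---
title: "Methods: exon-level titin splicing and passive-stress decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exon-level titin splicing and passive-stress decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titinpsi)
```

## The scientific problem

Titin is the ~4.2 MDa sarcomeric spring whose I-band region (tandem Ig
domains plus the intrinsically disordered PEVK segment) sets the passive
tension of striated muscle. Which PEVK and Z-repeat exons a muscle splices
into its titin transcripts determines the isoform's contour length and
therefore its stiffness. The *mdm* (muscular dystrophy with myositis)
mutation deletes 83 residues at titin's N2A–PEVK boundary and produces
muscles with abnormally high passive tension; two mechanisms can contribute:
altered titin splicing (shorter, stiffer isoforms) and increased collagen.

This package implements both halves of the analysis needed to separate
those mechanisms:

1. **Splicing**: exon-level percent-spliced-in (PSI) quantification of one
   transcript from spliced RNA-seq alignments, group comparison (ΔPSI,
   pooled SD, two-way ANOVA, Holm correction), PSI-weighted mass estimation
   of the PEVK segment, and amplicon-ladder prediction for confirmatory
   splice-variant PCR.
2. **Mechanics**: decomposition of skinned-fiber passive stress into
   titin-based and collagen-based components via serial trypsin / KCl / KI
   extraction.

Because the study's raw reads and per-bundle force traces are not publicly
deposited, the package ships simulators that generate data with the
statistical structure the analysis assumes, calibrated to the study's
group-level conditions. Everything downstream of raw data is computable and
tested.

## The transcript model and counting bins

A `gene_model` holds the ordered exons of one transcript (for mouse titin,
the 347-exon Ensembl transcript; any GTF/GFF3 or TSV exon table works).
Coordinates are 0-based half-open internally and 1-based inclusive at every
I/O boundary; exon 1 is the 5' exon in transcript orientation, so on the
minus strand (as for mouse *Ttn*) it is the genomically last exon. Named
domain regions default to Z-repeats = exons 10–14, PEVKI = 112–135,
PEVKII = 136–155, PEVKIII = 156–209, M-band exons = 342–347. Two presets
exist for the PEVKI start (112 from the structural segmentation, 113 from
the statistical analysis); both conventions are in circulation for this
transcript and we take no position, defaulting to 112 with adjacent regions
made non-overlapping.

The unit of quantification is the **counting bin**. Annotated exons are
split at observed splice-junction boundaries: a junction donor/acceptor
falling strictly inside an exon splits it into `.1`, `.2`, ... sub-bins
(numbered in transcript order), and a boundary falling outside every
annotated exon implies unannotated exonic sequence contiguous with the
nearest exon, which becomes a `_hang` bin. Only junctions with at least
`min_junction_reads` supporting reads (default 3) split the model; this
makes the binning a deterministic function of the annotation and the
observed junction set rather than of read-density heuristics. When two
junction boundaries extend into the same intronic gap from both sides, the
later interval is clipped at the earlier one's end so that bins never
overlap. `_hang` bins are excluded from exon-level tiling (the non-hang
bins of an exon always sum to the exon length) and are reported like any
other bin; whether to include them in region-level averages is left to the
analyst.

## PSI quantification

For each bin, a read is **inclusion** evidence when one of its aligned
blocks overlaps the bin, and **exclusion** evidence when one of its splice
junctions (CIGAR `N` gaps) spans the entire bin. A read contributes to a
bin at most once, and only primary, mapped, non-duplicate alignments with
`MAPQ >= 10` are counted (both thresholds configurable). PSI is

$$\psi = \frac{I/P_I}{I/P_I + E/P_E}$$

where $I, E$ are the inclusion and exclusion counts and $P_I, P_E$ the
*position* denominators: the number of distinct read placements that could
generate each class ($P_I = \text{bin length} + L - 1$,
$P_E = L - 1$ for aligned read length $L$). This normalization corrects
the length advantage of body reads over junction reads. A `raw` mode sets
both denominators to 1; the two agree whenever the evidence classes have
equal placement counts. PSI is reported as missing when total support
$I + E$ falls below `min_support` (default 10) — at lower support the
ratio's sampling error exceeds any effect size of interest here.

The classifier is verified against a brute-force per-read oracle (an
independent hand-written CIGAR walker that enumerates every read against
every bin) on hundreds of random toy fixtures; the two agree exactly.

## Group comparison

ΔPSI is the mean mutant PSI minus the mean wild-type PSI per bin, computed
separately for each muscle, so negative values mean higher inclusion in
wild type. The attached spread is the degrees-of-freedom-weighted pooled SD

$$SD = \sqrt{\frac{(n_1 - 1)s_1^2 + (n_2 - 1)s_2^2}{n_1 + n_2 - 2}}$$

appropriate for the small group sizes (3–5 samples) typical of such
designs.

Per-bin inference uses a two-way factorial ANOVA (genotype × muscle) on the
non-missing PSI values. The original analysis was run in JMP, whose
factorial default is Type III sums of squares; we fix **Type III with
sum-to-zero contrasts** and document it, since with unbalanced groups the
SS type matters. The implementation (an `lm` fit passed to `car::Anova`)
is tested to 1e-8 against a direct design-matrix least-squares oracle and
holds its nominal type-I error in null simulations. Missing PSI cells are
dropped listwise per bin — no imputation, given the small n.

Multiple testing uses the Holm step-down ("sequential Bonferroni")
procedure: sort the m p-values ascending and set
$p^{adj}_{(i)} = \max_{j \le i} \min\{1, (m - j + 1)\, p_{(j)}\}$. The
family size defaults to the number of tested bins but is exposed as a
parameter: the original analysis corrected across "142 transcripts", a
count we could not reconstruct exactly from the printed region bounds
(counting bins rather than exons may have been the unit), so we prefer an
explicit parameter over a guess.

## PEVK mass estimation

Given per-exon masses and group-level PSI, the expressed mass of an exon
range is estimated three ways: **minimum** (only exons with PSI = 1),
**maximum** (every exon with PSI > 0), and the **PSI-weighted**
intermediate $\sum_k m_k \psi_k$, which treats PSI as each exon's
inclusion probability and is the expectation of the segment mass under
independent inclusion (verified against a $2^K$-pattern enumeration
oracle). Comparing an estimated PSI with exact 0 or 1 is ill-posed in
floating point, so values within `psi_tolerance` (default 0.005) of the
endpoints are snapped to exactly 0/1 *before all three estimators*; this
preserves the ordering min ≤ weighted ≤ max for every PSI vector, which a
threshold-only rule would violate inside the tolerance band.

Per-exon masses can be supplied as a TSV (to reproduce any external mass
convention) or derived from the coding sequence using standard average
residue masses, residue masses only (no terminal water) so masses are
additive over exon ranges; codons spanning exon boundaries are apportioned
pro rata by nucleotide count. The published kDa figures for the PEVK
region do not state their mass convention, which is why the estimator and
the mass table are deliberately decoupled.

## Amplicon prediction

For a PCR assay whose primers flank a run of optional exons,
`predict_amplicons()` enumerates all subsets of the optional exons and
returns one product length per distinct subset sum. With the Z-repeat
assay's geometry (185 bp flank, three 138-bp exons) this gives the
599 / 461 / 323 / 185 bp gel ladder.

## Passive-stress decomposition

Stress is force over cross-sectional area, with the bundle treated as a
cylinder measured by its diameter. Steady-state stress of a ramp-and-hold
record (sarcomere length 2.6 → 3.0 µm at 0.04 µm/s, 60 s isometric hold)
is the mean of force/area over the **final 5 s** of the hold; the protocol
specifies only "until steady state", and 5 s is long relative to the
sampling noise yet an order of magnitude past the stress-relaxation time
constant, where the remaining transient is O(1e-5) of its initial
amplitude. The hold is detected as the trailing run of samples with
|SL − 3.0| ≤ 0.01 µm, matching the scale of SL-tracking resolution.

The decomposition follows the serial-extraction logic: trypsin
preferentially degrades the lysine-rich PEVK and hence titin; KCl and KI
then depolymerize the thick and thin filaments, removing titin's anchors.
The stress remaining after all three treatments is **collagen-based**; the
**titin-based** stress is control minus that residual, so the two
components sum to the total exactly by construction. Bundles whose stress
*increases* along the extraction sequence are flagged, never clipped, and
negative components are reported as-is — truncation at zero would bias
group means upward.

Group statistics use the bundle as the unit with a plain Welch test per
component. The original analysis Box–Cox-transformed the data and added a
random effect of muscle nested in genotype; those are standard model fits
orthogonal to the decomposition itself, and with simulated bundles there
is no muscle-level clustering to absorb, so we document the substitution
rather than reproduce it.

## What the simulators emulate — and what they do not

**Splice counts.** Per bin and sample, total junction-informative reads are
Poisson(coverage) and inclusion reads beta-binomial with mean ψ and
intra-class correlation ρ (binomial at ρ = 0). The beta-binomial is the
standard overdispersion model for inclusion ratios; ρ defaults to 0.01,
a mild biological replicate effect. The default true-PSI profile encodes
the qualitative pattern of the study as generator inputs: PEVK exons
124–127, 133–134, 138–145 shifted down in mdm (EDL and soleus; only
138–139 in psoas), Z-repeat exons 12–13 shifted up in mdm fast muscles,
and Mex5 (exon 346) at its reported group levels. Defaults use 4 samples
per group (within the study's 3–5) and coverage 1000.

The simulator does **not** model read-level effects: sequencing error,
mapping ambiguity, positional coverage bias, or paired-end fragment
geometry. Tests passing on simulated counts therefore validate the
estimator and the downstream statistics, not the upstream aligner; the
alignment-facing classifier is instead validated exactly against the
brute-force oracle on synthetic alignments.

**Fiber bundles.** Per bundle, total steady stress is drawn from the
genotype's truncated normal — mdm N(27.0, 0.97), WT N(13.0, 2.14) mN/mm²,
n = 20/21, the study's reported conditions. The collagen share is
1 − titin_fraction (titin fractions 20.4/27.0 and 10.5/13.0), and the
trypsin-resistant titin fractions are set so post-trypsin steady stresses
average 16.1 (mdm) and 8.3 (WT). Each condition is rendered as a ramp to a
peak of 1.4× the steady stress followed by exponential relaxation
(τ = 5 s) — values in the range typical for skinned-fiber stress
relaxation, not printed in the study — with Gaussian stress noise
(SD 0.2 mN/mm²) at 50 Hz and diameters uniform on 150–250 µm (a plausible
range for 4–5-fiber bundles). Because the relaxation transient is
multiplicative in the steady stress, the noise-free pipeline recovers the
configured titin fraction exactly; with noise, recovery of the group mean
is within 0.02 at n = 50.

The mechanics simulator does not model within-muscle correlation between
bundles, slow drift, fiber run-down across the four sequential stretches,
or incomplete extraction beyond the single trypsin-resistant fraction.

## Numerical choices and degenerate inputs

- PSI with support below `min_support` is `NA`, and `NA` propagates
  explicitly (dropped from group n, missing in Holm input without
  shrinking the declared family size if one is given).
- `pooled_sd` refuses n1 + n2 ≤ 2; single-sample groups carry SD 0 and a
  flag rather than `NA`, matching their use as point estimates.
- ANOVA requires two observed levels of each factor and returns `NULL`
  for all-missing bins.
- Bin splitting uses integer genomic coordinates throughout; ties (a
  junction boundary coinciding with an annotated exon edge) are no-ops.
- Zero-length exons, non-positive diameters, non-increasing time vectors,
  and missing treatment states are hard errors, not warnings.

## Problem sizes used by the test suite

The shipped tests run the classifier–oracle comparison on 100 random
fixtures of ≤ 5 exons and ≤ 200 reads, PSI recovery on 100 seeded
replicates of a 6-bin two-group design at coverage 1000, the estimator
ordering on 10,000 random PSI vectors, ANOVA against its least-squares
oracle on 100 unbalanced datasets plus a 1000-replicate null, and the
mechanics pipeline at the study's bundle counts — sizes chosen to give
stable Monte-Carlo margins while keeping the default suite fast.

## Known limitations

- PSI here is bin-marginal, not isoform-resolved; linked inclusion of
  distant exons on the same molecule is invisible at 75-bp read scale.
- The position-count normalization is one member of a family of
  Schafer-style corrections; with strongly non-uniform coverage the
  relative weighting of body and junction evidence shifts.
- The PEVK mass estimates inherit whatever convention the supplied mass
  table uses; sequence-derived masses assume full-length in-frame coding.
- The titin/collagen partition attributes *all* non-extractable stress to
  collagen; residual non-collagen structures (e.g. intermediate filaments)
  are folded into that term, as in the underlying experimental logic.
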