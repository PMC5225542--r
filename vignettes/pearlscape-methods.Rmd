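---
title: "Methods: seascape genomics and larval dispersal with pearlscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seascape genomics and larval dispersal with pearlscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pearlscape)
```

pearlscape is a single pipeline for range-wide seascape genomics of a
broadcast-spawning marine invertebrate: reduced-representation SNP
genotypes scored 0/1/2 (reference homozygote / alternate homozygote /
heterozygote) move through a quality-control cascade, population-genetic
diversity and structure statistics, a simulation-based F~ST~-outlier
scan, and — independently of the genetics — a Lagrangian larval-dispersal
simulation over gridded daily surface currents. This vignette records the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The genotype model and the synthetic generator

`simulate_genotypes()` draws data from a hierarchical island model. Per
base locus an ancestral frequency is uniform on [0.05, 0.95]; each
region (ocean basin) draws its frequency from a Balding–Nichols beta
around the ancestral value,

$$p_r \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right),$$

with dispersion `fst_between_regions`; each population draws likewise
around its region value with `fst_within_region`. Genotypes are drawn
with inbreeding: P(het) = 2pq(1 − F~IS~). Directional outlier loci use
the population-level dispersion multiplied by `outlier_fst_multiplier`;
balancing outliers use a near-zero dispersion at both levels. Missing
calls, clone-duplicate locus columns (sharing a clone id, with extra
missingness and genotyping error so the original column is the
better-quality member) and replicated individuals (with per-call
discordance `genotyping_error_rate`) are injected afterwards.

Defaults mirror the pearl-oyster survey the package is designed around:
two basins holding 4 and 10 populations at the survey's per-site sample
sizes (580 individuals in total), 11,587 base loci with a
clone-duplicate rate of 0.697 so that the raw matrix holds ~19.7k
columns and de-duplication discards ~41% of them, 15% of individuals
replicated, F~IS~ = 0.6 and a between-basin F~ST~ of 0.18 — the scale of
the published diversity and AMOVA results. Values the study leaves open
were fixed once at what we consider realistic for DArT-style marine
invertebrate data: a 10% missing-call rate, 1% genotyping error
(comfortably above the 95% repeatability filter for intact loci), and a
5x dispersion multiplier for planted directional outliers. The
generator reproduces the *statistical* structure the analyses assume —
it does not emulate linkage, allele-frequency spectra from a real site
ascertainment, batch effects, or isolation-by-distance within regions,
so passing parameter-recovery tests demonstrates correctness of the
estimators under the island model, not robustness to every feature of
real data.

## The QC cascade

`filter_cascade()` applies, in order: clone de-duplication (one SNP per
clone id: highest call rate, then highest MAF, then lowest input
position), call rate ≥ 0.65, PIC ≥ 0.01 with
PIC = 1 − (p² + q²) − 2p²q², MAF ≥ 0.02, replicate-based repeatability
≥ 0.95, removal of loci deviating from Hardy–Weinberg equilibrium,
removal of monomorphic loci, and pruning of one member of each
significantly linked pair. Every step appends a row to an accounting
ledger obeying `loci_in = loci_removed + loci_out`.

* **HWE.** The exact test works on Levene's conditional distribution of
  the heterozygote count given the allele counts; the p-value is the
  total mass of configurations no more probable than the one observed.
  Full enumeration is used whenever the minor-allele count is ≤ 100;
  beyond that a Metropolis chain on the heterozygote count (steps of
  ±2, Levene mass ratios) runs for 10,000 steps after 100,000
  dememorisation updates. Multiple testing is controlled by
  Benjamini–Hochberg across loci within each population, and a locus is
  removed when significant in all populations by default
  (`hwe_min_pops`), the most conservative pooling choice.
* **LD.** The genotypic test uses the G statistic on the 3×3 genotype
  table with a permutation null; the default significance level is
  10^-4^ at 10,000 permutations. Screening all O(L²) pairs is
  quadratic, so the cascade tests a seeded random sample of at most
  `ld_max_pairs` (default 10^5^) pairs; from each significant pair the
  lower-call-rate member is removed (ties to the higher index).

## Diversity and structure statistics

H~o~ is the mean heterozygote fraction over loci; H~n.b.~ applies the
2n/(2n − 1) small-sample correction per locus. F~IS~ is the
Weir–Cockerham within-population f, multilocus as one minus the ratio of
summed variance components. A = 1 + (fraction of loci polymorphic in the
population); Ar is the fraction of loci with within-population MAF in
(0, 0.05) — the "rare allelic richness" — reported because the rare tail
responds to bottlenecks before H~o~ does. Private alleles (Ap) count
(locus, allele) pairs seen in exactly one group, raw by default, with
hypergeometric rarefaction to the smallest group's gene count available
behind `rarefy = TRUE`. Individual metrics: MLH, HL (2pq-weighted
homozygosity), SH and IR follow their standard definitions; SH's
denominator is the mean observed heterozygosity of the loci the
individual is typed at (the expected-heterozygosity variant sits behind
`sh_method = "expected"` because the reference implementation's exact
normalisation is ambiguous).

Pairwise differentiation is Weir–Cockerham θ (ratio of summed
components), with significance from shuffling individuals between the
pair. Nei's standard genetic distance uses the unbiased 1978
homozygosity estimators. The hierarchical AMOVA partitions
allele-indicator variance over four nested levels (regions, populations,
individuals, within-individual) with unbalanced-design coefficients
computed per locus and components summed across loci; negative
components are reported as computed, and permutation p-values use
level-appropriate schemes (populations among regions; individuals among
populations within regions; allele re-pairing within populations).
Mantel tests regress raw F~ST~ on raw great-circle kilometres
(haversine, R = 6,371 km) with joint row/column permutation — no
linearisation is applied because the differentiation–distance
relationship is reported on the raw scales. Directional relative
migration compares each member of a pair against their hypothetical
pooled population via Nei's G~ST~: the receiving population of a strong
migration stream resembles the pool, so its G~ST~ against the pool is
small and the inbound estimate large; the matrix is normalised to a
maximum of 1 and bootstrap over individuals flags asymmetries whose
interval excludes zero.

Fine-scale structure uses 1 − psa (one minus the proportion of shared
alleles) between individuals, mutual k-nearest-neighbour graphs (an edge
requires membership in both neighbourhoods; ties break to the lower
index), and hand-rolled Saitou–Nei neighbour joining with deterministic
tie-breaking. Negative NJ branch lengths are clamped to zero with the
deficit transferred to the sister branch, preserving the joined pair's
path length, so additive matrices are reproduced exactly.

## Effective population size by linkage disequilibrium

`ne_ld()` averages the squared Pearson genotypic correlation over locus
pairs (excluding same-clone pairs and loci at MAF ≤ 0.02), subtracts the
sampling expectation, and back-transforms to Ne. Two calibration facts
drive the numerical choices, both established with forward Wright–Fisher
simulations (`simulate_wright_fisher()`):

* the drift component of the mean r² for unlinked loci is 1/(3Ne), and
* the sampling-noise expectation of this estimator is 1/(S − 1) — the
  exact null for a squared Pearson correlation — rather than the
  1/S-family coefficients published for the composite-disequilibrium
  estimator, which over-subtract here and bias Ne upward.

So `correction = "waples"` pairs the 1/(S − 1) null with the
random-mating quadratic back-transform (which absorbs the second-order
drift term), while `correction = "simple"` keeps the textbook
E(r²) = 1/S and Ne = 1/(3 r²_adj) closed form. A non-positive corrected
r² reports Ne = ∞, as printed for several wild populations in this
study system.

Confidence intervals default to a delete-one-individual jackknife on
r-bar², converted through a chi-square with moment-matched effective
degrees of freedom. The parametric alternative (`ci = "pairs"`) uses the
raw number of locus pairs as the degrees of freedom; with thousands of
loci the pairs share loci and are strongly dependent, which makes that
interval vanishingly narrow and its coverage near zero — it is retained
only for comparison with older software. The jackknife interval covers
a true Ne of 100 in ≥ 90% of replicates at 50 samples and 1,000 loci.

## The outlier scan

The scan conditions on heterozygosity in the FDIST tradition but with an
explicit, declared null: `simulate_null()` draws an island-model cloud
of (He, θ) at the observed sample sizes, iteratively recalibrating the
beta dispersion until the realised multilocus θ is within 3% of the
target (the data's own multilocus θ by default). Observed loci receive
empirical tail probabilities within 20 He-quantile bands of the cloud
(add-one counting so p is never zero), Benjamini–Hochberg control is
applied per tail, and the full FDR ladder
{0.001, 0.005, 0.01, 0.05, 0.1, 0.2} is reported. The neutral/adaptive
split defaults to the 0.01 working level and adaptive classification to
0.05, the two levels used in the study workflow this replaces — the
original used two external detectors whose intersection is not
reproducible from a single declared null, so single-detector counts are
not expected to match published joint counts. QQ verification implements
the two-plot rule: a p-value set "deviates" when more than 5% of points
leave the pointwise 95% beta order-statistic band, and detection is
confirmed when the outlier-removed replot is clean.

A note on power: because planted directional outliers draw their
population frequencies from a beta with multiplied dispersion, a
fraction of them realise low differentiation and are statistically
indistinguishable from neutral loci. With 8 populations of 40 and a 5x
multiplier the detector recovers the clear majority of planted loci and
ranks them with AUC > 0.9, but no detector can reach very high recall
under this planting scheme; oracle experiments with the true null put
the ceiling near 65–70%.

## The dispersal model

Particle displacement per step is Δx = u~p~Δt + K: forward Euler on the
bilinearly interpolated surface current plus a random-walk
eddy-diffusivity kick

$$K = \sqrt{-4E_h\,\Delta t\,\log(1 - R_{NA})}\;\cos(2\pi R_{NB})$$

per axis with independent uniform draws on [0, 1). The uniform draw is
required by the log(1 − R) form (a normal draw would leave the
expression undefined); the resulting per-axis displacement variance is
2E~h~Δt, which the tests verify to 2% at 10⁶ draws. Defaults follow the
study protocol: Δt = 1 h, E~h~ = 5 m²s⁻¹, 25,600 particles per seed
region per day for 14 days, 90-day runs with snapshots at the
configured extraction days. Temporal interpolation is linear between
daily fields; spatial interpolation is bilinear with land corners given
zero weight and the rest renormalised (all-land cells yield zero
velocity). Degrees↔metres conversion is local equirectangular
(111,320 m per degree latitude, × cos(lat) in longitude); per-step
displacements are far below a grid cell so curvature error is
negligible. A particle whose destination is a land cell stays put for
that step by default (`beaching = "freeze"` deactivates it instead);
one leaving the grid is deactivated and never moves again. Only surface
currents act — no vertical motion, mortality, swimming or settlement
competency. Randomness comes from one seeded R stream consumed in a
fixed order, so a fixed seed reproduces trajectories exactly.

Current fields are in-memory `current_field` objects with a plain-text
(CSV + JSON) serialisation; the analytic generators (`uniform`,
`solid_body`, `double_gyre`) retain their closed form in the metadata so
trajectories can be checked against exact orbits. Forward Euler is
first-order: a solid-body orbit at Δt = 360 s drifts in radius by under
1% over 10 days (the drift grows as T·ω²·Δt/2), which is the accuracy
regime the hourly default occupies for mesoscale flows.

Connectivity matrices report, per source region, the fraction of seeded
particles inside each sink polygon at a snapshot; denominators use all
seeded particles by default so deactivated particles count as
unconnected (an `"active"` denominator is available).

## Problem sizes used in the tests

The shipped test-suite and acceptance script run at reduced but
statistically meaningful scales chosen so every property remains
informative: parameter recovery at 2 × 100 individuals × 5,000 loci;
AMOVA recovery at 6 × 40 × 2,000; a 50,000-locus outlier null; Ne
coverage over 50 Wright–Fisher replicates of 50 × 1,000; 10⁶
diffusivity draws; a 2,400-step orbit. The full study scale (19.7k raw
loci × 580 + replicates) is the generator default and runs the same
code paths.

## Known limitations

Monte-Carlo LD screening of a sampled pair subset can miss linked pairs
that exhaustive screening would find; the HWE chain p-value carries
Monte-Carlo error of order 1/√steps; the AMOVA treats missing calls by
per-locus exclusion with per-locus design coefficients, which differs
slightly from listwise deletion when missingness is very uneven; the
migration network's bootstrap flags asymmetry, not absolute rate
significance; and the dispersal model is a surface-only, first-order
scheme — adequate for connectivity patterns, not for resolving
sub-grid coastal processes.
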