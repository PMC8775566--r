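---
title: "Mapping genotype- and age-specific drug response in inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genotype- and age-specific drug response in inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensigwas)
```

## The problem and the design

Inbred line panels such as the *Drosophila* Genetic Reference Panel make
each genotype measurable many times. `sensigwas` targets the resulting
factorial design: `n` fully inbred lines, each measured in a control and a
treated condition at two (or more) ages, with replicate individuals per
line x age x treatment cell, assay blocks nested within age, and body mass
recorded per individual as a nuisance covariate. The quantity of interest
is not only where genetic variation in the trait lies, but where genetic
variation in the *response to treatment* lies — and whether those are the
same loci.

## Models and estimators

**Full ANCOVA.** All records enter
`y = c + m + g + t + a + g:t + g:a + t:a + g:t:a + b(a) + e`
(`m` mass, `g` line, `t` treatment, `a` age, `b(a)` block within age).
`fit_full_ancova()` reports partial (Type III-style) F tests: each term's
sum of squares is the increase in residual SS when the term's sum-coded,
non-aliased columns are removed from the full model matrix, computed by QR
refits. This makes the tests order-independent; on a balanced design they
coincide with sequential tests, which the test suite asserts. The nested
block term is coded as per-age block contrasts (`age:block_f`) so that the
age main effect is never aliased by block indicators. Interactions of mass
with design factors are not modelled: the covariate enters with a single
common slope.

**Line means.** Within each age x treatment stratum,
`ls_line_means()` fits `value ~ mass + line + block` and reports each
line's prediction at the stratum grand-mean mass, averaging block effects
with equal weight — the standard least-squares (adjusted) mean. These are
invariant to translating mass or relabelling blocks. The worked two-line
example with masses (1,2)/(2,3) and values (1,2)/(4,5) gives a common
slope of 1 and adjusted means (2.0, 4.0) at the grand-mean mass 2.0.
If mass is constant the slope is dropped. `emmeans` reproduces these
values in the test suite; the internal implementation keeps the prediction
machinery explicit (a contrast matrix over the line x block grid) because
the simulation-based checks call it hundreds of times.

**Variance components.** `variance_components()` first removes the mass
slope (estimated with line in the model, so it is the within-line slope),
then applies the one-way method of moments:
`sigma2_error = MS_within`, `sigma2_line = (MS_between − MS_within)/n0`
with `n0 = (N − Σn_i²/N)/(k−1)`. Negative estimates are truncated at zero
for reporting but the raw value is retained, since downstream correlations
must know when a component is genuinely zero. REML would give similar
answers on these balanced designs but hides the moment structure the
worked examples pin down; the method-of-moments choice keeps the estimator
auditable against hand calculations such as the two-line case
({0,2},{4,6} → `sigma2_line = 7`, `sigma2_error = 2`).

**Genetic correlations.** `genetic_correlation()` divides the line-mean
covariance between two strata (unbiased `n−1` denominator, shared lines
only) by the product of the square roots of the truncated among-line
components. Because numerator and denominator are estimated from
different statistics, `|r|` can exceed 1; the estimate is flagged, never
clamped, and set undefined when a component is zero. With a 2 x 2 design
the pipeline labels the four canonical correlations `rGT1`, `rGT5`
(across treatments within each age) and `rGAC`, `rGAL` (across ages
within each treatment).

**Sensitivity index.** For each line at one age,
`S_i = d_i / D̄` with `d_i` the treated-minus-control difference of the
line's means and `D̄` the average of `d_j` over lines having both means.
Lines missing a treatment are excluded from numerator *and* denominator,
preserving the exact identity `mean(S) = 1`. The index is dimensionless
and invariant to scaling or shifting the phenotype. By default it is
computed on mass-adjusted LS-means so the GWA phenotypes stay
commensurable with the trait scans; `line_means_all(adjust = "raw")`
exposes the unadjusted alternative. A panel response `|D̄|` below
tolerance raises an explicit error rather than returning infinities.

**Marker tests.** Line-level phenotypes are regressed on the 0/1 inbred
genotype: the effect is the difference of class means and the p-value a
two-sided t with `n−2` df. The sensitivity scan adds the line's trait
value as a cofactor and reports the partial genotype test (`n−3` df), so
a variant must explain sensitivity variation *beyond* what its trait
effect predicts. Variants that are monomorphic or whose minor class holds
fewer than four lines (configurable) are reported as skipped, never given
a p-value; missing genotypes are dropped per variant. The trait scan is
fully vectorised (closed-form class-mean algebra over the genotype
matrix), which is what makes the two-million-test calibration run
practical; the cofactor scan uses a residualisation fast path with a
per-variant refit fallback when genotypes are missing.

**Candidates, genes, networks.** Candidate variants use strict
`p < 1e-5`; genes are assigned when a variant lies inside the gene or
strictly closer than 5000 bp to a boundary (a variant may hit several
genes). For network analysis the gene list is rebuilt at the stricter
`p < 1e-6`, combining control and treated candidates within an age.
Subnetworks over the global interaction graph admit one non-candidate
bridge gene between candidates: a bridge must be adjacent to at least two
mapped candidates, and bridge–bridge edges are excluded (two consecutive
non-candidates would exceed the one-gene allowance). The largest
subnetwork size (candidates plus bridges) is compared against `N = 1000`
uniform draws of the same number of mappable genes,
`p = (A + 1)/(N + 1)`, ties counting toward `A`. Hubs are nodes with more
than ten connections, counted within the subnetwork by default (a
`scope = "global"` switch is provided, since either reading of
"connections in the network" is defensible).

## The synthetic-data generator

`sim_config()` defaults describe the emulated study: 126 inbred lines,
30 flies per line x age x treatment cell, two ages and two treatments,
two blocks per age, and a mass covariate (mean 0.8 mg, SD 0.08 mg —
typical for adult male flies; mass is genotype-independent unless the
`mass_line_sd` knob is raised). Genotypes are independent biallelic sites
with frequencies uniform on the configured range; inbred lines carry one
homozygous class per site, coded 0/1. Phenotypes follow the full ANCOVA
model with independent normal deviations for line, line x age,
line x treatment, and line x age x treatment at configured variances.
The trait-unit variance defaults (line 1.0, interactions 0.15–0.3,
block 0.2, residual 4.0) put broad-sense heritability of a line mean near
0.9 with among-fly noise dominating single measurements, the familiar
regime for behavioural assays. Causal trait variants add their effect to
the line main effect; causal sensitivity variants add it to the
line x treatment deviation of the treated condition only, so planted
sensitivity loci carry no control-condition signal — the property that
makes the trait-cofactor scan's suppression behaviour testable.

The interaction network is a preferential-attachment (scale-free) graph;
the planted module is a connected dense subgraph (random spanning tree
plus chords to a mean intra-module degree near 5, the usual
planted-dense-subgraph construction, consistent with the dense wiring of
curated pathways). Genes harbouring the planted causal variants are
preferentially placed inside the module. Gene models are tiled with
realistic lengths (0.5–5 kb) and gaps (0.2–15 kb) so the 5 kb annotation
window is genuinely exercised.

What the generator does *not* emulate: linkage disequilibrium between
sites, population structure or relatedness, chromosomal inversions or
endosymbiont covariates, sex differences, and mass–genotype covariance by
default. Passing tests therefore demonstrate correctness of the
estimators and calibration under an idealised panel, not robustness to
the correlation structure of real panels.

## Numerical choices and degenerate inputs

* Seeds: every generator call derives its stream from `seed` and a stage
  name hash, and restores the caller's RNG state afterwards; a pipeline
  run is byte-identical under a fixed master seed.
* Rank deficiency: empty design cells abort the full ANCOVA with the cell
  named; aliased columns elsewhere are dropped by pivoted QR and term df
  are computed from realised ranks.
* A numerically perfect cofactor fit (zero residual) reports a null
  genotype statistic instead of 0/0.
* Variance truncation happens at exactly zero; the raw estimate is kept.
* Subnetwork reporting ties are broken by edge count then lexicographic
  node set; the size statistic itself is tie-free.
* Coordinates are 1-based inclusive internally; BED input/output converts
  from/to 0-based half-open.
* VCF input keeps biallelic records only; heterozygous or missing calls
  become missing genotypes (an inbred panel should not contain
  heterozygotes).

## Problem sizes used in the checks

The calibration suite runs two million null marker tests (126 lines,
ten batches of 2 x 10^5 variants), 100 replicates of the
variance-component recovery and 200 of the genetic-correlation recovery
at the full 126 x 30 design, 200 planted-sensitivity scans, and 50
planted-module permutation runs at 1000 permutations each. These sizes
were chosen so the Monte-Carlo standard errors are small relative to the
asserted tolerances.

## Known limitations

Method-of-moments components can be negative and are truncated; no
standard errors are attached to heritabilities or genetic correlations.
The association model carries no structure correction — appropriate for
a designed inbred panel, wrong for related individuals. The permutation
null draws genes uniformly, not degree-matched, matching the stated
resampling scheme; on heavy-tailed interaction graphs a degree-matched
null would be stricter. The sensitivity index has no per-line standard
error, so downstream scans treat all lines as equally informative.
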