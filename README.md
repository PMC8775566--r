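# sensigwas

Mapping genotype- and age-specific drug responses in panels of inbred lines.

Pharmacological treatments rarely act uniformly across a genetically diverse
population: the same drug can protect one genotype and harm another, and the
response can flip with age. Panels of fully inbred, genotyped lines (such as
the *Drosophila* Genetic Reference Panel, DGRP) make this tractable: every
genotype can be measured repeatedly, in treated and control conditions and at
several ages, so the genotype-by-treatment response itself becomes a mappable
phenotype. `sensigwas` implements that analysis end to end for quantitative
performance traits measured on individual animals, and ships a
synthetic-data generator with known ground truth so the whole pipeline is
testable without access to any panel's raw data.

## What it computes

Given individual records (line, age, treatment, block, body mass, trait
value), inbred genotypes coded 0/1 per line, gene models, and a
gene-interaction network:

1. **Full ANCOVA** `y = c + m + g + t + a + (all interactions) + b(a) + e`,
   with body mass `m` as covariate and block `b` nested in age, reporting
   order-independent partial (Type III-style) F tests per term.
2. **Mass-adjusted least-squares line means** per age x treatment stratum:
   each line's predicted value at the stratum grand-mean mass, averaging
   block effects equally.
3. **Falconer sensitivity index** per line and age:
   `S_i = d_i / D̄` with `d_i = treated mean − control mean` and `D̄` the
   panel-average response, so `mean(S) = 1` and sign tracks direction of
   response.
4. **Variance components and genetic correlations**: one-way
   method-of-moments among-line components per stratum, and
   `r_G = cov12 / (σ_L1 σ_L2)` between strata from line-mean covariances
   (the classic cross-environment genetic correlation; values outside
   [-1, 1] are flagged, never clamped).
5. **Single-marker GWA on line means** (`y = u + m·x + e`, t test with
   n−2 df), and a **sensitivity scan with the trait value as cofactor**
   (`S = u + γ·z + m·x + e`, partial t with n−3 df) that separates
   sensitivity loci from trait loci. Candidates use a strict `p < 1e-5`
   cutoff; genes are assigned within a strict 5 kb window.
6. **Bridged-subnetwork permutation test**: candidate genes (at a stricter
   `p < 1e-6`) are projected onto a global interaction graph allowing one
   non-candidate "bridge" gene between candidates; the size of the largest
   subnetwork is compared with 1000 uniform random gene draws,
   `p = (A + 1)/(N + 1)`. Hub genes are those with more than ten
   connections.

## Worked example

A small simulated panel (40 lines, 10 flies per cell, 2000 variants, a
300-gene interaction network with a planted 12-gene module):

```r
library(sensigwas)
cfg <- analysis_config(
  sim = sim_config(n_lines = 40, n_flies_per_cell = 10, n_variants = 2000,
                   maf_range = c(0.2, 0.5), causal_effect_size = 1.5,
                   network_n_genes = 300, planted_module_size = 12, seed = 2L),
  candidate_threshold = 1e-4, network_threshold = 1e-3,
  n_perm = 1000, min_class = 4, seed = 2L, outdir = "readme_run")
man <- run_pipeline(cfg)
man$results$ancova[, c("term", "df", "statistic", "p_value")]
```

```
                 term   df statistic   p_value
1             mass_mg    1    11.383  7.61e-04
2                line   39    33.496 6.13e-172
3           treatment    1  1098.585 2.03e-179
5      line:treatment   39     7.675  2.51e-37
9  line:treatment:age   39     1.090  3.26e-01
10          Residuals 1437        NA        NA
```

The strong `line:treatment` interaction is the signal of interest: lines
differ genetically in how much the treatment changes the trait. The
cross-condition genetic correlations quantify how much of the line ranking
is shared between conditions:

```r
man$results$genetic_correlations$rGT1
#> <genetic_correlation> rGT1 (young:control vs young:treated): r = 0.6522, cov12 = 2.627, 40 lines
head(man$results$sensitivity$old, 3)
#>    line_id age      d_i    D_bar         S
#> 1 line_001 old 4.714454 3.359882 1.4031606
#> 2 line_002 old 3.965967 3.359882 1.1803888
#> 3 line_003 old 2.557997 3.359882 0.7613355
```

`S = 1.40` means line_001's response to treatment at old age was 40% above
the panel average; `S < 0` (none here) would mean the treatment moved that
genotype's trait against the panel-average direction. Scans, candidate
tables, gene annotations, network components, and the permutation summaries
are all written under `outdir` with checksums in `manifest.json`.

A thin command-line wrapper over the same functions is provided in
`inst/scripts/sensigwas-pipeline.R`:

```sh
Rscript inst/scripts/sensigwas-pipeline.R all --seed 2 --outdir run1
```

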