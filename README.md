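# mitoload

Deleterious mutation load in populations, estimated from mitochondrial
protein-coding genes.

Domestication and breed formation shrink effective population sizes, so
purifying selection removes harmful amino-acid variants less efficiently
and young breeds carry a larger share of deleterious segregating SNPs.
`mitoload` quantifies this from concatenated mitochondrial CDS alignments
(e.g. the 13 protein-coding genes of cattle mitogenomes, 11,229 bp) and
relates the load to breed age:

* **πN, πS** — within-breed nonsynonymous and synonymous nucleotide
  diversities, computed as the mean pairwise **Pamilo–Bianchi–Li (PBL)**
  distance: codon positions are partitioned into 0-, 2- and 4-fold
  degeneracy classes under the vertebrate mitochondrial code (NCBI
  table 2), transition (S) and transversion (V) differences are tallied
  per class, and each class gets a Kimura 2-parameter correction
  `A = ln(1/(1−2P−Q))/2 − ln(1/(1−2Q))/4`, `B = ln(1/(1−2Q))/2`, composed
  as `dS = (L₂A₂ + L₄A₄)/(L₂+L₄) + B₄` and
  `dN = A₀ + (L₀B₀ + L₂B₂)/(L₀+L₂)`.
* **ωP = πN/πS** per breed — the within-population load ratio.
* **ωS = dN/dS** between the ingroup and an outgroup at species-level
  divergence (cow vs bison scale) — the neutrally fixable fraction of
  nonsynonymous change.
* **δ = (ωP − ωS)/ωP** — the fraction of segregating nonsynonymous
  variants that are deleterious, with standard errors from a codon-column
  bootstrap (100 replicates; the same resampled columns drive ωP and ωS
  so the two covary).
* **Breed age** — the coalescence distance of each breed (UPGMA root
  height of whole-alignment K2P distances, or half the mean pairwise
  distance) divided by the mitochondrial mutation rate
  `μ = 2.043 × 10⁻⁸` substitutions per site per year.
* **Age–load association** — Pearson and Spearman correlations between
  age and δ, on log10 and raw scales, with the closed-form two-sided
  p-value `t = r√((n−2)/(1−r²))`.

A coalescent codon simulator with separately tunable polymorphism-level
and divergence-level ω (plus GenBank-style fixture writers) makes the
whole pipeline testable without downloading anything.

## Worked example

Simulate a six-breed panel whose polymorphism-level ω decays with
genealogy depth (the situation the estimator is designed to detect), then
run the full analysis:

```r
library(mitoload)

cfg <- sim_config(
  n_breeds = 6, samples_per_breed = 8, n_codons = 1200,
  root_height_per_breed = exp(seq(log(5e-4), log(7e-3), length.out = 6)),
  omega_poly_per_breed  = exp(seq(log(0.6),  log(0.12), length.out = 6)),
  seed = 2026)
sim  <- simulate_study(cfg)

load <- estimate_breed_load(sim$alignment, sim$outgroup,
                            n_boot = 100, seed = 1)
glance(load)
#> # A tibble: 1 × 5
#>   n_breeds omega_P_fold_range omega_S mean_delta n_negative_delta
#>      <int>              <dbl>   <dbl>      <dbl>            <int>
#> 1        6               3.68   0.103      0.550                0

age <- estimate_breed_age(sim$alignment)
cor <- correlate_age_load(load, age)
glance(cor)
#> # A tibble: 1 × 5
#>        r p_value     n method  transform
#>    <dbl>   <dbl> <int> <chr>   <chr>
#> 1 -0.631   0.179     6 pearson log10
```

The `load` tibble has one row per included breed — e.g. the shallowest
breed comes out with `omega_P = 0.635` and `delta = 0.84`, the deepest
with `omega_P = 0.177` and `delta = 0.42` — and the pooled interspecies
ratio recovers the simulated `omega_div = 0.1` as `omega_S = 0.103`.
Ages span ~26 to ~240 thousand years across the simulated depths, and the
age–δ correlation is negative on both scales (r = −0.63 on log10 axes
here; small panels are noisy). `autoplot(load)` draws the per-breed ωP
bar chart with bootstrap SEs; `autoplot(cor)` the log–log scatter with
its regression line.

Breeds enter the analysis only if they have more than four sampled
mitogenomes and at least one synonymous and one nonsynonymous segregating
change (`breed_filter()` reports exclusions). File-based stages —
`pipeline_simulate()`, `pipeline_extract()` (GenBank → concatenated
FASTA), `pipeline_load()`, `pipeline_age()`, `pipeline_correlate()` —
hand off plain TSVs with version/config/seed headers; `inst/cli/mitoload.R`
wraps them for the shell.

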