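---
title: "Methods: mitochondrial deleterious-load estimation in mitoload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial deleterious-load estimation in mitoload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`mitoload` estimates the deleterious fraction of segregating amino-acid
variation in a set of populations (here: livestock breeds) from a single
concatenated alignment of mitochondrial protein-coding genes, and relates
that fraction to population age. The chain of quantities is:

1. **Pairwise PBL distances.** For each pair of in-frame coding
   sequences, every codon position is assigned a degeneracy class under
   the genetic code in use — 4-fold if all three single-base alternatives
   are synonymous, 0-fold if none is, 2-fold otherwise; mutations to stop
   codons count as nonsynonymous. Site totals L0, L2, L4 and
   transition/transversion difference counts S_i, V_i are accumulated per
   class, and a Kimura 2-parameter correction is applied per class with
   A_i, B_i = k2p(S_i/L_i, V_i/L_i). The synonymous distance is
   dS = (L2·A2 + L4·A4)/(L2 + L4) + B4 and the nonsynonymous distance is
   dN = A0 + (L0·B0 + L2·B2)/(L0 + L2). Transitions at 2-fold sites are
   thereby routed synonymous and transversions at 2-fold sites
   nonsynonymous — the convention of the counting method this package
   implements.
2. **Diversities and ratios.** πN and πS of a breed are the unweighted
   means of valid pairwise dN and dS over all n(n−1)/2 pairs;
   ωP = πN/πS. One pooled interspecies comparison of all included
   ingroup sequences against the outgroup gives ωS = dN/dS.
3. **Deleterious fraction.** δ = (ωP − ωS)/ωP. Since fixed interspecies
   differences approximate the neutrally acceptable fraction of
   nonsynonymous change, an excess of segregating nonsynonymous variation
   (ωP > ωS) is attributed to deleterious variants still visible to
   selection; δ ≤ 1 by construction, and δ < 0 (reported, never clamped)
   flags ωP below the interspecies ratio.
4. **Ages.** A breed's coalescence distance — substitutions per site from
   the sample's common ancestor to the tips — is estimated as the UPGMA
   root height of the whole-alignment K2P distance matrix and converted
   to years by dividing by μ.
5. **Association.** Pearson and Spearman correlations between age and δ,
   on log10 and raw scales, with the t-approximation p-value in both
   cases.

## Assumptions

* Sequences are frame-aligned and length-conserved. Bovine mitochondrial
  CDS are effectively indel-free, so the package enforces equal gene
  lengths across records and refuses to align; length disagreements are
  errors that name the gene and records so an external aligner can be
  applied first.
* The vertebrate mitochondrial code (NCBI table 2: AGA/AGG stops, ATA
  Met, TGA Trp) is the default and the only biologically defensible
  choice for these data; the standard code (table 1) is selectable.
* Codons containing gaps, ambiguity codes, or stops in either sequence of
  a pair are excluded pairwise (the analogue of pairwise deletion).
* Saturated pairwise distances (a K2P logarithm undefined) are flagged
  invalid and excluded from π averages with a reported count, rather than
  failing the breed: intraspecific mitochondrial data essentially never
  saturate, and a hard failure would be disproportionate.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| code table | 2 | — | vertebrate mitochondrial code |
| breed inclusion | n ≥ 5, ≥1 syn and ≥1 nonsyn variant | — | "more than four" sampled mitogenomes; both variant classes needed for a finite, informative ωP |
| bootstrap replicates | 100 | — | resampling unit is the codon column; SE is the sd across replicates |
| μ | 2.043e-8 | subs/site/year | bovine mitochondrial rate; ages are linear in 1/μ, so any other calibration rescales them exactly |
| age method | `upgma_root` | — | root height of the average-linkage tree; `half_mean_pairwise` is the simpler alternative and both equal d/2 for two sequences |
| κ (simulator) | 10 | rate ratio | strong mitochondrial transition bias |
| ω_div (simulator) | 0.1 | — | species-level dN/dS scale for mito protein genes |
| outgroup depth (simulator) | 0.05 | subs/site | cow–bison divergence scale |

## Numerical choices

* **Mixed-degeneracy sites** are split 50/50 between the two sequences'
  own classifications, for site totals and differences alike — the
  averaging convention of the method's source formulation. Multi-hit
  codons are compared position by position with no pathway enumeration;
  this can deviate slightly from implementations that weight pathways,
  and only on the rare codons with several differences.
* **2-fold-site routing.** Transitions at 2-fold sites are synonymous by
  convention. A synonymous *transversion* at a 2-fold site is routed into
  the synonymous (S) tally of its class; enumeration shows no such site
  exists under table 2, and under table 1 they are confined to arginine
  first positions and isoleucine third positions.
* The K2P transitional component A is applied exactly as defined and can
  be slightly negative when transversions dominate a class; it is not
  clamped.
* **Reproducibility contract.** Distances are pure elementary-function
  arithmetic with a fixed summation order; given identical input they
  reproduce to better than 1e-12, which is also the tolerance at which
  the test suite compares the implementation to an independent
  brute-force per-site oracle.
* **Bootstrap covariance.** Each replicate resamples codon columns with
  replacement and applies the *same* column multiset to the within-breed
  pairs and to the pooled ingroup-vs-outgroup pairs, so ωP and ωS covary
  within a replicate and se(δ) reflects that covariance. Replicates with
  no synonymous signal (πS = 0 or dS = 0) are dropped and counted (an
  error above 50%); replicates with πN = 0 leave δ undefined and
  contribute only to se(ωP).
* **UPGMA ties** are resolved deterministically by the ordering of
  `stats::hclust`; all stochastic stages take explicit integer seeds and
  are byte-identical across reruns.
* Degenerate inputs fail loudly: πS = 0 points the user at the breed
  filter, zero interspecies synonymous divergence is an error, the
  correlation requires at least three usable pairs and non-zero variance,
  and log10 correlations drop non-positive pairs with an explicit count
  (δ ≤ 0 cannot be log-transformed; the raw-scale correlation is always
  co-reported).

## Design decisions that were genuinely open

* **One ωS or many.** The interspecies ratio is computed once from the
  pooled comparison of all included ingroup sequences against the
  outgroup and shared across breeds, matching the single
  species-comparison design; per-breed ωS is available via
  `omega_s_mode = "per_breed"`. Likewise, whether the outgroup is one
  sequence or several is left to the input: all ingroup × outgroup pairs
  are averaged.
* **Distance-based ages.** Bayesian multispecies-coalescent machinery is
  deliberately not reimplemented; the package estimates the coalescence
  height from distances and tags every output row with the method name so
  the two kinds of estimate are never conflated. Both estimator variants
  are exposed because which population-scaled quantity one converts with
  μ is itself a modelling choice. The downstream use — distance divided
  by rate gives years — is preserved exactly.
* **Breed labels.** When GenBank records lack breed qualifiers the
  package requires an explicit sample-to-breed table rather than guessing
  from free-text fields.
* **Correlation scale.** The headline correlation is reported on log10
  axes (the scale of the figure it reproduces) with the raw-scale and
  rank-based versions always alongside, because the analysis scale of the
  original coefficient is not fixed by the figure alone.

## What the simulator does and does not emulate

`simulate_study()` builds each breed from an independent Kingman
coalescent genealogy rescaled to a chosen root height, evolves codons
with a K2P-biased process (transitions weighted κ), accepts nonsynonymous
changes at relative rate ω and rejects mutations to stop codons, and
emits ground truth: realized synonymous/nonsynonymous counts, genealogy
heights, and the implied δ = 1 − ω_div/ω_poly. Branch lengths are
realized substitutions per nucleotide site (event counts are Poisson with
mean length × sites), so distance-based estimators see the intended
depths. Defaults mirror the cattle-study scale: 18 breeds, 10 samples
each, 3,743 codons (11,229 bp), root heights 1.7e-4 to 7e-3 subs/site
(8.3–340 Kyr at μ = 2.043e-8), ω_poly decaying 0.6 → 0.12 with depth
against ω_div = 0.1.

It does **not** emulate: shared haplogroup structure between breeds (each
genealogy is independent), selection dynamics (ω differences are imposed,
not evolved from fitness effects, so there is no site-frequency-spectrum
signal), rate variation across sites, or indels and sequencing artefacts.
Passing tests therefore demonstrate that the estimators recover imposed
ω and depth parameters under the method's own model class — not that real
breed histories satisfy that model.

## Problem sizes used by the test suite

The suite exercises the full study scale once (18 breeds × 10 samples ×
3,743 codons with a 100-replicate bootstrap) and verifies the oracle
equivalence on 1,000 random pairs of up to 100 codons; the age estimator
is validated on 50 genealogies with 30 kb sequences. Shared fixtures for
arithmetic-level tests are much smaller (hundreds of codons), chosen so
the whole suite stays fast while every estimator is still exercised at
the scale it was designed for.

## Known limitations

* Counting-method estimates only: no maximum-likelihood codon models and
  no rate-variation correction, by design.
* Breeds are treated as independent points in the age–δ correlation; they
  share a genealogy in reality, and no phylogenetic correction is
  applied.
* π estimates on very shallow breeds rest on a handful of segregating
  sites; the bootstrap SEs are then large and δ is correspondingly
  uncertain. The inclusion filter removes the degenerate cases but not
  the merely noisy ones.
* The GenBank reader covers the flat-file subset produced by annotated
  mitogenome records (simple and complemented single-interval CDS); it
  skips features with `join()` locations with a warning rather than
  resolving them.
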