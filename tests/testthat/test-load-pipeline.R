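test_that("breed filter enforces sample count and both variant classes", {
  base <- strrep("ATGGGGCTA", 40)
  # five identical sequences: no variants
  mono <- codon_alignment(setNames(rep(base, 6), paste0("m", 1:6)),
                          breeds = "Mono")
  # four samples only
  small <- codon_alignment(setNames(rep(base, 4), paste0("t", 1:4)),
                           breeds = "Tiny")
  # six samples with one synonymous (GGG->GGA) and one
  # nonsynonymous (ATG->ATA is 0-fold at position 2? use CTA->CCA) change
  v1 <- base; substr(v1, 6, 6) <- "A"       # GGG -> GGA, synonymous
  v2 <- base; substr(v2, 8, 8) <- "C"       # CTA -> CCA, nonsynonymous
  poly <- codon_alignment(setNames(c(base, v1, v2, base, base, base),
                                   paste0("p", 1:6)), breeds = "Poly")
  # six samples with only the synonymous change segregating
  synonly <- codon_alignment(setNames(c(base, v1, base, base, base, base),
                                      paste0("s", 1:6)), breeds = "SynOnly")
  aln <- codon_alignment(
    c(mono$sequences, small$sequences, poly$sequences, synonly$sequences),
    c(mono$samples$sample_id, small$samples$sample_id,
      poly$samples$sample_id, synonly$samples$sample_id),
    c(mono$samples$breed, small$samples$breed, poly$samples$breed,
      synonly$samples$breed))
  ft <- breed_filter(aln)
  expect_equal(ft$included[ft$breed == "Poly"], TRUE)
  expect_equal(ft$reason[ft$breed == "Mono"], "no variants")
  expect_equal(ft$reason[ft$breed == "Tiny"], "n <= 4")
  expect_equal(ft$reason[ft$breed == "SynOnly"], "no nonsynonymous variant")
})

test_that("simulated breeds with both variant classes pass the filter", {
  sim <- small_study()
  ft <- breed_filter(sim$alignment)
  expect_true(all(ft$n == 6))
  expect_true(all(ft$included[ft$syn_changes > 0 & ft$nonsyn_changes > 0]))
})

test_that("pi values are means of pairwise distances", {
  aln <- tiny_alignment()  # s1 == s3, s2 differs by one synonymous transition
  pp <- pi_n_pi_s(aln)
  pw <- dnds_pairs(aln)
  d <- pw$dS[pw$id_a == "s1" & pw$id_b == "s2"]
  expect_equal(pp$pi_S, (0 + d + d) / 3)
  expect_equal(pp$pi_N, 0)
  expect_equal(pp$n_pairs, 3)
  expect_equal(pp$n_invalid_pairs, 0)
  # two sequences: pi equals the single pair's distances
  two <- subset_samples(aln, 1:2)
  pp2 <- pi_n_pi_s(two)
  expect_equal(pp2$pi_S, d)
})

test_that("duplicating every sequence leaves omega_P unchanged", {
  # under the all-pairs mean, duplication shrinks both pi values by exactly
  # (2n-2)/(2n-1) (the added self-pairs have distance zero), so their ratio
  # omega_P is invariant
  sim <- small_study()
  b <- subset_samples(sim$alignment, sim$alignment$samples$breed == "breed02")
  pp1 <- pi_n_pi_s(b)
  dup <- codon_alignment(rep(b$sequences, 2),
                         c(b$samples$sample_id,
                           paste0(b$samples$sample_id, "_dup")),
                         rep(b$samples$breed, 2))
  pp2 <- pi_n_pi_s(dup)
  n <- length(b$sequences)
  shrink <- (2 * n - 2) / (2 * n - 1)
  expect_equal(pp2$pi_N, pp1$pi_N * shrink, tolerance = 1e-12)
  expect_equal(pp2$pi_S, pp1$pi_S * shrink, tolerance = 1e-12)
  expect_equal(omega_p(pp2$pi_N, pp2$pi_S), omega_p(pp1$pi_N, pp1$pi_S),
               tolerance = 1e-12)
})

test_that("omega_p guards its denominator", {
  expect_equal(omega_p(0.002, 0.010), 0.2)
  expect_equal(omega_p(0, 0.01), 0)
  expect_error(omega_p(0.1, 0), "breed_filter")
})

test_that("delta follows the defining identity and its edge cases", {
  expect_equal(delta_fraction(0.3, 0.3), 0)
  expect_equal(delta_fraction(0.3, 0), 1)
  # exact identity delta(w, w(1-x)) = x over a grid
  for (w in seq(0.1, 1, by = 0.1)) {
    for (x in seq(0, 1, by = 0.1)) {
      expect_equal(delta_fraction(w, w * (1 - x)), x, tolerance = 1e-12)
    }
  }
  expect_warning(d <- delta_fraction(0.1, 0.2), "negative")
  expect_lt(d, 0)
  expect_error(delta_fraction(0, 0.1), "positive")
  # the study's printed pair: omega_P 0.59 with delta 0.86 implies
  # omega_S ~ 0.0826
  expect_equal(delta_fraction(0.59, 0.59 * (1 - 0.86)), 0.86)
  expect_equal(delta_fraction(0.59, 0.0826), 0.86, tolerance = 0.001)
})

test_that("interspecies omega recovers the divergence omega of the simulator", {
  cfg <- sim_config(n_breeds = 1, samples_per_breed = 3, n_codons = 2500,
                    root_height_per_breed = 1e-3,
                    omega_poly_per_breed = 0.3,
                    omega_div = 0.1, outgroup_depth = 0.05, seed = 21)
  sim <- simulate_study(cfg)
  os <- interspecies_omega_s(sim$alignment, sim$outgroup)
  expect_lt(abs(os$omega_S - 0.1), 0.03)
  # single ingroup vs single outgroup equals the plain pair distances
  one <- subset_samples(sim$alignment, 1)
  os1 <- interspecies_omega_s(one, sim$outgroup)
  d <- pair_dnds(count_codon_pair(one$sequences, sim$outgroup[[1]]))
  expect_equal(os1$d_N, d$dN)
  expect_equal(os1$d_S, d$dS)
  expect_equal(os1$omega_S, d$dN / d$dS)
  # outgroup identical to the ingroup sequence: all-zero divergence errors
  expect_error(interspecies_omega_s(one, one$sequences), "omega_S undefined")
})

test_that("bootstrap SEs are deterministic and the replicate table coheres", {
  sim <- small_study()
  b <- subset_samples(sim$alignment, sim$alignment$samples$breed == "breed03")
  b1 <- bootstrap_load(b, sim$outgroup, n_replicates = 60, seed = 123)
  b2 <- bootstrap_load(b, sim$outgroup, n_replicates = 60, seed = 123)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$se_delta, b2$se_delta)
  expect_gt(b1$se_omega_P, 0)
  expect_gt(b1$se_delta, 0)
  ok <- !b1$replicates$degenerate
  expect_equal(b1$se_omega_P, sd(b1$replicates$omega_P[ok]))
  # monomorphic breed violates the precondition
  mono <- codon_alignment(setNames(rep(strrep("ATG", 100), 5),
                                   paste0("m", 1:5)), breeds = "Mono")
  expect_error(bootstrap_load(mono, sim$outgroup), "breed_filter")
})

test_that("bootstrap SE shrinks with alignment length", {
  ses <- sapply(c(250, 1000), function(nc) {
    cfg <- sim_config(n_breeds = 1, samples_per_breed = 8, n_codons = nc,
                      root_height_per_breed = 4e-3,
                      omega_poly_per_breed = 0.4, seed = 31)
    sim <- simulate_study(cfg)
    b <- subset_samples(sim$alignment, 1:8)
    bootstrap_load(b, sim$outgroup, n_replicates = 60, seed = 5)$se_omega_P
  })
  expect_lt(ses[2], ses[1])
})

test_that("the study-level estimate reports per-breed load with shared omega_S", {
  sim <- small_study()
  load <- estimate_breed_load(sim$alignment, sim$outgroup, n_boot = 40,
                              seed = 2)
  expect_s3_class(load, "breed_load")
  expect_true(all(load$pi_N >= 0 & load$pi_S > 0))
  expect_equal(load$omega_P, load$pi_N / load$pi_S)
  expect_equal(unique(load$omega_S), attr(load, "omega_s")$omega_S)
  expect_equal(load$delta,
               (load$omega_P - load$omega_S) / load$omega_P)
  expect_true(all(load$delta <= 1))
  g <- glance(load)
  expect_equal(g$n_breeds, nrow(load))
  expect_equal(g$omega_P_fold_range,
               max(load$omega_P) / min(load$omega_P))
})
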