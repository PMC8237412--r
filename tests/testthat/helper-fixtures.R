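# Small simulated datasets shared across test files, built once per run.

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_breeds = 4, samples_per_breed = 6, n_codons = 300,
                        root_height_per_breed = c(1e-3, 2e-3, 4e-3, 6e-3),
                        omega_poly_per_breed = c(0.6, 0.4, 0.25, 0.15),
                        seed = 42)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

# a tiny hand-made alignment: 3 samples x 2 breeds won't pass filters,
# useful for arithmetic-level checks
tiny_alignment <- function() {
  codon_alignment(
    c(s1 = "ATAGGGGGGGGGTTA",
      s2 = "ATGGGGGGGGGATTA",
      s3 = "ATAGGGGGGGGGTTA"),
    breeds = c("X", "X", "X"))
}
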