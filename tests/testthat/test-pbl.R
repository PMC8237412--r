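code2 <- genetic_code(2)

test_that("identical sequences give zero differences and additive site counts", {
  s <- "ATAGGGGGGGGGTTA"
  ct <- count_codon_pair(s, s, code2)
  expect_equal(ct$codons_compared, 5)
  expect_equal(ct$S0 + ct$S2 + ct$S4 + ct$V0 + ct$V2 + ct$V4, 0)
  # L values are sums of each codon's degeneracy-triple class indicators
  trip <- lapply(c("ATA", "GGG", "GGG", "GGG", "TTA"),
                 codon_degeneracy, code = code2)
  expect_equal(ct$L0, sum(sapply(trip, function(t) sum(t == 0))))
  expect_equal(ct$L2, sum(sapply(trip, function(t) sum(t == 2))))
  expect_equal(ct$L4, sum(sapply(trip, function(t) sum(t == 4))))
  expect_equal(ct$L0 + ct$L2 + ct$L4, 3 * ct$codons_compared)
  d <- pair_dnds(ct)
  expect_equal(d$dN, 0)
  expect_equal(d$dS, 0)
})

test_that("the worked 5-codon pair routes its two transitions as specified", {
  ct <- count_codon_pair("ATAGGGGGGGGGTTA", "ATGGGGGGGGGATTA", code2)
  expect_equal(ct$codons_compared, 5)
  expect_equal(c(ct$L0, ct$L2, ct$L4), c(9, 3, 3))
  expect_equal(ct$S2, 1)  # ATA/ATG third position
  expect_equal(ct$S4, 1)  # GGG/GGA third position
  expect_equal(ct$S0 + ct$V0 + ct$V2 + ct$V4, 0)
  d <- pair_dnds(ct)
  expect_equal(d$dS, log(3) / 2, tolerance = 1e-12)
  expect_equal(d$dN, 0)
})

test_that("a lone C<->G difference at a 4-fold site is a transversion", {
  # GGC vs GGG: third position 4-fold in both, C/G is a transversion
  ct <- count_codon_pair("GGCAAA", "GGGAAA", code2)
  expect_equal(ct$V4, 1)
  expect_equal(ct$S0 + ct$S2 + ct$S4 + ct$V0 + ct$V2, 0)
})

test_that("K2P components match closed forms and flag saturation", {
  k <- k2p_components(0, 0)
  expect_equal(c(k$A, k$B), c(0, 0))
  k <- k2p_components(1 / 3, 0)
  expect_equal(k$A, log(3) / 2, tolerance = 1e-12)
  expect_equal(k$B, 0)
  k <- k2p_components(0.5, 0)
  expect_false(k$valid)
  expect_true(is.na(k$A))
  k <- k2p_components(0, 0.5)
  expect_false(k$valid)
  expect_error(k2p_components(-0.1, 0))
  expect_error(k2p_components(0.8, 0.4))
})

test_that("V4-only counts compose dS = A4 + B4 from the per-class K2P formula", {
  d <- pair_dnds(tibble::tibble(L0 = 10, L2 = 0, L4 = 10, S0 = 0, S2 = 0,
                                S4 = 0, V0 = 0, V2 = 0, V4 = 1))
  A4 <- -0.5 * log(1 - 0.1) + 0.25 * log(1 - 0.2)
  B4 <- -0.5 * log(1 - 0.2)
  expect_equal(d$dS, A4 + B4, tolerance = 1e-12)
  expect_equal(d$dS, 0.1084661, tolerance = 1e-6)
  expect_equal(d$dN, 0)
})

test_that("pair_dnds enforces the site-class preconditions", {
  expect_error(pair_dnds(tibble::tibble(L0 = 10, L2 = 0, L4 = 0, S0 = 0,
                                        S2 = 0, S4 = 0, V0 = 0, V2 = 0,
                                        V4 = 0)),
               "L2 \\+ L4")
  expect_error(pair_dnds(tibble::tibble(L0 = 0, L2 = 0, L4 = 10, S0 = 0,
                                        S2 = 0, S4 = 0, V0 = 0, V2 = 0,
                                        V4 = 0)),
               "L0 \\+ L2")
})

test_that("counting is symmetric in the sequence pair", {
  set.seed(11)
  for (i in 1:20) {
    pr <- random_pair(30, 6)
    ca <- count_codon_pair(pr$a, pr$b, code2)
    cb <- count_codon_pair(pr$b, pr$a, code2)
    expect_identical(ca, cb)
    expect_identical(pair_dnds(ca), pair_dnds(cb))
  }
})

test_that("pairwise codons with stops or ambiguity are excluded pairwise", {
  # middle codon is a stop in one sequence only
  ct <- count_codon_pair("AAAAGAAAA", "AAACGAAAA", code2)
  expect_equal(ct$codons_compared, 2)
  ct <- count_codon_pair("AAANNNAAA", "AAACGAAAA", code2)
  expect_equal(ct$codons_compared, 2)
  expect_error(count_codon_pair("AGA", "AGA", code2), "comparable")
})

test_that("dN/dS matches the independent brute-force oracle to 1e-12", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:250) {
    pr <- random_pair(sample(10:60, 1), sample(0:12, 1))
    ct <- count_codon_pair(pr$a, pr$b, code2)
    d <- pair_dnds(ct)
    o <- oracle_dnds(pr$a, pr$b)
    expect_equal(d$valid_dN, o$valid_dN)
    expect_equal(d$valid_dS, o$valid_dS)
    if (o$valid_dN) expect_lt(abs(d$dN - o$dN), 1e-12)
    if (o$valid_dS) expect_lt(abs(d$dS - o$dS), 1e-12)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 250)
})

test_that("small-distance limit: one synonymous transition among many codons", {
  # single difference pairs of >= 300 codons: dS ~ 1 / (syn sites)
  set.seed(5)
  gcv <- oracle_code(2)
  for (i in 1:5) {
    root <- random_root_sequence(400, seed = i)
    # plant one synonymous transition at a 4-fold site
    idx <- mitoload:::.encode_codons(root)
    four <- which(code2$degeneracy[idx, 3] == 4L)
    k <- four[1]
    mutated <- root
    cur <- substr(root, 3 * k, 3 * k)
    tgt <- c(A = "G", G = "A", C = "T", T = "C")[[cur]]
    substr(mutated, 3 * k, 3 * k) <- tgt
    ct <- count_codon_pair(root, mutated, code2)
    d <- pair_dnds(ct)
    syn_sites <- ct$L2 + ct$L4  # transition-synonymous site total
    expect_equal(d$dN, 0)
    expect_equal(d$dS, 1 / syn_sites, tolerance = 0.05)
  }
})

test_that("added synonymous transitions at 4-fold sites raise dS monotonically, dN fixed", {
  root <- random_root_sequence(200, seed = 9)
  idx <- mitoload:::.encode_codons(root)
  four <- which(code2$degeneracy[idx, 3] == 4L)
  mutated <- root
  prev_dS <- -1
  for (m in seq_len(min(8, length(four)))) {
    k <- four[m]
    cur <- substr(mutated, 3 * k, 3 * k)
    tgt <- c(A = "G", G = "A", C = "T", T = "C")[[cur]]
    substr(mutated, 3 * k, 3 * k) <- tgt
    d <- pair_dnds(count_codon_pair(root, mutated, code2))
    expect_gt(d$dS, prev_dS)
    expect_equal(d$dN, 0)
    prev_dS <- d$dS
  }
})

test_that("dnds_pairs returns one row per unordered pair", {
  aln <- tiny_alignment()
  pw <- dnds_pairs(aln, code2)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$dN, rep(0, 3))
  d12 <- pw$dS[pw$id_a == "s1" & pw$id_b == "s2"]
  d13 <- pw$dS[pw$id_a == "s1" & pw$id_b == "s3"]
  expect_equal(d13, 0)
  expect_gt(d12, 0)
})
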