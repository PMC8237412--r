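# Independent brute-force PBL oracle. Shares no code with the package:
# the genetic code comes from Biostrings, degeneracy is enumerated per
# codon by substitution-and-translate, tallies are accumulated in plain
# loops, and the K2P composition is written out separately.

oracle_code <- function(table_id = 2) {
  id <- if (table_id == 1) "1" else "2"
  gc <- Biostrings::getGeneticCode(id)
  names(gc) <- toupper(names(gc))
  gc
}

oracle_is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

oracle_syn <- function(codon, pos, base, gc) {
  # is the single-base change synonymous (and sense-preserving)?
  alt <- codon
  substr(alt, pos, pos) <- base
  gc[[codon]] != "*" && gc[[alt]] != "*" && gc[[codon]] == gc[[alt]]
}

oracle_degeneracy <- function(codon, pos, gc) {
  cur <- substr(codon, pos, pos)
  n <- 0
  for (b in setdiff(c("A", "C", "G", "T"), cur)) {
    if (oracle_syn(codon, pos, b, gc)) n <- n + 1
  }
  if (n == 3) 4 else if (n == 0) 0 else 2
}

oracle_k2p <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(list(A = NA, B = NA, valid = FALSE))
  list(A = 0.5 * log(1 / w1) - 0.25 * log(1 / w2),
       B = 0.5 * log(1 / w2), valid = TRUE)
}

# per-pair tallies and dN/dS, loops all the way down
oracle_dnds <- function(seq_a, seq_b, table_id = 2) {
  gc <- oracle_code(table_id)
  L <- c(`0` = 0, `2` = 0, `4` = 0)
  S <- c(`0` = 0, `2` = 0, `4` = 0)
  V <- c(`0` = 0, `2` = 0, `4` = 0)
  nc <- nchar(seq_a) / 3
  compared <- 0
  for (k in seq_len(nc)) {
    ca <- substr(seq_a, 3 * k - 2, 3 * k)
    cb <- substr(seq_b, 3 * k - 2, 3 * k)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (gc[[ca]] == "*" || gc[[cb]] == "*") next
    compared <- compared + 1
    for (p in 1:3) {
      da <- as.character(oracle_degeneracy(ca, p, gc))
      db <- as.character(oracle_degeneracy(cb, p, gc))
      L[da] <- L[da] + 0.5
      L[db] <- L[db] + 0.5
      ba <- substr(ca, p, p); bb <- substr(cb, p, p)
      if (ba == bb) next
      ts <- oracle_is_transition(ba, bb)
      # half to each sequence's own class; a synonymous transversion at a
      # 2-fold site goes to the S tally of its class
      for (side in 1:2) {
        cls <- if (side == 1) da else db
        ctx <- if (side == 1) ca else cb
        tgt <- if (side == 1) bb else ba
        syn_tv <- !ts && cls == "2" && oracle_syn(ctx, p, tgt, gc)
        if (ts || syn_tv) S[cls] <- S[cls] + 0.5
        else V[cls] <- V[cls] + 0.5
      }
    }
  }
  if (compared == 0) stop("no comparable codons")
  k <- lapply(c("0", "2", "4"), function(i) {
    if (L[[i]] > 0) oracle_k2p(S[[i]] / L[[i]], V[[i]] / L[[i]])
    else list(A = 0, B = 0, valid = TRUE)
  })
  names(k) <- c("0", "2", "4")
  valid_dS <- k[["2"]]$valid && k[["4"]]$valid
  valid_dN <- k[["0"]]$valid && k[["2"]]$valid
  dS <- if (valid_dS) {
    (L[["2"]] * k[["2"]]$A + L[["4"]] * k[["4"]]$A) /
      (L[["2"]] + L[["4"]]) + k[["4"]]$B
  } else NA
  dN <- if (valid_dN) {
    k[["0"]]$A + (L[["0"]] * k[["0"]]$B + L[["2"]] * k[["2"]]$B) /
      (L[["0"]] + L[["2"]])
  } else NA
  list(dN = dN, dS = dS, valid_dN = valid_dN, valid_dS = valid_dS,
       L = L, S = S, V = V, compared = compared)
}

# random sense-codon sequence and a mutated partner, for oracle sweeps
random_pair <- function(n_codons, n_mut, table_id = 2) {
  gc <- oracle_code(table_id)
  sense <- names(gc)[gc != "*"]
  a <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  b <- a
  for (m in seq_len(n_mut)) {
    for (try in 1:50) {
      pos <- sample(nchar(b), 1)
      base <- sample(c("A", "C", "G", "T"), 1)
      cand <- b
      substr(cand, pos, pos) <- base
      cod_i <- (pos - 1) %/% 3 + 1
      cod <- substr(cand, 3 * cod_i - 2, 3 * cod_i)
      if (gc[[cod]] != "*") { b <- cand; break }
    }
  }
  list(a = a, b = b)
}
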