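# Pamilo-Bianchi-Li pairwise dN/dS: codon sites are partitioned into 0-,
# 2- and 4-fold degeneracy classes, transition and transversion differences
# are tallied per class, and a Kimura 2-parameter correction is applied per
# class. Transitions at 2-fold sites are routed synonymous; a synonymous
# transversion at a 2-fold site (possible under the standard code, never
# under the vertebrate mitochondrial code) is routed into the synonymous
# tallies as well. Mixed-degeneracy sites are split 50/50 between the two
# sequences' own classifications, for sites and differences alike.

.TALLY_ROWS <- c("L0", "L2", "L4", "S0", "S2", "S4", "V0", "V2", "V4")

# Per-codon-column tallies for one sequence pair, as a 9 x C matrix over the
# *compared* columns (gap/ambiguous/stop codons in either sequence excluded
# pairwise). Kept per column so bootstrap replicates are weighted rowSums.
.pair_column_tallies <- function(ia, ib, code) {
  ok <- !is.na(ia) & !is.na(ib) & code$is_sense[ia] & code$is_sense[ib]
  ia <- ia[ok]
  ib <- ib[ok]
  n <- length(ia)
  tal <- matrix(0, nrow = 9L, ncol = n, dimnames = list(.TALLY_ROWS, NULL))
  if (n == 0L) return(list(tallies = tal, compared = ok))

  cls_row <- c(`0` = 1L, `2` = 2L, `4` = 3L)  # L rows; +3 for S, +6 for V
  for (p in 1:3) {
    basea <- .CODON_BASE[ia, p]
    baseb <- .CODON_BASE[ib, p]
    clsa <- cls_row[as.character(code$degeneracy[ia, p])]
    clsb <- cls_row[as.character(code$degeneracy[ib, p])]
    # site counts: half a site to each sequence's own class
    idx <- seq_len(n)
    tal[cbind(clsa, idx)] <- tal[cbind(clsa, idx)] + 0.5
    tal[cbind(clsb, idx)] <- tal[cbind(clsb, idx)] + 0.5

    d <- which(basea != baseb)
    if (length(d) == 0L) next
    ts <- .IS_TRANSITION[cbind(basea[d], baseb[d])]
    # each difference splits: half to A's class, half to B's class
    for (side in 1:2) {
      cls <- if (side == 1L) clsa[d] else clsb[d]
      ctx <- if (side == 1L) ia[d] else ib[d]
      tgt <- if (side == 1L) baseb[d] else basea[d]
      syn_tv <- !ts & cls == 2L & code$syn[cbind(ctx, rep(p, length(d)), tgt)]
      row <- ifelse(ts | syn_tv, cls + 3L, cls + 6L)
      tal[cbind(row, d)] <- tal[cbind(row, d)] + 0.5
    }
  }
  list(tallies = tal, compared = ok)
}

#' Tally PBL site classes and differences for a sequence pair
#'
#' Counts degeneracy-class site totals (L0, L2, L4) and per-class transition
#' (S) and transversion (V) differences between two frame-aligned coding
#' sequences. Codons containing gaps, ambiguity codes or stop codons in
#' either sequence are excluded pairwise. Each position's degeneracy is
#' taken from each sequence's own codon and the two classifications are
#' averaged, so site counts can be half-integral; observed differences split
#' the same way. A differing site is a transition or transversion by the
#' base pair alone (no pathway enumeration across multi-hit codons).
#'
#' @param seq_a,seq_b equal-length nucleotide strings, frame-aligned
#' @param code a [genetic_code()]
#' @return one-row tibble with `L0, L2, L4, S0, S2, S4, V0, V2, V4` and
#'   `codons_compared`
#' @examples
#' code <- genetic_code(2)
#' count_codon_pair("ATAGGGGGGGGGTTA", "ATGGGGGGGGGATTA", code)
#' @export
count_codon_pair <- function(seq_a, seq_b, code = genetic_code(2)) {
  ia <- .encode_codons(toupper(seq_a))
  ib <- .encode_codons(toupper(seq_b))
  if (length(ia) != length(ib)) {
    stop("sequences differ in length (", 3 * length(ia), " vs ",
         3 * length(ib), " nt)")
  }
  ct <- .pair_column_tallies(ia, ib, code)
  if (!any(ct$compared)) stop("no comparable codons in the pair")
  tot <- rowSums(ct$tallies)
  tibble::as_tibble(as.list(tot)) |>
    dplyr::mutate(codons_compared = sum(ct$compared))
}

#' Kimura 2-parameter transition and transversion components
#'
#' Given the proportions of transition (`P`) and transversion (`Q`)
#' differences, returns the K2P transitional component
#' `A = ln(1/(1-2P-Q))/2 - ln(1/(1-2Q))/4` and transversional component
#' `B = ln(1/(1-2Q))/2`. When a logarithm argument is non-positive the
#' distance is saturated: the component is `NA` and `valid` is `FALSE`
#' (no exception is thrown; callers propagate the flag).
#'
#' @param P,Q numeric vectors of transition / transversion proportions
#' @return tibble with columns `A`, `B`, `valid`
#' @examples
#' k2p_components(1 / 3, 0) # A = log(3)/2, B = 0
#' @export
k2p_components <- function(P, Q) {
  stopifnot(length(P) == length(Q))
  if (any(P < 0 | Q < 0 | P + Q > 1 + 1e-12, na.rm = TRUE)) {
    stop("require P, Q >= 0 and P + Q <= 1")
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  valid <- w1 > 0 & w2 > 0
  A <- ifelse(valid, -0.5 * log(w1) + 0.25 * log(w2), NA_real_)
  B <- ifelse(valid, -0.5 * log(w2), NA_real_)
  tibble::tibble(A = A, B = B, valid = valid)
}

# Vectorised PBL composition from class totals. L, S, V: n x 3 matrices
# (classes 0, 2, 4). Returns tibble of dN, dS, per-class components, flags.
.dnds_from_totals <- function(L, S, V) {
  comp <- vector("list", 3L)
  for (i in 1:3) {
    Li <- L[, i]
    P <- ifelse(Li > 0, S[, i] / Li, 0)
    Q <- ifelse(Li > 0, V[, i] / Li, 0)
    comp[[i]] <- k2p_components(P, Q)
  }
  L0 <- L[, 1]; L2 <- L[, 2]; L4 <- L[, 3]
  use0 <- L0 > 0; use2 <- L2 > 0; use4 <- L4 > 0
  zero_if_unused <- function(x, use) ifelse(use, x, 0)
  A0 <- zero_if_unused(comp[[1]]$A, use0)
  B0 <- zero_if_unused(comp[[1]]$B, use0)
  A2 <- zero_if_unused(comp[[2]]$A, use2)
  B2 <- zero_if_unused(comp[[2]]$B, use2)
  A4 <- zero_if_unused(comp[[3]]$A, use4)
  B4 <- zero_if_unused(comp[[3]]$B, use4)

  valid_dS <- (!use2 | comp[[2]]$valid) & (!use4 | comp[[3]]$valid)
  valid_dN <- (!use0 | comp[[1]]$valid) & (!use2 | comp[[2]]$valid)
  dS <- ifelse(valid_dS, (L2 * A2 + L4 * A4) / (L2 + L4) + B4, NA_real_)
  dN <- ifelse(valid_dN, A0 + (L0 * B0 + L2 * B2) / (L0 + L2), NA_real_)
  tibble::tibble(dN = dN, dS = dS,
                 A0 = A0, A2 = A2, A4 = A4, B0 = B0, B2 = B2, B4 = B4,
                 valid_dN = valid_dN, valid_dS = valid_dS)
}

#' PBL nonsynonymous and synonymous distances from pair tallies
#'
#' Composes the per-class K2P components into the Pamilo-Bianchi-Li
#' distances: `dS = (L2*A2 + L4*A4)/(L2 + L4) + B4` (substitutions per
#' synonymous site) and `dN = A0 + (L0*B0 + L2*B2)/(L0 + L2)` (per
#' nonsynonymous site), with `Ai, Bi = k2p_components(Si/Li, Vi/Li)`.
#' Classes with `Li = 0` contribute zero with zero weight. Saturated
#' logarithms flag the affected distance invalid (`NA`) rather than erroring.
#'
#' @param counts one-row tibble (or named list) as from [count_codon_pair()]
#' @return one-row tibble with `dN`, `dS`, per-class `A`/`B` components and
#'   `valid_dN`, `valid_dS`
#' @examples
#' code <- genetic_code(2)
#' count_codon_pair("ATAGGGGGGGGGTTA", "ATGGGGGGGGGATTA", code) |>
#'   pair_dnds()
#' @export
pair_dnds <- function(counts) {
  cn <- as.list(counts)
  L <- matrix(c(cn$L0, cn$L2, cn$L4), ncol = 3)
  S <- matrix(c(cn$S0, cn$S2, cn$S4), ncol = 3)
  V <- matrix(c(cn$V0, cn$V2, cn$V4), ncol = 3)
  if (any(L[, 2] + L[, 3] <= 0)) stop("L2 + L4 must be positive")
  if (any(L[, 1] + L[, 2] <= 0)) stop("L0 + L2 must be positive")
  .dnds_from_totals(L, S, V)
}

#' All pairwise PBL distances within an alignment
#'
#' @param alignment a [codon_alignment()] (or named character vector of
#'   equal-length coding sequences)
#' @param code a [genetic_code()]
#' @return tibble with one row per unordered pair: `id_a`, `id_b`, `dN`,
#'   `dS`, `valid_dN`, `valid_dS`
#' @export
dnds_pairs <- function(alignment, code = genetic_code(2)) {
  seqs <- if (inherits(alignment, "codon_alignment")) {
    stats::setNames(alignment$sequences, alignment$samples$sample_id)
  } else alignment
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  enc <- lapply(seqs, function(s) .encode_codons(toupper(s)))
  pairs <- utils::combn(n, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ct <- .pair_column_tallies(enc[[i]], enc[[j]], code)
    tot <- rowSums(ct$tallies)
    d <- .dnds_from_totals(matrix(tot[1:3], ncol = 3),
                           matrix(tot[4:6], ncol = 3),
                           matrix(tot[7:9], ncol = 3))
    tibble::tibble(id_a = names(seqs)[i], id_b = names(seqs)[j],
                   dN = d$dN, dS = d$dS,
                   valid_dN = d$valid_dN, valid_dS = d$valid_dS)
  })
  res
}
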