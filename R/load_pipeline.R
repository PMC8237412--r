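# Per-breed deleterious-load estimation: piN and piS as unweighted means of
# valid pairwise PBL distances, omega_P = piN/piS, a single pooled
# interspecies omega_S against the outgroup, the deleterious fraction
# delta = (omega_P - omega_S)/omega_P, and codon-column bootstrap standard
# errors in which the same resampled columns are applied to the ingroup and
# the outgroup so omega_P and omega_S covary.

# Full-width (9 x C) per-column tallies for one pair; excluded codons are
# zero columns so codon-column resampling is a weighted row sum.
.pair_tallies_full <- function(ia, ib, code) {
  C <- length(ia)
  ct <- .pair_column_tallies(ia, ib, code)
  full <- matrix(0, 9L, C)
  full[, which(ct$compared)] <- ct$tallies
  full
}

# Stacked tallies for a list of pairs: (9 * n_pairs) x C matrix, pair-major.
.stack_pair_tallies <- function(enc, pairs, code) {
  C <- length(enc[[1]])
  M <- matrix(0, 9L * ncol(pairs), C)
  for (k in seq_len(ncol(pairs))) {
    M[(k - 1L) * 9L + 1:9, ] <-
      .pair_tallies_full(enc[[pairs[1, k]]], enc[[pairs[2, k]]], code)
  }
  M
}

# Totals (9*P x R) -> tibble columns dN, dS as P x R matrices
.pair_dnds_matrix <- function(tot, P) {
  R <- ncol(tot)
  arr <- array(tot, dim = c(9L, P, R))
  as3 <- function(rows) matrix(aperm(arr[rows, , , drop = FALSE],
                                     c(2, 3, 1)), ncol = 3L)
  d <- .dnds_from_totals(as3(1:3), as3(4:6), as3(7:9))
  list(dN = matrix(d$dN, P, R), dS = matrix(d$dS, P, R))
}

.encode_alignment <- function(alignment) {
  lapply(alignment$sequences, .encode_codons)
}

.breed_variant_classes <- function(enc, code) {
  n <- length(enc)
  pairs <- utils::combn(n, 2L)
  tot <- numeric(9)
  for (k in seq_len(ncol(pairs))) {
    ct <- .pair_column_tallies(enc[[pairs[1, k]]], enc[[pairs[2, k]]], code)
    tot <- tot + rowSums(ct$tallies)
  }
  names(tot) <- .TALLY_ROWS
  c(syn = unname(tot["S2"] + tot["S4"] + tot["V4"]),
    nonsyn = unname(tot["S0"] + tot["V0"] + tot["V2"]))
}

#' Breed inclusion filter
#'
#' A breed enters the load analysis when it has more than four sampled
#' mitogenomes (n >= 5) and shows at least one synonymous and at least one
#' nonsynonymous segregating change, classified by the PBL site routing
#' (synonymous signal: transitions at 2-/4-fold sites and transversions at
#' 4-fold sites; nonsynonymous: everything at 0-fold plus transversions at
#' 2-fold sites). Both filters reduce estimation error in piN/piS ratios.
#'
#' @param alignment a [codon_alignment()] with breed labels
#' @param code a [genetic_code()]
#' @param min_n minimum sample count (default 5, i.e. "more than four")
#' @return tibble with `breed`, `n`, `syn_changes`, `nonsyn_changes`,
#'   `included`, `reason` ("" when included)
#' @export
breed_filter <- function(alignment, code = genetic_code(2), min_n = 5L) {
  stopifnot(inherits(alignment, "codon_alignment"))
  enc <- .encode_alignment(alignment)
  breeds <- alignment$samples$breed
  purrr::map_dfr(unique(breeds[!is.na(breeds)]), function(b) {
    rows <- which(breeds == b)
    n <- length(rows)
    syn <- NA_real_; nonsyn <- NA_real_
    if (n >= 2L) {
      vc <- .breed_variant_classes(enc[rows], code)
      syn <- vc[["syn"]]; nonsyn <- vc[["nonsyn"]]
    }
    reason <- if (n < min_n) {
      sprintf("n <= %d", min_n - 1L)
    } else if (syn == 0 && nonsyn == 0) {
      "no variants"
    } else if (syn == 0) {
      "no synonymous variant"
    } else if (nonsyn == 0) {
      "no nonsynonymous variant"
    } else ""
    tibble::tibble(breed = b, n = n, syn_changes = syn,
                   nonsyn_changes = nonsyn,
                   included = reason == "", reason = reason)
  })
}

#' Within-population nonsynonymous and synonymous diversity
#'
#' piN and piS are the unweighted means of the valid pairwise PBL dN and dS
#' over all n(n-1)/2 pairs. Saturated (invalid) pairwise values are
#' excluded from the respective mean and counted.
#'
#' @param alignment a [codon_alignment()] of one population (>= 2 sequences)
#' @param code a [genetic_code()]
#' @return one-row tibble: `pi_N`, `pi_S`, `n_pairs`, `n_invalid_pairs`
#' @export
pi_n_pi_s <- function(alignment, code = genetic_code(2)) {
  pw <- dnds_pairs(alignment, code)
  if (all(!pw$valid_dN) && all(!pw$valid_dS)) {
    stop("all pairwise distances are saturated")
  }
  tibble::tibble(
    pi_N = mean(pw$dN[pw$valid_dN]),
    pi_S = mean(pw$dS[pw$valid_dS]),
    n_pairs = nrow(pw),
    n_invalid_pairs = sum(!pw$valid_dN | !pw$valid_dS)
  )
}

#' Population omega: piN / piS
#'
#' @param pi_N,pi_S nonsynonymous and synonymous diversities
#' @return `pi_N / pi_S`
#' @export
omega_p <- function(pi_N, pi_S) {
  if (any(pi_S <= 0)) {
    stop("pi_S must be positive; breeds without synonymous variation ",
         "should have been excluded by breed_filter()")
  }
  pi_N / pi_S
}

#' Interspecies omega from ingroup-vs-outgroup divergence
#'
#' dN and dS are the means of the valid pairwise PBL distances over all
#' ingroup x outgroup pairs; omega_S = dN/dS proxies the neutrally fixable
#' fraction of nonsynonymous changes between the species.
#'
#' @param ingroup a [codon_alignment()] (or character vector of sequences)
#' @param outgroup one or more outgroup coding sequences (character vector),
#'   frame-compatible with the ingroup
#' @param code a [genetic_code()]
#' @return one-row tibble: `d_N`, `d_S`, `omega_S`, `n_pairs`,
#'   `n_invalid_pairs`
#' @export
interspecies_omega_s <- function(ingroup, outgroup, code = genetic_code(2)) {
  in_seqs <- if (inherits(ingroup, "codon_alignment")) {
    ingroup$sequences
  } else as.character(ingroup)
  outgroup <- as.character(outgroup)
  enc_in <- lapply(in_seqs, function(s) .encode_codons(toupper(s)))
  enc_out <- lapply(outgroup, function(s) .encode_codons(toupper(s)))
  dn <- c(); ds <- c(); vn <- c(); vs <- c()
  for (i in seq_along(enc_in)) {
    for (j in seq_along(enc_out)) {
      ct <- .pair_column_tallies(enc_in[[i]], enc_out[[j]], code)
      tot <- rowSums(ct$tallies)
      d <- .dnds_from_totals(matrix(tot[1:3], ncol = 3),
                             matrix(tot[4:6], ncol = 3),
                             matrix(tot[7:9], ncol = 3))
      dn <- c(dn, d$dN); ds <- c(ds, d$dS)
      vn <- c(vn, d$valid_dN); vs <- c(vs, d$valid_dS)
    }
  }
  if (!any(vn) || !any(vs)) stop("all ingroup-outgroup pairs are saturated")
  d_N <- mean(dn[vn]); d_S <- mean(ds[vs])
  if (d_S == 0) stop("zero synonymous divergence: omega_S undefined")
  tibble::tibble(d_N = d_N, d_S = d_S, omega_S = d_N / d_S,
                 n_pairs = length(dn),
                 n_invalid_pairs = sum(!vn | !vs))
}

#' Deleterious fraction of segregating nonsynonymous variants
#'
#' `delta = (omega_P - omega_S) / omega_P`: the excess of segregating
#' nonsynonymous variation over the neutrally fixable fraction, i.e. the
#' proportion of segregating amino-acid variants that are deleterious.
#' `delta <= 1` by construction; negative values (omega_P < omega_S) are
#' returned with a warning, not clamped - they are a diagnostic.
#'
#' @param omega_P population piN/piS (> 0)
#' @param omega_S interspecies dN/dS (>= 0)
#' @param warn warn when any delta is negative (default TRUE)
#' @return numeric vector of deleterious fractions
#' @examples
#' delta_fraction(0.59, 0.0826) # ~0.86
#' @export
delta_fraction <- function(omega_P, omega_S, warn = TRUE) {
  if (any(omega_P <= 0)) stop("omega_P must be positive")
  if (any(omega_S < 0)) stop("omega_S must be non-negative")
  d <- (omega_P - omega_S) / omega_P
  if (warn && any(d < 0)) {
    warning(sum(d < 0), " negative delta value(s): omega_P < omega_S",
            call. = FALSE)
  }
  d
}

# ---- bootstrap --------------------------------------------------------

# Shared machinery: given stacked tally matrices for the breed's pairs and
# for the omega_S pair set, draw R codon-column resamples and return the
# replicate table. weights W apply to both matrices (columns covary).
.boot_replicates <- function(M_breed, P_breed, M_out, P_out, C,
                             n_replicates) {
  W <- matrix(0, C, n_replicates)
  for (r in seq_len(n_replicates)) {
    W[, r] <- tabulate(sample.int(C, C, replace = TRUE), nbins = C)
  }
  bd <- .pair_dnds_matrix(M_breed %*% W, P_breed)
  od <- .pair_dnds_matrix(M_out %*% W, P_out)
  tibble::tibble(
    replicate = seq_len(n_replicates),
    pi_N = colMeans(bd$dN, na.rm = TRUE),
    pi_S = colMeans(bd$dS, na.rm = TRUE),
    d_N = colMeans(od$dN, na.rm = TRUE),
    d_S = colMeans(od$dS, na.rm = TRUE)
  ) |>
    dplyr::mutate(
      degenerate = is.na(.data$pi_S) | .data$pi_S == 0 |
        is.na(.data$d_S) | .data$d_S == 0 | is.na(.data$pi_N) |
        is.na(.data$d_N),
      omega_P = ifelse(.data$degenerate, NA_real_, .data$pi_N / .data$pi_S),
      omega_S = ifelse(.data$degenerate, NA_real_, .data$d_N / .data$d_S),
      # delta is undefined when a replicate has no nonsynonymous signal
      delta = ifelse(.data$degenerate | .data$omega_P <= 0, NA_real_,
                     (.data$omega_P - .data$omega_S) / .data$omega_P)
    )
}

#' Codon-bootstrap standard errors for one breed
#'
#' Resamples codon columns with replacement; the same resampled column set
#' is applied to the within-breed pairs and to the ingroup-vs-outgroup
#' pairs, so omega_P and omega_S covary within a replicate and the SE of
#' delta reflects that covariance. Replicates with zero synonymous signal
#' (pi_S = 0 or d_S = 0) are dropped and counted; more than 50% degenerate
#' replicates is an error.
#'
#' @param alignment a [codon_alignment()] of one breed (must pass the
#'   variant-class requirements of [breed_filter()])
#' @param outgroup outgroup coding sequence(s), character vector
#' @param n_replicates bootstrap replicates (default 100)
#' @param seed RNG seed
#' @param code a [genetic_code()]
#' @param omega_s_ingroup optional [codon_alignment()] (or sequences) to use
#'   as the ingroup of the omega_S comparison (default: the breed itself;
#'   the study pipeline passes the pooled ingroup here)
#' @return list with `se_omega_P`, `se_delta`, `replicates` (tibble),
#'   `n_degenerate`
#' @export
bootstrap_load <- function(alignment, outgroup, n_replicates = 100L,
                           seed = 1L, code = genetic_code(2),
                           omega_s_ingroup = NULL) {
  stopifnot(inherits(alignment, "codon_alignment"), n_replicates >= 2L)
  enc <- .encode_alignment(alignment)
  if (length(enc) < 2L) stop("need >= 2 sequences")
  vc <- .breed_variant_classes(enc, code)
  if (vc[["syn"]] == 0 || vc[["nonsyn"]] == 0) {
    stop("breed fails the variant-class precondition (needs >= 1 ",
         "synonymous and >= 1 nonsynonymous segregating change); ",
         "see breed_filter()")
  }
  out_seqs <- as.character(outgroup)
  enc_out <- lapply(out_seqs, function(s) .encode_codons(toupper(s)))
  in_seqs <- if (is.null(omega_s_ingroup)) {
    enc
  } else if (inherits(omega_s_ingroup, "codon_alignment")) {
    .encode_alignment(omega_s_ingroup)
  } else {
    lapply(as.character(omega_s_ingroup),
           function(s) .encode_codons(toupper(s)))
  }
  C <- length(enc[[1]])
  pairs_b <- utils::combn(length(enc), 2L)
  M_breed <- .stack_pair_tallies(enc, pairs_b, code)
  pairs_o <- rbind(rep(seq_along(in_seqs), each = length(enc_out)),
                   length(in_seqs) +
                     rep(seq_along(enc_out), times = length(in_seqs)))
  M_out <- .stack_pair_tallies(c(in_seqs, enc_out), pairs_o, code)

  set.seed(seed)
  reps <- .boot_replicates(M_breed, ncol(pairs_b), M_out, ncol(pairs_o), C,
                           n_replicates)
  n_bad <- sum(reps$degenerate)
  if (n_bad > n_replicates / 2) {
    stop("more than half of the bootstrap replicates are degenerate (",
         n_bad, "/", n_replicates, ")")
  }
  ok <- !reps$degenerate
  list(se_omega_P = stats::sd(reps$omega_P[ok]),
       se_delta = stats::sd(reps$delta[ok], na.rm = TRUE),
       replicates = reps,
       n_degenerate = n_bad)
}

#' Per-breed deleterious mutation load
#'
#' The study-level pipeline: applies [breed_filter()], computes piN, piS and
#' omega_P per included breed, a single pooled omega_S from all included
#' ingroup sequences against the outgroup (shared by all breeds; per-breed
#' omega_S available via `omega_s_mode = "per_breed"`), the deleterious
#' fraction delta per breed, and codon-bootstrap standard errors for
#' omega_P and delta.
#'
#' @param alignment a [codon_alignment()] with breed labels
#' @param outgroup outgroup coding sequence(s) at interspecies divergence
#' @param code a [genetic_code()] (default vertebrate mitochondrial)
#' @param n_boot bootstrap replicates (default 100); 0 skips the bootstrap
#' @param seed RNG seed for the bootstrap
#' @param omega_s_mode `"pooled"` (default, one omega_S shared by all
#'   breeds) or `"per_breed"`
#' @param min_n breed inclusion threshold (default 5 samples)
#' @return tibble of class `breed_load` with one row per included breed:
#'   `breed`, `n_samples`, `pi_N`, `pi_S`, `omega_P`, `se_omega_P`,
#'   `omega_S`, `delta`, `se_delta`, `n_boot`, `n_invalid_pairs`,
#'   `n_degenerate_reps`. The [breed_filter()] report is in
#'   `attr(, "filter")`, the interspecies comparison in `attr(, "omega_s")`.
#' @export
estimate_breed_load <- function(alignment, outgroup, code = genetic_code(2),
                                n_boot = 100L, seed = 1L,
                                omega_s_mode = c("pooled", "per_breed"),
                                min_n = 5L) {
  stopifnot(inherits(alignment, "codon_alignment"))
  omega_s_mode <- match.arg(omega_s_mode)
  filt <- breed_filter(alignment, code, min_n)
  keep <- filt$breed[filt$included]
  if (!length(keep)) stop("no breed passes the inclusion filter")
  pooled <- subset_samples(alignment,
                           alignment$samples$breed %in% keep)
  os_pooled <- interspecies_omega_s(pooled, outgroup, code)

  rows <- purrr::map_dfr(keep, function(b) {
    baln <- subset_samples(alignment, which(alignment$samples$breed == b))
    pp <- pi_n_pi_s(baln, code)
    os <- if (omega_s_mode == "pooled") {
      os_pooled
    } else {
      interspecies_omega_s(baln, outgroup, code)
    }
    om_p <- omega_p(pp$pi_N, pp$pi_S)
    dl <- delta_fraction(om_p, os$omega_S, warn = FALSE)
    se_op <- NA_real_; se_dl <- NA_real_; ndeg <- NA_integer_
    if (n_boot >= 2L) {
      bt <- bootstrap_load(
        baln, outgroup, n_replicates = n_boot,
        seed = seed + match(b, keep), code = code,
        omega_s_ingroup = if (omega_s_mode == "pooled") pooled else NULL)
      se_op <- bt$se_omega_P; se_dl <- bt$se_delta
      ndeg <- bt$n_degenerate
    }
    tibble::tibble(breed = b, n_samples = nrow(baln$samples),
                   pi_N = pp$pi_N, pi_S = pp$pi_S,
                   omega_P = om_p, se_omega_P = se_op,
                   omega_S = os$omega_S, delta = dl, se_delta = se_dl,
                   n_boot = as.integer(n_boot),
                   n_invalid_pairs = pp$n_invalid_pairs,
                   n_degenerate_reps = ndeg)
  })
  structure(rows, class = c("breed_load", class(rows)),
            filter = filt, omega_s = os_pooled,
            config = list(code_table = code$table_id, n_boot = n_boot,
                          seed = seed, omega_s_mode = omega_s_mode,
                          min_n = min_n))
}

#' @export
glance.breed_load <- function(x, ...) {
  tibble::tibble(
    n_breeds = nrow(x),
    omega_P_fold_range = fold_range(x$omega_P),
    omega_S = attr(x, "omega_s")$omega_S,
    mean_delta = mean(x$delta),
    n_negative_delta = sum(x$delta < 0)
  )
}
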