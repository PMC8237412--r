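# Codon machinery shared by the whole package. Codons are indexed 1..64 in
# TCAG order (index = 16*t1 + 4*t2 + t3 + 1 with T=0, C=1, A=2, G=3), the
# order in which NCBI translation tables print their amino-acid strings.

BASES <- c("T", "C", "A", "G")

# NCBI translation tables: 1 = standard, 2 = vertebrate mitochondrial
# (AGA/AGG stop, ATA Met, TGA Trp).
.TRANSL_TABLES <- list(
  `1` = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `2` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG"
)

.ALL_CODONS <- {
  g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

# codon index -> base index (1..4, TCAG) at each of the three positions
.CODON_BASE <- {
  i <- 0:63
  cbind(i %/% 16L, (i %/% 4L) %% 4L, i %% 4L) + 1L
}

# TRUE where the base pair (row, col) is a transition (T<->C or A<->G)
.IS_TRANSITION <- {
  pyr <- c(TRUE, TRUE, FALSE, FALSE)
  m <- outer(pyr, pyr, `==`) & !diag(4)
  m
}

#' Build a genetic code table
#'
#' Constructs the codon-to-amino-acid map plus the derived per-position
#' degeneracy classification used by the Pamilo-Bianchi-Li site partition.
#' The default for mitochondrial protein-coding genes is NCBI translation
#' table 2 (vertebrate mitochondrial: AGA/AGG are stops, ATA is Met,
#' TGA is Trp), giving 60 sense codons and 4 stops.
#'
#' @param table_id NCBI translation table number; 1 (standard) and 2
#'   (vertebrate mitochondrial) are supported.
#' @return An object of class `genetic_code`: a list with `table_id`, the
#'   named character vector `codon_to_aa` (stops as `"*"`), the logical
#'   `is_sense`, the 64 x 3 integer `degeneracy` matrix (0/2/4, `NA` for
#'   stop codons), and internal lookup tables used by the pairwise counters.
#' @examples
#' code <- genetic_code(2)
#' code$codon_to_aa[c("AGA", "ATA", "TGA")]
#' codon_degeneracy("GGG", code)
#' @export
genetic_code <- function(table_id = 2) {
  key <- as.character(table_id)
  if (!key %in% names(.TRANSL_TABLES)) {
    stop("unsupported translation table: ", table_id,
         " (supported: ", paste(names(.TRANSL_TABLES), collapse = ", "), ")")
  }
  aa <- strsplit(.TRANSL_TABLES[[key]], "")[[1]]
  names(aa) <- .ALL_CODONS
  is_sense <- aa != "*"

  # syn[c, p, b]: mutating codon c at position p to base b keeps the amino
  # acid AND yields a sense codon. Mutations to stops count nonsynonymous.
  syn <- array(NA, dim = c(64, 3, 4))
  for (p in 1:3) {
    for (b in 1:4) {
      mut <- .mutate_codon_idx(1:64, p, b)
      syn[, p, b] <- is_sense & is_sense[mut] & aa == aa[mut]
    }
  }

  # degeneracy class per codon position: 4 iff all three alternatives are
  # synonymous, 0 iff none, else 2; defined for sense codons only
  deg <- matrix(NA_integer_, 64, 3)
  for (p in 1:3) {
    n_syn <- integer(64)
    for (b in 1:4) {
      alt <- .CODON_BASE[, p] != b
      n_syn <- n_syn + as.integer(alt & syn[, p, b])
    }
    deg[, p] <- ifelse(is_sense, ifelse(n_syn == 3L, 4L,
                                        ifelse(n_syn == 0L, 0L, 2L)), NA_integer_)
  }
  rownames(deg) <- .ALL_CODONS

  structure(
    list(table_id = as.integer(table_id), codon_to_aa = aa,
         is_sense = is_sense, degeneracy = deg, syn = syn),
    class = "genetic_code"
  )
}

.mutate_codon_idx <- function(idx, pos, base) {
  b <- .CODON_BASE[idx, , drop = FALSE]
  b[, pos] <- base
  16L * (b[, 1] - 1L) + 4L * (b[, 2] - 1L) + b[, 3]
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI translation table", x$table_id, "-",
      sum(x$is_sense), "sense codons,", sum(!x$is_sense), "stops\n")
  invisible(x)
}

#' @describeIn genetic_code one row per codon with amino acid and the
#'   three-position degeneracy classes, as a tibble.
#' @param x a `genetic_code`
#' @param ... unused
#' @export
tidy.genetic_code <- function(x, ...) {
  tibble::tibble(
    codon = .ALL_CODONS,
    aa = unname(x$codon_to_aa),
    deg1 = x$degeneracy[, 1],
    deg2 = x$degeneracy[, 2],
    deg3 = x$degeneracy[, 3]
  )
}

#' Degeneracy classes of a codon
#'
#' Classifies each of the three codon positions into the 0-, 2- or 4-fold
#' degeneracy class: 4-fold if all three single-base alternatives are
#' synonymous, 0-fold if none is, 2-fold otherwise. Changes creating stop
#' codons count as nonsynonymous.
#'
#' @param codon a 3-mer over ACGT encoding a sense codon under `code`
#' @param code a [genetic_code()]
#' @return integer vector of length 3 with values in `{0, 2, 4}`
#' @export
codon_degeneracy <- function(codon, code = genetic_code(2)) {
  stopifnot(is.character(codon), length(codon) == 1L, nchar(codon) == 3L)
  idx <- match(toupper(codon), .ALL_CODONS)
  if (is.na(idx)) stop("not an unambiguous ACGT codon: ", codon)
  if (!code$is_sense[idx]) stop("stop codon has no degeneracy class: ", codon)
  unname(code$degeneracy[idx, ])
}

# Encode an upper-case nucleotide string into codon indices 1..64; codons
# containing non-ACGT symbols come back NA, stop codons are kept (callers
# decide exclusion).
.encode_codons <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(ch) %% 3L != 0L) {
    stop("sequence length ", length(ch), " is not a multiple of 3")
  }
  b <- match(ch, BASES)
  dim(b) <- c(3L, length(b) %/% 3L)
  idx <- 16L * (b[1, ] - 1L) + 4L * (b[2, ] - 1L) + b[3, ]
  idx
}

.decode_codons <- function(idx) {
  paste(.ALL_CODONS[idx], collapse = "")
}
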