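# Distance-based breed-age estimation. The coalescence distance of a breed
# (expected substitutions per site from the sample's common ancestor to the
# tips) is estimated from whole-alignment K2P distances - by default as the
# root height of the UPGMA tree - and converted to years by dividing by the
# per-site per-year mitochondrial mutation rate. This is a documented
# distance-based estimator, not a Bayesian multispecies-coalescent fit; the
# method tag travels with every output so the two are never conflated.

#' Default mitochondrial mutation rate (substitutions per site per year)
#' @export
MITO_MU <- 2.043e-8

#' Whole-alignment K2P distance matrix
#'
#' Kimura 2-parameter nucleotide distances over all aligned sites with
#' pairwise deletion of ambiguous sites (via [ape::dist.dna()]).
#'
#' @param alignment a [codon_alignment()] (>= 2 sequences)
#' @return symmetric numeric matrix (zero diagonal) with sample ids as
#'   dimnames
#' @export
whole_alignment_distances <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  n <- length(alignment$sequences)
  if (n < 2L) stop("need >= 2 sequences")
  mat <- do.call(rbind, strsplit(tolower(alignment$sequences), ""))
  rownames(mat) <- alignment$samples$sample_id
  dna <- ape::as.DNAbin(mat)
  d <- ape::dist.dna(dna, model = "K80", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(d))) {
    stop("saturated K2P distance in whole-alignment matrix")
  }
  d
}

#' Coalescence distance of a sample
#'
#' `"upgma_root"` (default): the root height of the UPGMA (average-linkage)
#' tree built from the distance matrix, i.e. half the height of the final
#' merge. `"half_mean_pairwise"`: half the mean off-diagonal distance. Both
#' equal d/2 for a single pair at distance d.
#'
#' @param dist_matrix symmetric distance matrix (e.g. from
#'   [whole_alignment_distances()])
#' @param method `"upgma_root"` or `"half_mean_pairwise"`
#' @return non-negative scalar, substitutions per site
#' @export
coalescence_distance <- function(dist_matrix,
                                 method = c("upgma_root",
                                            "half_mean_pairwise")) {
  method <- match.arg(method)
  dist_matrix <- as.matrix(dist_matrix)
  n <- nrow(dist_matrix)
  if (n < 2L) stop("need >= 2 sequences")
  if (method == "half_mean_pairwise") {
    return(mean(dist_matrix[lower.tri(dist_matrix)]) / 2)
  }
  if (all(dist_matrix == 0)) return(0)
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = "average")
  max(hc$height) / 2
}

#' Convert a coalescence distance to years
#'
#' @param distance substitutions per site (>= 0)
#' @param mu mutation rate, substitutions per site per year (default
#'   [MITO_MU] = 2.043e-8)
#' @return `distance / mu`, in years
#' @examples
#' age_years(1.6957e-4) # ~8,300 years
#' @export
age_years <- function(distance, mu = MITO_MU) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(distance < 0)) stop("distance must be non-negative")
  distance / mu
}

#' Per-breed coalescence ages
#'
#' Estimates each breed's coalescence distance from whole-alignment K2P
#' distances and converts it to years.
#'
#' @param alignment a [codon_alignment()] with breed labels
#' @param mu mutation rate per site per year (default [MITO_MU])
#' @param method passed to [coalescence_distance()]
#' @param min_n minimum samples per breed (default 2)
#' @return tibble of class `breed_age`: `breed`, `n_samples`,
#'   `coalescence_distance`, `mu`, `age_years`, `method`
#' @export
estimate_breed_age <- function(alignment, mu = MITO_MU,
                               method = c("upgma_root",
                                          "half_mean_pairwise"),
                               min_n = 2L) {
  stopifnot(inherits(alignment, "codon_alignment"))
  method <- match.arg(method)
  breeds <- alignment$samples$breed
  out <- purrr::map_dfr(unique(breeds[!is.na(breeds)]), function(b) {
    rows <- which(breeds == b)
    if (length(rows) < min_n) return(NULL)
    baln <- subset_samples(alignment, rows)
    d <- whole_alignment_distances(baln)
    cd <- coalescence_distance(d, method)
    tibble::tibble(breed = b, n_samples = length(rows),
                   coalescence_distance = cd, mu = mu,
                   age_years = age_years(cd, mu), method = method)
  })
  structure(out, class = c("breed_age", class(out)))
}

#' UPGMA tree of a breed, for export
#'
#' @param dist_matrix symmetric distance matrix
#' @return an [ape::as.phylo()] ultrametric tree
#' @export
upgma_tree <- function(dist_matrix) {
  hc <- stats::hclust(stats::as.dist(as.matrix(dist_matrix)),
                      method = "average")
  ape::as.phylo(hc)
}
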