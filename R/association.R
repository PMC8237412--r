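# Association between breed age and the deleterious fraction delta. The
# headline figure plots log10(age) against log10(delta) with a least-squares
# line; Pearson and Spearman coefficients are co-reported on both scales.

#' Correlation between two variables with optional log10 transform
#'
#' Pearson's r with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom;
#' Spearman's coefficient is Pearson on average ranks with the same t
#' approximation. With `transform = "log10"`, pairs containing a
#' non-positive value are dropped and counted before transforming. The
#' least-squares line is fitted on the analysis (possibly transformed)
#' scale.
#'
#' @param x,y equal-length numeric vectors (n >= 3 after dropping)
#' @param method `"pearson"` (default) or `"spearman"`
#' @param transform `"none"` (default) or `"log10"`
#' @return one-row tibble: `method`, `transform`, `r`, `p_value`, `n`,
#'   `n_dropped`, `slope`, `intercept`
#' @examples
#' correlate(1:10, 2 * (1:10)) # r = 1, slope = 2
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      transform = c("none", "log10")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (transform == "log10") keep <- keep & x > 0 & y > 0
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 usable pairs (have ", n, ")")
  if (transform == "log10") {
    x <- log10(x); y <- log10(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  xs <- if (method == "spearman") rank(x, ties.method = "average") else x
  ys <- if (method == "spearman") rank(y, ties.method = "average") else y
  r <- stats::cor(xs, ys)
  p <- .cor_p_value(r, n)
  fit <- stats::lm.fit(cbind(1, x), y)
  tibble::tibble(method = method, transform = transform, r = r,
                 p_value = p, n = n, n_dropped = n_dropped,
                 slope = fit$coefficients[2], intercept = fit$coefficients[1])
}

#' Two-sided p-value for a correlation coefficient
#'
#' Closed form from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom; `|r| = 1` maps to `p = 0`. Used for Pearson's r and, as the
#' large-sample approximation, for Spearman's coefficient on ranks.
#'
#' @param r correlation coefficient in `[-1, 1]`
#' @param n number of pairs (> 2)
#' @return two-sided p-value
#' @examples
#' correlation_p_value(-0.86, 18) # ~5e-6
#' @export
correlation_p_value <- function(r, n) {
  stopifnot(abs(r) <= 1, n > 2)
  if (1 - r^2 <= 0) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

.cor_p_value <- correlation_p_value

#' Fold range of a positive vector
#'
#' `max(x) / min(x)` - e.g. the spread of omega_P across breeds.
#'
#' @param values positive numeric vector, length >= 2
#' @return scalar ratio >= 1
#' @examples
#' fold_range(c(0.59, 0.116)) # ~5.1
#' @export
fold_range <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values) | values <= 0)) {
    stop("all values must be positive and finite")
  }
  max(values) / min(values)
}

#' Age-load association for a set of breeds
#'
#' Joins a [estimate_breed_load()] table with a [estimate_breed_age()]
#' table by breed and computes the age-delta correlation for every
#' combination of method (Pearson, Spearman) and scale (log10, raw).
#'
#' @param load a `breed_load` tibble (needs `breed`, `delta`)
#' @param age a `breed_age` tibble (needs `breed`, `age_years`)
#' @return object of class `age_load_cor`: list with `results` (4-row
#'   correlation tibble), `scatter` (per-breed table with log10 columns)
#'   and `n_nonpositive_delta`
#' @export
correlate_age_load <- function(load, age) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(load), "breed", "delta"),
    dplyr::select(tibble::as_tibble(age), "breed", "age_years"),
    by = "breed")
  if (nrow(joined) < 3L) stop("fewer than 3 breeds in common")
  grid <- tidyr::expand_grid(method = c("pearson", "spearman"),
                             transform = c("log10", "none"))
  results <- purrr::pmap_dfr(grid, function(method, transform) {
    correlate(joined$age_years, joined$delta, method, transform)
  })
  scatter <- joined |>
    dplyr::mutate(
      log10_age = ifelse(.data$age_years > 0,
                         log10(pmax(.data$age_years, 1e-300)), NA_real_),
      log10_delta = ifelse(.data$delta > 0,
                           log10(pmax(.data$delta, 1e-300)), NA_real_))
  structure(list(results = results, scatter = scatter,
                 n_nonpositive_delta = sum(joined$delta <= 0)),
            class = "age_load_cor")
}

#' @export
print.age_load_cor <- function(x, ...) {
  cat("<age_load_cor>", nrow(x$scatter), "breeds;",
      x$n_nonpositive_delta, "with delta <= 0 excluded from log scale\n")
  print(x$results)
  invisible(x)
}

#' @export
tidy.age_load_cor <- function(x, ...) x$results

#' @export
glance.age_load_cor <- function(x, ...) {
  head_row <- dplyr::filter(x$results, .data$method == "pearson",
                            .data$transform == "log10")
  tibble::tibble(r = head_row$r, p_value = head_row$p_value,
                 n = head_row$n, method = "pearson", transform = "log10")
}
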