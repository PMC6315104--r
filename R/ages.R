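#' The exponential-growth cell-age distribution
#'
#' In a steadily (exponentially) growing population the density of cell ages
#' \eqn{a \in [0,1]} (fraction of the cell cycle elapsed) is
#' \deqn{p(a) = 2 \ln 2 \cdot 2^{-a},}
#' i.e. newborn cells are twice as frequent as cells about to divide. The
#' corresponding CDF is \eqn{F(a) = 2(1 - 2^{-a})}, whose inverse underlies
#' the duplication-age estimator ([age_at_duplication()]).
#'
#' @param a vector of ages in `[0, 1]`.
#' @return `cell_age_density`/`cell_age_cdf` evaluate the density / CDF.
#' @seealso [sample_cell_ages()], [age_at_duplication()]
#' @export
cell_age_density <- function(a) {
  stopifnot(all(a >= 0 & a <= 1))
  2 * log(2) * 2^(-a)
}

#' @rdname cell_age_density
#' @export
cell_age_cdf <- function(a) {
  stopifnot(all(a >= 0 & a <= 1))
  2 * (1 - 2^(-a))
}

#' Sample cell ages from the exponential-growth age distribution
#'
#' Draws i.i.d. ages by inverse-CDF sampling: with \eqn{u \sim U(0,1)},
#' \eqn{a = -\log_2(1 - u/2)}.
#'
#' @param n number of cells (>= 1).
#' @param seed integer seed; identical seeds give identical draws.
#' @return numeric vector of `n` ages in `[0, 1]`.
#' @examples
#' a <- sample_cell_ages(1000, seed = 1)
#' mean(a < 0.5)                  # ~ 2 * (1 - 2^-0.5) = 0.586
#' @export
sample_cell_ages <- function(n, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stopf("`n` must be a single integer >= 1, got %s", deparse(n))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- runif(n)
  -log2(1 - u / 2)
}
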