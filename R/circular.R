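#' Circular mean of a sample of angles
#'
#' @param theta numeric vector of angles in radians.
#' @return Mean direction in \eqn{[-\pi, \pi)}.
#' @export
circ_mean <- function(theta) {
  if (length(theta) == 0L) stopf("circ_mean: empty input")
  Arg(sum(exp(1i * theta)))
}

#' Mean resultant length
#'
#' @param theta numeric vector of angles in radians.
#' @return \eqn{\bar{R} \in [0, 1]}.
#' @export
resultant_length <- function(theta) {
  if (length(theta) == 0L) stopf("resultant_length: empty input")
  Mod(sum(exp(1i * theta))) / length(theta)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle, using the mean resultant length \eqn{\bar R}, the statistic
#' \eqn{z = n \bar R^2}, and the standard small-sample series approximation
#' for the p-value (Zar).
#'
#' @param theta numeric vector of angles in radians (n >= 2).
#' @return list with `n`, `Rbar`, `z` and `p`.
#' @export
rayleigh_test <- function(theta) {
  n <- length(theta)
  if (n < 2L) stopf("rayleigh_test: need at least 2 angles, got %d", n)
  Rbar <- resultant_length(theta)
  z <- n * Rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  list(n = n, Rbar = Rbar, z = z, p = p)
}

#' Pairwise phase consistency (PPC)
#'
#' The mean cosine of all pairwise phase differences,
#' \deqn{PPC = \frac{2}{n(n-1)} \sum_{j<k} \cos(\theta_j - \theta_k),}
#' an unbiased estimator of phase-concentration squared: its expectation does
#' not depend on the number of spikes. Computed through the resultant-length
#' identity \eqn{PPC = (n^2 \bar R^2 - n) / (n(n-1))}, which is algebraically
#' exact (not an approximation of the double sum).
#'
#' @param theta numeric vector of angles in radians (n >= 2).
#' @return PPC value in \eqn{[-1, 1]} (up to floating point).
#' @export
ppc <- function(theta) {
  n <- length(theta)
  if (n < 2L) stopf("ppc: need at least 2 phases, got %d", n)
  S <- sum(exp(1i * theta))
  (Mod(S)^2 - n) / (n * (n - 1))
}

# Vectorized PPC over columns of a phase matrix (rows = observations).
ppc_cols <- function(theta_mat) {
  n <- nrow(theta_mat)
  if (is.null(n) || n < 2L) stopf("ppc_cols: need at least 2 rows")
  S2 <- colSums(cos(theta_mat))^2 + colSums(sin(theta_mat))^2
  (S2 - n) / (n * (n - 1))
}

# Vectorized Rayleigh p-values over columns of a phase matrix.
rayleigh_p_cols <- function(theta_mat) {
  n <- nrow(theta_mat)
  R2 <- (colSums(cos(theta_mat))^2 + colSums(sin(theta_mat))^2) / n^2
  z <- n * R2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  pmin(pmax(p, .Machine$double.xmin), 1)
}
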