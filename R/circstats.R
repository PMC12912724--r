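#' Circular mean of angles
#'
#' @param rad angles in radians.
#' @return mean direction in radians in `(-pi, pi]`, or `NA` if the
#'   resultant length is numerically zero.
#' @export
circ_mean <- function(rad) {
  z <- mean(exp(1i * rad))
  if (Mod(z) < 1e-12) return(NA_real_)
  Arg(z)
}

## Mean resultant length.
circ_r <- function(rad) Mod(mean(exp(1i * rad)))

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles deviates from uniformity on the circle.
#' The statistic is the mean resultant length `R = |mean(exp(i*theta))|`,
#' `z = n * R^2`, with the standard small-sample series approximation for
#' the p value (an exact Monte-Carlo p is available via `n_mc`).
#'
#' @param rad angles in radians (n >= 4).
#' @param n_mc if > 0, additionally compute a Monte-Carlo p value from
#'   `n_mc` uniform samples of the same size.
#' @param seed optional seed for the Monte-Carlo p.
#' @return list of class `circ_stat` with `statistic` (R), `z`, `p`, `n`
#'   (and `p_mc` when requested).
#' @export
rayleigh_test <- function(rad, n_mc = 0, seed = NULL) {
  n <- length(rad)
  if (n < 4) stop("Rayleigh test requires n >= 4")
  R <- circ_r(rad)
  z <- n * R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  out <- structure(list(statistic = R, z = z, p = p, n = n, method = "rayleigh"),
                   class = "circ_stat")
  if (n_mc > 0) {
    out$p_mc <- with_seed(seed, {
      null_z <- replicate(n_mc, {
        u <- stats::runif(n, 0, 2 * pi)
        n * circ_r(u)^2
      })
      (sum(null_z >= z) + 1) / (n_mc + 1)
    })
  }
  out
}

#' @export
print.circ_stat <- function(x, ...) {
  cat(sprintf("<circ_stat:%s> statistic = %.4f, p = %.4g, n = %d\n",
              x$method, x$statistic, x$p, x$n))
  invisible(x)
}

#' Pairwise phase consistency
#'
#' Mean cosine of the phase difference over all unordered pairs of angles,
#' a bias-free analog of the squared resultant length. Significance is
#' assessed against surrogates of uniformly distributed random phases.
#'
#' @param rad angles in radians (n >= 2).
#' @param n_perm number of uniform-phase surrogates for the p value
#'   (0 skips the permutation).
#' @param seed optional seed.
#' @return list of class `circ_stat` with `statistic` (PPC in `[-1, 1]`),
#'   `p` (NA when `n_perm = 0`), `n`.
#' @export
ppc <- function(rad, n_perm = 1000, seed = NULL) {
  n <- length(rad)
  if (n < 2) stop("PPC requires n >= 2")
  pairwise_ppc <- function(a) {
    d <- outer(a, a, `-`)
    mean(cos(d[upper.tri(d)]))
  }
  stat <- pairwise_ppc(rad)
  p <- NA_real_
  if (n_perm > 0) {
    p <- with_seed(seed, {
      null <- replicate(n_perm, {
        u <- stats::runif(n, 0, 2 * pi)
        ## resultant identity, O(n) per surrogate
        (n * circ_r(u)^2 - 1) / (n - 1)
      })
      (sum(null >= stat) + 1) / (n_perm + 1)
    })
  }
  structure(list(statistic = stat, p = p, n = n, method = "ppc"),
            class = "circ_stat")
}

#' Circular-circular correlation (Jammalamadaka-SenGupta)
#'
#' Correlation between two circular variables,
#' `r = sum(sin(a - ma) * sin(b - mb)) / sqrt(sum(sin^2(a - ma)) * sum(sin^2(b - mb)))`
#' with circular means `ma`, `mb`, and the standard asymptotic normal test.
#'
#' @param alpha,beta angle vectors in radians, equal length >= 5.
#' @return list of class `circ_stat` with `statistic` (r in `[-1, 1]`),
#'   `p`, `n`.
#' @export
circ_circ_corr <- function(alpha, beta) {
  n <- length(alpha)
  if (length(beta) != n) stop("alpha and beta must have equal length")
  if (n < 5) stop("circular correlation requires n >= 5")
  sa <- sin(alpha - circ_mean(alpha))
  sb <- sin(beta - circ_mean(beta))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12) stop("zero circular variance in one of the inputs")
  r <- sum(sa * sb) / den
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  if (l22 < 1e-12) stop("degenerate asymptotic variance")
  z <- sqrt(n * l20 * l02 / l22) * r
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(statistic = r, z = z, p = p, n = n, method = "circ_circ_corr"),
            class = "circ_stat")
}

#' Map a fold-specific phase onto the common full circle
#'
#' Periodic phase estimates live on `[0, 360/fold)` degrees (e.g. a sixfold
#' grid orientation on `[0, 60)`, a threefold phase on `[0, 120)`).
#' Multiplying by the fold maps both onto the full circle in radians so
#' that phases from different folds can be compared or correlated.
#'
#' @param phase_deg phase in degrees, `0 <= phase < 360/fold`.
#' @param fold rotational symmetry (positive integer).
#' @return angle in radians on `[0, 2*pi)`.
#' @export
#' @examples
#' fold_phase_to_circle(30, 6)  # pi
#' fold_phase_to_circle(60, 3)  # pi
fold_phase_to_circle <- function(phase_deg, fold) {
  if (any(phase_deg < 0 | phase_deg >= 360 / fold)) {
    stop(sprintf("phase must lie in [0, %g) degrees for fold %d", 360 / fold, fold))
  }
  deg2rad(fold * phase_deg)
}
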