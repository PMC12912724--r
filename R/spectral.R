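## Periodic Hann window (DFT-exact: its spectrum has support only on
## coefficients {-1, 0, 1}, so a pure fold-k tone leaks only into k-1, k+1).
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

## Remove a least-squares linear trend. Returns the residuals.
linear_detrend <- function(values) {
  n <- length(values)
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), values)$residuals
}

## Projection matrix of linear detrending (for vectorized permutation nulls).
detrend_matrix <- function(n) {
  X <- cbind(1, seq_len(n))
  diag(n) - X %*% solve(crossprod(X), t(X))
}

#' Fold spectrum of direction-binned values
#'
#' Directional periodicity analysis: per-direction-bin values (sorted in
#' ascending order of direction over one full circle) are linearly
#' detrended, tapered with a Hann window, and discrete-Fourier transformed.
#' The magnitude at DFT coefficient `f` is the spectral power at `f` cycles
#' per 360 degrees ("fold" f); folds run from 0 (DC) to the Nyquist fold
#' `floor(n_bins / 2)` (18 for the standard 36 bins of 10 degrees).
#'
#' @param values numeric vector of per-bin activity, sorted ascending by
#'   direction bin; length >= 8, no NAs.
#' @param detrend remove a least-squares linear trend first (default TRUE).
#' @param window apply the periodic Hann taper (default TRUE). Note that
#'   detrending and tapering trade exactness for robustness: the raw DFT
#'   magnitude (`detrend = FALSE, window = FALSE`) is exactly invariant
#'   under circular rotation of the direction labels and confines a pure
#'   tone to a single coefficient, whereas the tapered pipeline spreads a
#'   tone into its two neighboring folds and is only approximately
#'   rotation-invariant.
#' @return object of class `fold_spectrum`: `folds` (0..Nyquist),
#'   `magnitudes`, `n_bins`.
#' @export
#' @examples
#' th <- seq(0, 350, by = 10)
#' sp <- fold_spectrum(cos(3 * th * pi / 180))
#' sp$folds[which.max(sp$magnitudes)]  # 3
fold_spectrum <- function(values, detrend = TRUE, window = TRUE) {
  n <- length(values)
  if (n < 8) stop("need at least 8 direction bins")
  if (anyNA(values) || any(!is.finite(values))) stop("values contain NA/non-finite entries")
  w <- if (window) hann_window(n) else rep(1, n)
  if (detrend) values <- linear_detrend(values)
  coef <- stats::fft(w * values)
  nq <- n %/% 2
  structure(list(folds = 0:nq, magnitudes = Mod(coef[1:(nq + 1)]), n_bins = n),
            class = "fold_spectrum")
}

#' @export
print.fold_spectrum <- function(x, ...) {
  nz <- x$folds[-1][which.max(x$magnitudes[-1])]
  cat(sprintf("<fold_spectrum> %d bins, folds 0..%d, argmax (non-DC) fold %d\n",
              x$n_bins, max(x$folds), nz))
  invisible(x)
}

#' Label-shuffle permutation null for a fold spectrum
#'
#' Direction labels are randomly permuted `n_perm` times (equivalently, the
#' per-bin values are shuffled), the fold spectrum recomputed per shuffle,
#' and two thresholds derived: the per-fold 95th percentile (uncorrected)
#' and the 95th percentile of the across-fold maximum (family-wise error
#' corrected, max-statistic). The DC fold is excluded from the maximum
#' because detrending removes the mean by construction; its per-fold
#' threshold is still reported.
#'
#' @param values per-bin activity (sorted ascending by direction).
#' @param n_perm number of permutations (>= 100; the study standard is 5000).
#' @param seed optional seed.
#' @return object of class `perm_null`: `folds`, `uncorrected` (per-fold
#'   95th percentiles), `fwe` (max-statistic threshold), `n_perm`, `seed`.
#' @export
shuffle_null <- function(values, n_perm = 5000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  n <- length(values)
  nq <- n %/% 2
  D <- detrend_matrix(n)
  w <- hann_window(n)
  with_seed(seed, {
    perms <- vapply(seq_len(n_perm), function(i) values[sample.int(n)], numeric(n))
    mags <- Mod(stats::mvfft(w * (D %*% perms))[1:(nq + 1), , drop = FALSE])
    uncorrected <- apply(mags, 1, stats::quantile, probs = 0.95, names = FALSE)
    maxima <- apply(mags[-1, , drop = FALSE], 2, max)
    structure(list(folds = 0:nq,
                   uncorrected = uncorrected,
                   fwe = stats::quantile(maxima, 0.95, names = FALSE),
                   n_perm = n_perm, seed = seed),
              class = "perm_null")
  })
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> %d permutations, FWE threshold %.4f\n", x$n_perm, x$fwe))
  invisible(x)
}

#' Detect significant directional periodicities
#'
#' Sorts values in ascending order of direction, computes the fold spectrum
#' and its label-shuffle permutation null, and reports the folds whose
#' magnitude exceeds the max-statistic FWE threshold together with the
#' overall (non-DC) argmax fold.
#'
#' @param values per-bin activity values.
#' @param directions direction of each value in degrees (any order).
#' @param n_perm permutations for the null.
#' @param seed optional seed.
#' @return list: `spectrum` (a [fold_spectrum()]), `null` (a
#'   [shuffle_null()]), `significant_folds`, `argmax_fold`.
#' @export
detect_periodicity <- function(values, directions, n_perm = 5000, seed = NULL) {
  if (length(values) != length(directions)) stop("values and directions differ in length")
  ord <- order(wrap_deg(directions))
  v <- values[ord]
  sp <- fold_spectrum(v)
  null <- shuffle_null(v, n_perm = n_perm, seed = seed)
  nondc <- sp$folds[-1]
  mags <- sp$magnitudes[-1]
  list(spectrum = sp, null = null,
       significant_folds = nondc[mags > null$fwe],
       argmax_fold = nondc[which.max(mags)])
}

#' Resample direction-indexed values onto a uniform circular grid
#'
#' Periodic linear interpolation of values observed at arbitrary directions
#' onto `n_grid` uniformly spaced directions (0, 360/n_grid, ...). Values at
#' duplicate directions are averaged first. Needed when start-goal
#' directions are non-uniform (off-center goals) before spectral analysis.
#'
#' @param directions observed directions in degrees.
#' @param values observed values (same length).
#' @param n_grid number of uniform grid points.
#' @return list with `directions` (uniform grid, degrees) and `values`.
#' @export
circular_resample <- function(directions, values, n_grid = 36) {
  if (length(values) != length(directions)) stop("values and directions differ in length")
  d <- wrap_deg(directions)
  agg <- tapply(values, d, mean)
  dd <- as.numeric(names(agg))
  vv <- as.numeric(agg)
  if (length(dd) < 8) stop("need at least 8 distinct directions")
  ord <- order(dd)
  dd <- dd[ord]; vv <- vv[ord]
  ## periodic padding so interpolation wraps across 0/360
  dpad <- c(dd[length(dd)] - 360, dd, dd[1] + 360)
  vpad <- c(vv[length(vv)], vv, vv[1])
  grid <- (seq_len(n_grid) - 1) * 360 / n_grid
  out <- stats::approx(dpad, vpad, xout = grid)$y
  list(directions = grid, values = out)
}
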