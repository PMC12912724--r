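#' Analytic signal on the circular direction domain
#'
#' Discrete Hilbert transform of a signal sampled on a uniform grid over
#' the full circle. The signal is periodic by construction, so the analytic
#' signal is formed exactly in the Fourier domain (negative frequencies
#' zeroed, positive doubled, DC and Nyquist kept) with no edge padding.
#'
#' @param values real signal on a uniform direction grid (length >= 16).
#' @return list of class `analytic_signal`: `phase` (radians, `(-pi, pi]`),
#'   `amplitude` (envelope, >= 0), `n`.
#' @export
#' @examples
#' th <- 2 * pi * (0:71) / 72
#' a <- analytic_signal(cos(3 * th))
#' range(a$amplitude)  # ~1, 1
analytic_signal <- function(values) {
  n <- length(values)
  if (n < 16) stop("need at least 16 samples on the circular grid")
  if (anyNA(values)) stop("values contain NAs")
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(h * stats::fft(values), inverse = TRUE) / n
  structure(list(phase = wrap_pi(Arg(z)), amplitude = Mod(z), n = n),
            class = "analytic_signal")
}

## Phase-bin layout: n_bins equal bins with one bin centered at phase 0.
## Centers are reported in degrees, ordered ... -80, -40, 0, 40, 80 ...
phase_bin_centers <- function(n_bins) {
  w <- 360 / n_bins
  (seq_len(n_bins) - 1 - (n_bins %/% 2)) * w
}

phase_bin_index <- function(phase, n_bins) {
  w <- 2 * pi / n_bins
  idx <- floor((wrap_pi(phase) + w / 2) / w)      # 0-centered bin = 0
  ((idx + n_bins %/% 2) %% n_bins) + 1            # map to 1..n_bins, center order
}

#' Modulation index per phase bin
#'
#' Amplitude-phase coupling in the direction domain: phases are classified
#' into `n_bins` equal bins (one bin centered at phase 0) and, per bin, the
#' modulation index `M = |mean(A * exp(i*phase))|` is computed from the
#' composite analytic samples falling in that bin. Empty bins yield `NA`
#' and are flagged.
#'
#' @param amplitude amplitude samples (e.g. directional activity level of
#'   the faster periodic component).
#' @param phase phase samples in radians (instantaneous phase of the slower
#'   component), same length.
#' @param n_bins number of phase bins (default 9 bins of 40 degrees).
#' @return object of class `coupling_result` with `M`, `bin_centers`
#'   (degrees), `n_per_bin`, `empty_bins`.
#' @export
modulation_by_phase <- function(amplitude, phase, n_bins = 9) {
  if (length(amplitude) != length(phase)) stop("amplitude and phase differ in length")
  idx <- phase_bin_index(phase, n_bins)
  z <- amplitude * exp(1i * phase)
  M <- rep(NA_real_, n_bins)
  n_per <- tabulate(idx, n_bins)
  for (b in seq_len(n_bins)) {
    if (n_per[b] > 0) M[b] <- Mod(mean(z[idx == b]))
  }
  empty <- which(n_per == 0)
  if (length(empty)) {
    warning("empty phase bin(s): ", paste(phase_bin_centers(n_bins)[empty], collapse = ", "))
  }
  structure(list(M = M, bin_centers = phase_bin_centers(n_bins),
                 n_per_bin = n_per, empty_bins = empty),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  i <- which.max(if (!is.null(x$strength)) x$strength else x$M)
  cat(sprintf("<coupling_result> %d bins, argmax bin center %g deg\n",
              length(x$bin_centers), x$bin_centers[i]))
  invisible(x)
}

#' Circular-lag surrogate modulation indices
#'
#' Null distribution for the modulation index: the amplitude series is
#' circularly offset relative to the phase series at every possible nonzero
#' spatial lag, the per-bin modulation index recomputed per lag, and the
#' per-bin mean across lags returned as the surrogate baseline `M'`. The
#' coupling strength is `M - M'`.
#'
#' @inheritParams modulation_by_phase
#' @return object of class `coupling_result` with `M`, `M_surrogate`,
#'   `strength`, `bin_centers`, `n_lags`.
#' @export
shift_surrogates <- function(amplitude, phase, n_bins = 9) {
  n <- length(amplitude)
  obs <- modulation_by_phase(amplitude, phase, n_bins)
  surro <- matrix(NA_real_, n - 1, n_bins)
  for (lag in seq_len(n - 1)) {
    a_lag <- amplitude[((seq_len(n) - 1 + lag) %% n) + 1]
    surro[lag, ] <- suppressWarnings(modulation_by_phase(a_lag, phase, n_bins)$M)
  }
  Ms <- colMeans(surro, na.rm = TRUE)
  structure(list(M = obs$M, M_surrogate = Ms, strength = obs$M - Ms,
                 bin_centers = obs$bin_centers, n_per_bin = obs$n_per_bin,
                 empty_bins = obs$empty_bins, n_lags = n - 1),
            class = "coupling_result")
}

#' Directional amplitude-phase coupling between two periodic activity curves
#'
#' Full peak-alignment analysis between a faster periodic component (e.g. a
#' sixfold entorhinal tuning curve) and a slower one (e.g. a threefold
#' hippocampal tuning curve) over the direction domain. The instantaneous
#' phase of the slow signal is extracted with the circular Hilbert
#' transform; the directional activity level of the fast signal serves as
#' the amplitude weight (the Hilbert envelope of a noiseless pure tone is
#' constant and carries no directional information, so the activity curve
#' itself is the informative amplitude). Per-bin modulation indices and
#' circular-lag surrogate baselines are returned; peak-aligned signals
#' yield maximal coupling in the bin centered at phase 0.
#'
#' @param fast_values activity of the faster component on a uniform
#'   direction grid.
#' @param slow_values activity of the slower component on the same grid.
#' @param n_bins number of phase bins.
#' @return a `coupling_result` (see [shift_surrogates()]) plus
#'   `argmax_bin_center` (degrees).
#' @export
coupling_alignment <- function(fast_values, slow_values, n_bins = 9) {
  if (length(fast_values) != length(slow_values)) stop("signals differ in length")
  ph <- analytic_signal(slow_values)$phase
  out <- shift_surrogates(fast_values, ph, n_bins)
  out$argmax_bin_center <- out$bin_centers[which.max(out$M)]
  out
}

#' Least-squares FIR band-pass filter on the circular direction domain
#'
#' Designs a linear-phase (type I) FIR band-pass by least squares on a
#' dense frequency grid and applies it forward and backward (zero phase)
#' with circular boundary handling, i.e. the signal's DFT is multiplied by
#' the squared magnitude response. Frequencies are specified in folds
#' (cycles per 360 degrees).
#'
#' @param values signal on a uniform circular grid.
#' @param center_fold pass-band center in folds.
#' @param halfwidth_folds pass-band half width in folds.
#' @param order filter order (even; `order + 1` taps, must be < n/3).
#'   Default: the largest admissible even order.
#' @param transition_folds transition band width on each side, in folds.
#' @return filtered values (same length).
#' @export
fir_bandpass <- function(values, center_fold, halfwidth_folds = 1,
                         order = NULL, transition_folds = 1) {
  n <- length(values)
  if (is.null(order)) order <- 2 * ((ceiling(n / 3) - 1) %/% 2)
  if (order %% 2 != 0) stop("order must be even (type I linear-phase FIR)")
  if (order >= n / 3) stop("filter too long: order must be < n/3")
  nyq <- n / 2
  lo <- center_fold - halfwidth_folds
  hi <- center_fold + halfwidth_folds
  if (lo - transition_folds < 0 || hi + transition_folds > nyq) {
    stop("band (plus transition) must lie within (0, Nyquist)")
  }
  ## least-squares design of the zero-phase amplitude response
  ## A(nu) = c0 + sum_m 2 c_m cos(2 pi nu m), nu in cycles/sample
  M <- order / 2
  grid <- seq(0, 0.5, length.out = 16 * n)
  fold_grid <- grid * n
  keep <- fold_grid <= lo - transition_folds |
    (fold_grid >= lo & fold_grid <= hi) |
    fold_grid >= hi + transition_folds
  desired <- as.numeric(fold_grid >= lo & fold_grid <= hi)[keep]
  basis <- outer(grid[keep], 0:M, function(f, m) ifelse(m == 0, 1, 2) * cos(2 * pi * f * m))
  cfs <- stats::lsfit(basis, desired, intercept = FALSE)$coefficients
  ## normalize to unit gain at the pass-band center
  gain <- sum(ifelse(0:M == 0, 1, 2) * cos(2 * pi * (center_fold / n) * (0:M)) * cfs)
  cfs <- cfs / gain
  ## squared magnitude response at the DFT frequencies (forward + backward)
  nu <- (seq_len(n) - 1) / n
  nu <- pmin(nu, 1 - nu)
  A <- as.vector(outer(nu, 0:M, function(f, m) ifelse(m == 0, 1, 2) * cos(2 * pi * f * m)) %*% cfs)
  Re(stats::fft(stats::fft(values) * A^2, inverse = TRUE)) / n
}

#' Phase-locking value and phase-lag index between two circular signals
#'
#' Both signals (on the same uniform direction grid) are converted to
#' analytic form; per-sample phase differences give the phase-locking value
#' `PLV = |mean(exp(i*dphi))|` and the phase-lag index
#' `PLI = |mean(sign(sin(dphi)))|`. Surrogate distributions are obtained by
#' circularly shifting the second signal across all nonzero lags.
#'
#' @param sig_a,sig_b signals on the same uniform circular grid.
#' @param surrogates logical; also compute circular-shift surrogate
#'   distributions.
#' @return list of class `phase_lock_result`: `plv`, `pli`,
#'   `plv_surrogate`, `pli_surrogate` (vectors across lags, when requested).
#' @export
#' @examples
#' th <- 2 * pi * (0:71) / 72
#' phase_locking(cos(3 * th), cos(3 * th))$plv  # 1
phase_locking <- function(sig_a, sig_b, surrogates = TRUE) {
  if (length(sig_a) != length(sig_b)) stop("signals differ in length")
  n <- length(sig_a)
  pa <- analytic_signal(sig_a)$phase
  pb <- analytic_signal(sig_b)$phase
  plv_pli <- function(dphi) {
    c(plv = Mod(mean(exp(1i * dphi))), pli = abs(mean(sign(sin(dphi)))))
  }
  obs <- plv_pli(pa - pb)
  out <- list(plv = unname(obs["plv"]), pli = unname(obs["pli"]), n = n)
  if (surrogates) {
    sur <- vapply(seq_len(n - 1), function(lag) {
      plv_pli(pa - pb[((seq_len(n) - 1 + lag) %% n) + 1])
    }, numeric(2))
    out$plv_surrogate <- unname(sur["plv", ])
    out$pli_surrogate <- unname(sur["pli", ])
  }
  structure(out, class = "phase_lock_result")
}

#' @export
print.phase_lock_result <- function(x, ...) {
  cat(sprintf("<phase_lock_result> PLV = %.4f, PLI = %.4f, n = %d\n",
              x$plv, x$pli, x$n))
  invisible(x)
}
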