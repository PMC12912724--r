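## Single-session guard: the GLM builders operate on one session at a time.
one_session <- function(events) {
  s <- unique(events$session)
  if (length(s) != 1) stop("events must contain exactly one session; got ", length(s))
  s
}

#' Quadrature (sine/cosine) GLM design matrix
#'
#' Builds the sinusoidal-modulation design for one session: an intercept, a
#' linear drift, an unmodulated onset regressor over the direction trials,
#' and two parametric modulators `sin(k*theta)` and `cos(k*theta)` (lure
#' trials excluded), all event regressors convolved with the canonical
#' double-gamma HRF.
#'
#' @param events single-session [make_event_design()] rows.
#' @param k rotational symmetry of the modulators.
#' @param TR repetition time (s).
#' @param n_scans scans in the session (default from the event grid).
#' @return design matrix with columns `intercept`, `drift`, `onset`,
#'   `sin`, `cos`; attribute `k`.
#' @export
build_quadrature_design <- function(events, k, TR = 2, n_scans = NULL) {
  if (k < 1) stop("k must be >= 1")
  one_session(events)
  ev <- events[events$trial_type == "direction", ]
  if (!nrow(ev)) stop("no direction trials in events")
  if (is.null(n_scans)) n_scans <- session_scans(events, TR)
  th <- deg2rad(ev$direction_deg)
  X <- cbind(
    intercept = 1,
    drift = seq_len(n_scans) / n_scans,
    onset = convolve_events(ev$onset, rep(1, nrow(ev)), n_scans, TR),
    sin = convolve_events(ev$onset, sin(k * th), n_scans, TR),
    cos = convolve_events(ev$onset, cos(k * th), n_scans, TR))
  qr_rank <- qr(X)$rank
  if (qr_rank < ncol(X)) {
    attr(X, "rank_deficient") <- TRUE
    warning("quadrature design is rank deficient (degenerate directions?)")
  }
  attr(X, "k") <- k
  X
}

#' Fit a quadrature GLM by ordinary least squares
#'
#' @param series numeric vector, the session's voxel time series.
#' @param design matrix from [build_quadrature_design()].
#' @return object of class `quadrature_fit`: `beta_sine`, `beta_cosine`,
#'   `k`, `sigma2` (residual variance), `betas` (all coefficients).
#' @export
fit_quadrature <- function(series, design) {
  if (length(series) != nrow(design)) stop("series length does not match design rows")
  dq <- qr(design)
  if (dq$rank < ncol(design)) {
    bad <- colnames(design)[dq$pivot[seq(dq$rank + 1, ncol(design))]]
    stop("rank-deficient design; offending column(s): ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(design, series)
  b <- fit$coefficients
  structure(list(beta_sine = unname(b["sin"]), beta_cosine = unname(b["cos"]),
                 k = attr(design, "k"),
                 sigma2 = sum(fit$residuals^2) / (length(series) - ncol(design)),
                 betas = b),
            class = "quadrature_fit")
}

#' @export
print.quadrature_fit <- function(x, ...) {
  cat(sprintf("<quadrature_fit> k = %d, beta_sine = %.4g, beta_cosine = %.4g\n",
              x$k, x$beta_sine, x$beta_cosine))
  invisible(x)
}

#' Grid orientation from quadrature weights
#'
#' `phi = atan2(beta_sine, beta_cosine) / k`, mapped into `[0, 360/k)`
#' degrees. The two-argument arctangent resolves the quadrant ambiguity of
#' the one-argument ratio form so that phi is well defined over the full
#' fold range.
#'
#' @param fit a `quadrature_fit`, or a list with `beta_sine`,
#'   `beta_cosine`, `k`.
#' @return object of class `orientation_estimate`: `phi_deg`, `k`,
#'   `amplitude` (`sqrt(beta_sine^2 + beta_cosine^2)`).
#' @export
#' @examples
#' orientation_from_betas(list(beta_sine = 1, beta_cosine = 0, k = 6))$phi_deg  # 15
orientation_from_betas <- function(fit) {
  bs <- fit$beta_sine; bc <- fit$beta_cosine; k <- fit$k
  if (bs == 0 && bc == 0) stop("undefined orientation: both betas are zero")
  phi <- wrap_deg(rad2deg(atan2(bs, bc)) / k, 360 / k)
  structure(list(phi_deg = phi, k = k, amplitude = sqrt(bs^2 + bc^2)),
            class = "orientation_estimate")
}

#' @export
print.orientation_estimate <- function(x, ...) {
  cat(sprintf("<orientation_estimate> k = %d, phi = %.3f deg\n", x$k, x$phi_deg))
  invisible(x)
}

#' Circular mean of fold-specific orientations
#'
#' Averages per-voxel (or per-session) orientation estimates in
#' fold-multiplied space: the circular mean of `k * phi` divided by `k`,
#' wrap-aware on `[0, 360/k)`. A near-zero resultant (antipodal estimates
#' in folded space) is flagged as low confidence.
#'
#' @param phi_deg orientation estimates in degrees on `[0, 360/k)`.
#' @param k common fold.
#' @return object of class `orientation_estimate` with `phi_deg`, `k`,
#'   `resultant` and `low_confidence`.
#' @export
mean_grid_orientation <- function(phi_deg, k) {
  if (!length(phi_deg)) stop("empty orientation list")
  z <- mean(exp(1i * deg2rad(k * phi_deg)))
  low <- Mod(z) < 1e-8
  phi <- if (low) NA_real_ else wrap_deg(rad2deg(Arg(z)) / k, 360 / k)
  structure(list(phi_deg = phi, k = k, resultant = Mod(z), low_confidence = low),
            class = "orientation_estimate")
}

#' Cross-validated grid-alignment effect
#'
#' Odd/even session cross-validation of periodic directional modulation:
#' the orientation phi is estimated from the odd-numbered sessions (and, for
#' multi-voxel input, averaged across voxels with [mean_grid_orientation()]),
#' then the even-numbered sessions are refit with the single aligned
#' modulator `cos(k * (theta - phi))`; the held-out alignment effect is the
#' aligned beta averaged over even sessions (and voxels). For noiseless
#' forward data the held-out beta equals the planted amplitude.
#'
#' @param series scans x sessions matrix (single voxel) or scans x sessions
#'   x voxels array.
#' @param events full multi-session [make_event_design()] table.
#' @param k fold to test.
#' @param TR repetition time (s).
#' @return list: `phi_deg` (training-half orientation), `heldout_beta`
#'   (mean aligned beta over even sessions), `per_session_beta`.
#' @export
crossval_alignment <- function(series, events, k, TR = 2) {
  if (is.matrix(series)) series <- array(series, dim = c(dim(series), 1))
  sessions <- sort(unique(events$session))
  if (length(sessions) < 2) stop("need at least two sessions for cross-validation")
  if (dim(series)[2] != length(sessions)) stop("series columns must match sessions")
  odd <- sessions[sessions %% 2 == 1]
  even <- sessions[sessions %% 2 == 0]
  n_vox <- dim(series)[3]

  phis <- unlist(lapply(odd, function(s) {
    ev <- events[events$session == s, ]
    X <- build_quadrature_design(ev, k, TR, n_scans = dim(series)[1])
    vapply(seq_len(n_vox), function(v) {
      orientation_from_betas(fit_quadrature(series[, which(sessions == s), v], X))$phi_deg
    }, numeric(1))
  }))
  phi <- mean_grid_orientation(phis, k)$phi_deg

  betas <- vapply(even, function(s) {
    ev <- events[events$session == s & events$trial_type == "direction", ]
    n_scans <- dim(series)[1]
    X <- cbind(intercept = 1,
               drift = seq_len(n_scans) / n_scans,
               onset = convolve_events(ev$onset, rep(1, nrow(ev)), n_scans, TR),
               aligned = convolve_events(ev$onset,
                                         cos(k * deg2rad(ev$direction_deg - phi)),
                                         n_scans, TR))
    mean(vapply(seq_len(n_vox), function(v) {
      stats::lm.fit(X, series[, which(sessions == s), v])$coefficients["aligned"]
    }, numeric(1)))
  }, numeric(1))

  list(phi_deg = phi, heldout_beta = mean(betas),
       per_session_beta = stats::setNames(betas, paste0("session", even)))
}

#' Direction-bin GLM (binary regressors per 10-degree bin)
#'
#' Estimates per-direction-bin activity for the spectral analysis: path
#' directions are down-sampled into half-open bins `[b, b + width)` and each
#' bin enters the GLM as an HRF-convolved binary regressor. All sessions are
#' fit jointly with per-session intercepts and drifts. Empty bins are
#' allowed (with a warning) and return NA.
#'
#' @param series scans x sessions matrix (one voxel or ROI average).
#' @param events multi-session event table.
#' @param bin_width bin width in degrees (default 10; 360 must be divisible).
#' @param TR repetition time (s).
#' @return object of class `direction_bin_betas`: `bin_deg` (lower edges
#'   ascending 0..350), `beta`, `n_trials` per bin.
#' @export
fit_direction_bins <- function(series, events, bin_width = 10, TR = 2) {
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  n_bins <- 360 %/% bin_width
  sessions <- sort(unique(events$session))
  n_scans <- nrow(series)
  bins <- (seq_len(n_bins) - 1) * bin_width

  blocks <- lapply(seq_along(sessions), function(si) {
    s <- sessions[si]
    ev <- events[events$session == s & events$trial_type == "direction", ]
    bin_of <- floor(wrap_deg(ev$direction_deg) / bin_width) + 1
    Xbin <- vapply(seq_len(n_bins), function(b) {
      sel <- bin_of == b
      if (!any(sel)) return(numeric(n_scans))
      convolve_events(ev$onset[sel], rep(1, sum(sel)), n_scans, TR)
    }, numeric(n_scans))
    nuis <- matrix(0, n_scans, 2 * length(sessions))
    nuis[, 2 * si - 1] <- 1
    nuis[, 2 * si] <- seq_len(n_scans) / n_scans
    list(X = cbind(Xbin, nuis), y = series[, si], n = tabulate(bin_of, n_bins))
  })
  X <- do.call(rbind, lapply(blocks, `[[`, "X"))
  y <- unlist(lapply(blocks, `[[`, "y"))
  n_trials <- Reduce(`+`, lapply(blocks, `[[`, "n"))
  if (all(n_trials == 0)) stop("all direction bins are empty")
  if (any(n_trials == 0)) {
    warning("empty direction bin(s): ", paste(bins[n_trials == 0], collapse = ", "))
  }
  keep <- c(n_trials > 0, rep(TRUE, 2 * length(sessions)))
  b <- rep(NA_real_, ncol(X))
  b[keep] <- stats::lm.fit(X[, keep, drop = FALSE], y)$coefficients
  structure(list(bin_deg = bins, beta = b[seq_len(n_bins)], n_trials = n_trials),
            class = "direction_bin_betas")
}

#' Reconstruct the directional tuning curve from quadrature weights
#'
#' `beta_cosine * cos(k*theta) + beta_sine * sin(k*theta)` over a direction
#' grid; the curve's amplitude is `sqrt(beta_sine^2 + beta_cosine^2)` and
#' its maxima sit at the estimated orientation and its fold-symmetric
#' repetitions.
#'
#' @param fit a `quadrature_fit` (or compatible list).
#' @param theta_deg direction grid in degrees.
#' @return numeric vector of reconstructed activity.
#' @export
reconstruct_tuning <- function(fit, theta_deg = seq(0, 359)) {
  th <- deg2rad(theta_deg)
  fit$beta_cosine * cos(fit$k * th) + fit$beta_sine * sin(fit$k * th)
}
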