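#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the canonical parameterization
#' (response peak delay 6 s, undershoot delay 16 s, unit dispersions,
#' undershoot ratio 1/6), scaled to unit peak. The kernel is 0 at t = 0 and
#' peaks near 5 s.
#'
#' @param time_grid non-negative times in seconds.
#' @param peak_delay,undershoot_delay gamma shape parameters (rate 1).
#' @param undershoot_ratio relative amplitude of the undershoot.
#' @return kernel values on `time_grid`, unit peak.
#' @export
hrf_double_gamma <- function(time_grid, peak_delay = 6, undershoot_delay = 16,
                             undershoot_ratio = 1 / 6) {
  if (any(time_grid < 0)) stop("time grid must be non-negative")
  h <- stats::dgamma(time_grid, shape = peak_delay, rate = 1) -
    undershoot_ratio * stats::dgamma(time_grid, shape = undershoot_delay, rate = 1)
  h / max(h)
}

#' Event design for the object-matching task
#'
#' Builds the trial table of an event-related session structure: each
#' session holds `trials_per_session` direction trials (one per sampled
#' start location) plus `lures_per_session` lure trials (blank screen, no
#' direction) at random slots. Trials follow a fixed grid of 2 s fixation +
#' 10 s trial window; onsets mark the trial-window start within its
#' session. Directions are partitioned across sessions without replacement.
#'
#' @param directions vector of trial directions in degrees, length
#'   `n_sessions * trials_per_session` (e.g. from [sample_ring_starts()]).
#' @param n_sessions number of sessions.
#' @param trials_per_session direction trials per session.
#' @param lures_per_session lure trials per session.
#' @param fixation_s,trial_s fixation and trial-window durations (seconds).
#' @param seed optional seed (direction-to-session assignment, lure slots).
#' @return data.frame of class `event_design` with columns `onset`,
#'   `duration`, `direction_deg` (NA for lures), `session`, `trial_type`.
#' @export
make_event_design <- function(directions, n_sessions = 8, trials_per_session = 36,
                              lures_per_session = 4, fixation_s = 2, trial_s = 10,
                              seed = NULL) {
  n_dir <- n_sessions * trials_per_session
  if (length(directions) != n_dir) {
    stop(sprintf("need %d directions (%d sessions x %d trials), got %d",
                 n_dir, n_sessions, trials_per_session, length(directions)))
  }
  slot_s <- fixation_s + trial_s
  with_seed(seed, {
    assign_dir <- matrix(sample(directions), trials_per_session, n_sessions)
    out <- lapply(seq_len(n_sessions), function(s) {
      n_slot <- trials_per_session + lures_per_session
      lure_slots <- if (lures_per_session > 0) sort(sample.int(n_slot, lures_per_session)) else integer()
      type <- rep("direction", n_slot); type[lure_slots] <- "lure"
      dir <- rep(NA_real_, n_slot); dir[type == "direction"] <- assign_dir[, s]
      data.frame(onset = (seq_len(n_slot) - 1) * slot_s + fixation_s,
                 duration = trial_s,
                 direction_deg = dir,
                 session = s,
                 trial_type = type)
    })
    df <- do.call(rbind, out)
    class(df) <- c("event_design", "data.frame")
    df
  })
}

## Convolve per-event impulses (onset, amplitude) with the HRF on a fine
## grid and sample at scan times. Shared by the forward model and every GLM
## builder so that noiseless round trips are exact.
convolve_events <- function(onsets, amplitudes, n_scans, TR = 2, dt = 0.1,
                            hrf_span = 32) {
  n_fine <- ceiling(n_scans * TR / dt) + 1
  x <- numeric(n_fine)
  idx <- round(onsets / dt) + 1
  keep <- idx >= 1 & idx <= n_fine
  for (i in which(keep)) x[idx[i]] <- x[idx[i]] + amplitudes[i]
  h <- hrf_double_gamma(seq(0, hrf_span, by = dt))
  y <- stats::convolve(x, rev(h), type = "open")[seq_len(n_fine)]
  scan_idx <- round((seq_len(n_scans) - 1) * TR / dt) + 1
  y[scan_idx]
}

## Default scans per session from the event grid.
session_scans <- function(events, TR = 2, rest_s = 0) {
  per_session <- tapply(events$onset + events$duration, events$session, max)
  ceiling((max(per_session) + rest_s) / TR)
}

#' Simulate a direction-tuned voxel time series
#'
#' Forward model matched to the quadrature GLM: each direction trial
#' contributes an impulse at its onset with amplitude
#' `baseline + a * cos(k * (theta - phi))`, convolved with the canonical
#' double-gamma HRF and sampled at TR; i.i.d. Gaussian noise (optionally
#' AR(1)) is added per scan. Lure trials contribute nothing.
#'
#' @param events an [make_event_design()] table.
#' @param fold planted rotational symmetry k (>= 1).
#' @param phi_deg planted orientation in degrees (`[0, 360/fold)`).
#' @param amplitude planted directional modulation amplitude a.
#' @param baseline per-trial baseline response amplitude.
#' @param noise_sd Gaussian noise standard deviation.
#' @param ar1 optional AR(1) coefficient for temporally correlated noise.
#' @param TR repetition time in seconds.
#' @param n_scans scans per session (default: from the event grid).
#' @param seed optional seed.
#' @return numeric matrix, scans x sessions, of class `bold_series`.
#' @export
simulate_voxel <- function(events, fold = 6, phi_deg = 0, amplitude = 1,
                           baseline = 1, noise_sd = 0, ar1 = 0, TR = 2,
                           n_scans = NULL, seed = NULL) {
  if (is.null(n_scans)) n_scans <- session_scans(events, TR)
  sessions <- sort(unique(events$session))
  with_seed(seed, {
    out <- vapply(sessions, function(s) {
      ev <- events[events$session == s & events$trial_type == "direction", ]
      amp <- baseline + amplitude * cos(fold * deg2rad(ev$direction_deg - phi_deg))
      y <- convolve_events(ev$onset, amp, n_scans, TR)
      if (noise_sd > 0) {
        eps <- stats::rnorm(n_scans, 0, noise_sd)
        if (ar1 != 0) eps <- as.numeric(stats::filter(eps, ar1, method = "recursive"))
        y <- y + eps
      }
      y
    }, numeric(n_scans))
    structure(out, class = c("bold_series", "matrix"))
  })
}

## Von Mises sampler (Best & Fisher 1979 rejection scheme); mean mu, concentration
## kappa >= 0. Returns radians. Hand-rolled: no circular-statistics package
## is available in the dependency set.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap_pi(out + mu)
}

#' Simulate a multi-voxel region with von Mises-distributed orientations
#'
#' Per-voxel orientations are drawn von Mises around the shared region
#' orientation in fold-multiplied (k * phi) space with concentration
#' `kappa`, then divided by k; each voxel is simulated independently with
#' [simulate_voxel()].
#'
#' @inheritParams simulate_voxel
#' @param n_voxels number of voxels.
#' @param kappa von Mises concentration of voxel orientations in k*phi
#'   space (0 = uniform; Inf-like values = identical orientations).
#' @return list: `series` (array scans x sessions x voxels), `phi_voxel_deg`
#'   (per-voxel planted orientations, degrees).
#' @export
simulate_region <- function(events, n_voxels, fold = 6, phi_deg = 0, kappa = 10,
                            amplitude = 1, baseline = 1, noise_sd = 0, TR = 2,
                            seed = NULL) {
  if (n_voxels < 1) stop("n_voxels must be >= 1")
  with_seed(seed, {
    kphi <- if (is.finite(kappa)) {
      rvonmises(n_voxels, deg2rad(fold * phi_deg), kappa)
    } else {
      rep(deg2rad(fold * phi_deg), n_voxels)
    }
    phis <- wrap_deg(rad2deg(kphi) / fold, 360 / fold)
    series <- lapply(seq_len(n_voxels), function(v) {
      simulate_voxel(events, fold = fold, phi_deg = phis[v], amplitude = amplitude,
                     baseline = baseline, noise_sd = noise_sd, TR = TR,
                     seed = NULL)
    })
    arr <- array(unlist(series), dim = c(nrow(series[[1]]), ncol(series[[1]]), n_voxels))
    list(series = arr, phi_voxel_deg = phis)
  })
}

#' Simulate a per-direction behavioral performance vector
#'
#' Performance as a function of path direction with a planted periodicity:
#' `score(theta) = baseline + amplitude * cos(fold * (theta - phase)) + noise`.
#'
#' @param directions directions in degrees.
#' @param fold planted fold.
#' @param phase_deg planted phase in degrees.
#' @param amplitude planted modulation amplitude.
#' @param baseline mean performance level.
#' @param noise_sd Gaussian noise sd.
#' @param seed optional seed.
#' @return data.frame with columns `direction_deg`, `score`.
#' @export
simulate_behavior <- function(directions, fold = 3, phase_deg = 0, amplitude = 1,
                              baseline = 10, noise_sd = 0, seed = NULL) {
  if (!length(directions)) stop("directions must be non-empty")
  with_seed(seed, {
    score <- baseline + amplitude * cos(fold * deg2rad(directions - phase_deg)) +
      stats::rnorm(length(directions), 0, noise_sd)
    data.frame(direction_deg = wrap_deg(directions), score = score)
  })
}
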