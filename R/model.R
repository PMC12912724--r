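#' Grid-cell population parameters
#'
#' The entorhinal grid code is modeled as the sum of three cosine gratings
#' whose wave vectors are 60 degrees apart, evaluated on the task-space
#' lattice. One grid cell exists per lattice cell, distinguished only by
#' its spatial phase offset `c`; the grid orientation is constant across
#' the population. `orientation_deg` is the angle of the first grid axis
#' (the band/coherence direction); the three wave vectors are placed
#' perpendicular to the axes, at `orientation + 90 + {0, 60, 120}`. The
#' spatial scale is given as the grating period in lattice cells
#' (`omega = 2*pi / period` radians per cell).
#'
#' @param amplitude grating amplitude A.
#' @param period grating period in lattice cells (one grid module).
#' @param orientation_deg orientation of the first grid axis, degrees.
#' @param spec a [space_spec()] defining the lattice.
#' @return object of class `grid_params`: `A`, `omega`, `orientation_deg`,
#'   `wave_angles_deg` (3), `k` (3 x 2 unit wave vectors), `spec`.
#' @export
grid_params <- function(amplitude = 1, period = 9, orientation_deg = 15,
                        spec = space_spec()) {
  wave <- orientation_deg + 90 + c(0, 60, 120)
  k <- cbind(cos(deg2rad(wave)), sin(deg2rad(wave)))
  structure(list(A = amplitude, omega = 2 * pi / period,
                 orientation_deg = orientation_deg,
                 wave_angles_deg = wrap_deg(wave),
                 k = k, spec = spec),
            class = "grid_params")
}

#' @export
print.grid_params <- function(x, ...) {
  cat(sprintf("<grid_params> A = %g, period = %.3g cells, axes at {%s} deg\n",
              x$A, 2 * pi / x$omega,
              paste(grid_axes(x), collapse = ", ")))
  invisible(x)
}

#' Grid-axis orientations implied by the parameters
#'
#' @param params a [grid_params()].
#' @return the three axis orientations in degrees on `[0, 180)`.
#' @export
grid_axes <- function(params) {
  sort(wrap_deg(params$orientation_deg + c(0, 60, 120), 180))
}

#' Activity of one grid cell at one location
#'
#' `G = sum_i A * cos(omega * k_i . (r - c))` over the three gratings:
#' the firing of the cell with phase offset `c` when the agent is at `r`.
#' Maximal activity `3A` occurs when `r` coincides with `c` (modulo the
#' hexagonal pattern period).
#'
#' @param cell_offset grid-cell phase offset `c = c(x, y)`.
#' @param location agent location `r = c(x, y)`.
#' @param params a [grid_params()].
#' @return scalar activity in `[-3A, 3A]`.
#' @export
grid_code <- function(cell_offset, location, params = grid_params()) {
  d <- location - cell_offset
  sum(params$A * cos(params$omega * (params$k %*% d)))
}

#' Population activity pattern at one location
#'
#' Evaluates [grid_code()] for every cell offset of the lattice: the
#' momentary activity of the whole 45x45 grid-cell population when the
#' agent occupies `location`.
#'
#' @inheritParams grid_code
#' @return width x height matrix (cell offsets indexed `[x, y]`, 0-based
#'   offsets c = row/col index - 1).
#' @export
population_pattern <- function(location, params = grid_params()) {
  sp <- params$spec
  cx <- matrix(0:(sp$width - 1), sp$width, sp$height)
  cy <- matrix(0:(sp$height - 1), sp$width, sp$height, byrow = TRUE)
  out <- matrix(0, sp$width, sp$height)
  for (i in 1:3) {
    out <- out + params$A * cos(params$omega *
      (params$k[i, 1] * (location[1] - cx) + params$k[i, 2] * (location[2] - cy)))
  }
  out
}

#' Supercover rasterization of a straight lattice path
#'
#' Deterministically lists every lattice cell the straight segment from
#' `start` to `end` passes through (both endpoints included; at exact
#' corner crossings both side cells are included).
#'
#' @param start,end integer lattice points `c(x, y)`.
#' @return integer matrix of ordered locations, columns `x`, `y`.
#' @export
rasterize_path <- function(start, end) {
  x <- start[1]; y <- start[2]
  dx <- end[1] - start[1]; dy <- end[2] - start[2]
  nx <- abs(dx); ny <- abs(dy)
  sx <- sign(dx); sy <- sign(dy)
  pts <- vector("list", 2 * (nx + ny) + 1)
  pts[[1]] <- c(x, y)
  n_pts <- 1
  ix <- 0; iy <- 0
  add <- function(p) { n_pts <<- n_pts + 1; pts[[n_pts]] <<- p }
  while (ix < nx || iy < ny) {
    t1 <- (2 * ix + 1) * ny
    t2 <- (2 * iy + 1) * nx
    if (nx > 0 && ny > 0 && t1 == t2) {     # exact corner crossing
      add(c(x + sx, y)); add(c(x, y + sy))
      x <- x + sx; y <- y + sy; ix <- ix + 1; iy <- iy + 1
      add(c(x, y))
    } else if (iy >= ny || (ix < nx && t1 < t2)) {
      x <- x + sx; ix <- ix + 1
      add(c(x, y))
    } else {
      y <- y + sy; iy <- iy + 1
      add(c(x, y))
    }
  }
  out <- do.call(rbind, pts[seq_len(n_pts)])
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Path code: summed population activity along a trajectory
#'
#' The population pattern `V` formed by linearly summing the grid-cell
#' population activity over every rasterized location along the straight
#' path from `start` to `goal`. The path code is identical for a path
#' direction and its 180-degree opposite, so it represents the path's
#' orientation rather than its direction.
#'
#' @param start,goal integer lattice points.
#' @param params a [grid_params()].
#' @return width x height matrix of summed cell activity, with attributes
#'   `locations` (the rasterized path) and `orientation_deg` (path
#'   orientation on `[0, 180)`).
#' @export
path_code <- function(start, goal, params = grid_params()) {
  locs <- rasterize_path(start, goal)
  V <- matrix(0, params$spec$width, params$spec$height)
  for (i in seq_len(nrow(locs))) {
    V <- V + population_pattern(locs[i, ], params)
  }
  psi <- if (all(start == goal)) NA_real_ else
    wrap_deg(rad2deg(atan2(goal[2] - start[2], goal[1] - start[1])), 180)
  attr(V, "locations") <- locs
  attr(V, "orientation_deg") <- psi
  V
}

#' Orientation alignment profile of path codes
#'
#' For each orientation psi over `[0, 180)` degrees, a straight path is
#' built from the ring start at angle psi (radius `radius` around the
#' central goal) to the center, the population activity summed at
#' unit-spaced points along the continuous segment (avoiding lattice
#' rounding jitter in the profile), and the resulting path-code pattern
#' pooled to a scalar `delta(psi)`. The default pooling is the pattern
#' energy (sum of squared cell activity), which grows with the coherence of
#' the planar wave formed by aligned paths and exhibits exactly three peaks
#' over orientations, one per grid axis. A maximum-over-cells pooling is
#' available; it shares the threefold fundamental but adds genuine
#' secondary maxima at axis-perpendicular orientations.
#'
#' @param params a [grid_params()].
#' @param psi_deg orientation grid in degrees (default 1-degree steps).
#' @param radius ring radius in cells for the path starts.
#' @param pooling `"energy"` (sum of squares) or `"max"`.
#' @return data.frame of class `delta_profile` with columns `psi_deg`,
#'   `delta`; attribute `pooling`.
#' @export
delta_profile <- function(params = grid_params(), psi_deg = seq(0, 179),
                          radius = 21, pooling = c("energy", "max")) {
  pooling <- match.arg(pooling)
  if (radius > min(params$spec$prototype)) stop("ring radius exceeds the lattice")
  center <- params$spec$prototype
  n_pts <- ceiling(radius) + 1
  tt <- seq(0, 1, length.out = n_pts)
  delta <- vapply(psi_deg, function(psi) {
    s <- center + radius * c(cos(deg2rad(psi)), sin(deg2rad(psi)))
    V <- matrix(0, params$spec$width, params$spec$height)
    for (i in seq_len(n_pts)) {
      V <- V + population_pattern(s + tt[i] * (center - s), params)
    }
    if (pooling == "max") max(V) else sum(V^2)
  }, numeric(1))
  out <- data.frame(psi_deg = psi_deg, delta = delta)
  class(out) <- c("delta_profile", "data.frame")
  attr(out, "pooling") <- pooling
  out
}

#' Prominence-filtered local maxima of a circular profile
#'
#' Finds local maxima of a profile defined on a periodic axis (default
#' period 180 degrees for orientation profiles) and keeps those whose
#' prominence (height above the higher of the two flanking valleys toward
#' the nearest higher point) exceeds `min_prominence` times the profile
#' range.
#'
#' @param profile a [delta_profile()] or a data.frame with `psi_deg`,
#'   `delta`.
#' @param min_prominence minimum prominence as a fraction of the range.
#' @return psi values (degrees) of the retained peaks, ascending.
#' @export
delta_peaks <- function(profile, min_prominence = 0.05) {
  v <- profile$delta
  n <- length(v)
  rng <- diff(range(v))
  if (rng == 0) return(numeric())
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  cand <- which(v > v[prv] & v >= v[nxt])
  keep <- vapply(cand, function(i) {
    ## walk both ways until a strictly higher sample; track the valleys
    walk <- function(step) {
      j <- i; lowest <- v[i]
      for (s in seq_len(n - 1)) {
        j <- if (step > 0) nxt[j] else prv[j]
        if (v[j] > v[i]) break
        lowest <- min(lowest, v[j])
      }
      lowest
    }
    prom <- v[i] - max(walk(1), walk(-1))
    prom >= min_prominence * rng
  }, logical(1))
  sort(profile$psi_deg[cand[keep]])
}

#' Goal-directed vector field over the lattice
#'
#' The hippocampal goal representation combines a periodic directional term
#' and a Gaussian proximity term:
#' `C(R) = dir_amp * cos(delta_c * Phi_R + delta_eps) + exp(-||R - q||^2 / (2 sigma^2))`,
#' where `Phi_R = atan2(q_y - R_y, q_x - R_x)` is the allocentric direction
#' from `R` toward the goal `q`. `delta_c` (default 3, the three grid axes)
#' and `delta_eps` are the fold and phase inherited from the grid
#' orientation: by default `delta_eps = -delta_c * orientation`, placing
#' cosine peaks at one preferred direction per axis. `sigma` defaults to
#' the radius of the space. At `R == q` the direction is undefined; the
#' directional term is set to its circular mean (0) there.
#'
#' @param q goal location `c(x, y)`.
#' @param params a [grid_params()] (supplies orientation and lattice).
#' @param delta_c directional fold.
#' @param delta_eps_deg directional phase in degrees (default derived from
#'   the grid orientation).
#' @param sigma Gaussian spread in cells (default: space radius).
#' @param dir_amp amplitude of the directional term (0 gives a pure
#'   Gaussian proximity field).
#' @return object of class `goal_field`: `C` (width x height matrix), `q`,
#'   `delta_c`, `delta_eps_deg`, `sigma`, `dir_amp`.
#' @export
goal_field <- function(q, params = grid_params(), delta_c = 3,
                       delta_eps_deg = NULL, sigma = NULL, dir_amp = 1) {
  sp <- params$spec
  if (any(q < 0) || q[1] >= sp$width || q[2] >= sp$height) stop("goal outside the lattice")
  if (is.null(delta_eps_deg)) delta_eps_deg <- -delta_c * params$orientation_deg
  if (is.null(sigma)) sigma <- (sp$width - 1) / 2
  if (sigma <= 0) stop("sigma must be positive")
  Rx <- matrix(0:(sp$width - 1), sp$width, sp$height)
  Ry <- matrix(0:(sp$height - 1), sp$width, sp$height, byrow = TRUE)
  Phi <- atan2(q[2] - Ry, q[1] - Rx)
  d2 <- (Rx - q[1])^2 + (Ry - q[2])^2
  C <- dir_amp * cos(delta_c * Phi + deg2rad(delta_eps_deg)) + exp(-d2 / (2 * sigma^2))
  C[q[1] + 1, q[2] + 1] <- 1   # direction undefined at the goal: cosine -> its mean 0
  structure(list(C = C, q = q, delta_c = delta_c, delta_eps_deg = delta_eps_deg,
                 sigma = sigma, dir_amp = dir_amp, spec = sp),
            class = "goal_field")
}

## Chebyshev-ring offsets at radius s, fixed clockwise-from-East ordering
## (deterministic tie breaking for winner-take-all moves).
ring_offsets <- function(s) {
  off <- expand.grid(dx = -s:s, dy = -s:s)
  off <- off[pmax(abs(off$dx), abs(off$dy)) == s, ]
  ang <- wrap_deg(-rad2deg(atan2(off$dy, off$dx)))
  as.matrix(off[order(ang), ])
}

#' Winner-take-all navigation on a goal field
#'
#' From `start`, the agent repeatedly inspects the lattice ring at
#' Chebyshev radius `s` (starting at 1) around its current location and
#' moves to the ring location with the strongest field value, provided it
#' exceeds the value at the current location; otherwise the step size grows
#' by 1 up to `max_step`. Ties are broken by a fixed clockwise-from-East
#' neighbor ordering. The run terminates on reaching a cell within
#' Chebyshev distance 1 of the goal, when no improvement is found at any
#' admissible step size, or at `max_iters` (flagged).
#'
#' @param start integer lattice point.
#' @param field a [goal_field()].
#' @param max_step maximum step size in cells.
#' @param max_iters iteration guard.
#' @return object of class `nav_run`: `visited` (matrix of locations),
#'   `path_length` (sum of Euclidean inter-step distances), `reached`,
#'   `flagged`, `start`, `goal`.
#' @export
navigate <- function(start, field, max_step = 5, max_iters = 500) {
  sp <- field$spec
  C <- field$C
  q <- field$q
  offsets <- lapply(seq_len(max_step), ring_offsets)
  cur <- start
  visited <- matrix(NA_integer_, max_iters + 1, 2)
  visited[1, ] <- cur
  n_vis <- 1
  flagged <- FALSE
  repeat {
    if (max(abs(cur - q)) <= 1) break
    moved <- FALSE
    for (s in seq_len(max_step)) {
      cand <- sweep(offsets[[s]], 2, cur, `+`)
      ok <- cand[, 1] >= 0 & cand[, 1] < sp$width & cand[, 2] >= 0 & cand[, 2] < sp$height
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]
      vals <- C[cand[, 1] + 1 + cand[, 2] * sp$width]
      best <- which.max(vals)
      if (vals[best] > C[cur[1] + 1 + cur[2] * sp$width]) {
        cur <- cand[best, ]
        n_vis <- n_vis + 1
        visited[n_vis, ] <- cur
        moved <- TRUE
        break
      }
    }
    if (!moved) break
    if (n_vis > max_iters) { flagged <- TRUE; break }
  }
  visited <- visited[seq_len(n_vis), , drop = FALSE]
  colnames(visited) <- c("x", "y")
  steps <- diff(visited)
  structure(list(visited = visited,
                 path_length = if (nrow(visited) > 1) sum(sqrt(rowSums(steps^2))) else 0,
                 reached = max(abs(cur - q)) <= 1,
                 flagged = flagged, start = start, goal = q),
            class = "nav_run")
}

#' @export
print.nav_run <- function(x, ...) {
  cat(sprintf("<nav_run> (%d,%d) -> (%d,%d): length %.2f, %s%s\n",
              x$start[1], x$start[2], x$goal[1], x$goal[2], x$path_length,
              if (x$reached) "reached" else "stuck",
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Full navigation simulation across random goals
#'
#' Runs the goal-directed navigation protocol: `n_goals` goal locations are
#' drawn uniformly in the lattice interior (margin `ceiling(sigma/4)` from
#' the boundary); each goal is paired with `n_starts` starting locations
#' arranged in a ring around it, with the ring radius extending to the
#' space boundary (at most `max_radius`), so that start-goal distance is
#' controlled within a goal exactly as the task controls variant-prototype
#' distance. Per goal, path lengths are indexed by the start-to-goal
#' direction, sorted ascending, resampled onto a uniform direction grid,
#' and Fourier transformed; the mean fold spectrum across goals is compared
#' against a label-shuffle permutation threshold (max-statistic FWE across
#' non-DC folds).
#'
#' @param n_goals number of random goal locations.
#' @param n_starts starts per goal (evenly spaced ring angles).
#' @param params a [grid_params()].
#' @param delta_c,dir_amp directional fold and amplitude of the goal field.
#' @param sigma Gaussian spread (default: space radius).
#' @param max_radius maximum ring radius of the starting locations.
#' @param n_grid uniform direction grid for resampling.
#' @param n_perm permutations for the significance threshold.
#' @param max_step,max_iters navigation limits.
#' @param seed seed governing goal sampling and the permutation null.
#' @return object of class `phasesync_sim`: `runs` (data.frame with
#'   goal/start coordinates, direction, path length, flags), `folds`,
#'   `mean_magnitudes`, `fwe_threshold`, `uncorrected`,
#'   `significant_folds`, `argmax_fold`, `resampled` (n_goals x n_grid
#'   matrix of path lengths on the direction grid), `n_perm`, `seed`.
#' @export
run_simulation <- function(n_goals = 100, n_starts = 120, params = grid_params(),
                           delta_c = 3, dir_amp = 1, sigma = NULL,
                           max_radius = 21, n_grid = 36, n_perm = 5000,
                           max_step = 5, max_iters = 500, seed = NULL) {
  sp <- params$spec
  if (is.null(sigma)) sigma <- (sp$width - 1) / 2
  margin <- ceiling(sigma / 4)
  angles <- (seq_len(n_starts) - 1) * 360 / n_starts

  with_seed(seed, {
    goals <- cbind(sample(margin:(sp$width - 1 - margin), n_goals, replace = TRUE),
                   sample(margin:(sp$height - 1 - margin), n_goals, replace = TRUE))
    runs <- vector("list", n_goals)
    resampled <- matrix(NA_real_, n_goals, n_grid)
    for (g in seq_len(n_goals)) {
      q <- goals[g, ]
      radius <- min(max_radius,
                    q[1] - 1, q[2] - 1, sp$width - 2 - q[1], sp$height - 2 - q[2])
      field <- goal_field(q, params, delta_c = delta_c, sigma = sigma, dir_amp = dir_amp)
      res <- lapply(angles, function(a) {
        s <- q + round(radius * c(cos(deg2rad(a)), sin(deg2rad(a))))
        if (all(s == q)) return(NULL)
        nav <- navigate(s, field, max_step = max_step, max_iters = max_iters)
        data.frame(goal_x = q[1], goal_y = q[2], start_x = s[1], start_y = s[2],
                   direction_deg = path_direction(s, q, "toward_goal"),
                   path_length = nav$path_length,
                   reached = nav$reached, flagged = nav$flagged)
      })
      df <- do.call(rbind, res)
      runs[[g]] <- df
      rs <- circular_resample(df$direction_deg, df$path_length, n_grid)
      resampled[g, ] <- rs$values
    }
    runs <- do.call(rbind, runs)

    ## mean observed spectrum across goals
    nq <- n_grid %/% 2
    D <- detrend_matrix(n_grid)
    w <- hann_window(n_grid)
    Fm <- exp(-2i * pi * outer(0:nq, 0:(n_grid - 1)) / n_grid)
    Tm <- Fm %*% (w * D)                     # fold transform incl. detrend+window
    obs_mag <- Mod(Tm %*% t(resampled))      # (nq+1) x n_goals
    mean_mag <- rowMeans(obs_mag)

    ## permutation null: shuffle each goal's direction labels independently
    max_stat <- numeric(n_perm)
    perm_mean <- matrix(0, nq + 1, n_perm)
    for (p in seq_len(n_perm)) {
      P <- vapply(seq_len(n_goals), function(g) resampled[g, sample.int(n_grid)],
                  numeric(n_grid))
      m <- rowMeans(Mod(Tm %*% P))
      perm_mean[, p] <- m
      max_stat[p] <- max(m[-1])
    }
    fwe <- stats::quantile(max_stat, 0.95, names = FALSE)
    uncorrected <- apply(perm_mean, 1, stats::quantile, probs = 0.95, names = FALSE)
    folds <- 0:nq

    structure(list(runs = runs, folds = folds, mean_magnitudes = mean_mag,
                   fwe_threshold = fwe, uncorrected = uncorrected,
                   significant_folds = folds[-1][mean_mag[-1] > fwe],
                   argmax_fold = folds[-1][which.max(mean_mag[-1])],
                   resampled = resampled, n_perm = n_perm, seed = seed),
              class = "phasesync_sim")
  })
}

#' @export
print.phasesync_sim <- function(x, ...) {
  cat(sprintf("<phasesync_sim> %d runs, argmax fold %d, significant folds: %s\n",
              nrow(x$runs), x$argmax_fold,
              if (length(x$significant_folds)) paste(x$significant_folds, collapse = ", ")
              else "none"))
  invisible(x)
}
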