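#' Conceptual object-space specification
#'
#' The task space is a square lattice of object variants defined by two
#' morphable features. Feature length ratios relative to the central
#' prototype span `ratio_min`..`ratio_max` in steps of `ratio_step`, one
#' lattice cell per step, so a 45x45 lattice covers ratios 0.12..1.88 in
#' steps of 0.04. Coordinates are 0-based, x increases East, y increases
#' North, and the prototype (the goal of every trial) sits at the unique
#' central cell.
#'
#' @param width,height lattice size in cells (odd; default 45).
#' @param ratio_min,ratio_max,ratio_step feature-ratio range and step.
#' @return an object of class `space_spec` with fields `width`, `height`,
#'   `prototype` (c(x, y)), `ratio_min`, `ratio_max`, `ratio_step`.
#' @export
#' @examples
#' sp <- space_spec()
#' sp$prototype  # c(22, 22)
space_spec <- function(width = 45L, height = 45L,
                       ratio_min = 0.12, ratio_max = 1.88, ratio_step = 0.04) {
  width <- as.integer(width); height <- as.integer(height)
  if (width %% 2L == 0L || height %% 2L == 0L) {
    stop("lattice must be odd-sized so the prototype is a unique central cell")
  }
  if (abs(ratio_min + ratio_step * (width - 1) - ratio_max) > 1e-9) {
    stop("ratio_min + ratio_step * (width - 1) must equal ratio_max")
  }
  structure(
    list(width = width, height = height,
         prototype = c((width - 1L) %/% 2L, (height - 1L) %/% 2L),
         ratio_min = ratio_min, ratio_max = ratio_max, ratio_step = ratio_step),
    class = "space_spec")
}

#' @export
print.space_spec <- function(x, ...) {
  cat(sprintf("<space_spec> %dx%d lattice, prototype (%d,%d), ratios %.2f..%.2f step %.2f\n",
              x$width, x$height, x$prototype[1], x$prototype[2],
              x$ratio_min, x$ratio_max, x$ratio_step))
  invisible(x)
}

#' Direction of a path between two lattice points
#'
#' 0 degrees points East; angles increase counterclockwise (y northward).
#' Two conventions are supported: `"start_rel_end"` gives the angle of the
#' vector start - end ("movement from" the start, as used in the empirical
#' direction analyses), `"toward_goal"` gives the angle of end - start (as
#' used by the navigation model). The two differ by exactly 180 degrees.
#'
#' @param start,end integer lattice points, `c(x, y)`.
#' @param convention `"start_rel_end"` or `"toward_goal"`.
#' @return direction in degrees in `[0, 360)`.
#' @export
#' @examples
#' path_direction(c(44, 22), c(22, 22))                  # 0
#' path_direction(c(44, 22), c(22, 22), "toward_goal")   # 180
path_direction <- function(start, end, convention = c("start_rel_end", "toward_goal")) {
  convention <- match.arg(convention)
  if (all(start == end)) stop("degenerate direction: start == end")
  d <- if (convention == "start_rel_end") start - end else end - start
  wrap_deg(rad2deg(atan2(d[2], d[1])))
}

#' Shortest cardinal-step path length between two lattice points
#'
#' Movements are restricted to the four cardinal directions, so the optimal
#' path length is the Manhattan distance `|dx| + |dy|` (in lattice steps).
#'
#' @inheritParams path_direction
#' @return number of steps (non-negative integer).
#' @export
optimal_path_length <- function(start, end) {
  abs(start[1] - end[1]) + abs(start[2] - end[2])
}

#' Composite behavioral performance score
#'
#' Per-trial performance combines navigational efficiency and positional
#' accuracy: `score = T - T_opt + E / 0.04`, where `T` is the actual path
#' length in steps, `T_opt` the optimal (Manhattan) length, and `E` the
#' Euclidean feature-ratio distance between the ending location and the
#' goal; dividing by the feature step size 0.04 converts the ratio error to
#' step-equivalent units. Lower scores are better; a perfect trial scores 0.
#'
#' @param T actual path length (steps).
#' @param T_opt optimal path length (steps).
#' @param E feature-ratio distance between ending location and goal.
#' @param ratio_step feature step size converting ratio error to steps.
#' @return an object of class `performance_score` with fields `T`, `T_opt`,
#'   `E`, `score`.
#' @export
#' @examples
#' performance_score(30, 22, 0.16)$score  # 12
performance_score <- function(T, T_opt, E, ratio_step = 0.04) {
  stopifnot_scalar(T, "T"); stopifnot_scalar(T_opt, "T_opt"); stopifnot_scalar(E, "E")
  if (T < 0 || T_opt < 0 || E < 0) stop("T, T_opt and E must be non-negative")
  structure(list(T = T, T_opt = T_opt, E = E,
                 score = T - T_opt + E / ratio_step),
            class = "performance_score")
}

## Step sequence (differences of consecutive locations) of a path matrix.
path_steps <- function(path) {
  path <- as.matrix(path)
  if (nrow(path) < 2) stop("path must contain at least one step")
  diff(path)
}

#' Count unique net directions over consecutive step triplets
#'
#' Movement-strategy diagnostic: the raw step sequence is partitioned into
#' consecutive non-overlapping triplets (a trailing remainder of fewer than
#' three steps is dropped), each triplet is reduced to the direction of its
#' net displacement, and the number of distinct directions is returned. A
#' pure horizontal-vertical path (one axis completed, then the other) yields
#' 2; interleaved adjustment of both features yields more.
#'
#' @param path integer matrix of lattice locations (columns x, y), one row
#'   per visited location.
#' @return number of distinct triplet net-displacement directions.
#' @export
triplet_direction_count <- function(path) {
  steps <- path_steps(path)
  n <- nrow(steps)
  if (n < 3) stop("path must have at least 3 steps")
  n_trip <- n %/% 3
  dirs <- vapply(seq_len(n_trip), function(i) {
    net <- colSums(steps[(3 * i - 2):(3 * i), , drop = FALSE])
    if (all(net == 0)) return(NA_real_)
    wrap_deg(rad2deg(atan2(net[2], net[1])))
  }, numeric(1))
  length(unique(round(dirs[!is.na(dirs)], 9)))
}

#' Sample start locations on a peripheral ring with uniform direction bins
#'
#' Emulates the experimental sampling of object variants near the boundary
#' of the space: directions are drawn without replacement from a fine
#' angular precision grid (default 1.25 degrees), `per_bin` per angular bin
#' of `bin_width` degrees, guaranteeing exact per-bin uniformity; radial
#' distance to the prototype is controlled at `radius` plus a small jitter
#' so the starts form a near-boundary ring. Defaults reproduce the design
#' total of 288 start locations (24 per 30-degree bin over 12 bins).
#'
#' @param spec a [space_spec()].
#' @param per_bin starts per angular bin.
#' @param bin_width angular bin width in degrees (must divide 360).
#' @param precision angular precision grid in degrees.
#' @param radius nominal ring radius in cells.
#' @param radius_jitter maximum absolute integer radial jitter in cells.
#' @param seed optional integer seed; identical seeds give identical samples.
#' @return data.frame with columns `x`, `y`, `direction_deg` (direction from
#'   start toward the prototype, `"start_rel_end"` convention applies to the
#'   returned nominal direction of the variant relative to the goal) and
#'   `bin` (bin lower edge in degrees).
#' @export
sample_ring_starts <- function(spec = space_spec(), per_bin = 24L, bin_width = 30,
                               precision = 1.25, radius = 21, radius_jitter = 1L,
                               seed = NULL) {
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  n_bins <- 360 %/% bin_width
  slots_per_bin <- bin_width / precision
  if (abs(slots_per_bin - round(slots_per_bin)) > 1e-9) {
    stop("precision must divide bin_width")
  }
  slots_per_bin <- round(slots_per_bin)
  if (per_bin > slots_per_bin) {
    stop(sprintf("per_bin (%d) exceeds the %d precision slots per bin", per_bin, slots_per_bin))
  }
  with_seed(seed, {
    out <- lapply(seq_len(n_bins) - 1L, function(b) {
      lo <- b * bin_width
      slots <- lo + precision * (seq_len(slots_per_bin) - 1L)
      dirs <- sort(sample(slots, per_bin))
      r <- radius + sample.int(2L * radius_jitter + 1L, per_bin, replace = TRUE) -
        radius_jitter - 1L
      ## the variant sits at angle `dir` from the prototype; its movement
      ## direction "from" the variant is the same angle under start_rel_end
      x <- spec$prototype[1] + round(r * cos(deg2rad(dirs)))
      y <- spec$prototype[2] + round(r * sin(deg2rad(dirs)))
      data.frame(x = as.integer(x), y = as.integer(y),
                 direction_deg = dirs, bin = lo)
    })
    do.call(rbind, out)
  })
}

#' Construct a movement-strategy path between two lattice points
#'
#' `"horizontal_vertical"` completes all steps along one axis and then the
#' other (the strategy participants were discouraged from using);
#' `"radial_adjustment"` alternates one-unit adjustments between the two
#' axes until one axis is exhausted, then finishes on the other (the
#' instructed strategy). Both produce monotone paths of Manhattan length.
#'
#' @param start,goal integer lattice points `c(x, y)`.
#' @param strategy `"radial_adjustment"` or `"horizontal_vertical"`.
#' @param first_axis which axis moves first, `"x"` or `"y"`.
#' @return integer matrix of visited locations (rows), columns `x`, `y`,
#'   beginning at `start` and ending at `goal`.
#' @export
simulate_strategy_path <- function(start, goal,
                                   strategy = c("radial_adjustment", "horizontal_vertical"),
                                   first_axis = c("x", "y")) {
  strategy <- match.arg(strategy)
  first_axis <- match.arg(first_axis)
  if (all(start == goal)) stop("start must differ from goal")
  d <- goal - start
  sx <- sign(d[1]); sy <- sign(d[2])
  nx <- abs(d[1]); ny <- abs(d[2])
  steps_x <- matrix(rep(c(sx, 0), nx), ncol = 2, byrow = TRUE)
  steps_y <- matrix(rep(c(0, sy), ny), ncol = 2, byrow = TRUE)
  if (first_axis == "y") { tmp <- steps_x; steps_x <- steps_y; steps_y <- tmp }
  if (strategy == "horizontal_vertical") {
    steps <- rbind(steps_x, steps_y)
  } else {
    n1 <- nrow(steps_x); n2 <- nrow(steps_y)
    k <- min(n1, n2)
    inter <- matrix(0, 2 * k, 2)
    if (k > 0) {
      inter[seq(1, 2 * k, by = 2), ] <- steps_x[seq_len(k), , drop = FALSE]
      inter[seq(2, 2 * k, by = 2), ] <- steps_y[seq_len(k), , drop = FALSE]
    }
    steps <- rbind(inter,
                   if (n1 > k) steps_x[(k + 1):n1, , drop = FALSE],
                   if (n2 > k) steps_y[(k + 1):n2, , drop = FALSE])
  }
  path <- rbind(start, sweep(apply(steps, 2, cumsum), 2, start, `+`))
  dimnames(path) <- list(NULL, c("x", "y"))
  storage.mode(path) <- "integer"
  path
}

#' Write / read a lattice path as TSV
#'
#' Paths are serialized with columns `step_index`, `x`, `y`.
#'
#' @param path integer matrix of locations (columns x, y).
#' @param file path to a TSV file.
#' @return `read_path` returns the location matrix; `write_path` returns
#'   `file` invisibly.
#' @export
write_path <- function(path, file) {
  df <- data.frame(step_index = seq_len(nrow(path)) - 1L,
                   x = path[, 1], y = path[, 2])
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_path
#' @export
read_path <- function(file) {
  df <- utils::read.delim(file)
  need <- c("step_index", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("path TSV is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$step_index), ]
  as.matrix(df[, c("x", "y")])
}
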