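test_that("grid code attains 3A at the cell's own offset and respects pattern periodicity", {
  p <- grid_params(amplitude = 1.5)
  expect_equal(grid_code(c(10, 10), c(10, 10), p), 3 * 1.5)
  expect_equal(grid_code(c(3, 7), c(20, 20), grid_params(amplitude = 0)), 0)

  # hexagonal-lattice translation: period along an axis is 2 * period / sqrt(3)
  L <- 2 * (2 * pi / p$omega) / sqrt(3)
  t_vec <- L * c(cos(deg2rad(15)), sin(deg2rad(15)))
  for (r in list(c(5, 5), c(12.3, 20.1), c(30, 8))) {
    expect_equal(grid_code(c(10, 10), r + t_vec, p), grid_code(c(10, 10), r, p),
                 tolerance = 1e-9)
  }
})

test_that("population pattern peaks at the agent location and translates with it", {
  p <- grid_params()
  pat <- population_pattern(c(22, 22), p)
  expect_equal(dim(pat), c(45, 45))
  expect_equal(pat[23, 23], 3)          # c == r
  expect_equal(max(pat), 3, tolerance = 1e-9)
  expect_true(all(pat >= -3 - 1e-9 & pat <= 3 + 1e-9))

  L <- 2 * (2 * pi / p$omega) / sqrt(3)
  t_vec <- L * c(cos(deg2rad(15)), sin(deg2rad(15)))
  expect_equal(population_pattern(c(10, 10) + t_vec, p),
               population_pattern(c(10, 10), p), tolerance = 1e-9)
})

test_that("supercover rasterization covers lines deterministically", {
  straight <- rasterize_path(c(0, 0), c(4, 0))
  expect_equal(nrow(straight), 5)
  expect_equal(straight[, "y"], rep(0, 5))

  diag <- rasterize_path(c(0, 0), c(3, 3))
  expect_true(all(c(paste(1, 1), paste(2, 2)) %in% paste(diag[, 1], diag[, 2])))
  expect_equal(diag[1, ], c(x = 0, y = 0))
  expect_equal(diag[nrow(diag), ], c(x = 3, y = 3))

  expect_equal(rasterize_path(c(5, 5), c(5, 5)), cbind(x = 5, y = 5))
  expect_identical(rasterize_path(c(2, 1), c(9, 4)), rasterize_path(c(2, 1), c(9, 4)))
})

test_that("path codes collapse direction onto orientation (180-degree identity)", {
  p <- grid_params()
  q <- c(22, 22)
  for (s in list(c(1, 22), c(5, 8), c(40, 31))) {
    V <- path_code(s, q, p)
    V_op <- path_code(2 * q - s, q, p)
    # elementwise equality after point reflection of the cell lattice
    expect_equal(V_op[45:1, 45:1], unclass(V), tolerance = 1e-9, ignore_attr = TRUE)
    # identical multisets of cell activity and identical totals
    expect_equal(sort(as.vector(V_op)), sort(as.vector(V)), tolerance = 1e-9)
    expect_equal(sum(V_op), sum(V), tolerance = 1e-9)
  }
  expect_equal(attr(path_code(c(1, 22), q, p), "orientation_deg"), 0)
})

test_that("path code sums match the planar-wave (Dirichlet) closed form", {
  p <- grid_params()
  s <- c(1, 22); q <- c(22, 22)
  V <- path_code(s, q, p)
  locs <- attr(V, "locations")
  # independent closed form: V(c) = sum_i Re( S_i * exp(-i w k_i . c) ),
  # S_i = sum_j exp(i w k_i . r_j)
  cx <- matrix(0:44, 45, 45); cy <- matrix(0:44, 45, 45, byrow = TRUE)
  V_ref <- matrix(0, 45, 45)
  for (i in 1:3) {
    S <- sum(exp(1i * p$omega * (locs %*% p$k[i, ])))
    V_ref <- V_ref + Re(S * exp(-1i * p$omega * (p$k[i, 1] * cx + p$k[i, 2] * cy)))
  }
  expect_equal(unclass(V), V_ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("delta profile has three peaks on the grid axes and rotates with the grid", {
  p <- grid_params()
  dp <- delta_profile(p)
  expect_equal(dp$delta[dp$psi_deg == 15], dp$delta[dp$psi_deg == 75], tolerance = 0.05)
  peaks <- delta_peaks(dp)
  expect_length(peaks, 3)
  expect_equal(peaks, grid_axes(p), tolerance = 2)

  # dominant non-DC Fourier component at 3 cycles per 180 degrees
  sp <- fold_spectrum(dp$delta)
  expect_equal(sp$folds[-1][which.max(sp$magnitudes[-1])], 3)

  # rotating the grid rotates the peaks
  p2 <- grid_params(orientation_deg = 35)
  peaks2 <- delta_peaks(delta_profile(p2, psi_deg = seq(0, 179)))
  expect_equal(peaks2, grid_axes(p2), tolerance = 2)

  # max pooling keeps the threefold fundamental
  dpm <- delta_profile(p, psi_deg = seq(0, 178, by = 2), pooling = "max")
  spm <- fold_spectrum(dpm$delta)
  expect_equal(spm$folds[-1][which.max(spm$magnitudes[-1])], 3)
})

test_that("goal field combines the directional cosine and Gaussian proximity terms", {
  p <- grid_params()
  gf <- goal_field(c(22, 22), p)
  expect_equal(gf$C[23, 23], 1)                      # goal cell: Gaussian 1, cos -> 0
  expect_equal(gf$sigma, 22)
  expect_equal(gf$delta_eps_deg, -45)

  # pure proximity field peaks at the goal
  g0 <- goal_field(c(13, 30), p, dir_amp = 0)
  expect_equal(which(g0$C == max(g0$C)), 13 + 1 + 30 * 45)

  # delta_c = 3: directional term invariant under 120-degree rotation of Phi
  Phi <- seq(0, 2 * pi, length.out = 100)
  expect_equal(cos(3 * (Phi + 2 * pi / 3) + deg2rad(gf$delta_eps_deg)),
               cos(3 * Phi + deg2rad(gf$delta_eps_deg)), tolerance = 1e-12)
  expect_error(goal_field(c(50, 10), p), "outside")
})

test_that("winner-take-all navigation is deterministic and near-optimal on a proximity field", {
  p <- grid_params()
  g0 <- goal_field(c(22, 22), p, dir_amp = 0)
  adj <- navigate(c(23, 23), g0)
  expect_lte(adj$path_length, sqrt(2))
  expect_true(adj$reached)

  nv1 <- navigate(c(1, 22), g0)
  nv2 <- navigate(c(1, 22), g0)
  expect_identical(nv1, nv2)

  angles <- (0:119) * 3
  ratios <- vapply(angles, function(a) {
    s <- c(22, 22) + round(21 * c(cos(deg2rad(a)), sin(deg2rad(a))))
    nv <- navigate(s, g0)
    expect_true(nv$reached)
    nv$path_length / sqrt(sum((s - c(22, 22))^2))
  }, numeric(1))
  expect_lte(max(ratios), 1.2)
})

test_that("path length is bracketed by geometry and aligned directions are faster", {
  p <- grid_params()
  gf <- goal_field(c(22, 22), p)
  lens <- vapply(c(15, 75, 135, 195, 255, 315), function(a) {
    s <- c(22, 22) + round(21 * c(cos(deg2rad(a)), sin(deg2rad(a))))
    nv <- navigate(s, gf)
    expect_gte(nv$path_length + 1e-9,
               sqrt(sum((nv$visited[nrow(nv$visited), ] - s)^2)))
    nv$path_length
  }, numeric(1))
  # directions toward the goal at cos peaks {15,135,255} (start positions opposite)
  peak_dirs <- c(195, 315, 75); trough_dirs <- c(15, 135, 255)
  names(lens) <- c(15, 75, 135, 195, 255, 315)
  expect_lt(mean(lens[as.character(peak_dirs)]), mean(lens[as.character(trough_dirs)]))
})

test_that("a reduced random-goal simulation already shows the threefold spectrum", {
  sim <- run_simulation(n_goals = 10, n_starts = 48, n_perm = 200, seed = 31)
  expect_equal(sim$argmax_fold, 3)
  expect_true(3 %in% sim$significant_folds)
  expect_true(all(sim$runs$reached))
  expect_false(any(sim$runs$flagged))
  expect_equal(nrow(sim$runs), 10 * 48)

  # null control: without the directional term the threefold effect vanishes
  sim0 <- run_simulation(n_goals = 6, n_starts = 48, n_perm = 200, dir_amp = 0, seed = 32)
  expect_lt(max(sim0$mean_magnitudes[4]), sim$mean_magnitudes[4] / 5)
})
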