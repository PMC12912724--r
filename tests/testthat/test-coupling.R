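test_that("circular analytic signal extracts envelope and advancing phase", {
  th <- theta_grid(144)
  a3 <- analytic_signal(cos(3 * th))
  expect_equal(a3$amplitude, rep(1, 144), tolerance = 1e-9)
  expect_equal(a3$phase, phasesync:::wrap_pi(3 * th), tolerance = 1e-9)

  a6 <- analytic_signal(2 * cos(6 * th))
  expect_equal(a6$amplitude, rep(2, 144), tolerance = 1e-9)

  # cos(3*theta - 60 deg): phase zero (peak) lands at theta = 20 deg
  sh <- analytic_signal(cos(3 * th - pi / 3))
  peak <- th[which.min(abs(sh$phase))]
  expect_equal(peak * 180 / pi, 20, tolerance = 1.3)

  expect_error(analytic_signal(rnorm(10)), "at least 16")
})

test_that("modulation index bins are anchored at phase zero", {
  centers <- phasesync:::phase_bin_centers(9)
  expect_equal(centers, seq(-160, 160, by = 40))
  expect_equal(sum(centers == 0), 1)

  th <- theta_grid(360)
  ph <- phasesync:::wrap_pi(3 * th)
  m0 <- modulation_by_phase(rep(0, 360), ph)
  expect_equal(m0$M, rep(0, 9))

  # M is invariant when amplitude and phase are jointly rotated in direction
  A <- cos(6 * th)
  shift <- 37
  rot <- function(x) x[((seq_along(x) - 1 + shift) %% length(x)) + 1]
  expect_equal(modulation_by_phase(rot(A), rot(ph))$M,
               modulation_by_phase(A, ph)$M, tolerance = 1e-12)

  # empty bins are flagged
  expect_warning(mb <- modulation_by_phase(rep(1, 5), rep(0, 5), n_bins = 9), "empty")
  expect_true(all(is.na(mb$M[mb$bin_centers != 0])))
})

test_that("peak-aligned sixfold amplitude couples maximally at phase zero", {
  th <- theta_grid(360)
  ca <- coupling_alignment(cos(6 * th), cos(3 * th))
  expect_equal(ca$argmax_bin_center, 0)
  expect_gt(ca$strength[ca$bin_centers == 0], 0)
  expect_equal(which.max(ca$strength), which(ca$bin_centers == 0))

  # rotating the fast amplitude moves the coupled bin to 3 * delta
  ca40 <- coupling_alignment(cos(6 * (th - deg2rad(40))), cos(3 * th))
  expect_equal(ca40$argmax_bin_center, 120)

  # harmonic-relation controls: strength never exceeds the aligned sixfold case
  s6 <- ca$strength[ca$bin_centers == 0]
  for (fold in c(9, 12)) {
    ctrl <- coupling_alignment(cos(fold * th), cos(3 * th))
    expect_lt(max(ctrl$strength), s6)
  }
})

test_that("lag surrogates cancel coupling for lag-invariant amplitudes", {
  th <- theta_grid(90)
  ph <- phasesync:::wrap_pi(3 * th)
  flat <- shift_surrogates(rep(2, 90), ph)
  expect_equal(max(abs(flat$strength)), 0, tolerance = 1e-10)
})

test_that("least-squares FIR band-pass separates, preserves, and attenuates", {
  th <- theta_grid(360)
  x <- cos(3 * th) + cos(6 * th)
  y <- fir_bandpass(x, center_fold = 3)
  expect_gt(cor(y, cos(3 * th)), 0.99)

  tone <- fir_bandpass(cos(3 * th), center_fold = 3)
  expect_equal(max(abs(tone)), 1, tolerance = 0.05)       # pass band preserved

  stopped <- fir_bandpass(cos(6 * th), center_fold = 3)
  atten_db <- 20 * log10(max(abs(stopped)))
  expect_lt(atten_db, -20)                                 # stop band >= 20 dB down

  expect_error(fir_bandpass(x, 3, order = 200), "order must be < n/3|too long")
  expect_error(fir_bandpass(x, 3, order = 15), "even")
})

test_that("phase locking degenerate cases and symmetry", {
  th <- theta_grid(72)
  a <- cos(3 * th)
  same <- phase_locking(a, a, surrogates = FALSE)
  expect_equal(same$plv, 1, tolerance = 1e-9)
  expect_equal(same$pli, 0, tolerance = 1e-9)

  lag <- phase_locking(a, cos(3 * (th - deg2rad(30))), surrogates = FALSE)
  expect_equal(lag$plv, 1, tolerance = 1e-9)
  expect_equal(lag$pli, 1, tolerance = 1e-9)

  # PLV symmetric in its arguments; PLI unchanged under lag negation
  b <- cos(3 * (th - deg2rad(10))) + 0.2 * cos(6 * th)
  expect_equal(phase_locking(a, b, surrogates = FALSE)$plv,
               phase_locking(b, a, surrogates = FALSE)$plv, tolerance = 1e-12)
  neg <- phase_locking(a, cos(3 * (th + deg2rad(30))), surrogates = FALSE)
  expect_equal(neg$pli, 1, tolerance = 1e-9)

  # independent random-phase signals: PLV near the 1/sqrt(n) null scale
  set.seed(9)
  n <- 360
  plvs <- replicate(20, {
    s1 <- Re(stats::fft(stats::fft(rnorm(n)) * exp(2i * pi * runif(n)), inverse = TRUE))
    s2 <- Re(stats::fft(stats::fft(rnorm(n)) * exp(2i * pi * runif(n)), inverse = TRUE))
    phase_locking(s1, s2, surrogates = FALSE)$plv
  })
  expect_lt(mean(plvs), 4 / sqrt(n))

  # surrogate distributions cover all nonzero lags
  pl <- phase_locking(a, cos(3 * (th - deg2rad(30))))
  expect_length(pl$plv_surrogate, 71)
})
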