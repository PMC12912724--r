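# Shared synthetic fixtures, built in code at test time.

# Full 8-session design with the standard 288 ring directions.
full_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      starts <- sample_ring_starts(seed = 101)
      cache <<- make_event_design(starts$direction_deg, seed = 102)
    }
    cache
  }
})

# Compact 2-session design for cheap GLM tests.
small_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(103)
      dirs <- sample(seq(0, 358.75, by = 1.25), 72)
      cache <<- make_event_design(dirs, n_sessions = 2, lures_per_session = 2,
                                  seed = 104)
    }
    cache
  }
})

# Uniform direction grid in radians.
theta_grid <- function(n) 2 * pi * (seq_len(n) - 1) / n

expect_circ_close <- function(est_deg, true_deg, period, tol) {
  d <- (est_deg - true_deg) %% period
  d <- pmin(d, period - d)
  expect_lt(max(d), tol)
}
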