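test_that("integration yields the analytic antiderivative", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  A <- 2
  f <- 1
  v <- make_vertical(A * cos(2 * pi * f * t), fs = fs, t = t)
  vel <- integrate_signal(v)
  # oracle: the analytic antiderivative A/(2 pi f) sin(...), passed through
  # the same documented linear drift removal
  sine <- A / (2 * pi * f) * sin(2 * pi * f * t)
  expected <- stats::lm.fit(cbind(1, t), sine)$residuals
  expect_lt(max(abs(vel - expected)), 0.01 * A / (2 * pi * f))
  expect_equal(max(vel), max(expected), tolerance = 0.01)

  # zero in, zero out; pure DC is removed by the drift detrend
  expect_equal(integrate_signal(make_vertical(rep(0, 100))), rep(0, 100))
  vel_dc <- integrate_signal(make_vertical(rep(0.5, 200)))
  expect_lt(max(abs(vel_dc)), 1e-9)

  expect_error(integrate_signal(make_vertical(c(0, 1))),
               "insufficient-data")
})

test_that("noiseless walks are detected to within one sample", {
  aw <- constant_walk(n_steps = 10, fs = 100, seed = 0)
  ev <- detect_ics(pipeline_vertical(aw$recording))
  expect_equal(length(ev$ic_times), length(aw$truth_events$ic_times))
  m <- match_events(ev, aw$truth_events, tol_s = 0.05)
  expect_equal(m$misses, 0L)
  expect_equal(m$false_alarms, 0L)
  expect_lte(max(abs(m$errors_s)), 1 / 100 + 1e-9)
})

test_that("moderate noise still recovers nearly all contacts", {
  aw <- simulate_walk(walk_spec(n_steps = 10, noise_sigma_rel = 0.05,
                                seed = 4))
  ev <- detect_ics(pipeline_vertical(aw$recording))
  m <- match_events(ev, aw$truth_events, tol_s = 0.03)
  expect_gte(m$hits, 9L)
})

test_that("detected event count tracks the simulated step count across seeds", {
  for (seed in 0:9) {
    aw <- simulate_walk(walk_spec(n_steps = 12, noise_sigma_rel = 0.05,
                                  seed = seed))
    ev <- detect_ics(pipeline_vertical(aw$recording))
    expect_lte(abs(length(ev$ic_times) - (12 + 1)), 1)
  }
})

test_that("a flat signal yields zero events with a warning, not an error", {
  v <- make_vertical(rep(0, 400), fs = 100)
  expect_warning(ev <- detect_ics(v), "no initial contacts")
  expect_length(ev$ic_times, 0)
  expect_error(detect_ics(make_vertical(rep(0, 10), fs = 100)),
               "insufficient-data")
})

test_that("detection is translation-equivariant and amplitude-invariant", {
  aw <- constant_walk(n_steps = 8, seed = 2)
  v <- pipeline_vertical(aw$recording)
  ev <- detect_ics(v)

  shifted <- v
  shifted$t <- v$t + 5
  ev_s <- detect_ics(shifted)
  expect_equal(ev_s$ic_times, ev$ic_times + 5, tolerance = 1e-9)

  scaled <- v
  scaled$a_v <- v$a_v * 3.7
  ev_a <- detect_ics(scaled)
  expect_equal(ev_a$ic_times, ev$ic_times)
})

test_that("event matching is one-to-one within tolerance", {
  m <- match_events(c(1, 2, 3), c(1, 2, 3), tol_s = 0.1)
  expect_equal(m$hits, 3L)
  expect_equal(max(abs(m$errors_s)), 0)

  m2 <- match_events(c(1.01, 2.9), c(1, 2, 3), tol_s = 0.1)
  expect_equal(m2$hits, 2L)
  expect_equal(m2$misses, 1L)
  expect_equal(m2$false_alarms, 0L)

  m3 <- match_events(numeric(0), c(1, 2), tol_s = 0.1)
  expect_equal(m3$misses, 2L)

  expect_error(match_events(1, 1, tol_s = 0), "parameter error")
})

test_that("greedy matching agrees with brute force on separated events", {
  # brute-force: maximum bipartite matching by exhaustive assignment
  brute_hits <- function(det, tru, tol) {
    if (length(det) == 0 || length(tru) == 0) return(0L)
    best <- 0L
    assign_next <- function(di, used_t, hits) {
      if (di > length(det)) {
        best <<- max(best, hits)
        return()
      }
      assign_next(di + 1, used_t, hits)  # leave det[di] unmatched
      for (ti in seq_along(tru)) {
        if (!used_t[ti] && abs(det[di] - tru[ti]) <= tol) {
          used_t[ti] <- TRUE
          assign_next(di + 1, used_t, hits + 1L)
          used_t[ti] <- FALSE
        }
      }
    }
    assign_next(1L, logical(length(tru)), 0L)
    best
  }
  set.seed(5)
  for (rep in 1:5) {
    tru <- cumsum(runif(5, 0.5, 1))
    det <- tru + runif(5, -0.08, 0.08)
    det <- sort(det[runif(5) > 0.2])
    m <- match_events(det, tru, tol_s = 0.1)
    expect_equal(m$hits, brute_hits(det, tru, 0.1))
    expect_equal(m$hits + m$misses, length(tru))
    expect_equal(m$hits + m$false_alarms, length(det))
  }
})
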