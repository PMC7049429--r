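test_that("step and stride times are consecutive IC differences", {
  ev <- gait_events("s", "left", c(0, 0.54, 1.17))
  expect_equal(step_times(ev), c(0.54, 0.63))
  expect_equal(stride_times(ev), 1.17)
  expect_equal(step_times(gait_events("s", "left", c(0, 1))), 1)
  expect_error(step_times(gait_events("s", "left", 0.5)),
               "insufficient-events")
  expect_error(stride_times(gait_events("s", "left", c(0, 1))),
               "insufficient-events")

  # telescoping identity on an arbitrary event sequence
  ic <- cumsum(c(0, runif(9, 0.4, 0.8)))
  ev2 <- gait_events("s", "left", ic)
  st <- step_times(ev2)
  expect_equal(stride_times(ev2), st[-length(st)] + st[-1])
})

test_that("simulated constant cadence is recovered in the step times", {
  aw <- simulate_walk(walk_spec(n_steps = 20, step_time_mean = 0.55,
                                step_time_sd = 0, step_length_sd = 0,
                                noise_sigma_rel = 0, seed = 0))
  ev <- detect_ics(pipeline_vertical(aw$recording))
  expect_true(all(abs(step_times(ev) - 0.55) <= 1 / 100 + 1e-9))
  expect_true(all(abs(stride_times(ev) - 1.10) <= 2 / 100 + 1e-9))
})

test_that("vertical excursion matches the analytic double antiderivative", {
  fs <- 100
  f <- 1
  A <- 0.003
  t <- seq(0, 1, by = 1 / fs)
  v <- make_vertical(-A * (2 * pi * f)^2 * cos(2 * pi * f * t), fs, t)
  H <- vertical_excursion(v, 0, 1)
  expect_equal(H, 2 * A, tolerance = 0.02)

  expect_equal(vertical_excursion(make_vertical(rep(0, 200)), 0, 1), 0)
  expect_error(vertical_excursion(make_vertical(rep(0, 200)), 0.5, 0.505),
               "insufficient-data")
  expect_error(vertical_excursion(make_vertical(rep(0, 200)), 1, 0.5),
               "parameter error")
})

test_that("programmed excursions are recovered from the simulated signal", {
  aw <- constant_walk(n_steps = 8, seed = 1)
  v <- pipeline_vertical(aw$recording)
  truth <- aw$truth_params$per_step
  H_est <- vapply(seq_len(nrow(truth)), function(i) {
    vertical_excursion(v, truth$ic_start[i], truth$ic_end[i])
  }, numeric(1))
  expect_true(all(abs(H_est - truth$H) / truth$H < 0.05))
})

test_that("the pendulum chord maps excursion to step length", {
  cfg <- pendulum_config()
  expect_equal(step_length(0, cfg), 0)
  expect_equal(step_length(0.002, cfg),
               4 * 2 * sqrt(2 * 0.34 * 0.002 - 0.002^2))
  expect_equal(step_length(0.002, cfg), 0.2946, tolerance = 1e-4)
  expect_error(step_length(-0.001, cfg), "domain error")
  expect_error(step_length(0.7, cfg), "domain error")

  # monotone on [0, W_h] and continuous at the origin
  H <- seq(0, cfg$W_h, length.out = 200)
  L <- step_length(H, cfg)
  expect_true(all(diff(L) > 0))
  expect_lt(step_length(1e-12, cfg), 1e-5)
})

test_that("summary parameters obey their exact identities", {
  aw <- simulate_walk(walk_spec(n_steps = 14, noise_sigma_rel = 0.03,
                                seed = 6))
  v <- pipeline_vertical(aw$recording)
  gp <- summarize_gait(detect_ics(v), v)
  expect_identical(gp$stride_length_m, 2 * gp$step_length_m)
  expect_equal(gp$walking_speed_mps * gp$step_time_s, gp$step_length_m,
               tolerance = 1e-12)
  expect_equal(gp$step_time_s, mean(gp$per_step$step_time))
  expect_equal(gp$n_steps, nrow(gp$per_step))

  # a two-IC recording cannot produce a stride
  short <- gait_events("s", "left", c(0.5, 1.05))
  expect_error(summarize_gait(short, v), "insufficient-events")
})

test_that("a noiseless walk recovers all five programmed parameters", {
  aw <- simulate_walk(walk_spec(n_steps = 20, step_time_mean = 0.55,
                                step_length_mean = 0.30,
                                noise_sigma_rel = 0, seed = 0))
  gp <- estimate_gait(aw$recording)
  tp <- aw$truth_params
  for (p in gait_parameter_names()) {
    expect_lt(error_rate(gp[[p]], tp[[p]]), 5)
  }
})
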