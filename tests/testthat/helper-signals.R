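# Shared fixture builders. Everything is generated in code; no stored data.

# A vertical_signal directly from a numeric series (bypasses preprocessing),
# for oracle tests of the integration/excursion primitives.
make_vertical <- function(a, fs = 100, t = NULL) {
  if (is.null(t)) t <- seq(0, by = 1 / fs, length.out = length(a))
  structure(list(subject_id = "fix", leg = "left", fs = fs, t = t,
                 a_v = as.numeric(a), provenance = list()),
            class = "vertical_signal")
}

# A constant-parameter noiseless walk (sample-exact detection case).
constant_walk <- function(n_steps = 10, fs = 100, seed = 0, ...) {
  simulate_walk(walk_spec(n_steps = n_steps, step_time_sd = 0,
                          step_length_sd = 0, noise_sigma_rel = 0, fs = fs,
                          seed = seed, ...))
}

# Run the preprocessing front half of the pipeline.
pipeline_vertical <- function(rec) extract_vertical(tilt_correct(rec))

# A small feature table with a programmed group shift (in pooled-sd units)
# on step length and walking speed.
shifted_features <- function(n_pd = 20, n_hog = 20, shift_sd = 0, seed = 1) {
  set.seed(seed)
  n <- n_pd + n_hog
  grp <- factor(rep(c("PD", "HOG"), c(n_pd, n_hog)), levels = c("PD", "HOG"))
  sl <- rnorm(n, 0.37, 0.03) - ifelse(grp == "PD", shift_sd * 0.03, 0)
  st <- rnorm(n, 0.55, 0.03)
  data.frame(subject_id = sprintf("F%03d", seq_len(n)),
             step_time_s = st, stride_time_s = 2 * st, step_length_m = sl,
             stride_length_m = 2 * sl, walking_speed_mps = sl / st,
             group = grp)
}
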