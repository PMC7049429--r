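#' Extended inverted-pendulum configuration
#'
#' Geometry of the step-length model: during a step the knee-worn sensor
#' vaults over the stance foot like an inverted pendulum of effective length
#' `W_h` (sensor height above ground), and the chord length spanned for a
#' vertical excursion `H` is scaled by a dimensionless factor `K_I` that maps
#' the sensor's excursion to the centre-of-mass geometry. The protocol fixes
#' `W_h = 0.34` m, with `K_I = 4` chosen correspondingly.
#'
#' @param W_h sensor height above ground in metres.
#' @param K_I dimensionless mapping factor.
#' @return An object of class `pendulum_config`.
#' @export
pendulum_config <- function(W_h = 0.34, K_I = 4) {
  if (W_h <= 0 || K_I <= 0) {
    stop("parameter error: W_h and K_I must be positive", call. = FALSE)
  }
  structure(list(W_h = W_h, K_I = K_I), class = "pendulum_config")
}

#' Step times from initial contacts
#'
#' Consecutive initial contacts at a knee-worn sensor are alternating-foot
#' heel strikes, so `step_time[i] = IC[i+1] - IC[i]`.
#'
#' @param ev a [gait_events()] with at least 2 initial contacts.
#' @return Numeric vector of step times in seconds, length `|IC| - 1`.
#' @export
step_times <- function(ev) {
  ic <- if (inherits(ev, "gait_events")) ev$ic_times else as.numeric(ev)
  if (length(ic) < 2L) {
    stop("insufficient-events error: need at least 2 initial contacts",
         call. = FALSE)
  }
  diff(ic)
}

#' Stride times from initial contacts
#'
#' `stride_time[i] = IC[i+2] - IC[i]`: the interval between successive
#' same-foot contacts, identically the sum of two adjacent step times.
#'
#' @param ev a [gait_events()] with at least 3 initial contacts.
#' @return Numeric vector of stride times in seconds, length `|IC| - 2`.
#' @export
stride_times <- function(ev) {
  ic <- if (inherits(ev, "gait_events")) ev$ic_times else as.numeric(ev)
  if (length(ic) < 3L) {
    stop("insufficient-events error: need at least 3 initial contacts",
         call. = FALSE)
  }
  ic[-(1:2)] - ic[seq_len(length(ic) - 2L)]
}

#' Vertical excursion of the sensor between two initial contacts
#'
#' Double-integrates the vertical acceleration over `[ic_start, ic_end]`,
#' resetting the integration constants to zero at `ic_start` and removing the
#' least-squares line from the displacement segment (drift control for the
#' unconstrained double integration of noisy acceleration). Returns
#' `max - min` of the resulting displacement.
#'
#' @param v a `vertical_signal`.
#' @param ic_start,ic_end window bounds in seconds, inside the recording.
#' @return The excursion `H` in metres (non-negative).
#' @export
vertical_excursion <- function(v, ic_start, ic_end) {
  stopifnot(inherits(v, "vertical_signal"))
  if (ic_start >= ic_end) {
    stop("parameter error: ic_start must precede ic_end", call. = FALSE)
  }
  sel <- which(v$t >= ic_start & v$t <= ic_end)
  if (length(sel) < 3L) {
    stop("insufficient-data error: excursion window shorter than 3 samples",
         call. = FALSE)
  }
  tt <- v$t[sel]
  # over a complete IC-to-IC arc the mean vertical acceleration vanishes
  # (the sensor's vertical velocity is zero at both heel strikes); any
  # residual segment mean reflects gravity-estimate bias and would grow
  # quadratically under double integration, so it is removed first
  a_seg <- v$a_v[sel] - mean(v$a_v[sel])
  vel <- pracma::cumtrapz(tt, a_seg)[, 1L]
  disp <- pracma::cumtrapz(tt, vel)[, 1L]
  disp <- lm.fit(cbind(1, tt), disp)$residuals
  max(disp) - min(disp)
}

#' Step length from vertical excursion (extended inverted-pendulum model)
#'
#' `step_length = K_I * 2 * sqrt(2 * W_h * H - H^2)`: twice the chord
#' traversed by a pendulum of length `W_h` dropping by `H`, scaled by `K_I`.
#' Monotone increasing in `H` on `[0, W_h]`.
#'
#' @param H vertical excursion in metres, in `[0, 2 * W_h]`.
#' @param cfg a [pendulum_config()].
#' @return Step length in metres.
#' @export
step_length <- function(H, cfg = pendulum_config()) {
  stopifnot(inherits(cfg, "pendulum_config"))
  if (any(H < 0 | H > 2 * cfg$W_h)) {
    stop("domain error: H must lie in [0, 2 * W_h] (negative radicand)",
         call. = FALSE)
  }
  cfg$K_I * 2 * sqrt(2 * cfg$W_h * H - H^2)
}

#' Summarize a recording into the five gait characteristics
#'
#' Builds one step record per consecutive initial-contact pair (step time and
#' vertical excursion, hence step length), then aggregates: `step_time_s` and
#' `step_length_m` are arithmetic means over steps,
#' `stride_time_s` the mean of [stride_times()],
#' `stride_length_m = 2 * step_length_m` exactly, and
#' `walking_speed_mps = step_length_m / step_time_s` exactly (ratio of
#' means).
#'
#' @param ev a [gait_events()] with at least 3 initial contacts.
#' @param v the `vertical_signal` the events were detected from.
#' @param cfg a [pendulum_config()].
#' @return An object of class `gait_parameters`: list with `subject_id`,
#'   `leg`, the five parameters, `n_steps` and a `per_step` data.frame
#'   (`ic_start`, `ic_end`, `step_time`, `H`, `step_length`).
#' @export
summarize_gait <- function(ev, v, cfg = pendulum_config()) {
  stopifnot(inherits(ev, "gait_events"))
  ic <- ev$ic_times
  if (length(ic) < 3L) {
    stop("insufficient-events error: need at least 3 initial contacts ",
         "(stride undefined)", call. = FALSE)
  }
  st <- step_times(ev)
  H <- vapply(seq_len(length(ic) - 1L), function(i) {
    vertical_excursion(v, ic[i], ic[i + 1L])
  }, numeric(1))
  sl <- step_length(H, cfg)
  per_step <- data.frame(index = seq_along(st), ic_start = ic[-length(ic)],
                         ic_end = ic[-1L], step_time = st, H = H,
                         step_length = sl)
  mean_st <- mean(st)
  mean_sl <- mean(sl)
  structure(
    list(subject_id = ev$subject_id, leg = ev$leg,
         step_time_s = mean_st,
         stride_time_s = mean(stride_times(ev)),
         step_length_m = mean_sl,
         stride_length_m = 2 * mean_sl,
         walking_speed_mps = mean_sl / mean_st,
         n_steps = length(st), per_step = per_step,
         config = unclass(cfg)),
    class = "gait_parameters"
  )
}

#' @export
print.gait_parameters <- function(x, ...) {
  cat(sprintf("<gait_parameters> subject %s, %s leg (%d steps)\n",
              x$subject_id, x$leg, x$n_steps))
  cat(sprintf("  step time %.3f s, stride time %.3f s, step length %.3f m,\n",
              x$step_time_s, x$stride_time_s, x$step_length_m))
  cat(sprintf("  stride length %.3f m, walking speed %.3f m/s\n",
              x$stride_length_m, x$walking_speed_mps))
  invisible(x)
}

#' @export
as.data.frame.gait_parameters <- function(x, ...) {
  data.frame(subject_id = x$subject_id, leg = x$leg,
             step_time_s = x$step_time_s, stride_time_s = x$stride_time_s,
             step_length_m = x$step_length_m,
             stride_length_m = x$stride_length_m,
             walking_speed_mps = x$walking_speed_mps, n_steps = x$n_steps)
}

#' Full per-recording estimation chain
#'
#' Convenience wrapper running the whole pipeline on a raw recording:
#' [tilt_correct()] then [extract_vertical()] then [detect_ics()] then
#' [summarize_gait()].
#'
#' @param rec a [triaxial_recording()].
#' @param filter a [filter_spec()].
#' @param cfg a [pendulum_config()].
#' @param scale,refractory,prominence detection settings, see [detect_ics()].
#' @return A `gait_parameters` object.
#' @export
estimate_gait <- function(rec, filter = filter_spec(),
                          cfg = pendulum_config(), scale = NULL,
                          refractory = 0.25, prominence = 0.1) {
  v <- extract_vertical(tilt_correct(rec), filter)
  ev <- detect_ics(v, scale = scale, refractory = refractory,
                   prominence = prominence)
  summarize_gait(ev, v, cfg)
}
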