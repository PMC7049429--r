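#' Gait events container
#'
#' Ordered initial-contact (heel-strike) times detected from one recording.
#'
#' @param subject_id,leg identity of the source recording.
#' @param ic_times strictly increasing event times in seconds.
#' @param method_params list of detection settings (CWT scale, refractory
#'   period, prominence threshold); free-form for truth annotations.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(subject_id, leg, ic_times, method_params = list()) {
  ic_times <- as.numeric(ic_times)
  if (length(ic_times) > 1L && any(diff(ic_times) <= 0)) {
    stop("validation error: ic_times must be strictly increasing",
         call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), leg = leg,
                 ic_times = ic_times, method_params = method_params),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> subject %s, %s leg: %d initial contacts\n",
              x$subject_id, x$leg, length(x$ic_times)))
  invisible(x)
}

#' Integrate the vertical acceleration to a drift-free velocity
#'
#' Cumulative trapezoidal integration of the filtered vertical acceleration,
#' followed by removal of the least-squares line so the velocity series is
#' free of linear drift (integration of any residual bias).
#'
#' @param v a `vertical_signal` (see [extract_vertical()]).
#' @return Numeric vector of vertical velocity in m/s, same length as the
#'   input.
#' @export
integrate_signal <- function(v) {
  stopifnot(inherits(v, "vertical_signal"))
  n <- length(v$a_v)
  if (n < 3L) {
    stop("insufficient-data error: need at least 3 samples to integrate",
         call. = FALSE)
  }
  vel <- pracma::cumtrapz(v$t, v$a_v)[, 1L]
  fit <- lm.fit(cbind(1, v$t), vel)
  as.numeric(fit$residuals)
}

# Correlation of x with a first-derivative-of-Gaussian wavelet at the given
# scale (in samples): psi(u) = -u * exp(-u^2 / 2), the literal derivative of
# the standard Gaussian. The output approximates the *negative* smoothed
# first derivative of x, so maxima of dx/dt appear as minima of the
# transform. Edges are handled by reflection padding; output length equals
# input length.
cwt_gaus1 <- function(x, scale) {
  if (scale <= 0) stop("parameter error: scale must be positive", call. = FALSE)
  m <- max(2L, ceiling(4 * scale))
  u <- (-m:m) / scale
  k <- -u * exp(-u^2 / 2)
  k <- k / sqrt(sum(k^2))
  n <- length(x)
  left <- x[pmin(m, n - 1):1 + 1]          # reflected head
  right <- x[n - (1:pmin(m, n - 1))]       # reflected tail
  # degenerate very-short inputs: pad with endpoint values
  if (length(left) < m) left <- c(rep(x[1], m - length(left)), left)
  if (length(right) < m) right <- c(right, rep(x[n], m - length(right)))
  xp <- c(left, x, right)
  w <- stats::filter(xp, rev(k), method = "convolution", sides = 2)
  as.numeric(w[(m + 1):(m + n)])
}

#' Detect initial contacts from the vertical signal
#'
#' The filtered vertical acceleration is integrated ([integrate_signal()]),
#' the velocity series is differentiated by a continuous wavelet transform
#' with a first-derivative-of-Gaussian wavelet at a single scale, and initial
#' contacts are read off as local minima of the transformed series (the
#' heel-strike acceleration peak maps to a transform minimum under the
#' wavelet's sign convention). Minima closer together than the refractory
#' period are merged keeping the deeper one; shallow minima below the
#' prominence threshold are discarded; events within half a refractory period
#' of either recording boundary are dropped.
#'
#' @param v a `vertical_signal`.
#' @param scale CWT scale in samples; default `fs / 10` (a smoothing window
#'   on the step-frequency timescale).
#' @param refractory minimum inter-event gap in seconds (default 0.25 s, the
#'   shortest plausible step time).
#' @param prominence minimum minimum-depth, as a fraction of the transformed
#'   series' RMS (default 0.1).
#' @return A [gait_events()] object. If no events survive, a zero-length
#'   event set is returned with a warning.
#' @export
detect_ics <- function(v, scale = NULL, refractory = 0.25, prominence = 0.1) {
  stopifnot(inherits(v, "vertical_signal"))
  if (refractory <= 0) {
    stop("parameter error: refractory must be positive", call. = FALSE)
  }
  n <- length(v$a_v)
  dur <- v$t[n] - v$t[1L]
  if (n < 8L || dur < 2 * refractory) {
    stop("insufficient-data error: signal too short for event detection",
         call. = FALSE)
  }
  if (is.null(scale)) scale <- v$fs / 10
  vel <- integrate_signal(v)
  w <- cwt_gaus1(vel, scale)

  params <- list(scale = scale, refractory = refractory,
                 prominence = prominence)
  rms <- sqrt(mean(w^2))
  i <- 2:(n - 1)
  is_min <- w[i] < w[i - 1] & w[i] <= w[i + 1] & w[i] < 0 &
    (-w[i]) >= prominence * rms
  cand <- i[is_min]
  if (length(cand) > 0L) {
    # merge within the refractory period, deepest minimum wins
    ord <- cand[order(w[cand])]
    accepted <- numeric(0)
    for (idx in ord) {
      ti <- v$t[idx]
      if (all(abs(accepted - ti) >= refractory)) accepted <- c(accepted, ti)
    }
    ic <- sort(accepted)
    # edge policy
    ic <- ic[ic >= v$t[1L] + refractory / 2 & ic <= v$t[n] - refractory / 2]
  } else {
    ic <- numeric(0)
  }
  if (length(ic) == 0L) {
    warning("no initial contacts detected", call. = FALSE)
    ev <- gait_events(v$subject_id, v$leg, numeric(0), params)
    attr(ev, "empty") <- TRUE
    return(ev)
  }
  gait_events(v$subject_id, v$leg, ic, params)
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one nearest-neighbour matching within a time tolerance;
#' candidate pairs are accepted in order of increasing absolute timing error.
#' `hits + misses = |truth|` and `hits + false_alarms = |detected|`.
#'
#' @param detected,truth [gait_events()] objects (or numeric time vectors).
#' @param tol_s matching tolerance in seconds, positive.
#' @return List with `hits`, `misses`, `false_alarms` (counts) and `errors_s`
#'   (signed detected-minus-truth timing error per hit).
#' @export
match_events <- function(detected, truth, tol_s) {
  if (tol_s <= 0) stop("parameter error: tol_s must be positive", call. = FALSE)
  dt <- if (inherits(detected, "gait_events")) detected$ic_times else
    as.numeric(detected)
  tt <- if (inherits(truth, "gait_events")) truth$ic_times else
    as.numeric(truth)
  if (length(dt) == 0L || length(tt) == 0L) {
    return(list(hits = 0L, misses = length(tt), false_alarms = length(dt),
                errors_s = numeric(0)))
  }
  pairs <- expand.grid(d = seq_along(dt), t = seq_along(tt))
  pairs$err <- dt[pairs$d] - tt[pairs$t]
  # tolerance boundary made float-safe (inclusive at tol_s)
  pairs <- pairs[abs(pairs$err) <= tol_s * (1 + 1e-9) + 1e-12, , drop = FALSE]
  pairs <- pairs[order(abs(pairs$err)), , drop = FALSE]
  used_d <- logical(length(dt)); used_t <- logical(length(tt))
  errors <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    di <- pairs$d[r]; ti <- pairs$t[r]
    if (!used_d[di] && !used_t[ti]) {
      used_d[di] <- TRUE; used_t[ti] <- TRUE
      errors <- c(errors, pairs$err[r])
    }
  }
  hits <- sum(used_t)
  list(hits = hits, misses = length(tt) - hits,
       false_alarms = length(dt) - hits, errors_s = errors)
}

#' Write gait events to CSV
#'
#' Columns `subject_id,leg,ic_index,ic_time_s`.
#'
#' @param ev a [gait_events()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(ev, path) {
  stopifnot(inherits(ev, "gait_events"))
  df <- data.frame(subject_id = ev$subject_id, leg = ev$leg,
                   ic_index = seq_along(ev$ic_times),
                   ic_time_s = ev$ic_times)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
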