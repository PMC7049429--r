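#' Low-pass filter specification
#'
#' Butterworth low-pass settings applied to the vertical acceleration before
#' event detection. Defaults follow the device protocol: 4th order, 15 Hz
#' cutoff, applied forward-backward (zero phase) so event timings are not
#' delayed.
#'
#' @param order filter order.
#' @param cutoff_hz cutoff frequency in Hz; must stay below the Nyquist
#'   frequency of the recording it is applied to.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 15) {
  if (order < 1 || cutoff_hz <= 0) {
    stop("filter-spec error: order and cutoff_hz must be positive",
         call. = FALSE)
  }
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 kind = "low-pass Butterworth", phase = "zero-phase"),
            class = "filter_spec")
}

#' Dynamic tilt correction
#'
#' Rotates a recording into a gravity-referenced frame so the time-averaged
#' AP and ML accelerations vanish and the averaged vertical component carries
#' the full measured gravity magnitude. The correction applies two successive
#' planar rotations with angles `theta_ap = asin(mean(ap) / |mean acc|)` in
#' the AP-V plane and the analogous `theta_ml` in the ML-V plane, which
#' compensates a static sensor tilt on the knee mount.
#'
#' @param rec a [triaxial_recording()] with the sensor roughly upright
#'   (positive mean vertical acceleration).
#' @return The rotated [triaxial_recording()]; the applied angles (degrees)
#'   are stored in `attr(, "tilt_deg")`.
#' @export
tilt_correct <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  m <- c(ml = mean(rec$acc_ml), ap = mean(rec$acc_ap), v = mean(rec$acc_v))
  gmag <- sqrt(sum(m^2))
  if (gmag <= 0 || m[["v"]] <= 0) {
    stop("orientation error: mean vertical acceleration must be positive ",
         "(sensor inverted or no gravity reference)", call. = FALSE)
  }
  # AP-V plane rotation nulls the mean AP component exactly; atan2 of the
  # channel means equals asin(mean_ap / |mean acc|) for a pure AP tilt and
  # still nulls the mean when both tilts are present
  theta_ap <- atan2(m[["ap"]], m[["v"]])
  ap1 <- rec$acc_ap * cos(theta_ap) - rec$acc_v * sin(theta_ap)
  v1 <- rec$acc_ap * sin(theta_ap) + rec$acc_v * cos(theta_ap)
  # ML-V plane rotation nulls the mean ML component (AP is untouched here)
  theta_ml <- atan2(m[["ml"]], mean(v1))
  ml2 <- rec$acc_ml * cos(theta_ml) - v1 * sin(theta_ml)
  v2 <- rec$acc_ml * sin(theta_ml) + v1 * cos(theta_ml)
  out <- triaxial_recording(rec$subject_id, rec$leg, rec$t,
                            acc_ml = ml2, acc_ap = ap1, acc_v = v2,
                            fs = rec$fs)
  attr(out, "tilt_deg") <- c(ap = theta_ap, ml = theta_ml) * 180 / pi
  out
}

#' Extract the gravity-free filtered vertical acceleration
#'
#' Subtracts the recording-mean vertical value (the gravity estimate of the
#' tilt-corrected recording), converts g to m/s^2, and applies the zero-phase
#' Butterworth low-pass of `spec`. The result is the signal used for gait
#' event identification.
#'
#' @param rec a tilt-corrected [triaxial_recording()].
#' @param spec a [filter_spec()].
#' @return An object of class `vertical_signal`: list with `subject_id`,
#'   `leg`, `fs`, `t`, `a_v` (m/s^2, zero mean) and `provenance`.
#' @export
extract_vertical <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (!inherits(spec, "filter_spec")) stop("filter-spec error: need a filter_spec",
                                           call. = FALSE)
  if (spec$cutoff_hz >= rec$fs / 2) {
    stop("filter-spec error: cutoff must be below the Nyquist frequency ",
         sprintf("(%.3g >= %.3g Hz)", spec$cutoff_hz, rec$fs / 2),
         call. = FALSE)
  }
  gravity_g <- mean(rec$acc_v)
  a <- (rec$acc_v - gravity_g) * G_MS2
  bf <- signal::butter(spec$order, spec$cutoff_hz / (rec$fs / 2), type = "low")
  y <- signal::filtfilt(bf, a)
  y <- y - mean(y)
  structure(
    list(subject_id = rec$subject_id, leg = rec$leg, fs = rec$fs, t = rec$t,
         a_v = as.numeric(y),
         provenance = list(gravity_g = gravity_g,
                           tilt_deg = attr(rec, "tilt_deg"),
                           filter = unclass(spec),
                           order_of_ops = c("gravity subtraction",
                                            "g to m/s^2", "low-pass"))),
    class = "vertical_signal"
  )
}

#' @export
print.vertical_signal <- function(x, ...) {
  cat(sprintf("<vertical_signal> subject %s, %s leg: %d samples @ %.3f Hz\n",
              x$subject_id, x$leg, length(x$a_v), x$fs))
  cat(sprintf("  gravity estimate %.4f g, filter %s order %d @ %g Hz\n",
              x$provenance$gravity_g, x$provenance$filter$kind,
              x$provenance$filter$order, x$provenance$filter$cutoff_hz))
  invisible(x)
}
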