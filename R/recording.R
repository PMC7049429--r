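#' Construct a triaxial accelerometer recording
#'
#' Container for one subject-leg recording from a knee-worn triaxial
#' accelerometer. Axes follow the device convention: X = medial-lateral (ML),
#' Y = anterior-posterior (AP), Z = vertical (V). Acceleration is stored in g
#' (sensor native unit, full scale +/- 8 g); timestamps in seconds.
#'
#' @param subject_id subject identifier.
#' @param leg `"left"` or `"right"`.
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param acc_ml,acc_ap,acc_v acceleration channels in g, same length as `t`.
#' @param fs sampling rate in Hz; if `NULL`, inferred as the reciprocal of the
#'   median timestamp spacing.
#' @return An object of class `triaxial_recording`: a list with elements
#'   `subject_id`, `leg`, `fs`, `t0`, `t`, `acc_ml`, `acc_ap`, `acc_v`,
#'   `n_samples`.
#' @examples
#' t <- seq(0, 1, by = 1 / 32)
#' rec <- triaxial_recording("s1", "left", t,
#'                           acc_ml = rep(0, length(t)),
#'                           acc_ap = rep(0, length(t)),
#'                           acc_v = rep(1, length(t)))
#' rec$fs
#' @export
triaxial_recording <- function(subject_id, leg = c("left", "right"), t,
                               acc_ml, acc_ap, acc_v, fs = NULL) {
  leg <- match.arg(leg)
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2L) {
    stop("empty-input error: a recording needs at least 2 samples", call. = FALSE)
  }
  if (length(acc_ml) != n || length(acc_ap) != n || length(acc_v) != n) {
    stop("format error: all three channels must have the same length as t",
         call. = FALSE)
  }
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    stop("format error: timestamps must be finite and strictly increasing",
         call. = FALSE)
  }
  acc <- cbind(ml = as.numeric(acc_ml), ap = as.numeric(acc_ap),
               v = as.numeric(acc_v))
  if (any(!is.finite(acc))) {
    stop("format error: non-finite acceleration values", call. = FALSE)
  }
  if (any(abs(acc) > ACC_RANGE_G)) {
    stop("range error: acceleration exceeds the +/-8 g sensor range",
         call. = FALSE)
  }
  if (is.null(fs)) fs <- 1 / median(diff(t))
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) {
    stop("format error: sampling rate must be positive", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), leg = leg, fs = fs,
         t0 = t[1L], t = t, acc_ml = acc[, "ml"], acc_ap = acc[, "ap"],
         acc_v = acc[, "v"], n_samples = n),
    class = "triaxial_recording"
  )
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> subject %s, %s leg\n", x$subject_id, x$leg))
  cat(sprintf("  %d samples @ %.3f Hz (%.2f s), acceleration in g\n",
              x$n_samples, x$fs, x$t[x$n_samples] - x$t0))
  invisible(x)
}

#' Read a recording from CSV
#'
#' Expects the dialect `t,acc_ml,acc_ap,acc_v` (header row, seconds and g,
#' `.` decimal separator, UTF-8). One file per subject per leg, named
#' `<subject>_<leg>.csv`; subject id and leg are taken from the filename when
#' it follows that convention.
#'
#' @param path CSV file path.
#' @param fs_override optional sampling rate in Hz replacing the inferred one.
#' @param subject_id,leg override the filename-derived identity.
#' @return A [triaxial_recording()].
#' @export
read_recording <- function(path, fs_override = NULL, subject_id = NULL,
                           leg = NULL) {
  if (!file.exists(path)) {
    stop("format error: file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "acc_ml", "acc_ap", "acc_v")
  if (!all(need %in% names(df))) {
    stop("format error: recording CSV must have columns t,acc_ml,acc_ap,acc_v",
         call. = FALSE)
  }
  base <- sub("\\.csv$", "", basename(path))
  if (is.null(leg)) {
    leg <- if (grepl("_(left|right)$", base)) sub("^.*_", "", base) else "left"
  }
  if (is.null(subject_id)) subject_id <- sub("_(left|right)$", "", base)
  triaxial_recording(subject_id, leg, df$t, df$acc_ml, df$acc_ap, df$acc_v,
                     fs = fs_override)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]; full double precision is written so a
#' write/read round trip is lossless well beyond 6 decimals.
#'
#' @param rec a [triaxial_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "triaxial_recording"))
  df <- data.frame(t = rec$t, acc_ml = rec$acc_ml, acc_ap = rec$acc_ap,
                   acc_v = rec$acc_v)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
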