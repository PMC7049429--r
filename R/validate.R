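#' Percentage error rate against a reference value
#'
#' `|estimated - reference| / reference * 100`: the absolute percentage
#' deviation of an accelerometer estimate from the reference (e.g. 3D
#' motion-capture) value. Scale-invariant: multiplying both arguments by the
#' same positive constant leaves it unchanged.
#'
#' @param estimated,reference numeric vectors (recycled); `reference` must be
#'   strictly positive.
#' @return Percentage error(s), non-negative.
#' @examples
#' error_rate(0.34, 0.37)  # 8.108
#' @export
error_rate <- function(estimated, reference) {
  if (any(reference <= 0)) {
    stop("domain error: reference values must be positive", call. = FALSE)
  }
  abs(estimated - reference) / reference * 100
}

#' Pearson correlation with significance
#'
#' Product-moment correlation with a two-sided p-value from the t
#' distribution on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors, equal length `n >= 3`, non-constant.
#' @return List with `r`, `p_value` and `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) {
    stop("parameter error: x and y must have equal length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("parameter error: need at least 3 complete pairs", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined-correlation error: constant input", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Validate estimated gait parameters against a reference table
#'
#' Joins the algorithm's parameter table with a reference table on
#' `subject_id` and `leg` and produces, for each of the five gait
#' characteristics and each leg, the per-subject percentage errors
#' ([error_rate()]), their mean and standard deviation, and the Pearson
#' correlation between the paired columns.
#'
#' @param alg data.frame of estimates with columns `subject_id`, `leg` and
#'   the five parameter columns (see [gait_parameter_names()]).
#' @param ref reference data.frame with the same columns (e.g. from
#'   [read_reference_table()]).
#' @return Data.frame with one row per parameter x leg: `parameter`, `leg`,
#'   `n`, `mean_error_pct`, `sd_error_pct`, `pearson_r`, `p_value`.
#' @export
validation_report <- function(alg, ref) {
  pars <- gait_parameter_names()
  need <- c("subject_id", "leg", pars)
  if (!all(need %in% names(alg)) || !all(need %in% names(ref))) {
    stop("format error: both tables need subject_id, leg and the five ",
         "parameter columns", call. = FALSE)
  }
  joined <- merge(alg, ref, by = c("subject_id", "leg"),
                  suffixes = c("_alg", "_ref"))
  if (nrow(joined) == 0L) {
    stop("no-overlap error: tables share no subject_id/leg pairs",
         call. = FALSE)
  }
  out <- list()
  for (leg in unique(joined$leg)) {
    sub <- joined[joined$leg == leg, , drop = FALSE]
    for (p in pars) {
      est <- sub[[paste0(p, "_alg")]]
      rf <- sub[[paste0(p, "_ref")]]
      err <- error_rate(est, rf)
      r <- NA_real_; pv <- NA_real_
      if (nrow(sub) >= 3L && sd(est) > 0 && sd(rf) > 0) {
        ct <- correlate(est, rf)
        r <- ct$r; pv <- ct$p_value
      }
      out[[length(out) + 1L]] <- data.frame(
        parameter = p, leg = leg, n = nrow(sub),
        mean_error_pct = mean(err), sd_error_pct = sd(err),
        pearson_r = r, p_value = pv)
    }
  }
  do.call(rbind, out)
}
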