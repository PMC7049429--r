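#' Read a subject metadata table
#'
#' Reads one row per subject with the cohort metadata used for grouping and
#' reporting. Required columns: `subject_id`, `group` (one of `PD`, `HOG`).
#' Optional columns: `sex` (`M`/`F`), `age`, `updrs3`, `hy_stage`,
#' `disease_duration` (months), `tug` (s), `tinetti_gait` (0-12). Healthy
#' older group (HOG) subjects must have `updrs3 = 0` and
#' `disease_duration = 0`.
#'
#' @param path CSV file path.
#' @return A data.frame with one validated row per subject; `group` is a
#'   factor with levels `PD`, `HOG`.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) {
    stop("format error: file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_subject_table(df)
}

#' Validate a subject table
#'
#' @param df data.frame with the columns documented in [read_subject_table()].
#' @return The validated data.frame (possibly zero rows).
#' @export
validate_subject_table <- function(df) {
  need <- c("subject_id", "group")
  if (!all(need %in% names(df))) {
    stop("format error: subject table needs columns subject_id and group",
         call. = FALSE)
  }
  optional <- c("sex", "age", "updrs3", "hy_stage", "disease_duration",
                "tug", "tinetti_gait")
  for (col in optional) if (!col %in% names(df)) df[[col]] <- rep(NA, nrow(df))
  if (nrow(df) == 0L) {
    df$group <- factor(df$group, levels = c("PD", "HOG"))
    return(df)
  }
  if (!all(df$group %in% c("PD", "HOG"))) {
    stop("validation error: unknown group label (expected PD or HOG)",
         call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("validation error: duplicated subject_id", call. = FALSE)
  }
  hog <- df$group == "HOG"
  bad_updrs <- hog & !is.na(df$updrs3) & df$updrs3 != 0
  bad_dur <- hog & !is.na(df$disease_duration) & df$disease_duration != 0
  if (any(bad_updrs | bad_dur)) {
    stop("validation error: HOG subjects must have updrs3 = 0 and ",
         "disease_duration = 0", call. = FALSE)
  }
  if (any(!is.na(df$updrs3) & df$updrs3 < 0)) {
    stop("validation error: updrs3 must be >= 0", call. = FALSE)
  }
  tg <- df$tinetti_gait
  if (any(!is.na(tg) & (tg < 0 | tg > 12))) {
    stop("validation error: tinetti_gait must lie in 0..12", call. = FALSE)
  }
  hy <- df$hy_stage
  if (any(!is.na(hy) & (hy < 0 | hy > 5 | (hy * 2) %% 1 != 0))) {
    stop("validation error: hy_stage must lie in 0..5 in steps of 0.5",
         call. = FALSE)
  }
  df$group <- factor(df$group, levels = c("PD", "HOG"))
  df
}

#' Read a reference gait-parameter table
#'
#' Per-subject, per-leg gait parameters exported from an external reference
#' system (e.g. a 3D motion-capture system), used to validate the
#' accelerometer estimates. Columns: `subject_id`, `leg`, `step_time_s`,
#' `stride_time_s`, `step_length_m`, `stride_length_m`, `walking_speed_mps`;
#' all parameter values must be positive where present.
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) {
    stop("format error: file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "leg", gait_parameter_names())
  if (!all(need %in% names(df))) {
    stop("format error: reference table must have columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  vals <- as.matrix(df[gait_parameter_names()])
  if (any(!is.na(vals) & vals <= 0)) {
    stop("validation error: reference parameter values must be positive",
         call. = FALSE)
  }
  df
}

#' Names of the five gait characteristics
#'
#' @return Character vector of the five parameter column names used across
#'   the package's tables.
#' @export
gait_parameter_names <- function() {
  c("step_time_s", "stride_time_s", "step_length_m", "stride_length_m",
    "walking_speed_mps")
}
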