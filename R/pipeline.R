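#' Estimate gait parameters for every recording of a cohort
#'
#' Runs the full per-recording chain ([estimate_gait()]) over a simulated
#' cohort, a named list of recordings, or a directory of recording CSVs
#' (files named `<subject>_<leg>.csv`). Per-file failures are reported as
#' warnings and skipped; an error is raised only if every recording fails.
#'
#' @param x a `gait_cohort`, a list of [triaxial_recording()] /
#'   `annotated_walk` objects, or a directory path.
#' @param ... passed to [estimate_gait()].
#' @return Data.frame with one row per subject-leg: `subject_id`, `leg`, the
#'   five parameter columns and `n_steps`.
#' @export
estimate_cohort <- function(x, ...) {
  recs <- if (inherits(x, "gait_cohort")) {
    lapply(x$walks, function(w) w$recording)
  } else if (is.character(x) && length(x) == 1L) {
    files <- list.files(x, pattern = "_(left|right)\\.csv$", full.names = TRUE)
    if (length(files) == 0L) {
      stop("empty-input error: no recording CSVs found in ", x, call. = FALSE)
    }
    lapply(files, read_recording)
  } else if (is.list(x)) {
    lapply(x, function(r) if (inherits(r, "annotated_walk")) r$recording else r)
  } else {
    stop("format error: cannot interpret input as a cohort", call. = FALSE)
  }
  rows <- list()
  for (r in recs) {
    res <- tryCatch(as.data.frame(estimate_gait(r, ...)), error = function(e) {
      warning("skipping ", r$subject_id, " ", r$leg, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) {
    stop("data error: estimation failed for every recording", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a simulated cohort to disk
#'
#' Writes one recording CSV per subject-leg (`<subject>_<leg>.csv`), one
#' truth-event CSV per recording (`<subject>_<leg>_truth_events.csv`), an
#' aggregated `truth_params.csv`, the subject metadata table
#' (`subjects.csv`) and a small `manifest.csv` with the seed and separation
#' factor.
#'
#' @param cohort a `gait_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(cohort$walks)) {
    w <- cohort$walks[[key]]
    write_recording(w$recording, file.path(dir, paste0(key, ".csv")))
    write_events(w$truth_events,
                 file.path(dir, paste0(key, "_truth_events.csv")))
  }
  write.csv(cohort$truth, file.path(dir, "truth_params.csv"),
            row.names = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  write.csv(data.frame(seed = cohort$seed, separation = cohort$separation,
                       n_recordings = length(cohort$walks)),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
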