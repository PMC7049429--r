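#' Item maxima of the Tinetti mobility test (POMA)
#'
#' The balance section has 9 items whose maxima sum to 16; the gait section
#' has 8 items whose maxima sum to 12; every item is scored 0/1 or 0/1/2.
#' The per-item maxima follow the standard performance-oriented mobility
#' assessment instrument and are validated by those two section-sum
#' constraints.
#'
#' @return Named integer vector of per-item maxima for one section.
#' @export
tinetti_balance_maxima <- function() {
  c(sitting_balance = 1L, arises = 2L, attempts_to_arise = 2L,
    immediate_standing = 2L, standing_balance = 2L, nudge = 2L,
    eyes_closed = 1L, turning_360 = 2L, sitting_down = 2L)
}

#' @rdname tinetti_balance_maxima
#' @export
tinetti_gait_maxima <- function() {
  c(initiation = 1L, right_step_length_height = 2L,
    left_step_length_height = 2L, step_symmetry = 1L, step_continuity = 1L,
    path = 2L, trunk = 2L, walking_stance = 1L)
}

#' Fall-risk band from a Tinetti total score
#'
#' Totals of 18 or less indicate high fall risk, 19-23 moderate risk, and 24
#' or more low risk. A total partition of the 0-28 scale with no gaps;
#' monotone (a higher score never increases the risk band).
#'
#' @param total integer total score(s) in 0..28.
#' @return Character vector: `"high"`, `"moderate"` or `"low"`.
#' @examples
#' classify_risk(c(18, 19, 23, 24))
#' @export
classify_risk <- function(total) {
  if (any(!is.finite(total) | total %% 1 != 0 | total < 0 | total > 28)) {
    stop("validation error: total must be an integer in 0..28", call. = FALSE)
  }
  ifelse(total <= 18, "high", ifelse(total <= 23, "moderate", "low"))
}

#' Score a Tinetti mobility test form
#'
#' Sums the 9 balance and 8 gait item scores into section totals (maxima 16
#' and 12), a combined total (maximum 28) and the fall-risk band.
#'
#' @param balance_items numeric vector of 9 balance item scores, each within
#'   its item maximum (see [tinetti_balance_maxima()]).
#' @param gait_items numeric vector of 8 gait item scores.
#' @param subject_id optional identifier carried through.
#' @return An object of class `tinetti_form`: list with the item vectors,
#'   `balance_total`, `gait_total`, `total` and `risk`.
#' @examples
#' score_tinetti(tinetti_balance_maxima(), tinetti_gait_maxima())$total  # 28
#' @export
score_tinetti <- function(balance_items, gait_items, subject_id = NA_character_) {
  bmax <- tinetti_balance_maxima()
  gmax <- tinetti_gait_maxima()
  if (length(balance_items) != length(bmax)) {
    stop("shape error: expected ", length(bmax), " balance item scores",
         call. = FALSE)
  }
  if (length(gait_items) != length(gmax)) {
    stop("shape error: expected ", length(gmax), " gait item scores",
         call. = FALSE)
  }
  check_items <- function(x, mx, section) {
    if (any(!is.finite(x) | x %% 1 != 0 | x < 0 | x > mx)) {
      stop("validation error: ", section, " item score outside 0..max",
           call. = FALSE)
    }
  }
  check_items(balance_items, bmax, "balance")
  check_items(gait_items, gmax, "gait")
  bt <- as.integer(sum(balance_items))
  gt <- as.integer(sum(gait_items))
  structure(
    list(subject_id = subject_id,
         balance_items = stats::setNames(as.integer(balance_items), names(bmax)),
         gait_items = stats::setNames(as.integer(gait_items), names(gmax)),
         balance_total = bt, gait_total = gt, total = bt + gt,
         risk = classify_risk(bt + gt)),
    class = "tinetti_form"
  )
}

#' @export
print.tinetti_form <- function(x, ...) {
  cat(sprintf("<tinetti_form> subject %s: balance %d/16, gait %d/12, total %d/28 (%s fall risk)\n",
              x$subject_id, x$balance_total, x$gait_total, x$total, x$risk))
  invisible(x)
}

#' Score a CSV of Tinetti forms
#'
#' Input columns: `subject_id,b1..b9,g1..g8`; the output appends
#' `balance_total`, `gait_total`, `total` and `risk`.
#'
#' @param path input CSV path.
#' @return Data.frame with one scored row per subject.
#' @export
score_tinetti_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  bcols <- paste0("b", 1:9)
  gcols <- paste0("g", 1:8)
  if (!all(c("subject_id", bcols, gcols) %in% names(df))) {
    stop("format error: Tinetti CSV needs columns subject_id,b1..b9,g1..g8",
         call. = FALSE)
  }
  scored <- lapply(seq_len(nrow(df)), function(i) {
    f <- score_tinetti(as.numeric(df[i, bcols]), as.numeric(df[i, gcols]),
                       df$subject_id[i])
    data.frame(balance_total = f$balance_total, gait_total = f$gait_total,
               total = f$total, risk = f$risk)
  })
  cbind(df, do.call(rbind, scored))
}
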