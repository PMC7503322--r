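#' Exploration rate: unique cells visited per minute
#'
#' Sums the number of distinct cells visited per exploration phase
#' (counting the start cell) over the supplied phases and divides by the
#' total exploration time in minutes. Study 1's five 10-s phases divide by
#' 5/6 min; each study-2 block's five 5-s phases divide by 5/12 min.
#'
#' @param phases Phase-summary rows (from an `escape_test_record`), all
#'   with `phase == "explore"`.
#' @return Unique cells per minute.
#' @export
exploration_rate <- function(phases) {
  if (!nrow(phases)) stop("no exploration phases supplied", call. = FALSE)
  if (any(phases$phase != "explore")) {
    stop("exploration_rate() expects explore-phase records only",
         call. = FALSE)
  }
  sum(phases$n_unique) / (sum(phases$duration) / 60)
}

#' Number of successful escapes
#'
#' @param phases Phase-summary rows, all with `phase == "stress"`.
#' @return Count of stress phases ended by reaching a safe space.
#' @export
escape_count <- function(phases) {
  if (any(phases$phase != "stress")) {
    stop("escape_count() expects stress-phase records only", call. = FALSE)
  }
  sum(phases$escaped)
}

#' Escape efficiency: activity per minute per escape
#'
#' `(total moves / total stress time in minutes) / escapes`. Time is the
#' time actually spent in the stress phases (capped or ended early by an
#' escape); clamped edge presses count as moves. Higher values mean more
#' activity per successful escape, i.e. *less* efficient behaviour. With
#' zero escapes the quotient is undefined and returned as `NA`, which
#' propagates into downstream statistics as a missing value.
#'
#' @param phases Phase-summary rows, all with `phase == "stress"`.
#' @return Efficiency score, or `NA_real_` if there were no escapes.
#' @export
efficiency <- function(phases) {
  esc <- escape_count(phases)
  if (esc == 0L) return(NA_real_)
  (sum(phases$n_moves) / (sum(phases$duration) / 60)) / esc
}

#' Per-block behavioural metrics of an escape test
#'
#' @param record An [run_escape_test()] record.
#' @return Data frame with one row per block: `participant`, `block`,
#'   `exploration_per_min`, `unique_cells`, `escapes`, `moves_per_min`,
#'   `efficiency`.
#' @export
escape_metrics <- function(record) {
  stopifnot(inherits(record, "escape_test_record"))
  ph <- record$phases
  do.call(rbind, lapply(sort(unique(ph$block)), function(b) {
    ex <- ph[ph$block == b & ph$phase == "explore", ]
    st <- ph[ph$block == b & ph$phase == "stress", ]
    esc <- escape_count(st)
    data.frame(
      participant = record$participant_id,
      block = b,
      exploration_per_min = exploration_rate(ex),
      unique_cells = sum(ex$n_unique),
      escapes = esc,
      moves_per_min = sum(st$n_moves) / (sum(st$duration) / 60),
      efficiency = efficiency(st),
      stringsAsFactors = FALSE)
  }))
}

#' Mean cue-locked reaction time of a session
#'
#' Mean RT over trials with a press inside the response window; misses and
#' late presses are excluded. A session without a single in-window press
#' (a participant who "did not react to any cue") yields `NA` with
#' attribute `all_miss = TRUE` so it can be flagged and excluded rather
#' than crash downstream analyses.
#'
#' @param session A [simulate_session()] record.
#' @return Mean RT in seconds, or flagged `NA`.
#' @export
mean_rt <- function(session) {
  stopifnot(inherits(session, "session_record"))
  rt <- session$trials$rt
  ok <- !is.na(rt) & rt <= session$config$response_window
  if (!any(ok)) {
    return(structure(NA_real_, all_miss = TRUE))
  }
  mean(rt[ok])
}

#' Rate of correct responses in a study-2 EC session
#'
#' Fraction of trials answered with the correct button inside the response
#' window (misses and late presses count as incorrect).
#'
#' @param session A study-2 EC [simulate_session()] record.
#' @return Fraction in `[0, 1]`.
#' @export
correct_rate <- function(session) {
  stopifnot(inherits(session, "session_record"))
  if (session$study != 2L || session$condition != "EC") {
    stop("correct_rate() is defined for study-2 EC sessions only",
         call. = FALSE)
  }
  tr <- session$trials
  mean(!is.na(tr$rt) & tr$rt <= session$config$response_window & tr$correct)
}

#' Per-participant summary of the acute stress phase
#'
#' One row per session: mean RT (with all-miss flag), correct-response
#' rate (study-2 EC, else `NA`), the mean rating per item across probes,
#' and the pre/post affect scores.
#'
#' @param session A [simulate_session()] record.
#' @return One-row data frame.
#' @export
session_metrics <- function(session) {
  stopifnot(inherits(session, "session_record"))
  rt <- mean_rt(session)
  out <- data.frame(
    participant = session$participant_id,
    condition = session$condition,
    mean_rt = as.numeric(rt),
    all_miss = isTRUE(attr(rt, "all_miss")),
    correct_rate = if (session$study == 2L && session$condition == "EC") {
      correct_rate(session)
    } else NA_real_,
    stringsAsFactors = FALSE)
  for (it in unique(session$ratings$item)) {
    out[[paste0("rating_", it)]] <-
      mean(session$ratings$value[session$ratings$item == it])
  }
  for (i in seq_len(nrow(session$affect))) {
    out[[paste0(session$affect$score[i], "_pre")]] <- session$affect$pre[i]
    out[[paste0(session$affect$score[i], "_post")]] <- session$affect$post[i]
  }
  out
}
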