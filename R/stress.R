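#' Run one escapable-condition (EC) trial
#'
#' Applies the termination rule of the escapable condition. In study 1 any
#' press within the response window after cue onset terminates the
#' stressor; in study 2 the press must also be the correct button for the
#' trial's cue (looked up in `truth_map`). When the terminating condition
#' holds, `stress_duration = cue_onset + response_time`; otherwise
#' stimulation continues up to the trial's duration cap.
#'
#' @param template One-row trial template (a row of
#'   [build_trial_timeline()]): fields `trial`, `cue`, `cue_onset`,
#'   `max_duration`, `iti`.
#' @param response_time Seconds from cue onset, or `NA` for a miss.
#' @param button Button pressed, or `NA`.
#' @param config The [study_config()].
#' @param truth_map Named character vector cue -> correct button
#'   (required for study 2).
#' @return A one-row data frame (a trial record) with columns `trial`,
#'   `condition`, `cue`, `cue_onset`, `rt`, `button`, `correct`,
#'   `stress_duration`, `terminated`, `max_duration`, `iti`.
#' @examples
#' cfg <- study_config(1)
#' tl <- build_trial_timeline(cfg, 1)
#' run_ec_trial(tl[1, ], response_time = 0.4, button = "space", config = cfg)
#' @export
run_ec_trial <- function(template, response_time, button = NA_character_,
                         config, truth_map = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (!is.na(response_time) && response_time < 0) {
    stop("response_time must be >= 0 or NA", call. = FALSE)
  }
  if (config$study == 2L && is.null(truth_map)) {
    stop("study-2 EC trials require a `truth_map`", call. = FALSE)
  }
  in_window <- !is.na(response_time) &&
    response_time <= config$response_window
  correct <- if (config$study == 2L) {
    if (is.na(response_time) || is.na(button)) FALSE
    else identical(unname(truth_map[[template$cue]]), button)
  } else {
    # study 1: any press counts
    !is.na(response_time)
  }
  terminated <- if (config$study == 2L) in_window && correct else in_window
  stress <- if (terminated) template$cue_onset + response_time else
    template$max_duration
  trial_record(template, condition = "EC", rt = response_time,
               button = button, correct = correct,
               stress_duration = stress, terminated = terminated)
}

#' Run one yoked-condition (YC) trial
#'
#' The stress duration is fixed by the yoked schedule regardless of the
#' participant's response; responses are logged verbatim and never count
#' as terminating. The yoked duration must not exceed the trial's cap.
#'
#' @param template One-row trial template.
#' @param yoked_duration Predetermined stress duration (s).
#' @param yoked_onset Shifted cue onset (s from trial start).
#' @param response_time Seconds from (shifted) cue onset, or `NA`.
#' @param button Button pressed, or `NA`.
#' @return A one-row trial record data frame.
#' @export
run_yc_trial <- function(template, yoked_duration, yoked_onset,
                         response_time = NA_real_, button = NA_character_) {
  if (yoked_duration > template$max_duration + 1e-9) {
    stop(sprintf("yoked duration %.3f s exceeds the %.3f s cap of trial %d",
                 yoked_duration, template$max_duration, template$trial),
         call. = FALSE)
  }
  template$cue_onset <- yoked_onset
  trial_record(template, condition = "YC", rt = response_time,
               button = button, correct = NA,
               stress_duration = yoked_duration, terminated = FALSE)
}

run_cc_trial <- function(template, response_time, button = NA_character_) {
  # control condition mirrors EC timing with zero stimulation; a press
  # ends the trial early ("effectively shorten trials") which keeps RT
  # comparable but has no stress consequence
  trial_record(template, condition = "CC", rt = response_time,
               button = button, correct = NA,
               stress_duration = 0, terminated = FALSE)
}

trial_record <- function(template, condition, rt, button, correct,
                         stress_duration, terminated) {
  data.frame(
    trial = template$trial,
    condition = condition,
    cue = template$cue,
    cue_onset = template$cue_onset,
    rt = as.numeric(rt),
    button = as.character(button),
    correct = correct,
    stress_duration = as.numeric(stress_duration),
    terminated = terminated,
    max_duration = template$max_duration,
    iti = template$iti,
    stringsAsFactors = FALSE
  )
}

sample_yc_onsets <- function(durations, seed) {
  # cue onset uniform in [duration - 4, duration - 1]: the yoked cue is
  # shifted so that stimulation outlasts the cue by 1-4 s regardless of
  # the response; onsets are clipped at 0 (never triggered for the
  # paradigm's durations, which exceed 4 s)
  with_seed(seed, pmax(0, stats::runif(length(durations),
                                       durations - 4, durations - 1)))
}

#' Derive a one-to-one yoked schedule from an EC session (study 1)
#'
#' Copies the EC participant's per-trial stress durations verbatim —
#' yoking conserves stress exposure exactly — and samples the shifted cue
#' onset for each trial uniformly from `[duration - 4, duration - 1]`
#' seconds, so the yoked participant's stimulation continues 1-4 s past
#' their cue regardless of how fast they respond.
#'
#' @param ec_session A study-1 EC [simulate_session()] record.
#' @param seed Integer seed for the onset draws.
#' @return A data frame of class `yoked_schedule` with columns `trial`,
#'   `duration`, `cue_onset`; attributes `provenance = "one_to_one"` and
#'   `source_ids`.
#' @export
derive_yoked_schedule <- function(ec_session, seed) {
  stopifnot(inherits(ec_session, "session_record"))
  if (ec_session$condition != "EC") {
    stop("yoked schedules are derived from EC sessions only", call. = FALSE)
  }
  durations <- ec_session$trials$stress_duration
  sched <- data.frame(
    trial = ec_session$trials$trial,
    duration = durations,
    cue_onset = sample_yc_onsets(durations, seed)
  )
  structure(sched, class = c("yoked_schedule", "data.frame"),
            provenance = "one_to_one",
            source_ids = ec_session$participant_id)
}

#' Derive a pseudo-yoked schedule from a pool of EC sessions (study 2)
#'
#' Computes the per-trial-index mean stress duration across the supplied
#' EC sessions and assigns those means to trials in a seeded random
#' permutation, so the yoked group receives the same total exposure while
#' individual durations appear arbitrary. The permutation is
#' cap-constrained: positions are filled in increasing order of their
#' duration cap, choosing uniformly among the remaining mean durations
#' that fit, so the output is an exact permutation of the mean vector
#' *and* respects every trial's (decremented) cap. Feasibility is
#' guaranteed because each mean is bounded by its origin trial's cap.
#' Cue onsets are sampled as in [derive_yoked_schedule()].
#'
#' @param ec_sessions List of study-2 EC session records with equal trial
#'   counts.
#' @param seed Integer seed.
#' @return A `yoked_schedule` data frame with
#'   `provenance = "pseudo"`.
#' @export
derive_pseudo_yoked_schedule <- function(ec_sessions, seed) {
  if (!length(ec_sessions)) {
    stop("need at least one EC session", call. = FALSE)
  }
  if (inherits(ec_sessions, "session_record")) {
    ec_sessions <- list(ec_sessions)
  }
  for (s in ec_sessions) {
    stopifnot(inherits(s, "session_record"))
    if (s$condition != "EC") {
      stop("pseudo-yoked schedules are derived from EC sessions only",
           call. = FALSE)
    }
  }
  n_trials <- vapply(ec_sessions, function(s) nrow(s$trials), integer(1))
  if (length(unique(n_trials)) != 1L) {
    stop("EC sessions have unequal trial counts", call. = FALSE)
  }
  dur_mat <- vapply(ec_sessions, function(s) s$trials$stress_duration,
                    numeric(n_trials[1L]))
  means <- rowMeans(dur_mat)
  caps <- ec_sessions[[1L]]$trials$max_duration

  assigned <- numeric(length(means))
  with_seed(derive_seed(seed, "shuffle"), {
    remaining <- means
    for (pos in order(caps, seq_along(caps))) {
      elig <- which(remaining <= caps[pos] + 1e-9)
      if (!length(elig)) {
        stop("infeasible pseudo-yoked assignment (cap violated)",
             call. = FALSE) # unreachable for schedules built by this package
      }
      pick <- elig[sample.int(length(elig), 1L)]
      assigned[pos] <- remaining[pick]
      remaining <- remaining[-pick]
    }
  })
  stopifnot(all(assigned <= caps + 1e-9))
  sched <- data.frame(
    trial = seq_along(means),
    duration = assigned,
    cue_onset = sample_yc_onsets(assigned, derive_seed(seed, "onsets"))
  )
  structure(sched, class = c("yoked_schedule", "data.frame"),
            provenance = "pseudo",
            source_ids = vapply(ec_sessions, function(s) s$participant_id,
                                character(1)))
}

#' Simulate one full stress-induction session
#'
#' Runs an agent through the complete stress-induction phase of a study
#' variant under the given condition: the seeded trial timeline, per-trial
#' responses from the agent's RT model (and, for study-2 EC, its
#' trial-and-error learner with a per-participant random cue-button truth
#' map), the condition's termination rule, Likert ratings at every probe
#' index for every configured item, and pre/post affect scores. Everything
#' is deterministic given `(condition, agent, config, seed, yoke)`.
#'
#' The learner is updated only on trials with an in-window press: late or
#' missing presses never terminate the stressor regardless of button, so
#' they carry no information about the cue-button mapping.
#'
#' @param condition `"EC"`, `"YC"` or `"CC"`.
#' @param agent An [agent_spec()].
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @param participant_id Identifier copied into the record.
#' @param yoke A `yoked_schedule` (required for YC, forbidden otherwise).
#' @return An object of class `session_record`: list with `participant_id`,
#'   `condition`, `study`, `config`, `trials` (data frame), `ratings`
#'   (data frame `after_trial`, `probe`, `item`, `value`), `affect`
#'   (data frame `score`, `pre`, `post`), `truth_map` (study-2 EC),
#'   `seed`.
#' @examples
#' cfg <- study_config(1)
#' ec <- simulate_session("EC", agent_preset("ec_like"), cfg, seed = 1)
#' yc <- simulate_session("YC", agent_preset("yc_like"), cfg, seed = 2,
#'                        yoke = derive_yoked_schedule(ec, seed = 3))
#' sum(yc$trials$stress_duration) == sum(ec$trials$stress_duration)
#' @export
simulate_session <- function(condition = c("EC", "YC", "CC"), agent, config,
                             seed, participant_id = "P1", yoke = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(agent, "agent_spec"), inherits(config, "study_config"))
  if (condition == "YC" && is.null(yoke)) {
    stop("YC sessions require a `yoke` schedule", call. = FALSE)
  }
  if (condition != "YC" && !is.null(yoke)) {
    stop("`yoke` is only meaningful for YC sessions", call. = FALSE)
  }
  if (!is.null(yoke) && nrow(yoke) != config$n_trials) {
    stop("yoke schedule length does not match n_trials", call. = FALSE)
  }

  timeline <- build_trial_timeline(config, derive_seed(seed, "timeline"))
  buttons <- if (config$study == 2L) c("b1", "b2", "b3") else "space"
  truth_map <- NULL
  if (config$study == 2L && condition == "EC") {
    truth_map <- with_seed(derive_seed(seed, "truth"),
                           stats::setNames(sample(buttons), config$cue_set))
  }

  n <- config$n_trials
  window <- config$response_window
  study2 <- config$study == 2L
  rtm <- agent$rt
  lapse <- agent$learner$lapse_prob
  learns <- study2 && condition == "EC" &&
    agent$learner$family == "elimination"
  tl_cue <- timeline$cue; tl_onset <- timeline$cue_onset
  tl_max <- timeline$max_duration
  rt_v <- numeric(n); btn_v <- character(n); cor_v <- rep(NA, n)
  str_v <- numeric(n); term_v <- logical(n); onset_v <- tl_onset
  with_seed(derive_seed(seed, "behaviour"), {
    learner <- new_learner(config$cue_set, buttons)
    for (i in seq_len(n)) {
      # reaction time draw (inlined from sample_rt for the hot loop)
      rt <- if (rtm$miss_prob > 0 && stats::runif(1) < rtm$miss_prob) {
        NA_real_
      } else if (rtm$family == "constant") rtm$shift else
        rtm$shift + stats::rlnorm(1, rtm$meanlog, rtm$sdlog)
      button <- if (is.na(rt)) NA_character_
        else if (learns) choose_button(learner, tl_cue[i], lapse)
        else if (study2) buttons[sample.int(3L, 1L)]
        else "space"
      in_window <- !is.na(rt) && rt <= window
      if (condition == "EC") {
        correct <- if (study2) {
          !is.na(button) && identical(unname(truth_map[[tl_cue[i]]]), button)
        } else !is.na(rt)
        terminated <- if (study2) in_window && correct else in_window
        str_v[i] <- if (terminated) tl_onset[i] + rt else tl_max[i]
        term_v[i] <- terminated
        cor_v[i] <- correct
        if (learns && in_window) {
          learner <- update_learner(learner, tl_cue[i], button, terminated)
        }
      } else if (condition == "YC") {
        if (yoke$duration[i] > tl_max[i] + 1e-9) {
          stop(sprintf("yoked duration %.3f s exceeds the %.3f s cap of trial %d",
                       yoke$duration[i], tl_max[i], i), call. = FALSE)
        }
        str_v[i] <- yoke$duration[i]
        onset_v[i] <- yoke$cue_onset[i]
      } # CC: stress stays 0
      rt_v[i] <- rt; btn_v[i] <- button
    }
  })
  trials <- data.frame(
    trial = seq_len(n), condition = condition, cue = tl_cue,
    cue_onset = onset_v, rt = rt_v, button = btn_v, correct = cor_v,
    stress_duration = str_v, terminated = term_v, max_duration = tl_max,
    iti = timeline$iti, stringsAsFactors = FALSE)

  probes <- rating_probe_indices(config)
  ratings <- with_seed(derive_seed(seed, "ratings"), {
    rows <- expand.grid(item = config$rating_items,
                        probe = seq_along(probes),
                        stringsAsFactors = FALSE)
    rows <- rows[order(rows$probe, match(rows$item, config$rating_items)), ]
    data.frame(
      after_trial = probes[rows$probe],
      probe = rows$probe,
      item = rows$item,
      value = mapply(function(it, p) rating_value(agent, it, p),
                     rows$item, rows$probe, USE.NAMES = FALSE),
      row.names = NULL, stringsAsFactors = FALSE)
  })
  affect <- with_seed(derive_seed(seed, "affect"), sample_affect(agent))

  structure(list(
    participant_id = participant_id,
    condition = condition,
    study = config$study,
    config = config,
    trials = trials,
    ratings = ratings,
    affect = affect,
    truth_map = truth_map,
    agent_label = agent$label,
    seed = seed
  ), class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record '%s'> study %d %s: %d trials, total stress %.1f s\n",
              x$participant_id, x$study, x$condition, nrow(x$trials),
              sum(x$trials$stress_duration)))
  invisible(x)
}
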