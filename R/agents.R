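#' Specify a simulated participant
#'
#' An agent is a generative stand-in for a human participant. It bundles
#' four sub-models:
#'
#' * **Reaction times** — either a constant or a shifted lognormal
#'   (`shift + exp(Normal(meanlog, sdlog))`), with a per-trial miss
#'   probability (no press at all).
#' * **Learner** — for the study-2 three-cue task: `"elimination"` keeps a
#'   candidate-button set per cue and removes disconfirmed buttons
#'   (trial-and-error learning); `"random"` presses uniformly at random
#'   forever (used for yoked participants, whose feedback carries no
#'   signal). `lapse_prob` is the probability of pressing uniformly at
#'   random regardless of learner state.
#' * **Navigation policy** — how the agent moves on the escape grid:
#'   `"random_walk"` (uniform over the four moves); `"sweep"` (systematic
#'   boustrophedon scan with a progress pointer that persists across
#'   phases; scanning skill develops over the first trials, before which
#'   the agent wanders); `"memory_guided"` (in the stress phase with a
#'   remembered safe cell, walks a shortest Manhattan path to the nearest
#'   one, abandoning a stale target after `stale_persistence` moves and
#'   purging locations observed to be unsafe; otherwise sweeps); and
#'   `"frantic"` (momentum-biased walk — repeat the current heading with
#'   probability `momentum`, bouncing off walls — that is captured by
#'   remembered safe locations: in the stress phase it pursues the
#'   most-rehearsed remembered location first, stale or not, with
#'   imprecise steps (`nav_noise`), and with accumulating time on task its
#'   stress-free phases are increasingly spent clinging to remembered
#'   spots or the familiar start region (`safety_bias`) instead of
#'   exploring).
#'
#'   Spatial memory is tiered. A location seen lit in two or more distinct
#'   trials is consolidated and survives each trial transition with
#'   probability `memory_retention`; a location seen once survives with
#'   `fresh_retention` if first seen during a stress-free phase, or with
#'   `stress_encoding` if first encoded under acute stress (encoding under
#'   uncontrollable stress is impaired), and the survival of fresh
#'   memories erodes toward `stress_encoding` as the task progresses.
#'   Frantic agents keep remembered locations after seeing them unsafe
#'   (perseveration); memory-guided agents discard them on sight.
#'   `move_interval` is the time between key presses.
#' * **Ratings and affect** — Likert ratings are
#'   `round(baseline + slope * (probe - 1) + Normal(0, noise_sd))` clipped
#'   to 1..7; affect scores (STADI total, PANAS positive/negative) are
#'   Gaussian pre-scores plus a Gaussian pre-to-post shift.
#'
#' @param rt List: `family` (`"shifted_lognormal"` or `"constant"`),
#'   `shift`, `meanlog`, `sdlog`, `miss_prob`; for `"constant"` only
#'   `shift` (the RT itself) and `miss_prob` are used.
#' @param learner List: `family` (`"elimination"` or `"random"`),
#'   `lapse_prob`.
#' @param nav List: `family` (`"random_walk"`, `"sweep"`,
#'   `"memory_guided"`, `"frantic"`), `move_interval` (s),
#'   `memory_retention`, `fresh_retention`, `stress_encoding` (per-trial
#'   survival probabilities of consolidated, fresh, and stress-encoded
#'   memories; the latter two default to `memory_retention`),
#'   `stale_persistence` (stress moves before a memory-guided agent
#'   abandons a stale target), `safety_bias` (strength of the frantic
#'   agent's pull towards remembered spots in stress-free phases),
#'   `nav_noise` (probability of an astray step during frantic pursuit),
#'   `momentum` (heading-repeat probability of the undirected walk).
#' @param ratings Named list; per rating item a numeric vector
#'   `c(baseline, slope, noise_sd)` on the 1-7 scale.
#' @param affect Named list; per score a numeric vector
#'   `c(pre_mean, pre_sd, shift_mean, shift_sd)`.
#' @param label Optional preset name.
#' @return An object of class `agent_spec`.
#' @seealso [agent_preset()] for the shipped `ec_like` / `yc_like` /
#'   `cc_like` presets.
#' @export
agent_spec <- function(rt = list(family = "constant", shift = 0.3,
                                 miss_prob = 0),
                       learner = list(family = "elimination",
                                      lapse_prob = 0),
                       nav = list(family = "random_walk",
                                  move_interval = 0.25,
                                  memory_retention = 1,
                                  stale_persistence = 3L),
                       ratings = list(),
                       affect = list(),
                       label = "custom") {
  rt <- utils::modifyList(list(family = "shifted_lognormal", shift = 0,
                               meanlog = log(0.3), sdlog = 0.3,
                               miss_prob = 0), rt)
  learner <- utils::modifyList(list(family = "elimination", lapse_prob = 0),
                               learner)
  nav <- utils::modifyList(list(family = "random_walk", move_interval = 0.25,
                                memory_retention = 1, fresh_retention = NULL,
                                stress_encoding = NULL,
                                stale_persistence = 3L, safety_bias = 0.6,
                                nav_noise = 0, momentum = 0.6),
                           nav)
  if (is.null(nav$fresh_retention)) nav$fresh_retention <- nav$memory_retention
  if (is.null(nav$stress_encoding)) nav$stress_encoding <- nav$fresh_retention
  rt$family <- match.arg(rt$family, c("shifted_lognormal", "constant"))
  learner$family <- match.arg(learner$family, c("elimination", "random"))
  nav$family <- match.arg(nav$family,
                          c("random_walk", "sweep", "memory_guided",
                            "frantic"))
  stopifnot(rt$miss_prob >= 0, rt$miss_prob <= 1,
            learner$lapse_prob >= 0, learner$lapse_prob <= 1,
            nav$move_interval > 0,
            nav$memory_retention >= 0, nav$memory_retention <= 1,
            nav$fresh_retention >= 0, nav$fresh_retention <= 1,
            nav$stress_encoding >= 0, nav$stress_encoding <= 1,
            nav$stale_persistence >= 0,
            nav$safety_bias >= 0, nav$safety_bias <= 1,
            nav$nav_noise >= 0, nav$nav_noise <= 1,
            nav$momentum >= 0, nav$momentum <= 1)
  for (it in names(ratings)) {
    r <- ratings[[it]]
    if (length(r) != 3L || r[1] < 1 || r[1] > 7 || r[3] < 0) {
      stop(sprintf("rating model for '%s' must be c(baseline in [1,7], slope, noise_sd >= 0)",
                   it), call. = FALSE)
    }
  }
  structure(list(rt = rt, learner = learner, nav = nav,
                 ratings = ratings, affect = affect, label = label),
            class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat(sprintf("<agent_spec '%s'> rt: %s, learner: %s, nav: %s (interval %.2f s, retention %.2f)\n",
              x$label, x$rt$family, x$learner$family, x$nav$family,
              x$nav$move_interval, x$nav$memory_retention))
  invisible(x)
}

#' Shipped participant presets
#'
#' Three named agent presets express the behavioural phenotypes the
#' paradigm is designed to detect. `ec_like` (escapable-stress history):
#' fast reaction times, reliable trial-and-error learning, and a
#' deliberate, memory-guided grid search that becomes systematic with
#' task experience and quickly abandons stale safe locations. `yc_like`
#' (inescapable-stress history): slower reaction times, no learnable
#' contingency, and a frantic, high-activity search — many more key
#' presses per minute, rigid habitual memory for old safe locations
#' combined with impaired encoding of new ones under acute stress,
#' perseverative returns to relocated (stale) spots, growing passivity in
#' the stress-free phases, and imprecise pursuit. `cc_like` (no-stress
#' control, study 1): fastest reaction times, calm ratings, memory-guided
#' search.
#'
#' All parameter values are documented choices of this package (the
#' paradigm itself provides no participant model); see the methods
#' vignette for the rationale.
#'
#' @param name `"ec_like"`, `"yc_like"` or `"cc_like"`.
#' @return An [agent_spec()].
#' @examples
#' agent_preset("ec_like")
#' @export
agent_preset <- function(name = c("ec_like", "yc_like", "cc_like")) {
  name <- match.arg(name)
  switch(name,
    ec_like = agent_spec(
      rt = list(family = "shifted_lognormal", shift = 0.15,
                meanlog = log(0.25), sdlog = 0.25, miss_prob = 0.03),
      learner = list(family = "elimination", lapse_prob = 0.02),
      nav = list(family = "memory_guided", move_interval = 0.20,
                 memory_retention = 1, stale_persistence = 3L),
      ratings = list(
        aversiveness = c(5.6, 0.05, 0.8),
        control      = c(4.4, -0.10, 0.8),
        exhaustion   = c(3.8, 0.15, 0.8),
        frustration  = c(3.5, 0.10, 0.8),
        helplessness = c(3.2, 0.05, 0.9)),
      affect = list(
        STADI    = c(31, 6, 2.5, 3),
        PANASpos = c(30, 5, -3.0, 3),
        PANASneg = c(14, 3, 2.5, 2.5)),
      label = "ec_like"),
    yc_like = agent_spec(
      rt = list(family = "shifted_lognormal", shift = 0.2,
                meanlog = log(0.38), sdlog = 0.3, miss_prob = 0.08),
      learner = list(family = "random", lapse_prob = 0),
      nav = list(family = "frantic", move_interval = 0.12,
                 memory_retention = 1, fresh_retention = 1,
                 stress_encoding = 0.05, safety_bias = 0.6,
                 nav_noise = 0.1, momentum = 0.85,
                 stale_persistence = 3L),
      ratings = list(
        aversiveness = c(5.6, 0.10, 0.8),
        control      = c(2.6, -0.15, 0.8),
        exhaustion   = c(4.3, 0.20, 0.8),
        frustration  = c(4.2, 0.15, 0.9),
        helplessness = c(4.1, 0.10, 0.9)),
      affect = list(
        STADI    = c(32, 6, 3.5, 3),
        PANASpos = c(30, 5, -3.5, 3),
        PANASneg = c(15, 3.5, 3.5, 2.5)),
      label = "yc_like"),
    cc_like = agent_spec(
      rt = list(family = "shifted_lognormal", shift = 0.12,
                meanlog = log(0.22), sdlog = 0.25, miss_prob = 0.02),
      learner = list(family = "elimination", lapse_prob = 0.02),
      nav = list(family = "memory_guided", move_interval = 0.20,
                 memory_retention = 1, stale_persistence = 3L),
      ratings = list(
        aversiveness = c(1.8, 0.00, 0.6),
        control      = c(5.8, -0.05, 0.7),
        exhaustion   = c(2.2, 0.05, 0.7),
        frustration  = c(1.8, 0.05, 0.7),
        helplessness = c(1.6, 0.00, 0.6)),
      affect = list(
        STADI    = c(31, 6, 0.0, 2.5),
        PANASpos = c(30, 5, -1.5, 2.5),
        PANASneg = c(13.5, 3, -0.5, 2)),
      label = "cc_like")
  )
}

#' Draw an individual participant from an agent population
#'
#' A preset describes a population average; individual simulated
#' participants vary around it. `sample_participant()` jitters the
#' reaction-time scale (lognormal `meanlog` shifted by `Normal(0, 0.3)`)
#' and each rating item's baseline (`Normal(0, 0.8)`, clipped to the 1-7
#' scale). Navigation parameters are not jittered: between-participant
#' variability on the grid already arises from the random safe layouts
#' and stochastic policies. Deterministic given the seed.
#'
#' @param agent An [agent_spec()] describing the population.
#' @param seed Integer seed identifying the participant.
#' @return An [agent_spec()] for one individual.
#' @export
sample_participant <- function(agent, seed) {
  stopifnot(inherits(agent, "agent_spec"))
  with_seed(seed, {
    if (agent$rt$family == "shifted_lognormal") {
      agent$rt$meanlog <- agent$rt$meanlog + stats::rnorm(1, 0, 0.3)
    }
    for (it in names(agent$ratings)) {
      b <- agent$ratings[[it]][1] + stats::rnorm(1, 0, 0.8)
      agent$ratings[[it]][1] <- min(7, max(1, b))
    }
    agent
  })
}

#' Sample one cue-locked reaction time
#'
#' Draws from the agent's RT model using the current RNG stream: with
#' probability `miss_prob` the trial is a miss (`NA`), otherwise a
#' constant or a shifted-lognormal draw. The median of the
#' shifted-lognormal is `shift + exp(meanlog)`.
#'
#' @param agent An [agent_spec()].
#' @param n Number of draws.
#' @return Numeric vector of RTs in seconds, `NA` for misses.
#' @export
sample_rt <- function(agent, n = 1L) {
  stopifnot(inherits(agent, "agent_spec"))
  m <- agent$rt
  rt <- if (m$family == "constant") {
    rep(m$shift, n)
  } else {
    m$shift + stats::rlnorm(n, m$meanlog, m$sdlog)
  }
  if (m$miss_prob > 0) rt[stats::runif(n) < m$miss_prob] <- NA_real_
  rt
}

# Learner -------------------------------------------------------------------

#' Create a fresh trial-and-error learner state
#'
#' For each cue the learner holds the set of still-plausible buttons; a cue
#' is resolved once a press terminated the stressor.
#'
#' @param cues Character vector of cue identifiers.
#' @param buttons Character vector of available buttons.
#' @return An object of class `learner_state`.
#' @export
new_learner <- function(cues, buttons) {
  stopifnot(length(cues) >= 1L, length(buttons) >= 1L)
  structure(list(
    buttons = buttons,
    candidates = stats::setNames(rep(list(buttons), length(cues)), cues),
    resolved = stats::setNames(rep(NA_character_, length(cues)), cues)
  ), class = "learner_state")
}

#' Choose a button for a cue
#'
#' With probability `lapse_prob` the press is uniform over all buttons;
#' otherwise it is uniform over the cue's current candidate set (the
#' correct button, deterministically, once the cue is resolved).
#'
#' @param state A [new_learner()] state.
#' @param cue Cue identifier.
#' @param lapse_prob Lapse probability.
#' @return A button identifier.
#' @export
choose_button <- function(state, cue, lapse_prob = 0) {
  stopifnot(inherits(state, "learner_state"))
  if (!cue %in% names(state$candidates)) {
    stop(sprintf("unknown cue '%s'", cue), call. = FALSE)
  }
  if (lapse_prob > 0 && stats::runif(1) < lapse_prob) {
    return(state$buttons[sample.int(length(state$buttons), 1L)])
  }
  set <- state$candidates[[cue]]
  set[sample.int(length(set), 1L)]
}

#' Update the learner with trial feedback
#'
#' A press that terminated the stressor resolves the cue to that button;
#' a press that did not is removed from the cue's candidate set. If the
#' removal would empty the set (inconsistent feedback, e.g. after a
#' lapse-confounded history), the full button set is restored instead.
#'
#' @param state A [new_learner()] state.
#' @param cue Cue identifier.
#' @param button The button that was pressed.
#' @param terminated Did the press terminate the stressor?
#' @return The updated `learner_state`.
#' @export
update_learner <- function(state, cue, button, terminated) {
  stopifnot(inherits(state, "learner_state"))
  if (!cue %in% names(state$candidates)) {
    stop(sprintf("unknown cue '%s'", cue), call. = FALSE)
  }
  if (isTRUE(terminated)) {
    state$candidates[[cue]] <- button
    state$resolved[[cue]] <- button
  } else {
    remaining <- setdiff(state$candidates[[cue]], button)
    state$candidates[[cue]] <- if (length(remaining)) remaining else
      state$buttons
    if (!length(remaining)) state$resolved[[cue]] <- NA_character_
  }
  state
}

# Ratings and affect ---------------------------------------------------------

#' Generate one Likert rating
#'
#' `round(baseline + slope * (probe_number - 1) + Normal(0, noise_sd))`,
#' clipped to the integer scale 1..7. Items missing from the agent's rating
#' model use a flat neutral baseline of 4.
#'
#' @param agent An [agent_spec()].
#' @param item Rating item identifier.
#' @param probe_number 1-based probe index.
#' @return Integer in 1..7.
#' @export
rating_value <- function(agent, item, probe_number) {
  stopifnot(inherits(agent, "agent_spec"), probe_number >= 1)
  m <- agent$ratings[[item]]
  if (is.null(m)) m <- c(4, 0, 0)
  v <- round(m[1] + m[2] * (probe_number - 1) + stats::rnorm(1, 0, m[3]))
  as.integer(min(7, max(1, v)))
}

sample_affect <- function(agent) {
  scores <- c("STADI", "PANASpos", "PANASneg")
  pre <- post <- numeric(length(scores))
  for (i in seq_along(scores)) {
    m <- agent$affect[[scores[i]]]
    if (is.null(m)) m <- c(30, 5, 0, 2)
    pre[i] <- stats::rnorm(1, m[1], m[2])
    post[i] <- pre[i] + stats::rnorm(1, m[3], m[4])
  }
  data.frame(score = scores, pre = pre, post = post,
             stringsAsFactors = FALSE)
}

# Navigation -----------------------------------------------------------------

# moves are encoded 1 = up, 2 = down, 3 = left, 4 = right
MOVE_NAMES <- c("up", "down", "left", "right")

boustrophedon_path <- function(size) {
  # fixed scan order over all cells: row 0 left-to-right, row 1
  # right-to-left, ... ; cells encoded as row * size + col (0-based)
  unlist(lapply(seq_len(size) - 1L, function(r) {
    cols <- if (r %% 2L == 0L) 0:(size - 1L) else (size - 1L):0
    r * size + cols
  }))
}

#' Create mutable navigation state for an agent
#'
#' Holds the agent's remembered safe cells, sweep progress, last move, and
#' stale-pursuit counter across phases and trials of an escape test.
#'
#' @param agent An [agent_spec()].
#' @param size Grid side length.
#' @return An environment of class `nav_state`.
#' @export
new_nav_state <- function(agent, size = 15L) {
  e <- new.env(parent = emptyenv())
  e$family <- agent$nav$family
  e$interval <- agent$nav$move_interval
  e$retention <- agent$nav$memory_retention
  e$fresh_retention <- agent$nav$fresh_retention
  e$stress_encoding <- agent$nav$stress_encoding
  e$persistence <- agent$nav$stale_persistence
  e$safety_bias <- agent$nav$safety_bias
  e$nav_noise <- agent$nav$nav_noise
  e$momentum <- agent$nav$momentum
  e$size <- as.integer(size)
  e$path <- boustrophedon_path(size)
  e$path_pos <- order(e$path) # path index of each cell (1-based over 0-based cells)
  e$known <- integer(0)       # remembered safe cells
  e$strength <- integer(0)    # rehearsals (distinct trials seen) per cell
  e$last_seen <- integer(0)   # trial number of the last rehearsal
  e$fragile <- logical(0)     # first seen under acute stress (poor encoding)
  e$trial_no <- 1L            # current trial, set by the test runner
  e$inactive <- integer(0)    # remembered cells already tried this phase
  e$sticky_memory <- agent$nav$family == "frantic" # perseveration: stale
  # cells stay remembered after being seen unsafe (only retention erodes them)
  e$sweep_idx <- NA_integer_
  e$last_move <- NA_integer_
  e$pursuit <- 0L             # stress moves spent pursuing a stale target
  class(e) <- c("nav_state", "environment")
  e
}

nav_forget <- function(nav) {
  # memory survival over a trial transition is tiered: consolidated
  # locations (seen lit in >= 2 distinct trials) survive with
  # memory_retention; locations seen once during a stress-free phase with
  # fresh_retention; locations first encoded under acute stress with
  # stress_encoding -- encoding under acute stress is impaired, so such
  # memories rarely outlive the trial unless rehearsed
  if (length(nav$known) &&
      (nav$retention < 1 || nav$fresh_retention < 1 ||
       nav$stress_encoding < 1)) {
    # encoding quality also erodes with accumulating time on task: late
    # fresh memories survive no better than stress-encoded ones
    ramp <- min(1, (nav$trial_no - 1) / 5)
    fresh_eff <- nav$fresh_retention +
      (nav$stress_encoding - nav$fresh_retention) * ramp
    surv <- ifelse(nav$strength >= 2L, nav$retention,
                   ifelse(nav$fragile, nav$stress_encoding, fresh_eff))
    keep <- stats::runif(length(nav$known)) < surv
    nav$known <- nav$known[keep]
    nav$strength <- nav$strength[keep]
    nav$last_seen <- nav$last_seen[keep]
    nav$fragile <- nav$fragile[keep]
  }
  invisible(nav)
}

nav_note_safe <- function(nav, cell, stress = FALSE) {
  # a rehearsal is one *trial* in which the cell was seen lit: repeated
  # visits within a trial do not consolidate
  i <- match(cell, nav$known)
  if (is.na(i)) {
    nav$known <- c(nav$known, cell)
    nav$strength <- c(nav$strength, 1L)
    nav$last_seen <- c(nav$last_seen, nav$trial_no)
    nav$fragile <- c(nav$fragile, isTRUE(stress))
  } else if (nav$last_seen[i] < nav$trial_no) {
    nav$strength[i] <- nav$strength[i] + 1L
    nav$last_seen[i] <- nav$trial_no
    nav$fragile[i] <- FALSE # rehearsal consolidates
  }
  invisible(nav)
}

nav_drop_known <- function(nav, cells) {
  keep <- !(nav$known %in% cells)
  nav$known <- nav$known[keep]
  nav$strength <- nav$strength[keep]
  nav$last_seen <- nav$last_seen[keep]
  nav$fragile <- nav$fragile[keep]
  invisible(nav)
}

blocked_move <- function(mv, row, col, size) {
  (mv == 1L && row == 0L) || (mv == 2L && row == size - 1L) ||
    (mv == 3L && col == 0L) || (mv == 4L && col == size - 1L)
}

step_towards <- function(row, col, trow, tcol) {
  # one step along a shortest Manhattan path, row-first on ties/diagonals
  if (row != trow) {
    if (trow < row) 1L else 2L
  } else if (col != tcol) {
    if (tcol < col) 3L else 4L
  } else {
    NA_integer_
  }
}

search_step <- function(nav, row, col) {
  # searching skill develops with task experience: early trials wander
  # (momentum walk), later trials follow the systematic boustrophedon
  # sweep; fully systematic from the sixth trial on
  skill <- min(1, nav$trial_no / 3)
  if (skill < 1 && stats::runif(1) >= skill) {
    if (!is.na(nav$last_move) && stats::runif(1) < nav$momentum &&
        !blocked_move(nav$last_move, row, col, nav$size)) {
      return(nav$last_move)
    }
    return(sample.int(4L, 1L))
  }
  sweep_step(nav, row, col)
}

sweep_step <- function(nav, row, col) {
  cell <- row * nav$size + col
  if (is.na(nav$sweep_idx)) {
    nav$sweep_idx <- nav$path_pos[cell + 1L] %% length(nav$path) + 1L
  }
  target <- nav$path[nav$sweep_idx]
  while (target == cell) {
    nav$sweep_idx <- nav$sweep_idx %% length(nav$path) + 1L
    target <- nav$path[nav$sweep_idx]
  }
  step_towards(row, col, target %/% nav$size, target %% nav$size)
}

nearest_known <- function(nav, row, col, cells = nav$known) {
  d <- abs(cells %/% nav$size - row) + abs(cells %% nav$size - col)
  cells[order(d, cells)][1L]
}

strongest_known <- function(nav, row, col, cells) {
  # habit-ordered recall: the most-rehearsed location first (stress
  # shifts search from goal-directed to habitual); ties by distance
  d <- abs(cells %/% nav$size - row) + abs(cells %% nav$size - col)
  st <- nav$strength[match(cells, nav$known)]
  cells[order(-st, d, cells)][1L]
}

#' One navigation-policy step
#'
#' Queries the agent's navigation policy for the next move given the
#' current observation. Stale flags mark remembered safe cells that are no
#' longer safe (after a between-block relocation); the runner supplies
#' them, the policies differ in how quickly they react to staleness.
#'
#' @param nav A [new_nav_state()] environment.
#' @param row,col Current position (0-based).
#' @param phase `"explore"` or `"stress"`.
#' @param safes Integer vector of currently safe cells (`row * size + col`),
#'   used only to derive stale flags for remembered cells.
#' @return Move code: 1 = up, 2 = down, 3 = left, 4 = right.
#' @export
nav_policy_step <- function(nav, row, col, phase, safes) {
  mv <- switch(nav$family,
    random_walk = sample.int(4L, 1L),
    sweep = sweep_step(nav, row, col),
    memory_guided = {
      if (phase == "stress" && length(nav$known)) {
        target <- nearest_known(nav, row, col)
        if (!(target %in% safes)) { # stale
          if (nav$pursuit >= nav$persistence) {
            nav_drop_known(nav, nav$known[!(nav$known %in% safes)])
            if (length(nav$known)) target <- nearest_known(nav, row, col)
            else target <- NA_integer_
          } else {
            nav$pursuit <- nav$pursuit + 1L
          }
        }
        if (is.na(target)) search_step(nav, row, col)
        else step_towards(row, col, target %/% nav$size, target %% nav$size)
      } else {
        search_step(nav, row, col)
      }
    },
    frantic = {
      active <- setdiff(nav$known, nav$inactive)
      if (phase == "explore" &&
          stats::runif(1) < nav$safety_bias * min(1, (nav$trial_no - 1) / 5)) {
        # progressive passivity: with accumulating time under
        # uncontrollable stress the stress-free phase is increasingly
        # spent clinging to remembered safe spots (or to the familiar
        # start region when none is remembered) instead of covering new
        # ground; the pull ramps up over the first six trials
        target <- if (length(active)) {
          strongest_known(nav, row, col, active)
        } else if (length(nav$known)) {
          strongest_known(nav, row, col, nav$known)
        } else {
          (nav$size %/% 2L) * nav$size + nav$size %/% 2L
        }
        mv <- step_towards(row, col, target %/% nav$size, target %% nav$size)
        if (is.na(mv) || stats::runif(1) < nav$nav_noise) {
          sample.int(4L, 1L)
        } else mv
      } else if (phase == "stress" && length(active)) {
        # captured by memory, stale or not: heads for the most-rehearsed
        # remembered location not yet tried this phase; stale cells stay
        # remembered (perseveration) and recapture the walk next phase.
        # pursuit is imprecise: with prob nav_noise the step goes astray
        # (resources squandered on undirected movement)
        if (stats::runif(1) < nav$nav_noise) {
          sample.int(4L, 1L)
        } else {
          target <- strongest_known(nav, row, col, active)
          step_towards(row, col, target %/% nav$size, target %% nav$size)
        }
      } else if (!is.na(nav$last_move) &&
                 stats::runif(1) < nav$momentum &&
                 !blocked_move(nav$last_move, row, col, nav$size)) {
        # dashing: keep the current heading until a wall is hit
        nav$last_move
      } else {
        sample.int(4L, 1L)
      }
    }
  )
  if (is.na(mv)) mv <- sample.int(4L, 1L) # already on target: jiggle
  nav$last_move <- mv
  mv
}
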