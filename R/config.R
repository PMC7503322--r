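#' Grid configuration for the escape behaviour test
#'
#' Geometry and timing of the grid-world escape test (the human translation
#' of the shuttle-box task): a square grid with hidden safe cells, a
#' stress-free exploration phase and a stress phase per trial, optionally
#' organised in blocks with safe-space relocation between blocks.
#'
#' @param size Cells per side of the square grid.
#' @param n_safe Number of hidden safe cells.
#' @param n_blocks Number of blocks.
#' @param n_trials_per_block Trials per block.
#' @param explore_duration Length of the stress-free exploration phase (s).
#' @param stress_cap Maximum length of the stress phase (s).
#' @param reset_between_phases Reset position to the grid centre at the
#'   start of every phase (`TRUE`, study-2 style) or let the stress phase
#'   start where exploration ended (`FALSE`, study-1 style)?
#' @param relocate_safes_between_blocks Resample safe cells for block 2?
#' @return An object of class `grid_config`.
#' @examples
#' grid_config()                        # study-1 geometry
#' grid_config(n_blocks = 2, explore_duration = 5, stress_cap = 5,
#'             reset_between_phases = TRUE,
#'             relocate_safes_between_blocks = TRUE)
#' @export
grid_config <- function(size = 15L, n_safe = 4L, n_blocks = 1L,
                        n_trials_per_block = 5L, explore_duration = 10,
                        stress_cap = 20, reset_between_phases = FALSE,
                        relocate_safes_between_blocks = FALSE) {
  g <- list(size = as.integer(size), n_safe = as.integer(n_safe),
            n_blocks = as.integer(n_blocks),
            n_trials_per_block = as.integer(n_trials_per_block),
            explore_duration = as.numeric(explore_duration),
            stress_cap = as.numeric(stress_cap),
            reset_between_phases = isTRUE(reset_between_phases),
            relocate_safes_between_blocks = isTRUE(relocate_safes_between_blocks))
  if (g$size < 2L) stop("grid `size` must be at least 2", call. = FALSE)
  if (g$n_safe < 1L || g$n_safe >= g$size^2) {
    stop("`n_safe` must be in [1, size^2 - 1]", call. = FALSE)
  }
  if (g$n_blocks < 1L || g$n_trials_per_block < 1L) {
    stop("`n_blocks` and `n_trials_per_block` must be positive", call. = FALSE)
  }
  if (g$explore_duration <= 0 || g$stress_cap <= 0) {
    stop("`explore_duration` and `stress_cap` must be positive", call. = FALSE)
  }
  structure(g, class = "grid_config")
}

grid_defaults <- function(study) {
  if (study == 1L) {
    grid_config()
  } else {
    grid_config(n_blocks = 2L, explore_duration = 5, stress_cap = 5,
                reset_between_phases = TRUE,
                relocate_safes_between_blocks = TRUE)
  }
}

study_defaults <- function(study) {
  if (study == 1L) {
    list(
      n_trials = 40L,
      cue_set = "cue",
      pre_cue_duration = 6.0,
      response_window = 1.0,
      max_duration_base = 15.0,
      max_duration_decrement = 0.0,
      decrement_interval = 40L,
      iti_base = 1.0,
      iti_jitter = 0.25,
      rating_interval = 10L,
      rating_items = c("aversiveness", "control", "exhaustion",
                       "frustration", "helplessness"),
      n_shocks_per_precue = 4L,
      grid = grid_defaults(1L)
    )
  } else {
    # study 2: three cues, decrement schedule, no shocks (noise only);
    # pre-cue duration and ITI are inherited from study 1 (not separately
    # specified for the improved paradigm) but remain overridable.
    list(
      n_trials = 60L,
      cue_set = c("circle", "triangle", "square"),
      pre_cue_duration = 6.0,
      response_window = 1.0,
      max_duration_base = 10.0,
      max_duration_decrement = 0.5,
      decrement_interval = 15L,
      iti_base = 1.0,
      iti_jitter = 0.25,
      rating_interval = 15L,
      rating_items = c("aversiveness", "control", "exhaustion",
                       "helplessness"),
      n_shocks_per_precue = 0L,
      grid = grid_defaults(2L)
    )
  }
}

#' Build a validated study configuration
#'
#' Returns the full parameter set of one study variant of the paradigm.
#' Study 1 is the initial three-group design: 40 trials, a single cue after
#' 6 s of pre-cue stimulation, a 1-s response window, a fixed 15-s cap on
#' stimulation, ratings after every 10th trial, and a 15x15 escape grid
#' with one block of five trials (10-s exploration, 20-s stress cap).
#' Study 2 is the improved two-group design: 60 trials over three cues,
#' a 10-s cap that shrinks by 0.5 s after every 15th trial, ratings after
#' every 15th trial, and a two-block escape grid (5-s phases, position
#' reset each phase, safe spaces relocated for block 2).
#'
#' @param study Study variant, `1` or `2`.
#' @param ... Field overrides by name (e.g. `n_trials = 80`). Unknown
#'   fields are an error.
#' @return An object of class `study_config`.
#' @examples
#' study_config(1)
#' study_config(2, pre_cue_duration = 4)
#' @export
study_config <- function(study, ...) {
  if (!(length(study) == 1L && study %in% c(1, 2))) {
    stop("`study` must be 1 or 2", call. = FALSE)
  }
  study <- as.integer(study)
  cfg <- study_defaults(study)
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      stop("overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, names(cfg))
    if (length(unknown)) {
      stop("unknown study_config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (f in nm) cfg[[f]] <- overrides[[f]]
  }
  cfg$study <- study
  cfg$n_trials <- as.integer(cfg$n_trials)
  cfg$rating_interval <- as.integer(cfg$rating_interval)
  cfg$decrement_interval <- as.integer(cfg$decrement_interval)
  cfg$n_shocks_per_precue <- as.integer(cfg$n_shocks_per_precue)
  for (f in c("pre_cue_duration", "response_window", "max_duration_base",
              "max_duration_decrement", "iti_base", "iti_jitter")) {
    cfg[[f]] <- as.numeric(cfg[[f]])
  }
  cfg <- structure(cfg, class = "study_config")
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  if (cfg$n_trials < 1L) fail("n_trials", "must be positive")
  if (!length(cfg$cue_set) || anyDuplicated(cfg$cue_set)) {
    fail("cue_set", "must be a non-empty set of distinct cue identifiers")
  }
  if (cfg$n_trials %% length(cfg$cue_set) != 0L) {
    fail("n_trials", sprintf("%d not divisible by the number of cues (%d)",
                             cfg$n_trials, length(cfg$cue_set)))
  }
  if (cfg$rating_interval < 1L || cfg$n_trials %% cfg$rating_interval != 0L) {
    fail("rating_interval",
         sprintf("%d does not divide n_trials = %d",
                 cfg$rating_interval, cfg$n_trials))
  }
  for (f in c("pre_cue_duration", "response_window", "max_duration_base",
              "iti_base")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) fail(f, "must be positive")
  }
  if (cfg$max_duration_decrement < 0) {
    fail("max_duration_decrement", "must be non-negative")
  }
  if (cfg$max_duration_decrement > 0 && cfg$decrement_interval < 1L) {
    fail("decrement_interval", "must be positive when a decrement is set")
  }
  if (cfg$iti_jitter < 0 || cfg$iti_jitter >= cfg$iti_base) {
    fail("iti_jitter", "must lie in [0, iti_base)")
  }
  if (!length(cfg$rating_items)) fail("rating_items", "must be non-empty")
  last_max <- max_stress_duration(cfg, cfg$n_trials)
  if (last_max <= 0) {
    fail("max_duration_decrement", "drives the duration cap to zero or below")
  }
  if (cfg$response_window > last_max) {
    fail("response_window",
         sprintf("%.3f s exceeds the %.3f s duration cap of trial %d",
                 cfg$response_window, last_max, cfg$n_trials))
  }
  if (!inherits(cfg$grid, "grid_config")) {
    fail("grid", "must be a grid_config object")
  }
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> study %d: %d trials, %d cue(s), cap %.1f s",
              x$study, x$n_trials, length(x$cue_set), x$max_duration_base))
  if (x$max_duration_decrement > 0) {
    cat(sprintf(" (-%.1f s / %d trials)", x$max_duration_decrement,
                x$decrement_interval))
  }
  cat(sprintf("\n  ratings every %d trials: %s\n", x$rating_interval,
              paste(x$rating_items, collapse = ", ")))
  g <- x$grid
  cat(sprintf("  grid %dx%d, %d safe, %d block(s) x %d trials, explore %.0f s, stress <= %.0f s\n",
              g$size, g$size, g$n_safe, g$n_blocks, g$n_trials_per_block,
              g$explore_duration, g$stress_cap))
  invisible(x)
}

#' Maximum stress duration for a given trial
#'
#' The per-trial cap on aversive stimulation. In study 2 the cap starts at
#' `max_duration_base` and decreases by `max_duration_decrement` after
#' every `decrement_interval`-th trial (10.0 s on trials 1-15, 9.5 s on
#' 16-30, 9.0 s on 31-45, 8.5 s on 46-60); with a zero decrement (study 1)
#' it is constant.
#'
#' @param config A [study_config()].
#' @param trial_index Trial index (1-based), possibly vectorised.
#' @return Maximum stress duration(s) in seconds.
#' @examples
#' max_stress_duration(study_config(2), c(1, 16, 60))  # 10.0 9.5 8.5
#' @export
max_stress_duration <- function(config, trial_index) {
  stopifnot(inherits(config, "study_config"))
  if (any(trial_index < 1L | trial_index > config$n_trials)) {
    stop(sprintf("trial_index out of range [1, %d]", config$n_trials),
         call. = FALSE)
  }
  if (config$max_duration_decrement == 0) {
    return(rep(config$max_duration_base, length(trial_index)))
  }
  config$max_duration_base -
    config$max_duration_decrement *
      floor((trial_index - 1) / config$decrement_interval)
}

#' Construct a seeded trial timeline
#'
#' Builds the per-trial schedule of one stress-induction session: a
#' balanced random cue order (each cue appears exactly
#' `n_trials / length(cue_set)` times), the nominal cue onset (the pre-cue
#' stimulation duration), the per-trial duration cap from the decrement
#' schedule, and inter-trial intervals drawn uniformly from
#' `iti_base +/- iti_jitter`. The result is a pure function of
#' `(config, seed)`.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return A data frame with one row per trial and columns `trial`, `cue`,
#'   `cue_onset`, `max_duration`, `iti`.
#' @examples
#' tl <- build_trial_timeline(study_config(2), seed = 1)
#' table(tl$cue)   # each cue exactly 20 times
#' @export
build_trial_timeline <- function(config, seed) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_trials
  k <- length(config$cue_set)
  with_seed(seed, {
    cues <- sample(rep(config$cue_set, each = n %/% k))
    itis <- stats::runif(n, config$iti_base - config$iti_jitter,
                         config$iti_base + config$iti_jitter)
    data.frame(
      trial = seq_len(n),
      cue = cues,
      cue_onset = rep(config$pre_cue_duration, n),
      max_duration = max_stress_duration(config, seq_len(n)),
      iti = itis,
      stringsAsFactors = FALSE
    )
  })
}

#' Trial indices at which ratings are probed
#'
#' Ratings are collected after every `rating_interval`-th trial, so the
#' probe indices are the multiples of the interval up to `n_trials`
#' (study 1: 10, 20, 30, 40; study 2: 15, 30, 45, 60).
#'
#' @param config A [study_config()].
#' @return Integer vector of trial indices.
#' @export
rating_probe_indices <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seq.int(config$rating_interval, config$n_trials,
          by = config$rating_interval)
}
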