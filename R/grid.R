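#' Place hidden safe spaces on the grid
#'
#' Samples `n_safe` distinct cells uniformly without replacement from the
#' grid minus `excluded` (the start cell is always excluded by the test
#' runner so no trial can begin already solved). Deterministic given the
#' seed.
#'
#' @param grid A [grid_config()].
#' @param excluded Integer vector of excluded cells (`row * size + col`,
#'   0-based).
#' @param seed Integer seed.
#' @return Sorted integer vector of `n_safe` cell codes.
#' @examples
#' g <- grid_config()
#' place_safe_spaces(g, excluded = 7L * 15L + 7L, seed = 1)
#' @export
place_safe_spaces <- function(grid, excluded = integer(0), seed) {
  stopifnot(inherits(grid, "grid_config"))
  cells <- setdiff(0:(grid$size^2 - 1L), as.integer(excluded))
  if (length(cells) < grid$n_safe) {
    stop(sprintf("cannot place %d safe spaces on %d eligible cells",
                 grid$n_safe, length(cells)), call. = FALSE)
  }
  sort(with_seed(seed, sample(cells, grid$n_safe)))
}

#' Apply one move on the grid
#'
#' One-cell orthogonal displacement; a move off the edge leaves the
#' position unchanged (but still counts as a key press in the activity
#' metrics).
#'
#' @param position Length-2 integer vector `c(row, col)`, 0-based.
#' @param move Move code 1-4 or name `"up"`, `"down"`, `"left"`, `"right"`.
#' @param size Grid side length.
#' @return The new `c(row, col)`.
#' @examples
#' apply_move(c(7, 7), "up")    # c(6, 7)
#' apply_move(c(0, 3), "up")    # clamped: c(0, 3)
#' @export
apply_move <- function(position, move, size = 15L) {
  if (is.character(move)) move <- match(move, MOVE_NAMES)
  if (is.na(move) || !(move %in% 1:4)) {
    stop("invalid move token", call. = FALSE)
  }
  row <- position[1L]; col <- position[2L]
  if (row < 0 || row >= size || col < 0 || col >= size) {
    stop("position off the grid", call. = FALSE)
  }
  switch(move,
         c(max(row - 1L, 0L), col),
         c(min(row + 1L, size - 1L), col),
         c(row, max(col - 1L, 0L)),
         c(row, min(col + 1L, size - 1L)))
}

#' Run one phase (exploration or stress) on the grid
#'
#' Queries the navigation policy every `move_interval` seconds until the
#' phase duration elapses or, in the stress phase, a safe cell is entered.
#' Entering a safe cell reveals it (it "lights up green") in both phases
#' and adds it to (or rehearses it in) the agent's memory; standing on a
#' remembered cell that is no longer safe marks it as tried for this
#' phase and — for non-perseverative policies — removes it from memory.
#' If a stress phase starts on a safe cell the escape is immediate
#' (latency 0, no moves).
#'
#' @param start Length-2 integer `c(row, col)`, 0-based.
#' @param nav A [new_nav_state()] (mutated: memory, sweep progress).
#' @param safes Integer vector of safe cell codes.
#' @param duration Phase duration cap in seconds.
#' @param stress Is this a stress phase?
#' @return A list of class `trajectory` with `events` (data frame: `t`,
#'   `move`, `row`, `col`, `on_safe`), `start`, `escaped`,
#'   `escape_latency`, `phase_duration`, `n_moves`, `n_unique` (distinct
#'   cells including the start), `end` position.
#' @export
run_phase <- function(start, nav, safes, duration, stress) {
  core <- run_phase_core(start, nav, safes, duration, stress)
  idx <- seq_len(core$n_moves)
  structure(list(
    events = data.frame(t = core$t[idx], move = MOVE_NAMES[core$mv[idx]],
                        row = core$row[idx], col = core$col[idx],
                        on_safe = core$on_safe[idx],
                        stringsAsFactors = FALSE),
    start = core$start,
    phase = core$phase,
    escaped = core$escaped,
    escape_latency = core$escape_latency,
    phase_duration = core$phase_duration,
    n_moves = core$n_moves,
    n_unique = core$n_unique,
    end = core$end
  ), class = "trajectory")
}

run_phase_core <- function(start, nav, safes, duration, stress) {
  stopifnot(duration > 0)
  size <- nav$size
  n_steps <- as.integer(floor(duration / nav$interval + 1e-9))
  t_v <- numeric(n_steps); mv_v <- integer(n_steps)
  row_v <- integer(n_steps); col_v <- integer(n_steps)
  safe_v <- logical(n_steps)
  visited <- logical(size^2)
  row <- as.integer(start[1L]); col <- as.integer(start[2L])
  visited[row * size + col + 1L] <- TRUE
  phase <- if (stress) "stress" else "explore"
  nav$pursuit <- 0L
  nav$inactive <- integer(0)
  # rotate the initial heading over phases so undirected search fans out
  # into a different grid sector each phase instead of retracing one
  nav$last_move <- (2L * nav$trial_no + as.integer(stress)) %% 4L + 1L
  escaped <- FALSE; latency <- NA_real_; k <- 0L

  observe_stale <- function(cell) {
    # standing on a remembered cell that is not lit: mark it tried for
    # this phase; sticky memories (perseveration) survive the observation
    nav$inactive <- c(nav$inactive, cell)
    if (!nav$sticky_memory) nav_drop_known(nav, cell)
  }

  start_cell <- row * size + col
  if (start_cell %in% safes) {
    nav_note_safe(nav, start_cell, stress)
    if (stress) { escaped <- TRUE; latency <- 0 }
  } else if (start_cell %in% nav$known) {
    observe_stale(start_cell)
  }

  if (!escaped) {
    for (step in seq_len(n_steps)) {
      mv <- nav_policy_step(nav, row, col, phase, safes)
      if (mv == 1L) row <- max(row - 1L, 0L)
      else if (mv == 2L) row <- min(row + 1L, size - 1L)
      else if (mv == 3L) col <- max(col - 1L, 0L)
      else col <- min(col + 1L, size - 1L)
      k <- step
      t_v[k] <- step * nav$interval
      mv_v[k] <- mv; row_v[k] <- row; col_v[k] <- col
      cell <- row * size + col
      visited[cell + 1L] <- TRUE
      if (cell %in% safes) {
        safe_v[k] <- TRUE
        nav_note_safe(nav, cell, stress)
        if (stress) { escaped <- TRUE; latency <- t_v[k]; break }
      } else if (cell %in% nav$known && !(cell %in% nav$inactive)) {
        observe_stale(cell)
      }
    }
  }

  list(t = t_v, mv = mv_v, row = row_v, col = col_v, on_safe = safe_v,
       start = c(start[1L], start[2L]),
       phase = phase,
       escaped = escaped,
       escape_latency = latency,
       phase_duration = if (escaped) latency else duration,
       n_moves = k,
       n_unique = sum(visited),
       end = c(row, col))
}

#' Run a full escape behaviour test for one agent
#'
#' Executes the grid task of the given study variant: `"study1"` — one
#' block of five trials, start at the grid centre (7, 7), 10-s exploration
#' then a stress phase capped at 20 s, the stress phase starting where
#' exploration ended, one fixed safe layout; `"study2"` — two blocks of
#' five trials, 5-s phases, position reset to the centre at every phase
#' start, and safe spaces relocated to fresh random cells for block 2.
#' The agent's memory of safe locations persists across trials and,
#' stale, across the block-2 relocation; survival of a remembered
#' location over a trial transition follows the tiered memory model of
#' [agent_spec()] (consolidated vs fresh vs stress-encoded).
#'
#' @param agent An [agent_spec()].
#' @param variant `"study1"` or `"study2"`.
#' @param seed Integer seed.
#' @param participant_id Identifier copied into the record.
#' @param grid Optional [grid_config()] override.
#' @return An object of class `escape_test_record`: list with `phases`
#'   (one summary row per phase), `moves` (one row per key press),
#'   `layouts` (safe cells per block), `variant`, `participant_id`,
#'   `seed`. If the block-2 layout happens to equal block 1 by chance the
#'   record carries `layout_repeat = TRUE`.
#' @export
run_escape_test <- function(agent, variant = c("study1", "study2"), seed,
                            participant_id = "P1", grid = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(agent, "agent_spec"))
  if (is.null(grid)) grid <- grid_defaults(if (variant == "study1") 1L else 2L)
  size <- grid$size
  centre <- c(size %/% 2L, size %/% 2L)
  centre_cell <- centre[1L] * size + centre[2L]

  layouts <- vector("list", grid$n_blocks)
  layouts[[1L]] <- place_safe_spaces(grid, excluded = centre_cell,
                                     seed = derive_seed(seed, "layout", 1L))
  if (grid$n_blocks > 1L) {
    for (b in 2:grid$n_blocks) {
      layouts[[b]] <- if (grid$relocate_safes_between_blocks) {
        place_safe_spaces(grid, excluded = centre_cell,
                          seed = derive_seed(seed, "layout", b))
      } else layouts[[1L]]
    }
  }
  layout_repeat <- grid$n_blocks > 1L &&
    grid$relocate_safes_between_blocks &&
    identical(layouts[[1L]], layouts[[2L]])

  nav <- new_nav_state(agent, size)
  n_ph <- grid$n_blocks * grid$n_trials_per_block * 2L
  p_block <- integer(n_ph); p_trial <- integer(n_ph)
  p_phase <- character(n_ph); p_srow <- integer(n_ph)
  p_scol <- integer(n_ph); p_dur <- numeric(n_ph)
  p_esc <- logical(n_ph); p_lat <- numeric(n_ph)
  p_moves <- integer(n_ph); p_uni <- integer(n_ph)
  mv_chunks <- vector("list", n_ph)
  pi <- 0L
  with_seed(derive_seed(seed, "nav"), {
    first_trial <- TRUE
    for (b in seq_len(grid$n_blocks)) {
      safes <- layouts[[b]]
      for (tr in seq_len(grid$n_trials_per_block)) {
        if (!first_trial) {
          nav_forget(nav)
          nav$trial_no <- nav$trial_no + 1L
        }
        first_trial <- FALSE
        pos <- centre
        for (ph in c("explore", "stress")) {
          stress <- ph == "stress"
          if (stress && grid$reset_between_phases) pos <- centre
          traj <- run_phase_core(
            pos, nav, safes,
            if (stress) grid$stress_cap else grid$explore_duration, stress)
          pos <- traj$end
          pi <- pi + 1L
          p_block[pi] <- b; p_trial[pi] <- tr; p_phase[pi] <- ph
          p_srow[pi] <- traj$start[1L]; p_scol[pi] <- traj$start[2L]
          p_dur[pi] <- traj$phase_duration
          p_esc[pi] <- if (stress) traj$escaped else NA
          p_lat[pi] <- if (stress) traj$escape_latency else NA_real_
          p_moves[pi] <- traj$n_moves; p_uni[pi] <- traj$n_unique
          if (traj$n_moves > 0L) {
            idx <- seq_len(traj$n_moves)
            mv_chunks[[pi]] <- list(
              block = rep.int(b, traj$n_moves),
              trial = rep.int(tr, traj$n_moves),
              phase = rep.int(ph, traj$n_moves),
              t = traj$t[idx], move = traj$mv[idx],
              row = traj$row[idx], col = traj$col[idx],
              on_safe = traj$on_safe[idx])
          }
        }
      }
    }
  })
  mv_chunks <- mv_chunks[!vapply(mv_chunks, is.null, logical(1))]
  gather <- function(f) unlist(lapply(mv_chunks, `[[`, f),
                               use.names = FALSE)
  moves <- if (!length(mv_chunks)) {
    data.frame(block = integer(0), trial = integer(0),
               phase = character(0), t = numeric(0), move = character(0),
               row = integer(0), col = integer(0), on_safe = logical(0),
               stringsAsFactors = FALSE)
  } else data.frame(
    block = as.integer(gather("block")), trial = as.integer(gather("trial")),
    phase = gather("phase"), t = gather("t"),
    move = MOVE_NAMES[gather("move")],
    row = as.integer(gather("row")), col = as.integer(gather("col")),
    on_safe = gather("on_safe"), stringsAsFactors = FALSE)
  structure(list(
    participant_id = participant_id,
    variant = variant,
    grid = grid,
    layouts = layouts,
    layout_repeat = layout_repeat,
    phases = data.frame(
      block = p_block, trial = p_trial, phase = p_phase,
      start_row = p_srow, start_col = p_scol, duration = p_dur,
      escaped = p_esc, escape_latency = p_lat, n_moves = p_moves,
      n_unique = p_uni, stringsAsFactors = FALSE),
    moves = moves,
    seed = seed
  ), class = "escape_test_record")
}

#' @export
print.escape_test_record <- function(x, ...) {
  st <- x$phases[x$phases$phase == "stress", ]
  cat(sprintf("<escape_test_record '%s'> %s: %d blocks, %d stress trials, %d escapes\n",
              x$participant_id, x$variant, x$grid$n_blocks, nrow(st),
              sum(st$escaped)))
  invisible(x)
}
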