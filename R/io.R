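# CSV round-trip helpers ----------------------------------------------------
# numeric fields are serialised with %.17g so read(write(x)) == x exactly

fmt_cell <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
  } else if (is.logical(x)) {
    ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
  } else {
    x <- as.character(x)
    ifelse(is.na(x), "NA",
           ifelse(grepl('[",\n]', x),
                  paste0('"', gsub('"', '""', x), '"'), x))
  }
}

write_csv_exact <- function(df, path) {
  cols <- lapply(df, fmt_cell)
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
}

read_csv_exact <- function(path, col_classes) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = "NA")
  for (nm in names(col_classes)) {
    if (!nm %in% names(df)) {
      stop(sprintf("schema mismatch in %s: missing column '%s'",
                   basename(path), nm), call. = FALSE)
    }
    df[[nm]] <- switch(col_classes[[nm]],
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       logical = as.logical(df[[nm]]),
                       character = as.character(df[[nm]]))
  }
  df
}

flatten_config <- function(config) {
  g <- config$grid
  c(study = config$study,
    n_trials = config$n_trials,
    cue_set = paste(config$cue_set, collapse = ";"),
    pre_cue_duration = sprintf("%.17g", config$pre_cue_duration),
    response_window = sprintf("%.17g", config$response_window),
    max_duration_base = sprintf("%.17g", config$max_duration_base),
    max_duration_decrement = sprintf("%.17g", config$max_duration_decrement),
    decrement_interval = config$decrement_interval,
    iti_base = sprintf("%.17g", config$iti_base),
    iti_jitter = sprintf("%.17g", config$iti_jitter),
    rating_interval = config$rating_interval,
    rating_items = paste(config$rating_items, collapse = ";"),
    n_shocks_per_precue = config$n_shocks_per_precue,
    grid.size = g$size, grid.n_safe = g$n_safe,
    grid.n_blocks = g$n_blocks,
    grid.n_trials_per_block = g$n_trials_per_block,
    grid.explore_duration = sprintf("%.17g", g$explore_duration),
    grid.stress_cap = sprintf("%.17g", g$stress_cap),
    grid.reset_between_phases = g$reset_between_phases,
    grid.relocate_safes_between_blocks = g$relocate_safes_between_blocks)
}

unflatten_config <- function(kv) {
  num <- function(x) as.numeric(x)
  study_config(
    as.integer(kv[["study"]]),
    n_trials = as.integer(kv[["n_trials"]]),
    cue_set = strsplit(kv[["cue_set"]], ";", fixed = TRUE)[[1]],
    pre_cue_duration = num(kv[["pre_cue_duration"]]),
    response_window = num(kv[["response_window"]]),
    max_duration_base = num(kv[["max_duration_base"]]),
    max_duration_decrement = num(kv[["max_duration_decrement"]]),
    decrement_interval = as.integer(kv[["decrement_interval"]]),
    iti_base = num(kv[["iti_base"]]),
    iti_jitter = num(kv[["iti_jitter"]]),
    rating_interval = as.integer(kv[["rating_interval"]]),
    rating_items = strsplit(kv[["rating_items"]], ";", fixed = TRUE)[[1]],
    n_shocks_per_precue = as.integer(kv[["n_shocks_per_precue"]]),
    grid = grid_config(
      size = as.integer(kv[["grid.size"]]),
      n_safe = as.integer(kv[["grid.n_safe"]]),
      n_blocks = as.integer(kv[["grid.n_blocks"]]),
      n_trials_per_block = as.integer(kv[["grid.n_trials_per_block"]]),
      explore_duration = num(kv[["grid.explore_duration"]]),
      stress_cap = num(kv[["grid.stress_cap"]]),
      reset_between_phases = as.logical(kv[["grid.reset_between_phases"]]),
      relocate_safes_between_blocks =
        as.logical(kv[["grid.relocate_safes_between_blocks"]])))
}

#' Write a session record to CSV logs
#'
#' Serialises one stress-induction session into three plain-text files
#' under `dir`: `<id>_trials.csv` (one row per trial),
#' `<id>_ratings.csv` (one row per probe x item) and `<id>_meta.csv`
#' (key/value pairs: identifiers, seed, affect scores, truth map, and the
#' flattened configuration). Numeric fields keep full precision so
#' [read_session()] restores the record exactly.
#'
#' @param session A [simulate_session()] record.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- session$participant_id
  paths <- file.path(dir, paste0(id, c("_trials.csv", "_ratings.csv",
                                       "_meta.csv")))
  write_csv_exact(session$trials, paths[1])
  write_csv_exact(session$ratings, paths[2])
  meta <- c(participant_id = id,
            condition = session$condition,
            study = session$study,
            seed = sprintf("%.0f", session$seed),
            agent_label = session$agent_label,
            truth_map = if (is.null(session$truth_map)) "" else
              paste(names(session$truth_map), session$truth_map,
                    sep = "=", collapse = ";"),
            stats::setNames(sprintf("%.17g", session$affect$pre),
                            paste0("affect_pre.", session$affect$score)),
            stats::setNames(sprintf("%.17g", session$affect$post),
                            paste0("affect_post.", session$affect$score)),
            flatten_config(session$config))
  write_csv_exact(data.frame(key = names(meta), value = unname(meta),
                             stringsAsFactors = FALSE), paths[3])
  invisible(paths)
}

#' Read a session record back from CSV logs
#'
#' Inverse of [write_session()]: `read_session(dir, id)` restores the
#' exact record, including the configuration. Unknown extra columns in
#' the trial log are preserved (forward compatibility); missing expected
#' columns raise a schema error naming the column.
#'
#' @param dir Directory holding the three CSV files.
#' @param participant_id Participant identifier (file prefix).
#' @return A `session_record`.
#' @export
read_session <- function(dir, participant_id) {
  paths <- file.path(dir, paste0(participant_id,
                                 c("_trials.csv", "_ratings.csv",
                                   "_meta.csv")))
  trials <- read_csv_exact(paths[1], c(
    trial = "integer", condition = "character", cue = "character",
    cue_onset = "numeric", rt = "numeric", button = "character",
    correct = "logical", stress_duration = "numeric",
    terminated = "logical", max_duration = "numeric", iti = "numeric"))
  ratings <- read_csv_exact(paths[2], c(
    after_trial = "integer", probe = "integer", item = "character",
    value = "integer"))
  meta_df <- read_csv_exact(paths[3], c(key = "character",
                                        value = "character"))
  meta <- stats::setNames(meta_df$value, meta_df$key)
  need <- c("participant_id", "condition", "study", "seed")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("schema mismatch in meta: missing key(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  config <- unflatten_config(meta)
  scores <- sub("^affect_pre\\.", "",
                grep("^affect_pre\\.", names(meta), value = TRUE))
  affect <- data.frame(
    score = scores,
    pre = as.numeric(meta[paste0("affect_pre.", scores)]),
    post = as.numeric(meta[paste0("affect_post.", scores)]),
    stringsAsFactors = FALSE)
  truth_map <- NULL
  if ("truth_map" %in% names(meta) && !is.na(meta[["truth_map"]]) &&
      nzchar(meta[["truth_map"]])) {
    kv <- strsplit(strsplit(meta[["truth_map"]], ";", fixed = TRUE)[[1]],
                   "=", fixed = TRUE)
    truth_map <- stats::setNames(vapply(kv, `[`, "", 2),
                                 vapply(kv, `[`, "", 1))
  }
  structure(list(
    participant_id = unname(meta[["participant_id"]]),
    condition = unname(meta[["condition"]]),
    study = as.integer(meta[["study"]]),
    config = config,
    trials = trials,
    ratings = ratings,
    affect = affect,
    truth_map = truth_map,
    agent_label = if ("agent_label" %in% names(meta))
      unname(meta[["agent_label"]]) else NA_character_,
    seed = as.numeric(meta[["seed"]])
  ), class = "session_record")
}

#' Write an escape-test record to CSV logs
#'
#' Three files per participant: `<id>_moves.csv` (one row per key press:
#' block, trial, phase, timestamp, move, resulting row/col, on_safe flag),
#' `<id>_phases.csv` (one summary row per phase) and `<id>_layout.csv`
#' (safe cells per block).
#'
#' @param record An [run_escape_test()] record.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_escape_test <- function(record, dir) {
  stopifnot(inherits(record, "escape_test_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- record$participant_id
  paths <- file.path(dir, paste0(id, c("_moves.csv", "_phases.csv",
                                       "_layout.csv")))
  write_csv_exact(record$moves, paths[1])
  write_csv_exact(record$phases, paths[2])
  size <- record$grid$size
  layout <- do.call(rbind, lapply(seq_along(record$layouts), function(b) {
    cells <- record$layouts[[b]]
    data.frame(block = b, cell = cells, row = cells %/% size,
               col = cells %% size)
  }))
  write_csv_exact(layout, paths[3])
  invisible(paths)
}

#' Read an escape-test record's logs
#'
#' Restores the `moves`, `phases` and `layouts` tables written by
#' [write_escape_test()]. The full record object additionally needs the
#' grid configuration, which the caller supplies (it is part of the run
#' manifest, not of the per-participant logs).
#'
#' @param dir Directory holding the CSV files.
#' @param participant_id Participant identifier.
#' @return A list with `moves`, `phases`, `layouts`.
#' @export
read_escape_test <- function(dir, participant_id) {
  paths <- file.path(dir, paste0(participant_id,
                                 c("_moves.csv", "_phases.csv",
                                   "_layout.csv")))
  moves <- read_csv_exact(paths[1], c(
    block = "integer", trial = "integer", phase = "character",
    t = "numeric", move = "character", row = "integer", col = "integer",
    on_safe = "logical"))
  phases <- read_csv_exact(paths[2], c(
    block = "integer", trial = "integer", phase = "character",
    start_row = "integer", start_col = "integer", duration = "numeric",
    escaped = "logical", escape_latency = "numeric", n_moves = "integer",
    n_unique = "integer"))
  layout <- read_csv_exact(paths[3], c(block = "integer", cell = "integer",
                                       row = "integer", col = "integer"))
  layouts <- lapply(sort(unique(layout$block)),
                    function(b) layout$cell[layout$block == b])
  list(moves = moves, phases = phases, layouts = layouts)
}

#' Write a run manifest
#'
#' Records what produced a directory of outputs: package version, the
#' command, the root seed, the flattened configuration, and an inventory
#' of every output file with its MD5 checksum. Re-running the same
#' command with the same seed reproduces files with identical checksums.
#'
#' @param dir Output directory (manifest written as `MANIFEST.dcf`).
#' @param command Free-text command description.
#' @param config A [study_config()] or `NULL`.
#' @param seed Root seed.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, command, config = NULL, seed = NA) {
  files <- setdiff(list.files(dir, recursive = TRUE), "MANIFEST.dcf")
  sums <- tools::md5sum(file.path(dir, files))
  fields <- list(
    Package = "shuttlebox",
    Version = as.character(utils::packageVersion("shuttlebox")),
    Command = command,
    Seed = sprintf("%.0f", seed),
    Config = if (is.null(config)) "" else
      paste(names(flatten_config(config)), flatten_config(config),
            sep = "=", collapse = "; "),
    Files = paste(sprintf("%s %s", unname(sums), files), collapse = "\n ")
  )
  path <- file.path(dir, "MANIFEST.dcf")
  write.dcf(do.call(data.frame, c(fields, stringsAsFactors = FALSE,
                                  check.names = FALSE)), path)
  invisible(path)
}
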