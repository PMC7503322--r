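#' Simulate a complete multi-group experiment
#'
#' Runs a full cohort through the stress induction and the escape
#' behaviour test of a study variant. Study 1 pairs each yoked participant
#' one-to-one with the same-numbered escapable participant (so
#' `n_yc <= n_ec`) and includes a no-stress control group; study 2
#' pseudo-yokes every YC participant to the shuffled per-trial mean
#' durations of the whole EC pool and has no control group. Per-participant
#' seeds, yoking seeds and grid seeds are derived from the root seed, so
#' the experiment is a pure function of its arguments.
#'
#' @param study 1 or 2.
#' @param n_ec,n_yc,n_cc Group sizes (`n_cc` is ignored for study 2).
#' @param seed Root seed.
#' @param agents Named list of [agent_spec()]s per condition; defaults to
#'   the shipped presets.
#' @param config Optional [study_config()] override.
#' @return An object of class `experiment`: list with `sessions` (named
#'   list of session records), `escape_tests`, `acute` (per-participant
#'   session metrics), `escape` (per-participant x block escape metrics),
#'   `study`, `config`, `seed`.
#' @examples
#' ex <- simulate_experiment(2, n_ec = 6, n_yc = 4, seed = 1)
#' head(ex$escape)
#' @export
simulate_experiment <- function(study, n_ec, n_yc, n_cc = 0, seed,
                                agents = NULL, config = NULL) {
  if (is.null(config)) config <- study_config(study)
  study <- config$study
  if (is.null(agents)) {
    agents <- list(EC = agent_preset("ec_like"),
                   YC = agent_preset("yc_like"),
                   CC = agent_preset("cc_like"))
  }
  if (study == 2L) n_cc <- 0
  if (study == 1L && n_yc > n_ec) {
    stop("study 1 yokes one-to-one: n_yc must not exceed n_ec",
         call. = FALSE)
  }
  variant <- if (study == 1L) "study1" else "study2"
  ids <- c(sprintf("EC%02d", seq_len(n_ec)),
           sprintf("YC%02d", seq_len(n_yc)),
           if (n_cc > 0) sprintf("CC%02d", seq_len(n_cc)))
  conds <- c(rep("EC", n_ec), rep("YC", n_yc), rep("CC", n_cc))

  # each participant is an individual draw from the preset population
  indiv <- lapply(seq_along(ids), function(i)
    sample_participant(agents[[conds[i]]], derive_seed(seed, "pop", i)))

  sessions <- vector("list", length(ids)); names(sessions) <- ids
  for (i in seq_len(n_ec)) {
    sessions[[i]] <- simulate_session("EC", indiv[[i]], config,
                                      derive_seed(seed, "participant", i),
                                      participant_id = ids[i])
  }
  ec_sessions <- sessions[seq_len(n_ec)]
  for (j in seq_len(n_yc)) {
    i <- n_ec + j
    yoke <- if (study == 1L) {
      derive_yoked_schedule(ec_sessions[[j]], derive_seed(seed, "yoke", j))
    } else {
      derive_pseudo_yoked_schedule(ec_sessions, derive_seed(seed, "yoke", j))
    }
    sessions[[i]] <- simulate_session("YC", indiv[[i]], config,
                                      derive_seed(seed, "participant", i),
                                      participant_id = ids[i], yoke = yoke)
  }
  if (n_cc > 0) {
    for (j in seq_len(n_cc)) {
      i <- n_ec + n_yc + j
      sessions[[i]] <- simulate_session("CC", indiv[[i]], config,
                                        derive_seed(seed, "participant", i),
                                        participant_id = ids[i])
    }
  }

  escape_tests <- vector("list", length(ids)); names(escape_tests) <- ids
  for (i in seq_along(ids)) {
    escape_tests[[i]] <- run_escape_test(
      indiv[[i]], variant, derive_seed(seed, "grid", i),
      participant_id = ids[i], grid = config$grid)
  }

  acute <- do.call(rbind, lapply(sessions, session_metrics))
  rownames(acute) <- NULL
  escape <- do.call(rbind, lapply(seq_along(ids), function(i) {
    m <- escape_metrics(escape_tests[[i]])
    m$condition <- conds[i]
    m[, c("participant", "condition", setdiff(names(m),
                                              c("participant", "condition")))]
  }))
  rownames(escape) <- NULL

  structure(list(sessions = sessions, escape_tests = escape_tests,
                 acute = acute, escape = escape, study = study,
                 config = config, seed = seed),
            class = "experiment")
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf("<experiment> study %d, seed %s: %s\n", x$study,
              format(x$seed),
              paste(sprintf("%s n=%d", names(table(x$acute$condition)),
                            table(x$acute$condition)), collapse = ", ")))
  invisible(x)
}

rating_long <- function(experiment, item) {
  do.call(rbind, lapply(experiment$sessions, function(s) {
    r <- s$ratings[s$ratings$item == item, ]
    if (!nrow(r)) return(NULL)
    data.frame(participant = s$participant_id, condition = s$condition,
               probe = r$probe, value = r$value, stringsAsFactors = FALSE)
  }))
}

affect_long <- function(experiment, score) {
  a <- experiment$acute
  pre <- a[[paste0(score, "_pre")]]
  post <- a[[paste0(score, "_post")]]
  data.frame(participant = rep(a$participant, 2),
             condition = rep(a$condition, 2),
             time = rep(c("1pre", "2post"), each = nrow(a)),
             value = c(pre, post), stringsAsFactors = FALSE)
}

report_row <- function(section, variable, effect, sr, p_adj = NA_real_,
                       correction = NULL, n_used = NA_integer_,
                       n_excluded = 0L) {
  df <- as.data.frame(sr)
  data.frame(section = section, variable = variable, effect = effect,
             test = df$test, statistic = df$statistic, df1 = df$df1,
             df2 = df$df2, p = df$p,
             p_adj = if (is.na(p_adj)) df$p else p_adj,
             correction = if (is.null(correction)) df$correction else
               correction,
             effect_kind = df$effect_kind, effect_size = df$effect,
             epsilon_gg = df$epsilon_gg, n_used = n_used,
             n_excluded = n_excluded, stringsAsFactors = FALSE)
}

outlier_filter <- function(values) {
  # returns a keep-mask applying the extreme-outlier fence where defined
  if (sum(is.finite(values)) < 4L) return(!is.na(values))
  m <- extreme_outlier_mask(values)
  !is.na(m) & m
}

screen_rm_values <- function(data, value) {
  # extreme-outlier screening before a repeated-measures analysis: values
  # outside the 3 IQR fence (pooled over groups and within-levels) are set
  # missing, which drops the subject listwise in mixed_rm_anova()
  vals <- data[[value]]
  if (sum(is.finite(vals)) >= 4L) {
    m <- extreme_outlier_mask(vals)
    vals[!is.na(m) & !m] <- NA_real_
    data[[value]] <- vals
  }
  data
}

#' Full analysis report of a simulated experiment
#'
#' Reproduces the paradigm's analysis layout on simulated data:
#' manipulation checks (group x probe rmANOVA on aversiveness and
#' perceived-control ratings), the acute-phase family (helplessness,
#' exhaustion, frustration where present, and reaction time; t-tests for
#' two groups, one-way ANOVA/Kruskal-Wallis for three; Bonferroni over
#' the family), the affect family (group x time rmANOVA on STADI total
#' and PANAS positive/negative; Bonferroni over the three scores), and
#' the escape-behaviour family (study 2: group x block rmANOVA on
#' exploration, escapes, efficiency; study 1: Kruskal-Wallis; Bonferroni
#' over the three metrics). Extreme outliers are excluded per variable
#' before the univariate tests; participants with an undefined efficiency
#' in any block are dropped listwise from the efficiency rmANOVA and
#' counted in the report.
#'
#' The Bonferroni family memberships (each phase's dependent variables
#' form one family) are this package's documented choice; the rule, not
#' the composition, is prescribed by the paradigm.
#'
#' @param experiment A [simulate_experiment()] result.
#' @return Data frame with one row per reported effect.
#' @export
analysis_report <- function(experiment) {
  stopifnot(inherits(experiment, "experiment"))
  acute <- experiment$acute
  study <- experiment$study
  two_groups <- study == 2L
  rows <- list()

  # -- manipulation checks: group x probe rmANOVAs on ratings -------------
  for (item in c("aversiveness", "control")) {
    rl <- rating_long(experiment, item)
    if (item == "aversiveness") rl <- rl[rl$condition != "CC", ]
    if (length(unique(rl$condition)) < 2L) next
    rm <- mixed_rm_anova(rl, "value", "participant", "condition", "probe")
    for (eff in names(rm)) {
      rows[[length(rows) + 1L]] <- report_row(
        "manipulation", item, eff, rm[[eff]],
        n_used = attr(rm, "n_used"))
    }
  }

  # -- acute family: ratings + RT ----------------------------------------
  acute_vars <- intersect(
    c("rating_helplessness", "rating_exhaustion", "rating_frustration",
      "mean_rt"), names(acute))
  m_acute <- length(acute_vars)
  for (v in acute_vars) {
    vals <- acute[[v]]
    keep <- outlier_filter(vals)
    if (v == "mean_rt") keep <- keep & !acute$all_miss
    sr <- if (two_groups) {
      t_test_two_sample(vals[keep & acute$condition == "EC"],
                        vals[keep & acute$condition == "YC"])
    } else if (v %in% c("rating_helplessness", "rating_frustration")) {
      kruskal_wallis(vals[keep], acute$condition[keep])
    } else {
      anova_oneway(vals[keep], acute$condition[keep])
    }
    rows[[length(rows) + 1L]] <- report_row(
      "acute", sub("^rating_", "", v), "group", sr,
      p_adj = bonferroni_family(sr$p, m_acute), correction = "bonferroni",
      n_used = sum(keep), n_excluded = sum(!keep))
  }

  # -- affect family: group x time rmANOVAs ------------------------------
  affect_scores <- c("STADI", "PANASpos", "PANASneg")
  for (sc in affect_scores) {
    al <- affect_long(experiment, sc)
    rm <- mixed_rm_anova(al, "value", "participant", "condition", "time")
    for (eff in names(rm)) {
      sr <- rm[[eff]]
      rows[[length(rows) + 1L]] <- report_row(
        "affect", sc, eff, sr,
        p_adj = bonferroni_family(sr$p, length(affect_scores)),
        correction = "bonferroni", n_used = attr(rm, "n_used"))
    }
  }

  # -- escape family ------------------------------------------------------
  esc <- experiment$escape
  esc_vars <- c("exploration_per_min", "escapes", "efficiency")
  for (v in esc_vars) {
    if (study == 2L) {
      rm <- mixed_rm_anova(screen_rm_values(esc, v), v, "participant",
                           "condition", "block")
      for (eff in names(rm)) {
        sr <- rm[[eff]]
        rows[[length(rows) + 1L]] <- report_row(
          "escape", v, eff, sr,
          p_adj = bonferroni_family(sr$p, length(esc_vars)),
          correction = "bonferroni", n_used = attr(rm, "n_used"),
          n_excluded = attr(rm, "n_dropped"))
      }
    } else {
      vals <- esc[[v]]
      keep <- !is.na(vals) & outlier_filter(vals)
      sr <- kruskal_wallis(vals[keep], esc$condition[keep])
      rows[[length(rows) + 1L]] <- report_row(
        "escape", v, "group", sr,
        p_adj = bonferroni_family(sr$p, length(esc_vars)),
        correction = "bonferroni", n_used = sum(keep),
        n_excluded = sum(!keep))
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate the efficiency group-by-block interaction experiment
#'
#' Repeatedly simulates the full study-2 pipeline (`n_ec` escapable-like
#' vs `n_yc` yoked-like participants through stress induction and the
#' two-block escape test) and tests the efficiency group x block
#' interaction, Bonferroni-corrected over the three escape metrics. Used
#' to check that the preset phenotypes reliably reproduce the paradigm's
#' qualitative signature: a significant interaction with the yoked group
#' worsening (higher efficiency scores, i.e. less efficient) from block 1
#' to block 2.
#'
#' @param n_reps Number of replicate experiments.
#' @param n_ec,n_yc Group sizes.
#' @param seed Root seed; replicate r uses `derive_seed(seed, "rep", r)`.
#' @param alpha Family-wise significance level.
#' @return Data frame with one row per replicate: interaction `F`, raw and
#'   Bonferroni-adjusted p, the block means of YC efficiency, and logical
#'   `significant`, `yc_worsened`, `success`.
#' @export
replicate_efficiency_interaction <- function(n_reps = 100, n_ec = 50,
                                             n_yc = 50, seed = 1,
                                             alpha = 0.05) {
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ex <- simulate_experiment(2, n_ec = n_ec, n_yc = n_yc,
                              seed = derive_seed(seed, "rep", r))
    rm <- mixed_rm_anova(screen_rm_values(ex$escape, "efficiency"),
                         "efficiency", "participant", "condition", "block")
    inter <- rm$interaction
    p_adj <- bonferroni_family(inter$p, 3)
    yc <- ex$escape[ex$escape$condition == "YC", ]
    yc_wide <- merge(yc[yc$block == 1, c("participant", "efficiency")],
                     yc[yc$block == 2, c("participant", "efficiency")],
                     by = "participant", suffixes = c("_b1", "_b2"))
    cc <- stats::complete.cases(yc_wide)
    m1 <- mean(yc_wide$efficiency_b1[cc])
    m2 <- mean(yc_wide$efficiency_b2[cc])
    sig <- p_adj < alpha
    wors <- m2 > m1
    out[[r]] <- data.frame(rep = r, F = inter$statistic, p = inter$p,
                           p_adj = p_adj, yc_eff_b1 = m1, yc_eff_b2 = m2,
                           significant = sig, yc_worsened = wors,
                           success = sig && wors)
  }
  do.call(rbind, out)
}
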