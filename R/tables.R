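#' Printed a-priori group-comparison summaries
#'
#' The published group-comparison tables of the two studies, transcribed
#' as structured inputs: per-group sample sizes, sex counts, and the
#' mean (SD) rows for age, working-memory IQ, alertness (study 1) and
#' age, education (study 2). Sex counts are reconstructed from the
#' printed percentages and group sizes (e.g. 56% of 27 -> 15 female).
#' These are inputs for worked-example statistics, not simulated data.
#'
#' @return A list with elements `study1` and `study2`, each containing
#'   `sex` (2 x k count matrix) and one [group_summary()] per continuous
#'   variable.
#' @export
apriori_summaries <- function() {
  list(
    study1 = list(
      groups = c("EC", "YC", "CC"),
      n = c(27L, 26L, 27L),
      sex = rbind(female = c(EC = 15, YC = 15, CC = 15),
                  male   = c(EC = 12, YC = 11, CC = 12)),
      age = group_summary(c("EC", "YC", "CC"), n = c(27, 26, 27),
                          mean = c(23.48, 25, 25.85),
                          sd = c(3.74, 4.26, 4.3)),
      iq = group_summary(c("EC", "YC", "CC"), n = c(27, 26, 27),
                         mean = c(100.89, 104.58, 104.3),
                         sd = c(9.55, 11.53, 13.99)),
      alertness = group_summary(c("EC", "YC", "CC"), n = c(27, 26, 27),
                                mean = c(45.3, 43.96, 42.11),
                                sd = c(6.31, 6.99, 6.31))
    ),
    study2 = list(
      groups = c("EC", "YC"),
      n = c(62L, 38L),
      sex = rbind(female = c(EC = 33, YC = 22),
                  male   = c(EC = 29, YC = 16)),
      age = group_summary(c("EC", "YC"), n = c(62, 38),
                          mean = c(22.77, 24.26), sd = c(3.99, 4.2)),
      education = group_summary(c("EC", "YC"), n = c(62, 38),
                                mean = c(7.84, 8.03), sd = c(1.43, 1.55))
    )
  )
}

#' Recompute the recomputable a-priori worked examples
#'
#' Recomputes, from the printed counts/means/SDs in
#' [apriori_summaries()], every a-priori statistic that is recoverable
#' without raw data: the sex chi-square of each study (2x3 uncorrected;
#' 2x2 with Yates correction), the study-1 one-way ANOVAs on
#' working-memory IQ and alertness with partial eta squared, and the
#' study-2 age t-test with Cohen's d. The age Kruskal-Wallis (study 1)
#' and education Wilcoxon (study 2) need raw ranks and are not
#' recomputable from summaries.
#'
#' @return Data frame with one row per recomputed statistic: `study`,
#'   `variable`, `test`, `statistic`, `df1`, `df2`, `p`, `effect_kind`,
#'   `effect`, and the `printed_*` reference values at the source's
#'   rounding.
#' @examples
#' apriori_worked_examples()
#' @export
apriori_worked_examples <- function() {
  s <- apriori_summaries()
  rows <- list(
    cbind(study = 1, variable = "sex",
          as.data.frame(chi_square_independence(s$study1$sex)),
          printed_statistic = 0.03, printed_p = 0.984,
          printed_effect = NA_real_),
    cbind(study = 1, variable = "working_memory_iq",
          as.data.frame(anova_oneway(s$study1$iq)),
          printed_statistic = NA_real_, printed_p = 0.45,
          printed_effect = 0.02),
    cbind(study = 1, variable = "alertness",
          as.data.frame(anova_oneway(s$study1$alertness)),
          printed_statistic = NA_real_, printed_p = 0.24,
          printed_effect = 0.04),
    cbind(study = 2, variable = "sex",
          as.data.frame(chi_square_independence(s$study2$sex)),
          printed_statistic = 0.06, printed_p = 0.80,
          printed_effect = NA_real_),
    cbind(study = 2, variable = "age",
          as.data.frame(t_test_two_sample(s$study2$age)),
          printed_statistic = NA_real_, printed_p = 0.08,
          printed_effect = -0.36)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
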