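#' Construct a group summary table
#'
#' Printed summary statistics (group sizes, means, SDs) are first-class
#' inputs to the pipeline: the t-test and one-way ANOVA can be recomputed
#' exactly from them, which is how the worked examples from published
#' comparison tables are reproduced.
#'
#' @param label Group labels.
#' @param n Group sizes (each >= 2).
#' @param mean Group means.
#' @param sd Group standard deviations (>= 0).
#' @return A data frame of class `group_summary`.
#' @examples
#' group_summary(c("EC", "YC"), n = c(62, 38),
#'               mean = c(22.77, 24.26), sd = c(3.99, 4.2))
#' @export
group_summary <- function(label, n, mean, sd) {
  stopifnot(length(label) == length(n), length(n) == length(mean),
            length(mean) == length(sd))
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  structure(data.frame(label = as.character(label), n = as.integer(n),
                       mean = as.numeric(mean), sd = as.numeric(sd),
                       stringsAsFactors = FALSE),
            class = c("group_summary", "data.frame"))
}

summarise_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  lv <- unique(as.character(groups))
  group_summary(lv,
                n = vapply(lv, function(g) sum(groups == g), numeric(1)),
                mean = vapply(lv, function(g) mean(values[groups == g]),
                              numeric(1)),
                sd = vapply(lv, function(g) stats::sd(values[groups == g]),
                            numeric(1)))
}

#' Assemble a test-result record
#'
#' Common container for every test in the pipeline: statistic, degrees of
#' freedom, p value, effect size (and kind), Greenhouse-Geisser epsilon
#' where applicable, and the correction applied.
#'
#' @param test Test name.
#' @param statistic Test statistic value.
#' @param df,df2 Degrees of freedom (df2 `NA` for single-df tests).
#' @param p P value.
#' @param effect_kind One of `"partial_eta2"`, `"eta2_H"`, `"cohen_d"`,
#'   `"none"`.
#' @param effect Effect-size value.
#' @param epsilon_gg Greenhouse-Geisser epsilon, or `NA`.
#' @param correction `"none"`, `"yates"`, `"gg"`, `"holm"`, `"bonferroni"`.
#' @param note Free-text note (e.g. exclusion counts).
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(test, statistic, df, df2 = NA_real_, p,
                        effect_kind = "none", effect = NA_real_,
                        epsilon_gg = NA_real_, correction = "none",
                        note = "") {
  stopifnot(p >= 0, p <= 1 + 1e-12)
  structure(list(test = test, statistic = statistic, df = df, df2 = df2,
                 p = min(p, 1), effect_kind = effect_kind, effect = effect,
                 epsilon_gg = epsilon_gg, correction = correction,
                 note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- if (is.na(x$df2)) sprintf("%g", x$df) else
    sprintf("%g, %g", x$df, x$df2)
  eff <- if (x$effect_kind == "none") "" else
    sprintf(", %s = %.3f", x$effect_kind, x$effect)
  gg <- if (is.na(x$epsilon_gg)) "" else
    sprintf(" (GG eps = %.3f)", x$epsilon_gg)
  cat(sprintf("<stat_result> %s(%s) = %.3f, p = %.4g%s%s [%s]\n",
              x$test, dfs, x$statistic, x$p, eff, gg, x$correction))
  invisible(x)
}

#' @export
as.data.frame.stat_result <- function(x, ...) {
  data.frame(test = x$test, statistic = x$statistic, df1 = x$df,
             df2 = x$df2, p = x$p, effect_kind = x$effect_kind,
             effect = x$effect, epsilon_gg = x$epsilon_gg,
             correction = x$correction, note = x$note,
             stringsAsFactors = FALSE)
}

#' Extreme-outlier inclusion mask
#'
#' Flags values outside `[Q1 - 3 IQR, Q3 + 3 IQR]` — the "extreme outlier"
#' fence of box-plot screening — for exclusion. Quartiles use linear
#' interpolation (quantile type 7, the R default). `NA`s are kept in the
#' mask as `NA`.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return Logical vector, `TRUE` = keep.
#' @examples
#' extreme_outlier_mask(c(1, 2, 3, 4, 100))  # the 100 is excluded
#' @export
extreme_outlier_mask <- function(values) {
  finite <- values[is.finite(values)]
  if (length(finite) < 4L) {
    stop("need at least 4 finite values for the outlier fence",
         call. = FALSE)
  }
  q <- stats::quantile(finite, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 3 * iqr
  hi <- q[2] + 3 * iqr
  ifelse(is.na(values), NA, values >= lo & values <= hi)
}

#' Chi-square test of independence
#'
#' Pearson chi-square on a contingency table. By default Yates continuity
#' correction is applied to 2x2 tables and not to larger ones — the
#' combination consistent with published group-comparison tables of the
#' paradigm.
#'
#' @param table Matrix of non-negative integer counts (>= 2x2).
#' @param continuity Apply Yates correction? Default: `TRUE` iff 2x2.
#' @return A [stat_result()].
#' @examples
#' sex <- rbind(female = c(15, 15, 15), male = c(12, 11, 12))
#' chi_square_independence(sex)  # X2 ~ 0.03
#' @export
chi_square_independence <- function(table, continuity = NULL) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("need at least a 2x2 table", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in the contingency table", call. = FALSE)
  }
  if (is.null(continuity)) {
    continuity <- nrow(table) == 2L && ncol(table) == 2L
  }
  ct <- stats::chisq.test(table, correct = continuity)
  stat_result("chi_square", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p = ct$p.value,
              correction = if (continuity) "yates" else "none")
}

#' Two-sample Student t-test (raw data or printed summaries)
#'
#' Pooled-variance t-test with Cohen's d
#' (`d = (m1 - m2) / s_pooled`,
#' `s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`).
#' Accepts either two raw-data vectors or a two-row [group_summary()];
#' both paths give identical results because the raw path first reduces to
#' the summaries. Degenerate input (both variances zero) yields t = 0 and
#' d = 0 at equal means and a flagged infinite statistic otherwise.
#'
#' @param x A two-row [group_summary()], or the first group's raw values.
#' @param y Second group's raw values (when `x` is raw data).
#' @return A [stat_result()] with `effect_kind = "cohen_d"`.
#' @examples
#' age <- group_summary(c("EC", "YC"), n = c(62, 38),
#'                      mean = c(22.77, 24.26), sd = c(3.99, 4.2))
#' t_test_two_sample(age)  # d ~ -0.37 (prints as -0.36 at the source's rounding)
#' @export
t_test_two_sample <- function(x, y = NULL) {
  gs <- if (inherits(x, "group_summary")) x else
    summarise_groups(c(x, y), rep(c("g1", "g2"), c(length(x), length(y))))
  if (nrow(gs) != 2L) stop("need exactly two groups", call. = FALSE)
  n1 <- gs$n[1]; n2 <- gs$n[2]
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * gs$sd[1]^2 + (n2 - 1) * gs$sd[2]^2) / df
  delta <- gs$mean[1] - gs$mean[2]
  if (sp2 == 0) {
    if (delta == 0) {
      return(stat_result("t_test", 0, df = df, p = 1,
                         effect_kind = "cohen_d", effect = 0))
    }
    return(stat_result("t_test", sign(delta) * Inf, df = df, p = 0,
                       effect_kind = "cohen_d", effect = sign(delta) * Inf,
                       note = "degenerate: zero pooled variance"))
  }
  tval <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  stat_result("t_test", tval, df = df,
              p = 2 * stats::pt(-abs(tval), df),
              effect_kind = "cohen_d", effect = delta / sqrt(sp2))
}

#' One-way between-subjects ANOVA (raw data or printed summaries)
#'
#' `F = (SSb / (k - 1)) / (SSw / (N - k))` with partial eta squared
#' `SSb / (SSb + SSw)`. The sums of squares are recovered exactly from
#' per-group `(n, mean, sd)`, so the test runs identically from raw data
#' and from printed summary tables.
#'
#' @param x A [group_summary()], or raw values.
#' @param groups Group labels (when `x` is raw data).
#' @return A [stat_result()] with `effect_kind = "partial_eta2"`.
#' @export
anova_oneway <- function(x, groups = NULL) {
  gs <- if (inherits(x, "group_summary")) x else summarise_groups(x, groups)
  k <- nrow(gs)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  N <- sum(gs$n)
  grand <- sum(gs$n * gs$mean) / N
  ssb <- sum(gs$n * (gs$mean - grand)^2)
  ssw <- sum((gs$n - 1) * gs$sd^2)
  if (ssw == 0 && ssb == 0) {
    return(stat_result("anova_oneway", 0, df = k - 1, df2 = N - k, p = 1,
                       effect_kind = "partial_eta2", effect = 0))
  }
  fval <- (ssb / (k - 1)) / (ssw / (N - k))
  stat_result("anova_oneway", fval, df = k - 1, df2 = N - k,
              p = stats::pf(fval, k - 1, N - k, lower.tail = FALSE),
              effect_kind = "partial_eta2", effect = ssb / (ssb + ssw))
}

#' Kruskal-Wallis test with eta-squared-H effect size
#'
#' Rank-based k-group comparison (tie-corrected H via
#' [stats::kruskal.test()]) with the effect size
#' `eta2_H = (H - k + 1) / (N - k)`, which can be slightly negative for
#' null data and is reported as-is.
#'
#' @param values Raw values.
#' @param groups Group labels.
#' @return A [stat_result()] with `effect_kind = "eta2_H"`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- is.finite(values)
  values <- values[ok]; groups <- factor(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  N <- length(values)
  kt <- stats::kruskal.test(values, groups)
  h <- unname(kt$statistic)
  stat_result("kruskal_wallis", h, df = unname(kt$parameter),
              p = if (is.nan(kt$p.value)) 1 else kt$p.value,
              effect_kind = "eta2_H", effect = (h - k + 1) / (N - k))
}

#' Mixed (split-plot) repeated-measures ANOVA
#'
#' Two-way mixed ANOVA with one between-subjects factor (group) and one
#' within-subjects factor, for balanced or unbalanced group sizes. Between
#' effect: one-way ANOVA on subject means. Within and interaction effects:
#' univariate tests on orthonormally contrast-transformed data with
#' type-III (unweighted-marginal) sums of squares, tested against the
#' subject-by-within error stratum. With more than two within levels the
#' Greenhouse-Geisser epsilon is estimated from the pooled within-group
#' covariance of the transformed data and applied to the within and
#' interaction degrees of freedom; with two levels sphericity holds
#' trivially and epsilon is exactly 1. Partial eta squared is reported per
#' effect. Subjects missing any within level (e.g. an undefined efficiency
#' score in one block) are dropped listwise and counted in the `note`
#' field — mirroring the reduced error degrees of freedom such exclusions
#' produce in practice.
#'
#' @param data Long-format data frame.
#' @param value,subject,between,within Column names.
#' @return A named list of [stat_result()]s: `between`, `within`,
#'   `interaction`; attribute `n_dropped` gives the listwise-deleted
#'   subject count and `n_used` the analysed count.
#' @export
mixed_rm_anova <- function(data, value, subject, between, within) {
  stopifnot(all(c(value, subject, between, within) %in% names(data)))
  d <- data.frame(y = as.numeric(data[[value]]),
                  s = as.character(data[[subject]]),
                  g = as.character(data[[between]]),
                  w = as.character(data[[within]]),
                  stringsAsFactors = FALSE)
  wlev <- sort(unique(d$w))
  k <- length(wlev)
  if (k < 2L) stop("need >= 2 within-factor levels", call. = FALSE)
  gmap <- unique(d[, c("s", "g")])
  if (anyDuplicated(gmap$s)) {
    stop("each subject must belong to exactly one between-level",
         call. = FALSE)
  }
  d <- d[is.finite(d$y), ]
  counts <- table(d$s)
  complete <- names(counts)[counts == k]
  n_dropped <- length(unique(gmap$s)) - length(complete)
  d <- d[d$s %in% complete, ]
  subjects <- sort(unique(d$s))
  N <- length(subjects)
  glev <- sort(unique(gmap$g[gmap$s %in% complete]))
  g <- length(glev)
  if (g < 2L) stop("need >= 2 between-levels after exclusions", call. = FALSE)
  if (N < g + 1L) stop("too few complete subjects", call. = FALSE)

  # wide matrix Y: subjects x within-levels
  Y <- matrix(NA_real_, N, k, dimnames = list(subjects, wlev))
  Y[cbind(match(d$s, subjects), match(d$w, wlev))] <- d$y
  grp <- gmap$g[match(subjects, gmap$s)]
  n_j <- as.numeric(table(factor(grp, levels = glev)))
  note <- sprintf("%d subject(s) dropped listwise; %d analysed", n_dropped, N)

  # between-subjects stratum: one-way ANOVA on subject means, SS x k to
  # stay on the classic split-plot scale (F and eta^2 are unaffected)
  m_i <- rowMeans(Y)
  mbar_j <- tapply(m_i, factor(grp, levels = glev), mean)
  grand_w <- mean(m_i)
  ssb <- k * sum(n_j * (mbar_j - grand_w)^2)
  ssw <- k * sum((m_i - mbar_j[match(grp, glev)])^2)
  f_b <- (ssb / (g - 1)) / (ssw / (N - g))
  res <- list(between = stat_result(
    "rm_anova", f_b, df = g - 1, df2 = N - g,
    p = stats::pf(f_b, g - 1, N - g, lower.tail = FALSE),
    effect_kind = "partial_eta2", effect = ssb / (ssb + ssw), note = note))

  # within stratum: orthonormal contrasts (orthogonal to the unit vector)
  C <- t(stats::contr.poly(k))
  Z <- Y %*% t(C)                                 # N x (k-1)
  Zbar <- rowsum(Z, factor(grp, levels = glev)) / n_j  # g x (k-1) cell means
  Ew <- crossprod(Z - Zbar[match(grp, glev), , drop = FALSE])
  sse <- sum(diag(Ew))
  df_e <- (N - g) * (k - 1)

  # GG epsilon from the pooled within-group covariance of Z
  S <- Ew / (N - g)
  eps <- if (k > 2L) {
    (sum(diag(S)))^2 / ((k - 1) * sum(S * S))
  } else 1
  eps <- min(1, max(eps, 1 / (k - 1)))

  # within main effect: type-III (unweighted marginal means)
  u <- colMeans(Zbar)
  ss_t <- (g^2 / sum(1 / n_j)) * sum(u^2)
  # interaction: group effect on the transformed variables
  zw <- colSums(Zbar * n_j) / N
  ss_i <- sum(n_j * rowSums((Zbar - matrix(zw, g, k - 1, byrow = TRUE))^2))

  # numerical floor: with exactly constant within-subject profiles both
  # numerator and error collapse to rounding residue; report F = 0
  y_scale <- max(sum((Y - mean(Y))^2), .Machine$double.eps)
  within_f <- function(ss, df1) {
    if (ss + sse <= 1e-10 * y_scale) {
      return(stat_result("rm_anova", 0, df = df1, df2 = df_e, p = 1,
                         effect_kind = "partial_eta2", effect = 0,
                         epsilon_gg = eps, correction = "none",
                         note = note))
    }
    fval <- (ss / df1) / (sse / df_e)
    gg <- k > 2L
    p <- stats::pf(fval, df1 * eps, df_e * eps, lower.tail = FALSE)
    stat_result("rm_anova", fval, df = df1, df2 = df_e, p = p,
                effect_kind = "partial_eta2", effect = ss / (ss + sse),
                epsilon_gg = eps, correction = if (gg) "gg" else "none",
                note = note)
  }
  res$within <- within_f(ss_t, k - 1)
  res$interaction <- within_f(ss_i, (g - 1) * (k - 1))
  attr(res, "n_dropped") <- n_dropped
  attr(res, "n_used") <- N
  res
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down Holm adjustment with monotonicity enforcement (via
#' [stats::p.adjust()]).
#'
#' @param p P values in `[0, 1]`.
#' @return Adjusted p values in input order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

#' Bonferroni family-wise correction with explicit family size
#'
#' `min(1, p * m)` where `m` is the size of the test family — which may
#' exceed the number of p values passed in, e.g. when one of several
#' dependent variables in a family is analysed at a time.
#'
#' @param p P values.
#' @param m Family size (>= `length(p)`).
#' @return Adjusted p values.
#' @export
bonferroni_family <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (m < length(p)) {
    stop("family size m must be >= the number of tests", call. = FALSE)
  }
  pmin(1, p * m)
}
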