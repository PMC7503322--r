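test_that("extreme-outlier fence uses type-7 quartiles and 3 IQR", {
  # {1,2,3,4,100}: Q1 = 2, Q3 = 4, IQR = 2 -> fences [-4, 10]
  expect_equal(extreme_outlier_mask(c(1, 2, 3, 4, 100)),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(extreme_outlier_mask(rep(5, 6)))) # IQR 0, all equal kept
  x <- c(-8, -2, 0, 2, 8, 50)
  expect_equal(extreme_outlier_mask(-x), extreme_outlier_mask(x))
  expect_error(extreme_outlier_mask(c(1, 2, 3)), "at least 4")
  expect_equal(extreme_outlier_mask(c(1, NA, 2, 3, 4)),
               c(TRUE, NA, TRUE, TRUE, TRUE))
})

test_that("chi-square reproduces the printed sex comparisons", {
  s <- apriori_summaries()
  r1 <- chi_square_independence(s$study1$sex) # 2x3: no correction
  expect_equal(round(r1$statistic, 2), 0.03)
  expect_equal(r1$df, 2)
  expect_equal(round(r1$p, 3), 0.984)
  expect_equal(r1$correction, "none")
  r2 <- chi_square_independence(s$study2$sex) # 2x2: Yates by default
  expect_equal(round(r2$statistic, 2), 0.06)
  expect_equal(round(r2$p, 2), 0.80)
  expect_equal(r2$correction, "yates")
  # independent table (outer product of margins) -> X2 = 0
  ind <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(chi_square_independence(round(ind * 100),
                                       continuity = FALSE)$statistic, 0)
  expect_error(chi_square_independence(matrix(c(1, 0, 2, 0), 2)),
               "marginal")
})

test_that("summary-statistic t-test matches raw-data t.test and printed d", {
  s <- apriori_summaries()
  r <- t_test_two_sample(s$study2$age)
  expect_equal(round(r$effect, 3), -0.366)
  expect_equal(r$df, 98)
  expect_equal(round(r$p, 2), 0.08)

  set.seed(10)
  x <- rnorm(20, 5, 2); y <- rnorm(25, 6, 2)
  mine <- t_test_two_sample(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  # summary path equals raw path exactly when summaries match the data
  gs <- group_summary(c("a", "b"), c(20, 25), c(mean(x), mean(y)),
                      c(sd(x), sd(y)))
  expect_equal(t_test_two_sample(gs)$statistic, mine$statistic)
  ident <- t_test_two_sample(c(1, 1, 1), c(1, 1, 1))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$effect, 0)
})

test_that("summary-statistic one-way ANOVA matches aov and printed eta2", {
  s <- apriori_summaries()
  iq <- anova_oneway(s$study1$iq)
  expect_equal(round(iq$effect, 2), 0.02)
  expect_equal(round(iq$p, 2), 0.45)
  al <- anova_oneway(s$study1$alertness)
  expect_equal(round(al$effect, 2), 0.04)

  set.seed(11)
  vals <- c(rnorm(15, 0), rnorm(12, 0.5), rnorm(18, 1))
  grp <- rep(c("a", "b", "c"), c(15, 12, 18))
  mine <- anova_oneway(vals, grp)
  ref <- summary(aov(vals ~ grp))[[1]]
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  flat <- anova_oneway(group_summary(c("a", "b"), c(5, 5), c(2, 2),
                                     c(1, 1)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$effect, 0)
})

test_that("Kruskal-Wallis H and eta2_H follow the rank computation", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("a", "b", "c"), each = 3)
  r <- kruskal_wallis(vals, grp)
  ref <- kruskal.test(vals, factor(grp))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$effect, (r$statistic - 3 + 1) / (9 - 3))
  # rank invariance under monotone relabelling
  r2 <- kruskal_wallis(exp(vals), grp)
  expect_equal(r2$statistic, r$statistic)
  # identical groups: H = 0, eta2_H = (1-k)/(N-k) reported as-is
  r0 <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect, (0 - 3 + 1) / (9 - 3))
})

test_that("mixed rmANOVA agrees with car's type-III univariate oracle", {
  skip_if_not_installed("car")
  check_against_car <- function(n_per_group, k, effect = 0.5) {
    g <- length(n_per_group)
    N <- sum(n_per_group)
    grp <- factor(rep(letters[1:g], n_per_group))
    subj <- sprintf("s%03d", 1:N)
    Y <- matrix(rnorm(N * k), N, k)
    Y <- Y + outer(as.integer(grp), 1:k, function(a, b) effect * a * b / k)
    long <- data.frame(subject = rep(subj, k),
                       group = rep(as.character(grp), k),
                       time = rep(sprintf("t%d", 1:k), each = N),
                       y = as.vector(Y))
    mine <- mixed_rm_anova(long, "y", "subject", "group", "time")
    mlm <- lm(Y ~ grp, contrasts = list(grp = contr.sum))
    idata <- data.frame(time = factor(sprintf("t%d", 1:k)))
    ca <- car::Anova(mlm, idata = idata, idesign = ~time, type = 3)
    cs <- suppressWarnings(summary(ca, multivariate = FALSE))$univariate.tests
    expect_equal(mine$between$statistic, cs["grp", "F value"], tolerance = 1e-6)
    expect_equal(mine$within$statistic, cs["time", "F value"], tolerance = 1e-6)
    expect_equal(mine$interaction$statistic, cs["grp:time", "F value"],
                 tolerance = 1e-6)
    if (k > 2) {
      gg <- suppressWarnings(summary(ca, multivariate = FALSE))$pval.adjustments
      expect_equal(mine$within$epsilon_gg, gg["time", "GG eps"],
                   tolerance = 1e-6)
      expect_equal(mine$within$p, gg["time", "Pr(>F[GG])"],
                   tolerance = 1e-6)
    }
  }
  set.seed(20)
  check_against_car(c(10, 10), k = 2)        # balanced, two levels
  check_against_car(c(14, 9), k = 2)         # unbalanced
  check_against_car(c(12, 8), k = 4)         # unbalanced with GG
  check_against_car(c(8, 10, 7), k = 3)      # three groups
})

test_that("mixed rmANOVA degenerate patterns and listwise deletion", {
  # no within-subject change + group offsets: within/interaction F = 0
  d <- expand.grid(subject = sprintf("s%d", 1:20), time = c("t1", "t2"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 10, "a", "b")
  d$y <- ifelse(d$group == "a", 1, 3) +
    rep(rnorm(20, 0, 0.2), 2)[match(d$subject,
                                    sprintf("s%d", 1:20))] * 0
  d$y <- d$y + as.integer(sub("s", "", d$subject)) / 100
  rm <- mixed_rm_anova(d, "y", "subject", "group", "time")
  expect_equal(rm$within$statistic, 0, tolerance = 1e-10)
  expect_equal(rm$interaction$statistic, 0, tolerance = 1e-10)
  expect_gt(rm$between$statistic, 1)
  expect_equal(rm$within$epsilon_gg, 1) # k = 2: sphericity trivially holds

  # subjects with a missing level are dropped and counted
  d$y[d$subject == "s3" & d$time == "t2"] <- NA
  rm2 <- mixed_rm_anova(d, "y", "subject", "group", "time")
  expect_equal(attr(rm2, "n_dropped"), 1L)
  expect_equal(attr(rm2, "n_used"), 19L)
})

test_that("Holm and Bonferroni corrections obey their defining properties", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(bonferroni_family(0.013, 3), 0.039)
  expect_equal(bonferroni_family(0.5, 4), 1)
  expect_equal(bonferroni_family(c(0.1, 0.2), 2), c(0.2, 0.4))
  expect_error(bonferroni_family(c(0.1, 0.2, 0.3), 2), "family size")

  set.seed(30)
  for (i in 1:40) {
    p <- runif(sample(2:25, 1))
    h <- holm_adjust(p)
    expect_true(all(h >= p))                        # dominance
    expect_true(all(diff(h[order(p)]) >= -1e-15))   # monotone in raw order
    expect_equal(h, p.adjust(p, "holm"))
    b <- bonferroni_family(p, length(p) + 2L)
    expect_true(all(b >= h - 1e-15))                # Bonferroni >= Holm
    expect_true(all(b <= 1))
  }
})

test_that("a-priori worked examples recompute all five printed statistics", {
  ex <- apriori_worked_examples()
  expect_equal(nrow(ex), 5L)
  chi <- ex[ex$test == "chi_square", ]
  expect_equal(round(chi$statistic, 2), chi$printed_statistic)
  eta <- ex[ex$test == "anova_oneway", ]
  expect_equal(round(eta$effect, 2), eta$printed_effect)
  aget <- ex[ex$variable == "age", ]
  # printed inputs are themselves rounded to 2 dp; agree within 0.01
  expect_lt(abs(aget$effect - aget$printed_effect), 0.01)
  expect_equal(round(aget$p, 2), aget$printed_p)
})
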