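test_that("reaction-time model: constant, miss, and shifted-lognormal median", {
  a <- constant_agent(rt = 0.3)
  set.seed(1)
  expect_equal(sample_rt(a, 10), rep(0.3, 10))
  a_miss <- constant_agent(miss = 1)
  expect_true(all(is.na(sample_rt(a_miss, 10))))
  a_ln <- agent_spec(rt = list(family = "shifted_lognormal", shift = 0.2,
                               meanlog = log(0.3), sdlog = 0.4,
                               miss_prob = 0))
  set.seed(42)
  rts <- sample_rt(a_ln, 10000)
  # median of shift + lognormal = shift + exp(meanlog) = 0.5
  expect_equal(median(rts), 0.5, tolerance = 0.04)
  expect_true(all(rts > 0.2))
})

test_that("button choice is uniform over candidates and lapses uniformly", {
  st <- new_learner(c("circle", "triangle"), c("b1", "b2", "b3"))
  set.seed(5)
  draws <- replicate(9000, choose_button(st, "circle", lapse_prob = 0))
  expect_gt(chisq.test(table(draws))$p.value, 0.01)
  st2 <- update_learner(st, "circle", "b2", terminated = TRUE)
  expect_equal(choose_button(st2, "circle", lapse_prob = 0), "b2")
  set.seed(6)
  lapses <- replicate(3000, choose_button(st2, "circle", lapse_prob = 1))
  expect_gt(chisq.test(table(lapses))$p.value, 0.01)
  expect_error(choose_button(st, "square", 0), "unknown cue")
})

test_that("elimination learner shrinks candidate sets and self-repairs", {
  st <- new_learner("c1", c("b1", "b2", "b3"))
  st <- update_learner(st, "c1", "b2", terminated = FALSE)
  expect_setequal(st$candidates$c1, c("b1", "b3"))
  st <- update_learner(st, "c1", "b3", terminated = TRUE)
  expect_equal(st$resolved[["c1"]], "b3")
  expect_equal(st$candidates$c1, "b3")
  # inconsistent feedback: removing the last candidate restores the set
  st <- update_learner(st, "c1", "b3", terminated = FALSE)
  expect_setequal(st$candidates$c1, c("b1", "b2", "b3"))
})

test_that("zero-lapse elimination commits at most 2 errors per cue", {
  # worst case over 3 buttons: two disconfirmations then the correct one
  cfg <- study_config(2)
  agent <- constant_agent(rt = 0.3)
  for (seed in 1:10) {
    s <- simulate_session("EC", agent, cfg, seed = seed)
    errs <- tapply(!s$trials$correct, s$trials$cue, sum)
    expect_true(all(errs <= 2), info = sprintf("seed %d", seed))
    expect_lte(sum(!s$trials$correct), 6)
    # long-run correct rate: the tail of the session is error-free
    tail_tr <- s$trials[s$trials$trial > 20, ]
    expect_true(all(tail_tr$correct))
  }
})

test_that("navigation policies take lawful single steps", {
  ag <- constant_agent(nav_family = "memory_guided")
  nav <- new_nav_state(ag, 15L)
  nav$known <- 7L * 15L + 10L # (7, 10)
  nav$strength <- 2L; nav$last_seen <- 1L; nav$fragile <- FALSE
  mv <- nav_policy_step(nav, 7L, 7L, "stress", safes = nav$known)
  expect_equal(mv, 4L) # right, along the shortest Manhattan path

  ag_sweep <- constant_agent(nav_family = "sweep")
  n1 <- new_nav_state(ag_sweep, 15L); n1$trial_no <- 10L # fully skilled
  n2 <- new_nav_state(ag_sweep, 15L); n2$trial_no <- 10L
  path1 <- replicate(30, nav_policy_step(n1, 7L, 7L, "explore", integer(0)))
  path2 <- replicate(30, nav_policy_step(n2, 7L, 7L, "explore", integer(0)))
  expect_identical(path1, path2) # deterministic, repeatable

  ag_rw <- constant_agent(nav_family = "random_walk")
  nrw <- new_nav_state(ag_rw, 15L)
  set.seed(2)
  expect_true(all(replicate(50, nav_policy_step(nrw, 0L, 0L, "explore",
                                                integer(0))) %in% 1:4))
})

test_that("memory model: retention, staleness, and encoding tiers", {
  ag <- agent_spec(nav = list(family = "frantic", memory_retention = 0,
                              fresh_retention = 0, stress_encoding = 0))
  nav <- new_nav_state(ag, 15L)
  nav$known <- c(3L, 100L); nav$strength <- c(3L, 3L)
  nav$last_seen <- c(1L, 1L); nav$fragile <- c(FALSE, FALSE)
  set.seed(1)
  shuttlebox:::nav_forget(nav)
  expect_length(nav$known, 0L) # retention 0 clears everything

  # stale persistence: memory-guided abandons a stale target after
  # `stale_persistence` stress moves and falls back to systematic search
  ag_mg <- constant_agent(nav_family = "memory_guided",
                          stale_persistence = 2L)
  nmg <- new_nav_state(ag_mg, 15L); nmg$trial_no <- 10L
  nmg$known <- 0L; nmg$strength <- 5L; nmg$last_seen <- 1L
  nmg$fragile <- FALSE
  set.seed(3)
  for (i in 1:3) nav_policy_step(nmg, 7L, 7L, "stress", safes = 224L)
  expect_length(nmg$known, 0L) # stale cell dropped after persistence
})

test_that("Likert generator is linear in probes, rounded, and clipped", {
  flat <- agent_spec(ratings = list(control = c(6, 0, 0)))
  expect_equal(rating_value(flat, "control", 1), 6L)
  expect_equal(rating_value(flat, "control", 4), 6L)
  ceilinged <- agent_spec(ratings = list(control = c(7, 1, 0)))
  expect_equal(rating_value(ceilinged, "control", 4), 7L)
  drift <- agent_spec(ratings = list(exhaustion = c(4, 0.2, 0.5)))
  set.seed(9)
  vals <- replicate(10000, rating_value(drift, "exhaustion", 4))
  expect_true(all(vals %in% 1:7))
  expect_equal(mean(vals), 4.6, tolerance = 0.03) # 4 + 0.2 * 3
})

test_that("presets express opposite search phenotypes on the study-2 grid", {
  # the yoked phenotype presses faster (more activity) but escapes less
  # in block 2 than the escapable phenotype (stochastic, moderate n)
  ec <- agent_preset("ec_like"); yc <- agent_preset("yc_like")
  stats <- sapply(1:60, function(i) {
    rec_e <- run_escape_test(ec, "study2", seed = derive_seed(21, "e", i))
    rec_y <- run_escape_test(yc, "study2", seed = derive_seed(21, "y", i))
    me <- escape_metrics(rec_e); my <- escape_metrics(rec_y)
    c(mpm_e = mean(me$moves_per_min), mpm_y = mean(my$moves_per_min),
      b2_e = me$escapes[me$block == 2], b2_y = my$escapes[my$block == 2])
  })
  expect_true(all(stats["mpm_y", ] > stats["mpm_e", ]))
  expect_gt(mean(stats["b2_e", ]), mean(stats["b2_y", ]))
  expect_lt(t.test(stats["b2_y", ], stats["b2_e", ],
                   alternative = "less")$p.value, 0.01)
})
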