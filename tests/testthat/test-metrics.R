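test_that("metric definitions match hand-computed examples", {
  # 12 distinct cells in one 10-s trial -> 72 cells/min
  ph <- data.frame(block = 1, trial = 1, phase = "explore",
                   duration = 10, n_unique = 12, n_moves = 9,
                   escaped = NA)
  expect_equal(exploration_rate(ph), 72)
  # never-moving study-1 agent: 5 start cells over 50 s -> 6 cells/min
  ph5 <- data.frame(block = 1, trial = 1:5, phase = "explore",
                    duration = 10, n_unique = 1, n_moves = 0, escaped = NA)
  expect_equal(exploration_rate(ph5), 6)
  # 30 moves over 60 s with 3 escapes -> (30 per min) / 3 = 10
  st <- data.frame(block = 1, trial = 1:3, phase = "stress",
                   duration = 20, n_unique = 5, n_moves = 10,
                   escaped = TRUE)
  expect_equal(escape_count(st), 3L)
  expect_equal(efficiency(st), 10)
  # doubling activity at fixed escapes and time doubles the score
  st2 <- st; st2$n_moves <- 20
  expect_equal(efficiency(st2), 20)
  # zero escapes -> undefined
  st$escaped <- FALSE
  expect_true(is.na(efficiency(st)))
  expect_error(exploration_rate(st), "explore")
  expect_error(escape_count(ph), "stress")
})

test_that("module metrics equal brute-force recomputation from raw logs", {
  agents <- list(agent_preset("ec_like"), agent_preset("yc_like"),
                 constant_agent(nav_family = "random_walk"))
  n_checked <- 0L
  for (a in seq_along(agents)) {
    for (i in 1:12) {
      rec <- run_escape_test(agents[[a]], "study2",
                             seed = derive_seed(31, "om", a * 100 + i))
      m <- escape_metrics(rec)
      o <- oracle_metrics(rec)
      expect_equal(m$exploration_per_min, o$exploration)
      expect_equal(m$escapes, o$escapes)
      expect_equal(m$efficiency, o$efficiency)
      expect_equal(is.na(m$efficiency), m$escapes == 0)
      n_checked <- n_checked + nrow(m)
    }
  }
  expect_gte(n_checked, 70L)
})

test_that("mean RT averages in-window responses and flags all-miss sessions", {
  cfg <- study_config(1)
  s <- simulate_session("EC", constant_agent(rt = 0.3), cfg, seed = 2)
  expect_equal(mean_rt(s), 0.3)
  s$trials$rt[1:3] <- c(0.2, 0.4, NA)
  s$trials$rt[4:40] <- NA
  expect_equal(as.numeric(mean_rt(s)), 0.3)
  s$trials$rt[] <- NA
  rt <- mean_rt(s)
  expect_true(is.na(rt))
  expect_true(attr(rt, "all_miss"))
  s$trials$rt[] <- 1.4 # all late: excluded like misses
  expect_true(is.na(mean_rt(s)))
})

test_that("correct rate counts in-window correct presses only", {
  cfg <- study_config(2)
  s <- simulate_session("EC", constant_agent(rt = 0.3), cfg, seed = 3)
  expect_gte(correct_rate(s), 0.9) # zero-lapse elimination: <= 6 errors
  s_miss <- simulate_session("EC", constant_agent(miss = 1), cfg, seed = 3)
  expect_equal(correct_rate(s_miss), 0)
  # random presser: expectation 1/3 within binomial error
  rnd <- agent_spec(rt = list(family = "constant", shift = 0.3,
                              miss_prob = 0),
                    learner = list(family = "elimination", lapse_prob = 1))
  rates <- sapply(1:20, function(i)
    correct_rate(simulate_session("EC", rnd, cfg,
                                  seed = derive_seed(5, "rnd", i))))
  expect_equal(mean(rates), 1 / 3, tolerance = 0.05)
  cc <- simulate_session("CC", constant_agent(), study_config(1), seed = 1)
  expect_error(correct_rate(cc), "study-2 EC")
})

test_that("metrics survive a CSV round trip unchanged", {
  rec <- run_escape_test(agent_preset("yc_like"), "study2", seed = 17)
  dir <- withr::local_tempdir()
  write_escape_test(rec, dir)
  logs <- read_escape_test(dir, rec$participant_id)
  rec2 <- rec
  rec2$phases <- logs$phases
  rec2$moves <- logs$moves
  expect_equal(escape_metrics(rec2), escape_metrics(rec))
})
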