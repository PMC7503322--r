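test_that("EC termination rule: in-window press stops the stressor", {
  cfg <- study_config(1)
  tl <- build_trial_timeline(cfg, 1)
  r <- run_ec_trial(tl[1, ], response_time = 0.4, button = "space",
                    config = cfg)
  expect_equal(r$stress_duration, 6.4)
  expect_true(r$terminated)
  late <- run_ec_trial(tl[1, ], response_time = 1.3, button = "space",
                       config = cfg)
  expect_equal(late$stress_duration, 15)
  expect_false(late$terminated)
  miss <- run_ec_trial(tl[1, ], response_time = NA, config = cfg)
  expect_equal(miss$stress_duration, 15)
})

test_that("study-2 EC requires the correct button and honours the decrement", {
  cfg <- study_config(2)
  tl <- build_trial_timeline(cfg, 1)
  truth <- stats::setNames(c("b1", "b2", "b3"),
                           c("circle", "triangle", "square"))
  tpl <- tl[20, ]
  wrong <- setdiff(c("b1", "b2", "b3"), truth[[tpl$cue]])[1]
  r_wrong <- run_ec_trial(tpl, 0.4, wrong, cfg, truth)
  expect_equal(r_wrong$stress_duration, 9.5) # cap for trials 16-30
  expect_false(r_wrong$terminated)
  r_right <- run_ec_trial(tpl, 0.4, truth[[tpl$cue]], cfg, truth)
  expect_equal(r_right$stress_duration, 6.4)
  expect_true(r_right$terminated)
  expect_error(run_ec_trial(tpl, 0.4, "b1", cfg), "truth_map")
})

test_that("one-to-one yoking copies durations exactly", {
  cfg <- study_config(1)
  for (i in 1:5) {
    ec <- simulate_session("EC", agent_preset("ec_like"), cfg,
                           seed = derive_seed(3, "ec", i))
    sched <- derive_yoked_schedule(ec, seed = derive_seed(3, "yk", i))
    expect_identical(sched$duration, ec$trials$stress_duration)
    yc <- simulate_session("YC", agent_preset("yc_like"), cfg,
                           seed = derive_seed(3, "yc", i), yoke = sched)
    expect_identical(yc$trials$stress_duration, ec$trials$stress_duration)
  }
  cc <- simulate_session("CC", agent_preset("cc_like"), cfg, seed = 1)
  expect_error(derive_yoked_schedule(cc, 1), "EC")
})

test_that("yoked cue onsets follow the 1-4 s pre-response law, uniformly", {
  durations <- rep(10, 10000)
  onsets <- shuttlebox:::sample_yc_onsets(durations, seed = 99)
  gap <- durations - onsets
  expect_true(all(gap >= 1 & gap <= 4))
  ks <- suppressWarnings(stats::ks.test(onsets, "punif", 6, 9))
  expect_gt(ks$p.value, 0.01)
  # clipping guard: tiny durations never produce negative onsets
  expect_true(all(shuttlebox:::sample_yc_onsets(rep(0.5, 100), 1) >= 0))
})

test_that("pseudo-yoking permutes the EC per-trial mean vector exactly", {
  cfg <- study_config(2)
  ecs <- lapply(1:6, function(i)
    simulate_session("EC", agent_preset("ec_like"), cfg,
                     seed = derive_seed(4, "ec", i)))
  means <- rowMeans(vapply(ecs, function(s) s$trials$stress_duration,
                           numeric(60)))
  sched <- derive_pseudo_yoked_schedule(ecs, seed = 11)
  expect_equal(sort(sched$duration), sort(means))      # exact permutation
  expect_equal(sum(sched$duration), sum(means))        # conservation
  expect_true(all(sched$duration <=
                    max_stress_duration(cfg, 1:60) + 1e-9)) # cap respected
  expect_identical(derive_pseudo_yoked_schedule(ecs, seed = 11)$duration,
                   sched$duration)                     # seed-deterministic
  expect_false(identical(derive_pseudo_yoked_schedule(ecs, 12)$duration,
                         sched$duration))
  expect_error(derive_pseudo_yoked_schedule(list(), 1), "at least one")
})

test_that("YC stress duration ignores the response entirely", {
  cfg <- study_config(1)
  tl <- build_trial_timeline(cfg, 1)
  r1 <- run_yc_trial(tl[1, ], yoked_duration = 6.4, yoked_onset = 3.1,
                     response_time = 0.3, button = "space")
  expect_equal(r1$stress_duration, 6.4)
  expect_false(r1$terminated)
  r2 <- run_yc_trial(tl[1, ], 6.4, 3.1, response_time = NA)
  expect_equal(r2$stress_duration, 6.4)
  expect_error(run_yc_trial(tl[1, ], 16, 12), "cap")
})

test_that("sessions integrate timing, ratings, affect, and conditions", {
  cfg <- study_config(1)
  ec <- simulate_session("EC", constant_agent(rt = 0.3), cfg, seed = 8)
  expect_equal(nrow(ec$trials), 40L)
  expect_true(all(ec$trials$terminated))
  expect_equal(sum(ec$trials$stress_duration), 40 * 6.3)
  expect_equal(nrow(ec$ratings), 4L * 5L)
  expect_setequal(unique(ec$ratings$after_trial), c(10L, 20L, 30L, 40L))
  expect_true(all(ec$ratings$value %in% 1:7))
  expect_equal(ec$affect$score, c("STADI", "PANASpos", "PANASneg"))

  cc <- simulate_session("CC", constant_agent(), cfg, seed = 9)
  expect_true(all(cc$trials$stress_duration == 0))

  expect_error(simulate_session("YC", constant_agent(), cfg, seed = 1),
               "yoke")
  expect_error(simulate_session("EC", constant_agent(), cfg, seed = 1,
                                yoke = data.frame()), "yoke")

  # determinism: identical arguments give identical sessions
  expect_identical(simulate_session("EC", constant_agent(0.3), cfg, 8)$trials,
                   ec$trials)
})
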