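test_that("safe-space placement is uniform, exclusion-aware, and seeded", {
  g <- grid_config()
  centre <- 7L * 15L + 7L
  s1 <- place_safe_spaces(g, excluded = centre, seed = 1)
  expect_length(s1, 4L)
  expect_false(centre %in% s1)
  expect_false(anyDuplicated(s1) > 0)
  expect_identical(place_safe_spaces(g, centre, 1), s1)

  # inclusion frequency ~ 4/224 for every eligible cell
  draws <- unlist(lapply(1:4000, function(i)
    place_safe_spaces(g, centre, seed = i)))
  counts <- tabulate(draws + 1L, nbins = 225)[-(centre + 1L)]
  expect_gt(chisq.test(counts)$p.value, 0.01)

  g_all <- grid_config(n_safe = 224)
  expect_error(place_safe_spaces(g_all, excluded = c(centre, 0L), seed = 1),
               "cannot place")
})

test_that("moves displace one cell and clamp at edges", {
  expect_equal(apply_move(c(7L, 7L), "up"), c(6L, 7L))
  expect_equal(apply_move(c(0L, 3L), "up"), c(0L, 3L))
  expect_equal(apply_move(c(14L, 14L), "right"), c(14L, 14L))
  pos <- c(5L, 5L)
  for (m in c("up", "down", "left", "right")) pos <- apply_move(pos, m)
  expect_equal(pos, c(5L, 5L)) # 4-cycle returns to start
  expect_error(apply_move(c(7L, 7L), "diagonal"), "invalid move")
  expect_error(apply_move(c(20L, 0L), "up"), "off the grid")
})

test_that("run_phase caps events, reveals safes, and ends stress on escape", {
  ag <- constant_agent(nav_family = "sweep", move_interval = 0.5)
  nav <- new_nav_state(ag, 15L); nav$trial_no <- 10L
  tr <- run_phase(c(7L, 7L), nav, safes = 224L, duration = 10, stress = FALSE)
  expect_lte(nrow(tr$events), 20L) # 10 s at 0.5 s per move
  expect_equal(tr$phase_duration, 10)
  expect_false(tr$escaped)

  # start adjacent to a safe cell, memory-guided: one move escapes
  ag2 <- constant_agent(nav_family = "memory_guided")
  nav2 <- new_nav_state(ag2, 15L); nav2$trial_no <- 10L
  safe <- 7L * 15L + 8L
  nav2$known <- safe; nav2$strength <- 3L; nav2$last_seen <- 1L
  nav2$fragile <- FALSE
  tr2 <- run_phase(c(7L, 7L), nav2, safes = safe, duration = 5,
                   stress = TRUE)
  expect_true(tr2$escaped)
  expect_equal(tr2$n_moves, 1L)
  expect_equal(tr2$escape_latency, 0.25)
  expect_equal(tr2$phase_duration, 0.25)

  # no safe reachable: full cap, escaped = FALSE
  nav3 <- new_nav_state(constant_agent(), 15L)
  set.seed(1)
  tr3 <- run_phase(c(7L, 7L), nav3, safes = integer(0) + 224L,
                   duration = 2, stress = TRUE)
  if (!tr3$escaped) expect_equal(tr3$phase_duration, 2)
  expect_lte(tr3$n_unique, tr3$n_moves + 1L)
})

test_that("escape-test structure follows the study variants", {
  rec1 <- run_escape_test(agent_preset("ec_like"), "study1", seed = 5)
  expect_equal(nrow(rec1$phases), 10L) # 1 block x 5 trials x 2 phases
  expect_length(rec1$layouts, 1L)
  expect_true(all(rec1$phases$start_row[rec1$phases$phase == "explore"] == 7L))
  # study 1 keeps the position across the explore->stress boundary
  ex_rows <- rec1$phases[rec1$phases$phase == "explore", ]
  st_rows <- rec1$phases[rec1$phases$phase == "stress", ]
  expect_false(all(st_rows$start_row == 7L & st_rows$start_col == 7L))

  rec2 <- run_escape_test(agent_preset("ec_like"), "study2", seed = 5)
  expect_equal(nrow(rec2$phases), 20L) # 2 blocks x 5 trials x 2 phases
  expect_length(rec2$layouts, 2L)
  expect_true(all(rec2$phases$start_row == 7L & rec2$phases$start_col == 7L))
  expect_false(identical(rec2$layouts[[1]], rec2$layouts[[2]]))
  expect_true(all(rec2$phases$escape_latency <= 5, na.rm = TRUE))
  expect_true(all(rec2$phases$duration[!rec2$phases$escaped &
                                         rec2$phases$phase == "stress"] == 5))

  # reproducibility: identical (variant, agent, seed) -> identical record
  rec2b <- run_escape_test(agent_preset("ec_like"), "study2", seed = 5)
  expect_identical(rec2b$phases, rec2$phases)
  expect_identical(rec2b$moves, rec2$moves)
})

test_that("a perfect-memory agent heads for the stale location after relocation", {
  # find a seed where the agent knows a block-1 safe by the end of block 1
  ag <- constant_agent(nav_family = "memory_guided")
  rec <- run_escape_test(ag, "study2", seed = 42)
  b1 <- rec$layouts[[1]]; b2 <- rec$layouts[[2]]
  stale <- setdiff(b1, b2)
  first_stress_b2 <- rec$moves[rec$moves$block == 2 & rec$moves$trial == 1 &
                                 rec$moves$phase == "stress", ]
  if (nrow(first_stress_b2) >= 3 && length(stale)) {
    # early block-2 stress moves reduce the distance to some stale cell
    d_to <- function(row, col, cells)
      min(abs(cells %/% 15 - row) + abs(cells %% 15 - col))
    d0 <- d_to(7, 7, stale)
    d3 <- d_to(first_stress_b2$row[3], first_stress_b2$col[3], stale)
    expect_lte(d3, d0)
  } else succeed("agent escaped immediately; stale pursuit not observable")
})

test_that("memory-guided search beats a random walk on the study-1 grid", {
  n <- 150
  esc <- sapply(1:n, function(i) {
    mg <- run_escape_test(constant_agent(nav_family = "memory_guided"),
                          "study1", seed = derive_seed(13, "m", i))
    rw <- run_escape_test(constant_agent(nav_family = "random_walk"),
                          "study1", seed = derive_seed(13, "r", i))
    c(mg = sum(mg$phases$escaped, na.rm = TRUE),
      rw = sum(rw$phases$escaped, na.rm = TRUE))
  })
  expect_lt(t.test(esc["mg", ], esc["rw", ],
                   alternative = "greater")$p.value, 0.01)
})
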