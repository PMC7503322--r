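# shared fixtures: deterministic agents and tiny configs built in code

constant_agent <- function(rt = 0.3, miss = 0, nav_family = "random_walk",
                           ...) {
  agent_spec(rt = list(family = "constant", shift = rt, miss_prob = miss),
             learner = list(family = "elimination", lapse_prob = 0),
             nav = utils::modifyList(
               list(family = nav_family, move_interval = 0.25), list(...)),
             label = "fixture")
}

# a session whose trial durations are handed in directly (for yoking tests)
session_with_durations <- function(durations, config = study_config(1),
                                   condition = "EC", id = "FIX") {
  s <- simulate_session(condition, constant_agent(), config, seed = 1,
                        participant_id = id)
  stopifnot(length(durations) == nrow(s$trials))
  s$trials$stress_duration <- as.numeric(durations)
  s
}
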