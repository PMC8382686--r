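# Shared fixtures: small configs and deterministic policies used across tests.

tiny_config <- function(n_rounds = 12, ...) {
  game_config(n_rounds = n_rounds, switch_round = min(6, n_rounds), ...)
}

# All confederates on period 1 (always available): fully deterministic phase 1.
all_available_config <- function(n_rounds = 120, ...) {
  game_config(n_rounds = n_rounds, schedules = c(1, 1, 1), ...)
}

constant_policy <- function(alloc) {
  force(alloc)
  function(round, history) alloc
}

expect_valid_log <- function(log, config = attr(log, "config")) {
  expect_silent(validate_game_log(log, config))
}
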