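test_that("a fresh agent processes counterparts in uniform random order", {
  cfg <- game_config()
  agent <- cognitive_agent(cfg, "full")
  withr::with_seed(8, {
    firsts <- replicate(6000, {
      k <- length(agent$cum_payoff)
      w <- exp((agent$cum_payoff - max(agent$cum_payoff)) / agent$utilities$s)
      sample.int(k, 1, prob = pmax(w, 1e-12))
    })
  })
  expect_equal(mean(firsts == 1), 1 / 3, tolerance = 0.025)
  expect_equal(mean(firsts == 2), 1 / 3, tolerance = 0.025)

  # dominant cumulative payoff is processed first at low temperature
  agent$cum_payoff <- c(100, 0, 0)
  withr::with_seed(9, d <- decide_allocations(agent, 1))
  # with payoff gap 100 and s = 0.5 the Boltzmann weight of the others is ~0
  w <- exp((agent$cum_payoff - max(agent$cum_payoff)) / agent$utilities$s)
  expect_lt(max(w[2:3]), 1e-12)
})

test_that("decided allocations always respect the endowment", {
  cfg <- game_config()
  specs <- confederate_specs(cfg)
  withr::with_seed(21, {
    agent <- cognitive_agent(cfg, "full")
    for (r in 1:80) {
      d <- decide_allocations(agent, r)
      expect_true(all(d$allocations >= 0))
      expect_lte(sum(d$allocations), cfg$endowment)
      rec <- settle_round(d$allocations, r, cfg, specs)
      agent <- observe_feedback(d$agent, rec, cfg)
    }
  })
})

test_that("feedback composes memory, trust and utility updates", {
  cfg <- all_available_config()
  specs <- confederate_specs(cfg)
  agent <- cognitive_agent(cfg, "full")
  withr::with_seed(5, d <- decide_allocations(agent, 1))
  rec <- settle_round(c(10, 0, 0), 1, cfg, specs)
  # patch the record to the forced allocation for a deterministic check
  agent2 <- observe_feedback(d$agent, rec, cfg)
  # instance stored with the observed 75% return fraction
  expect_length(agent2$memory$chunks, 1)
  expect_equal(agent2$memory$chunks[[1]]$value, 0.75)
  # trust increased: 30 returned vs expectation 0.6 * 40 = 24
  expect_gt(agent2$state$trust[1], agent$state$trust[1])
  # non-interacted counterparts were discounted
  expect_equal(agent2$state$trust[2], agent$params$initial_trust - agent$params$delta)
  # cumulative payoff tracks returns
  expect_equal(agent2$cum_payoff, c(30, 0, 0))
  # fired rules were reinforced with the (normalized) round reward
  expect_gt(length(agent2$utilities$utilities), 0)
})

test_that("round clock mismatches are rejected", {
  cfg <- game_config()
  specs <- confederate_specs(cfg)
  agent <- cognitive_agent(cfg, "full")
  rec2 <- settle_round(c(0, 0, 0), 2, cfg, specs)
  expect_error(observe_feedback(agent, rec2, cfg), "clock error")
  withr::with_seed(1, d <- decide_allocations(agent, 1))
  expect_error(observe_feedback(d$agent, rec2, cfg), "clock error")
})

test_that("the no_trust lesion touches no accumulator and earns own payoff plus kept", {
  cfg <- all_available_config()
  specs <- confederate_specs(cfg)
  agent <- cognitive_agent(cfg, "no_trust")
  withr::with_seed(3, d <- decide_allocations(agent, 1))
  rec <- settle_round(c(10, 5, 0), 1, cfg, specs)
  agent2 <- observe_feedback(d$agent, rec, cfg)
  expect_equal(agent2$state$trust, agent$state$trust)
  expect_equal(agent2$state$invest, c(0, 0, 0))
  # own payoff: (30-10) + (15-5) = 30; kept = 25
  expect_equal(agent2$last_reward, 30 + 25)
})

test_that("the trust_only lesion keeps trust but never develops trust necessity", {
  cfg <- game_config()
  sim <- run_model_game("trust_only", cfg, n_runs = 3, seed = 5)
  for (tr in sim$traces) {
    expect_true(all(tr$invest == 0))
    expect_false(any(tr$regime == "trust_necessity"))
  }
})

test_that("simulations are reproducible and return complete curves", {
  cfg <- game_config(n_rounds = 30)
  s1 <- run_model_game("full", cfg, n_runs = 2, seed = 11)
  s2 <- run_model_game("full", cfg, n_runs = 2, seed = 11)
  expect_identical(s1$curves, s2$curves)
  expect_identical(s1$logs[[1]], s2$logs[[1]])
  expect_equal(nrow(s1$curves), 30 * 3)
  expect_valid_log(s1$logs[[1]])
  expect_valid_log(s1$logs[[2]])
  # curves are the across-run means of the per-run logs
  manual <- (s1$logs[[1]]$allocation + s1$logs[[2]]$allocation) / 2
  expect_equal(s1$curves$allocation,
               manual[order(s1$logs[[1]]$confederate_id, s1$logs[[1]]$round)])
})
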