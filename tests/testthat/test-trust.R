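zero_params <- function(...) trust_params(initial_trust = 0, ...)

test_that("regime classification is total and matches the threshold rules", {
  p <- zero_params()
  st <- trust_state(3, p)
  st$trust <- c(1.0, -0.5, -0.5)
  st$invest <- c(0, -0.5, 0.5)
  expect_equal(classify_regime(st, 1, p), "trust")
  expect_equal(classify_regime(st, 2, p), "distrust")
  expect_equal(classify_regime(st, 3, p), "trust_necessity")
  # exhaustive over sign combinations: exactly one regime each
  for (tr in c(-1, 0, 1)) for (inv in c(-1, 0, 1)) {
    st$trust[1] <- tr; st$invest[1] <- inv
    r <- classify_regime(st, 1, p)
    expect_true(r %in% c("trust", "distrust", "trust_necessity"))
  }
})

test_that("trust integrates net outcome and expectation violation, saturating", {
  p <- zero_params()
  st <- trust_state(1, p)
  # net-outcome rule: +0.5 for returning 3x on 10 of 40
  st1 <- update_on_outcome(st, 1, allocated = 10, returned = 30,
                           endowment = 40, p)
  expect_equal(st1$trust[1], 0.5)
  # returning exactly the allocation is neutral
  st2 <- update_on_outcome(st, 1, allocated = 10, returned = 10,
                           endowment = 40, p)
  expect_equal(st2$trust[1], 0)
  # a met expectation adds nothing beyond the net outcome
  st3 <- update_on_outcome(st, 1, 10, 30, 40, p, expected = 30)
  expect_equal(st3$trust[1], 0.5)
  # a violated expectation costs mu per normalized point of shortfall:
  # +0.5 net + 2 * (30 - 38)/40 = +0.1
  st4 <- update_on_outcome(st, 1, 10, 30, 40, p, expected = 38)
  expect_equal(st4$trust[1], 0.1)
  # break-even return below expectation is a pure loss of trust
  st5 <- update_on_outcome(st, 1, 10, 10, 40, p, expected = 30)
  expect_equal(st5$trust[1], -1)
  # trust saturates at the cap
  st$trust[1] <- 1.9
  st6 <- update_on_outcome(st, 1, 10, 30, 40, p)
  expect_equal(st6$trust[1], p$trust_cap)
  # zero allocation: no evidence, trust untouched, invest decays
  st$trust[1] <- 0
  st$invest[1] <- 0.8
  st7 <- update_on_outcome(st, 1, 0, 0, 40, p)
  expect_equal(st7$trust[1], 0)
  expect_equal(st7$invest[1], 0.4)
})

test_that("interaction consumes trust-invest; portfolio failure feeds it", {
  p <- zero_params()
  st <- trust_state(3, p)
  st$invest <- c(0.8, 0.2, 0.2)
  st1 <- update_on_outcome(st, 1, 10, 10, 40, p)
  expect_equal(st1$invest[1], 0.4)
  # portfolio shortfall of 8 points spreads kappa * 8/40 to non-interacted
  st2 <- update_need_on_portfolio(st, c(2, 3), round_net = -8, endowment = 40,
                                  params = p)
  expect_equal(st2$invest[2:3], c(0.3, 0.3))
  expect_equal(st2$invest[1], 0.8)
  expect_equal(st2$trust, st$trust)
  # profitable portfolio decays the need
  st3 <- update_need_on_portfolio(st, c(2, 3), round_net = 12, endowment = 40,
                                  params = p)
  expect_equal(st3$invest[2:3], c(0.1, 0.1))
})

test_that("trust is discounted on rounds without interaction", {
  p <- zero_params(delta = 0.1)
  st <- trust_state(1, p)
  st$trust[1] <- 2.0
  expect_equal(discount_on_unavailability(st, 1, p)$trust[1], 1.9)
  p0 <- trust_params(delta = 0, initial_trust = 0)
  expect_equal(discount_on_unavailability(st, 1, p0)$trust[1], 2.0)
})

test_that("a never-allocated-to counterpart's trust declines at delta per round", {
  cfg <- game_config()
  p <- trust_params()
  log <- run_game(constant_policy(c(0, 0, 0)), cfg, seed = 2)
  trace <- infer_accumulators(log, p, cfg)
  tr3 <- trace$trust[trace$confederate_id == 3]
  expect_equal(tr3, p$initial_trust - p$delta * seq_len(120))
})

test_that("rewards follow the three-regime scheme plus the endowment kept", {
  expect_equal(compute_reward("trust", own_payoff = 12, other_payoff = 4,
                              allocated = 10, kept = 30), 46)
  expect_equal(compute_reward("distrust", 0, 0, allocated = 5, kept = 35), 30)
  expect_equal(compute_reward("trust_necessity", 0, other_payoff = 16,
                              allocated = 10, kept = 30), 46)
  expect_error(compute_reward("bogus", 0, 0, 0), "unknown regime")
})

test_that("phase-1 generosity builds trust until expectations calibrate", {
  # interacting every round with an always-available 75%-return counterpart:
  # trust rises while returns beat the blended expectation, then plateaus;
  # it never decreases through the high-trustworthiness phase.
  cfg <- all_available_config()
  p <- trust_params()
  log <- run_game(constant_policy(c(20, 0, 0)), cfg, seed = 4)
  trace <- infer_accumulators(log, p, cfg)
  tr1 <- trace$trust[trace$confederate_id == 1][1:70]
  expect_true(all(diff(tr1) >= 0))
  expect_gt(tr1[5], p$initial_trust)  # early surprise raises trust
  # after the switch to the neutral strategy, trust collapses
  tr_all <- trace$trust[trace$confederate_id == 1]
  expect_lt(tr_all[85], 0)
  expect_lt(min(tr_all[71:120]), tr_all[70])
})
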