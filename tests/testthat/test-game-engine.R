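test_that("config invariants are enforced", {
  expect_error(game_config(endowment = 0), "endowment")
  expect_error(game_config(multiplier = 0.5), "multiplier")
  expect_error(game_config(switch_round = 200), "switch_round")
  expect_error(game_config(phase1_return_frac = 1.2), "phase1_return_frac")
  expect_error(game_config(schedules = c(1, 0.5)), "schedule")
  cfg <- game_config()
  expect_equal(cfg$endowment, 40)
  expect_equal(cfg$multiplier, 4)
  expect_equal(cfg$n_rounds, 120L)
  expect_equal(cfg$switch_round, 70L)
  expect_equal(cfg$schedules, c(1, 3, 6))
})

test_that("multiplied amount follows the four-fold rule and rejects bad input", {
  cfg <- game_config()
  expect_equal(multiplied_amount(4, cfg), 16)
  expect_equal(multiplied_amount(0, cfg), 0)
  expect_equal(multiplied_amount(10, cfg), 40)
  expect_error(multiplied_amount(-1, cfg), "invalid allocation")
  expect_error(multiplied_amount(41, cfg), "invalid allocation")
})

test_that("availability draws match schedule periods", {
  cfg <- game_config()
  specs <- confederate_specs(cfg)
  # period 1: always available
  expect_true(all(replicate(50, availability_draw(specs[1, ]))))
  # period 3: empirical frequency about 1/3
  withr::with_seed(42, {
    draws <- replicate(1e5, availability_draw(specs[2, ]))
  })
  expect_equal(mean(draws), 1 / 3, tolerance = 0.03)
  # identical seed, identical spec: identical draw sequence
  d1 <- withr::with_seed(7, replicate(100, availability_draw(specs[3, ])))
  d2 <- withr::with_seed(7, replicate(100, availability_draw(specs[3, ])))
  expect_identical(d1, d2)
})

test_that("phase-1 returns are a deterministic 75% of the multiplied amount", {
  cfg <- game_config()
  spec <- confederate_specs(cfg)[1, ]
  expect_equal(confederate_return(16, round = 10, spec, cfg), 12)
  expect_equal(confederate_return(0, round = 1, spec, cfg), 0)
  # round-half-up on fractional returns: 0.75 * 6 = 4.5 -> 5
  expect_equal(confederate_return(6, round = 70, spec, cfg), 5)
})

test_that("phase-2 returns average 25% of the multiplied amount, bounded by it", {
  cfg <- game_config()
  spec <- confederate_specs(cfg)[1, ]
  withr::with_seed(11, {
    draws <- replicate(1e4, confederate_return(160, round = 71, spec, cfg))
  })
  expect_true(all(draws >= 0 & draws <= 160))
  expect_equal(mean(draws), 40, tolerance = 0.3 / 40)
})

test_that("settle_round fills every ledger field per the stated rules", {
  cfg <- all_available_config()
  withr::with_seed(1, rec <- settle_round(c(4, 0, 0), round = 5, cfg))
  expect_equal(rec$kept[1], 36)
  expect_equal(rec$given, c(16, 0, 0))
  expect_equal(rec$returned, c(12, 0, 0))
  expect_equal(rec$sender_total[1], 48)

  # unavailable confederate: allocation refunded, sender made whole
  cfg2 <- game_config(schedules = c(1, 1e9, 1))
  withr::with_seed(1, rec2 <- settle_round(c(0, 5, 0), round = 3, cfg2))
  expect_false(rec2$available[2])
  expect_equal(rec2$refunded[1], 5)
  expect_equal(rec2$sender_total[1], 40)

  withr::with_seed(1, rec3 <- settle_round(c(0, 0, 0), round = 1, cfg))
  expect_equal(rec3$sender_total[1], 40)

  expect_error(settle_round(c(30, 20, 0), 1, cfg), "invalid allocation")
  expect_error(settle_round(c(-1, 0, 0), 1, cfg), "invalid allocation")
})

test_that("run_game produces complete, reproducible, invariant-satisfying logs", {
  cfg <- game_config()
  log0 <- run_game(constant_policy(c(0, 0, 0)), cfg, seed = 3)
  expect_equal(nrow(log0), 120 * 3)
  expect_true(all(log0$sender_total == 40))
  expect_valid_log(log0)

  log1 <- run_game(constant_policy(c(10, 0, 0)), cfg, seed = 3)
  expect_true(all(log1$sender_total[log1$round <= 70] == 60))
  expect_valid_log(log1)

  log2 <- run_game(constant_policy(c(10, 0, 0)), cfg, seed = 3)
  expect_identical(log1, log2)

  # errors from a bad policy carry the round index
  bad <- function(round, history) if (round == 4) c(50, 0, 0) else c(0, 0, 0)
  expect_error(run_game(bad, cfg, seed = 1), "round 4")
})

test_that("endowment is conserved and phase-1 profit identity holds in random games", {
  cfg <- game_config(n_rounds = 60)
  withr::with_seed(99, {
    for (i in 1:5) {
      policy <- function(round, history) {
        a <- sample(0:13, 3)
        a
      }
      log <- run_game(policy, cfg)
      expect_valid_log(log)
      by_round <- split(log, log$round)
      for (rec in by_round) {
        expect_equal(rec$kept[1] + sum(rec$allocation), 40)
        inter <- rec$available & rec$allocation > 0
        # rounds <= 70 here: returned is exactly round(3 * allocation)
        expect_equal(rec$returned[inter], floor(3 * rec$allocation[inter] + 0.5))
      }
    }
  })
})

test_that("phase-2 strategy is break-even and availability rates converge", {
  cfg <- game_config(n_rounds = 120)
  logs <- lapply(1:40, function(s)
    run_game(constant_policy(c(5, 5, 5)), cfg, seed = 1000 + s))
  all_rows <- dplyr::bind_rows(logs)
  p2 <- all_rows[all_rows$round > 70 & all_rows$available, ]
  # mean(returned - allocated) per interaction -> 0
  expect_equal(mean(p2$returned - p2$allocation), 0, tolerance = 0.1)
  rates <- tapply(all_rows$available, all_rows$confederate_id, mean)
  expect_equal(as.numeric(rates), c(1, 1 / 3, 1 / 6), tolerance = 0.05)
})
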