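# Round mechanics of the multi-arm trust game: availability draws, the
# multiplier, the two confederate return policies, and round settlement.
# Monetary quantities are integer points; fractional returns round half-up.

round_half_up <- function(x) floor(x + 0.5)

#' Draw a confederate's availability for one round
#'
#' A confederate on schedule period `p` is available each round independently
#' with probability `1/p`, so availability occurs every `p` rounds on average;
#' period 1 means available on every round. Uses the current R random stream.
#'
#' @param spec One row of [confederate_specs()] (or any list with a
#'   `schedule_period` field).
#' @return Logical scalar.
#' @export
availability_draw <- function(spec) {
  p <- spec$schedule_period
  stopifnot(is.numeric(p), length(p) == 1, p >= 1)
  if (p == 1) return(TRUE)
  stats::runif(1) < 1 / p
}

#' Multiplied amount given to an available receiver
#'
#' @param allocation Points the sender allocated (0 to `endowment`).
#' @param config A [game_config()].
#' @return `multiplier * allocation`, in points.
#' @export
#' @examples
#' multiplied_amount(4, game_config())  # 16
multiplied_amount <- function(allocation, config) {
  if (any(allocation < 0) || any(allocation > config$endowment)) {
    stop("invalid allocation: must lie in [0, endowment].", call. = FALSE)
  }
  config$multiplier * allocation
}

#' Points returned by a confederate receiver
#'
#' Phase 1 (rounds up to `switch_round`): the confederate returns a
#' deterministic `phase1_return_frac` of the multiplied amount, rounded
#' half-up — with the defaults, three times the allocated amount. Phase 2: a
#' stochastic integer return drawn as Binomial(`given`, `phase2_return_frac`),
#' bounded in `[0, given]` with mean exactly `phase2_return_frac * given` —
#' with the defaults the sender gets back, on average, exactly what it
#' allocated (the neutral, break-even strategy).
#'
#' @param given Multiplied points the confederate received this round.
#' @param round 1-based round index.
#' @param spec One row of [confederate_specs()].
#' @param config A [game_config()].
#' @return Integer points returned.
#' @export
#' @examples
#' confederate_return(16, round = 10, confederate_specs(game_config())[1, ],
#'                    game_config())  # 12
confederate_return <- function(given, round, spec, config) {
  stopifnot(given >= 0)
  if (round <= config$switch_round) {
    round_half_up(spec$phase1_return_frac * given)
  } else {
    stats::rbinom(1, size = as.integer(given), prob = spec$phase2_return_frac)
  }
}

#' Settle one round of the game
#'
#' Draws each confederate's availability, applies the multiplier and return
#' policies, refunds allocations made to unavailable confederates, and returns
#' the complete per-round ledger. The sender keeps `endowment - sum(allocations)`
#' and ends the round with `kept + refunded + sum(returned)` points.
#'
#' @param allocations Numeric vector of points, one per confederate;
#'   non-negative, summing to at most the endowment.
#' @param round 1-based round index.
#' @param config A [game_config()].
#' @param specs Confederate specs, see [confederate_specs()].
#' @return A tibble with one row per confederate and columns `round`,
#'   `confederate_id`, `allocation`, `available`, `given`, `returned`, `kept`,
#'   `refunded`, `sender_total` (the last three are per-round values repeated
#'   on each row).
#' @export
settle_round <- function(allocations, round, config, specs = confederate_specs(config)) {
  k <- nrow(specs)
  if (length(allocations) != k) {
    stop(sprintf("expected %d allocations, got %d.", k, length(allocations)),
         call. = FALSE)
  }
  if (any(allocations < 0) || sum(allocations) > config$endowment) {
    stop(sprintf(
      "invalid allocation on round %d: each must be >= 0 and their sum <= %g.",
      round, config$endowment), call. = FALSE)
  }
  available <- vapply(seq_len(k), function(i) availability_draw(specs[i, ]),
                      logical(1))
  given <- ifelse(available, multiplied_amount(allocations, config), 0)
  returned <- vapply(seq_len(k), function(i) {
    if (available[i]) {
      as.numeric(confederate_return(given[i], round, specs[i, ], config))
    } else 0
  }, numeric(1))
  kept <- config$endowment - sum(allocations)
  refunded <- sum(allocations[!available])
  tibble::tibble(
    round = as.integer(round),
    confederate_id = specs$confederate_id,
    allocation = as.numeric(allocations),
    available = available,
    given = as.numeric(given),
    returned = returned,
    kept = kept,
    refunded = refunded,
    sender_total = kept + refunded + sum(returned)
  )
}

#' Simulate a full game under a sender policy
#'
#' Runs the round loop: on each round the policy proposes allocations given the
#' history so far, the round is settled by [settle_round()], and the record is
#' appended to the log. With a fixed seed and a deterministic policy the log is
#' bit-identical across replays.
#'
#' @param policy `function(round, history)` returning a numeric vector of
#'   allocations (one per confederate); `history` is the long-format log of
#'   rounds settled so far (zero rows on round 1).
#' @param config A [game_config()].
#' @param specs Confederate specs, see [confederate_specs()].
#' @param seed Optional integer; when supplied the global RNG is seeded (and
#'   restored on exit).
#' @return A `matg_log`: a long tibble, `n_rounds * n_confederates` rows, the
#'   columns of [settle_round()], with the config attached as attribute
#'   `config`.
#' @export
#' @examples
#' cfg <- game_config(n_rounds = 5)
#' log <- run_game(function(round, history) c(10, 0, 0), cfg, seed = 1)
run_game <- function(policy, config, specs = confederate_specs(config),
                     seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  rows <- vector("list", config$n_rounds)
  history <- empty_log(config)
  for (r in seq_len(config$n_rounds)) {
    alloc <- policy(r, history)
    rec <- tryCatch(
      settle_round(alloc, r, config, specs),
      error = function(e) {
        stop(sprintf("round %d: %s", r, conditionMessage(e)), call. = FALSE)
      }
    )
    rows[[r]] <- rec
    history <- dplyr::bind_rows(history, rec)
  }
  new_game_log(history, config)
}

empty_log <- function(config) {
  tibble::tibble(
    round = integer(), confederate_id = integer(), allocation = numeric(),
    available = logical(), given = numeric(), returned = numeric(),
    kept = numeric(), refunded = numeric(), sender_total = numeric()
  )
}

new_game_log <- function(tbl, config) {
  structure(tbl, config = config,
            class = c("matg_log", class(tibble::tibble())))
}

#' Validate a game log against the paradigm's bookkeeping rules
#'
#' Re-checks every invariant of the per-round ledger: consecutive 1-based
#' rounds, conservation of the endowment (`kept + sum(allocations)`), the
#' multiplier identity for available confederates, zero `given`/`returned` on
#' unavailable rounds, returns bounded by the amount given, refunds equal to
#' the allocations of unavailable confederates, and the sender-total identity.
#'
#' @param log A game log tibble (long format).
#' @param config The [game_config()] the log claims to follow; defaults to the
#'   log's attached config.
#' @return The log, invisibly, if valid; otherwise an error naming the first
#'   offending round and rule.
#' @export
validate_game_log <- function(log, config = attr(log, "config")) {
  if (is.null(config)) {
    stop("no config attached to log; pass one explicitly.", call. = FALSE)
  }
  need <- c("round", "confederate_id", "allocation", "available", "given",
            "returned", "kept", "refunded", "sender_total")
  missing <- setdiff(need, names(log))
  if (length(missing) > 0) {
    stop(sprintf("log is missing column(s): %s.",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rounds <- sort(unique(log$round))
  if (!identical(as.integer(rounds), seq_len(config$n_rounds))) {
    stop(sprintf("rounds must be exactly 1..%d.", config$n_rounds),
         call. = FALSE)
  }
  fail <- function(round, rule) {
    stop(sprintf("log invariant violated on round %d: %s.", round, rule),
         call. = FALSE)
  }
  tol <- 1e-9
  for (r in rounds) {
    rec <- log[log$round == r, ]
    if (abs(rec$kept[1] + sum(rec$allocation) - config$endowment) > tol) {
      fail(r, "kept + sum(allocations) must equal the endowment")
    }
    if (any(abs(rec$given - ifelse(rec$available,
                                   config$multiplier * rec$allocation, 0)) > tol)) {
      fail(r, "given must be multiplier * allocation when available, else 0")
    }
    if (any(rec$returned < -tol | rec$returned > rec$given + tol)) {
      fail(r, "returned must lie in [0, given]")
    }
    if (abs(rec$refunded[1] - sum(rec$allocation[!rec$available])) > tol) {
      fail(r, "refunded must equal allocations to unavailable confederates")
    }
    if (abs(rec$sender_total[1] -
            (rec$kept[1] + rec$refunded[1] + sum(rec$returned))) > tol) {
      fail(r, "sender_total must equal kept + refunded + sum(returned)")
    }
  }
  invisible(log)
}

# Seed the global RNG for the calling frame, restoring the prior state on exit.
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
  invisible(seed)
}

# Derive independent sub-seeds below 2^31 from one master seed.
derive_seeds <- function(seed, n) {
  local_seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
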