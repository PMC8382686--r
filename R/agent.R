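# The sender agent: each round it orders the counterparts by learned payoff,
# predicts each one's return by blending episodic instances, selects an
# allocation adjustment from procedural utilities in the (regime, predicted
# return) context, and after feedback encodes instances, updates the trust
# accumulators, and reinforces the fired rules with the round's total reward.

#' Create a cognitive sender agent
#'
#' The agent combines three learning systems: an instance memory with
#' activation-weighted blending ([memory_store()]), trust and trust-invest
#' accumulators ([trust_params()]), and procedural utilities over
#' increase/decrease/hold allocation rules ([utility_table()]). Lesioned
#' variants remove the trust-invest accumulator (`"trust_only"`) or both
#' accumulators (`"no_trust"`, whose round reward reduces to the sender's own
#' payoff plus the endowment kept).
#'
#' @param config A [game_config()].
#' @param variant `"full"`, `"trust_only"` or `"no_trust"`.
#' @param trust A [trust_params()].
#' @param memory A fresh [memory_store()] (sets `d` and `tau`).
#' @param utilities A fresh [utility_table()] (sets `alpha`, `s`, `step`).
#' @return A `matg_agent` object.
#' @export
cognitive_agent <- function(config,
                            variant = c("full", "trust_only", "no_trust"),
                            trust = trust_params(),
                            memory = memory_store(),
                            utilities = utility_table()) {
  variant <- match.arg(variant)
  k <- length(config$schedules)
  structure(
    list(
      config = config,
      variant = variant,
      params = trust,
      memory = memory,
      utilities = utilities,
      state = trust_state(k, trust),
      cum_payoff = rep(0, k),
      last_alloc = rep(0, k),
      last_return_frac = rep(NA_real_, k),
      last_interaction_round = rep(NA_integer_, k),
      current_round = NA_integer_,
      last_observed_round = 0L,
      fired = list(context = character(), action = character())
    ),
    class = "matg_agent"
  )
}

#' @export
print.matg_agent <- function(x, ...) {
  cat(sprintf("<matg_agent> variant '%s', %d counterpart(s), after round %d\n",
              x$variant, length(x$cum_payoff), x$last_observed_round))
  invisible(x)
}

# Variant-aware regime: the no_trust lesion has no accumulators (its reward is
# handled separately); trust_only lacks the invest accumulator, so trust
# necessity can never arise.
agent_regime <- function(agent, counterpart) {
  if (agent$variant == "no_trust") return("none")
  regime <- classify_regime(agent$state, counterpart, agent$params)
  if (agent$variant == "trust_only" && regime == "trust_necessity") {
    regime <- "distrust"
  }
  regime
}

# Prior return-fraction prediction before any experience with a counterpart.
prior_prediction <- function(params) {
  min(max(0.5 + 0.1 * params$initial_trust, 0), 1)
}

#' Decide this round's allocations
#'
#' Counterparts are processed in an order sampled by a Boltzmann rule over
#' cumulative received payoff (uniform on round 1), sharing the procedural
#' noise temperature. For each counterpart the agent blends a return
#' prediction from memory (falling back to the prior when it has no
#' experience), selects increase/decrease/hold in the (regime, predicted
#' return) context, and applies it to the previous allocation, clipped so the
#' running total never exceeds the endowment.
#'
#' @param agent A [cognitive_agent()].
#' @param round 1-based round index.
#' @return A list with elements `agent` (the updated agent, holding the fired
#'   rules) and `allocations` (numeric, one per counterpart).
#' @export
decide_allocations <- function(agent, round) {
  k <- length(agent$cum_payoff)
  cfg <- agent$config
  s <- agent$utilities$s
  w <- exp((agent$cum_payoff - max(agent$cum_payoff)) / s)
  w <- pmax(w, 1e-12)
  order_cp <- sample.int(k, k, prob = w)
  remaining <- cfg$endowment
  alloc <- numeric(k)
  fired_ctx <- character(k)
  fired_act <- character(k)
  for (j in seq_len(k)) {
    cp <- order_cp[j]
    regime <- agent_regime(agent, cp)
    gap <- round - agent$last_interaction_round[cp]
    mem_ctx <- memory_context(agent$last_return_frac[cp], gap)
    pred <- blended_prediction(agent$memory, cp, mem_ctx, round)
    if (is.na(pred)) pred <- prior_prediction(agent$params)
    ctx <- rule_context(regime, predicted_return_bin(pred, cfg$multiplier))
    bias <- switch(regime,
      trust_necessity = c(increase = agent$params$invest_bias),
      distrust = c(decrease = agent$params$withdraw_bias),
      NULL)
    action <- select_rule(agent$utilities, ctx, bias = bias)
    alloc[cp] <- apply_action(action, agent$last_alloc[cp], remaining,
                              agent$utilities$step)
    remaining <- remaining - alloc[cp]
    fired_ctx[j] <- ctx
    fired_act[j] <- action
  }
  agent$current_round <- as.integer(round)
  agent$fired <- list(context = fired_ctx, action = fired_act)
  list(agent = agent, allocations = alloc)
}

#' Learn from one settled round
#'
#' For every counterpart that was available and allocated to, the observed
#' return fraction is encoded as an instance and the trust accumulator is
#' updated on the net outcome; every other counterpart's trust is discounted.
#' The round's total reward — the regime-dependent per-counterpart rewards plus
#' the endowment kept — then reinforces every rule that fired this round. Works
#' both in forward simulation (after [decide_allocations()]) and in yoked
#' replay of a logged round (no prior decision; no rules to reinforce).
#'
#' @param agent A [cognitive_agent()].
#' @param record One round of a game log (the tibble from [settle_round()] or
#'   an equivalent list of per-confederate vectors).
#' @param config A [game_config()]; defaults to the agent's.
#' @return The updated agent, with the round's total reward attached as field
#'   `last_reward`.
#' @export
observe_feedback <- function(agent, record, config = agent$config) {
  r <- record$round[1]
  if (!is.na(agent$current_round)) {
    if (r != agent$current_round) {
      stop(sprintf("clock error: observed round %d but decided round %d.",
                   r, agent$current_round), call. = FALSE)
    }
  } else if (r != agent$last_observed_round + 1L) {
    stop(sprintf("clock error: observed round %d after round %d.",
                 r, agent$last_observed_round), call. = FALSE)
  }
  k <- length(agent$cum_payoff)
  ord <- order(record$confederate_id)
  allocation <- record$allocation[ord]
  available <- record$available[ord]
  given <- record$given[ord]
  returned <- record$returned[ord]
  kept <- record$kept[1]

  # Rewards use the start-of-round regime — the state under which the
  # decisions were made. Refunded allocations count as retained endowment,
  # and the regime rewards apply to actually-transferred points only: an
  # annulled transaction is neither a distrust exposure nor an investment.
  refunded <- record$refunded[1]
  total_reward <- kept + refunded
  for (cp in seq_len(k)) {
    interacted <- available[cp] && allocation[cp] > 0
    own <- if (interacted) returned[cp] - allocation[cp] else 0
    other <- if (interacted) given[cp] - returned[cp] else 0
    transferred <- if (interacted) allocation[cp] else 0
    if (agent$variant == "no_trust") {
      total_reward <- total_reward + own
    } else {
      regime <- agent_regime(agent, cp)
      total_reward <- total_reward +
        compute_reward(regime, own, other, transferred, kept = 0)
    }
  }

  interacted <- available & allocation > 0
  for (cp in seq_len(k)) {
    if (interacted[cp]) {
      value <- returned[cp] / given[cp]
      gap <- r - agent$last_interaction_round[cp]
      mem_ctx <- memory_context(agent$last_return_frac[cp], gap)
      if (agent$variant != "no_trust") {
        # expectation at decision time: memory not yet updated with this round
        pred <- blended_prediction(agent$memory, cp, mem_ctx, r)
        if (is.na(pred)) pred <- prior_prediction(agent$params)
        agent$state <- update_on_outcome(agent$state, cp, allocation[cp],
                                         returned[cp], config$endowment,
                                         agent$params,
                                         expected = pred * given[cp])
      }
      agent$memory <- encode_instance(agent$memory, cp, mem_ctx, value, r)
      agent$last_return_frac[cp] <- value
      agent$last_interaction_round[cp] <- as.integer(r)
      agent$cum_payoff[cp] <- agent$cum_payoff[cp] + returned[cp]
    } else if (agent$variant != "no_trust") {
      agent$state <- discount_on_unavailability(agent$state, cp, agent$params)
    }
  }
  if (agent$variant == "full") {
    round_net <- sum(returned[interacted] - allocation[interacted])
    agent$state <- update_need_on_portfolio(agent$state, which(!interacted),
                                            round_net, config$endowment,
                                            agent$params)
  }
  if (agent$variant == "trust_only") {
    agent$state$invest[] <- 0
  }

  # utilities learn on endowment units so the Boltzmann temperature is
  # commensurate with the reward scale
  agent$utilities <- reinforce_rules(agent$utilities, agent$fired$context,
                                     agent$fired$action,
                                     total_reward / config$endowment)
  agent$fired <- list(context = character(), action = character())
  agent$current_round <- NA_integer_
  agent$last_observed_round <- as.integer(r)
  agent$last_alloc <- allocation
  agent$last_reward <- total_reward
  agent
}

# Fast internal settlement returning plain vectors (same mechanics and RNG
# semantics as settle_round, without the tibble overhead).
settle_round_core <- function(allocations, round, config, periods,
                              phase1_frac, phase2_frac) {
  k <- length(periods)
  available <- logical(k)
  for (i in seq_len(k)) {
    available[i] <- if (periods[i] == 1) TRUE else stats::runif(1) < 1 / periods[i]
  }
  given <- ifelse(available, config$multiplier * allocations, 0)
  returned <- numeric(k)
  for (i in seq_len(k)) {
    if (available[i]) {
      returned[i] <- if (round <= config$switch_round) {
        round_half_up(phase1_frac[i] * given[i])
      } else {
        stats::rbinom(1, size = as.integer(given[i]), prob = phase2_frac[i])
      }
    }
  }
  kept <- config$endowment - sum(allocations)
  refunded <- sum(allocations[!available])
  list(round = rep(as.integer(round), k), confederate_id = seq_len(k),
       allocation = allocations, available = available, given = given,
       returned = returned, kept = rep(kept, k), refunded = rep(refunded, k),
       sender_total = rep(kept + refunded + sum(returned), k))
}

#' Simulate the cognitive model playing the game
#'
#' Runs `n_runs` independently seeded games of the chosen model variant and
#' averages the allocation curves across runs — the quantity model fits are
#' scored on. Per-run logs and accumulator traces are retained unless
#' `keep_logs = FALSE`.
#'
#' @param variant `"full"`, `"trust_only"` or `"no_trust"`.
#' @param config A [game_config()].
#' @param specs Confederate specs; default [confederate_specs()] of `config`.
#' @param trust A [trust_params()].
#' @param memory A fresh [memory_store()].
#' @param utilities A fresh [utility_table()].
#' @param n_runs Number of simulated games.
#' @param seed Integer master seed; per-run seeds are derived from it.
#' @param keep_logs Keep per-run logs and traces? Default `TRUE`.
#' @return A `matg_sim` object: list with `curves` (tibble `round`,
#'   `confederate_id`, `allocation` — the mean across runs), `logs` and
#'   `traces` (lists, if kept), `variant`, `n_runs`, `seed`, `config`.
#' @export
run_model_game <- function(variant = c("full", "trust_only", "no_trust"),
                           config = game_config(),
                           specs = confederate_specs(config),
                           trust = trust_params(),
                           memory = memory_store(),
                           utilities = utility_table(),
                           n_runs = 100, seed = NULL, keep_logs = TRUE) {
  variant <- match.arg(variant)
  stopifnot(n_runs >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  run_seeds <- derive_seeds(seed, n_runs)
  k <- nrow(specs)
  n <- config$n_rounds
  periods <- specs$schedule_period
  alloc_sum <- matrix(0, n, k)
  logs <- if (keep_logs) vector("list", n_runs) else NULL
  traces <- if (keep_logs) vector("list", n_runs) else NULL
  for (run in seq_len(n_runs)) {
    local_seed(run_seeds[run])
    agent <- cognitive_agent(config, variant, trust, memory, utilities)
    rec_rows <- if (keep_logs) vector("list", n) else NULL
    tr_trust <- matrix(0, n, k)
    tr_invest <- matrix(0, n, k)
    for (r in seq_len(n)) {
      d <- decide_allocations(agent, r)
      agent <- d$agent
      rec <- settle_round_core(d$allocations, r, config, periods,
                               specs$phase1_return_frac,
                               specs$phase2_return_frac)
      agent <- observe_feedback(agent, rec, config)
      alloc_sum[r, ] <- alloc_sum[r, ] + d$allocations
      tr_trust[r, ] <- agent$state$trust
      tr_invest[r, ] <- agent$state$invest
      if (keep_logs) rec_rows[[r]] <- rec
    }
    if (keep_logs) {
      log_tbl <- tibble::as_tibble(
        lapply(stats::setNames(names(rec_rows[[1]]), names(rec_rows[[1]])),
               function(col) unlist(lapply(rec_rows, `[[`, col)))
      )
      logs[[run]] <- new_game_log(log_tbl, config)
      traces[[run]] <- trace_tibble(tr_trust, tr_invest, trust)
    }
  }
  curves <- tibble::tibble(
    round = rep(seq_len(n), k),
    confederate_id = rep(seq_len(k), each = n),
    allocation = as.vector(alloc_sum) / n_runs
  )
  structure(
    list(curves = curves, logs = logs, traces = traces, variant = variant,
         n_runs = n_runs, seed = seed, config = config, trust = trust),
    class = "matg_sim"
  )
}

trace_tibble <- function(tr_trust, tr_invest, params) {
  n <- nrow(tr_trust)
  k <- ncol(tr_trust)
  trust <- as.vector(tr_trust)
  invest <- as.vector(tr_invest)
  structure(
    tibble::tibble(
      round = rep(seq_len(n), k),
      confederate_id = rep(seq_len(k), each = n),
      trust = trust,
      invest = invest,
      regime = classify_regime_values(trust, invest, params)
    ),
    class = c("matg_trace", class(tibble::tibble()))
  )
}

#' @export
print.matg_sim <- function(x, ...) {
  cat(sprintf("<matg_sim> variant '%s', %d run(s), %d rounds, seed %s\n",
              x$variant, x$n_runs, x$config$n_rounds, format(x$seed)))
  cat("mean allocation by phase:\n")
  sw <- x$config$switch_round
  s <- dplyr::summarise(
    dplyr::group_by(x$curves, .data$confederate_id,
                    phase = ifelse(.data$round <= sw, "phase1", "phase2")),
    allocation = mean(.data$allocation), .groups = "drop"
  )
  print(tidyr::pivot_wider(s, names_from = "phase", values_from = "allocation"))
  invisible(x)
}
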