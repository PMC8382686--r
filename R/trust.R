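# Trust and trust-invest accumulators. Trust integrates normalized net
# outcomes of interactions and is discounted on rounds without interaction;
# trust-invest rises while outcomes fail to pay off and decays otherwise.
# Together with two thresholds they classify each counterpart into one of
# three regimes — trust, distrust, trust necessity — which select the reward
# the procedural system learns from.

#' Parameters of the trust accumulators
#'
#' @param trust_threshold Threshold above which the trust accumulator puts a
#'   counterpart in the trust regime. Default 0.
#' @param invest_threshold Threshold above which the trust-invest accumulator
#'   puts a below-trust-threshold counterpart in the trust-necessity regime.
#'   Default 0.05 — a small positive level, so trust necessity requires a
#'   meaningful unmet need: because invest decays geometrically with every
#'   interaction, a zero threshold would make necessity permanent once ignited,
#'   whereas a positive one lets the regime (and with it the reallocation bump)
#'   fade once the portfolio quiets down.
#' @param eta Gain on the net-outcome component of the trust update: trust
#'   grows by `eta * (returned - allocated) / endowment` per interaction.
#'   Default 1.
#' @param mu Gain on the expectation-violation component: when an expected
#'   return is supplied, trust additionally moves by
#'   `mu * (returned - expected) / endowment`. Default 2 — violations weigh
#'   about twice as much per point as realized gains, the usual magnitude of
#'   loss aversion.
#' @param trust_cap Upper saturation of the trust accumulator (state trust is
#'   bounded; accumulated goodwill cannot grow without limit, which is what
#'   keeps a betrayal shock decisive). Default 2.
#' @param delta Trust discount applied on every round without an interaction
#'   with the counterpart (unavailable, or simply not allocated to). Default
#'   0.15 — large enough that trust in an intermittently available counterpart
#'   erodes between interactions faster than routine calibrated returns can
#'   replenish it, which is what makes behavioral trust track the interaction
#'   schedule.
#' @param kappa Trust-invest rate: interacting with a counterpart decays its
#'   invest accumulator by the factor `1 - kappa`; while it goes unexplored and
#'   the round's investments fail to pay off, invest grows by `kappa` times the
#'   normalized portfolio shortfall ([update_need_on_portfolio()]). Default
#'   0.5.
#' @param invest_bias Strength of the trust-development drive: while a
#'   counterpart is in the trust-necessity regime, the `increase` allocation
#'   rule receives this selection-time utility bonus (in endowment-reward
#'   units), so the agent actively invests rather than waiting for slow
#'   reinforcement to discover that investing pays. Learned utilities stack on
#'   top and can override it. Default 0.5.
#' @param withdraw_bias The mirror-image withdrawal drive: while a counterpart
#'   is in the distrust regime, the `decrease` rule receives this
#'   selection-time bonus, producing the sharp pull-back from a counterpart
#'   whose trust has collapsed instead of a slow reinforcement-paced decline.
#'   Default 0.5.
#' @param initial_trust Starting value of every counterpart's trust
#'   accumulator; also nudges the prior return prediction of a fresh agent.
#'   Default 1 — one endowment's worth of initial goodwill, so a fresh
#'   counterpart starts inside the trust regime and the agent extends trust
#'   before any evidence (without it, distrust is self-sealing: nothing is
#'   ever allocated, so nothing is ever learned).
#' @return A `matg_trust_params` object.
#' @export
trust_params <- function(trust_threshold = 0, invest_threshold = 0.05,
                         eta = 1, mu = 2, delta = 0.15, kappa = 0.5,
                         invest_bias = 0.5, withdraw_bias = 0.5,
                         initial_trust = 1, trust_cap = 2) {
  stopifnot(eta > 0, mu >= 0, kappa > 0, delta >= 0, invest_bias >= 0,
            withdraw_bias >= 0, trust_cap >= initial_trust)
  structure(
    list(trust_threshold = trust_threshold,
         invest_threshold = invest_threshold,
         eta = eta, mu = mu, delta = delta, kappa = kappa,
         invest_bias = invest_bias, withdraw_bias = withdraw_bias,
         initial_trust = initial_trust, trust_cap = trust_cap),
    class = "matg_trust_params"
  )
}

#' Initialize trust state for a set of counterparts
#'
#' @param n_counterparts Number of counterparts.
#' @param params A [trust_params()].
#' @return A `matg_trust_state` with per-counterpart `trust` (at
#'   `initial_trust`) and `invest` (at 0) accumulators.
#' @export
trust_state <- function(n_counterparts, params = trust_params()) {
  structure(
    list(trust = rep(params$initial_trust, n_counterparts),
         invest = rep(0, n_counterparts)),
    class = "matg_trust_state"
  )
}

#' Classify a counterpart's trust regime
#'
#' Exactly one regime applies for any accumulator values: trust above its
#' threshold is `"trust"`; otherwise invest above its threshold is
#' `"trust_necessity"`; otherwise `"distrust"`.
#'
#' @param state A [trust_state()].
#' @param counterpart Counterpart index.
#' @param params A [trust_params()].
#' @return One of `"trust"`, `"distrust"`, `"trust_necessity"`.
#' @export
classify_regime <- function(state, counterpart, params = trust_params()) {
  classify_regime_values(state$trust[counterpart], state$invest[counterpart],
                         params)
}

# Vectorized core used by traces.
classify_regime_values <- function(trust, invest, params) {
  ifelse(trust > params$trust_threshold, "trust",
         ifelse(invest > params$invest_threshold, "trust_necessity",
                "distrust"))
}

#' Update accumulators after an interaction outcome
#'
#' The trust accumulator integrates two endowment-normalized signals: the net
#' outcome, `eta * (returned - allocated) / endowment` (profitable reciprocity
#' builds trust, exploitation erodes it), and — when the caller supplies the
#' return it `expected` — the expectation violation,
#' `mu * (returned - expected) / endowment` (a counterpart that returns less
#' than anticipated loses trust even when the sender still breaks even). The
#' accumulator saturates at `trust_cap`, so goodwill is bounded and a sharp
#' violation is always decisive. The cognitive agent passes its blended
#' instance-memory prediction as the expectation; without one the update
#' reduces to the plain net-outcome rule.
#'
#' Any interaction consumes the trust-invest accumulator (decay by the factor
#' `1 - kappa`): the need to develop trust with a counterpart falls while one
#' is actually interacting with it (see [update_need_on_portfolio()] for how
#' it builds up). A zero allocation carries no evidence: trust is untouched
#' and invest simply decays.
#'
#' @param state A [trust_state()].
#' @param counterpart Counterpart index.
#' @param allocated Points the sender allocated this round.
#' @param returned Points the counterpart returned.
#' @param endowment Per-round endowment (the normalizer).
#' @param params A [trust_params()].
#' @param expected Expected return in points; `NULL` (default) applies the
#'   net-outcome rule alone.
#' @return The updated state.
#' @export
#' @examples
#' st <- trust_state(1, trust_params(initial_trust = 0))
#' update_on_outcome(st, 1, allocated = 10, returned = 30, endowment = 40)$trust
#' # +0.5: three times the allocation came back
update_on_outcome <- function(state, counterpart, allocated, returned,
                              endowment, params = trust_params(),
                              expected = NULL) {
  stopifnot(allocated >= 0)
  if (allocated == 0) {
    state$invest[counterpart] <- state$invest[counterpart] * (1 - params$kappa)
    return(state)
  }
  delta_trust <- params$eta * (returned - allocated) / endowment
  if (!is.null(expected)) {
    delta_trust <- delta_trust +
      params$mu * (returned - expected) / endowment
  }
  state$trust[counterpart] <- min(state$trust[counterpart] + delta_trust,
                                  params$trust_cap)
  state$invest[counterpart] <- state$invest[counterpart] * (1 - params$kappa)
  state
}

#' Discount trust on a round without interaction
#'
#' Trust is decremented by `delta` even though no evidence of untrustworthiness
#' was observed — recency-driven trust discounting. The invest accumulator is
#' unchanged.
#'
#' @inheritParams update_on_outcome
#' @return The updated state.
#' @export
discount_on_unavailability <- function(state, counterpart,
                                       params = trust_params()) {
  state$trust[counterpart] <- state$trust[counterpart] - params$delta
  state
}

#' Update trust-invest of non-interacted counterparts from the portfolio
#' outcome
#'
#' Trust necessity is not purely dyadic: when the round's investments fail to
#' pay off overall, the need to develop trust extends to the counterparts one
#' is *not* interacting with. For every counterpart in `counterparts` the
#' invest accumulator rises by `kappa * max(-round_net, 0) / endowment` when
#' the portfolio net outcome is non-positive, and decays by the factor
#' `1 - kappa` when the portfolio pays off. Trust is untouched (it is
#' discounted separately, see [discount_on_unavailability()]).
#'
#' @param state A [trust_state()].
#' @param counterparts Indices of the counterparts without an interaction this
#'   round.
#' @param round_net Sum of `returned - allocated` over this round's
#'   interactions (0 if there were none).
#' @param endowment Per-round endowment (the normalizer).
#' @param params A [trust_params()].
#' @return The updated state.
#' @export
update_need_on_portfolio <- function(state, counterparts, round_net,
                                     endowment, params = trust_params()) {
  if (length(counterparts) == 0) return(state)
  if (round_net <= 0) {
    state$invest[counterparts] <- state$invest[counterparts] +
      params$kappa * (-round_net) / endowment
  } else {
    state$invest[counterparts] <- state$invest[counterparts] *
      (1 - params$kappa)
  }
  state
}

#' Regime-dependent round reward for one counterpart
#'
#' In the trust regime the reward is the joint payoff of trustor and trustee;
#' in distrust, a negative reward equal to the points allocated; in trust
#' necessity, the trustee's payoff alone (rewarding trust development). The
#' endowment kept is itself rewarded and may be added here via `kept` (the
#' agent adds it once per round, not once per counterpart).
#'
#' @param regime Output of [classify_regime()].
#' @param own_payoff Sender's net payoff from this counterpart this round
#'   (returned minus allocated; 0 if no interaction).
#' @param other_payoff Counterpart's payoff (given minus returned).
#' @param allocated Points allocated to the counterpart.
#' @param kept Points kept from the endowment (default 0).
#' @return The reward, in points.
#' @export
#' @examples
#' compute_reward("trust", own_payoff = 12, other_payoff = 4,
#'                allocated = 10, kept = 30)  # 46
compute_reward <- function(regime, own_payoff, other_payoff, allocated,
                           kept = 0) {
  base <- switch(regime,
    trust = own_payoff + other_payoff,
    distrust = -allocated,
    trust_necessity = other_payoff,
    stop(sprintf("unknown regime '%s'.", regime), call. = FALSE)
  )
  base + kept
}
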