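---
title: "The multi-arm trust game and its cognitive model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multi-arm trust game and its cognitive model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matg)
```

## The paradigm

In the multi-arm trust game (MATG) a sender repeatedly splits a per-round
endowment of 40 points between itself and three receivers. A receiver that
chooses to interact is given four times the points allocated to it and may
return any share; a receiver that does not interact forfeits the transfer and
the sender's allocation is refunded. The three receivers here are scripted
confederates that differ only in availability: one interacts every round, one
every three rounds on average, one every six. Through round 70 every
confederate returns 75% of the multiplied amount — three times the
allocation, a highly profitable arrangement for the sender. From round 71 the
strategy turns neutral: an integer return drawn as Binomial(given, 0.25), so
the sender gets back, in expectation, exactly what it allocated.

`game_config()` holds these constants; `settle_round()` and `run_game()`
implement the bookkeeping, and `validate_game_log()` re-checks every ledger
identity (conservation of the endowment, the multiplier rule, refunds,
sender totals) on anything the package reads or writes.

Availability is modeled as an independent Bernoulli draw with probability
1/period per round — the simplest process consistent with "available every
*p* rounds on average" plus unpredictability. The phase-2 return is a
binomial rather than, say, a rounded Gaussian because it is bounded in
`[0, given]`, integer-valued, and has exactly the advertised mean. Monetary
amounts are integer points throughout; the deterministic phase-1 return
rounds half-up.

## The cognitive model

The sender agent (`cognitive_agent()`, run in bulk by `run_model_game()`)
combines three learning systems.

**Instance memory with blending.** Every experienced interaction is stored as
an episodic chunk: the counterpart, the observed return as a fraction of the
amount given, and a one-step discretized sequence context — the previous
return bin (none / low < 0.4 / neutral 0.4–0.6 / high > 0.6) and the
rounds-since-last-interaction bin (1 / 2–3 / 4+). Identical observations
merge, appending an encoding timestamp, so frequency strengthens one trace.
Retrieval strength is the base-level activation
\(A = \ln \sum_j (t_{now} - t_j)^{-d}\) with decay `d = 0.5`, and the
predicted return is the activation-weighted blend
\(\sum_i p_i v_i,\; p_i \propto e^{A_i/\tau}\) over chunks matching the
counterpart and context (falling back to all of the counterpart's chunks when
the context is new), with blending temperature `tau = 0.25`. A counterpart
with no history gets the prior prediction `0.5 + 0.1 * initial_trust`.
Context matching is what makes expectations recalibrate within a round or two
of a strategy shift: once the previous return falls into a new bin, only
recent instances match.

**Trust and trust-invest accumulators.** Each counterpart has two
accumulators (`trust_state()`, parameters in `trust_params()`).

Trust integrates two endowment-normalized signals per interaction:

* net outcome, `eta * (returned - allocated) / endowment` — profitable
  reciprocity builds trust (`eta = 1`);
* expectation violation, `mu * (returned - expected) / endowment`, with the
  expectation taken from the memory blend — a counterpart returning less than
  anticipated loses trust even when the sender breaks even (`mu = 2`;
  violations weigh about twice as much per point as gains, the usual
  magnitude of loss aversion).

Trust saturates at `trust_cap = 2`: state trust is bounded, so accumulated
goodwill cannot grow without limit and a sharp violation is always decisive.
On every round without an interaction, trust is discounted by
`delta = 0.15` — trust decays in the absence of evidence, which is what makes
behavioral trust track the interaction schedule. The default is set so that a
period-3 counterpart's trust erodes slightly faster between interactions than
routine calibrated returns replenish it. Trust starts at `initial_trust = 1`
(one endowment of goodwill): an agent that starts in distrust never allocates
and therefore never learns, so some initial trust extension is a structural
necessity.

Trust-invest tracks the *unmet need to develop trust*. Interacting with a
counterpart consumes it (decay by `1 - kappa`, `kappa = 0.5`); while a
counterpart goes unexplored and the round's investments fail to pay off
overall, it grows by `kappa` times the normalized portfolio shortfall
(`update_need_on_portfolio()`). The portfolio coupling is what lets the need
to develop trust with a neglected counterpart rise when a *different*
counterpart turns untrustworthy — without it, a counterpart the agent has
stopped allocating to could never enter trust necessity at all, and the
post-switch reallocation could not begin within a few rounds of the shift.

The two accumulators classify each counterpart into exactly one regime
(`classify_regime()`): **trust** when trust exceeds its threshold (0),
otherwise **trust necessity** when invest exceeds its threshold, otherwise
**distrust**. The invest threshold defaults to 0.05 rather than 0: invest
decays geometrically and never reaches zero exactly, so a zero threshold
would make necessity permanent once ignited; a small positive level makes it
require a meaningful unmet need and lets the reallocation episode fade.

**Regime-dependent rewards and procedural learning.** After feedback the
agent receives one summed round reward: the endowment retained (points kept
plus refunds), plus a regime-dependent term per counterpart — the joint
payoff of both parties under trust, minus the transferred points under
distrust, the counterpart's payoff alone under trust necessity (rewarding
trust development). Rewards are scaled to endowment units before utility
learning so the Boltzmann selection temperature is commensurate with them.
Allocation decisions are adjustments of the previous allocation — increase
by `step = 4` points, decrease, or hold — selected by Boltzmann sampling
(`s = 0.5`) over utilities keyed by (regime, predicted-return bin), where the
predicted return per allocated point is binned as below / near / above
break-even (near means within ±25%). Every rule that fired in a round is
updated once with the round's total reward via `U <- U + alpha (R - U)`,
`alpha = 0.2`. Counterparts are processed in an order sampled by a Boltzmann
rule over cumulative received payoff (uniform on round one), sharing the
procedural temperature, and the running endowment constraint is enforced
sequentially.

Because rules are credited with the *shared* round total, per-counterpart
reward differences are a weak, noisy signal. The regimes therefore also gate
behavior directly: while a counterpart is in trust necessity the `increase`
rule gets a selection-time utility bonus (`invest_bias = 0.5`) — the
trust-development drive — and while it is in distrust the `decrease` rule
gets the mirror-image bonus (`withdraw_bias = 0.5`). These biases implement
the idea that trust states trigger strategies rather than merely re-weighting
slow reinforcement; learned utilities stack on top and can override either
drive when it keeps failing.

**Lesioned variants.** `trust_only` disables the invest accumulator (no
trust necessity, no investment drive); `no_trust` disables both accumulators,
reducing the reward to the sender's own payoff plus the endowment retained.
The full model's post-switch signature — a sharp allocation drop for the
always-available counterpart and a transient allocation increase for the
intermittently available ones — requires both accumulators: without invest
the bump disappears; without trust there is neither a drop nor a bump.

## What the defaults produce

With the default configuration and parameters, the full model run at
a hundred seeds or more shows: allocations to the always-available
counterpart rising across rounds 1–70 to roughly two thirds of the endowment
while the intermittently available counterparts stay near the floor; after
the switch, a drop of the first counterpart's allocations within about ten
rounds, beginning immediately; and a transient rise of the other two
counterparts' allocations relative to their late-phase-1 level. These are the
properties asserted by the test suite (`test-acceptance.R`); the numbers the
package actually produces are computed there and by `scripts/acceptance.R`,
not quoted here.

## Fitting and yoked inference

`fit_metrics()` scores a model's mean allocation curves against target
curves by Pearson correlation and root-mean-squared deviation over the
flattened (round × counterpart) series, full-length and per strategy phase
(rounds 1–70 and 71–end); per-counterpart metrics are available via
`by_confederate = TRUE`. Joint scoring across counterparts is the package's
choice where either convention would be defensible. `grid_fit()` is a plain
grid search — the objective is stochastic and low-dimensional, so common
random numbers across grid points (one master seed) plus exhaustive
evaluation is more robust than gradient methods; ties break toward higher
correlation, then toward the lexicographically earlier parameter vector.

`infer_accumulators()` replays a behavioral log through the learning rules in
place of the model's own decisions: the instance memory is rebuilt from the
logged outcomes (to supply expectations), trust updates on the logged
returns, and discounting and the portfolio coupling apply exactly as in a
forward run. The result — the latent trust and trust-invest trajectories the
model attributes to that behavior — is a pure, deterministic function of the
log and the parameters, and on a model-generated log it reproduces the
forward trace exactly.

## The synthetic cohort generator

No participant data ship with the package, so `generate_cohort()` produces
human-like logs from a piecewise-linear allocation template
(`synthetic_profile()`): a linear phase-1 trend per counterpart, a sharp
post-switch drop for the high-schedule counterpart (20 points over 3 rounds
by default), an immediate bump with linear decay for the others (5 points
over 15 rounds), a slight overall phase-2 decline, and integer Gaussian
round-level noise (sd 3 points), clipped and rescaled to the endowment. The
default cohort size is 38. Returns and refunds are produced by the real game
engine, so every generated log passes the full ledger validation.

The template is deliberately *not* model-generated: fitting the model to its
own output is a separate exercise (parameter recovery), whereas template
targets test the pipeline against model-misspecified data, as human data
would. The generator emulates only the mean dynamics and round-level noise —
it has no individual-difference structure, no trait covariates, and no
erratic-responder clusters, so tests that pass against it show the pipeline
works and the lesion logic discriminates, not that the model fits any
particular human sample.

## Numerical choices and scales

Chunk values are binned to the nearest 0.05 for merging; blending weights are
computed with the max-activation shift for numerical stability. Boltzmann
order weights are floored at 1e-12 so a dominant counterpart never zeroes the
sampling distribution. Log validation uses a 1e-9 tolerance. Test and script
problem sizes — around a hundred runs for qualitative curves, tens of runs
per grid point, 3×3 recovery grids over three seeds, 30-participant
cohorts — were chosen as the smallest sizes at which the Monte-Carlo error is
comfortably below the effects being asserted.

## Known limitations

* The accumulator update laws are this package's own concrete design;
  the underlying theory constrains their shape (trust tracks outcomes and
  violated expectations and decays without evidence; invest tracks unmet
  need) but not their exact form. All parameters are exposed and fittable.
* Trust necessity is fed by the portfolio outcome but remains per
  counterpart; richer cross-counterpart structure (e.g. similarity-weighted
  generalization) is out of scope.
* The confederates' outside option when declining to interact is irrelevant
  to sender-side computation and is not modeled.
* The bump's decay profile depends on the invest threshold and `kappa`
  jointly; the package asserts transience qualitatively, not a time constant.
* Condition labels ("animacy"/"inanimacy") are metadata only; no behavioral
  difference is implemented.
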