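# matg

Simulation, cognitive modeling, fitting and latent-state inference for the
**multi-arm trust game (MATG)** — an iterated trust game in which one sender
splits a 40-point per-round endowment among three receivers who are only
intermittently available to interact, receive four times the points allocated
to them, and return a share. The package is for researchers in behavioral and
computational cognitive science who study how trust is built, discounted when
partners are unavailable, and strategically rebuilt after a trustworthiness
shift.

## The game and the model

Scripted confederate receivers differ only in availability (every round,
every 3 rounds on average, every 6). Through round 70 each returns 75% of the
multiplied amount — three times the allocation — and from round 71 a neutral,
break-even return drawn as Binomial(given, 0.25).

The sender model combines three learning systems:

* **Instance memory with blending.** Interactions are stored as episodic
  chunks with base-level activation
  *A* = ln Σ<sub>j</sub> (t − t<sub>j</sub>)<sup>−d</sup>; the predicted
  return fraction is the activation-weighted blend
  Σ p<sub>i</sub> v<sub>i</sub>, p<sub>i</sub> ∝ e<sup>A<sub>i</sub>/τ</sup>
  over chunks matching a discretized one-step sequence context.
* **Trust and trust-invest accumulators.** Per counterpart, trust integrates
  the net outcome η(returned − allocated)/endowment plus the expectation
  violation μ(returned − expected)/endowment (capped above), and is
  discounted by δ on every round without interaction. Trust-invest tracks the
  unmet need to develop trust: consumed by interaction, fed by the
  portfolio's failures. The accumulators classify each counterpart as
  *trust*, *distrust*, or *trust necessity*, which selects the round reward
  (joint payoff / −allocation / counterpart's payoff) and gates investment
  and withdrawal drives.
* **Procedural utility learning.** Increase/decrease/hold allocation rules,
  one utility per (regime, predicted-return bin) context, reinforced by the
  summed round reward via U ← U + α(R − U) and selected by Boltzmann sampling
  with temperature s.

Lesioned variants remove the invest accumulator (`trust_only`) or both
accumulators (`no_trust`) to attribute behavioral signatures to components.

## Worked example

```r
library(matg)

cfg <- game_config()
cfg
#> <matg_config>
#>   endowment 40 x4 multiplier, 120 rounds (switch after 70)
#>   returns: phase 1 75% of multiplied, phase 2 25% mean
#>   schedules: every 1, 3, 6 round(s) on average

sim <- run_model_game("full", cfg, n_runs = 100, seed = 7)
glance(sim)
#> # A tibble: 3 × 5
#>   variant n_runs confederate_id mean_allocation_phase1 mean_allocation_phase2
#> 1 full       100              1                  18.6                    8.01
#> 2 full       100              2                   5.55                   3.66
#> 3 full       100              3                   2.54                   4.46
```

The always-available confederate (id 1) attracts the bulk of the endowment
while it returns three times the allocation, then loses most of it once its
strategy turns neutral; the rarely available confederate (id 3) *gains*
allocation in phase 2 — the trust-necessity-driven reallocation.
`autoplot(sim)` draws the mean allocation curves with the strategy switch
marked.

Yoked inference reads out the latent accumulators behind any behavioral log:

```r
trace <- infer_accumulators(sim$logs[[1]], trust_params(), cfg)
dplyr::filter(trace, round %in% c(70, 75), confederate_id == 1)
#> # A tibble: 2 × 5
#>   round confederate_id trust invest regime
#> 1    70              1  2         0 trust
#> 2    75              1 -6.05      0 distrust
```

Trust in the always-available counterpart sits at its cap through the
generous phase and collapses within a few rounds of the switch.

Other entry points: `generate_cohort()` builds synthetic human-like cohorts
for fitting; `grid_fit()` fits any variant to target allocation curves by
correlation and RMSD (with `tidy()`/`glance()` methods); `write_game_log()` /
`read_game_log()` exchange validated round-by-round CSV logs; `exec/matg`
exposes `simulate`, `synth`, `fit` and `infer` subcommands for shell use.

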