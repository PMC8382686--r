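# Synthetic human-like game logs. A piecewise-linear allocation template per
# counterpart carries the empirical signature — allocations to the
# always-available counterpart rise during the high-trustworthiness phase and
# drop sharply after the strategy switch, while the rarely available
# counterparts receive little until a transient post-switch bump — and
# integer Gaussian noise plus the real game engine make every log
# mechanically valid.

#' Profile of a synthetic participant cohort
#'
#' Parameters of the piecewise-linear mean allocation template. Defaults encode
#' the qualitative empirical pattern: a rise to roughly two thirds of the
#' endowment for the always-available counterpart over the first phase, floor
#' allocations to the intermittently available counterparts, then a sharp
#' post-switch drop for the former and a decaying bump for the latter.
#'
#' @param phase1_start Template allocation on round 1, one value per
#'   counterpart (points).
#' @param phase1_slope Linear slope during phase 1 (points/round).
#' @param drop Post-switch drop of the first (high-schedule) counterpart's
#'   template (points), reached linearly over `drop_rounds` rounds.
#' @param drop_rounds Rounds over which the drop completes.
#' @param bump Post-switch bump added to every other counterpart's template
#'   (points), decaying linearly to 0 over `bump_rounds` rounds.
#' @param bump_rounds Duration of the bump (rounds); 0 disables it.
#' @param phase2_slope Drift applied to all counterparts after the switch
#'   (points/round), on top of drop/bump.
#' @param noise_sd Standard deviation of the integer-rounded Gaussian noise
#'   added to each per-round template value (points).
#' @param n_participants Cohort size. Default 38.
#' @return A `matg_profile` object.
#' @export
synthetic_profile <- function(phase1_start = c(4, 4, 4),
                              phase1_slope = c(0.33, 0.02, 0),
                              drop = 20,
                              drop_rounds = 3,
                              bump = 5,
                              bump_rounds = 15,
                              phase2_slope = -0.03,
                              noise_sd = 3,
                              n_participants = 38) {
  stopifnot(length(phase1_start) == length(phase1_slope),
            drop_rounds >= 1, bump_rounds >= 0, noise_sd >= 0,
            n_participants >= 1)
  structure(
    list(phase1_start = phase1_start, phase1_slope = phase1_slope,
         drop = drop, drop_rounds = drop_rounds,
         bump = bump, bump_rounds = bump_rounds,
         phase2_slope = phase2_slope, noise_sd = noise_sd,
         n_participants = as.integer(n_participants)),
    class = "matg_profile"
  )
}

#' Analytic allocation template of a synthetic profile
#'
#' The noise-free piecewise-linear mean allocations, clipped to
#' `[0, endowment]` and proportionally rescaled on any round where the row sum
#' would exceed the endowment.
#'
#' @param profile A [synthetic_profile()].
#' @param config A [game_config()].
#' @return A numeric matrix, `n_rounds` by `n_counterparts`.
#' @export
allocation_template <- function(profile, config = game_config()) {
  k <- length(profile$phase1_start)
  stopifnot(k == length(config$schedules))
  n <- config$n_rounds
  sw <- config$switch_round
  tpl <- matrix(0, n, k)
  for (cp in seq_len(k)) {
    r1 <- seq_len(sw)
    tpl[r1, cp] <- profile$phase1_start[cp] + profile$phase1_slope[cp] * (r1 - 1)
    if (sw < n) {
      r2 <- seq(sw + 1L, n)
      base <- tpl[sw, cp] + profile$phase2_slope * (r2 - sw)
      if (cp == 1) {
        ramp <- pmin((r2 - sw) / profile$drop_rounds, 1)
        base <- base - profile$drop * ramp
      } else if (profile$bump_rounds > 0) {
        decay <- pmax(1 - (r2 - sw - 1) / profile$bump_rounds, 0)
        base <- base + profile$bump * decay
      }
      tpl[r2, cp] <- base
    }
  }
  tpl <- pmin(pmax(tpl, 0), config$endowment)
  over <- rowSums(tpl) > config$endowment
  tpl[over, ] <- tpl[over, , drop = FALSE] *
    (config$endowment / rowSums(tpl[over, , drop = FALSE]))
  tpl
}

#' Generate one synthetic participant's game log
#'
#' Adds integer-rounded Gaussian noise to the profile template, clips each
#' allocation to be non-negative and rescales rounds whose total would exceed
#' the endowment, then plays the resulting allocation sequence through the real
#' game engine ([run_game()]) so availability, multiplication, returns and
#' refunds obey the paradigm exactly.
#'
#' @param profile A [synthetic_profile()].
#' @param config A [game_config()].
#' @param specs Confederate specs.
#' @param seed Optional integer seed.
#' @return A `matg_log`.
#' @export
generate_participant_log <- function(profile, config = game_config(),
                                     specs = confederate_specs(config),
                                     seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  tpl <- allocation_template(profile, config)
  noise <- matrix(stats::rnorm(length(tpl), 0, profile$noise_sd),
                  nrow(tpl), ncol(tpl))
  alloc <- round_half_up(tpl + noise)
  alloc <- pmax(alloc, 0)
  over <- rowSums(alloc) > config$endowment
  if (any(over)) {
    scaled <- floor(alloc[over, , drop = FALSE] *
                      (config$endowment / rowSums(alloc[over, , drop = FALSE])))
    alloc[over, ] <- scaled
  }
  run_game(function(round, history) alloc[round, ], config, specs)
}

#' Generate a synthetic cohort and its mean allocation curves
#'
#' Independent seeded participants from one profile; the mean curves are
#' computed exactly as in [run_model_game()] and can be used directly as
#' fitting targets for [grid_fit()].
#'
#' @param profile A [synthetic_profile()].
#' @param config A [game_config()].
#' @param specs Confederate specs.
#' @param n Number of participants; defaults to the profile's.
#' @param seed Master seed; per-participant seeds are derived from it.
#' @return A `matg_cohort` object: list with `logs` (list of `matg_log`),
#'   `curves` (tibble `round`, `confederate_id`, `allocation`), `profile`,
#'   `config`, `seed`.
#' @export
generate_cohort <- function(profile, config = game_config(),
                            specs = confederate_specs(config),
                            n = profile$n_participants, seed = 1) {
  seeds <- derive_seeds(seed, n)
  logs <- lapply(seq_len(n), function(i) {
    generate_participant_log(profile, config, specs, seed = seeds[i])
  })
  all_rows <- dplyr::bind_rows(logs)
  curves <- dplyr::summarise(
    dplyr::group_by(all_rows, .data$round, .data$confederate_id),
    allocation = mean(.data$allocation), .groups = "drop"
  )
  structure(
    list(logs = logs, curves = curves, profile = profile, config = config,
         seed = seed),
    class = "matg_cohort"
  )
}

#' @export
print.matg_cohort <- function(x, ...) {
  cat(sprintf("<matg_cohort> %d participant(s), %d rounds, seed %s\n",
              length(x$logs), x$config$n_rounds, format(x$seed)))
  invisible(x)
}
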