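#' Configuration of a multi-arm trust game
#'
#' Bundles every fixed constant of the paradigm: the sender's per-round
#' endowment, the multiplier applied to points a receiver accepts, the number
#' of rounds, the round at which the confederate receivers switch their return
#' strategy, the return fractions of the two strategy phases, and the
#' availability schedules of the confederates.
#'
#' Defaults reproduce the standard design: a 40-point endowment multiplied by
#' four over 120 rounds; confederates return 75\% of the multiplied amount
#' (three times the allocation) through round 70, then a stochastic 25\% on
#' average (break-even for the sender) from round 71 on; the three confederates
#' are available every round, every 3 rounds on average, and every 6 rounds on
#' average.
#'
#' @param endowment Points the sender may allocate each round. Default 40.
#' @param multiplier Factor applied to an accepted allocation. Default 4.
#' @param n_rounds Number of rounds in a game. Default 120.
#' @param switch_round Last round of the high-trustworthiness phase; rounds
#'   `1..switch_round` use `phase1_return_frac`, later rounds the stochastic
#'   phase-2 policy. Default 70 (capped at `n_rounds` for short games).
#' @param phase1_return_frac Deterministic fraction of the multiplied amount
#'   returned during phase 1. Default 0.75.
#' @param phase2_return_frac Mean fraction of the multiplied amount returned
#'   during phase 2 (binomial draw, see [confederate_return()]). Default 0.25.
#' @param schedules Integer vector of availability periods, one per
#'   confederate: a confederate with period `p` is available each round
#'   independently with probability `1/p` (always, for `p = 1`). Default
#'   `c(1, 3, 6)`.
#' @param condition_label Free-text metadata (e.g. "animacy"/"inanimacy"); has
#'   no behavioral effect.
#' @param seed Optional integer recorded with the config for provenance.
#'
#' @return A `matg_config` object (a named list).
#' @seealso [confederate_specs()], [run_game()], [read_config()]
#' @export
#' @examples
#' cfg <- game_config()
#' cfg$endowment
game_config <- function(endowment = 40,
                        multiplier = 4,
                        n_rounds = 120,
                        switch_round = min(70, n_rounds),
                        phase1_return_frac = 0.75,
                        phase2_return_frac = 0.25,
                        schedules = c(1, 3, 6),
                        condition_label = "animacy",
                        seed = NULL) {
  cfg <- structure(
    list(
      endowment = as.numeric(endowment),
      multiplier = as.numeric(multiplier),
      n_rounds = as.integer(n_rounds),
      switch_round = as.integer(switch_round),
      phase1_return_frac = as.numeric(phase1_return_frac),
      phase2_return_frac = as.numeric(phase2_return_frac),
      schedules = as.numeric(schedules),
      condition_label = as.character(condition_label),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "matg_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "matg_config"))
  if (!isTRUE(cfg$endowment > 0)) {
    stop("`endowment` must be > 0.", call. = FALSE)
  }
  if (!isTRUE(cfg$multiplier >= 1)) {
    stop("`multiplier` must be >= 1.", call. = FALSE)
  }
  if (!isTRUE(cfg$n_rounds >= 1)) {
    stop("`n_rounds` must be >= 1.", call. = FALSE)
  }
  if (!isTRUE(cfg$switch_round >= 1 && cfg$switch_round <= cfg$n_rounds)) {
    stop("`switch_round` must lie in [1, n_rounds].", call. = FALSE)
  }
  for (f in c("phase1_return_frac", "phase2_return_frac")) {
    if (!isTRUE(cfg[[f]] >= 0 && cfg[[f]] <= 1)) {
      stop(sprintf("`%s` must lie in [0, 1].", f), call. = FALSE)
    }
  }
  if (length(cfg$schedules) < 1 || any(cfg$schedules < 1)) {
    stop("every schedule period must be >= 1.", call. = FALSE)
  }
  cfg
}

#' @export
print.matg_config <- function(x, ...) {
  cat("<matg_config>\n")
  cat(sprintf("  endowment %g x%g multiplier, %d rounds (switch after %d)\n",
              x$endowment, x$multiplier, x$n_rounds, x$switch_round))
  cat(sprintf("  returns: phase 1 %.0f%% of multiplied, phase 2 %.0f%% mean\n",
              100 * x$phase1_return_frac, 100 * x$phase2_return_frac))
  cat(sprintf("  schedules: every %s round(s) on average\n",
              paste(x$schedules, collapse = ", ")))
  invisible(x)
}

#' Confederate receiver specifications
#'
#' Expands a game configuration into one row per confederate receiver with its
#' availability period and phase-keyed return policy. Confederate ids are
#' 1-based and index into `config$schedules`.
#'
#' @param config A [game_config()].
#' @return A tibble with columns `confederate_id`, `schedule_period`,
#'   `phase1_return_frac`, `phase2_return_frac`.
#' @export
#' @examples
#' confederate_specs(game_config())
confederate_specs <- function(config) {
  validate_config(config)
  tibble::tibble(
    confederate_id = seq_along(config$schedules),
    schedule_period = config$schedules,
    phase1_return_frac = config$phase1_return_frac,
    phase2_return_frac = config$phase2_return_frac
  )
}
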