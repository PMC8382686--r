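# Model evaluation: correlation / RMSD fit metrics over round windows, grid
# search over model parameters against target allocation curves, and yoked
# inference of the trust accumulators from a behavioral log.

#' Correlation and RMSD between allocation curves
#'
#' Curves are aligned on (round, confederate) and flattened across both before
#' scoring: `r` is the Pearson correlation and `rmsd` the root mean squared
#' deviation over all pairs in the window. Per-counterpart metrics are also
#' reported via `by_confederate`.
#'
#' @param model_curves,target_curves Tibbles with columns `round`,
#'   `confederate_id`, `allocation`, covering the same (round, confederate)
#'   grid.
#' @param rounds Optional integer vector restricting the window (e.g. `1:70`);
#'   default: all rounds present in both curves.
#' @param by_confederate Also compute per-counterpart metrics? Default `FALSE`.
#' @return A one-row tibble with `r`, `rmsd`, `n` (and, with
#'   `by_confederate = TRUE`, a tibble of per-counterpart rows instead).
#'   If either flattened series is constant `r` is `NA` with a warning —
#'   the correlation is undefined there.
#' @export
#' @examples
#' m <- tibble::tibble(round = 1:3, confederate_id = 1, allocation = 0:2)
#' t <- tibble::tibble(round = 1:3, confederate_id = 1, allocation = c(0, 2, 4))
#' fit_metrics(m, t)  # r = 1, rmsd = sqrt(5/3)
fit_metrics <- function(model_curves, target_curves, rounds = NULL,
                        by_confederate = FALSE) {
  need <- c("round", "confederate_id", "allocation")
  for (nm in list(model = model_curves, target = target_curves)) {
    if (!all(need %in% names(nm))) {
      stop("curves need columns round, confederate_id, allocation.",
           call. = FALSE)
    }
  }
  joined <- dplyr::inner_join(
    model_curves[need], target_curves[need],
    by = c("round", "confederate_id"), suffix = c("_model", "_target")
  )
  if (nrow(joined) != nrow(model_curves) || nrow(joined) != nrow(target_curves)) {
    stop("alignment error: model and target curves cover different (round, confederate) grids.",
         call. = FALSE)
  }
  if (!is.null(rounds)) joined <- joined[joined$round %in% rounds, ]
  if (nrow(joined) == 0) stop("empty evaluation window.", call. = FALSE)
  score <- function(d) {
    r <- if (stats::sd(d$allocation_model) == 0 ||
             stats::sd(d$allocation_target) == 0) {
      warning("constant series: correlation undefined.", call. = FALSE)
      NA_real_
    } else {
      stats::cor(d$allocation_model, d$allocation_target)
    }
    tibble::tibble(
      r = r,
      rmsd = sqrt(mean((d$allocation_model - d$allocation_target)^2)),
      n = nrow(d)
    )
  }
  if (by_confederate) {
    dplyr::group_modify(dplyr::group_by(joined, .data$confederate_id),
                        function(d, key) score(d)) |>
      dplyr::ungroup()
  } else {
    score(joined)
  }
}

# The three standard evaluation windows.
fit_windows <- function(config) {
  list(full = seq_len(config$n_rounds),
       phase1 = seq_len(config$switch_round),
       phase2 = seq(config$switch_round + 1L, config$n_rounds))
}

#' Grid-search fit of a model variant to target allocation curves
#'
#' Every grid point is simulated with [run_model_game()] (common master seed
#' across points, so differences reflect parameters rather than noise) and
#' scored with [fit_metrics()] on the full window plus the two strategy-phase
#' windows. The winner minimizes full-window RMSD; ties break toward higher
#' full-window `r`, then toward the lexicographically earlier parameter vector.
#'
#' @param variant Model variant to fit.
#' @param grid Data frame of candidate parameters; recognized columns are
#'   `eta`, `delta`, `kappa`, `initial_trust`, `trust_threshold`,
#'   `invest_threshold` (trust parameters) and `alpha`, `s`, `step`
#'   (procedural parameters). Unlisted parameters keep their defaults.
#' @param target_curves Tibble of target mean allocations (`round`,
#'   `confederate_id`, `allocation`).
#' @param config A [game_config()].
#' @param n_runs Simulated games per grid point.
#' @param seed Master seed shared across grid points.
#' @param memory A [memory_store()] template (sets `d`, `tau`).
#' @return A `matg_fit` object; see [tidy.matg_fit()] and [glance.matg_fit()].
#' @export
grid_fit <- function(variant, grid, target_curves, config = game_config(),
                     n_runs = 50, seed = 1, memory = memory_store()) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) stop("empty parameter grid.", call. = FALSE)
  trust_names <- c("eta", "delta", "kappa", "initial_trust",
                   "trust_threshold", "invest_threshold")
  proc_names <- c("alpha", "s", "step")
  unknown <- setdiff(names(grid), c(trust_names, proc_names))
  if (length(unknown) > 0) {
    stop(sprintf("unknown grid parameter(s): %s.",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  grid <- dplyr::arrange(grid, dplyr::across(dplyr::everything()))
  windows <- fit_windows(config)
  rows <- vector("list", nrow(grid))
  curves_best <- NULL
  for (i in seq_len(nrow(grid))) {
    point <- as.list(grid[i, ])
    tr <- do.call(trust_params, point[intersect(names(point), trust_names)])
    ut <- do.call(utility_table, point[intersect(names(point), proc_names)])
    sim <- run_model_game(variant, config, trust = tr, utilities = ut,
                          memory = memory, n_runs = n_runs, seed = seed,
                          keep_logs = FALSE)
    met <- lapply(windows, function(w) {
      suppressWarnings(fit_metrics(sim$curves, target_curves, rounds = w))
    })
    rows[[i]] <- tibble::tibble(
      !!!point,
      r_full = met$full$r, rmsd_full = met$full$rmsd,
      r_phase1 = met$phase1$r, rmsd_phase1 = met$phase1$rmsd,
      r_phase2 = met$phase2$r, rmsd_phase2 = met$phase2$rmsd,
      .curves = list(sim$curves)
    )
  }
  results <- dplyr::bind_rows(rows)
  ranked <- dplyr::arrange(dplyr::mutate(results, .i = dplyr::row_number()),
                           .data$rmsd_full, dplyr::desc(.data$r_full),
                           .data$.i)
  best <- ranked[1, ]
  structure(
    list(
      variant = variant,
      best_params = as.list(best[intersect(names(grid), names(best))]),
      best_curves = best$.curves[[1]],
      metrics = tibble::tibble(
        window = c("full", "phase1", "phase2"),
        r = c(best$r_full, best$r_phase1, best$r_phase2),
        rmsd = c(best$rmsd_full, best$rmsd_phase1, best$rmsd_phase2)
      ),
      results = dplyr::select(results, -".curves"),
      target_curves = target_curves,
      config = config, n_runs = n_runs, seed = seed
    ),
    class = "matg_fit"
  )
}

#' @export
print.matg_fit <- function(x, ...) {
  cat(sprintf("<matg_fit> variant '%s', %d grid point(s), %d runs/point\n",
              x$variant, nrow(x$results), x$n_runs))
  cat("best parameters:",
      paste(names(x$best_params), unlist(x$best_params), sep = " = ",
            collapse = ", "), "\n")
  print(x$metrics)
  invisible(x)
}

#' Infer trust accumulators from a behavioral log (yoked replay)
#'
#' Feeds the logged decisions and payoffs through the model's learning rules in
#' place of its own: each round, interacted counterparts update trust on the
#' logged return relative to the model's blended expectation (the instance
#' memory is replayed alongside), all others are discounted, and the
#' trust-invest accumulators track the portfolio outcome exactly as in a
#' forward run. The result is the latent trust / trust-invest trajectory the
#' model attributes to the behavior in the log — a pure, deterministic function
#' of the log and the parameters.
#'
#' @param log A game log (from [run_game()], [read_game_log()], or a
#'   `matg_sim` run).
#' @param params A [trust_params()].
#' @param config A [game_config()]; defaults to the log's attached config.
#' @param variant `"full"` or `"trust_only"` (the `no_trust` lesion has no
#'   accumulators to infer).
#' @param memory A fresh [memory_store()] (sets the replayed memory's `d` and
#'   `tau`).
#' @return A `matg_trace` tibble: `round`, `confederate_id`, `trust`, `invest`,
#'   `regime` — accumulator values after each round's update.
#' @export
infer_accumulators <- function(log, params = trust_params(),
                               config = attr(log, "config"),
                               variant = c("full", "trust_only"),
                               memory = memory_store()) {
  variant <- match.arg(variant)
  if (is.null(config)) {
    stop("no config attached to log; pass one explicitly.", call. = FALSE)
  }
  ids <- sort(unique(log$confederate_id))
  k <- length(ids)
  n <- config$n_rounds
  if (!identical(sort(unique(log$round)), seq_len(n))) {
    stop("alignment error: log does not cover rounds 1..n_rounds.",
         call. = FALSE)
  }
  state <- trust_state(k, params)
  tr_trust <- matrix(0, n, k)
  tr_invest <- matrix(0, n, k)
  ord <- order(log$round, log$confederate_id)
  allocation <- matrix(log$allocation[ord], n, k, byrow = TRUE)
  available <- matrix(log$available[ord], n, k, byrow = TRUE)
  given <- matrix(log$given[ord], n, k, byrow = TRUE)
  returned <- matrix(log$returned[ord], n, k, byrow = TRUE)
  last_frac <- rep(NA_real_, k)
  last_round <- rep(NA_integer_, k)
  for (r in seq_len(n)) {
    interacted <- available[r, ] & allocation[r, ] > 0
    for (cp in seq_len(k)) {
      if (interacted[cp]) {
        gap <- r - last_round[cp]
        mem_ctx <- memory_context(last_frac[cp], gap)
        pred <- blended_prediction(memory, cp, mem_ctx, r)
        if (is.na(pred)) pred <- prior_prediction(params)
        state <- update_on_outcome(state, cp, allocation[r, cp],
                                   returned[r, cp], config$endowment, params,
                                   expected = pred * given[r, cp])
        value <- returned[r, cp] / given[r, cp]
        memory <- encode_instance(memory, cp, mem_ctx, value, r)
        last_frac[cp] <- value
        last_round[cp] <- r
      } else {
        state <- discount_on_unavailability(state, cp, params)
      }
    }
    if (variant == "full") {
      round_net <- sum(returned[r, interacted] - allocation[r, interacted])
      state <- update_need_on_portfolio(state, which(!interacted), round_net,
                                        config$endowment, params)
    } else {
      state$invest[] <- 0
    }
    tr_trust[r, ] <- state$trust
    tr_invest[r, ] <- state$invest
  }
  trace_tibble(tr_trust, tr_invest, params)
}
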