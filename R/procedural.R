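# Procedural learning: a small set of allocation-adjustment rules (increase /
# decrease / hold), one utility per (context, action), reinforced by the
# delivered round reward and selected by Boltzmann sampling.

RULE_ACTIONS <- c("increase", "decrease", "hold")

#' Create a utility table over allocation-adjustment rules
#'
#' A rule is an action (`increase`, `decrease`, `hold`) in a context (the
#' counterpart's trust regime crossed with the binned predicted return).
#' Utilities start at 0 for unseen contexts and track delivered rewards via the
#' difference-learning rule `U <- U + alpha * (R - U)`.
#'
#' @param alpha Utility learning rate in `(0, 1]`. Default 0.2.
#' @param s Selection noise (Boltzmann temperature); as `s -> 0` selection
#'   becomes greedy. Default 0.5.
#' @param step Points added or removed per adjustment. Default 4 (10\% of the
#'   standard endowment).
#' @return A `matg_utilities` object.
#' @export
utility_table <- function(alpha = 0.2, s = 0.5, step = 4) {
  stopifnot(alpha > 0, alpha <= 1, s > 0, step >= 1)
  structure(list(utilities = list(), alpha = alpha, s = s, step = step),
            class = "matg_utilities")
}

#' @export
print.matg_utilities <- function(x, ...) {
  cat(sprintf("<matg_utilities> %d context(s), alpha = %g, s = %g, step = %g\n",
              length(x$utilities), x$alpha, x$s, x$step))
  invisible(x)
}

# Context key for a rule: regime x predicted-return bin.
rule_context <- function(regime, pred_bin) paste(regime, pred_bin, sep = "|")

# Predicted-return bin relative to the allocation: a predicted fraction f of
# the multiplied amount pays back f * multiplier per allocated point.
predicted_return_bin <- function(pred_frac, multiplier) {
  ratio <- pred_frac * multiplier
  if (ratio < 0.75) "under" else if (ratio <= 1.25) "near" else "over"
}

context_utilities <- function(table, context) {
  u <- table$utilities[[context]]
  if (is.null(u)) {
    u <- stats::setNames(rep(0, length(RULE_ACTIONS)), RULE_ACTIONS)
  }
  u
}

#' Difference-learning utility update
#'
#' @param U Current utility.
#' @param R Delivered reward.
#' @param alpha Learning rate.
#' @return `U + alpha * (R - U)`.
#' @export
#' @examples
#' update_utility(0, 10, 0.2)  # 2
update_utility <- function(U, R, alpha) {
  U + alpha * (R - U)
}

#' Sample an allocation-adjustment action
#'
#' Boltzmann selection over the context's utilities with temperature `s`:
#' `P(a) = exp(U_a / s) / sum(exp(U / s))`. Unseen contexts have all-zero
#' utilities, so each action is equally likely. A selection-time `bias` can
#' tilt specific actions without touching the stored utilities — the agent
#' uses it for the trust-development drive in the trust-necessity regime,
#' where investing is the point; learned utilities accumulate on top and can
#' override the bias if investing keeps failing.
#'
#' @param table A [utility_table()].
#' @param context Context key (see [utility_table()]).
#' @param bias Optional named numeric vector (names among `increase`,
#'   `decrease`, `hold`) added to the utilities at selection time only.
#' @return One of `"increase"`, `"decrease"`, `"hold"`.
#' @export
select_rule <- function(table, context, bias = NULL) {
  u <- context_utilities(table, context)
  if (!is.null(bias)) u[names(bias)] <- u[names(bias)] + bias
  w <- exp((u - max(u)) / table$s)
  sample(RULE_ACTIONS, 1, prob = w / sum(w))
}

#' Apply an adjustment action to the previous allocation
#'
#' @param action `"increase"`, `"decrease"` or `"hold"`.
#' @param previous Previous allocation, in points.
#' @param remaining Points still unallocated from this round's endowment.
#' @param step Adjustment size, in points.
#' @return The new allocation, clipped to `[0, remaining]`.
#' @export
apply_action <- function(action, previous, remaining, step) {
  stopifnot(previous >= 0)
  proposed <- switch(action,
    increase = previous + step,
    decrease = previous - step,
    hold = previous,
    stop(sprintf("unknown action '%s'.", action), call. = FALSE)
  )
  min(max(proposed, 0), remaining)
}

# Update every rule that fired this round exactly once with the round's total
# reward. `fired` is a data-frame-like list with context and action vectors.
reinforce_rules <- function(table, fired_context, fired_action, reward) {
  if (length(fired_context) == 0) return(table)
  keys <- paste(fired_context, fired_action, sep = "@")
  keep <- !duplicated(keys)
  for (i in which(keep)) {
    ctx <- fired_context[i]
    u <- context_utilities(table, ctx)
    u[fired_action[i]] <- update_utility(u[fired_action[i]], reward,
                                         table$alpha)
    table$utilities[[ctx]] <- u
  }
  table
}

#' Dump or load a utility table as JSON
#'
#' Serializes the learned utilities together with `alpha`, `s` and `step` so a
#' mid-run procedural state can be reproduced exactly.
#'
#' @param table A [utility_table()].
#' @param path File path.
#' @return `write_utilities()` returns `path` invisibly; `read_utilities()` a
#'   table.
#' @export
write_utilities <- function(table, path) {
  jsonlite::write_json(
    list(alpha = table$alpha, s = table$s, step = table$step,
         utilities = lapply(table$utilities, as.list)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_utilities
#' @export
read_utilities <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  table <- utility_table(alpha = x$alpha, s = x$s, step = x$step)
  table$utilities <- lapply(x$utilities, function(u) unlist(u)[RULE_ACTIONS])
  table
}
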