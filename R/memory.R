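# Instance-based episodic memory: chunks encode one observed interaction
# outcome (return fraction) in a discretized sequence context; retrieval
# strength follows the base-level learning equation (recency + frequency) and
# predictions are activation-weighted blends over matching instances.

#' Create an empty instance memory store
#'
#' Chunks are episodic traces of interactions with a counterpart: the observed
#' return as a fraction of the amount given, tagged with a discretized sequence
#' context (the previous observed return bin and the rounds-since-interaction
#' bin). Identical observations are merged, appending the encoding round to the
#' existing chunk, so frequency strengthens the trace.
#'
#' @param d Base-level decay exponent; activation of a chunk encoded at rounds
#'   \eqn{t_j} and queried at round \eqn{n} is
#'   \eqn{\ln \sum_j (n - t_j)^{-d}}. Default 0.5.
#' @param tau Blending temperature: candidate chunks are weighted by
#'   \eqn{\exp(A_i/\tau)}. Default 0.25.
#' @return A `matg_memory` object.
#' @export
memory_store <- function(d = 0.5, tau = 0.25) {
  stopifnot(d > 0, tau > 0)
  structure(list(chunks = list(), d = d, tau = tau), class = "matg_memory")
}

#' @export
print.matg_memory <- function(x, ...) {
  cat(sprintf("<matg_memory> %d chunk(s), d = %g, tau = %g\n",
              length(x$chunks), x$d, x$tau))
  invisible(x)
}

# Discretization used as the one-step sequence context.
# prev_frac: last observed return fraction for this counterpart (NA if none);
# gap: rounds since the last interaction with it (NA if none).
memory_context <- function(prev_frac, gap) {
  ret_bin <- if (is.na(prev_frac)) {
    "none"
  } else if (prev_frac < 0.4) {
    "low"
  } else if (prev_frac <= 0.6) {
    "neutral"
  } else {
    "high"
  }
  gap_bin <- if (is.na(gap)) {
    "none"
  } else if (gap <= 1) {
    "1"
  } else if (gap <= 3) {
    "2-3"
  } else {
    "4+"
  }
  paste(ret_bin, gap_bin, sep = "|")
}

# Values are binned to the nearest 0.05 for chunk identity so that repeated
# near-identical outcomes strengthen one trace rather than fragmenting memory.
bin_value <- function(value) round(value * 20) / 20

#' Encode an interaction instance into memory
#'
#' If a chunk with the same counterpart, context and (binned) value already
#' exists, the round is appended to its encoding history — re-occurrence
#' strengthens the trace. Otherwise a new chunk is created.
#'
#' @param store A [memory_store()].
#' @param counterpart Confederate id.
#' @param context Context key, see the store's documentation; any scalar string.
#' @param value Observed return fraction in `[0, 1]`.
#' @param round 1-based round of encoding. Memory shares one clock: the round
#'   may not precede any existing encoding time (several counterparts may
#'   encode within one round), and each chunk's encoding history stays strictly
#'   increasing.
#' @return The updated store.
#' @export
encode_instance <- function(store, counterpart, context, value, round) {
  stopifnot(inherits(store, "matg_memory"), value >= 0, value <= 1)
  times <- unlist(lapply(store$chunks, `[[`, "encodings"))
  if (length(times) > 0 && round < max(times)) {
    stop(sprintf("clock error: round %d precedes the latest encoding (%d).",
                 round, max(times)), call. = FALSE)
  }
  v <- bin_value(value)
  for (i in seq_along(store$chunks)) {
    ch <- store$chunks[[i]]
    if (ch$counterpart == counterpart && ch$context == context &&
        ch$value == v) {
      if (round <= max(ch$encodings)) {
        stop(sprintf(
          "clock error: chunk already encoded at round %d.", max(ch$encodings)),
          call. = FALSE)
      }
      store$chunks[[i]]$encodings <- c(ch$encodings, as.integer(round))
      return(store)
    }
  }
  store$chunks[[length(store$chunks) + 1L]] <- list(
    counterpart = counterpart, context = context, value = v,
    encodings = as.integer(round)
  )
  store
}

#' Base-level activation of a chunk
#'
#' Activation reflects recency and frequency of a chunk's encodings:
#' \eqn{A = \ln \sum_j (now - t_j)^{-d}}. More encodings raise it; the passage
#' of time lowers it.
#'
#' @param chunk One element of a store's `chunks` list (needs an `encodings`
#'   field of round indices).
#' @param now Current round; must be strictly after every encoding.
#' @param d Decay exponent.
#' @return Activation (a real number).
#' @export
#' @examples
#' activation(list(encodings = c(1, 4)), now = 5, d = 0.5)  # log(1 + 0.5)
activation <- function(chunk, now, d = 0.5) {
  t <- chunk$encodings
  if (length(t) == 0) {
    stop("retrieval failure: chunk has no encodings.", call. = FALSE)
  }
  if (now <= max(t)) {
    stop("`now` must be strictly after every encoding.", call. = FALSE)
  }
  log(sum((now - t)^(-d)))
}

#' Blended prediction of a counterpart's return fraction
#'
#' Candidate chunks are those matching the counterpart and context; when none
#' match the context, all of the counterpart's chunks are used. Candidates are
#' weighted by a Boltzmann function of their activation,
#' \eqn{p_i \propto \exp(A_i/\tau)}, and the prediction is the weighted mean of
#' their values — always a convex combination, so it lies within the candidate
#' value range.
#'
#' @param store A [memory_store()].
#' @param counterpart Confederate id.
#' @param context Context key.
#' @param now Current round.
#' @return The blended return fraction, or `NA_real_` when the store holds no
#'   chunk for the counterpart (the caller falls back to its prior).
#' @export
blended_prediction <- function(store, counterpart, context, now) {
  idx <- which(vapply(store$chunks, function(ch) ch$counterpart == counterpart,
                      logical(1)))
  if (length(idx) == 0) return(NA_real_)
  match_ctx <- idx[vapply(store$chunks[idx],
                          function(ch) ch$context == context, logical(1))]
  cand <- if (length(match_ctx) > 0) match_ctx else idx
  a <- vapply(store$chunks[cand], activation, numeric(1),
              now = now, d = store$d)
  v <- vapply(store$chunks[cand], `[[`, numeric(1), "value")
  w <- exp((a - max(a)) / store$tau)
  sum(w * v) / sum(w)
}

#' Dump or load an instance memory as JSON lines
#'
#' One chunk per line: `counterpart`, `context`, `value`, `encodings`. The
#' store's `d` and `tau` are carried on a header line.
#'
#' @param store A [memory_store()].
#' @param path File path.
#' @return `write_memory()` returns `path` invisibly; `read_memory()` a store.
#' @export
write_memory <- function(store, path) {
  header <- jsonlite::toJSON(list(d = store$d, tau = store$tau),
                             auto_unbox = TRUE)
  lines <- vapply(store$chunks, function(ch) {
    as.character(jsonlite::toJSON(ch, auto_unbox = TRUE))
  }, character(1))
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' @rdname write_memory
#' @export
read_memory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty memory file.", call. = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  store <- memory_store(d = header$d, tau = header$tau)
  store$chunks <- lapply(lines[-1], function(l) {
    ch <- jsonlite::fromJSON(l)
    ch$encodings <- as.integer(ch$encodings)
    ch
  })
  store
}
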