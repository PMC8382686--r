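# Readers and writers for the package's plain-text interchange formats:
# game logs and accumulator traces as CSV, configurations and run manifests
# as JSON. Reads re-validate every invariant so malformed or inconsistent
# files fail loudly, naming the offending column or round.

LOG_COLUMNS <- c("round", "confederate_id", "allocation", "available",
                 "given", "returned", "kept", "refunded", "sender_total")

#' Write or read a game log as CSV
#'
#' The dialect is fixed: one row per round and confederate with columns
#' `round, confederate_id, allocation, available, given, returned, kept,
#' refunded, sender_total`. Reading re-validates all bookkeeping invariants
#' via [validate_game_log()]; writing then reading reproduces the log exactly.
#'
#' @param log A `matg_log`.
#' @param path File path.
#' @param config For `read_game_log()`: the [game_config()] the log follows;
#'   when omitted, endowment, multiplier and round count are inferred from the
#'   data (sufficient for validation).
#' @return `write_game_log()` returns `path` invisibly; `read_game_log()` a
#'   validated `matg_log`.
#' @export
write_game_log <- function(log, path) {
  readr::write_csv(tibble::as_tibble(log)[LOG_COLUMNS], path)
  invisible(path)
}

#' @rdname write_game_log
#' @export
read_game_log <- function(path, config = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop(sprintf("parse error: '%s' is missing or empty.", path),
         call. = FALSE)
  }
  tbl <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                                          progress = FALSE))
  missing <- setdiff(LOG_COLUMNS, names(tbl))
  if (length(missing) > 0) {
    stop(sprintf("parse error: missing column(s) %s.",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tbl) == 0) stop("parse error: no rounds in file.", call. = FALSE)
  tbl <- tbl[LOG_COLUMNS]
  tbl$round <- as.integer(tbl$round)
  tbl$confederate_id <- as.integer(tbl$confederate_id)
  tbl$available <- as.logical(tbl$available)
  if (is.null(config)) config <- infer_config(tbl)
  log <- new_game_log(tbl, config)
  validate_game_log(log, config)
  log
}

# Reconstruct the constants a log implies: endowment from conservation,
# multiplier from any available allocated round, n_rounds from the index.
infer_config <- function(tbl) {
  first <- tbl[tbl$round == min(tbl$round), ]
  endowment <- first$kept[1] + sum(first$allocation)
  mult_rows <- tbl[tbl$available & tbl$allocation > 0, ]
  multiplier <- if (nrow(mult_rows) > 0) {
    mult_rows$given[1] / mult_rows$allocation[1]
  } else 4
  game_config(endowment = endowment, multiplier = multiplier,
              n_rounds = max(tbl$round), switch_round = max(tbl$round),
              schedules = rep(1, length(unique(tbl$confederate_id))))
}

#' Write or read an accumulator trace as CSV
#'
#' Tidy format: `round, confederate_id, trust, invest, regime`.
#'
#' @param trace A `matg_trace` (see [infer_accumulators()]).
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a tibble.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("round", "confederate_id", "trust", "invest", "regime")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    stop(sprintf("parse error: missing column(s) %s.",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(tbl[need], class = c("matg_trace", class(tibble::tibble())))
}

#' Write or read a game configuration as JSON
#'
#' Reading validates the schema: unknown fields are rejected, missing fields
#' take the standard defaults (40-point endowment, multiplier 4, 120 rounds,
#' switch after 70, 75\%/25\% return fractions, schedules 1/3/6), and the
#' config invariants are enforced.
#'
#' @param config A [game_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   validated [game_config()].
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(x)) stop("parse error: config must be a JSON object.",
                        call. = FALSE)
  known <- names(formals(game_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    stop(sprintf("schema error at /%s: unknown field.", unknown[1]),
         call. = FALSE)
  }
  tryCatch(
    do.call(game_config, x),
    error = function(e) {
      stop(sprintf("schema error: %s", conditionMessage(e)), call. = FALSE)
    }
  )
}

#' Write a run manifest
#'
#' Records what a run needs to be reproduced: a canonical hash of the
#' configuration (stable under key reordering), the seed, the model variant,
#' the package version, and the output paths. Written before any run output.
#'
#' @param config A [game_config()].
#' @param seed Integer seed of the run.
#' @param variant Model variant label.
#' @param outputs Character vector of output paths.
#' @param path Manifest destination.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, seed, variant, outputs, path) {
  manifest <- list(
    config_hash = config_hash(config),
    seed = seed,
    variant = variant,
    package_version = as.character(utils::packageVersion("matg")),
    outputs = as.character(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Canonical MD5 of a config: fields sorted by name, serialized to JSON.
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           null = "null")), tmp)
  unname(tools::md5sum(tmp))
}
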