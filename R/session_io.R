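## Session logging and persistence. Logs are JSON lines: a header record
## first, one checkpoint record per line as the session progresses, and a
## final record at normal termination -- append-safe, so a crashed session
## always retains its last completed checkpoint.

#' Session log
#'
#' The protocol file written for every training session: identifier, start
#' timestamp, runtime, number of feedback clicks, periodic coordinate
#' checkpoints, the final stimulus coordinates, the RNG seed, and a digest of
#' the active configuration (so silent parameter drift between sessions is
#' detectable).
#'
#' @param session_id identifier.
#' @param started_at ISO 8601 timestamp string.
#' @param runtime_s session runtime, seconds.
#' @param click_count number of feedback clicks.
#' @param checkpoints list of `list(elapsed_s, coordinates)` snapshots,
#'   ordered by elapsed time.
#' @param final_coordinates data frame `id, x_deg, y_deg` at termination.
#' @param seed RNG seed used (or `NULL`).
#' @param config_digest checksum of the active config, see [config_digest()].
#' @param aborted logical: did the session terminate abnormally?
#' @return Object of class `session_log`.
#' @export
session_log <- function(session_id, started_at, runtime_s, click_count,
                        checkpoints, final_coordinates, seed = NULL,
                        config_digest = NA_character_, aborted = FALSE) {
  if (length(checkpoints) > 1) {
    el <- vapply(checkpoints, `[[`, numeric(1), "elapsed_s")
    if (is.unsorted(el)) stop("checkpoints must be ordered by elapsed time", call. = FALSE)
  }
  structure(
    list(session_id = session_id, started_at = started_at,
         runtime_s = runtime_s, click_count = click_count,
         checkpoints = checkpoints, final_coordinates = final_coordinates,
         seed = seed, config_digest = config_digest, aborted = aborted),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log %s: %g s, %d clicks, %d checkpoints%s>\n",
              x$session_id, x$runtime_s, x$click_count, length(x$checkpoints),
              if (isTRUE(x$aborted)) ", ABORTED" else ""))
  invisible(x)
}

#' Digest of a configuration object
#'
#' Canonical-JSON MD5 checksum; changes if and only if some configuration
#' field changes. Recorded in every session log.
#'
#' @param config any list-like configuration object.
#' @return Hex digest string.
#' @export
config_digest <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           null = "null")), tmp)
  unname(tools::md5sum(tmp))
}

.coords_to_df <- function(x) {
  data.frame(id = as.character(x$id), x_deg = as.numeric(x$x_deg),
             y_deg = as.numeric(x$y_deg), stringsAsFactors = FALSE)
}

#' Write and read session logs
#'
#' JSON-lines format: the first line is a `header` record, each checkpoint is
#' appended as its own `checkpoint` line, and a `final` record closes the
#' file at normal termination. `read_session_log()` of a file truncated after
#' checkpoint *k* recovers those *k* checkpoints and flags the log as
#' aborted; a malformed line raises a parse error naming the offending
#' record. Write-then-read is lossless.
#'
#' @param log a [session_log()].
#' @param path file path.
#' @return `read_session_log()` returns a `session_log`; `write_session_log()`
#'   returns `path` invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  ser <- function(x) as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                                   null = "null", na = "null"))
  lines <- ser(list(record = "header", session_id = log$session_id,
                    started_at = log$started_at, seed = log$seed,
                    config_digest = log$config_digest))
  for (cp in log$checkpoints) {
    lines <- c(lines, ser(list(record = "checkpoint", elapsed_s = cp$elapsed_s,
                               coordinates = cp$coordinates)))
  }
  if (!isTRUE(log$aborted)) {
    lines <- c(lines, ser(list(record = "final", runtime_s = log$runtime_s,
                               click_count = log$click_count,
                               final_coordinates = log$final_coordinates)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("log parse error: file is empty", call. = FALSE)
  recs <- lapply(seq_along(lines), function(i) {
    r <- tryCatch(jsonlite::fromJSON(lines[i]),
                  error = function(e) stop(sprintf(
                    "log parse error at line %d: %s", i, conditionMessage(e)),
                    call. = FALSE))
    if (is.null(r$record)) {
      stop(sprintf("log parse error at line %d: missing field 'record'", i),
           call. = FALSE)
    }
    r
  })
  hdr <- recs[[1]]
  if (!identical(hdr$record, "header")) {
    stop("log parse error: first record must be the header", call. = FALSE)
  }
  for (f in c("session_id", "started_at")) {
    if (is.null(hdr[[f]])) {
      stop(sprintf("log parse error: header missing field '%s'", f), call. = FALSE)
    }
  }
  cps <- Filter(function(r) identical(r$record, "checkpoint"), recs)
  fin <- Filter(function(r) identical(r$record, "final"), recs)
  checkpoints <- lapply(cps, function(r) {
    if (is.null(r$elapsed_s)) {
      stop("log parse error: checkpoint missing field 'elapsed_s'", call. = FALSE)
    }
    list(elapsed_s = r$elapsed_s, coordinates = .coords_to_df(r$coordinates))
  })
  if (length(fin) == 0) {
    last <- if (length(checkpoints) > 0) checkpoints[[length(checkpoints)]] else NULL
    return(session_log(
      session_id = hdr$session_id, started_at = hdr$started_at,
      runtime_s = if (is.null(last)) 0 else last$elapsed_s,
      click_count = NA_integer_,
      checkpoints = checkpoints,
      final_coordinates = if (is.null(last)) NULL else last$coordinates,
      seed = hdr$seed, config_digest = hdr$config_digest, aborted = TRUE))
  }
  f <- fin[[length(fin)]]
  session_log(session_id = hdr$session_id, started_at = hdr$started_at,
              runtime_s = f$runtime_s, click_count = f$click_count,
              checkpoints = checkpoints,
              final_coordinates = .coords_to_df(f$final_coordinates),
              seed = hdr$seed, config_digest = hdr$config_digest,
              aborted = FALSE)
}

#' Read a training configuration from JSON
#'
#' @param path JSON file whose fields match [training_config()] arguments.
#' @return A `training_config`.
#' @export
read_training_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  known <- names(formals(training_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  do.call(training_config, raw)
}
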