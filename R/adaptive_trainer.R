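## The training engine: stimulus scheduling with the device's timing model
## and the feedback-driven relocation rule that tracks the intact/defect
## border. A detected stimulus steps toward a reference point placed in the
## central area of the defect; a missed stimulus steps the same distance away
## from the reference point, back toward intact field. Over many trials the
## stimuli straddle the true border, compensating for field improvement and
## for small fixation inaccuracies.

#' Training configuration
#'
#' Holds the timing, stimulus and relocation parameters of a training
#' session. Defaults mirror the device's training mode: 3-degree stimuli of
#' nominally 1000 cd/m2 shown for 750 ms on a dark background, each followed
#' by a 2000 ms response window plus a uniformly random extra break of up to
#' 1500 ms; the central fixation cross changes colour at uniform random
#' intervals between 3000 and 7000 ms to help maintain fixation.
#'
#' The relocation step `step_deg` is not dictated by the hardware; the
#' default of 0.5 degrees is about one stimulus radius at the validation
#' stimulus size and is comparable to the perimeter's ~0.44 degree
#' measurement error, so a single step never jumps across a resolvable
#' border. It is logged with every session.
#'
#' @param stimulus_size_deg stimulus diameter, degrees.
#' @param stimulus_luminance nominal luminance label, cd/m2 (metadata only).
#' @param display_ms stimulus display duration.
#' @param response_window_ms fixed response gap after each stimulus.
#' @param extra_break_max_ms upper bound of the uniform random extra break.
#' @param fixation_color_change_min_ms,fixation_color_change_max_ms bounds of
#'   the uniform interval between fixation-cross colour changes.
#' @param step_deg relocation step, degrees, > 0.
#' @param reference_point numeric length-2; custom reference point inside the
#'   central area of the field defect.
#' @param intact_anchor numeric length-2; a point well inside intact field,
#'   used only to break the degenerate case of a miss while sitting exactly
#'   on the reference point.
#' @param session_duration_s total session length, seconds.
#' @param persistence_mode `"cumulative"` (relocated coordinates carry over
#'   to the next session) or `"reset"` (progress is documented but relocated
#'   coordinates are discarded and initial positions restored).
#' @param checkpoint_interval_s how often the session log snapshots stimulus
#'   coordinates.
#' @param fov_deg full field of view used to clamp outward moves.
#' @param seed RNG seed recorded in the log; `NULL` leaves the RNG alone.
#' @return Object of class `training_config`.
#' @export
training_config <- function(stimulus_size_deg = 3,
                            stimulus_luminance = 1000,
                            display_ms = 750,
                            response_window_ms = 2000,
                            extra_break_max_ms = 1500,
                            fixation_color_change_min_ms = 3000,
                            fixation_color_change_max_ms = 7000,
                            step_deg = 0.5,
                            reference_point = c(20, 0),
                            intact_anchor = c(0, 0),
                            session_duration_s = 300,
                            persistence_mode = c("cumulative", "reset"),
                            checkpoint_interval_s = 60,
                            fov_deg = 90,
                            seed = NULL) {
  persistence_mode <- match.arg(persistence_mode)
  durs <- c(display_ms, response_window_ms, fixation_color_change_min_ms,
            fixation_color_change_max_ms, checkpoint_interval_s)
  if (any(!is.finite(durs)) || any(durs <= 0) || extra_break_max_ms < 0) {
    stop("all durations must be positive", call. = FALSE)
  }
  if (fixation_color_change_max_ms < fixation_color_change_min_ms) {
    stop("fixation colour-change interval bounds are inverted", call. = FALSE)
  }
  if (!is.numeric(step_deg) || step_deg <= 0) stop("step_deg must be > 0", call. = FALSE)
  stopifnot(length(reference_point) == 2, length(intact_anchor) == 2,
            session_duration_s >= 0, fov_deg > 0)
  structure(
    list(stimulus_size_deg = stimulus_size_deg,
         stimulus_luminance = stimulus_luminance,
         display_ms = display_ms,
         response_window_ms = response_window_ms,
         extra_break_max_ms = extra_break_max_ms,
         fixation_color_change_min_ms = fixation_color_change_min_ms,
         fixation_color_change_max_ms = fixation_color_change_max_ms,
         step_deg = step_deg,
         reference_point = as.numeric(reference_point),
         intact_anchor = as.numeric(intact_anchor),
         session_duration_s = session_duration_s,
         persistence_mode = persistence_mode,
         checkpoint_interval_s = checkpoint_interval_s,
         fov_deg = fov_deg,
         seed = seed),
    class = "training_config"
  )
}

#' Training stimulus state
#'
#' A stimulus with its initial and current coordinates and the full
#' relocation history. The current position always equals the last history
#' entry (or the initial position while the history is empty).
#'
#' @param id identifier.
#' @param x_deg,y_deg initial coordinates in device degrees.
#' @return Object of class `stimulus_state`.
#' @export
stimulus_state <- function(id, x_deg, y_deg) {
  stopifnot(is.finite(x_deg), is.finite(y_deg))
  structure(
    list(id = id,
         initial = c(x_deg, y_deg),
         current = c(x_deg, y_deg),
         history = data.frame(trial = integer(0), x_deg = numeric(0),
                              y_deg = numeric(0), detected = logical(0))),
    class = "stimulus_state"
  )
}

#' Build a presentation schedule for one session
#'
#' Stimuli are cycled, each cycle a fresh uniform shuffle, so every stimulus
#' appears once per cycle in randomized order. Consecutive onsets are
#' separated by `display_ms + response_window_ms + U(0, extra_break_max_ms)`.
#' Fixation-cross colour changes are interleaved at independent
#' `U(min, max)` intervals. The schedule is truncated at the session
#' duration (an event must finish displaying within the session) and is
#' deterministic for a fixed `config$seed`.
#'
#' @param config a [training_config()].
#' @param stimuli non-empty list of [stimulus_state()] objects.
#' @return Data frame of events with columns `onset_ms`, `type`
#'   (`"stimulus"` or `"fixation_change"`), `stimulus_id`, ordered by onset.
#' @export
schedule_session <- function(config, stimuli) {
  stopifnot(inherits(config, "training_config"))
  if (length(stimuli) == 0) stop("at least one stimulus is required", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  total_ms <- config$session_duration_s * 1000
  ids <- vapply(stimuli, function(s) as.character(s$id), character(1))

  onsets <- numeric(0); ev_ids <- character(0)
  t <- 0
  repeat {
    if (t + config$display_ms > total_ms) break
    for (id in sample(ids, length(ids))) {
      if (t + config$display_ms > total_ms) break
      onsets <- c(onsets, t); ev_ids <- c(ev_ids, id)
      t <- t + config$display_ms + config$response_window_ms +
        stats::runif(1, 0, config$extra_break_max_ms)
    }
  }
  fix <- numeric(0)
  tf <- stats::runif(1, config$fixation_color_change_min_ms,
                     config$fixation_color_change_max_ms)
  while (tf <= total_ms) {
    fix <- c(fix, tf)
    tf <- tf + stats::runif(1, config$fixation_color_change_min_ms,
                            config$fixation_color_change_max_ms)
  }
  ev <- rbind(
    data.frame(onset_ms = onsets, type = rep("stimulus", length(onsets)),
               stimulus_id = ev_ids, stringsAsFactors = FALSE),
    data.frame(onset_ms = fix, type = rep("fixation_change", length(fix)),
               stimulus_id = rep(NA_character_, length(fix)),
               stringsAsFactors = FALSE)
  )
  ev <- ev[order(ev$onset_ms, ev$type), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Relocate a stimulus after user feedback
#'
#' Detected: the stimulus moves `step_deg` along the straight line toward the
#' reference point, landing exactly on it when closer than one step.
#' Missed: it moves `step_deg` along the same line extended away from the
#' reference point, toward intact field, clamped radially to the device's
#' half field of view. A miss while sitting exactly on the reference point
#' (direction undefined) steps toward `intact_anchor` instead.
#'
#' @param stim a [stimulus_state()].
#' @param detected logical; did the user click for this presentation?
#' @param config a [training_config()].
#' @param trial trial index recorded in the history.
#' @return The updated `stimulus_state`.
#' @export
relocate <- function(stim, detected, config, trial = nrow(stim$history) + 1L) {
  stopifnot(inherits(stim, "stimulus_state"), inherits(config, "training_config"))
  cur <- stim$current
  ref <- config$reference_point
  step <- config$step_deg
  d <- angular_distance(cur, ref)
  if (detected) {
    new <- if (d <= step) ref else cur + step * (ref - cur) / d
  } else {
    dir <- if (d == 0) config$intact_anchor - cur else cur - ref
    nd <- sqrt(sum(dir^2))
    if (nd == 0) dir <- c(-1, 0) else dir <- dir / nd  # anchor on reference: arbitrary fixed direction
    new <- cur + step * dir
    half <- config$fov_deg / 2
    r <- sqrt(sum(new^2))
    if (r > half) new <- new * (half / r)
  }
  stim$current <- new
  stim$history <- rbind(stim$history,
                        data.frame(trial = as.integer(trial), x_deg = new[1],
                                   y_deg = new[2], detected = detected))
  stim
}

#' Run one training session
#'
#' Schedules the session, asks the responder about each stimulus
#' presentation, applies the relocation rule after every presentation, and
#' assembles a [session_log()]. With `persistence_mode = "reset"` the
#' relocated coordinates are recorded in the log but the returned stimuli are
#' restored to their initial positions ("progress is documented but changed
#' coordinates are deleted"); in `"cumulative"` mode the updated coordinates
#' carry over.
#'
#' A responder failure mid-session aborts with a partial log: checkpoints
#' written so far are preserved on the error condition.
#'
#' @param config a [training_config()].
#' @param responder `function(position, size_deg)` returning `TRUE` for a
#'   click (e.g. from [make_observer_responder()]).
#' @param stimuli list of [stimulus_state()] objects.
#' @return List with `stimuli` (updated list) and `log` (a `session_log`).
#' @export
run_training_session <- function(config, responder, stimuli) {
  stopifnot(inherits(config, "training_config"), is.function(responder))
  events <- schedule_session(config, stimuli)
  sev <- events[events$type == "stimulus", , drop = FALSE]
  byid <- stats::setNames(stimuli, vapply(stimuli, function(s) as.character(s$id), character(1)))
  snapshot <- function() {
    do.call(rbind, lapply(byid, function(s) {
      data.frame(id = as.character(s$id), x_deg = s$current[1], y_deg = s$current[2],
                 stringsAsFactors = FALSE)
    }))
  }
  clicks <- 0L
  checkpoints <- list()
  next_cp <- config$checkpoint_interval_s * 1000
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  i <- 0L
  abort <- NULL
  for (k in seq_len(nrow(sev))) {
    id <- sev$stimulus_id[k]
    i <- i + 1L
    det <- tryCatch(isTRUE(responder(byid[[id]]$current, config$stimulus_size_deg)),
                    error = function(e) e)
    if (inherits(det, "error")) { abort <- det; break }
    if (det) clicks <- clicks + 1L
    byid[[id]] <- relocate(byid[[id]], det, config, trial = i)
    while (sev$onset_ms[k] >= next_cp) {
      checkpoints[[length(checkpoints) + 1]] <-
        list(elapsed_s = next_cp / 1000, coordinates = snapshot())
      next_cp <- next_cp + config$checkpoint_interval_s * 1000
    }
  }
  checkpoints[[length(checkpoints) + 1]] <-
    list(elapsed_s = config$session_duration_s, coordinates = snapshot())
  log <- session_log(
    session_id = paste0("session-", format(Sys.time(), "%Y%m%d%H%M%S")),
    started_at = started,
    runtime_s = config$session_duration_s,
    click_count = clicks,
    checkpoints = checkpoints,
    final_coordinates = snapshot(),
    seed = config$seed,
    config_digest = config_digest(config),
    aborted = !is.null(abort)
  )
  if (!is.null(abort)) {
    cond <- structure(
      class = c("vftrain_session_abort", "error", "condition"),
      list(message = paste0("responder failed mid-session: ", conditionMessage(abort)),
           call = NULL, partial_log = log)
    )
    stop(cond)
  }
  out <- unname(byid)
  if (config$persistence_mode == "reset") {
    out <- lapply(out, function(s) { s$current <- s$initial; s$history <- s$history[0, ]; s })
  }
  list(stimuli = out, log = log)
}

#' Read and write stimulus-set files
#'
#' A stimulus set is stored as a JSON array of `{id, x_deg, y_deg}` objects;
#' after a cumulative-mode session the trainer writes the set back with the
#' relocated coordinates.
#'
#' @param stimuli list of [stimulus_state()] objects.
#' @param path file path.
#' @return `read_stimuli()` returns a list of `stimulus_state`;
#'   `write_stimuli()` returns `path` invisibly.
#' @export
write_stimuli <- function(stimuli, path) {
  df <- do.call(rbind, lapply(stimuli, function(s) {
    data.frame(id = as.character(s$id), x_deg = s$current[1], y_deg = s$current[2],
               stringsAsFactors = FALSE)
  }))
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (!all(c("id", "x_deg", "y_deg") %in% names(df))) {
    stop("stimulus file must contain id, x_deg, y_deg", call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) stimulus_state(df$id[i], df$x_deg[i], df$y_deg[i]))
}
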