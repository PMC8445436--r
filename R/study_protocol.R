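## The blind-spot validation protocol: a monocular run of 150 brief, small
## stimuli -- 25 warm-up detectable trials, a scored block of 15 blind-spot
## plus 85 detectable trials in random order, and 25 detectable buffer
## trials. Warm-up and buffer are always excluded from analysis. Because the
## blind spot is an absolute scotoma, every click on a blind-spot stimulus
## indicates imperfect fixation (or guessing), so the confusion matrix of the
## scored block measures how precisely the device places stimuli.

#' Validation study configuration
#'
#' Defaults follow the standard protocol: 0.33-degree stimuli displayed for
#' 200 ms, a 2000 ms response window, then a random break of 0-1000 ms;
#' 25 warm-up trials, 100 scored (15 blind-spot + 85 detectable), 25 buffer.
#'
#' @param n_warmup,n_blindspot,n_detectable,n_buffer trial counts, >= 0.
#' @param stimulus_size_deg stimulus diameter, degrees.
#' @param display_ms display duration.
#' @param response_window_ms response window after each stimulus.
#' @param break_max_ms upper bound of the uniform random inter-trial break.
#' @param seed RNG seed for sequence shuffling and position sampling.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_warmup = 25, n_blindspot = 15, n_detectable = 85,
                         n_buffer = 25, stimulus_size_deg = 0.33,
                         display_ms = 200, response_window_ms = 2000,
                         break_max_ms = 1000, seed = NULL) {
  counts <- c(n_warmup, n_blindspot, n_detectable, n_buffer)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("trial counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(display_ms > 0, response_window_ms > 0, break_max_ms >= 0)
  structure(
    list(n_warmup = n_warmup, n_blindspot = n_blindspot,
         n_detectable = n_detectable, n_buffer = n_buffer,
         stimulus_size_deg = stimulus_size_deg, display_ms = display_ms,
         response_window_ms = response_window_ms, break_max_ms = break_max_ms,
         seed = seed),
    class = "study_config"
  )
}

# Intact-field positions available for detectable stimuli: intact cells
# excluding a one-pitch margin around any intact/defect transition, so the
# ground-truth category of every sampled position is unambiguous.
.detectable_pool <- function(field) {
  intact <- field$cells[field$cells$status == "intact", c("x_deg", "y_deg")]
  margin <- border_zone(field, width = 2 * field$pitch_deg)
  if (nrow(margin) > 0) {
    key <- function(df) paste(df$x_deg, df$y_deg)
    intact <- intact[!(key(intact) %in% key(margin)), , drop = FALSE]
  }
  intact
}

#' Build the trial sequence for one subject
#'
#' Warm-up and buffer blocks contain only detectable positions; the scored
#' block is a uniform shuffle of `n_blindspot` blind-spot sites (all at the
#' mapped blind spot's centroid) and `n_detectable` intact-field sites drawn
#' uniformly without replacement from the intact cells away from the
#' scotoma's border. Deterministic for a fixed `config$seed`.
#'
#' @param config a [study_config()].
#' @param field ground-truth `visual_field` containing a defect.
#' @return Data frame with columns `index`, `block`
#'   (`warmup`/`scored`/`buffer`), `category` (`blindspot`/`detectable`),
#'   `x_deg`, `y_deg`, plus onset times `onset_ms`.
#' @export
build_trial_sequence <- function(config, field) {
  stopifnot(inherits(config, "study_config"), inherits(field, "visual_field"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pool <- .detectable_pool(field)
  n_det_total <- config$n_warmup + config$n_detectable + config$n_buffer
  if (nrow(pool) < n_det_total) {
    stop(sprintf("field has only %d usable intact cells, %d needed",
                 nrow(pool), n_det_total), call. = FALSE)
  }
  det_idx <- sample(nrow(pool), n_det_total)
  det <- pool[det_idx, , drop = FALSE]
  bs <- blind_spot_stimulus_sites(field, max(config$n_blindspot, 1))
  if (config$n_blindspot == 0) bs <- bs[0, , drop = FALSE]

  blocks <- c(rep("warmup", config$n_warmup),
              rep("scored", config$n_blindspot + config$n_detectable),
              rep("buffer", config$n_buffer))
  category <- rep("detectable", length(blocks))
  x <- numeric(length(blocks)); y <- numeric(length(blocks))

  scored_cat <- sample(c(rep("blindspot", config$n_blindspot),
                         rep("detectable", config$n_detectable)))
  category[blocks == "scored"] <- scored_cat

  di <- 1L; bi <- 1L
  for (i in seq_along(blocks)) {
    if (category[i] == "blindspot") {
      x[i] <- bs[bi, 1]; y[i] <- bs[bi, 2]; bi <- bi + 1L
    } else {
      x[i] <- det$x_deg[di]; y[i] <- det$y_deg[di]; di <- di + 1L
    }
  }
  gap <- config$display_ms + config$response_window_ms +
    stats::runif(length(blocks), 0, config$break_max_ms)
  onset <- c(0, cumsum(gap))[seq_along(blocks)]
  data.frame(index = seq_along(blocks), block = blocks, category = category,
             x_deg = x, y_deg = y, onset_ms = onset, stringsAsFactors = FALSE)
}

.classify_trial <- function(block, category, clicked) {
  if (block != "scored") return("excluded")
  if (category == "blindspot") { if (clicked) "FP" else "TN" }
  else { if (clicked) "TP" else "FN" }
}

#' Run the validation study for one subject
#'
#' Presents the full trial sequence to a responder and classifies every
#' scored trial: a blind-spot trial is a true negative without a click and a
#' false positive with one; a detectable trial is a true positive with a
#' click and a false negative without. Warm-up and buffer clicks are logged
#' but never classified. An ideal observer yields (TN, FP, FN, TP) =
#' (15, 0, 0, 85) under the default configuration.
#'
#' @param config a [study_config()].
#' @param field ground-truth `visual_field`.
#' @param responder `function(position, category, block)` returning `TRUE`
#'   for a click; see [make_observer_responder()] and [rate_responder()].
#' @return List with `records` (data frame of trial records: sequence columns
#'   plus `clicked` and `classification`) and `matrix` (a
#'   [confusion_matrix()]).
#' @export
run_study <- function(config, field, responder) {
  stopifnot(is.function(responder))
  seq_df <- build_trial_sequence(config, field)
  clicked <- logical(nrow(seq_df))
  for (i in seq_len(nrow(seq_df))) {
    clicked[i] <- isTRUE(responder(c(seq_df$x_deg[i], seq_df$y_deg[i]),
                                   seq_df$category[i], seq_df$block[i]))
  }
  seq_df$clicked <- clicked
  seq_df$classification <- mapply(.classify_trial, seq_df$block,
                                  seq_df$category, seq_df$clicked)
  cls <- seq_df$classification
  m <- confusion_matrix(tn = sum(cls == "TN"), fp = sum(cls == "FP"),
                        fn = sum(cls == "FN"), tp = sum(cls == "TP"))
  list(records = seq_df, matrix = m)
}

#' Run a cohort of validation studies
#'
#' @param configs list of [study_config()] objects, one per subject.
#' @param fields list of ground-truth fields, same length.
#' @param responders list of responders, same length.
#' @return List with `matrices` (per-subject [confusion_matrix()]), `records`
#'   (per-subject trial-record data frames), `pooled` (summed matrix),
#'   `summary` ([cohort_summary()]), and `pooled_accuracy`. Zero subjects
#'   yield an empty report.
#' @export
run_cohort <- function(configs, fields, responders) {
  n <- length(configs)
  if (length(fields) != n || length(responders) != n) {
    stop("configs, fields and responders must have equal length", call. = FALSE)
  }
  if (n == 0) {
    return(list(matrices = list(), records = list(), pooled = NULL,
                summary = NULL, pooled_accuracy = NA_real_))
  }
  runs <- lapply(seq_len(n), function(i) run_study(configs[[i]], fields[[i]], responders[[i]]))
  ms <- lapply(runs, `[[`, "matrix")
  pooled <- pool_matrices(ms)
  list(matrices = ms,
       records = lapply(runs, `[[`, "records"),
       pooled = pooled,
       summary = cohort_summary(ms),
       pooled_accuracy = accuracy(pooled))
}

#' Write per-subject study results
#'
#' Emits the trial records as CSV and a JSON summary of the confusion counts
#' and metrics, mirroring the device's per-participant results files.
#'
#' @param result a [run_study()] result.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return Invisibly, the metric list written to JSON.
#' @export
write_study_result <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(result$records, csv_path, row.names = FALSE, quote = FALSE)
  }
  m <- result$matrix
  summary <- c(list(tn = m$tn, fp = m$fp, fn = m$fn, tp = m$tp),
               as.list(metrics_report(m)))
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
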