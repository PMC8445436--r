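## Simulated observers: stand-ins for human participants. The stochastic
## observer answers presentations from a ground-truth visual field with
## fixation jitter, lapses and guesses; the rate responder replays a subject
## described only by per-category response rates, either stochastically or as
## exact deterministic quotas (needed to reproduce printed per-subject
## tables).

#' Observer model parameters
#'
#' `fixation_jitter_sd_deg` is the standard deviation of an isotropic
#' Gaussian gaze error added to every presentation, modelling residual
#' fixation inaccuracy (the headset has no eye tracker during training).
#' `lapse_rate` is the probability of failing to report a visible stimulus;
#' `guess_rate` the probability of clicking for an invisible one
#' ("trigger-happiness"). All default to 0: the ideal, fully compliant
#' observer.
#'
#' @param fixation_jitter_sd_deg Gaussian gaze-error SD, degrees, >= 0.
#' @param lapse_rate,guess_rate probabilities in \[0, 1\].
#' @param seed optional RNG seed applied when the observer is constructed
#'   into a responder.
#' @return Object of class `observer_params`.
#' @export
observer_params <- function(fixation_jitter_sd_deg = 0, lapse_rate = 0,
                            guess_rate = 0, seed = NULL) {
  if (fixation_jitter_sd_deg < 0) stop("jitter SD must be >= 0", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate > 1 || guess_rate < 0 || guess_rate > 1) {
    stop("lapse_rate and guess_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(list(fixation_jitter_sd_deg = fixation_jitter_sd_deg,
                 lapse_rate = lapse_rate, guess_rate = guess_rate, seed = seed),
            class = "observer_params")
}

#' @rdname observer_params
#' @param path JSON file with any of the `observer_params` fields.
#' @export
read_observer_params <- function(path) {
  raw <- jsonlite::fromJSON(path)
  do.call(observer_params, raw[intersect(names(raw),
    c("fixation_jitter_sd_deg", "lapse_rate", "guess_rate", "seed"))])
}

#' Answer one stimulus presentation from a ground-truth field
#'
#' The effective retinal position is the nominal position plus the Gaussian
#' fixation jitter. If the effective position classifies as intact field the
#' observer detects with probability `1 - lapse_rate`; otherwise (defect or
#' untested) it clicks with probability `guess_rate`. With all noise
#' parameters at zero the response is a deterministic function of the field
#' status at the nominal position: detection of the (jittered) stimulus
#' centre only, appropriate while stimuli are small relative to the scotoma.
#'
#' @param params an [observer_params()].
#' @param field a [make_field()] ground-truth map.
#' @param position numeric length-2 nominal stimulus position, degrees.
#' @return Logical: did the observer click?
#' @export
respond <- function(params, field, position) {
  stopifnot(inherits(params, "observer_params"), inherits(field, "visual_field"))
  eff <- position
  if (params$fixation_jitter_sd_deg > 0) {
    eff <- eff + stats::rnorm(2, 0, params$fixation_jitter_sd_deg)
  }
  if (classify_point(field, eff) == "intact") {
    params$lapse_rate == 0 || stats::runif(1) >= params$lapse_rate
  } else {
    params$guess_rate > 0 && stats::runif(1) < params$guess_rate
  }
}

#' Wrap an observer into a trainer/study responder
#'
#' @param params an [observer_params()].
#' @param field ground-truth `visual_field`.
#' @return `function(position, ...)` suitable for [run_training_session()]
#'   and [run_study()].
#' @export
make_observer_responder <- function(params, field) {
  if (!is.null(params$seed)) set.seed(params$seed)
  function(position, ...) respond(params, field, position)
}

#' Responder defined by per-category response rates
#'
#' Replays a subject known only through summary rates: `sen`, the fraction of
#' blind-spot-category stimuli correctly *not* reacted to, and `spe`, the
#' fraction of detectable-category stimuli correctly reacted to (the study's
#' inverted naming convention; see [sen()]). Two styles:
#'
#' * `"quota"` (deterministic): over `n_blindspot` blind-spot trials the
#'   responder withholds clicks on exactly `round(n_blindspot * sen)` of them
#'   and clicks the remainder; over `n_detectable` detectable trials it
#'   clicks exactly `round(n_detectable * spe)`. This reproduces a printed
#'   per-subject confusion matrix bit-exactly.
#' * `"stochastic"`: each blind-spot trial draws a click with probability
#'   `1 - sen`, each detectable trial with probability `spe`.
#'
#' The returned closure has signature `function(position, category, block)`
#' where `category` is `"blindspot"` or `"detectable"`; [run_study()] supplies
#' both. Quota counting is restricted to the scored block -- warm-up and
#' buffer trials are answered like detectable stimuli (always clicked, the
#' modal behaviour) but never consume the quota, so the scored-block counts
#' come out exact regardless of the surrounding blocks.
#'
#' @param sen,spe rates in \[0, 1\].
#' @param mode `"quota"` or `"stochastic"`.
#' @param n_blindspot,n_detectable expected scored trial counts (quota mode).
#' @return Responder closure.
#' @export
rate_responder <- function(sen, spe, mode = c("quota", "stochastic"),
                           n_blindspot = 15, n_detectable = 85) {
  mode <- match.arg(mode)
  if (sen < 0 || sen > 1 || spe < 0 || spe > 1) {
    stop("sen and spe must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "stochastic") {
    return(function(position, category, block = "scored") {
      if (identical(category, "blindspot")) stats::runif(1) < (1 - sen)
      else stats::runif(1) < spe
    })
  }
  quiet_bs <- round(n_blindspot * sen)     # correct non-reactions to issue first
  click_det <- round(n_detectable * spe)   # correct reactions to issue first
  seen <- new.env(parent = emptyenv())
  seen$bs <- 0L; seen$det <- 0L
  function(position, category, block = "scored") {
    if (!identical(block, "scored")) return(TRUE)
    if (identical(category, "blindspot")) {
      seen$bs <- seen$bs + 1L
      seen$bs > quiet_bs
    } else {
      seen$det <- seen$det + 1L
      seen$det <= click_det
    }
  }
}
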