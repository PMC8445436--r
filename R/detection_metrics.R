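## Confusion-matrix statistics in the validation study's own convention.
## NOTE on the convention: the study treats a blind-spot stimulus that is
## correctly NOT reacted to as a true negative and builds "sensitivity" on
## the true negatives -- the inverse of the usual epidemiological assignment.
## The implementation keeps that convention verbatim rather than silently
## normalising it, and documents the inversion here and in the vignette:
##   sen = tn / (tn + fp)   fraction of blind-spot stimuli with no click
##   spe = tp / (tp + fn)   fraction of detectable stimuli clicked
##   ppv = tn / (tn + fn)   correct blind-spot calls among all non-reactions
##   npv = tp / (tp + fp)   correct detections among all reactions

#' Confusion matrix of a blind-spot validation run
#'
#' Counts follow the study's category semantics: `tn` blind-spot stimuli
#' without a click (correct non-reaction), `fp` blind-spot stimuli with a
#' click (false reaction), `fn` detectable stimuli without a click (missed
#' detection), `tp` detectable stimuli with a click (correct reaction).
#' `tn + fp` is the number of blind-spot trials, `tp + fn` the number of
#' detectable trials.
#'
#' @param tn,fp,fn,tp non-negative integer counts, not all zero.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9)) {
    stop("confusion-matrix counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("confusion matrix must contain at least one trial", call. = FALSE)
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: TN=%d FP=%d FN=%d TP=%d (blind-spot %d, detectable %d)>\n",
              x$tn, x$fp, x$fn, x$tp, x$tn + x$fp, x$tp + x$fn))
  invisible(x)
}

.safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Detection metrics of a confusion matrix
#'
#' Individual accessors for the seven per-subject statistics plus pooled
#' accuracy, in the study's inverted naming convention (see
#' [confusion_matrix()]): `sen()` is the fraction of blind-spot stimuli
#' correctly not reacted to, `spe()` the fraction of detectable stimuli
#' correctly reacted to, `ppv()`/`npv()` the predictive values of a
#' non-reaction / reaction, `hit_rate()` the fraction of all scored trials
#' classified correctly, `random_hit_rate()` the hit rate expected by chance
#' given the response and category marginals, `ratz()` the chance-corrected
#' gain of the hit rate, and `accuracy()` `(tp + tn) / N`.
#'
#' The random hit rate is the marginal chance agreement
#' `q * D/N + (1 - q) * B/N`, with `q = (tp + fp)/N` the click rate, `D` the
#' detectable total and `B` the blind-spot total: the probability that a
#' random re-pairing of this subject's clicks with the trial categories
#' yields a correct classification. The RATZ index is
#' `(hr - rhr) / (1 - rhr)`, the gain of the observed hit rate over chance
#' relative to its maximum possible gain (undefined when `rhr == 1`).
#'
#' Metrics with a zero denominator return `NA`.
#'
#' @param m a [confusion_matrix()].
#' @return A fraction in \[0, 1\], or `NA` when undefined.
#' @export
sen <- function(m) .safe_ratio(m$tn, m$tn + m$fp)

#' @rdname sen
#' @export
spe <- function(m) .safe_ratio(m$tp, m$tp + m$fn)

#' @rdname sen
#' @export
ppv <- function(m) .safe_ratio(m$tn, m$tn + m$fn)

#' @rdname sen
#' @export
npv <- function(m) .safe_ratio(m$tp, m$tp + m$fp)

#' @rdname sen
#' @export
hit_rate <- function(m) .safe_ratio(m$tn + m$tp, m$tn + m$fp + m$fn + m$tp)

#' @rdname sen
#' @export
random_hit_rate <- function(m) {
  n <- m$tn + m$fp + m$fn + m$tp
  if (n == 0) return(NA_real_)
  q <- (m$tp + m$fp) / n          # click rate
  d <- (m$tp + m$fn) / n          # detectable fraction
  b <- (m$tn + m$fp) / n          # blind-spot fraction
  q * d + (1 - q) * b
}

#' @rdname sen
#' @export
ratz <- function(m) {
  rhr <- random_hit_rate(m)
  if (is.na(rhr) || rhr >= 1) return(NA_real_)
  (hit_rate(m) - rhr) / (1 - rhr)
}

#' @rdname sen
#' @export
accuracy <- function(m) .safe_ratio(m$tp + m$tn, m$tn + m$fp + m$fn + m$tp)

#' All metrics of one matrix as a one-row data frame
#'
#' @param m a [confusion_matrix()].
#' @return Data frame with columns `sen`, `spe`, `ppv`, `npv`, `hr`, `rhr`,
#'   `ratz`, `acc` (unrounded; use [round_half_up()] for table display).
#' @export
metrics_report <- function(m) {
  data.frame(sen = sen(m), spe = spe(m), ppv = ppv(m), npv = npv(m),
             hr = hit_rate(m), rhr = random_hit_rate(m), ratz = ratz(m),
             acc = accuracy(m))
}

#' Half-up rounding for table display
#'
#' Published tables round halves away from zero; base `round()` rounds half
#' to even. Used only for display, never inside computations.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 3) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Pool per-subject confusion matrices
#'
#' @param ms list of [confusion_matrix()] objects.
#' @return A single `confusion_matrix` of summed counts.
#' @export
pool_matrices <- function(ms) {
  stopifnot(length(ms) > 0)
  confusion_matrix(
    tn = sum(vapply(ms, `[[`, numeric(1), "tn")),
    fp = sum(vapply(ms, `[[`, numeric(1), "fp")),
    fn = sum(vapply(ms, `[[`, numeric(1), "fn")),
    tp = sum(vapply(ms, `[[`, numeric(1), "tp"))
  )
}

#' Cohort summary: mean and SD of each metric
#'
#' Unweighted mean and sample standard deviation of every per-subject metric
#' over a list of confusion matrices, as in a cohort summary table.
#'
#' @param ms non-empty list of [confusion_matrix()] objects.
#' @return Data frame with columns `metric`, `mean`, `sd` plus rounded
#'   display columns `mean_3` and `sd_3`.
#' @export
cohort_summary <- function(ms) {
  if (length(ms) == 0) stop("cohort_summary needs at least one matrix", call. = FALSE)
  tab <- do.call(rbind, lapply(ms, metrics_report))
  data.frame(
    metric = names(tab),
    mean = vapply(tab, mean, numeric(1)),
    sd = if (nrow(tab) > 1) vapply(tab, stats::sd, numeric(1)) else rep(0, ncol(tab)),
    mean_3 = round_half_up(vapply(tab, mean, numeric(1)), 3),
    sd_3 = round_half_up(if (nrow(tab) > 1) vapply(tab, stats::sd, numeric(1))
                         else rep(0, ncol(tab)), 3),
    row.names = NULL
  )
}

#' Spearman-Brown prophecy correction
#'
#' Corrects a split-half correlation to full test length:
#' `2 r / (1 + r)`.
#'
#' @param r half-test correlation, > -1.
#' @return Corrected reliability coefficient.
#' @export
spearman_brown <- function(r) {
  if (is.na(r)) return(NA_real_)
  if (r <= -1) stop("Spearman-Brown is undefined at r = -1", call. = FALSE)
  2 * r / (1 + r)
}

#' Split-half reliability of blind-spot correct rejections
#'
#' Splits each subject's scored trials odd/even within each stimulus
#' category (in presentation order), counts blind-spot correct rejections
#' (no-click trials) per half, correlates the two half-counts across
#' subjects (Pearson), and applies the Spearman-Brown correction. The
#' odd/even split is this implementation's choice of scheme.
#'
#' @param records_list list (one element per subject) of trial-record data
#'   frames as returned by [run_study()]; needs >= 3 subjects.
#' @return List with elements `r` and `corrected`; both `NA` when either
#'   half has zero variance across subjects.
#' @export
split_half_reliability <- function(records_list) {
  if (length(records_list) < 3) stop("need at least 3 subjects", call. = FALSE)
  halves <- vapply(records_list, function(rec) {
    bs <- rec[rec$block == "scored" & rec$category == "blindspot", , drop = FALSE]
    k <- seq_len(nrow(bs))
    c(a = sum(!bs$clicked[k %% 2 == 1]), b = sum(!bs$clicked[k %% 2 == 0]))
  }, numeric(2))
  a <- halves["a", ]; b <- halves["b", ]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, corrected = NA_real_))
  }
  r <- stats::cor(a, b)
  list(r = r, corrected = spearman_brown(r))
}

#' Reconstruct per-subject confusion matrices from summary rates
#'
#' Given per-subject `sen` and `spe` rates from a run of the standard scored
#' block (`n_blindspot` blind-spot + `n_detectable` detectable trials), the
#' integer counts are exactly recoverable: `tn = round(n_blindspot * sen)`,
#' `tp = round(n_detectable * spe)`.
#'
#' @param subjects data frame with columns `sen` and `spe` (one row per
#'   subject).
#' @param n_blindspot,n_detectable scored trial counts per category.
#' @return List of [confusion_matrix()] objects, one per row.
#' @export
reconstruct_matrices <- function(subjects, n_blindspot = 15, n_detectable = 85) {
  stopifnot(is.data.frame(subjects), all(c("sen", "spe") %in% names(subjects)))
  lapply(seq_len(nrow(subjects)), function(i) {
    tn <- round(n_blindspot * subjects$sen[i])
    tp <- round(n_detectable * subjects$spe[i])
    confusion_matrix(tn = tn, fp = n_blindspot - tn, fn = n_detectable - tp, tp = tp)
  })
}

#' Reproduce the validation-cohort evaluation from a subject-rate table
#'
#' Takes a per-subject table of `sen`/`spe` rates (such as the bundled
#' 40-subject validation fixture, see
#' `system.file("extdata", "validation_subjects.csv", package = "vftrain")`),
#' reconstructs each confusion matrix, recomputes every metric, and returns
#' the per-subject metric table (3-decimal display rounding), the cohort
#' mean/SD summary, the pooled counts with pooled accuracy, and -- when the
#' input carries a `ratz` column of previously published values -- a
#' discrepancy report listing rows where the chance-correction formula does
#' not reproduce the published RATZ value.
#'
#' @param subjects data frame with columns `subject`, `sen`, `spe` and
#'   optionally `ratz` (published values to check against).
#' @param n_blindspot,n_detectable scored trial counts per category.
#' @return List with `per_subject`, `summary`, `pooled` (list of counts and
#'   `accuracy`), and `discrepancies`.
#' @export
reproduce_validation <- function(subjects, n_blindspot = 15, n_detectable = 85) {
  ms <- reconstruct_matrices(subjects, n_blindspot, n_detectable)
  per <- do.call(rbind, lapply(ms, metrics_report))
  per <- cbind(subject = subjects$subject,
               do.call(rbind, lapply(ms, function(m) {
                 data.frame(tn = m$tn, fp = m$fp, fn = m$fn, tp = m$tp)
               })),
               as.data.frame(lapply(per, round_half_up, digits = 3)))
  pooled <- pool_matrices(ms)
  disc <- data.frame(subject = character(0), ratz_published = numeric(0),
                     ratz_computed = numeric(0))
  if ("ratz" %in% names(subjects)) {
    comp <- round_half_up(vapply(ms, ratz, numeric(1)), 3)
    bad <- which(abs(comp - subjects$ratz) > 5e-4)
    disc <- data.frame(subject = subjects$subject[bad],
                       ratz_published = subjects$ratz[bad],
                       ratz_computed = comp[bad])
  }
  list(
    per_subject = per,
    summary = cohort_summary(ms),
    pooled = list(tn = pooled$tn, fp = pooled$fp, fn = pooled$fn, tp = pooled$tp,
                  accuracy = accuracy(pooled)),
    discrepancies = disc
  )
}
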