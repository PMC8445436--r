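# Published per-subject values used as expected results below were verified
# row by row against the validation cohort table (see helper-validation.R).

test_that("per-matrix metrics follow the study's inverted convention", {
  perfect <- confusion_matrix(15, 0, 0, 85)
  expect_equal(sen(perfect), 1)
  expect_equal(spe(perfect), 1)
  expect_equal(ppv(perfect), 1)
  expect_equal(npv(perfect), 1)
  expect_equal(hit_rate(perfect), 1)
  expect_equal(round_half_up(random_hit_rate(perfect), 3), 0.745)
  expect_equal(ratz(perfect), 1)
  expect_equal(accuracy(perfect), 1)

  s01 <- confusion_matrix(14, 1, 1, 84)
  expect_equal(round_half_up(sen(s01), 3), 0.933)
  expect_equal(round_half_up(spe(s01), 3), 0.988)
  expect_equal(round_half_up(random_hit_rate(s01), 3), 0.745)
  expect_equal(round_half_up(ratz(s01), 3), 0.922)

  s36 <- confusion_matrix(13, 2, 8, 77)
  expect_equal(round_half_up(sen(s36), 3), 0.867)
  expect_equal(round_half_up(spe(s36), 3), 0.906)
  expect_equal(round_half_up(ppv(s36), 3), 0.619)
  expect_equal(round_half_up(npv(s36), 3), 0.975)
  expect_equal(round_half_up(hit_rate(s36), 3), 0.900)
  expect_equal(round_half_up(random_hit_rate(s36), 3), 0.703)

  s40 <- confusion_matrix(14, 1, 3, 82)
  expect_equal(round_half_up(ppv(s40), 3), 0.824)
  expect_equal(round_half_up(npv(s40), 3), 0.988)

  expect_equal(accuracy(confusion_matrix(0, 15, 85, 0)), 0)
  expect_equal(accuracy(confusion_matrix(588, 12, 28, 3372)), 0.990)
})

test_that("undefined metrics return NA markers", {
  no_bs <- confusion_matrix(0, 0, 5, 80)
  expect_true(is.na(sen(no_bs)))
  no_det <- confusion_matrix(10, 5, 0, 0)
  expect_true(is.na(spe(no_det)))
  expect_true(is.na(npv(confusion_matrix(10, 0, 5, 0))))  # no reactions at all
  # rhr = 1 only if one category is empty and responses match it entirely
  degenerate <- confusion_matrix(10, 0, 0, 0)
  expect_equal(random_hit_rate(degenerate), 1)
  expect_true(is.na(ratz(degenerate)))
  expect_error(confusion_matrix(-1, 0, 0, 5), "non-negative")
  expect_error(confusion_matrix(0, 0, 0, 0), "at least one")
})

test_that("random hit rate equals the permutation oracle", {
  set.seed(314)
  for (i in 1:6) {
    n_bs <- sample(5:20, 1)
    n_det <- 100 - n_bs
    tn <- sample(0:n_bs, 1); tp <- sample(0:n_det, 1)
    m <- confusion_matrix(tn, n_bs - tn, n_det - tp, tp)
    expect_equal(random_hit_rate(m), oracle_rhr(m, 2000), tolerance = 0.01)
  }
})

test_that("metric invariants hold over random matrices", {
  set.seed(2718)
  for (i in 1:200) {
    tn <- sample(0:15, 1); fp <- 15 - tn
    tp <- sample(0:85, 1); fn <- 85 - tp
    m <- confusion_matrix(tn, fp, fn, tp)
    vals <- unlist(metrics_report(m)[c("sen", "spe", "ppv", "npv", "hr", "rhr", "acc")])
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 1 + 1e-12))
    # ratz is chance-corrected: below-chance performance goes negative, but
    # it never exceeds 1 and its sign tracks hr - rhr
    rhr <- random_hit_rate(m)
    if (!is.na(ratz(m))) {
      expect_equal(hit_rate(m) >= rhr, ratz(m) >= 0)
      expect_lte(ratz(m), 1)
    }
  }
})

test_that("pooling is order-invariant and the cohort summary is unweighted", {
  ms <- reconstruct_matrices(bundled_subjects())
  set.seed(1)
  shuffled <- ms[sample(length(ms))]
  expect_identical(unclass(pool_matrices(ms)), unclass(pool_matrices(shuffled)))
  expect_equal(accuracy(pool_matrices(ms)), accuracy(pool_matrices(shuffled)))

  one <- cohort_summary(list(confusion_matrix(15, 0, 0, 85)))
  expect_true(all(one$mean[one$metric %in% c("sen", "spe", "ppv", "npv", "hr", "acc")] == 1))
  expect_true(all(one$sd == 0))
  expect_error(cohort_summary(list()), "at least one")
})

test_that("Spearman-Brown prophecy behaves at its landmarks", {
  expect_equal(round_half_up(spearman_brown(0.547), 3), 0.707)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  expect_error(spearman_brown(-1), "undefined")
})

test_that("split-half reliability: exact cases", {
  mk_rec <- function(clicks) {
    data.frame(block = "scored", category = "blindspot", clicked = clicks)
  }
  # identical halves by construction: k no-click pairs then clicks, so the
  # odd-half and even-half correct-rejection counts both equal k
  recs <- lapply(c(0, 3, 5, 7), function(k) {
    mk_rec(c(rep(FALSE, 2 * k), rep(TRUE, 14 - 2 * k)))
  })
  out <- split_half_reliability(recs)
  expect_equal(out$r, 1)
  expect_equal(out$corrected, 1)
  # all subjects identical: zero variance -> undefined marker
  same <- lapply(1:5, function(i) mk_rec(rep(FALSE, 14)))
  expect_true(is.na(split_half_reliability(same)$r))
  expect_error(split_half_reliability(recs[1:2]), "at least 3")
})

test_that("split-half reliability is self-consistent under a known generator", {
  # Subjects draw a correct-rejection rate from Beta(20, 1); blind-spot trials
  # are Bernoulli. Two independent replicate batches of the same generator
  # must agree on the mean corrected reliability within Monte-Carlo error.
  # (Scaled down from the full 500-replicate design to keep the suite fast.)
  sim_cohort <- function(n_subj = 40) {
    lapply(seq_len(n_subj), function(i) {
      s <- rbeta(1, 20, 1)
      data.frame(block = "scored", category = "blindspot",
                 clicked = runif(15) > s)
    })
  }
  batch <- function(reps) {
    vapply(seq_len(reps), function(r) {
      out <- split_half_reliability(sim_cohort())
      if (is.na(out$corrected)) NA_real_ else out$corrected
    }, numeric(1))
  }
  set.seed(101); a <- batch(120)
  set.seed(909); b <- batch(120)
  se <- sqrt(stats::var(a, na.rm = TRUE) / sum(!is.na(a)) +
             stats::var(b, na.rm = TRUE) / sum(!is.na(b)))
  expect_lt(abs(mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)), 4 * se + 0.02)
})

test_that("matrix reconstruction from rates recovers exact integer counts", {
  ms <- reconstruct_matrices(data.frame(sen = c(1, 0.933, 0.867),
                                        spe = c(1, 0.988, 0.906)))
  expect_equal(vapply(ms, `[[`, numeric(1), "tn"), c(15, 14, 13))
  expect_equal(vapply(ms, `[[`, numeric(1), "tp"), c(85, 84, 77))
  expect_true(all(vapply(ms, function(m) m$tn + m$fp == 15 && m$tp + m$fn == 85,
                         logical(1))))
})

test_that("the reproduction report flags rows the chance-correction formula cannot match", {
  rep <- reproduce_validation(bundled_subjects())
  expect_equal(nrow(rep$per_subject), 40)
  # single-error rows published as RATZ = 1 are flagged (formula gives < 1),
  # as are the three multi-error rows with unreproducible published values
  expect_true(all(c("36", "29", "40") %in% rep$discrepancies$subject))
  expect_gt(nrow(rep$discrepancies), 10)
  # subjects whose published RATZ the formula does reproduce are not flagged
  expect_false("01" %in% rep$discrepancies$subject)
  expect_false("02" %in% rep$discrepancies$subject)
})
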