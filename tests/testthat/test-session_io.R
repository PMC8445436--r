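make_session <- function(seed = 51, duration = 120) {
  cfg <- training_config(reference_point = c(20, 0), step_deg = 0.5,
                         session_duration_s = duration, seed = seed,
                         checkpoint_interval_s = 30)
  run_training_session(cfg, function(pos, size) pos[1] < 10,
                       list(stimulus_state("a", 5, 0), stimulus_state("b", 12, 2)))
}

test_that("session logs round-trip losslessly through JSON lines", {
  res <- make_session()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(res$log, path)
  back <- read_session_log(path)
  expect_identical(back$session_id, res$log$session_id)
  expect_equal(back$click_count, res$log$click_count)
  expect_equal(back$runtime_s, res$log$runtime_s)
  expect_equal(length(back$checkpoints), length(res$log$checkpoints))
  expect_equal(back$final_coordinates$x_deg, res$log$final_coordinates$x_deg)
  expect_identical(back$config_digest, res$log$config_digest)
  expect_false(back$aborted)
  # final snapshot equals the last checkpoint at normal termination
  last <- back$checkpoints[[length(back$checkpoints)]]$coordinates
  expect_equal(last$x_deg, back$final_coordinates$x_deg)
})

test_that("a truncated log recovers its checkpoints and flags abnormal termination", {
  res <- make_session()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(res$log, path)
  lines <- readLines(path)
  k <- length(res$log$checkpoints) - 1
  writeLines(lines[1:(1 + k)], path)  # header + first k checkpoints, no final
  back <- read_session_log(path)
  expect_true(back$aborted)
  expect_equal(length(back$checkpoints), k)
  expect_true(is.na(back$click_count))
})

test_that("malformed logs raise parse errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"record":"header","session_id":"x","started_at":"t"}',
               '{not json'), path)
  expect_error(read_session_log(path), "line 2")
  writeLines('{"session_id":"x"}', path)
  expect_error(read_session_log(path), "record")
  writeLines('{"record":"header","session_id":"x"}', path)
  expect_error(read_session_log(path), "started_at")
  file.create(path)
  expect_error(read_session_log(path), "empty")
})

test_that("config digest changes iff a config field changes", {
  a <- training_config(seed = 1)
  b <- training_config(seed = 1)
  expect_identical(config_digest(a), config_digest(b))
  for (tweak in list(list(step_deg = 0.25), list(display_ms = 500),
                     list(reference_point = c(19, 0)), list(seed = 2))) {
    c_ <- do.call(training_config, utils::modifyList(list(seed = 1), tweak))
    expect_false(identical(config_digest(c_), config_digest(a)))
  }
})

test_that("training configs load from JSON with schema validation", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(step_deg = 0.25, session_duration_s = 10,
                            reference_point = c(18, -2), seed = 4),
                       path, auto_unbox = TRUE)
  cfg <- read_training_config(path)
  expect_equal(cfg$step_deg, 0.25)
  expect_equal(cfg$reference_point, c(18, -2))
  expect_equal(cfg$display_ms, 750)  # defaults fill the rest
  jsonlite::write_json(list(step_dg = 0.25), path, auto_unbox = TRUE)
  expect_error(read_training_config(path), "unknown config field")
})

test_that("CLI: convert and make-field", {
  out <- capture.output(vft_cli(c("convert", "--x-mm", "0", "--y-mm", "0")))
  expect_match(out, "^0\\.000000 0\\.000000$")
  out2 <- capture.output(vft_cli(c("convert", "--x-mm", "100", "--y-mm", "0")))
  expect_match(out2, "^21\\.945")

  dir <- withr::local_tempdir()
  fpath <- file.path(dir, "field.csv")
  capture.output(vft_cli(c("make-field", "--type", "blindspot", "--pitch", "0.75",
                           "--extent", "22.5", "--out", fpath)))
  f <- read_field(fpath)
  expect_identical(classify_point(f, c(14.5, -1)), "defect")

  expect_error(vft_cli(c("convert", "--x-mm", "1")), "--y-mm")
  expect_error(vft_cli(c("frobnicate")), "unknown command")
  expect_error(vft_cli(c("make-field", "--type", "nope", "--out", fpath)),
               "unknown field type")
})

test_that("CLI: train writes logs and an updated stimulus set", {
  dir <- withr::local_tempdir()
  fpath <- file.path(dir, "field.csv")
  capture.output(vft_cli(c("make-field", "--type", "blindspot", "--pitch", "0.75",
                           "--extent", "22.5", "--out", fpath)))
  cpath <- file.path(dir, "config.json")
  jsonlite::write_json(list(session_duration_s = 30, seed = 8,
                            reference_point = c(14.5, -1)),
                       cpath, auto_unbox = TRUE)
  outdir <- file.path(dir, "out")
  capture.output(vft_cli(c("train", "--config", cpath, "--field", fpath,
                           "--sessions", "2", "--out-dir", outdir)))
  expect_true(file.exists(file.path(outdir, "session-001.jsonl")))
  expect_true(file.exists(file.path(outdir, "session-002.jsonl")))
  log1 <- read_session_log(file.path(outdir, "session-001.jsonl"))
  expect_false(log1$aborted)
  stims <- read_stimuli(file.path(outdir, "stimuli.json"))
  expect_gt(length(stims), 0)
})

test_that("CLI: simulate-study is seed-reproducible and ideal observers are perfect", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  msg <- capture.output(vft_cli(c("simulate-study", "--subjects", "3",
                                  "--seed", "7", "--out", dir1)))
  expect_match(msg, "pooled accuracy 1\\.000")
  capture.output(vft_cli(c("simulate-study", "--subjects", "3",
                           "--seed", "7", "--out", dir2)))
  expect_identical(readLines(file.path(dir1, "pooled.json")),
                   readLines(file.path(dir2, "pooled.json")))
  expect_identical(readLines(file.path(dir1, "subject-02.csv")),
                   readLines(file.path(dir2, "subject-02.csv")))
  pooled <- jsonlite::fromJSON(file.path(dir1, "pooled.json"))
  expect_equal(pooled$accuracy, 1)
  expect_equal(pooled$tn, 3 * 15)
})

test_that("CLI: reproduce-validation reports the pooled accuracy from the bundled table", {
  dir <- withr::local_tempdir()
  msg <- capture.output(vft_cli(c("reproduce-validation", "--out", dir)))
  expect_match(msg[1], "TN=588 FP=12 FN=28 TP=3372")
  expect_match(msg[1], "accuracy 0\\.990")
  pooled <- jsonlite::fromJSON(file.path(dir, "pooled.json"))
  expect_equal(pooled$accuracy, 0.99)
  per <- utils::read.csv(file.path(dir, "per_subject_metrics.csv"))
  expect_equal(nrow(per), 40)
  expect_true(file.exists(file.path(dir, "ratz_discrepancies.csv")))
})
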