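# Published per-subject results of the 40-subject blind-spot validation
# cohort (all seven printed statistics per subject), used by the reproduction
# tests. sen/spe also ship as the CSV fixture under extdata; the full table is
# kept in code so the per-row checks do not depend on the fixture file.
validation_table <- function() {
  perfect <- c(sen = 1, spe = 1, ppv = 1, npv = 1, hr = 1, rhr = .745, ratz = 1)
  r933 <- c(sen = .933, spe = .988, ppv = .933, npv = .988, hr = .980, rhr = .745, ratz = .922)
  r933s1 <- c(sen = .933, spe = 1, ppv = 1, npv = .988, hr = .990, rhr = .752, ratz = 1)
  rsp988 <- c(sen = 1, spe = .988, ppv = .938, npv = 1, hr = .990, rhr = .738, ratz = 1)
  rsp976 <- c(sen = 1, spe = .976, ppv = .882, npv = 1, hr = .980, rhr = .731, ratz = 1)
  rows <- list(
    "01" = r933, "02" = perfect, "03" = r933s1, "04" = perfect, "05" = rsp988,
    "06" = perfect, "07" = perfect, "08" = rsp988, "09" = perfect, "10" = rsp976,
    "11" = perfect, "12" = perfect, "13" = perfect, "14" = rsp988, "15" = rsp988,
    "16" = rsp976, "17" = r933, "18" = perfect, "19" = r933, "20" = rsp988,
    "21" = rsp988, "22" = r933s1, "23" = perfect, "24" = perfect, "25" = rsp988,
    "26" = perfect, "27" = r933s1, "28" = perfect,
    "29" = c(sen = .867, spe = .988, ppv = .929, npv = .977, hr = .970, rhr = .752, ratz = .916),
    "30" = perfect, "31" = perfect, "32" = r933, "33" = perfect, "34" = perfect,
    "35" = perfect,
    "36" = c(sen = .867, spe = .906, ppv = .619, npv = .975, hr = .900, rhr = .703, ratz = .831),
    "37" = perfect, "38" = rsp988, "39" = perfect,
    "40" = c(sen = .933, spe = .965, ppv = .824, npv = .988, hr = .960, rhr = .731, ratz = .920)
  )
  out <- as.data.frame(do.call(rbind, rows))
  cbind(subject = names(rows), out, row.names = NULL)
}

bundled_subjects <- function() {
  utils::read.csv(system.file("extdata", "validation_subjects.csv", package = "vftrain"),
                  stringsAsFactors = FALSE, colClasses = c(subject = "character"))
}

# Independent oracle for the random hit rate: mean fraction of correct
# classifications over random re-pairings of the click labels with the trial
# categories.
oracle_rhr <- function(m, n_shuffle = 10000) {
  cats <- c(rep("b", m$tn + m$fp), rep("d", m$tp + m$fn))
  clicks <- c(rep(FALSE, m$tn), rep(TRUE, m$fp), rep(TRUE, m$tp), rep(FALSE, m$fn))
  mean(replicate(n_shuffle, {
    perm <- sample(clicks)
    mean(ifelse(cats == "b", !perm, perm))
  }))
}

# Small blind-spot field shared across tests (extent trimmed for speed).
test_blindspot_field <- function(pitch = 0.75, extent = 22.5) {
  make_field(list(blind_spot_scotoma()), pitch_deg = pitch, extent_deg = extent)
}
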