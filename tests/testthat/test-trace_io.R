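# Reading, windowing, regularization, and coverage filtering.

write_fixture <- function(samples, labels) {
  sp <- tempfile(fileext = ".csv"); lp <- tempfile(fileext = ".csv")
  write.csv(samples, sp, row.names = FALSE)
  write.csv(labels, lp, row.names = FALSE)
  list(samples = sp, labels = lp)
}

test_that("load_cohort groups samples per patient and vital", {
  samples <- data.frame(
    patient_id = rep(c("a", "b"), each = 3), vital = "sao2",
    offset_seconds = rep(c(0, 300, 600), 2), value = c(95, 96, 97, 91, 92, 93))
  f <- write_fixture(samples, data.frame(patient_id = c("a", "b"), label = c(0, 1)))
  coh <- load_cohort(f$samples, f$labels)
  expect_length(coh$patients, 2)
  expect_equal(nrow(coh$patients[["a"]]$series$sao2), 3)
  expect_equal(coh$patients[["b"]]$series$sao2$value, c(91, 92, 93))
  expect_equal(unname(cohort_labels(coh)), c(0L, 1L))
})

test_that("load_cohort handles empty files, duplicates, and bad schemas", {
  empty <- data.frame(patient_id = character(), vital = character(),
                      offset_seconds = numeric(), value = numeric())
  f <- write_fixture(empty, data.frame(patient_id = character(), label = integer()))
  expect_length(load_cohort(f$samples, f$labels)$patients, 0)

  # duplicated (patient, vital, t): last kept, count reported
  samples <- data.frame(
    patient_id = "a", vital = "sao2",
    offset_seconds = c(0, 300, 600, 300, 900, 600, 1200, 1500, 1800, 2100),
    value = 1:10)
  dedup <- samples[!duplicated(samples[c("patient_id", "vital", "offset_seconds")],
                               fromLast = TRUE), ]
  dedup <- dedup[order(dedup$offset_seconds), ]
  f <- write_fixture(samples, data.frame(patient_id = "a", label = 1))
  expect_message(coh <- load_cohort(f$samples, f$labels), "dropped 2 duplicated")
  expect_equal(coh$patients[["a"]]$series$sao2$value, dedup$value)

  # unknown vitals skipped with a warning
  samples$vital <- c(rep("sao2", 8), "unknown_channel", "unknown_channel")
  f <- write_fixture(samples, data.frame(patient_id = "a", label = 0))
  expect_warning(load_cohort(f$samples, f$labels), "unknown vital")

  # schema errors
  f <- write_fixture(data.frame(pid = "a", vital = "sao2",
                                offset_seconds = 0, value = 1),
                     data.frame(patient_id = "a", label = 0))
  expect_error(load_cohort(f$samples, f$labels), "missing required column")
  f <- write_fixture(data.frame(patient_id = "a", vital = "sao2",
                                offset_seconds = 0, value = 1),
                     data.frame(patient_id = "a", label = 2))
  expect_error(load_cohort(f$samples, f$labels), "labels must be 0")
})

test_that("write_cohort/load_cohort round-trips grouped samples", {
  set.seed(4)
  sc <- generate_cohort(generator_config(n_patients = 8, seed = 4))
  sp <- tempfile(fileext = ".csv"); lp <- tempfile(fileext = ".csv")
  write_cohort(sc$cohort, sp, lp)
  back <- load_cohort(sp, lp)
  expect_setequal(names(back$patients), names(sc$cohort$patients))
  for (pid in names(back$patients)) {
    for (v in names(sc$cohort$patients[[pid]]$series)) {
      orig <- sc$cohort$patients[[pid]]$series[[v]]
      keep <- !is.na(orig$values)
      got <- back$patients[[pid]]$series[[v]]
      expect_equal(got$t, (which(keep) - 1) * orig$period)
      expect_equal(got$value, orig$values[keep])
    }
  }
  expect_equal(cohort_labels(back), cohort_labels(sc$cohort))
})

test_that("window_first_24h keeps [0, 86400) and is idempotent", {
  df <- data.frame(t = c(0, 3600, 86399, 86400), value = 1:4)
  w <- window_first_24h(df)
  expect_equal(w$value, 1:3)
  expect_identical(window_first_24h(w), w)

  expect_error(window_first_24h(data.frame(t = 90000, value = 1)),
               "empty series")

  df48 <- data.frame(t = (0:575) * 300, value = rnorm(576))
  expect_equal(nrow(window_first_24h(df48)), 288)

  s <- vital_series("sao2", rnorm(576), period = 300)
  expect_length(window_first_24h(s)$values, 288)
  expect_identical(window_first_24h(window_first_24h(s)),
                   window_first_24h(s))
})

test_that("regularize snaps, interpolates short gaps, and leaves long gaps missing", {
  reg <- regularize(data.frame(t = (0:10) * 300, value = 1:11), "sao2",
                    period = 300, max_gap = 900)
  expect_equal(reg$values, 1:11)

  reg <- regularize(data.frame(t = c(0, 600), value = c(90, 110)), "sao2",
                    period = 300, max_gap = 900)
  expect_equal(reg$values, c(90, 100, 110))

  # one 2-h gap with max_gap 1800 -> gap grid points missing
  t <- c(0, 300, 600, 600 + 7200, 600 + 7500)
  reg <- regularize(data.frame(t = t, value = c(1, 2, 3, 10, 11)), "sao2",
                    period = 300, max_gap = 1800)
  expect_equal(sum(is.na(reg$values)), 7200 / 300 - 1)

  expect_error(regularize(data.frame(t = 0, value = 1), "sao2", period = 0),
               "period")
})

test_that("regularize never leaves the convex hull of bracketing observations", {
  set.seed(9)
  for (rep in 1:20) {
    t <- sort(sample(0:100, 12) * 300)
    v <- rnorm(12, 90, 5)
    reg <- regularize(data.frame(t = t, value = v), "sao2", period = 300,
                      max_gap = 3600)
    filled <- which(!is.na(reg$values))
    expect_true(all(reg$values[filled] >= min(v) - 1e-9 &
                      reg$values[filled] <= max(v) + 1e-9))
  }
})

test_that("coverage_filter uses a strict threshold and is monotone", {
  series_for <- function(present) {
    lapply(seq_len(10), function(i) {
      ser <- list(heartrate = vital_series("heartrate", rnorm(5, 80)))
      if (i <= present) ser$sao2 <- vital_series("sao2", rnorm(5, 96))
      patient_record(paste0("p", i), i %% 2, ser)
    })
  }
  coh6 <- cohort(series_for(6), VITALS)
  expect_true("sao2" %in% coverage_filter(coh6, 0.5))
  coh5 <- cohort(series_for(5), VITALS)
  expect_false("sao2" %in% coverage_filter(coh5, 0.5))   # 0.5 is strict

  expect_error(coverage_filter(cohort(list(), VITALS)), "empty cohort")

  # eICU-style per-vital missingness: 0.73% missing always retained at 0.5,
  # and the filter agrees with the realized per-vital coverage
  set.seed(31)
  sc <- generate_cohort(generator_config(n_patients = 400, seed = 31))
  kept <- coverage_filter(sc$cohort, 0.5)
  expect_true(all(c("sao2", "heartrate", "respiration") %in% kept))
  present <- sapply(VITALS, function(v) mean(sapply(sc$cohort$patients,
    function(p) !is.null(p$series[[v]]))))
  expect_setequal(kept, VITALS[present > 0.5])

  # monotone non-increasing in threshold
  thresholds <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  sizes <- sapply(thresholds, function(th) length(coverage_filter(sc$cohort, th)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("prepare_cohort produces one shared grid", {
  set.seed(5)
  sc <- generate_cohort(generator_config(n_patients = 6, seed = 5))
  coh <- prepare_cohort(sc$cohort)
  lens <- unlist(lapply(coh$patients, function(p)
    vapply(p$series, length, integer(1))))
  expect_true(all(lens == 288))
})
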