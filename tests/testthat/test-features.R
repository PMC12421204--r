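# Relative extrema, power in band, statistics, moving windows, and the
# assembled feature matrix.

spectrum_of <- function(absc, ord) {
  s <- fft_spectrum(vital_series("sao2", rnorm(2 * length(ord))))
  s$abscissa <- absc; s$ordinate <- ord
  s
}

test_that("relative_extrema matches hand enumeration and handles degenerate spectra", {
  sp <- spectrum_of(0:4, c(0, 1, 0, 2, 0))
  got <- relative_extrema(sp, n = 2, eps = 1)
  expect_equal(got$position, c(3, 1))
  expect_equal(got$value, c(2, 1))
  top1 <- relative_extrema(sp, n = 1, eps = 1)
  expect_equal(top1$position, 3)

  # strictly monotone: only the right boundary is a relative maximum
  mono <- spectrum_of(0:9, (1:10) / 2)
  got <- relative_extrema(mono, n = 3, eps = 2)
  expect_equal(got$found, 1)
  expect_equal(got$position, c(9, NA, NA))
  expect_equal(got$value, c(5, NA, NA))
  # ... and the left boundary the only relative minimum
  got <- relative_extrema(mono, n = 2, eps = 2, mode = "min")
  expect_equal(got$position, c(0, NA))

  expect_error(relative_extrema(sp, n = 0, eps = 1), "n")
  expect_error(relative_extrema(sp, n = 2, eps = -1), "eps")
})

test_that("relative_extrema agrees with the brute-force neighborhood oracle", {
  set.seed(201)
  for (rep in 1:150) {
    L <- sample(c(30, 65, 129), 1)
    ord <- if (rep %% 3 == 0) sample(0:5, L, replace = TRUE) else rnorm(L)^2
    absc <- (seq_len(L) - 1) / L
    eps <- sample(1:4, 1) / L
    n <- sample(1:6, 1)
    mode <- sample(c("max", "min"), 1)
    sp <- spectrum_of(absc, ord)
    got <- relative_extrema(sp, n = n, eps = eps, mode = mode)
    want <- oracle_relative_extrema(absc, ord, n, eps, mode)
    expect_identical(got$found, want$found)
    expect_equal(got$position, want$position)
    expect_equal(got$value, want$value)
  }
})

test_that("power_in_band partitions conserve total power", {
  sp <- spectrum_of(0:5, c(1, 2, 3, 4, 5, 6))
  expect_equal(unname(power_in_band(sp, 3)), c(6, 15))

  expect_equal(unname(power_in_band(sp, 6)), 21)   # L = full length

  set.seed(202)
  for (rep in 1:30) {
    L <- sample(1:20, 1)
    ord <- rnorm(sample(10:150, 1))^2
    sp <- spectrum_of(seq_along(ord), ord)
    expect_equal(sum(power_in_band(sp, L)), sum(ord))
  }

  # explicit center/bandwidth band
  sp <- spectrum_of((0:99) / 100, rep(1, 100))
  expect_equal(power_in_band_range(sp, 0.25, 0.05), 11)

  sp$ordinate <- numeric(0); sp$abscissa <- numeric(0)
  expect_error(power_in_band(sp, 5), "empty")
})

test_that("statistical_features match textbook definitions", {
  got <- statistical_features(rep(3.5, 10))
  expect_equal(unname(got[c("mean", "median", "min", "max", "first", "last")]),
               rep(3.5, 6))
  expect_equal(unname(got[c("std", "variance")]), c(0, 0))

  got <- statistical_features(c(1, 2, 3, 4))
  expect_equal(unname(got["mean"]), 2.5)
  expect_equal(unname(got["variance"]), 5 / 3)
  expect_equal(unname(got["std"]), sqrt(5 / 3))
  expect_equal(unname(got[c("q25", "q75")]), c(1.75, 3.25))

  # missing values ignored; first/last are first/last observed
  got <- statistical_features(c(NA, 7, 8, NA, 9, NA))
  expect_equal(unname(got[c("first", "last", "mean")]), c(7, 9, 8))

  expect_true(all(is.na(statistical_features(c(NA_real_, NA_real_)))))

  set.seed(203)
  got <- statistical_features(rnorm(10000, 96, 2))
  expect_equal(unname(got["mean"]), 96, tolerance = 0.1 / 96)
  expect_equal(unname(got["std"]), 2, tolerance = 0.1 / 2)
})

test_that("moving_window_extrema finds planted sudden changes and nothing else", {
  const <- moving_window_extrema(rep(96, 50), k = 12)
  expect_equal(nrow(const$rise), 0)
  expect_equal(nrow(const$drop), 0)
  expect_true(all(is.na(const$features)))

  # flat baseline with one dip
  x <- rep(96, 288); x[101] <- 82
  s <- vital_series("sao2", x, period = 300)
  got <- moving_window_extrema(s, k = 12)
  expect_equal(nrow(got$drop), 1)
  expect_equal(got$drop$value, 82)
  expect_equal(got$drop$time, 100 * 300)
  expect_equal(nrow(got$rise), 0)

  expect_error(moving_window_extrema(rnorm(10), k = 12), "window error")
  expect_error(moving_window_extrema(rnorm(30), k = 2), "k")
})

test_that("moving_window_extrema agrees with the brute-force window scan", {
  set.seed(204)
  for (rep in 1:150) {
    N <- sample(40:120, 1)
    x <- rnorm(N, 90, 3)
    if (rep %% 4 == 0) x[sample(N, 3)] <- 90 + c(-25, 25, -18)  # planted jumps
    if (rep %% 5 == 0) x[sample(N, 2)] <- NA                    # missing samples
    k <- sample(c(5, 8, 12, 20), 1)
    cm <- sample(c(2, 3), 1)
    n <- sample(1:4, 1)
    got <- moving_window_extrema(x, k = k, n = n, c = cm)
    want <- oracle_moving_window(x, k, n, cm)
    expect_equal(nrow(got$rise), want$rise$count)
    expect_equal(nrow(got$drop), want$drop$count)
    expect_equal(unname(got$features[paste0("rise_value_", seq_len(n))]),
                 want$rise$value)
    expect_equal(unname(got$features[paste0("drop_value_", seq_len(n))]),
                 want$drop$value)
    expect_equal(unname(got$features[paste0("drop_time_", seq_len(n))]),
                 as.numeric(want$drop$index - 1))
  }
})

test_that("feature names follow the grammar and round-trip through the parser", {
  cfg <- feature_config()
  nms <- feature_names(cfg, 288)
  expect_equal(anyDuplicated(nms), 0)
  parsed <- lapply(nms, parse_feature_name)
  expect_true(all(vapply(parsed, function(p) p$vital %in% VITALS, logical(1))))
  techniques <- vapply(parsed, `[[`, character(1), "technique")
  expect_setequal(unique(techniques), c("stat", "sudden", "fft", "psd", "ac", "wt"))

  # the published example names parse
  p <- parse_feature_name("sao2_wt_morl_length5_power-in-band_1")
  expect_equal(p[c("vital", "technique", "wavelet", "family")],
               list(vital = "sao2", technique = "wt", wavelet = "morl",
                    family = "power-in-band"))
  p <- parse_feature_name("sao2_sudden-drop_value_1")
  expect_equal(p$technique, "sudden")
  p <- parse_feature_name("stat_sao2_last")
  expect_equal(p[c("vital", "stat")], list(vital = "sao2", stat = "last"))

  expect_error(parse_feature_name("sao2_wt_power-in-band_1"), "grammar")
  expect_error(parse_feature_name("bogus_fft_power-in-band_1"), "grammar")
})

test_that("build_feature_matrix has deterministic shape matching the closed form", {
  set.seed(205)
  sc <- generate_cohort(generator_config(n_patients = 20, seed = 205))
  coh <- sc$cohort

  stats_cfg <- feature_config(vitals = "sao2", transforms = character(0),
                              include_sudden = FALSE)
  fm <- build_feature_matrix(coh, stats_cfg)
  expect_equal(ncol(fm$X), 10)
  expect_equal(nrow(fm$X), 20)

  cfg <- feature_config()
  fm1 <- suppressWarnings(build_feature_matrix(coh, cfg))
  fm2 <- suppressWarnings(build_feature_matrix(coh, cfg))
  expect_identical(fm1$X, fm2$X)

  # closed-form column count from the configuration
  N <- 288
  lens <- c(fft = N / 2 + 1, psd = N / 2 + 1, ac = 41, wt = N)
  per_1d <- function(len) 4 * cfg$n_extrema + ceiling(len / cfg$band_length)
  expected_per_vital <- 10 + 4 * cfg$window_n +
    per_1d(lens["fft"]) + per_1d(lens["psd"]) + per_1d(lens["ac"]) +
    3 * 4 * per_1d(lens["wt"])
  expect_equal(ncol(fm1$X), unname(6 * expected_per_vital))
  expect_equal(fm1$names, feature_names(cfg, N))
})

test_that("batch feature extraction equals the per-series operations", {
  set.seed(206)
  sc <- generate_cohort(generator_config(n_patients = 12, dropout = 0.05,
                                         seed = 206))
  coh <- sc$cohort
  cfg <- feature_config(vitals = "sao2", wt_scales = c(2, 16))
  fm <- suppressWarnings(build_feature_matrix(coh, cfg))
  eps <- cfg$eps_bins
  for (pid in sample(names(coh$patients), 5)) {
    s <- coh$patients[[pid]]$series[["sao2"]]
    if (is.null(s)) next
    row <- fm$X[pid, ]
    expect_equal(unname(row[paste0("stat_sao2_", c("mean", "std", "min", "last"))]),
                 unname(statistical_features(s)[c("mean", "std", "min", "last")]))
    si <- impute_series(s)
    fs <- fft_spectrum(si)
    ex <- relative_extrema(fs, n = cfg$n_extrema, eps = eps / 288)
    expect_equal(unname(row[paste0("sao2_fft_relative-maxima-position_", 1:5)]),
                 ex$position)
    expect_equal(unname(row[paste0("sao2_fft_relative-maxima-value_", 1:5)]),
                 ex$value)
    pb <- power_in_band(psd_spectrum(si), cfg$band_length)
    expect_equal(unname(row[paste0("sao2_psd_length5_power-in-band_",
                                   seq_along(pb))]),
                 unname(pb))
    acs <- autocorrelation(si, cfg$ac_max_lag)
    exa <- relative_extrema(acs, n = cfg$n_extrema, eps = eps, mode = "min")
    expect_equal(unname(row[paste0("sao2_ac_relative-minima-value_", 1:5)]),
                 exa$value)
    wsc <- wavelet_scalogram(si, wavelet_spec("cmor", cfg$wt_scales,
                                              center = cfg$cmor_center,
                                              bandwidth = cfg$cmor_bandwidth))
    r2 <- scalogram_row(wsc, 2)
    pb2 <- power_in_band(r2, cfg$band_length)
    expect_equal(unname(row[paste0("sao2_wt_cmor_row2_length5_power-in-band_",
                                   seq_along(pb2))]),
                 unname(pb2), tolerance = 1e-9)
    mw <- moving_window_extrema(s, k = cfg$window_k, n = cfg$window_n,
                                c = cfg$sd_mult)
    expect_equal(unname(row[paste0("sao2_sudden-drop_value_", 1:5)]),
                 unname(mw$features[paste0("drop_value_", 1:5)]))
  }
})

test_that("scaling a series scales statistics by alpha and band power by alpha^2", {
  set.seed(207)
  x <- rnorm(128, 90, 4)
  a <- 3.7
  s1 <- statistical_features(x); s2 <- statistical_features(a * x)
  for (nm in c("mean", "std", "min", "max", "first", "last"))
    expect_equal(unname(s2[nm]), a * unname(s1[nm]), tolerance = 1e-12)
  p1 <- power_in_band(psd_spectrum(vital_series("sao2", x)), 5)
  p2 <- power_in_band(psd_spectrum(vital_series("sao2", a * x)), 5)
  expect_equal(unname(p2), a^2 * unname(p1), tolerance = 1e-9)
})

test_that("feature values are finite or missing", {
  set.seed(208)
  sc <- generate_cohort(generator_config(n_patients = 15, dropout = 0.1,
                                         seed = 208))
  fm <- suppressWarnings(build_feature_matrix(sc$cohort))
  expect_true(all(is.finite(fm$X) | is.na(fm$X)))
})
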