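# Feature extraction: relative extrema, power in band, summary statistics,
# moving-window sudden changes, and assembly of the patients x features matrix.

STAT_NAMES <- c("mean", "median", "std", "variance", "q25", "q75",
                "min", "max", "first", "last")
EXTREMA_FAMILIES <- c("relative-maxima-position", "relative-maxima-value",
                      "relative-minima-position", "relative-minima-value")

#' Relative extrema of a spectrum
#'
#' A point is a relative maximum iff its ordinate is greater than or equal to
#' every ordinate within abscissa distance `eps` (boundary points are compared
#' against their one-sided neighborhood, so a global maximum is never
#' dropped). At most one extremum is reported per `eps`-neighborhood; tied
#' candidates keep the smallest abscissa. The top `n` extrema are selected by
#' ordinate (largest for `mode = "max"`, smallest for `mode = "min"`); when
#' only `m < n` exist, the trailing `n - m` slots are missing.
#'
#' @param spectrum A `frequency_spectrum`.
#' @param n Number of extrema slots.
#' @param eps Neighborhood half-width in abscissa units. Default: 3 abscissa
#'   bins.
#' @param mode `"max"` or `"min"`.
#' @return List with `position` (abscissa of each extremum, length `n`,
#'   NA-padded), `value` (ordinates, length `n`), and `found` (number of
#'   extrema located).
#' @export
relative_extrema <- function(spectrum, n = 5, eps = NULL,
                             mode = c("max", "min")) {
  mode <- match.arg(mode)
  xa <- spectrum$abscissa
  yo <- spectrum$ordinate
  if (!length(yo)) stop("empty spectrum", call. = FALSE)
  if (is.null(eps)) eps <- 3 * stats::median(diff(xa))
  if (!is.numeric(eps) || eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  tol <- eps * 1e-9
  L <- length(yo)
  cand <- integer(0)
  for (i in seq_len(L)) {
    nb <- yo[abs(xa - xa[i]) <= eps + tol]
    ok <- if (mode == "max") all(nb <= yo[i]) else all(nb >= yo[i])
    if (ok) cand <- c(cand, i)
  }
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || xa[i] - xa[kept[length(kept)]] > eps + tol)
      kept <- c(kept, i)
  }
  ord <- if (mode == "max") {
    order(-yo[kept], xa[kept])
  } else {
    order(yo[kept], xa[kept])
  }
  kept <- kept[ord]
  m <- length(kept)
  pos <- rep(NA_real_, n)
  val <- rep(NA_real_, n)
  take <- seq_len(min(n, m))
  pos[take] <- xa[kept[take]]
  val[take] <- yo[kept[take]]
  list(position = pos, value = val, found = m, mode = mode)
}

#' Power-in-band features of a spectrum
#'
#' Partitions the ordinate vector into consecutive non-overlapping segments of
#' `segment_length` bins (the last segment may be shorter) and returns the
#' per-segment sums. Band 1 is the first segment: the lowest-frequency band
#' for FFT/PSD spectra, the earliest time segment for scalogram rows. The
#' segment sums always add up to the total power exactly.
#'
#' @param spectrum A `frequency_spectrum`.
#' @param segment_length Segment length `L >= 1` in bins.
#' @return Named numeric vector `band_1 .. band_ceil(len/L)`.
#' @export
power_in_band <- function(spectrum, segment_length = 5) {
  yo <- spectrum$ordinate
  if (!length(yo)) stop("empty spectrum", call. = FALSE)
  L <- as.integer(segment_length)
  if (is.na(L) || L < 1) stop("`segment_length` must be >= 1", call. = FALSE)
  grp <- (seq_along(yo) - 1L) %/% L
  sums <- as.numeric(rowsum(yo, grp))
  names(sums) <- paste0("band_", seq_along(sums))
  sums
}

#' Power within an explicit frequency band
#'
#' Band specified by center and half-bandwidth on the abscissa scale: sums the
#' ordinates with abscissa in `[center - bandwidth, center + bandwidth]`.
#'
#' @param spectrum A `frequency_spectrum`.
#' @param center,bandwidth Band center and half-width in abscissa units.
#' @return A single power value.
#' @export
power_in_band_range <- function(spectrum, center, bandwidth) {
  if (!length(spectrum$ordinate)) stop("empty spectrum", call. = FALSE)
  inb <- spectrum$abscissa >= center - bandwidth &
    spectrum$abscissa <= center + bandwidth
  sum(spectrum$ordinate[inb])
}

#' Summary-statistic features of a raw series
#'
#' Conventional summaries of the non-missing samples: mean, median, SD and
#' variance (denominator N-1), 25th/75th percentiles (linear interpolation),
#' min, max, and the first and last observed value. An all-missing series
#' yields all-missing features.
#'
#' @param series A `vital_series` (or numeric vector; `NA`s ignored).
#' @return Named numeric vector of the 10 statistics.
#' @export
statistical_features <- function(series) {
  v <- if (inherits(series, "vital_series")) series$values else as.numeric(series)
  v <- v[!is.na(v)]
  out <- rep(NA_real_, length(STAT_NAMES))
  names(out) <- STAT_NAMES
  if (!length(v)) return(out)
  q <- unname(quantile(v, c(0.25, 0.75), type = 7))
  out[] <- c(mean(v), median(v),
             if (length(v) > 1) sd(v) else 0,
             if (length(v) > 1) var(v) else 0,
             q[1], q[2], min(v), max(v), v[1], v[length(v)])
  out
}

#' Sudden rises and drops from moving windows
#'
#' Slides a window of `k` consecutive samples (stride 1) along the series;
#' within each window the mean and population SD (denominator `k`) are
#' computed from the `k` observations, the candidate sample included. A
#' sample strictly above `mean + c * SD` in any window containing it is a
#' sudden rise; strictly below `mean - c * SD`, a sudden drop. Samples flagged
#' by several windows are reported once, with the first flagging window.
#' Rises are ranked by descending value and drops by ascending value; the top
#' `n` (time, value) pairs per direction are returned, missing-padded. A
#' zero-SD window flags nothing, and windows containing missing samples are
#' skipped.
#'
#' @param series A `vital_series` (or numeric vector).
#' @param k Window size in samples (`3 <= k <= N`). Default 12 (1 h at a
#'   300 s cadence).
#' @param n Number of feature slots per direction.
#' @param c SD multiplier; default 3 (the 3-SD rule).
#' @return List with data frames `rise` and `drop` (columns `index`, `time`,
#'   `value`, `window`), and `features`, a named vector of the `4 n` values
#'   `rise_time_1..n, rise_value_1..n, drop_time_1..n, drop_value_1..n`
#'   (times in seconds since admission).
#' @export
moving_window_extrema <- function(series, k = 12, n = 5, c = 3) {
  is_vs <- inherits(series, "vital_series")
  v <- if (is_vs) series$values else as.numeric(series)
  k <- as.integer(k)
  if (k < 3) stop("`k` must be >= 3", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (c <= 0) stop("`c` must be > 0", call. = FALSE)
  if (k > length(v))
    stop("window error: `k` exceeds the series length", call. = FALSE)
  res <- cpp_moving_window(matrix(v, ncol = 1), k, max(n, length(v)), c)
  t0 <- if (is_vs) series$t0 else 0
  period <- if (is_vs) series$period else 1
  to_time <- function(idx) t0 + (idx - 1) * period
  mk <- function(ti, vi, wi, count) {
    m <- count
    data.frame(index = ti[seq_len(m), 1], time = to_time(ti[seq_len(m), 1]),
               value = vi[seq_len(m), 1], window = wi[seq_len(m), 1])
  }
  rise <- mk(res$rise_t, res$rise_v, res$rise_w, res$rise_count[1])
  drop <- mk(res$drop_t, res$drop_v, res$drop_w, res$drop_count[1])
  pad <- function(x, n) { out <- rep(NA_real_, n); out[seq_len(min(n, length(x)))] <- x[seq_len(min(n, length(x)))]; out }
  feats <- c(pad(rise$time, n), pad(rise$value, n),
             pad(drop$time, n), pad(drop$value, n))
  names(feats) <- c(paste0("rise_time_", seq_len(n)),
                    paste0("rise_value_", seq_len(n)),
                    paste0("drop_time_", seq_len(n)),
                    paste0("drop_value_", seq_len(n)))
  list(rise = rise, drop = drop, features = feats, k = k, n = n, c = c)
}

#' Feature-extraction configuration
#'
#' Defaults: all six vitals; all four transforms; all three wavelet families;
#' 5 extrema slots per mode with a 3-bin neighborhood; band segment length 5;
#' autocorrelation to lag 40; moving windows of 12 samples with the 3-SD rule
#' and 5 slots per direction; wavelet features from 4 logarithmically spaced
#' scale rows of the default 32-scale grid.
#'
#' @param vitals Vitals to extract features for.
#' @param transforms Subset of `c("fft", "psd", "ac", "wt")`.
#' @param wavelets Subset of `c("morl", "cmor", "mexh")`.
#' @param n_extrema Extrema slots per mode.
#' @param eps_bins Extrema neighborhood half-width in abscissa bins.
#' @param band_length Power-in-band segment length (bins).
#' @param ac_max_lag Autocorrelation maximum lag (samples).
#' @param window_k,window_n,sd_mult Moving-window size, slots per direction,
#'   and SD multiplier.
#' @param wt_scales Scales (samples) at which scalogram rows are turned into
#'   features.
#' @param cmor_center,cmor_bandwidth Complex Morlet parameters.
#' @param include_stats,include_sudden Toggle the statistical and
#'   moving-window families.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(vitals = VITALS,
                           transforms = c("fft", "psd", "ac", "wt"),
                           wavelets = c("morl", "cmor", "mexh"),
                           n_extrema = 5, eps_bins = 3, band_length = 5,
                           ac_max_lag = 40,
                           window_k = 12, window_n = 5, sd_mult = 3,
                           wt_scales = default_scales()[c(1, 11, 21, 32)],
                           cmor_center = 1.0, cmor_bandwidth = 1.5,
                           include_stats = TRUE, include_sudden = TRUE) {
  vitals <- VITALS[VITALS %in% unlist(vitals)]
  transforms <- intersect(c("fft", "psd", "ac", "wt"), unlist(transforms))
  wavelets <- intersect(c("morl", "cmor", "mexh"), unlist(wavelets))
  wt_scales <- as.numeric(unlist(wt_scales))
  stopifnot(n_extrema >= 1, eps_bins >= 1, band_length >= 1,
            ac_max_lag >= 1, window_k >= 3, window_n >= 1, sd_mult > 0)
  structure(list(vitals = vitals, transforms = transforms, wavelets = wavelets,
                 n_extrema = as.integer(n_extrema),
                 eps_bins = as.integer(eps_bins),
                 band_length = as.integer(band_length),
                 ac_max_lag = as.integer(ac_max_lag),
                 window_k = as.integer(window_k),
                 window_n = as.integer(window_n), sd_mult = sd_mult,
                 wt_scales = as.numeric(wt_scales),
                 cmor_center = cmor_center, cmor_bandwidth = cmor_bandwidth,
                 include_stats = isTRUE(include_stats),
                 include_sudden = isTRUE(include_sudden)),
            class = "feature_config")
}

extrema_names <- function(prefix, n) {
  as.vector(vapply(EXTREMA_FAMILIES, function(f)
    paste0(prefix, "_", f, "_", seq_len(n)), character(n)))
}

band_names <- function(prefix, L, len) {
  nb <- ceiling(len / L)
  paste0(prefix, "_length", L, "_power-in-band_", seq_len(nb))
}

spectrum_lengths <- function(config, n_samples) {
  c(fft = floor(n_samples / 2) + 1,
    psd = floor(n_samples / 2) + 1,
    ac = min(config$ac_max_lag, n_samples - 1) + 1,
    wt = n_samples)
}

#' Feature names generated by a configuration
#'
#' Deterministic column order of [build_feature_matrix()]: per vital, the
#' statistical family, the moving-window family, then each transform in
#' config order (extrema slots, then power-in-band segments; wavelet features
#' per family and scale row).
#'
#' Names follow the grammar
#' `<vital>_<transform>[_<wavelet>][_row<R>][_length<L>]_<family>_<index>`,
#' `stat_<vital>_<stat>`, or `<vital>_sudden-<rise|drop>_<time|value>_<index>`
#' and parse back with [parse_feature_name()].
#'
#' @param config A [feature_config()].
#' @param n_samples Length of the regular series the features are computed
#'   from.
#' @return Character vector of feature names.
#' @export
feature_names <- function(config, n_samples) {
  lens <- spectrum_lengths(config, n_samples)
  out <- character(0)
  for (v in config$vitals) {
    if (config$include_stats)
      out <- c(out, paste0("stat_", v, "_", STAT_NAMES))
    if (config$include_sudden)
      out <- c(out, paste0(v, "_sudden-rise_time_", seq_len(config$window_n)),
               paste0(v, "_sudden-rise_value_", seq_len(config$window_n)),
               paste0(v, "_sudden-drop_time_", seq_len(config$window_n)),
               paste0(v, "_sudden-drop_value_", seq_len(config$window_n)))
    for (tr in config$transforms) {
      if (tr == "wt") {
        for (wv in config$wavelets) {
          for (r in seq_along(config$wt_scales)) {
            prefix <- paste0(v, "_wt_", wv, "_row", r)
            out <- c(out, extrema_names(prefix, config$n_extrema),
                     band_names(prefix, config$band_length, lens[["wt"]]))
          }
        }
      } else {
        prefix <- paste0(v, "_", tr)
        out <- c(out, extrema_names(prefix, config$n_extrema),
                 band_names(prefix, config$band_length, lens[[tr]]))
      }
    }
  }
  out
}

#' Parse a feature name back into its components
#'
#' @param name A single feature name.
#' @return List with `vital`, `technique` (one of fft, psd, ac, wt, stat,
#'   sudden) and the remaining components (`wavelet`, `row`, `length`,
#'   `family`, `index`, `stat` where applicable).
#' @export
parse_feature_name <- function(name) {
  vit_re <- paste(VITALS, collapse = "|")
  m <- regmatches(name, regexec(paste0("^stat_(", vit_re, ")_([a-z0-9]+)$"), name))[[1]]
  if (length(m))
    return(list(vital = m[2], technique = "stat", stat = m[3]))
  m <- regmatches(name, regexec(paste0(
    "^(", vit_re, ")_sudden-(rise|drop)_(time|value)_([0-9]+)$"), name))[[1]]
  if (length(m))
    return(list(vital = m[2], technique = "sudden", direction = m[3],
                component = m[4], index = as.integer(m[5])))
  m <- regmatches(name, regexec(paste0(
    "^(", vit_re, ")_(fft|psd|ac|wt)",
    "(_(morl|cmor|mexh))?(_row([0-9]+))?(_length([0-9]+))?",
    "_(relative-maxima-position|relative-maxima-value|",
    "relative-minima-position|relative-minima-value|power-in-band)",
    "_([0-9]+)$"), name))[[1]]
  if (length(m)) {
    tech <- m[3]
    if (tech == "wt" && m[5] == "")
      stop("grammar error: wavelet features need a wavelet family: ", name,
           call. = FALSE)
    return(list(vital = m[2], technique = tech,
                wavelet = if (m[5] != "") m[5] else NULL,
                row = if (m[7] != "") as.integer(m[7]) else NULL,
                length = if (m[9] != "") as.integer(m[9]) else NULL,
                family = m[10], index = as.integer(m[11])))
  }
  stop("grammar error: unparseable feature name: ", name, call. = FALSE)
}

# ---- batch helpers (matrix = samples x patients, NA columns allowed) ------

# extrema + band feature rows for a batch of uniform-grid spectra
# ordmat: bins x patients; absc: abscissa values; returns features x patients
batch_spectrum_features <- function(ordmat, absc, config) {
  n_pat <- ncol(ordmat)
  ne <- config$n_extrema
  ex_max <- cpp_relative_extrema(ordmat, config$eps_bins, ne, TRUE)
  ex_min <- cpp_relative_extrema(ordmat, config$eps_bins, ne, FALSE)
  pos_of <- function(p) {
    out <- matrix(NA_real_, nrow(p), ncol(p))
    ok <- !is.na(p)
    out[ok] <- absc[p[ok]]
    out
  }
  grp <- (seq_len(nrow(ordmat)) - 1L) %/% config$band_length
  bands <- rowsum(ordmat, grp)
  rbind(pos_of(ex_max$pos), ex_max$val, pos_of(ex_min$pos), ex_min$val, bands)
}

# all features for one vital; raw, imp: samples x patients matrices
batch_vital_features <- function(raw, imp, period, config) {
  n_samples <- nrow(raw)
  n_pat <- ncol(raw)
  lens <- spectrum_lengths(config, n_samples)
  blocks <- list()

  if (config$include_stats) {
    stat <- apply(raw, 2, statistical_features)
    blocks[[length(blocks) + 1L]] <- stat
  }
  if (config$include_sudden) {
    mw <- cpp_moving_window(raw, config$window_k, config$window_n,
                            config$sd_mult)
    to_time <- function(idx) (idx - 1) * period
    blocks[[length(blocks) + 1L]] <- rbind(
      to_time(mw$rise_t), mw$rise_v, to_time(mw$drop_t), mw$drop_v)
  }

  ok <- !colSums(is.na(imp))          # columns fully observed after imputation
  sub <- imp[, ok, drop = FALSE]
  nok <- sum(ok)
  half <- lens[["fft"]]

  scatter <- function(featsub, nrow_out) {
    out <- matrix(NA_real_, nrow_out, n_pat)
    if (nok) out[, ok] <- featsub
    out
  }

  needs_fourier <- any(c("fft", "psd") %in% config$transforms)
  if (needs_fourier && nok) {
    centered <- sweep(sub, 2, colMeans(sub))
    Fm <- mvfft(centered)
  }
  for (tr in config$transforms) {
    nfeat <- 4 * config$n_extrema + ceiling(lens[[tr]] / config$band_length)
    if (tr == "fft") {
      feat <- if (nok) {
        mag <- Mod(Fm)[seq_len(half), , drop = FALSE]
        batch_spectrum_features(mag, (seq_len(half) - 1) / n_samples, config)
      }
      blocks[[length(blocks) + 1L]] <- scatter(if (nok) feat else NULL, nfeat)
    } else if (tr == "psd") {
      feat <- if (nok) {
        p2 <- Mod(Fm)^2 / n_samples^2
        p1 <- p2[seq_len(half), , drop = FALSE]
        dbl <- seq(2L, half)
        if (n_samples %% 2L == 0L) dbl <- dbl[-length(dbl)]
        p1[dbl, ] <- 2 * p1[dbl, , drop = FALSE]
        batch_spectrum_features(p1, (seq_len(half) - 1) / n_samples, config)
      }
      blocks[[length(blocks) + 1L]] <- scatter(if (nok) feat else NULL, nfeat)
    } else if (tr == "ac") {
      ml <- min(config$ac_max_lag, n_samples - 1)
      feat <- if (nok) {
        centered_ac <- sweep(sub, 2, colMeans(sub))
        m <- nextn(2 * n_samples, c(2, 3, 5))
        xp <- rbind(centered_ac, matrix(0, m - n_samples, nok))
        S <- Mod(mvfft(xp))^2
        rk <- Re(mvfft(S, inverse = TRUE))[seq_len(ml + 1), , drop = FALSE] / m
        r0 <- rk[1, ]
        r0[r0 == 0] <- NA_real_        # zero-variance: undefined -> NA
        rk <- sweep(rk, 2, r0, "/")
        batch_spectrum_features(rk, 0:ml, config)
      }
      blocks[[length(blocks) + 1L]] <- scatter(if (nok) feat else NULL, nfeat)
    } else if (tr == "wt") {
      nrow_wav <- nfeat * length(config$wt_scales)
      for (wv in config$wavelets) {
        feat <- if (nok) {
          spec <- wavelet_spec(wv, scales = sort(config$wt_scales),
                               center = config$cmor_center,
                               bandwidth = config$cmor_bandwidth)
          rows <- lapply(seq_along(config$wt_scales), function(r) {
            kern <- wavelet_kernel(spec, config$wt_scales[r])
            mags <- Mod(conv_rows(sub, kern))
            batch_spectrum_features(mags, 0:(n_samples - 1), config)
          })
          do.call(rbind, rows)
        }
        blocks[[length(blocks) + 1L]] <- scatter(if (nok) feat else NULL,
                                                 nrow_wav)
      }
    }
  }
  do.call(rbind, blocks)
}

#' Assemble the patients-by-features matrix
#'
#' For every patient and configured vital: statistical features on the raw
#' series, moving-window sudden-change features on the raw series, and
#' relative-extrema plus power-in-band features on every enabled transform
#' output (wavelet features per configured scale row). Patients lacking a
#' vital get missing values for all its features. Spectral transforms run on
#' the imputed series ([impute_series()] policy); statistics and moving
#' windows see the raw series with its missingness.
#'
#' @param x A prepared `cohort` (all series regular, identical grids; see
#'   [prepare_cohort()]).
#' @param config A [feature_config()].
#' @return An object of class `feature_matrix`: list with `X` (patients x
#'   features, with NA for missing values), `patient_ids`, `names`, `label`.
#' @export
build_feature_matrix <- function(x, config = feature_config()) {
  pats <- x$patients
  n_pat <- length(pats)
  if (!n_pat) stop("empty cohort", call. = FALSE)
  lengths <- unlist(lapply(pats, function(p)
    vapply(p$series, function(s) length(s$values), integer(1))))
  if (!length(lengths))
    stop("cohort has no series; run prepare_cohort() first", call. = FALSE)
  n_samples <- unique(lengths)
  if (length(n_samples) != 1L)
    stop("all series must share one grid length; run prepare_cohort()",
         call. = FALSE)
  periods <- unique(unlist(lapply(pats, function(p)
    vapply(p$series, function(s) s$period, numeric(1)))))
  if (length(periods) != 1L)
    stop("all series must share one sampling period", call. = FALSE)
  if (config$window_k > n_samples)
    stop("window error: window_k exceeds the series length", call. = FALSE)

  nms <- feature_names(config, n_samples)
  rows <- vector("list", length(config$vitals))
  for (vi in seq_along(config$vitals)) {
    v <- config$vitals[vi]
    raw <- matrix(NA_real_, n_samples, n_pat)
    for (j in seq_len(n_pat)) {
      s <- pats[[j]]$series[[v]]
      if (!is.null(s)) raw[, j] <- s$values
    }
    imp <- raw
    has_obs <- colSums(!is.na(raw)) > 0L
    for (j in which(has_obs & colSums(is.na(raw)) > 0L)) {
      obs <- which(!is.na(raw[, j]))
      imp[, j] <- if (length(obs) == 1L) raw[obs, j] else
        approx(obs, raw[obs, j], xout = seq_len(n_samples), rule = 2)$y
    }
    rows[[vi]] <- batch_vital_features(raw, imp, periods, config)
  }
  X <- t(do.call(rbind, rows))
  if (nrow(X) != n_pat || ncol(X) != length(nms))
    stop("internal assembly error: inconsistent feature counts", call. = FALSE)
  dimnames(X) <- list(names(pats), nms)
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing))
    warning(sprintf("%d feature column(s) are all-missing after assembly",
                    sum(all_missing)), call. = FALSE)
  structure(list(X = X, patient_ids = names(pats), names = nms,
                 label = unname(cohort_labels(x))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features, %.1f%% missing\n",
              nrow(x$X), ncol(x$X), 100 * mean(is.na(x$X))))
  invisible(x)
}

#' Subset the columns of a feature matrix
#'
#' @param x A `feature_matrix`.
#' @param cols Logical/integer/character column selector.
#' @return A `feature_matrix` with the selected columns.
#' @export
subset_features <- function(x, cols) {
  X <- x$X[, cols, drop = FALSE]
  structure(list(X = X, patient_ids = x$patient_ids, names = colnames(X),
                 label = x$label),
            class = "feature_matrix")
}

#' Write / read a feature matrix as delimited text
#'
#' @param x A `feature_matrix`.
#' @param path CSV path.
#' @return `x` invisibly (write); a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(patient_id = x$patient_ids, label = x$label,
                   x$X, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(x)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- data.table::fread(path, showProgress = FALSE)
  X <- as.matrix(df[, -(1:2)])
  rownames(X) <- as.character(df$patient_id)
  structure(list(X = X, patient_ids = as.character(df$patient_id),
                 names = colnames(X), label = as.integer(df$label)),
            class = "feature_matrix")
}
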