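# Independent brute-force oracles. These deliberately share no code with the
# package implementation: direct definitions, O(N^2) where that is the
# simplest correct form.

# direct DFT, one-sided magnitudes of the mean-removed series
oracle_dft_magnitude <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  half <- floor(n / 2) + 1
  sapply(seq_len(half) - 1, function(k) {
    re <- sum(x * cos(-2 * pi * k * (seq_len(n) - 1) / n))
    im <- sum(x * sin(-2 * pi * k * (seq_len(n) - 1) / n))
    sqrt(re^2 + im^2)
  })
}

# PSD via the autocovariance route: biased r(k), two-sided transform
# S_j = (r0 + 2 sum_k r_k cos(2 pi j k / N)) / N at Fourier frequencies,
# folded one-sided with interior doubling
oracle_psd_acov <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  r <- sapply(0:(n - 1), function(k)
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n)
  half <- floor(n / 2) + 1
  s2 <- sapply(seq_len(half) - 1, function(j)
    (r[1] + 2 * sum(r[-1] * cos(2 * pi * j * seq_len(n - 1) / n))) / n)
  s2 <- pmax(s2, 0)
  dbl <- seq(2, half)
  if (n %% 2 == 0) dbl <- dbl[-length(dbl)]
  s2[dbl] <- 2 * s2[dbl]
  s2
}

# neighborhood-scan relative extrema: full O(L^2) pairwise comparison,
# greedy left-to-right dedupe, top-n by ordinate
oracle_relative_extrema <- function(absc, ord, n, eps, mode = "max") {
  L <- length(ord)
  is_ext <- logical(L)
  for (i in seq_len(L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (abs(absc[j] - absc[i]) <= eps + eps * 1e-9) {
        if (mode == "max" && ord[j] > ord[i]) ok <- FALSE
        if (mode == "min" && ord[j] < ord[i]) ok <- FALSE
      }
    }
    is_ext[i] <- ok
  }
  kept <- integer(0)
  for (i in which(is_ext)) {
    if (!length(kept) || absc[i] - absc[kept[length(kept)]] > eps + eps * 1e-9)
      kept <- c(kept, i)
  }
  o <- if (mode == "max") order(-ord[kept], absc[kept]) else
    order(ord[kept], absc[kept])
  kept <- kept[o]
  pos <- rep(NA_real_, n); val <- rep(NA_real_, n)
  take <- seq_len(min(n, length(kept)))
  pos[take] <- absc[kept[take]]
  val[take] <- ord[kept[take]]
  list(position = pos, value = val, found = length(kept))
}

# direct moving-window scan; population SD; first flagging window kept
oracle_moving_window <- function(x, k, n, cmult) {
  N <- length(x)
  first_rise <- rep(NA_integer_, N)
  first_drop <- rep(NA_integer_, N)
  for (w in seq_len(N - k + 1)) {
    win <- x[w:(w + k - 1)]
    if (anyNA(win)) next
    m <- mean(win)
    s <- sqrt(mean((win - m)^2))
    for (j in seq_len(k)) {
      i <- w + j - 1
      if (win[j] > m + cmult * s && is.na(first_rise[i])) first_rise[i] <- w
      if (win[j] < m - cmult * s && is.na(first_drop[i])) first_drop[i] <- w
    }
  }
  rank_dir <- function(first, decreasing) {
    idx <- which(!is.na(first))
    idx <- idx[order(if (decreasing) -x[idx] else x[idx], idx)]
    pos <- rep(NA_integer_, n); val <- rep(NA_real_, n)
    take <- seq_len(min(n, length(idx)))
    pos[take] <- idx[take]; val[take] <- x[idx[take]]
    list(index = pos, value = val, count = length(idx))
  }
  list(rise = rank_dir(first_rise, TRUE), drop = rank_dir(first_drop, FALSE))
}

make_regular_cohort <- function(values_by_patient, vital = "sao2",
                                labels = NULL, period = 300) {
  n <- length(values_by_patient)
  if (is.null(labels)) labels <- rep_len(c(0, 1), n)
  pats <- lapply(seq_len(n), function(i)
    patient_record(sprintf("P%03d", i), labels[i],
                   setNames(list(vital_series(vital, values_by_patient[[i]],
                                              period = period)), vital)))
  cohort(pats, vital)
}
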