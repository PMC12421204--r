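# Frequency / lag / scale decompositions of vital-sign series.

new_spectrum <- function(transform, abscissa, ordinate, vital = NA_character_,
                         period = NA_real_) {
  structure(list(transform = transform, abscissa = abscissa,
                 ordinate = ordinate, vital = vital, period = period),
            class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat(sprintf("<frequency_spectrum> %s, %d bins, abscissa [%g, %g]\n",
              x$transform, length(x$ordinate), min(x$abscissa), max(x$abscissa)))
  invisible(x)
}

series_values_checked <- function(series, op) {
  v <- if (inherits(series, "vital_series")) series$values else as.numeric(series)
  if (length(v) < 2L)
    stop(op, ": series must have at least 2 samples", call. = FALSE)
  if (anyNA(v))
    stop(op, ": series contains missing values; impute upstream (see impute_series)",
         call. = FALSE)
  v
}

#' One-sided FFT magnitude spectrum
#'
#' Removes the series mean (the DC term otherwise dominates every band
#' feature) and returns the one-sided magnitude spectrum
#' `|sum_t v_t exp(-i 2 pi k t / N)|` for `k = 0 .. floor(N/2)`, with the
#' abscissa in cycles per sample.
#'
#' @param series A fully observed `vital_series` (or numeric vector).
#' @return A `frequency_spectrum` with `transform = "fft"`.
#' @export
fft_spectrum <- function(series) {
  v <- series_values_checked(series, "fft_spectrum")
  n <- length(v)
  x <- v - mean(v)
  half <- floor(n / 2) + 1L
  mag <- Mod(fft(x))[seq_len(half)]
  new_spectrum("fft", (seq_len(half) - 1) / n, mag,
               vital = if (inherits(series, "vital_series")) series$vital else NA_character_,
               period = if (inherits(series, "vital_series")) series$period else NA_real_)
}

#' One-sided power spectral density
#'
#' Periodogram of the mean-removed series, normalized so that the total
#' (two-sided) power equals the biased sample variance `sum (v - mean)^2 / N`:
#' the two-sided ordinate is `|X_k|^2 / N^2`, which is exactly the discrete
#' transform of the biased autocovariance sequence `r(k)` divided by `N`. The
#' returned one-sided spectrum doubles the interior bins so that
#' `sum(ordinate)` is again the biased variance.
#'
#' @inheritParams fft_spectrum
#' @return A `frequency_spectrum` with `transform = "psd"`; non-negative
#'   ordinates.
#' @export
psd_spectrum <- function(series) {
  v <- series_values_checked(series, "psd_spectrum")
  n <- length(v)
  x <- v - mean(v)
  p2 <- Mod(fft(x))^2 / n^2            # two-sided, sums to biased variance
  half <- floor(n / 2) + 1L
  p1 <- p2[seq_len(half)]
  dbl <- seq(2L, half)                  # interior bins appear twice two-sided
  if (n %% 2L == 0L) dbl <- dbl[-length(dbl)]   # even N: Nyquist is unique
  p1[dbl] <- 2 * p1[dbl]
  new_spectrum("psd", (seq_len(half) - 1) / n, p1,
               vital = if (inherits(series, "vital_series")) series$vital else NA_character_,
               period = if (inherits(series, "vital_series")) series$period else NA_real_)
}

#' Normalized autocorrelation sequence
#'
#' Biased (divide-by-N) autocovariance normalized so that `r(0) = 1`,
#' computed for lags `0 .. max_lag`. Small coefficients indicate a
#' fluctuating trace, large ones a stable one.
#'
#' @inheritParams fft_spectrum
#' @param max_lag Largest lag in samples (`1 <= max_lag < N`).
#' @return A `frequency_spectrum` with `transform = "ac"`, abscissa in lag
#'   samples, ordinates in `[-1, 1]`.
#' @export
autocorrelation <- function(series, max_lag = 40) {
  v <- series_values_checked(series, "autocorrelation")
  n <- length(v)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= n)
    stop("`max_lag` must satisfy 1 <= max_lag < N", call. = FALSE)
  if (var(v) == 0)
    stop("degenerate series: autocorrelation undefined for zero variance",
         call. = FALSE)
  r <- drop(acf(v, lag.max = max_lag, type = "correlation",
                plot = FALSE, demean = TRUE)$acf)
  new_spectrum("ac", 0:max_lag, r,
               vital = if (inherits(series, "vital_series")) series$vital else NA_character_,
               period = if (inherits(series, "vital_series")) series$period else NA_real_)
}

#' Describe a continuous wavelet transform
#'
#' @param family `"morl"` (real Morlet, `cos(5t) exp(-t^2/2)`), `"cmor"`
#'   (complex Morlet with bandwidth `B` and center frequency `C`,
#'   `(pi B)^{-1/2} exp(i 2 pi C t) exp(-t^2/B)`), or `"mexh"` (Mexican hat,
#'   `(2 / (sqrt(3) pi^{1/4})) (1 - t^2) exp(-t^2/2)`).
#' @param scales Strictly increasing positive scales `a`, in samples. Default:
#'   32 logarithmically spaced scales in `[1, 64]`, spanning 5-minute to
#'   several-hour rhythms at a 300 s cadence.
#' @param center,bandwidth Complex Morlet parameters (used for `"cmor"` only).
#' @return An object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(family = c("morl", "cmor", "mexh"),
                         scales = default_scales(),
                         center = 1.0, bandwidth = 1.5) {
  family <- match.arg(family)
  scales <- as.numeric(scales)
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be strictly increasing and positive", call. = FALSE)
  structure(list(family = family, scales = scales, center = center,
                 bandwidth = bandwidth),
            class = "wavelet_spec")
}

#' Default scale grid for wavelet scalograms
#'
#' @param n_scales Number of scales.
#' @param range Scale range in samples.
#' @return Numeric vector of logarithmically spaced scales.
#' @export
default_scales <- function(n_scales = 32, range = c(1, 64)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n_scales))
}

# sampled, scaled, conjugated mother wavelet for one scale (kernel over
# integer offsets -L..L, zero-extension boundary handled by the caller)
wavelet_kernel <- function(spec, a) {
  L <- switch(spec$family,
    morl = ceiling(6 * a),
    mexh = ceiling(6 * a),
    cmor = ceiling(a * sqrt(18 * spec$bandwidth))
  )
  u <- (-L):L
  t <- u / a
  psi <- switch(spec$family,
    morl = cos(5 * t) * exp(-t^2 / 2),
    mexh = (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2),
    cmor = (pi * spec$bandwidth)^-0.5 *
      exp(complex(real = -t^2 / spec$bandwidth, imaginary = 2 * pi * spec$center * t))
  )
  Conj(psi) / sqrt(a)
}

# full linear convolution of columns of (possibly complex) matrix x with a
# (possibly complex) kernel, via zero-padded FFT; returns rows L+1 .. L+N,
# i.e. cross-correlation of the signal with the reversed kernel aligned to
# the signal grid (zero extension outside the observed window)
conv_rows <- function(xmat, kern) {
  n <- nrow(xmat)
  lk <- length(kern)
  L <- (lk - 1L) / 2L
  m <- nextn(n + lk - 1L, c(2, 3, 5))
  fx <- mvfft(rbind(xmat, matrix(0, m - n, ncol(xmat))))
  fk <- fft(c(rev(kern), rep(0+0i, m - lk)))
  full <- mvfft(fx * fk, inverse = TRUE) / m
  full[(L + 1L):(L + n), , drop = FALSE]
}

#' Continuous wavelet scalogram
#'
#' Computes `|W(a, b)| = | (1/sqrt(a)) sum_t v_t conj(psi((t - b)/a)) |` for
#' every scale `a` in the spec and every sample position `b`, with zero
#' extension beyond the series boundaries. Complex families are reduced to
#' their modulus, so the scalogram is always a non-negative scales-by-time
#' matrix.
#'
#' @inheritParams fft_spectrum
#' @param spec A [wavelet_spec()].
#' @return An object of class `scalogram`: list with the `spec`, `times`
#'   (0-based sample indices) and the `magnitudes` matrix (scales x time).
#' @export
wavelet_scalogram <- function(series, spec = wavelet_spec()) {
  if (!inherits(spec, "wavelet_spec"))
    stop("`spec` must be a wavelet_spec", call. = FALSE)
  v <- series_values_checked(series, "wavelet_scalogram")
  n <- length(v)
  xmat <- matrix(v, ncol = 1)
  mags <- matrix(0, length(spec$scales), n)
  for (si in seq_along(spec$scales)) {
    kern <- wavelet_kernel(spec, spec$scales[si])
    mags[si, ] <- Mod(conv_rows(xmat, kern))
  }
  structure(list(spec = spec, times = 0:(n - 1), magnitudes = mags,
                 vital = if (inherits(series, "vital_series")) series$vital else NA_character_,
                 period = if (inherits(series, "vital_series")) series$period else NA_real_),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %s, %d scales x %d samples, |W| in [%g, %g]\n",
              x$spec$family, nrow(x$magnitudes), ncol(x$magnitudes),
              min(x$magnitudes), max(x$magnitudes)))
  invisible(x)
}

#' Extract one scale row of a scalogram as a spectrum
#'
#' The row's abscissa is the (0-based) sample position `b`, so band features
#' on a scalogram row resolve *when* power at that scale occurred; band 1 is
#' the earliest segment.
#'
#' @param x A `scalogram`.
#' @param row Scale row index.
#' @return A `frequency_spectrum` with `transform = "wt"`.
#' @export
scalogram_row <- function(x, row) {
  if (row < 1 || row > nrow(x$magnitudes)) stop("invalid scale row", call. = FALSE)
  new_spectrum("wt", x$times, x$magnitudes[row, ], vital = x$vital,
               period = x$period)
}

#' Dump a spectrum to delimited text
#'
#' Two-column (abscissa, ordinate) CSV for inspection.
#'
#' @param x A `frequency_spectrum`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  data.table::fwrite(data.frame(abscissa = x$abscissa, ordinate = x$ordinate),
                     path)
  invisible(x)
}
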