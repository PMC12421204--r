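# Reading, validating, windowing and regularizing vital-sign traces.

#' Construct a regularly sampled vital-sign series
#'
#' A `vital_series` holds one vital-sign trace for one ICU stay on a strictly
#' regular time grid: sample `i` (0-based) sits at `t0 + i * period` seconds
#' after ICU admission. Missing grid points are `NA`.
#'
#' @param vital One of `"sao2"`, `"heartrate"`, `"respiration"`, `"st1"`,
#'   `"st2"`, `"st3"`.
#' @param values Numeric vector of measurements (may contain `NA`).
#' @param t0 Time of the first grid point, seconds since admission.
#' @param period Grid spacing in seconds (> 0). Default 300 s, the cadence of
#'   eICU-style periodic vital extracts.
#' @return An object of class `vital_series`.
#' @export
vital_series <- function(vital, values, t0 = 0, period = 300) {
  vital <- match.arg(vital, VITALS)
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("`period` must be a single positive number of seconds", call. = FALSE)
  if (t0 < 0) stop("`t0` must be non-negative", call. = FALSE)
  structure(
    list(vital = vital, t0 = as.numeric(t0), period = as.numeric(period),
         values = as.numeric(values)),
    class = "vital_series"
  )
}

#' @export
print.vital_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<vital_series> %s: %d samples @ %gs (t0=%gs), %d missing\n",
              x$vital, n, x$period, x$t0, sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.vital_series <- function(x) length(x$values)

# sample times in seconds since admission
series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1L) * series$period
}

#' Construct a patient record
#'
#' @param patient_id Opaque identifier (coerced to character).
#' @param label Discharge status: 1 = expired, 0 = alive.
#' @param series Named list of `vital_series` (at most one per vital) or of
#'   raw sample data frames with columns `t`, `value`.
#' @param static Optional named list of static covariates (age, sex, ...).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, label, series = list(), static = NULL) {
  if (!label %in% c(0, 1))
    stop("`label` must be 0 (alive) or 1 (expired)", call. = FALSE)
  nm <- names(series)
  if (length(series) && (is.null(nm) || anyDuplicated(nm)))
    stop("`series` must be uniquely named by vital", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id), label = as.integer(label),
         series = series, static = static),
    class = "patient_record"
  )
}

#' Construct a cohort
#'
#' An ordered collection of [patient_record()]s with the list of vitals in
#' play. Patient ids must be unique.
#'
#' @param patients List of `patient_record` objects.
#' @param vitals_used Character vector, subset of the six supported vitals.
#' @return An object of class `cohort`.
#' @export
cohort <- function(patients, vitals_used = VITALS) {
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient ids in cohort", call. = FALSE)
  vitals_used <- VITALS[VITALS %in% vitals_used]
  names(patients) <- ids
  structure(list(patients = patients, vitals_used = vitals_used),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  labs <- cohort_labels(x)
  cat(sprintf("<cohort> %d patients (%d expired, %.2f%%), vitals: %s\n",
              length(x$patients), sum(labs),
              if (length(labs)) 100 * mean(labs) else 0,
              paste(x$vitals_used, collapse = ", ")))
  invisible(x)
}

#' Extract the outcome labels of a cohort
#'
#' @param x A `cohort`.
#' @return Named integer vector (1 = expired, 0 = alive), one per patient.
#' @export
cohort_labels <- function(x) {
  vapply(x$patients, function(p) p$label, integer(1))
}

#' Load a cohort from long-format delimited text
#'
#' Reads a long-format table with one row per (patient, vital, time) sample
#' plus a separate label table, and groups the samples into a [cohort()].
#' Duplicate (patient, vital, t) rows keep the last occurrence; the number of
#' dropped rows is reported. Rows with unknown vital names are skipped with a
#' warning.
#'
#' @param path Path to the sample table (CSV/TSV; delimiter sniffed by
#'   `data.table::fread`).
#' @param labels_path Path to the label table with columns for patient id and
#'   label (0/1).
#' @param schema Named character vector remapping the expected column names
#'   `patient_id`, `vital`, `offset_seconds`, `value`, `label` to the names
#'   used in the files.
#' @return A `cohort` whose per-patient series are raw sample data frames
#'   (columns `t`, `value`, sorted by `t`); use [window_first_24h()] and
#'   [regularize()] to put them on a grid.
#' @export
load_cohort <- function(path, labels_path,
                        schema = c(patient_id = "patient_id", vital = "vital",
                                   offset_seconds = "offset_seconds",
                                   value = "value", label = "label")) {
  def <- c(patient_id = "patient_id", vital = "vital",
           offset_seconds = "offset_seconds", value = "value", label = "label")
  def[names(schema)] <- schema
  schema <- def

  dt <- data.table::fread(path, showProgress = FALSE)
  need <- schema[c("patient_id", "vital", "offset_seconds", "value")]
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("sample table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data.table::setnames(dt, unname(need),
                       c("patient_id", "vital", "offset_seconds", "value"))

  lab <- data.table::fread(labels_path, showProgress = FALSE)
  lneed <- schema[c("patient_id", "label")]
  lmiss <- setdiff(lneed, names(lab))
  if (length(lmiss))
    stop("label table is missing required column(s): ",
         paste(lmiss, collapse = ", "), call. = FALSE)
  data.table::setnames(lab, unname(lneed), c("patient_id", "label"))
  if (anyDuplicated(lab$patient_id))
    stop("label table has duplicated patient ids", call. = FALSE)
  if (nrow(lab) && !all(lab$label %in% c(0, 1)))
    stop("labels must be 0 (alive) or 1 (expired)", call. = FALSE)

  if (nrow(dt)) {
    unknown <- !(dt$vital %in% VITALS)
    if (any(unknown)) {
      warning(sprintf("skipping %d rows with unknown vital name(s): %s",
                      sum(unknown),
                      paste(unique(dt$vital[unknown]), collapse = ", ")),
              call. = FALSE)
      dt <- dt[!unknown, ]
    }
    data.table::setorder(dt, patient_id, vital, offset_seconds)
    ndup <- nrow(dt)
    dt <- unique(dt, by = c("patient_id", "vital", "offset_seconds"),
                 fromLast = TRUE)
    ndup <- ndup - nrow(dt)
    if (ndup > 0)
      message(sprintf("dropped %d duplicated (patient, vital, t) rows (kept last)",
                      ndup))
    data.table::setorder(dt, patient_id, vital, offset_seconds)
  }

  ids <- as.character(lab$patient_id)
  patient_id <- NULL # NSE guard
  patients <- lapply(seq_along(ids), function(i) {
    pid <- ids[i]
    sub <- if (nrow(dt)) dt[dt$patient_id == pid, ] else dt
    ser <- list()
    if (nrow(sub)) {
      for (v in unique(sub$vital)) {
        sv <- sub[sub$vital == v, ]
        ser[[v]] <- data.frame(t = as.numeric(sv$offset_seconds),
                               value = as.numeric(sv$value))
      }
    }
    patient_record(pid, lab$label[i], ser)
  })
  cohort(patients, vitals_used = if (nrow(dt)) unique(dt$vital) else VITALS)
}

#' Write a cohort to long-format delimited text
#'
#' Inverse of [load_cohort()]: emits one row per non-missing sample plus a
#' label table. Regular series are written with their grid times.
#'
#' @param x A `cohort`.
#' @param path,labels_path Output file paths (CSV).
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, path, labels_path) {
  rows <- list()
  for (p in x$patients) {
    for (v in names(p$series)) {
      s <- p$series[[v]]
      if (inherits(s, "vital_series")) {
        keep <- !is.na(s$values)
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p$patient_id, vital = v,
          offset_seconds = series_times(s)[keep], value = s$values[keep])
      } else {
        keep <- !is.na(s$value)
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p$patient_id, vital = v,
          offset_seconds = s$t[keep], value = s$value[keep])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), vital = character(),
               offset_seconds = numeric(), value = numeric())
  data.table::fwrite(out, path)
  labs <- data.frame(patient_id = names(x$patients),
                     label = unname(cohort_labels(x)))
  data.table::fwrite(labs, labels_path)
  invisible(x)
}

#' Restrict a trace to the first 24 hours of the ICU stay
#'
#' Keeps samples with `t` in the half-open window `[0, 86400)` seconds.
#' Idempotent. Errors when nothing survives the window.
#'
#' @param x A `vital_series` or a raw sample data frame (columns `t`,
#'   `value`).
#' @param window_s Window length in seconds (default 24 h).
#' @return Object of the same kind, restricted to the window.
#' @export
window_first_24h <- function(x, window_s = 86400) {
  if (inherits(x, "vital_series")) {
    keep <- series_times(x) < window_s
    if (!any(keep))
      stop("empty series: no samples in the first-24h window", call. = FALSE)
    vital_series(x$vital, x$values[keep], t0 = x$t0, period = x$period)
  } else {
    keep <- x$t >= 0 & x$t < window_s
    if (!any(keep))
      stop("empty series: no samples in the first-24h window", call. = FALSE)
    x[keep, , drop = FALSE]
  }
}

#' Snap irregular samples onto a regular grid
#'
#' Snaps each sample to the nearest grid point `i * period` (grid anchored at
#' admission, 0-based), keeping the last sample when several snap to the same
#' point. Internal gaps between consecutive observed grid points are filled by
#' linear interpolation when the gap between the bracketing observations is at
#' most `max_gap` seconds; longer gaps, and leading/trailing stretches, stay
#' missing. Interpolated values therefore never leave the convex hull of the
#' two bracketing observations.
#'
#' @param samples Data frame with columns `t` (seconds, sorted) and `value`.
#' @param vital Vital name for the resulting series.
#' @param period Grid spacing in seconds (> 0).
#' @param max_gap Largest gap (seconds) bridged by interpolation. Default
#'   1800 s (30 min).
#' @param n Optional fixed grid length; when given the grid is
#'   `0, period, ..., (n-1) * period` regardless of where samples fall,
#'   otherwise the grid ends at the last observed sample.
#' @return A [vital_series()].
#' @export
regularize <- function(samples, vital, period = 300, max_gap = 1800, n = NULL) {
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("`period` must be a single positive number of seconds", call. = FALSE)
  t <- samples$t
  v <- samples$value
  ok <- !is.na(v)
  t <- t[ok]; v <- v[ok]
  if (!length(t)) {
    if (is.null(n)) stop("no observed samples to regularize", call. = FALSE)
    return(vital_series(vital, rep(NA_real_, n), t0 = 0, period = period))
  }
  idx <- as.integer(round(t / period))         # nearest grid point, 0-based
  if (is.null(n)) n <- max(idx) + 1L
  grid <- rep(NA_real_, n)
  keep <- idx >= 0L & idx < n
  grid[idx[keep] + 1L] <- v[keep]              # later samples overwrite earlier

  obs <- which(!is.na(grid))
  if (length(obs) >= 2L) {
    for (j in seq_len(length(obs) - 1L)) {
      a <- obs[j]; b <- obs[j + 1L]
      if (b - a > 1L && (b - a) * period <= max_gap) {
        ii <- (a + 1L):(b - 1L)
        grid[ii] <- grid[a] + (grid[b] - grid[a]) * (ii - a) / (b - a)
      }
    }
  }
  vital_series(vital, grid, t0 = 0, period = period)
}

#' Fill missing values of a regular series for transform input
#'
#' Linear interpolation across internal gaps and edge hold (first/last
#' observed value) at the boundaries. Spectral transforms require a fully
#' observed series; this is the canonical upstream imputation.
#'
#' @param series A `vital_series`.
#' @return A `vital_series` with no missing values.
#' @export
impute_series <- function(series) {
  v <- series$values
  if (!anyNA(v)) return(series)
  obs <- which(!is.na(v))
  if (!length(obs))
    stop("cannot impute an all-missing series", call. = FALSE)
  if (length(obs) == 1L) {
    v[] <- v[obs]
  } else {
    v <- approx(obs, v[obs], xout = seq_along(v), rule = 2)$y
  }
  vital_series(series$vital, v, t0 = series$t0, period = series$period)
}

#' Select vitals with sufficient patient coverage
#'
#' Returns, in canonical order, the vitals for which the fraction of patients
#' with a non-empty series (at least one non-missing sample) strictly exceeds
#' `threshold` -- the ">50% of patients" inclusion rule.
#'
#' @param x A `cohort`.
#' @param threshold Coverage fraction in (0, 1]; default 0.5.
#' @return Character vector of retained vitals.
#' @export
coverage_filter <- function(x, threshold = 0.5) {
  if (!length(x$patients)) stop("empty cohort", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  n <- length(x$patients)
  frac <- vapply(VITALS, function(v) {
    has <- vapply(x$patients, function(p) {
      s <- p$series[[v]]
      if (is.null(s)) return(FALSE)
      vals <- if (inherits(s, "vital_series")) s$values else s$value
      any(!is.na(vals))
    }, logical(1))
    mean(has)
  }, numeric(1))
  VITALS[frac > threshold]
}

#' Window and regularize every series of a cohort
#'
#' Applies [window_first_24h()] and [regularize()] to every patient/vital
#' trace, dropping (with a summary warning) vitals whose window is empty for a
#' patient. Raw sample series and already-regular series are both accepted.
#'
#' @param x A `cohort`.
#' @inheritParams regularize
#' @param window_s First-24h window length in seconds.
#' @return A `cohort` whose series are all `vital_series` of identical length
#'   `window_s / period`.
#' @export
prepare_cohort <- function(x, period = 300, max_gap = 1800, window_s = 86400) {
  n_grid <- as.integer(floor(window_s / period))
  dropped <- 0L
  patients <- lapply(x$patients, function(p) {
    ser <- list()
    for (v in names(p$series)) {
      s <- p$series[[v]]
      res <- tryCatch({
        if (inherits(s, "vital_series")) {
          s <- window_first_24h(s, window_s)
          if (abs(s$period - period) > 1e-9 || s$t0 != 0 ||
              length(s$values) != n_grid) {
            df <- data.frame(t = series_times(s), value = s$values)
            s <- regularize(df, v, period, max_gap, n = n_grid)
          }
          s
        } else {
          s <- window_first_24h(s, window_s)
          regularize(s, v, period, max_gap, n = n_grid)
        }
      }, error = function(e) NULL)
      if (is.null(res)) dropped <<- dropped + 1L else ser[[v]] <- res
    }
    patient_record(p$patient_id, p$label, ser, p$static)
  })
  if (dropped > 0L)
    warning(sprintf("dropped %d patient-vital traces with no samples in the window",
                    dropped), call. = FALSE)
  cohort(patients, x$vitals_used)
}
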