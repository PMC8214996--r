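#' Region-of-interest window
#'
#' The time window retained for analysis. The default 0.27-0.6 ms window is
#' where staged photoacoustic traces show their largest between-group
#' variation.
#'
#' @param start,end Window bounds in seconds, `0 <= start < end`.
#' @return A list of class `roi_window`.
#' @export
roi_window <- function(start = 0.27e-3, end = 0.6e-3) {
  if (!(start >= 0 && start < end)) {
    abort("`roi_window` requires 0 <= start < end.")
  }
  structure(list(start = start, end = end), class = "roi_window")
}

# Least-squares polynomial baseline over sample index; order 0 = mean.
fit_baseline <- function(x, order) {
  n <- length(x)
  if (order >= n) abort("Baseline polynomial order must be below the signal length.")
  if (order == 0L) return(rep(mean(x), n))
  idx <- seq_len(n)
  unname(stats::fitted(stats::lm(x ~ stats::poly(idx, degree = order))))
}

map_samples <- function(spectra, f) {
  spectra$samples <- lapply(spectra$samples, f)
  spectra
}

#' Pre-processing stages for photoacoustic spectra
#'
#' Tibble-in/tibble-out verbs for the four pre-processing steps and ROI
#' selection. All operate on the `samples` list column and preserve every
#' metadata column.
#'
#' * `pa_detrend()` subtracts the least-squares straight line over sample
#'   index.
#' * `pa_correct_baseline()` subtracts a least-squares polynomial baseline of
#'   the given order (order 0 removes the mean).
#' * `pa_subtract_background()` subtracts a background trace elementwise; the
#'   background must match each spectrum's length and sampling rate.
#' * `pa_normalize()` divides by the maximum absolute amplitude, so
#'   `max(abs(samples)) == 1`; idempotent; errors on an all-zero trace.
#' * `pa_extract_roi()` keeps samples with 0-based index in
#'   `[round(start * rate), round(end * rate))` — a half-open window with
#'   boundaries rounded half away from zero — and updates `start_time`.
#'
#' @param spectra A spectra tibble (see [generate_spectra()]).
#' @param order Baseline polynomial order (non-negative integer).
#' @param background Numeric vector, or one-row spectra tibble, to subtract.
#' @param roi A [roi_window()].
#' @return The spectra tibble with transformed `samples`.
#' @name preprocess_stages
NULL

#' @rdname preprocess_stages
#' @export
pa_detrend <- function(spectra) {
  assert_spectra(spectra)
  map_samples(spectra, function(x) {
    if (length(x) < 2L) abort("Detrending needs at least 2 samples.")
    idx <- seq_along(x)
    fit <- stats::lm.fit(cbind(1, idx), x)
    x - fit$fitted.values
  })
}

#' @rdname preprocess_stages
#' @export
pa_correct_baseline <- function(spectra, order = 2L) {
  assert_spectra(spectra)
  if (order < 0L) abort("`order` must be non-negative.")
  map_samples(spectra, function(x) x - fit_baseline(x, as.integer(order)))
}

#' @rdname preprocess_stages
#' @export
pa_subtract_background <- function(spectra, background) {
  assert_spectra(spectra)
  if (is.data.frame(background)) {
    assert_spectra(background, "background")
    if (nrow(background) != 1L) abort("`background` must be a single trace.")
    if (any(spectra$sampling_rate != background$sampling_rate)) {
      abort("Background sampling rate does not match the spectra.")
    }
    background <- background$samples[[1]]
  }
  map_samples(spectra, function(x) {
    if (length(x) != length(background)) {
      abort("Background length does not match the spectra.")
    }
    x - background
  })
}

#' @rdname preprocess_stages
#' @export
pa_normalize <- function(spectra) {
  assert_spectra(spectra)
  map_samples(spectra, function(x) {
    m <- max(abs(x))
    if (m == 0) abort("Cannot normalize an all-zero spectrum.")
    x / m
  })
}

#' @rdname preprocess_stages
#' @export
pa_extract_roi <- function(spectra, roi = roi_window()) {
  assert_spectra(spectra)
  if (!inherits(roi, "roi_window")) abort("`roi` must be a `roi_window`.")
  n_out <- integer(nrow(spectra))
  for (i in seq_len(nrow(spectra))) {
    x <- spectra$samples[[i]]
    rate <- spectra$sampling_rate[i]
    record_end <- spectra$start_time[i] + length(x) / rate
    if (roi$start < spectra$start_time[i] - 1e-12 || roi$end > record_end + 1e-12) {
      abort("ROI window falls outside the recorded span.")
    }
    i0 <- round_half_away((roi$start - spectra$start_time[i]) * rate)
    i1 <- round_half_away((roi$end - spectra$start_time[i]) * rate)
    if (i1 <= i0) abort("ROI window is empty at this sampling rate.")
    spectra$samples[[i]] <- x[(i0 + 1):i1]
  }
  spectra$start_time <- roi$start
  spectra
}

#' Run the full pre-processing chain
#'
#' Applies detrend -> baseline correction -> (optional) background
#' subtraction -> normalization -> ROI extraction, in that fixed order, to
#' every spectrum. Stages can be switched off individually; the order never
#' changes. Normalization runs before ROI selection so the window inherits
#' the full-record amplitude scale.
#'
#' @inheritParams preprocess_stages
#' @param detrend,normalize Logical switches for the respective stages.
#' @param baseline_order Baseline polynomial order, or `NULL` to skip.
#' @param background Optional background trace (`NULL` skips the stage).
#' @return The pre-processed spectra tibble.
#' @examples
#' spectra <- generate_spectra(
#'   study_design(n_tissues = 1, n_positions = 1, n_replicates = 1),
#'   class_templates(), seed = 1
#' )
#' roi <- pa_preprocess(spectra)
#' lengths(roi$samples) # all 858
#' @export
pa_preprocess <- function(spectra,
                          roi = roi_window(),
                          detrend = TRUE,
                          baseline_order = 2L,
                          background = NULL,
                          normalize = TRUE) {
  assert_spectra(spectra)
  if (detrend) spectra <- pa_detrend(spectra)
  if (!is.null(baseline_order)) {
    spectra <- pa_correct_baseline(spectra, baseline_order)
  }
  if (!is.null(background)) spectra <- pa_subtract_background(spectra, background)
  if (normalize) spectra <- pa_normalize(spectra)
  pa_extract_roi(spectra, roi)
}
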