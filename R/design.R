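#' Study design for an ex vivo photoacoustic staging experiment
#'
#' Describes the acquisition layout: how many time-point groups are recorded,
#' how many tissues per group, positions per tissue and replicate traces per
#' position, together with the digitizer settings. The defaults reproduce a
#' five-group design (control day 0 plus days 5/10/15/20 after tumor
#' induction) with 5 tissues x 4 positions x 5 replicates, i.e. 100 traces
#' per group and 500 in total, sampled at 2.6 MHz for 2 ms (5200 samples).
#'
#' @param group_labels Ordered character vector of group (time-point) labels.
#' @param n_tissues Number of tissues sampled per group.
#' @param n_positions Number of probe positions per tissue.
#' @param n_replicates Number of replicate traces per position.
#' @param sampling_rate Digitizer sampling frequency in Hz.
#' @param record_duration Record length in seconds.
#'
#' @return A list of class `study_design`.
#' @examples
#' design <- study_design()
#' design$n_spectra # 500
#' @export
study_design <- function(group_labels = c("day0", "day5", "day10", "day15", "day20"),
                         n_tissues = 5L,
                         n_positions = 4L,
                         n_replicates = 5L,
                         sampling_rate = 2.6e6,
                         record_duration = 2e-3) {
  if (length(group_labels) < 1L || anyDuplicated(group_labels) > 0L) {
    abort("`group_labels` must be a non-empty vector of unique labels.")
  }
  counts <- c(n_tissues = n_tissues, n_positions = n_positions, n_replicates = n_replicates)
  if (any(counts < 1L) || any(counts != as.integer(counts))) {
    abort("Tissue/position/replicate counts must be positive integers.")
  }
  if (sampling_rate <= 0 || record_duration <= 0) {
    abort("`sampling_rate` and `record_duration` must be positive.")
  }
  n_samples <- sampling_rate * record_duration
  if (abs(n_samples - round(n_samples)) > 1e-6) {
    abort("`sampling_rate` x `record_duration` must be a whole number of samples.")
  }
  design <- list(
    group_labels = as.character(group_labels),
    n_groups = length(group_labels),
    n_tissues = as.integer(n_tissues),
    n_positions = as.integer(n_positions),
    n_replicates = as.integer(n_replicates),
    sampling_rate = sampling_rate,
    record_duration = record_duration,
    n_samples = as.integer(round(n_samples))
  )
  design$n_spectra <- design$n_groups * design$n_tissues *
    design$n_positions * design$n_replicates
  structure(design, class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat("  groups:    ", paste(x$group_labels, collapse = ", "), "\n")
  cat(sprintf(
    "  layout:     %d tissues x %d positions x %d replicates (%d spectra)\n",
    x$n_tissues, x$n_positions, x$n_replicates, x$n_spectra
  ))
  cat(sprintf(
    "  sampling:   %.3g Hz for %.3g s (%d samples)\n",
    x$sampling_rate, x$record_duration, x$n_samples
  ))
  invisible(x)
}

#' Per-group waveform templates for the synthetic generator
#'
#' Each group is modelled as a mixture of two to three damped sinusoidal
#' transients with a smooth quadratic onset ramp, riding on a slow polynomial
#' baseline plus white Gaussian noise. Groups differ in overall amplitude
#' (strictly increasing with day index, mimicking the stronger photoacoustic
#' response of advancing tumors) and, controlled by `shape_drift`, in
#' component frequency, onset and mixing weights. All component frequencies
#' sit well below a quarter of the 2.6 MHz sampling rate so that signal
#' energy concentrates in the level-2 approximation subband.
#'
#' @param labels Group labels, one template per label.
#' @param amplitudes Per-group amplitude scales (arbitrary units); must be
#'   strictly increasing.
#' @param shape_drift Multiplier on all per-group waveform-shape increments
#'   (frequency, onset and mixing-weight steps). `0` makes every group share
#'   one waveform shape so groups differ only in amplitude; `1` (default)
#'   gives the drift used throughout the package.
#' @param noise_sd Standard deviation of the additive white noise (a.u.).
#' @param drift_sd Standard deviation of each random baseline polynomial
#'   coefficient (a.u.).
#' @param tissue_effect_sd,position_effect_sd Standard deviations of the
#'   log-normal multiplicative random effects shared by all traces of one
#'   tissue / one position.
#' @param onset_jitter_sd Per-trace onset jitter standard deviation, seconds.
#'
#' @return A tibble of class `class_templates`, one row per group, with a
#'   `components` list column of per-component parameters (`freq` Hz,
#'   `damping` 1/s, `onset` s, `rel_amp`, `phase` rad).
#' @examples
#' tpl <- class_templates()
#' tpl$amplitude
#' @export
class_templates <- function(labels = c("day0", "day5", "day10", "day15", "day20"),
                            amplitudes = seq(1, 2.4, length.out = length(labels)),
                            shape_drift = 1,
                            noise_sd = 0.01,
                            drift_sd = 0.02,
                            tissue_effect_sd = 0.08,
                            position_effect_sd = 0.05,
                            onset_jitter_sd = 1e-6) {
  if (length(amplitudes) != length(labels)) {
    abort("`amplitudes` must have one entry per label.")
  }
  if (any(diff(amplitudes) <= 0)) {
    abort("`amplitudes` must be strictly increasing across groups.")
  }
  j <- seq_along(labels) - 1 # 0-based day index
  components <- lapply(j, function(i) {
    tibble(
      freq = c(8.0e4 + shape_drift * i * 1.5e4,
               1.3e5 + shape_drift * i * 8e3,
               4.5e4),
      damping = c(2.5e4, 4.0e4, 1.5e4),
      onset = c(3.0e-4 + shape_drift * i * 5e-6,
                3.8e-4 + shape_drift * i * 8e-6,
                4.5e-4),
      rel_amp = c(1, 0.5 + shape_drift * i * 0.08, 0.3),
      phase = c(0, pi / 3, pi / 7)
    )
  })
  out <- tibble(
    label = as.character(labels),
    amplitude = amplitudes,
    components = components,
    noise_sd = noise_sd,
    drift_sd = drift_sd,
    tissue_effect_sd = tissue_effect_sd,
    position_effect_sd = position_effect_sd,
    onset_jitter_sd = onset_jitter_sd
  )
  class(out) <- c("class_templates", class(out))
  out
}

#' Tumor volume from caliper measurements
#'
#' The standard ellipsoid approximation used in xenograft studies:
#' \eqn{V = \mathrm{width}^2 \times \mathrm{length} / 2}, in cubic
#' millimetres when inputs are in millimetres. Vectorized.
#'
#' @param width Tumor width in mm (non-negative).
#' @param length Tumor length in mm (non-negative).
#' @return Tumor volume in mm^3.
#' @examples
#' tumor_volume(10, 20) # 1000
#' @export
tumor_volume <- function(width, length) {
  if (any(width < 0, na.rm = TRUE) || any(length < 0, na.rm = TRUE)) {
    abort("`width` and `length` must be non-negative.")
  }
  width^2 * length / 2
}
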