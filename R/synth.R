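#' Generate a synthetic photoacoustic dataset
#'
#' Draws one time-domain trace per (group, tissue, position, replicate) cell
#' of the study design. Each trace is the group's template waveform — a
#' mixture of damped sinusoids with smooth onsets — multiplied by log-normal
#' tissue- and position-level random effects (shared by every trace nested
#' under that tissue/position), plus a slow random polynomial baseline and
#' white Gaussian noise. One master seed fans out deterministically into
#' per-tissue, per-position and per-trace substreams, so any subset of the
#' dataset is reproducible on its own.
#'
#' @param design A [study_design()].
#' @param templates A [class_templates()] tibble with one row per group label
#'   in `design`.
#' @param seed Integer master seed.
#'
#' @return A tibble with one row per trace: `id`, `label`, `tissue_id`,
#'   `position_id`, `replicate_id`, `provenance` (`"original"`),
#'   `scale_factor` (1), `origin_id` (= `id`), `sampling_rate`, `start_time`
#'   and a `samples` list column of numeric vectors.
#' @examples
#' spectra <- generate_spectra(
#'   study_design(n_tissues = 1, n_positions = 1, n_replicates = 1),
#'   class_templates(), seed = 1
#' )
#' nrow(spectra) # 5
#' @export
generate_spectra <- function(design, templates, seed) {
  if (!inherits(design, "study_design")) abort("`design` must be a `study_design`.")
  if (!inherits(templates, "class_templates")) {
    abort("`templates` must be a `class_templates` tibble.")
  }
  missing <- setdiff(design$group_labels, templates$label)
  if (length(missing) > 0L) {
    abort(sprintf(
      "No template for group label(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  seed <- as.integer(seed)
  nyquist_bound <- design$sampling_rate / 4
  t <- seq(0, by = 1 / design$sampling_rate, length.out = design$n_samples)

  grid <- expand.grid(
    replicate_id = seq_len(design$n_replicates),
    position_id = seq_len(design$n_positions),
    tissue_id = seq_len(design$n_tissues),
    label = design$group_labels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("label", "tissue_id", "position_id", "replicate_id")]
  grid$group_idx <- match(grid$label, design$group_labels)

  # Counter scheme: every (group, tissue, position, replicate) cell owns a
  # unique counter; tissue and position effects use counters of their own so
  # replicates nested under them share the same draw.
  per_group <- design$n_tissues * design$n_positions * design$n_replicates

  samples <- vector("list", nrow(grid))
  for (row in seq_len(nrow(grid))) {
    g <- grid$group_idx[row]
    tpl <- templates[templates$label == grid$label[row], ]
    comp <- tpl$components[[1]]
    if (any(comp$freq >= nyquist_bound)) {
      abort("Template component frequencies must stay below sampling_rate / 4.")
    }

    tissue_counter <- (g - 1L) * design$n_tissues + grid$tissue_id[row]
    pos_counter <- ((g - 1L) * design$n_tissues + grid$tissue_id[row] - 1L) *
      design$n_positions + grid$position_id[row]
    trace_counter <- (g - 1L) * per_group +
      (grid$tissue_id[row] - 1L) * design$n_positions * design$n_replicates +
      (grid$position_id[row] - 1L) * design$n_replicates +
      grid$replicate_id[row]

    tissue_effect <- local_rnorm(substream_seed(seed, 1L, tissue_counter), 1L)
    position_effect <- local_rnorm(substream_seed(seed, 2L, pos_counter), 1L)
    amp <- tpl$amplitude * exp(tpl$tissue_effect_sd * tissue_effect +
                                 tpl$position_effect_sd * position_effect)

    draws <- local_rnorm(
      substream_seed(seed, 3L, trace_counter),
      design$n_samples + 3L + nrow(comp)
    )
    noise <- draws[seq_len(design$n_samples)] * tpl$noise_sd
    drift_coef <- draws[design$n_samples + 1:3] * tpl$drift_sd
    jitter <- draws[design$n_samples + 3L + seq_len(nrow(comp))] * tpl$onset_jitter_sd

    u <- t / design$record_duration
    x <- drift_coef[1] + drift_coef[2] * u + drift_coef[3] * u^2 + noise
    for (k in seq_len(nrow(comp))) {
      x <- x + amp * comp$rel_amp[k] *
        damped_pulse(t, comp$freq[k], comp$damping[k],
                     comp$onset[k] + jitter[k], comp$phase[k])
    }
    samples[[row]] <- x
  }

  tibble(
    id = sprintf(
      "%s_t%d_p%d_r%d", grid$label, grid$tissue_id,
      grid$position_id, grid$replicate_id
    ),
    label = grid$label,
    tissue_id = grid$tissue_id,
    position_id = grid$position_id,
    replicate_id = grid$replicate_id,
    provenance = "original",
    scale_factor = 1,
    origin_id = sprintf(
      "%s_t%d_p%d_r%d", grid$label, grid$tissue_id,
      grid$position_id, grid$replicate_id
    ),
    sampling_rate = design$sampling_rate,
    start_time = 0,
    samples = samples
  )
}

# One damped sinusoidal transient with a C^1 quadratic onset ramp,
# (t-t0)^2 exp(-damping (t-t0)), normalized to unit peak envelope. The smooth
# rise keeps the transient's spectral tails far below the onset-step
# broadband leakage a hard gate would produce.
damped_pulse <- function(t, freq, damping, onset, phase) {
  u <- t - onset
  env <- numeric(length(t))
  pos <- u > 0
  peak <- (2 / damping)^2 * exp(-2)
  env[pos] <- u[pos]^2 * exp(-damping * u[pos]) / peak
  env * sin(2 * pi * freq * u + phase)
}

# Draw from an isolated RNG substream without disturbing the caller's RNG
# state (generate_spectra is a pure function of (design, templates, seed)).
local_rnorm <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  rnorm(n)
}
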