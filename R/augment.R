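#' Amplitude-rescaling augmentation plan
#'
#' The grid of scale factors used to expand the dataset. The default grid
#' 0.5, 1.0, ..., 4.5 (nine factors) gives a 10-fold expansion once originals
#' are kept alongside their rescaled variants. Note the printed grid contains
#' 1.0, whose rescaled copy equals its original up to provenance; the grid is
#' kept as-is for fidelity to the published augmentation scheme.
#'
#' @param factors Positive scale factors.
#' @return A list of class `augment_plan`.
#' @export
augment_plan <- function(factors = seq(0.5, 4.5, by = 0.5)) {
  if (length(factors) == 0L) abort("`factors` must be non-empty.")
  if (any(factors <= 0)) abort("All augmentation factors must be positive.")
  structure(list(factors = as.double(factors)), class = "augment_plan")
}

#' Rescale spectra by a fixed factor
#'
#' Multiplies every sample by `factor`, preserving the class label and
#' metadata. The result is marked `provenance = "augmented"` with the factor
#' recorded in `scale_factor`; `origin_id` keeps pointing at the source
#' trace. Rescaled traces are deliberately not re-normalized — re-normalizing
#' would cancel the scale and defeat the augmentation.
#'
#' @param spectra A spectra tibble.
#' @param factor A single positive scale factor.
#' @return The rescaled spectra tibble with new `id`s derived from the
#'   source ids.
#' @export
pa_rescale <- function(spectra, factor) {
  assert_spectra(spectra)
  if (length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    abort("`factor` must be a single positive number.")
  }
  spectra$samples <- lapply(spectra$samples, function(x) x * factor)
  spectra$origin_id <- spectra$id
  spectra$id <- sprintf("%s_x%g", spectra$id, factor)
  spectra$provenance <- "augmented"
  spectra$scale_factor <- factor
  spectra
}

#' Expand a dataset by amplitude rescaling
#'
#' Returns the original spectra together with one rescaled copy per plan
#' factor, so the output holds `n * (1 + length(factors))` rows (10-fold at
#' the default nine-factor grid). Labels are preserved, so per-class counts
#' scale uniformly.
#'
#' @param spectra A spectra tibble (typically pre-processed ROI traces).
#' @param plan An [augment_plan()].
#' @return The combined original + augmented spectra tibble.
#' @examples
#' spectra <- generate_spectra(
#'   study_design(n_tissues = 1, n_positions = 1, n_replicates = 1),
#'   class_templates(), seed = 1
#' )
#' nrow(pa_augment(spectra)) # 50 = 5 originals x 10
#' @export
pa_augment <- function(spectra, plan = augment_plan()) {
  assert_spectra(spectra)
  if (!inherits(plan, "augment_plan")) abort("`plan` must be an `augment_plan`.")
  augmented <- lapply(plan$factors, function(f) pa_rescale(spectra, f))
  out <- bind_rows(c(list(spectra), augmented))
  as_tibble(out)
}
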