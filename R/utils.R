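# Internal helpers shared across stages.

# Round half away from zero (base round() rounds half to even). Window
# boundaries use this so sample counts are stable across platforms.
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Deterministic fan-out of one master seed into per-stage / per-unit
# substreams. The scheme is a fixed affine hash modulo the largest 32-bit
# prime, so any (stream, index) pair maps to a reproducible seed that can be
# re-derived without replaying the whole run.
substream_seed <- function(master, stream, index = 0L) {
  master <- as.double(master) %% 2147483647
  (master * 48271 + stream * 1664525 + index * 22695477 + 12345) %% 2147483647
}

# The spectra container is an ordinary tibble; these checks keep stage
# functions honest about the columns they rely on.
spectra_cols <- c(
  "id", "label", "tissue_id", "position_id", "replicate_id",
  "provenance", "scale_factor", "origin_id", "sampling_rate",
  "start_time", "samples"
)

assert_spectra <- function(spectra, arg = "spectra") {
  if (!is.data.frame(spectra) || nrow(spectra) == 0L) {
    abort(sprintf("`%s` must be a non-empty data frame of spectra.", arg))
  }
  missing <- setdiff(spectra_cols, names(spectra))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing spectra column(s): %s.", arg,
      paste(missing, collapse = ", ")
    ))
  }
  if (!is.list(spectra$samples)) {
    abort(sprintf("`%s$samples` must be a list column of numeric vectors.", arg))
  }
  invisible(spectra)
}

# Map a list-column of equal-length sample vectors to a matrix (rows =
# spectra). Errors on ragged lengths, which every whole-set stage forbids.
samples_matrix <- function(spectra) {
  lens <- lengths(spectra$samples)
  if (length(unique(lens)) != 1L) {
    abort("All spectra must have the same length (ragged sample vectors).")
  }
  do.call(rbind, spectra$samples)
}

feature_prefix <- "aa2_"

feature_columns <- function(data) {
  grep(paste0("^", feature_prefix), names(data), value = TRUE)
}

metadata_columns <- function(data) {
  setdiff(names(data), feature_columns(data))
}
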