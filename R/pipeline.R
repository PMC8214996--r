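#' Pipeline configuration
#'
#' Gathers every tunable of the end-to-end analysis with defaults matching
#' the published study design: 2.6 MHz sampling, 0.27-0.6 ms ROI,
#' rescaling factors 0.5-4.5 in steps of 0.5, db6 wavelet at level 2, top-10
#' mRMR features, 80/20 stratified splits repeated 10 times over RBF,
#' polynomial and linear kernels.
#'
#' @param design A [study_design()].
#' @param templates A [class_templates()] tibble.
#' @param roi A [roi_window()].
#' @param baseline_order Baseline polynomial order (NULL skips).
#' @param augment_factors Rescaling grid.
#' @param wavelet,level Wavelet packet settings.
#' @param k Number of mRMR-selected features.
#' @param mrmr_scheme `"mid"` or `"miq"`.
#' @param kernels SVM kernels to evaluate.
#' @param train_fraction,n_repeats,split_policy Hold-out settings.
#' @param seed Master seed for the whole run.
#' @return A list of class `pa_config`.
#' @export
pa_config <- function(design = study_design(),
                      templates = class_templates(),
                      roi = roi_window(),
                      baseline_order = 2L,
                      augment_factors = seq(0.5, 4.5, by = 0.5),
                      wavelet = "db6",
                      level = 2L,
                      k = 10L,
                      mrmr_scheme = "mid",
                      kernels = c("rbf", "polynomial", "linear"),
                      train_fraction = 0.8,
                      n_repeats = 10L,
                      split_policy = "paper",
                      seed = 1L) {
  config <- list(
    design = design, templates = templates, roi = roi,
    baseline_order = baseline_order, augment_factors = augment_factors,
    wavelet = wavelet, level = level, k = k, mrmr_scheme = mrmr_scheme,
    kernels = kernels, train_fraction = train_fraction,
    n_repeats = n_repeats, split_policy = split_policy,
    seed = as.integer(seed)
  )
  structure(config, class = "pa_config")
}

#' Run the full staging pipeline
#'
#' Executes generate -> preprocess -> augment -> wavelet features -> mRMR ->
#' repeated SVM hold-out from a single configuration, optionally writing
#' every tabular artifact plus a JSON manifest (configuration summary,
#' derived seeds, session package versions) to `output_dir`. Identical
#' configuration and seed give identical artifacts.
#'
#' @param config A [pa_config()].
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @param spectra Optional pre-recorded spectra tibble (e.g. from
#'   [read_spectra_csv()]); when supplied the synthetic generator is skipped.
#' @param quiet Suppress per-stage progress messages.
#' @return (Invisibly) a list with `spectra`, `roi_spectra`, `augmented`,
#'   `features`, `ranking`, `feature_matrix`, `holdout`, `summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pa_config(), output_dir = NULL,
                         spectra = NULL, quiet = FALSE) {
  if (!inherits(config, "pa_config")) abort("`config` must be a `pa_config`.")
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[pastage] ", fmt), ...))
  }
  t0 <- Sys.time()

  if (is.null(spectra)) {
    say("simulate: %d spectra", config$design$n_spectra)
    spectra <- generate_spectra(config$design, config$templates, config$seed)
  }
  say("preprocess: ROI %.3g-%.3g ms", config$roi$start * 1e3, config$roi$end * 1e3)
  roi_spectra <- pa_preprocess(
    spectra, roi = config$roi, baseline_order = config$baseline_order
  )
  say("augment: factors %s", paste(config$augment_factors, collapse = ", "))
  augmented <- pa_augment(roi_spectra, augment_plan(config$augment_factors))
  say("features: %s level %d", config$wavelet, config$level)
  features <- extract_aa2_features(augmented, config$wavelet, config$level)
  say("select: mRMR top %d (%s)", config$k, config$mrmr_scheme)
  ranking <- mrmr_rank(features, k = config$k, scheme = config$mrmr_scheme)
  feature_matrix <- build_feature_matrix(features, ranking, config$k)
  say("evaluate: %d repeats x %s", config$n_repeats,
      paste(config$kernels, collapse = "/"))
  holdout <- repeated_holdout(
    feature_matrix,
    kernels = config$kernels, n_repeats = config$n_repeats,
    seed = config$seed, train_fraction = config$train_fraction,
    policy = config$split_policy
  )
  summary_tbl <- report_table(holdout)

  manifest <- list(
    seed = config$seed,
    split_seeds = unique(holdout$summary$seed),
    n_original = sum(augmented$provenance == "original"),
    n_augmented = sum(augmented$provenance == "augmented"),
    n_total = nrow(augmented),
    n_features_extracted = length(feature_columns(features)),
    selected_features = ranking$feature,
    n_reports = length(holdout$reports),
    kernels = config$kernels,
    n_repeats = config$n_repeats,
    split_policy = config$split_policy,
    roi_ms = c(config$roi$start, config$roi$end) * 1e3,
    wavelet = config$wavelet,
    level = config$level,
    augment_factors = config$augment_factors,
    r_version = as.character(getRversion()),
    package_versions = list(
      pastage = as.character(utils::packageVersion("pastage")),
      e1071 = as.character(utils::packageVersion("e1071"))
    ),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_spectra_csv(augmented, file.path(output_dir, "spectra.csv"))
    readr::write_csv(features, file.path(output_dir, "features.csv"))
    readr::write_csv(ranking, file.path(output_dir, "ranking.csv"))
    readr::write_csv(summary_tbl, file.path(output_dir, "summary.csv"))
    jsonlite::write_json(
      lapply(holdout$reports, function(r) list(
        kernel = r$kernel, seed = r$seed, accuracy = r$accuracy,
        confusion = as.data.frame.matrix(unclass(r$confusion)),
        metrics = r$metrics
      )),
      file.path(output_dir, "reports.json"),
      auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(
      manifest, file.path(output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
    say("artifacts written to %s", output_dir)
  }

  invisible(list(
    spectra = spectra, roi_spectra = roi_spectra, augmented = augmented,
    features = features, ranking = ranking, feature_matrix = feature_matrix,
    holdout = holdout, summary = summary_tbl, manifest = manifest
  ))
}

#' Read and write spectra as wide CSV
#'
#' One row per trace: the metadata columns `id`, `label`, `tissue_id`,
#' `position_id`, `replicate_id`, `provenance`, `scale_factor`, `origin_id`,
#' `sampling_rate`, `start_time`, then sample columns `s00001`, `s00002`,
#' .... `write_spectra_csv()` followed by `read_spectra_csv()` restores
#' values and metadata exactly (write uses full double precision).
#'
#' @param spectra A spectra tibble of equal-length traces.
#' @param path CSV file path.
#' @return `read_spectra_csv()` returns a spectra tibble;
#'   `write_spectra_csv()` returns `path` invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  assert_spectra(spectra)
  X <- samples_matrix(spectra)
  colnames(X) <- sprintf("s%05d", seq_len(ncol(X)))
  meta_cols <- setdiff(spectra_cols, "samples")
  out <- bind_cols(spectra[, meta_cols], as_tibble(X))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- setdiff(spectra_cols, "samples")
  missing <- setdiff(meta_cols, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf(
      "Spectra CSV is missing column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  sample_cols <- grep("^s[0-9]+$", names(raw), value = TRUE)
  if (length(sample_cols) == 0L) abort("Spectra CSV has no sample columns.")
  X <- as.matrix(raw[, sample_cols])
  if (!is.numeric(X) || anyNA(X)) {
    abort("Sample columns must be numeric with no missing values (ragged rows?).")
  }
  out <- as_tibble(raw[, meta_cols])
  out$samples <- lapply(seq_len(nrow(X)), function(i) unname(X[i, ]))
  out
}
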