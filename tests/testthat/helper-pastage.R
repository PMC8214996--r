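# Shared fixtures and independent oracles, all built in code.

# Minimal spectra tibble around bare sample vectors, for stage-level tests.
make_spectra <- function(samples, rate = 2.6e6, label = "day0",
                         start_time = 0) {
  if (!is.list(samples)) samples <- list(samples)
  n <- length(samples)
  tibble::tibble(
    id = sprintf("spc%d", seq_len(n)),
    label = rep_len(label, n),
    tissue_id = 1L, position_id = 1L, replicate_id = seq_len(n),
    provenance = "original", scale_factor = 1,
    origin_id = sprintf("spc%d", seq_len(n)),
    sampling_rate = rate, start_time = start_time,
    samples = samples
  )
}

# Small acquisition design used by the slower property tests.
small_design <- function() {
  study_design(n_tissues = 2, n_positions = 2, n_replicates = 2)
}

# Independent brute-force oracle for one periodized analysis step: direct
# circular convolution + downsampling by 2, scalar arithmetic only.
bf_dwt_step <- function(x, filt) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  L <- length(filt$lo)
  K <- n / 2
  a <- numeric(K)
  d <- numeric(K)
  for (k in 0:(K - 1)) {
    sa <- 0
    sd_ <- 0
    for (j in 0:(L - 1)) {
      xi <- x[((2 * k + j) %% n) + 1]
      sa <- sa + filt$lo[j + 1] * xi
      sd_ <- sd_ + filt$hi[j + 1] * xi
    }
    a[k + 1] <- sa
    d[k + 1] <- sd_
  }
  list(a = a, d = d)
}

# Independent replay of the greedy mRMR criterion (MID scheme) using the
# public MI estimator and plain loops.
bf_mrmr_replay <- function(feats, labels, k) {
  p <- ncol(feats)
  relevance <- vapply(
    seq_len(p), function(j) mutual_information(feats[[j]], labels), numeric(1)
  )
  selected <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(k)) {
    best_j <- NA_integer_
    best_crit <- -Inf
    for (j in seq_len(p)) {
      if (j %in% selected) next
      crit <- relevance[j]
      if (length(selected) > 0) {
        red <- mean(vapply(
          selected,
          function(s) mutual_information(feats[[j]], feats[[s]]), numeric(1)
        ))
        crit <- crit - red
      }
      if (crit > best_crit + 1e-12) {
        best_crit <- crit
        best_j <- j
      }
    }
    selected <- c(selected, best_j)
    scores <- c(scores, best_crit)
  }
  list(selected = selected, scores = scores)
}

# A fixed-prediction stand-in classifier for evaluate_model() arithmetic
# tests.
fixed_predictor <- function(predictions) {
  structure(list(predictions = predictions), class = "fixed_predictor")
}

predict.fixed_predictor <- function(object, newdata, ...) {
  rep_len(object$predictions, nrow(newdata))
}

# S3 dispatch from inside the package finds methods on the global search
# path, so register the test-only method there.
assign("predict.fixed_predictor", predict.fixed_predictor, envir = globalenv())

# Run the downstream pipeline (features -> mRMR -> polynomial hold-out) on a
# generated dataset and return the mean test accuracy.
downstream_accuracy <- function(spectra, seed, n_repeats = 2,
                                policy = "grouped") {
  feats <- extract_aa2_features(pa_augment(pa_preprocess(spectra)))
  rk <- mrmr_rank(feats, k = 10)
  fm <- build_feature_matrix(feats, rk, 10)
  ho <- repeated_holdout(fm, kernels = "polynomial", n_repeats = n_repeats,
                         seed = seed, policy = policy)
  mean(generics::tidy(ho)$accuracy)
}
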