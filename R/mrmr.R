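# Equal-frequency discretization of a continuous feature into integer codes.
# Quantile bins are invariant to monotone rescaling, which matters here
# because augmentation multiplies whole feature rows by factors up to 4.5.
discretize_ef <- function(x, n_bins) {
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE, type = 7))
  if (length(breaks) < 2L) return(rep.int(1L, length(x)))
  as.integer(cut(x, breaks = breaks, include.lowest = TRUE))
}

default_bins <- function(n) min(256L, as.integer(ceiling(sqrt(n))))

# MI in nats from two integer/factor code vectors via the empirical joint
# frequency table.
mi_from_codes <- function(cx, cy) {
  joint <- table(cx, cy)
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Mutual information between a feature and labels
#'
#' Empirical mutual information (in nats) between a continuous feature --
#' discretized into equal-frequency bins -- and a discrete label vector, or
#' between two continuous features (both discretized). Computed by direct
#' summation over the joint frequency table; always non-negative.
#'
#' @param x Numeric feature values, or a discrete vector.
#' @param y Class labels (character/factor), or a second numeric feature.
#' @param n_bins Number of quantile bins for continuous inputs; defaults to
#'   `ceiling(sqrt(n))` capped at 256.
#' @return Mutual information in nats.
#' @examples
#' y <- rep(c("a", "b"), each = 50)
#' x <- as.numeric(y == "a")
#' mutual_information(x, y) # = log(2)
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (is.null(n_bins)) n_bins <- default_bins(length(x))
  cx <- if (is.numeric(x)) discretize_ef(x, n_bins) else as.integer(factor(x))
  cy <- if (is.numeric(y)) discretize_ef(y, n_bins) else as.integer(factor(y))
  if (!is.numeric(y) && length(unique(cy)) < 2L) {
    abort("`y` must contain at least 2 distinct classes.")
  }
  mi_from_codes(cx, cy)
}

#' Greedy mRMR ranking of feature columns
#'
#' Minimal-redundancy maximal-relevance selection: the first feature
#' maximizes relevance `MI(x; labels)`; each subsequent feature maximizes
#' the difference criterion `MI(x; labels) - mean over selected s of
#' MI(x; s)` (the "MID" scheme; `"miq"` uses the quotient instead). The
#' importance score attached to each entry is the criterion value at the
#' moment of selection, so the first score is the plain relevance. Ties are
#' broken towards the lower column index, making rankings reproducible.
#'
#' @param features A data frame of numeric feature columns. Metadata columns
#'   (`id`, `label`, `origin_id`, `provenance`, `scale_factor`) are dropped
#'   automatically, so the output of [extract_aa2_features()] can be passed
#'   directly.
#' @param labels Class labels, one per row. If missing, a `label` column in
#'   `features` is used.
#' @param k Number of features to rank.
#' @param scheme `"mid"` (difference, default) or `"miq"` (quotient).
#' @param n_bins Quantile-bin count for the MI estimator.
#' @return A tibble of class `mrmr_ranking` with columns `rank`, `feature`
#'   (column name), `coefficient` (1-based position among feature columns)
#'   and `score`.
#' @export
mrmr_rank <- function(features, labels = NULL, k = 10L,
                      scheme = c("mid", "miq"), n_bins = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(labels)) {
    if (!"label" %in% names(features)) {
      abort("Provide `labels` or include a `label` column in `features`.")
    }
    labels <- features$label
  }
  meta <- intersect(
    c("id", "label", "origin_id", "provenance", "scale_factor"),
    names(features)
  )
  feats <- features[, setdiff(names(features), meta), drop = FALSE]
  if (!all(vapply(feats, is.numeric, logical(1)))) {
    abort("All feature columns must be numeric.")
  }
  p <- ncol(feats)
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be >= 1.")
  if (k > p) abort("`k` exceeds the number of feature columns.")
  y <- as.integer(factor(labels))
  if (length(unique(y)) < 2L) abort("Need at least 2 classes.")
  if (length(y) != nrow(feats)) abort("`labels` length must match rows.")

  if (is.null(n_bins)) n_bins <- default_bins(nrow(feats))
  codes <- vapply(feats, discretize_ef, integer(nrow(feats)), n_bins = n_bins)
  relevance <- apply(codes, 2L, mi_from_codes, cy = y)

  selected <- integer(0)
  scores <- numeric(0)
  redundancy <- matrix(NA_real_, nrow = p, ncol = k - 1L)
  for (step in seq_len(k)) {
    remaining <- setdiff(seq_len(p), selected)
    if (step == 1L) {
      crit <- relevance[remaining]
    } else {
      red <- rowMeans(redundancy[remaining, seq_len(step - 1L), drop = FALSE])
      crit <- switch(scheme,
        mid = relevance[remaining] - red,
        miq = relevance[remaining] / pmax(red, .Machine$double.eps)
      )
    }
    pick <- remaining[which.max(crit)] # which.max takes the first max: low-index tie-break
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
    if (step < k) {
      for (j in setdiff(seq_len(p), selected)) {
        redundancy[j, step] <- mi_from_codes(codes[, j], codes[, pick])
      }
    }
  }

  out <- tibble(
    rank = seq_len(k),
    feature = names(feats)[selected],
    coefficient = selected,
    score = scores
  )
  class(out) <- c("mrmr_ranking", class(out))
  out
}

#' Assemble the selected-feature matrix
#'
#' Keeps the top-`k` ranked feature columns (in ranking order) together with
#' labels and provenance metadata -- the input the classifiers train on.
#'
#' @param features Feature table, e.g. from [extract_aa2_features()].
#' @param ranking An [mrmr_rank()] result with at least `k` entries.
#' @param k Number of leading ranked features to keep.
#' @return A tibble with the metadata columns of `features` followed by the
#'   `k` selected feature columns.
#' @export
build_feature_matrix <- function(features, ranking, k = 10L) {
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be >= 1.")
  if (!inherits(ranking, "mrmr_ranking")) abort("`ranking` must be an `mrmr_ranking`.")
  if (nrow(ranking) < k) abort("`ranking` has fewer than `k` entries.")
  keep <- ranking$feature[seq_len(k)]
  if (!all(keep %in% names(features))) {
    abort("Ranking refers to feature columns absent from `features`.")
  }
  meta <- intersect(
    c("id", "label", "origin_id", "provenance", "scale_factor"),
    names(features)
  )
  out <- features[, c(meta, keep), drop = FALSE]
  if (anyNA(out)) abort("Feature matrix contains missing values.")
  as_tibble(out)
}
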