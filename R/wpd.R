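# Orthonormal Daubechies analysis lowpass filters (convolution order). The
# highpass mate is derived by the quadrature-mirror relation
# h[j] = (-1)^j g[L-1-j], so each pair generates an orthonormal circular
# filter bank.
.wavelet_lo <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852,
          0.030841381835560764, -0.18703481171909309,
          -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db6 = c(-1.0773010853084796e-03, 4.7772575109455108e-03,
          5.5384220116149613e-04, -3.1582039317486030e-02,
          2.7522865530305727e-02, 9.7501605587323043e-02,
          -1.2976686756726194e-01, -2.2626469396543983e-01,
          3.1525035170919763e-01, 7.5113390802109536e-01,
          4.9462389039845306e-01, 1.1154074335010947e-01)
)

#' Orthonormal wavelet filter pair
#'
#' @param wavelet One of `"haar"`, `"db2"`, `"db4"`, `"db6"`.
#' @return A list with the analysis lowpass (`lo`) and highpass (`hi`)
#'   filters and the wavelet name.
#' @export
wavelet_filters <- function(wavelet = "db6") {
  lo <- .wavelet_lo[[wavelet]]
  if (is.null(lo)) {
    abort(sprintf(
      "Unknown wavelet '%s'; available: %s.", wavelet,
      paste(names(.wavelet_lo), collapse = ", ")
    ))
  }
  L <- length(lo)
  hi <- (-1)^(seq_len(L) - 1) * rev(lo)
  list(wavelet = wavelet, lo = lo, hi = hi)
}

# One analysis step of the periodized orthonormal filter bank, batched over
# signals held in matrix rows. Odd-length signals are zero-padded by one
# sample first: the padded transform is an isometry of the padded vector,
# whose energy equals the original's, so energy conservation and perfect
# reconstruction are exact at every length (the pad is provably restored as
# zero on inversion and dropped).
wpd_step_mat <- function(X, filt) {
  n <- ncol(X)
  if (n %% 2L == 1L) X <- cbind(X, 0)
  m <- ncol(X)
  K <- m %/% 2L
  L <- length(filt$lo)
  A <- matrix(0, nrow(X), K)
  D <- matrix(0, nrow(X), K)
  base <- 2L * (seq_len(K) - 1L)
  for (j in seq_len(L)) {
    col <- (base + j - 1L) %% m + 1L
    A <- A + filt$lo[j] * X[, col, drop = FALSE]
    D <- D + filt$hi[j] * X[, col, drop = FALSE]
  }
  list(a = A, d = D)
}

# Inverse of wpd_step_mat: reassemble a parent of length n from its two
# children (transpose of the orthonormal analysis operator, then drop the
# pad sample if n is odd).
wpd_inverse_step_mat <- function(A, D, n, filt) {
  K <- ncol(A)
  m <- 2L * K
  L <- length(filt$lo)
  X <- matrix(0, nrow(A), m)
  base <- 2L * (seq_len(K) - 1L)
  for (j in seq_len(L)) {
    col <- (base + j - 1L) %% m + 1L
    X[, col] <- X[, col] + filt$lo[j] * A + filt$hi[j] * D
  }
  X[, seq_len(n), drop = FALSE]
}

#' Wavelet packet decomposition of a single trace
#'
#' Recursively splits both approximation and detail branches with the
#' periodized orthonormal filter bank, producing the full binary tree down
#' to `level`. Nodes are labelled `"depth.index"` in natural (filter-bank)
#' order, so node `(2,0)` — conventionally "AA2" — is the twice-lowpassed
#' approximation band. Child vectors have `ceiling(parent/2)` coefficients
#' and the transform conserves energy exactly, so the squared coefficients
#' of any complete level sum to the signal energy.
#'
#' @param x Numeric signal, at least as long as the filter.
#' @param wavelet Wavelet name (see [wavelet_filters()]).
#' @param level Decomposition depth, `>= 1`.
#' @return An object of class `wpd_tree` with per-node coefficient vectors.
#' @examples
#' tree <- wpd_decompose(sin(seq_len(64)), "db6", 2)
#' lengths(tree$nodes[c("2.0", "2.1", "2.2", "2.3")]) # all 16
#' @export
wpd_decompose <- function(x, wavelet = "db6", level = 2L) {
  filt <- wavelet_filters(wavelet)
  level <- as.integer(level)
  if (level < 1L) abort("`level` must be >= 1.")
  if (length(x) < length(filt$lo)) {
    abort("Signal shorter than the wavelet filter.")
  }
  if (any(!is.finite(x))) abort("Signal contains non-finite samples.")

  nodes <- list("0.0" = x)
  lengths_by_level <- c(length(x))
  current <- list(x)
  for (d in seq_len(level)) {
    nxt <- vector("list", 2L * length(current))
    for (i in seq_along(current)) {
      step <- wpd_step_mat(matrix(current[[i]], nrow = 1L), filt)
      nxt[[2L * i - 1L]] <- drop(step$a)
      nxt[[2L * i]] <- drop(step$d)
    }
    names(nxt) <- sprintf("%d.%d", d, seq_along(nxt) - 1L)
    nodes <- c(nodes, nxt)
    lengths_by_level <- c(lengths_by_level, length(nxt[[1]]))
    current <- nxt
  }
  nodes[["0.0"]] <- NULL
  structure(
    list(
      wavelet = wavelet, level = level, input_length = length(x),
      lengths_by_level = lengths_by_level, nodes = nodes
    ),
    class = "wpd_tree"
  )
}

#' @export
print.wpd_tree <- function(x, ...) {
  cat(sprintf(
    "<wpd_tree> %s, level %d, input length %d\n",
    x$wavelet, x$level, x$input_length
  ))
  leaf <- sprintf("%d.%d", x$level, seq_len(2L^x$level) - 1L)
  cat("  leaf nodes:", paste(leaf, collapse = ", "),
      sprintf("(%d coefficients each)\n", length(x$nodes[[leaf[1]]])))
  invisible(x)
}

level_nodes <- function(tree, level = tree$level) {
  sprintf("%d.%d", level, seq_len(2L^level) - 1L)
}

#' Per-subband energy fractions of a wavelet packet tree
#'
#' The fraction of total squared-coefficient energy held by each node of the
#' deepest level. Because the transform is orthonormal the level total
#' equals the signal energy, so fractions are also fractions of signal
#' energy. Node `"2.0"` at level 2 is the approximation ("AA2") band.
#'
#' @param tree A [wpd_decompose()] result.
#' @return A tibble with columns `node` and `fraction` (sums to 1).
#' @export
energy_distribution <- function(tree) {
  if (!inherits(tree, "wpd_tree")) abort("`tree` must be a `wpd_tree`.")
  leaf <- level_nodes(tree)
  energy <- vapply(tree$nodes[leaf], function(v) sum(v^2), numeric(1))
  total <- sum(energy)
  if (total == 0) abort("Energy fractions are undefined for an all-zero signal.")
  tibble(node = leaf, fraction = unname(energy / total))
}

#' Reconstruct the signal from a wavelet packet tree
#'
#' Inverts the analysis filter bank from the deepest level upwards. The
#' transform is orthonormal, so reconstruction is exact to floating-point
#' accuracy; zeroing detail nodes before reconstruction yields the
#' corresponding band-limited approximation.
#'
#' @param tree A [wpd_decompose()] result (node vectors may be modified, but
#'   all deepest-level nodes must be present).
#' @return The reconstructed numeric signal.
#' @export
wpd_reconstruct <- function(tree) {
  if (!inherits(tree, "wpd_tree")) abort("`tree` must be a `wpd_tree`.")
  filt <- wavelet_filters(tree$wavelet)
  leaf <- level_nodes(tree)
  if (!all(leaf %in% names(tree$nodes))) {
    abort("Tree is missing deepest-level nodes; cannot reconstruct.")
  }
  current <- tree$nodes[leaf]
  for (d in rev(seq_len(tree$level))) {
    parent_len <- tree$lengths_by_level[d]
    parents <- vector("list", length(current) %/% 2L)
    for (i in seq_along(parents)) {
      parents[[i]] <- drop(wpd_inverse_step_mat(
        matrix(current[[2L * i - 1L]], nrow = 1L),
        matrix(current[[2L * i]], nrow = 1L),
        parent_len, filt
      ))
    }
    current <- parents
  }
  current[[1]]
}

#' Approximation-band feature table
#'
#' Decomposes every spectrum to `level` with the chosen wavelet and keeps
#' the approximation-band (repeated lowpass, node `(level, 0)`; "AA2" at
#' level 2) coefficients as features: one row per spectrum, one column per
#' coefficient in filter-output order, named `aa2_001`, `aa2_002`, ....
#' Class labels and provenance metadata are carried through. The transform
#' is linear, so a rescaled trace yields the rescaled feature row.
#'
#' @param spectra A spectra tibble of equal-length traces.
#' @param wavelet,level Passed to the decomposition.
#' @return A tibble: `id`, `label`, `origin_id`, `provenance`,
#'   `scale_factor`, then the coefficient columns.
#' @examples
#' spectra <- generate_spectra(
#'   study_design(n_tissues = 1, n_positions = 1, n_replicates = 1),
#'   class_templates(), seed = 1
#' ) |> pa_preprocess()
#' dim(extract_aa2_features(spectra)) # 5 x (5 + 215)
#' @export
extract_aa2_features <- function(spectra, wavelet = "db6", level = 2L) {
  assert_spectra(spectra)
  filt <- wavelet_filters(wavelet)
  X <- samples_matrix(spectra)
  if (ncol(X) < length(filt$lo)) abort("Spectra shorter than the wavelet filter.")
  for (d in seq_len(level)) {
    X <- wpd_step_mat(X, filt)$a
  }
  colnames(X) <- sprintf("%s%03d", feature_prefix, seq_len(ncol(X)))
  bind_cols(
    spectra[, c("id", "label", "origin_id", "provenance", "scale_factor")],
    as_tibble(X)
  )
}
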