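test_that("filter pairs are orthonormal quadrature mirrors", {
  for (w in c("haar", "db2", "db4", "db6")) {
    filt <- wavelet_filters(w)
    expect_equal(sum(filt$lo^2), 1)
    expect_equal(sum(filt$lo), sqrt(2))
    expect_equal(sum(filt$lo * filt$hi), 0)
    L <- length(filt$lo)
    for (shift in if (L >= 4) seq(2, L - 2, by = 2) else integer(0)) {
      expect_equal(sum(filt$lo[1:(L - shift)] * filt$lo[(shift + 1):L]), 0,
                   tolerance = 1e-12)
    }
  }
  expect_error(wavelet_filters("sym8"), "Unknown wavelet")
})

test_that("node lengths follow the ceil-halving rule", {
  tree <- wpd_decompose(rnorm(858), "db6", 2)
  expect_named(tree$nodes, c("1.0", "1.1", "2.0", "2.1", "2.2", "2.3"))
  expect_true(all(lengths(tree$nodes[c("1.0", "1.1")]) == 429L))
  expect_true(all(lengths(tree$nodes[c("2.0", "2.1", "2.2", "2.3")]) == 215L))
  expect_error(wpd_decompose(rnorm(8), "db6"), "shorter than")
})

test_that("the transform conserves energy and reconstructs exactly", {
  set.seed(31)
  for (n in c(64, 215, 858)) {
    x <- rnorm(n)
    tree <- wpd_decompose(x, "db6", 2)
    leaf_energy <- sum(vapply(
      tree$nodes[c("2.0", "2.1", "2.2", "2.3")],
      function(v) sum(v^2), numeric(1)
    ))
    expect_equal(leaf_energy, sum(x^2), tolerance = 1e-9)
    # every level preserves the total, not just the deepest
    lvl1 <- sum(vapply(tree$nodes[c("1.0", "1.1")], function(v) sum(v^2),
                       numeric(1)))
    expect_equal(lvl1, sum(x^2), tolerance = 1e-9)
    expect_equal(wpd_reconstruct(tree), x, tolerance = 1e-9)
  }
})

test_that("decomposition is linear nodewise", {
  set.seed(13)
  x <- rnorm(128)
  y <- rnorm(128)
  tx <- wpd_decompose(x)
  ty <- wpd_decompose(y)
  tz <- wpd_decompose(2.5 * x - 0.7 * y)
  for (node in names(tz$nodes)) {
    expect_equal(tz$nodes[[node]],
                 2.5 * tx$nodes[[node]] - 0.7 * ty$nodes[[node]])
  }
})

test_that("coefficients match a brute-force periodic convolution oracle", {
  set.seed(17)
  x <- rnorm(16)
  for (w in c("haar", "db2")) {
    filt <- wavelet_filters(w)
    tree <- wpd_decompose(x, w, 2)
    step1 <- bf_dwt_step(x, filt)
    expect_equal(tree$nodes[["1.0"]], step1$a)
    expect_equal(tree$nodes[["1.1"]], step1$d)
    expect_equal(tree$nodes[["2.0"]], bf_dwt_step(step1$a, filt)$a)
    expect_equal(tree$nodes[["2.1"]], bf_dwt_step(step1$a, filt)$d)
    expect_equal(tree$nodes[["2.2"]], bf_dwt_step(step1$d, filt)$a)
    expect_equal(tree$nodes[["2.3"]], bf_dwt_step(step1$d, filt)$d)
  }
})

test_that("energy fractions behave like an orthonormal subband split", {
  # DC-dominated signal: the double-lowpass node captures essentially all
  const <- wpd_decompose(rep(3, 256))
  dist <- energy_distribution(const)
  expect_gt(dist$fraction[dist$node == "2.0"], 0.999)
  expect_equal(sum(dist$fraction), 1, tolerance = 1e-12)

  # white noise: level-2 equipartition at 1/4 per node on average
  set.seed(23)
  fractions <- matrix(0, 2000, 4)
  for (i in seq_len(2000)) {
    fractions[i, ] <- energy_distribution(wpd_decompose(rnorm(64)))$fraction
  }
  expect_true(all(abs(colMeans(fractions) - 0.25) < 0.01))

  # a pure high-band signal has no approximation energy
  tree <- wpd_decompose(rnorm(256))
  for (node in c("2.0", "2.1", "2.2")) tree$nodes[[node]][] <- 0
  hi <- wpd_reconstruct(tree)
  redist <- energy_distribution(wpd_decompose(hi))
  expect_lt(redist$fraction[redist$node == "2.0"], 1e-9)
  # orthonormality: the band-limited signal keeps exactly the kept energy
  expect_equal(sum(hi^2), sum(tree$nodes[["2.3"]]^2), tolerance = 1e-9)

  expect_error(energy_distribution(wpd_decompose(rep(0, 64))), "all-zero")
})

test_that("an all-zero tree reconstructs to the zero signal", {
  tree <- wpd_decompose(rnorm(100))
  for (node in names(tree$nodes)) tree$nodes[[node]][] <- 0
  expect_equal(wpd_reconstruct(tree), rep(0, 100))
})

test_that("the feature table holds approximation coefficients per spectrum", {
  sp <- generate_spectra(
    study_design(n_tissues = 1, n_positions = 1, n_replicates = 2),
    class_templates(), seed = 6
  ) |> pa_preprocess()
  feats <- extract_aa2_features(sp)
  expect_equal(nrow(feats), nrow(sp))
  aa2_cols <- grep("^aa2_", names(feats), value = TRUE)
  expect_length(aa2_cols, 215L)
  # batch path agrees with the single-trace decomposition
  tree <- wpd_decompose(sp$samples[[1]], "db6", 2)
  expect_equal(unlist(feats[1, aa2_cols], use.names = FALSE),
               tree$nodes[["2.0"]])
  # linearity: a rescaled trace gives the rescaled feature row
  scaled <- extract_aa2_features(pa_rescale(sp, 3))
  expect_equal(unlist(scaled[1, aa2_cols], use.names = FALSE),
               3 * unlist(feats[1, aa2_cols], use.names = FALSE))
  # zero trace maps to the zero row
  zero <- extract_aa2_features(make_spectra(rep(0, 858)))
  expect_equal(unlist(zero[1, grep("^aa2_", names(zero))], use.names = FALSE),
               rep(0, 215))
  # ragged input is rejected
  ragged <- dplyr::bind_rows(make_spectra(rnorm(64)), make_spectra(rnorm(65)))
  expect_error(extract_aa2_features(ragged), "same length")
})
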