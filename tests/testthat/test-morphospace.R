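make_ensemble <- function(n = 6, k = 5, jitter = 0.05, seed = 101) {
  set.seed(seed)
  base <- matrix(rnorm(k * 3, sd = 5), k, 3, dimnames = list(1:k, NULL))
  gpa(lapply(seq_len(n), function(i)
    base + matrix(rnorm(k * 3, sd = jitter), k, 3)))
}

test_that("degenerate ensembles give degenerate spectra", {
  base <- toy_tetrahedron(jitter = 0.3, seed = 5)
  m <- shape_pca(gpa(lapply(1:4, function(i) base)))
  expect_true(length(m$eigenvalues) == 0 || all(m$eigenvalues < 1e-15))

  # exactly two distinct shapes: rank one, all variance on PC1
  other <- toy_tetrahedron(jitter = 0.3, seed = 6)
  m2 <- shape_pca(gpa(list(base, base, other, other)))
  expect_length(m2$eigenvalues, 1)
  expect_equal(m2$proportions[[1]], 1.0)
  expect_error(shape_pca(gpa(list(base, other))), "at least 3")
})

test_that("eigen-decomposition matches a cyclic-Jacobi oracle", {
  ens <- tangent_project(make_ensemble())
  m <- shape_pca(ens)
  flat <- t(apply(ens$aligned, 3, function(a) as.vector(t(a))))
  cov_ <- stats::cov(flat)
  jac <- jacobi_eigen(cov_)
  nn <- seq_along(m$eigenvalues)
  expect_equal(m$eigenvalues, jac$values[nn], tolerance = 1e-8,
               ignore_attr = TRUE)
  for (j in nn) {
    # loadings agree up to sign
    expect_equal(abs(sum(m$loadings[, j] * jac$vectors[, j])), 1,
                 tolerance = 1e-6)
  }
})

test_that("PCA conserves total variance and reconstructs the data", {
  ens <- make_ensemble(n = 8, k = 6, seed = 102)
  m <- shape_pca(ens)
  flat <- t(apply(tangent_project(ens)$aligned, 3, function(a) as.vector(t(a))))
  total <- sum(sweep(flat, 2, colMeans(flat))^2) / (nrow(flat) - 1)
  expect_equal(sum(m$eigenvalues), total, tolerance = 1e-10)

  expect_true(all(abs(colMeans(m$scores)) < 1e-12))
  expect_equal(unname(crossprod(m$loadings)),
               diag(length(m$eigenvalues)), tolerance = 1e-10)
  recon <- sweep(m$scores %*% t(m$loadings), 2, m$center, `+`)
  expect_equal(unname(recon), unname(flat), tolerance = 1e-8)
  expect_lte(length(m$eigenvalues), min(m$n_specimens - 1, 3 * m$n_landmarks - 7))
})

test_that("scores are invariant (up to sign) to joint rotation of the aligned data", {
  ens <- make_ensemble(n = 7, k = 5, seed = 103)
  m <- shape_pca(ens)
  set.seed(104)
  r <- random_rotation()
  rot <- ens
  for (i in seq_len(dim(ens$aligned)[3]))
    rot$aligned[, , i] <- ens$aligned[, , i] %*% r
  rot$consensus <- ens$consensus %*% r
  m2 <- shape_pca(rot)
  for (j in seq_along(m$eigenvalues)) {
    agree <- max(abs(m2$scores[, j] - m$scores[, j]),
                 abs(m2$scores[, j] + m$scores[, j]))
    expect_equal(min(max(abs(m2$scores[, j] - m$scores[, j])),
                     max(abs(m2$scores[, j] + m$scores[, j]))), 0,
                 tolerance = 1e-8)
  }
  expect_equal(m2$eigenvalues, m$eigenvalues, tolerance = 1e-10)
})

test_that("variance table proportions are exact eigenvalue ratios", {
  m <- shape_pca(make_ensemble(n = 6, k = 5, seed = 105))
  vt <- variance_table(m)
  expect_equal(vt$proportion, vt$eigenvalue / sum(vt$eigenvalue))
  expect_equal(vt$cumulative[nrow(vt)], 1, tolerance = 1e-9)
  expect_true(all(diff(vt$cumulative) >= 0))
  expect_true(all(diff(vt$eigenvalue) <= 1e-15))
})

test_that("broken-stick thresholds equal the harmonic-sum formula", {
  expect_equal(broken_stick(1), 1.0)
  expect_equal(broken_stick(3), c(0.6111, 0.2778, 0.1111), tolerance = 1e-4)
  for (p in c(2, 5, 12, 28)) {
    b <- broken_stick(p)
    expect_equal(sum(b), 1, tolerance = 1e-12)
    expect_true(all(diff(b) < 0))
    # direct harmonic sums, computed the slow way
    direct <- vapply(seq_len(p), function(k) sum(1 / (k:p)) / p, numeric(1))
    expect_equal(b, direct, tolerance = 1e-14)
  }
  expect_error(broken_stick(0), "positive")
  # independent reference implementation
  expect_equal(broken_stick(9), unname(rev(sort(vegan::bstick(9, tot.var = 1)))),
               tolerance = 1e-12)
})

test_that("component selection obeys strict broken-stick comparison and fixed k", {
  m <- stub_model(eigenvalues = c(3, 1))      # proportions exactly (0.75, 0.25)
  expect_identical(select_components(m, "broken_stick"), 0L)
  m2 <- stub_model(eigenvalues = c(0.9, 0.05, 0.05))
  expect_identical(select_components(m2, "broken_stick"), 1L)
  expect_identical(select_components(m2, "fixed_k", k = 4), 3L)
  m3 <- stub_model(eigenvalues = rep(1, 8))
  expect_identical(select_components(m3, "fixed_k", k = 4), 4L)
})

test_that("confidence bands implement mean +/- 1.96 sample SD", {
  m <- stub_model(scores = cbind(PC1 = c(-2, 0, 2)))
  b <- confidence_bands(m, pcs = 1)
  expect_equal(b$sd, 2)
  expect_equal(b$half_width, 3.92)
  expect_equal(c(b$lower, b$upper), c(-3.92, 3.92))

  # degenerate: identical scores
  b0 <- confidence_bands(stub_model(scores = cbind(PC1 = rep(1.3, 5))), pcs = 1)
  expect_equal(b0$half_width, 0)
  expect_equal(b0$lower, b0$upper)
  expect_equal(b0$mean, 1.3)

  expect_error(confidence_bands(stub_model(scores = cbind(PC1 = 1)), 1),
               "at least 2")
  expect_error(confidence_bands(m, pcs = 1, multiplier = 0), "positive")
  expect_error(confidence_bands(m, pcs = 5), "do not exist")
})

test_that("outlier flagging is strict and correctly targeted", {
  set.seed(9)
  sc <- cbind(PC1 = rnorm(20, sd = 0.1), PC2 = rnorm(20, sd = 0.05))
  rownames(sc) <- sprintf("s%02d", 1:20)
  # plant one specimen far out on PC2
  sc["s07", "PC2"] <- mean(sc[, "PC2"]) + 3 * sd(sc[, "PC2"])
  m <- stub_model(scores = sc)
  bands <- confidence_bands(m, pcs = 1:2)
  rep <- flag_outliers(m, bands)
  expect_true("s07" %in% rep$per_pc$PC2)
  # flags agree with a direct check
  for (j in 1:2) {
    direct <- sc[, j] < bands$lower[j] | sc[, j] > bands$upper[j]
    expect_identical(unname(rep$flags[, j]), unname(direct))
  }
  # all-inside case
  m2 <- stub_model(scores = cbind(PC1 = c(-1, 0, 1, 0.5, -0.5)))
  rep2 <- flag_outliers(m2, confidence_bands(m2, pcs = 1))
  expect_length(rep2$per_pc$PC1, 0)
})

test_that("about 5% of Gaussian scores fall outside their own 95% band", {
  set.seed(2024)
  m <- stub_model(scores = cbind(PC1 = rnorm(10000)))
  rep <- flag_outliers(m, confidence_bands(m, pcs = 1))
  rate <- mean(rep$flags[, 1])
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("shape reconstruction along a PC is linear and invertible", {
  m <- shape_pca(make_ensemble(n = 6, k = 5, seed = 106))
  expect_equal(unname(reconstruct_shape(m, 1, 0)), unname(m$mean_shape))
  for (s in c(-0.07, 0.013)) {
    shp <- reconstruct_shape(m, 2, s)
    back <- sum((as.vector(t(shp)) - m$center) * m$loadings[, 2])
    expect_equal(back, s, tolerance = 1e-10)
  }
  d <- as.vector(t(reconstruct_shape(m, 1, 0.05) -
                     reconstruct_shape(m, 1, -0.05)))
  cosine <- sum(d * m$loadings[, 1]) / sqrt(sum(d^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-10)
  expect_error(reconstruct_shape(m, 99, 1), "does not exist")
})

test_that("loading sign convention puts the largest element positive", {
  m <- shape_pca(make_ensemble(n = 8, k = 6, seed = 107))
  for (j in seq_along(m$eigenvalues)) {
    expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
  }
})
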