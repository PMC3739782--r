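test_that("the skull template is exactly mirror-symmetric and deterministic", {
  scheme <- psittacosaur_scheme()
  tpl <- skull_template()
  pts <- tpl$points
  expect_equal(nrow(pts), 56)
  for (id in names(scheme$bilateral_pairs)) {
    mate <- as.character(scheme$bilateral_pairs[[id]])
    expect_identical(pts[id, c("x", "z")], pts[mate, c("x", "z")],
                     ignore_attr = TRUE)
    expect_identical(pts[id, "y"], -pts[mate, "y"], ignore_attr = TRUE)
  }
  expect_true(all(pts[as.character(scheme$midline_ids), "y"] == 0))
  expect_identical(skull_template()$points, pts)
  expect_error(skull_template(length = -1), "positive")

  # anatomy-consistent placement: rostral landmarks rostral, jugal horns
  # widest, temporal landmarks caudal
  expect_lt(pts["1", "x"], pts["23", "x"])
  expect_equal(unname(max(abs(pts[, "y"]))), abs(pts["24", "y"]))
  expect_gt(pts["29", "z"], pts["1", "z"])
})

test_that("identity-magnitude deformations are exact no-ops", {
  tpl <- skull_template()
  for (mode in c("dorsoventral_compression", "mediolateral_compression",
                 "unilateral_crush", "allometric_juvenile"))
    expect_identical(deform(tpl, deformation_spec(mode, 1))$points,
                     tpl$points, info = mode)
  expect_identical(deform(tpl, deformation_spec("caudal_rotation", 0))$points,
                   tpl$points)
})

test_that("uniform dorsoventral compression halves z offsets exactly", {
  tpl <- skull_template()
  out <- deform(tpl, deformation_spec("dorsoventral_compression", 0.5))
  zc <- mean(range(tpl$points[, "z"]))
  expect_equal(out$points[, "z"] - zc, (tpl$points[, "z"] - zc) * 0.5)
  expect_identical(out$points[, "y"], tpl$points[, "y"])
  expect_identical(out$points[, "x"], tpl$points[, "x"])
})

test_that("mediolateral compression scales width only", {
  tpl <- skull_template()
  out <- deform(tpl, deformation_spec("mediolateral_compression", 0.7))
  expect_equal(out$points[, "y"], tpl$points[, "y"] * 0.7)
  expect_identical(out$points[, "x"], tpl$points[, "x"])
  expect_identical(out$points[, "z"], tpl$points[, "z"])
})

test_that("unilateral crush moves one side toward the midline, leaving the other near-intact", {
  tpl <- skull_template()
  out <- deform(tpl, deformation_spec("unilateral_crush", 0.6,
                                      side = "left", falloff = 0.15))
  left <- tpl$points[, "y"] > 0.3 * max(tpl$points[, "y"])
  right <- tpl$points[, "y"] < 0.3 * min(tpl$points[, "y"])
  expect_true(all(out$points[left, "y"] < tpl$points[left, "y"]))
  expect_equal(out$points[right, "y"], tpl$points[right, "y"],
               tolerance = 1e-12)
  # breaks the bilateral symmetry (the taphonomic signal)
  expect_false(isTRUE(all.equal(abs(out$points["24", "y"]),
                                abs(out$points["52", "y"]))))
})

test_that("caudal rotation leaves the rostrum bit-identical and matches a rotation-matrix oracle", {
  tpl <- skull_template()
  theta <- 0.2
  out <- deform(tpl, deformation_spec("caudal_rotation", theta,
                                      hinge_fraction = 0.5))
  x <- tpl$points[, "x"]
  xh <- min(x) + 0.5 * diff(range(x))
  zc <- mean(range(tpl$points[, "z"]))
  rostral <- x <= xh
  expect_identical(out$points[rostral, ], tpl$points[rostral, ])
  # explicit 2x2 rotation applied pointwise in the x-z plane
  for (id in rownames(tpl$points)[!rostral]) {
    dx <- tpl$points[id, "x"] - xh
    dz <- tpl$points[id, "z"] - zc
    expect_equal(unname(out$points[id, "x"]),
                 xh + cos(theta) * dx + sin(theta) * dz, tolerance = 1e-12)
    expect_equal(unname(out$points[id, "z"]),
                 zc - sin(theta) * dx + cos(theta) * dz, tolerance = 1e-12)
    expect_equal(out$points[id, "y"], tpl$points[id, "y"],
                 ignore_attr = TRUE)
  }
})

test_that("operator composition is ordered", {
  tpl <- skull_template()
  a <- deformation_spec("dorsoventral_compression", 0.6)
  b <- deformation_spec("caudal_rotation", 0.3)
  ab <- deform(tpl, list(a, b))$points
  ba <- deform(tpl, list(b, a))$points
  expect_false(isTRUE(all.equal(ab, ba)))
})

test_that("invalid deformation parameters are rejected", {
  expect_error(deformation_spec("dorsoventral_compression", 0), "\\(0, 1\\]")
  expect_error(deformation_spec("dorsoventral_compression", 1.2), "\\(0, 1\\]")
  expect_error(deformation_spec("caudal_rotation", 2), "radians")
  expect_error(deformation_spec("unilateral_crush", 0.5, hinge_fraction = 2),
               "hinge_fraction")
  expect_error(deformation_spec("whatever", 0.5))
})

test_that("cohort simulation is reproducible and honours its spec", {
  tpl <- skull_template()
  a <- simulate_cohort(tpl, cohort_spec(seed = 7))
  b <- simulate_cohort(tpl, cohort_spec(seed = 7))
  expect_identical(lapply(a, `[[`, "points"), lapply(b, `[[`, "points"))
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  c_ <- simulate_cohort(tpl, cohort_spec(seed = 8))
  expect_false(identical(a[[1]]$points, c_[[1]]$points))

  truth <- attr(a, "truth")
  expect_equal(nrow(truth), 28)
  expect_equal(sum(truth$age_class == "juvenile"), 3)
  expect_error(cohort_spec(n_specimens = 2), "at least 3")
  expect_error(cohort_spec(mode_mixture = list(
    dorsoventral_compression = list(weight = 0.5, magnitude = c(0.6, 1)))),
    "sum to 1")
})

test_that("a noiseless single-mode cohort at fixed magnitude is shape-constant", {
  tpl <- skull_template()
  cs <- cohort_spec(n_specimens = 5,
                    mode_mixture = list(dorsoventral_compression =
                                          list(weight = 1,
                                               magnitude = c(0.7, 0.7))),
                    individual_variation_sd = 0, digitizing_noise_sd = 0,
                    n_juveniles = 0, seed = 1)
  co <- simulate_cohort(tpl, cs)
  for (i in 2:5) expect_equal(co[[i]]$points, co[[1]]$points)
  m <- shape_pca(gpa(apply_exclusions(co, psittacosaur_scheme())$configs))
  expect_true(length(m$eigenvalues) == 0 || all(m$eigenvalues < 1e-15))
})

test_that("a single dominant mode is recovered as PC1 with high alignment", {
  tpl <- skull_template()
  cs <- cohort_spec(n_specimens = 15,
                    mode_mixture = list(dorsoventral_compression =
                                          list(weight = 1,
                                               magnitude = c(0.6, 1))),
                    individual_variation_sd = 0.3, digitizing_noise_sd = 0.1,
                    n_juveniles = 0, seed = 5)
  co <- simulate_cohort(tpl, cs)
  m <- shape_pca(gpa(apply_exclusions(co, psittacosaur_scheme())$configs))
  rr <- recovery_report(co, m, tpl)
  row <- rr$modes[rr$modes$mode == "dorsoventral_compression", ]
  expect_identical(row$best_pc, 1L)
  expect_gt(row$cosine, 0.95)
})

test_that("juveniles occupy a displaced region of the morphospace", {
  tpl <- skull_template()
  # mild taphonomic deformation so the comparison is between the juvenile
  # shape offset and individual variation, as in the displacement condition
  mild <- list(dorsoventral_compression = list(weight = 0.5,
                                               magnitude = c(0.9, 1)),
               mediolateral_compression = list(weight = 0.5,
                                               magnitude = c(0.9, 1)))
  co <- simulate_cohort(tpl, cohort_spec(
    n_specimens = 20, n_juveniles = 6, juvenile_scale = c(0.45, 0.55),
    mode_mixture = mild,
    individual_variation_sd = 0.3, digitizing_noise_sd = 0.1, seed = 12))
  truth <- attr(co, "truth")
  m <- shape_pca(gpa(apply_exclusions(co, psittacosaur_scheme())$configs))
  juv <- truth$age_class == "juvenile"
  sc <- m$scores[, 1:3]
  centroid_dist <- sqrt(sum((colMeans(sc[juv, ]) - colMeans(sc[!juv, ]))^2))
  within <- mean(sqrt(rowSums(sweep(sc[!juv, ], 2, colMeans(sc[!juv, ]))^2)))
  expect_gt(centroid_dist, within)
})

test_that("truth sidecars round-trip with the cohort files", {
  tpl <- skull_template()
  co <- simulate_cohort(tpl, cohort_spec(n_specimens = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_true(file.exists(paste0(path, ".truth.json")))
  back <- read_landmarks(path, "csv")
  expect_identical(lapply(back, `[[`, "points"),
                   lapply(unclass(co), `[[`, "points"))
  side <- jsonlite::read_json(paste0(path, ".truth.json"),
                              simplifyVector = TRUE)
  expect_equal(side$seed, 3)
  expect_equal(side$truth$specimen, attr(co, "truth")$specimen)
})
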