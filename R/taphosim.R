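## Template landmark positions as fractions of skull length (xf, rostrum at
## 0), half-width (yf) and height (zf), for the midline and right-side ids of
## the bundled 56-landmark scheme. Left-side ids 31-56 mirror ids 3-28 across
## the sagittal plane. Positions follow the anatomical labels: naris ring
## rostral and low, orbit ring mid-skull, temporal fenestrae caudal, jugal
## horn at maximal width, supratemporal fenestrae on the skull roof.
.template_frac <- data.frame(
  id = 1:30,
  xf = c(0.00, 0.08, 0.30, 0.09, 0.12, 0.15, 0.12, 0.38, 0.45, 0.52, 0.45,
         0.55, 0.62, 0.68, 0.74, 0.68, 0.60, 0.66, 0.52, 0.78, 0.78, 0.82,
         0.95, 0.58, 0.76, 0.82, 0.88, 0.82, 0.82, 0.45),
  yf = c(0.00, 0.00, 0.15, 0.30, 0.30, 0.30, 0.30, 0.45, 0.42, 0.45, 0.48,
         0.40, 0.48, 0.46, 0.48, 0.50, 0.52, 0.52, 0.38, 0.42, 0.44, 0.40,
         0.30, 1.00, 0.18, 0.10, 0.18, 0.26, 0.00, 0.00),
  zf = c(0.35, 0.75, 0.95, 0.55, 0.62, 0.55, 0.48, 0.65, 0.80, 0.65, 0.50,
         0.88, 0.45, 0.58, 0.45, 0.32, 0.25, 0.20, 0.85, 0.55, 0.25, 0.40,
         0.80, 0.38, 0.92, 0.95, 0.92, 0.92, 1.00, 0.92))

#' Parametric bilaterally symmetric skull landmark template
#'
#' Builds an idealized 56-landmark skull configuration consistent with the
#' bundled psittacosaurid scheme: rostral landmarks near x = 0, the naris,
#' orbit and temporal-fenestra rings as planar loops, the jugal-horn
#' landmarks at maximal lateral excursion, and the squamosal/quadrate
#' landmarks caudally. The template is exactly mirror-symmetric across the
#' sagittal (x-z) plane: paired landmarks map onto each other under
#' `y -> -y` and midline landmarks have `y = 0`. Construction is fully
#' deterministic.
#'
#' @param length,width,height overall skull dimensions in mm (defaults 200,
#'   140, 90 — an adult-sized skull, wider than tall).
#' @param jugal_flare extra lateral offset of the jugal-horn landmark beyond
#'   the half-width (mm, default 10).
#' @param scheme the landmark scheme (default [psittacosaur_scheme()]).
#' @return A `landmark_config` with 56 landmarks and adult metadata.
#' @export
skull_template <- function(length = 200, width = 140, height = 90,
                           jugal_flare = 10, scheme = psittacosaur_scheme()) {
  if (length <= 0 || width <= 0 || height <= 0 || jugal_flare < 0)
    stop("skull dimensions must be positive")
  tf <- .template_frac
  right <- cbind(x = tf$xf * length,
                 y = -(tf$yf * (width / 2) +
                         ifelse(tf$id == 24, jugal_flare, 0)),
                 z = tf$zf * height)
  rownames(right) <- tf$id
  ## midline landmarks stay on y = 0 by construction (yf = 0)
  left <- right[as.character(3:28), , drop = FALSE]
  left[, "y"] <- -left[, "y"]
  rownames(left) <- 31:56
  pts <- rbind(right, left)
  pts <- pts[as.character(scheme$ids), , drop = FALSE]
  landmark_config("template", pts,
                  metadata = specimen_metadata(
                    nominal_taxon = "synthetic",
                    age_class = "adult",
                    skull_length = length,
                    source = "taphomorph::skull_template"))
}

#' Taphonomic deformation specification
#'
#' A parametric operator emulating a burial-deformation style
#' (taphomorphotype):
#'
#' * `dorsoventral_compression` — z offsets from the mid-height plane
#'   multiplied by `magnitude` (a compression factor c in (0, 1]); uniform,
#'   or graded caudally when `hinge_fraction` is supplied.
#' * `mediolateral_compression` — y offsets from the sagittal plane
#'   multiplied by c.
#' * `unilateral_crush` — y compressed toward the midline by c on one `side`
#'   only, smoothly graded across a band of relative width `falloff` so the
#'   midline stays continuous.
#' * `caudal_rotation` — landmarks caudal to the hinge rigidly rotated by
#'   `magnitude` (an angle in radians) about the mediolateral axis through
#'   the hinge; the rostrum is untouched, exaggerating its apparent length.
#' * `allometric_juvenile` — isotropic scale `magnitude` (s in (0, 1]) plus
#'   the juvenile shape offset (relatively enlarged orbits, shortened
#'   rostrum) proportional to 1 - s.
#'
#' @param mode one of the five mode names above.
#' @param magnitude mode-specific parameter (see above). `1` (or `0` for
#'   `caudal_rotation`) is the identity.
#' @param side `"left"` or `"right"` (unilateral_crush only).
#' @param hinge_fraction rostrocaudal hinge position as a fraction of skull
#'   length (default 0.6); used by `caudal_rotation` and by caudally graded
#'   compression. `NULL` for uniform compression.
#' @param falloff smoothness of spatially graded crushing, as a fraction of
#'   the relevant dimension (default 0.15).
#' @return Object of class `deformation_spec`.
#' @export
deformation_spec <- function(mode = c("dorsoventral_compression",
                                      "mediolateral_compression",
                                      "unilateral_crush",
                                      "caudal_rotation",
                                      "allometric_juvenile"),
                             magnitude, side = c("left", "right"),
                             hinge_fraction = NULL, falloff = 0.15) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  if (mode %in% c("dorsoventral_compression", "mediolateral_compression",
                  "unilateral_crush", "allometric_juvenile")) {
    if (magnitude <= 0 || magnitude > 1)
      stop("compression/scale factor must be in (0, 1]")
  } else if (abs(magnitude) > pi / 2) {
    stop("rotation angle must be within [-pi/2, pi/2] radians")
  }
  if (!is.null(hinge_fraction) &&
      (hinge_fraction < 0 || hinge_fraction > 1))
    stop("hinge_fraction must be in [0, 1]")
  if (falloff < 0) stop("falloff must be nonnegative")
  structure(list(mode = mode, magnitude = magnitude, side = side,
                 hinge_fraction = hinge_fraction, falloff = falloff),
            class = "deformation_spec")
}

.smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

## orbit-ring and rostral-region ids used by the juvenile shape offset
.orbit_ids <- c(8:11, 36:39)

#' Apply taphonomic deformation operators to a configuration
#'
#' Operators compose left-to-right when `spec` is a list; order matters and
#' is preserved in the output metadata.
#'
#' @param config a `landmark_config`.
#' @param spec a `deformation_spec` or a list of them.
#' @return The deformed `landmark_config`.
#' @seealso [deformation_spec()] for the operator definitions.
#' @export
deform <- function(config, spec) {
  stopifnot(inherits(config, "landmark_config"))
  if (inherits(spec, "deformation_spec")) spec <- list(spec)
  pts <- config$points
  for (sp in spec) pts <- .apply_deformation(pts, sp)
  landmark_config(config$specimen_id, pts, missing = config$missing,
                  metadata = config$metadata)
}

.apply_deformation <- function(pts, sp) {
  stopifnot(inherits(sp, "deformation_spec"))
  ## identity magnitudes are exact no-ops (no floating-point round trip)
  if ((sp$mode == "caudal_rotation" && sp$magnitude == 0) ||
      (sp$mode != "caudal_rotation" && sp$magnitude == 1))
    return(pts)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  xr <- range(x)
  zc <- mean(range(z))
  yc <- mean(range(y))
  switch(sp$mode,
    dorsoventral_compression = {
      w <- if (is.null(sp$hinge_fraction)) 1
      else {
        xf <- (x - xr[1]) / diff(xr)
        if (sp$falloff > 0)
          .smoothstep((xf - sp$hinge_fraction) / sp$falloff)
        else as.numeric(xf > sp$hinge_fraction)
      }
      f <- 1 - (1 - sp$magnitude) * w
      pts[, 3] <- zc + f * (z - zc)
    },
    mediolateral_compression = {
      pts[, 2] <- yc + sp$magnitude * (y - yc)
    },
    unilateral_crush = {
      yrel <- y - yc
      half <- max(abs(yrel))
      u <- if (sp$side == "left") yrel else -yrel
      s <- if (sp$falloff > 0) .smoothstep(u / (sp$falloff * half))
           else as.numeric(u > 0)
      pts[, 2] <- yc + yrel * (1 - (1 - sp$magnitude) * s)
    },
    caudal_rotation = {
      hf <- if (is.null(sp$hinge_fraction)) 0.6 else sp$hinge_fraction
      xh <- xr[1] + hf * diff(xr)
      caudal <- x > xh
      th <- sp$magnitude
      dx <- x[caudal] - xh; dz <- z[caudal] - zc
      pts[caudal, 1] <- xh + cos(th) * dx + sin(th) * dz
      pts[caudal, 3] <- zc - sin(th) * dx + cos(th) * dz
    },
    allometric_juvenile = {
      s <- sp$magnitude
      o <- 1 - s
      ctr <- colMeans(pts)
      pts <- sweep(sweep(pts, 2, ctr), 2, rep(s, 3), `*`)
      pts <- sweep(pts, 2, ctr, `+`)
      ids <- as.integer(rownames(pts))
      ## enlarged orbits: push each orbit ring radially out from its center
      for (side_ids in list(intersect(ids, 8:11), intersect(ids, 36:39))) {
        if (length(side_ids) >= 2) {
          rows <- match(as.character(side_ids), rownames(pts))
          oc <- colMeans(pts[rows, , drop = FALSE])
          pts[rows, ] <- sweep(sweep(pts[rows, , drop = FALSE], 2, oc),
                               2, rep(1 + 0.5 * o, 3), `*`)
          pts[rows, ] <- sweep(pts[rows, , drop = FALSE], 2, oc, `+`)
        }
      }
      ## shortened rostrum: pull rostral landmarks caudally toward the
      ## quarter-length plane
      x2 <- pts[, 1]
      xr2 <- range(x2)
      xq <- xr2[1] + 0.25 * diff(xr2)
      rost <- x2 < xq
      pts[rost, 1] <- x2[rost] + 0.3 * o * (xq - x2[rost])
    },
    stop("unknown deformation mode: ", sp$mode))
  pts
}

#' Simulated-cohort specification
#'
#' Defines the composition of a synthetic cohort: how many specimens, the
#' mixture of taphonomic deformation modes and their magnitude ranges
#' (uniform draws), the per-landmark noise levels, and the number of
#' juveniles. Defaults emulate a 28-skull fossil cohort dominated by
#' dorsoventral and mediolateral compression, with occasional unilateral
#' crushing and caudal rotation, three juveniles, and digitizing noise small
#' relative to individual variation.
#'
#' @param n_specimens cohort size (default 28, >= 3).
#' @param mode_mixture named list: each element is `list(weight =, magnitude
#'   = c(lo, hi))`, names being [deformation_spec()] modes. Weights must be
#'   nonnegative and sum to 1.
#' @param individual_variation_sd per-coordinate biological variation SD in
#'   mm (default 1.5 on a ~200 mm skull).
#' @param digitizing_noise_sd per-coordinate measurement noise SD in mm
#'   (default 0.5).
#' @param n_juveniles number of specimens receiving the juvenile size/shape
#'   operator first (default 3).
#' @param juvenile_scale range of the juvenile isotropic scale factor
#'   (default c(0.4, 0.6)).
#' @param assignment `"single"` (default): each specimen receives one mode
#'   drawn from the mixture weights — distinct taphomorphotypes, as when
#'   different burial events crush different skulls in different ways.
#'   `"compose"`: every specimen receives every mode, each magnitude drawn
#'   independently from its range — continuous co-occurring deformation.
#'   Under `"compose"` the deformation magnitudes are statistically
#'   independent across modes, so the shape covariance is diagonal in the
#'   mode basis and PCA can recover the generating directions; under
#'   `"single"` the cluster structure itself adds a between-mode covariance
#'   term that rotates the PC axes away from the pure mode directions.
#' @param seed integer RNG seed; the cohort is fully reproducible from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_specimens = 28,
                        mode_mixture = list(
                          dorsoventral_compression =
                            list(weight = 0.4, magnitude = c(0.6, 0.95)),
                          mediolateral_compression =
                            list(weight = 0.3, magnitude = c(0.7, 0.95)),
                          unilateral_crush =
                            list(weight = 0.2, magnitude = c(0.6, 0.9)),
                          caudal_rotation =
                            list(weight = 0.1, magnitude = c(0.05, 0.3))),
                        individual_variation_sd = 1.5,
                        digitizing_noise_sd = 0.5,
                        n_juveniles = 3,
                        juvenile_scale = c(0.4, 0.6),
                        assignment = c("single", "compose"),
                        seed = 1) {
  assignment <- match.arg(assignment)
  if (n_specimens < 3) stop("n_specimens must be at least 3")
  w <- vapply(mode_mixture, `[[`, numeric(1), "weight")
  if (any(w < 0)) stop("mixture weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (individual_variation_sd < 0 || digitizing_noise_sd < 0)
    stop("noise standard deviations must be nonnegative")
  if (n_juveniles < 0 || n_juveniles > n_specimens)
    stop("n_juveniles must be between 0 and n_specimens")
  structure(list(n_specimens = as.integer(n_specimens),
                 mode_mixture = mode_mixture,
                 individual_variation_sd = individual_variation_sd,
                 digitizing_noise_sd = digitizing_noise_sd,
                 n_juveniles = as.integer(n_juveniles),
                 juvenile_scale = juvenile_scale,
                 assignment = assignment,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of taphonomically deformed skulls
#'
#' For each specimen a deformation mode is drawn from the mixture, its
#' magnitude drawn uniformly from the mode's range, and the operator applied
#' to the template; juveniles receive the allometric size/shape operator
#' first. Independent isotropic Gaussian perturbations are then added per
#' landmark: individual (biological) variation followed by digitizing noise.
#' The generating truth (mode, magnitude, side, age class) is attached as the
#' `"truth"` attribute, and everything is reproducible from the spec's seed.
#'
#' @param template a `landmark_config`, usually [skull_template()].
#' @param spec a [cohort_spec()].
#' @return List of `landmark_config` objects (class `taphomorph_cohort`) with
#'   attributes `truth` (data frame) and `seed`.
#' @export
simulate_cohort <- function(template = skull_template(),
                            spec = cohort_spec()) {
  stopifnot(inherits(template, "landmark_config"),
            inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  k <- nrow(template$points)
  modes <- names(spec$mode_mixture)
  w <- vapply(spec$mode_mixture, `[[`, numeric(1), "weight")
  ids <- sprintf("sim%02d", seq_len(spec$n_specimens))
  truth <- data.frame(specimen = ids, mode = NA_character_,
                      magnitude = NA_real_, side = NA_character_,
                      age_class = "adult", juvenile_scale = NA_real_)
  if (spec$assignment == "compose")
    for (m in modes) truth[[paste0("mag_", m)]] <- NA_real_
  cohort <- vector("list", spec$n_specimens)
  for (i in seq_len(spec$n_specimens)) {
    ops <- list()
    juvenile <- i <= spec$n_juveniles
    if (juvenile) {
      s <- stats::runif(1, spec$juvenile_scale[1], spec$juvenile_scale[2])
      ops <- c(ops, list(deformation_spec("allometric_juvenile", s)))
      truth$age_class[i] <- "juvenile"
      truth$juvenile_scale[i] <- s
    }
    if (spec$assignment == "single") {
      mode <- sample(modes, 1, prob = w)
      rng <- spec$mode_mixture[[mode]]$magnitude
      mag <- stats::runif(1, rng[1], rng[2])
      side <- if (mode == "unilateral_crush")
        sample(c("left", "right"), 1) else "left"
      ops <- c(ops, list(deformation_spec(mode, mag, side = side)))
      truth$mode[i] <- mode
      truth$magnitude[i] <- mag
      truth$side[i] <- if (mode == "unilateral_crush") side else NA_character_
    } else {
      for (mode in modes) {
        rng <- spec$mode_mixture[[mode]]$magnitude
        mag <- stats::runif(1, rng[1], rng[2])
        side <- if (mode == "unilateral_crush")
          sample(c("left", "right"), 1) else "left"
        ops <- c(ops, list(deformation_spec(mode, mag, side = side)))
        truth[[paste0("mag_", mode)]][i] <- mag
      }
      truth$mode[i] <- "compose"
    }
    cf <- deform(template, ops)
    pts <- cf$points +
      matrix(stats::rnorm(3 * k, sd = spec$individual_variation_sd), k, 3) +
      matrix(stats::rnorm(3 * k, sd = spec$digitizing_noise_sd), k, 3)
    cohort[[i]] <- landmark_config(
      ids[i], pts, metadata = specimen_metadata(
        nominal_taxon = mode,
        age_class = if (juvenile) "juvenile" else "adult",
        source = sprintf("taphomorph::simulate_cohort seed=%d", spec$seed)))
  }
  structure(cohort, truth = truth, seed = spec$seed, modes = modes,
            class = c("taphomorph_cohort", "list"))
}

#' Deformation-axis recovery diagnostics
#'
#' Measures whether the PCA recovered the simulated deformation modes: for
#' each generating mode, the mode's direction vector is the difference
#' between the template deformed at a reference magnitude and the undeformed
#' template, both expressed in the model's frame (centered, unit size,
#' rotated onto the consensus, tangent-projected if the model was), and
#' normalized. The report gives the absolute cosine between each mode
#' direction and each PC loading, the best-matching PC, and the specimens'
#' true labels alongside their scores.
#'
#' @param cohort a `taphomorph_cohort` (its `"truth"` attribute is required).
#' @param model the `morphospace_model` fitted on that cohort.
#' @param template the generating template configuration.
#' @param reference_magnitude named numeric vector of reference magnitudes
#'   per mode (defaults: compression/crush 0.8, rotation 0.2 rad, juvenile
#'   scale 0.5).
#' @param n_pcs how many leading PCs to compare against (default 4).
#' @return Object of class `recovery_report`: `modes` (data frame `mode`,
#'   `best_pc`, `cosine` — the best single-axis |cos| — and `span_cosine`,
#'   the norm of the direction's projection onto the span of the compared
#'   PCs), `cosines` (mode x PC matrix of |cos|), `specimens` (truth labels
#'   joined with leading PC scores).
#' @export
recovery_report <- function(cohort, model, template = skull_template(),
                            reference_magnitude = NULL, n_pcs = 4) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop("cohort carries no truth labels")
  stopifnot(inherits(model, "morphospace_model"))
  defaults <- c(dorsoventral_compression = 0.8,
                mediolateral_compression = 0.8,
                unilateral_crush = 0.75,
                caudal_rotation = 0.2,
                allometric_juvenile = 0.5)
  if (!is.null(reference_magnitude))
    defaults[names(reference_magnitude)] <- reference_magnitude
  n_pcs <- min(n_pcs, length(model$eigenvalues))
  modes <- unique(truth$mode)
  if (any(modes == "compose"))
    modes <- attr(cohort, "modes")
  base <- .model_frame_vector(template$points, model)
  cosines <- t(vapply(modes, function(m) {
    sides <- unique(stats::na.omit(truth$side[truth$mode == m]))
    side <- if (length(sides)) sides[1] else "left"
    def <- deform(template, deformation_spec(m, defaults[[m]], side = side))
    d <- .model_frame_vector(def$points, model) - base
    d <- d / sqrt(sum(d^2))
    abs(as.vector(crossprod(model$loadings[, seq_len(n_pcs), drop = FALSE],
                            d)))
  }, numeric(n_pcs)))
  dimnames(cosines) <- list(modes, paste0("PC", seq_len(n_pcs)))
  best <- apply(cosines, 1, which.max)
  specimens <- cbind(truth,
                     as.data.frame(model$scores[, seq_len(n_pcs),
                                                drop = FALSE]))
  structure(list(
    modes = data.frame(mode = modes, best_pc = as.integer(best),
                       cosine = cosines[cbind(seq_along(modes), best)],
                       ## alignment with the whole retained subspace: norm of
                       ## the direction's projection onto span(PC1..PCn_pcs)
                       span_cosine = sqrt(rowSums(cosines^2)),
                       row.names = NULL),
    cosines = cosines, specimens = specimens),
    class = "recovery_report")
}

.model_frame_vector <- function(pts, model) {
  ## restrict to the model's landmark set (exclusions may have been applied
  ## downstream of the generating template)
  ids <- rownames(model$mean_shape)
  if (!is.null(ids) && !is.null(rownames(pts))) {
    if (!all(ids %in% rownames(pts)))
      stop("configuration lacks landmarks required by the model")
    pts <- pts[ids, , drop = FALSE]
  }
  x <- .center_scale(pts)$coords
  x <- x %*% optimal_rotation(x, model$consensus)
  v <- flatten_config(x)
  if (model$tangent) {
    chat <- flatten_config(model$consensus)
    chat <- chat / sqrt(sum(chat^2))
    v <- v + (1 - sum(v * chat)) * chat
  }
  v
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$modes)
  invisible(x)
}

#' Write a simulated cohort to landmark files with a truth sidecar
#'
#' @param cohort a `taphomorph_cohort`.
#' @param path landmark file path.
#' @param dialect landmark dialect (see [write_landmarks()]).
#' @param truth_path JSON sidecar path (default: `path` with `.truth.json`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, dialect = "csv",
                         truth_path = paste0(path, ".truth.json")) {
  write_landmarks(cohort, path, dialect = dialect)
  truth <- attr(cohort, "truth")
  jsonlite::write_json(list(seed = attr(cohort, "seed"), truth = truth),
                       truth_path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
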