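#' Optimal proper rotation (orthogonal Procrustes with no reflection)
#'
#' Returns the 3x3 proper rotation matrix `R` (determinant +1) minimizing
#' `||X R - target||` in the Frobenius norm, via singular value decomposition
#' with the determinant correction. Reflections are never returned: in
#' taphonomic data the left/right asymmetry is signal, and a reflection would
#' silently destroy it.
#'
#' @param x K x 3 matrix of (centered) coordinates to rotate.
#' @param target K x 3 matrix to rotate onto.
#' @return 3 x 3 rotation matrix with determinant +1.
#' @keywords internal
optimal_rotation <- function(x, target) {
  a <- crossprod(target, x)           # t(target) %*% x
  sv <- svd(a)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Procrustes distance between two aligned configurations
#'
#' Square root of the summed squared landmark distances after the optimal
#' proper rotation of `b` onto `a`. Symmetric, and zero exactly when the two
#' shapes are identical up to rotation. Inputs are expected to be centered
#' (as produced by [gpa()]); translation and scale are not removed here.
#'
#' @param a,b K x 3 coordinate matrices with equal landmark counts.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3)
    stop("configurations must be K x 3 with equal landmark counts")
  r <- optimal_rotation(b, a)
  sqrt(sum((b %*% r - a)^2))
}

.center_scale <- function(x) {
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  s <- sqrt(sum(xc^2))
  if (s == 0) stop("degenerate configuration: zero centroid size")
  list(coords = xc / s, size = s)
}

.check_not_collinear <- function(x, id) {
  xc <- sweep(x, 2, colMeans(x))
  if (qr(xc)$rank < 2)
    stop("degenerate (all-collinear) configuration: ", id)
}

#' Generalized Procrustes Analysis
#'
#' Superimposes a set of landmark configurations by removing position (each
#' configuration centered on its centroid), size (each rescaled to unit
#' centroid size; original sizes are kept for allometry tests), and
#' orientation (each rotated by the proper rotation minimizing its summed
#' squared distance to the consensus; consensus re-estimated until
#' convergence). The result is expressed in a canonical frame (consensus
#' rotated onto its principal axes with a deterministic sign convention), so
#' the output does not depend on how the input specimens happened to be
#' oriented.
#'
#' @param configs list of `landmark_config` objects (or bare K x 3 matrices)
#'   sharing one landmark set with no missing landmarks; at least 2.
#' @param tol convergence tolerance: root-summed-square change of the unit-
#'   size consensus between iterations (default 1e-10).
#' @param max_iter iteration cap (default 200). On hitting it the partial
#'   result is returned with `converged = FALSE` and a warning.
#' @return An object of class `aligned_ensemble`: list with `specimen_ids`,
#'   `aligned` (K x 3 x n array), `centroid_sizes` (original units),
#'   `consensus` (K x 3 arithmetic mean of the aligned configurations),
#'   `iterations`, `converged`, `residual_history` (summed squared distances
#'   to the consensus after each iteration) and `tangent` (FALSE; see
#'   [tangent_project()]).
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 200) {
  if (length(configs) < 2) stop("GPA needs at least 2 specimens")
  mats <- lapply(configs, function(cf) {
    if (inherits(cf, "landmark_config")) {
      if (length(cf$missing))
        stop("specimen ", cf$specimen_id, " has missing landmarks")
      cf$points
    } else as.matrix(cf)
  })
  ids <- lapply(mats, rownames)
  if (!is.null(ids[[1]])) {
    same <- vapply(ids, identical, logical(1), y = ids[[1]])
    if (!all(same)) stop("specimens must share the same landmark set")
  }
  k <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, integer(1)) != k))
    stop("specimens must share the same landmark set")
  if (k < 4) stop("at least 4 landmarks are required")
  sp_ids <- vapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    if (inherits(cf, "landmark_config")) cf$specimen_id else paste0("spec", i)
  }, character(1))
  for (i in seq_along(mats)) .check_not_collinear(mats[[i]], sp_ids[i])

  cs <- lapply(mats, .center_scale)
  x <- lapply(cs, `[[`, "coords")
  sizes <- vapply(cs, `[[`, numeric(1), "size")

  consensus <- x[[1]]                      # initial consensus: first specimen
  resid_hist <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    x <- lapply(x, function(xi) xi %*% optimal_rotation(xi, consensus))
    new_mean <- Reduce(`+`, x) / length(x)
    resid_hist <- c(resid_hist,
                    sum(vapply(x, function(xi) sum((xi - new_mean)^2),
                               numeric(1))))
    new_consensus <- new_mean / sqrt(sum(new_mean^2))
    if (sqrt(sum((new_consensus - consensus)^2)) < tol) {
      consensus <- new_consensus
      converged <- TRUE
      break
    }
    consensus <- new_consensus
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter,
            " iterations; returning partial result")

  ## canonical orientation: principal axes of the consensus, with each axis
  ## signed so the landmark of largest |coordinate| on it is positive, then
  ## the properness (det +1) restored on the last axis if needed
  mean_shape <- Reduce(`+`, x) / length(x)
  v <- eigen(crossprod(mean_shape), symmetric = TRUE)$vectors
  for (j in 1:3) {
    cj <- mean_shape %*% v[, j]
    if (cj[which.max(abs(cj))] < 0) v[, j] <- -v[, j]
  }
  if (det(v) < 0) v[, 3] <- -v[, 3]
  x <- lapply(x, function(xi) xi %*% v)
  mean_shape <- mean_shape %*% v

  aligned <- array(unlist(x), dim = c(k, 3, length(x)),
                   dimnames = list(rownames(mats[[1]]), c("x", "y", "z"),
                                   sp_ids))
  structure(
    list(specimen_ids = sp_ids, aligned = aligned, centroid_sizes =
           stats::setNames(sizes, sp_ids), consensus = mean_shape,
         iterations = iter, converged = converged,
         residual_history = resid_hist, tangent = FALSE),
    class = "aligned_ensemble")
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<aligned_ensemble> %d specimens x %d landmarks; ",
                     "%d GPA iterations (%s)%s\n"),
              length(x$specimen_ids), nrow(x$consensus), x$iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$tangent) "; tangent-projected" else ""))
  invisible(x)
}

#' Project an aligned ensemble onto the tangent space at the consensus
#'
#' Aligned shapes live on a curved manifold (the unit-size constraint); PCA
#' assumes a linear space. This orthogonal projection maps each aligned
#' configuration onto the hyperplane tangent to that manifold at the (unit-
#' size) consensus. The projection is idempotent and, for ensembles with
#' small shape variation, moves each coordinate by O(rho^2) where rho is the
#' Procrustes distance to the consensus.
#'
#' @param ensemble an `aligned_ensemble`.
#' @return The ensemble with projected coordinates, updated consensus, and
#'   `tangent = TRUE`.
#' @export
tangent_project <- function(ensemble) {
  stopifnot(inherits(ensemble, "aligned_ensemble"))
  chat <- flatten_config(ensemble$consensus)
  chat <- chat / sqrt(sum(chat^2))
  n <- dim(ensemble$aligned)[3]
  for (i in seq_len(n)) {
    xi <- flatten_config(ensemble$aligned[, , i])
    xi <- xi + (1 - sum(xi * chat)) * chat
    ensemble$aligned[, , i] <- unflatten_config(xi)
  }
  ensemble$consensus <- apply(ensemble$aligned, c(1, 2), mean)
  ensemble$tangent <- TRUE
  ensemble
}

#' Aligned coordinates as a long data frame
#'
#' @param ensemble an `aligned_ensemble`.
#' @return data frame with columns `specimen`, `landmark_id`, `x`, `y`, `z`,
#'   `centroid_size`.
#' @export
aligned_to_df <- function(ensemble) {
  stopifnot(inherits(ensemble, "aligned_ensemble"))
  k <- nrow(ensemble$consensus)
  ids <- rownames(ensemble$consensus)
  if (is.null(ids)) ids <- as.character(seq_len(k))
  do.call(rbind, lapply(seq_along(ensemble$specimen_ids), function(i) {
    data.frame(specimen = ensemble$specimen_ids[i], landmark_id = ids,
               x = ensemble$aligned[, 1, i], y = ensemble$aligned[, 2, i],
               z = ensemble$aligned[, 3, i],
               centroid_size = unname(ensemble$centroid_sizes[i]),
               row.names = NULL)
  }))
}
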