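#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance matrix (n-1 divisor) of the
#' flattened 3K aligned coordinates about their mean, partitioning the
#' ensemble's shape variance into orthogonal axes. By default the ensemble is
#' first projected onto the tangent space at the consensus (see
#' [tangent_project()]).
#'
#' Superimposition removes 7 degrees of freedom in 3D (3 translation, 3
#' rotation, 1 size), so trailing eigenvalues are numerically null; any
#' eigenvalue below `null_tol` times the largest is treated as exactly zero
#' and its component dropped. Each retained loading is signed so that its
#' element of largest magnitude is positive (PC signs are otherwise
#' arbitrary).
#'
#' @param ensemble an `aligned_ensemble` from [gpa()] with at least 3
#'   specimens.
#' @param tangent project onto the tangent space first (default TRUE). Set to
#'   FALSE to analyse the aligned coordinates as-is.
#' @param null_tol relative cutoff below which an eigenvalue counts as null
#'   (default 1e-12).
#' @return An object of class `morphospace_model`: `eigenvalues` (descending),
#'   `proportions` (fractions of total variance), `cumulative`, `scores`
#'   (n x P, centered columns), `loadings` (3K x P orthonormal columns),
#'   `center` (3K mean of the analysed coordinates), `mean_shape` (K x 3),
#'   `consensus` (the ensemble consensus, for projecting new specimens),
#'   `centroid_sizes`, `n_specimens`, `n_landmarks`, `tangent`.
#' @export
shape_pca <- function(ensemble, tangent = TRUE, null_tol = 1e-12) {
  stopifnot(inherits(ensemble, "aligned_ensemble"))
  n <- dim(ensemble$aligned)[3]
  if (n < 3) stop("PCA needs at least 3 specimens")
  if (tangent && !ensemble$tangent) ensemble <- tangent_project(ensemble)
  k <- nrow(ensemble$consensus)
  flat <- t(apply(ensemble$aligned, 3, flatten_config))  # n x 3K
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > null_tol * ev[1]
  ev <- ev[keep]
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  ## sign convention: largest-|.| element of each loading is positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (length(ev))
    colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(ev))
  rownames(scores) <- ensemble$specimen_ids
  structure(
    list(eigenvalues = ev, proportions = ev / sum(ev),
         cumulative = cumsum(ev) / sum(ev), scores = scores,
         loadings = loadings, center = pc$center,
         mean_shape = unflatten_config(pc$center,
                                       rownames(ensemble$consensus)),
         consensus = ensemble$consensus,
         centroid_sizes = ensemble$centroid_sizes,
         n_specimens = n, n_landmarks = k, tangent = ensemble$tangent),
    class = "morphospace_model")
}

#' @export
print.morphospace_model <- function(x, ...) {
  cat(sprintf("<morphospace_model> %d specimens, %d landmarks, %d non-null PCs\n",
              x$n_specimens, x$n_landmarks, length(x$eigenvalues)))
  print(utils::head(variance_table(x), 4))
  invisible(x)
}

#' Variance accounting table
#'
#' @param model a `morphospace_model`.
#' @return data frame with columns `pc`, `eigenvalue`, `proportion`,
#'   `cumulative` (proportions as fractions summing to 1).
#' @export
variance_table <- function(model) {
  stopifnot(inherits(model, "morphospace_model"))
  data.frame(pc = seq_along(model$eigenvalues),
             eigenvalue = model$eigenvalues,
             proportion = model$proportions,
             cumulative = model$cumulative,
             row.names = NULL)
}

#' Broken-stick expected variance proportions
#'
#' Expected proportion of the k-th largest piece when a unit stick is broken
#' at random into `p` pieces: `b_k = (1/p) * sum_{i=k}^{p} 1/i`. A PC is
#' conventionally judged interpretable when its observed variance proportion
#' exceeds this chance expectation.
#'
#' @param p number of components (>= 1).
#' @return numeric vector of `p` strictly decreasing thresholds summing to 1.
#' @export
broken_stick <- function(p) {
  p <- as.integer(p)
  if (is.na(p) || p < 1) stop("p must be a positive integer")
  rev(cumsum(1 / (p:1))) / p
}

#' Number of components to retain
#'
#' @param model a `morphospace_model`.
#' @param rule `"broken_stick"` (largest prefix of PCs whose proportions each
#'   strictly exceed the broken-stick thresholds, stopping at the first
#'   failure) or `"fixed_k"` (return `k` as configured; useful when components
#'   are retained by interpretability rather than by the stick rule).
#' @param k retained count for `rule = "fixed_k"` (default 4).
#' @return integer count (possibly 0 under `broken_stick`).
#' @export
select_components <- function(model, rule = c("broken_stick", "fixed_k"),
                              k = 4) {
  stopifnot(inherits(model, "morphospace_model"))
  rule <- match.arg(rule)
  if (rule == "fixed_k") return(as.integer(min(k, length(model$eigenvalues))))
  p <- length(model$eigenvalues)
  thr <- broken_stick(p)
  above <- model$proportions > thr
  first_fail <- which(!above)[1]
  if (is.na(first_fail)) p else first_fail - 1L
}

#' Per-axis 95% confidence bands of PC scores
#'
#' For each requested PC, the interval `mean +/- multiplier * sd` of the
#' specimen scores, with the sample (n-1) standard deviation and multiplier
#' 1.96 by default (the normal 95% band). Specimens outside a band differ
#' statistically from the mean of the whole sample on that axis — not
#' necessarily from any other group.
#'
#' @param model a `morphospace_model` with at least 2 specimens.
#' @param pcs integer vector of PC indices (default 1:4, capped at the number
#'   of non-null PCs).
#' @param multiplier half-width multiplier (default 1.96).
#' @return data frame of class `confidence_bands` with columns `pc`, `mean`,
#'   `sd`, `half_width`, `lower`, `upper`.
#' @export
confidence_bands <- function(model, pcs = 1:4, multiplier = 1.96) {
  stopifnot(inherits(model, "morphospace_model"))
  if (model$n_specimens < 2) stop("confidence bands need at least 2 specimens")
  if (multiplier <= 0) stop("multiplier must be positive")
  pcs <- pcs[pcs <= length(model$eigenvalues)]
  if (!length(pcs)) stop("requested PCs do not exist in the model")
  out <- do.call(rbind, lapply(pcs, function(j) {
    s <- model$scores[, j]
    m <- mean(s); sd_ <- stats::sd(s)
    data.frame(pc = j, mean = m, sd = sd_, half_width = multiplier * sd_,
               lower = m - multiplier * sd_, upper = m + multiplier * sd_)
  }))
  rownames(out) <- NULL
  class(out) <- c("confidence_bands", class(out))
  out
}

#' Flag specimens outside the confidence bands
#'
#' @param model the `morphospace_model` the bands were computed from.
#' @param bands output of [confidence_bands()].
#' @return list of class `outlier_report`: `per_pc` (named list mapping
#'   `"PC<j>"` to the specimen ids strictly outside that band) and `flags`
#'   (n x length(pcs) logical matrix).
#' @export
flag_outliers <- function(model, bands) {
  stopifnot(inherits(model, "morphospace_model"),
            inherits(bands, "confidence_bands"))
  flags <- sapply(seq_len(nrow(bands)), function(r) {
    s <- model$scores[, bands$pc[r]]
    s < bands$lower[r] | s > bands$upper[r]
  })
  flags <- matrix(flags, nrow = model$n_specimens,
                  dimnames = list(rownames(model$scores),
                                  paste0("PC", bands$pc)))
  per_pc <- lapply(seq_len(ncol(flags)), function(j)
    rownames(flags)[flags[, j]])
  names(per_pc) <- colnames(flags)
  structure(list(per_pc = per_pc, flags = flags), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  for (pc in names(x$per_pc)) {
    ids <- x$per_pc[[pc]]
    cat(pc, ": ", if (length(ids)) paste(ids, collapse = ", ")
        else "(none outside band)", "\n", sep = "")
  }
  invisible(x)
}

#' Reconstruct a shape along a PC axis
#'
#' Linear reconstruction `mean_shape + score * loading`, the basis of
#' wireframe figures showing what a strongly positive or negative score on an
#' axis looks like anatomically.
#'
#' @param model a `morphospace_model`.
#' @param pc PC index.
#' @param score coordinate along the axis (e.g. an observed extreme score).
#' @return K x 3 coordinate matrix.
#' @export
reconstruct_shape <- function(model, pc, score) {
  stopifnot(inherits(model, "morphospace_model"))
  if (pc < 1 || pc > length(model$eigenvalues)) stop("PC does not exist")
  v <- model$center + score * model$loadings[, pc]
  unflatten_config(v, rownames(model$mean_shape))
}

#' Project configurations into an existing morphospace
#'
#' Aligns new configurations (e.g. replicate digitizations of one specimen)
#' to the model's consensus — centering, unit-size scaling, optimal proper
#' rotation, and tangent projection if the model used it — then expresses
#' them as PC scores of the fitted model. The model itself is unchanged, so
#' scores of the original specimens keep their meaning.
#'
#' @param model a `morphospace_model`.
#' @param configs list of `landmark_config` objects (or K x 3 matrices) with
#'   the model's landmark set.
#' @return matrix of scores (one row per configuration) on the model's PCs.
#' @export
project_scores <- function(model, configs) {
  stopifnot(inherits(model, "morphospace_model"))
  if (inherits(configs, "landmark_config") || is.matrix(configs))
    configs <- list(configs)
  chat <- flatten_config(model$consensus)
  chat <- chat / sqrt(sum(chat^2))
  ids <- rownames(model$mean_shape)
  rows <- lapply(configs, function(cf) {
    x <- if (inherits(cf, "landmark_config")) cf$points else as.matrix(cf)
    if (!is.null(ids) && !is.null(rownames(x)) && all(ids %in% rownames(x)))
      x <- x[ids, , drop = FALSE]
    if (nrow(x) != model$n_landmarks)
      stop("configuration landmark count does not match the model")
    x <- .center_scale(x)$coords
    x <- x %*% optimal_rotation(x, model$consensus)
    v <- flatten_config(x)
    if (model$tangent) v <- v + (1 - sum(v * chat)) * chat
    (v - model$center) %*% model$loadings
  })
  out <- do.call(rbind, rows)
  nm <- vapply(configs, function(cf)
    if (inherits(cf, "landmark_config")) cf$specimen_id else NA_character_,
    character(1))
  if (!anyNA(nm)) rownames(out) <- nm
  out
}
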