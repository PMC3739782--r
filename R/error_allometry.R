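#' Replicate-digitization error protocol
#'
#' One specimen is digitized R times; the replicates are projected into the
#' morphospace (see [project_scores()]) and their Euclidean distances to the
#' replicate mean, restricted to the first few PCs, are compared with the
#' distances of all other specimens to that same mean. If the replicate cloud
#' does not overlap the other specimens, measurement error is negligible
#' relative to between-specimen shape differences.
#'
#' @param scores specimen x PC score matrix of the other specimens (the
#'   replicated specimen itself should not be among them).
#' @param replicates R x PC score matrix of the replicate digitizations
#'   (R >= 2), on the same PC axes.
#' @param pcs PC indices to use (default 1:4).
#' @return Object of class `error_sample`: `mean_vector` (replicate mean on
#'   the chosen PCs), `replicate_distances`, `other_distances` (named by
#'   specimen), `overlap` (TRUE iff the farthest replicate is at least as far
#'   from the mean as the nearest other specimen), `pcs`.
#' @export
error_distances <- function(scores, replicates, pcs = 1:4) {
  scores <- as.matrix(scores); replicates <- as.matrix(replicates)
  if (nrow(replicates) < 2) stop("at least 2 replicates are required")
  if (ncol(scores) != ncol(replicates))
    stop("replicates and scores must share PC axes")
  pcs <- pcs[pcs <= ncol(scores)]
  if (!length(pcs)) stop("no requested PC exists in the score matrices")
  rs <- replicates[, pcs, drop = FALSE]
  os <- scores[, pcs, drop = FALSE]
  mv <- colMeans(rs)
  rd <- sqrt(rowSums(sweep(rs, 2, mv)^2))
  od <- sqrt(rowSums(sweep(os, 2, mv)^2))
  structure(list(mean_vector = mv, replicate_distances = rd,
                 other_distances = od,
                 overlap = max(rd) >= min(od), pcs = pcs),
            class = "error_sample")
}

#' @export
print.error_sample <- function(x, ...) {
  cat(sprintf(paste0("<error_sample> %d replicates (max distance %.4g), ",
                     "%d other specimens (min distance %.4g): %s\n"),
              length(x$replicate_distances), max(x$replicate_distances),
              length(x$other_distances), min(x$other_distances),
              if (x$overlap) "OVERLAP" else "no overlap"))
  invisible(x)
}

## all permutations of 1..n as an (n!) x n matrix; used for the exact
## Spearman null at small n
.perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank tests of PC scores against centroid size (allometry)
#'
#' Rank correlation is used instead of a parametric slope test because fossil
#' cohorts rarely have normally distributed centroid sizes. Ties receive
#' midranks. Two-sided p-values come from full permutation enumeration for
#' n <= 10 and from the t approximation
#' `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom otherwise.
#'
#' @param scores specimen x PC score matrix.
#' @param sizes per-specimen centroid sizes (positive), same length/order as
#'   the score rows.
#' @param pcs PC indices to test (default 1:4).
#' @param subset_label label recorded in the result (e.g. `"all-28"`).
#' @return data frame with columns `pc`, `r_s`, `p_value`, `n`,
#'   `subset_label`.
#' @export
spearman_allometry <- function(scores, sizes, pcs = 1:4,
                               subset_label = "all") {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (length(sizes) != n) stop("one size per specimen is required")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("sizes must be positive and finite")
  if (n < 4) stop("at least 4 specimens are required")
  if (stats::sd(sizes) == 0)
    stop("sizes are constant: rank correlation is undefined")
  pcs <- pcs[pcs <= ncol(scores)]
  yr <- rank(sizes)                         # midranks for ties
  out <- do.call(rbind, lapply(pcs, function(j) {
    xr <- rank(scores[, j])
    r <- suppressWarnings(stats::cor(xr, yr))
    p <- if (is.na(r)) NA_real_
    else if (n <= 10) .spearman_exact_p(xr, yr, r)
    else {
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      min(1, 2 * stats::pt(-abs(tt), df = n - 2))
    }
    data.frame(pc = j, r_s = r, p_value = p, n = n,
               subset_label = subset_label)
  }))
  rownames(out) <- NULL
  out
}

.spearman_exact_p <- function(xr, yr, r_obs) {
  n <- length(xr)
  perms <- .perm_matrix(n)
  ys <- as.vector(scale(yr))
  xs <- as.vector(scale(xr))
  r_all <- (matrix(ys[perms], nrow(perms), n) %*% xs) / (n - 1)
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

#' Removal-based sensitivity re-analysis
#'
#' Drops the named specimens and re-runs the whole shape analysis —
#' superimposition, PCA and allometry tests — on the reduced cohort. This is
#' a full re-fit, not a projection of the old scores: removing specimens
#' changes the consensus and hence every aligned coordinate.
#'
#' @param configs list of `landmark_config` objects (exclusions already
#'   applied; no missing landmarks).
#' @param drop character vector of specimen ids to remove (may be empty, in
#'   which case the result is identical to the full analysis).
#' @param pcs PC indices for the allometry tests (default 1:4).
#' @param tangent,gpa_tol,max_iter pipeline settings passed through to
#'   [gpa()] and [shape_pca()].
#' @param subset_label label for the result; defaults to `"all-<n>"` or
#'   `"minus-<ids>"`.
#' @return list with `model` (the re-fitted `morphospace_model`), `allometry`
#'   (data frame from [spearman_allometry()]) and `subset_label`.
#' @export
sensitivity_rerun <- function(configs, drop = character(), pcs = 1:4,
                              tangent = TRUE, gpa_tol = 1e-10,
                              max_iter = 200, subset_label = NULL) {
  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  unknown <- setdiff(drop, ids)
  if (length(unknown))
    stop("unknown specimen id(s) in drop list: ",
         paste(unknown, collapse = ", "))
  keep <- !(ids %in% drop)
  if (sum(keep) < 4) stop("dropping would leave fewer than 4 specimens")
  sub <- configs[keep]
  if (is.null(subset_label))
    subset_label <- if (length(drop)) paste0("minus-", paste(drop, collapse = "+"))
                    else paste0("all-", sum(keep))
  ens <- gpa(sub, tol = gpa_tol, max_iter = max_iter)
  model <- shape_pca(ens, tangent = tangent)
  allom <- spearman_allometry(model$scores, model$centroid_sizes, pcs = pcs,
                              subset_label = subset_label)
  list(model = model, allometry = allom, subset_label = subset_label)
}
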