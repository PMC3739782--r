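# Independent oracles and fixture builders shared across the test files.

# rotation matrix from z-y-x Euler angles
euler_rotation <- function(a, b, c) {
  rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, 3,
               byrow = TRUE)
  rz %*% ry %*% rx
}

random_rotation <- function() {
  euler_rotation(stats::runif(1, -pi, pi), stats::runif(1, -pi / 2, pi / 2),
                 stats::runif(1, -pi, pi))
}

# brute-force rotation search: minimal ||X R - target||^2 over proper
# rotations, coarse Euler grid refined down to ~1e-3 rad resolution
grid_search_rotation <- function(x, target) {
  obj <- function(p) sum((x %*% euler_rotation(p[1], p[2], p[3]) - target)^2)
  best <- NULL; best_val <- Inf
  gr <- seq(-pi, pi, by = 0.35)
  grb <- seq(-pi / 2, pi / 2, by = 0.35)
  for (a in gr) for (b in grb) for (c in gr) {
    v <- obj(c(a, b, c))
    if (v < best_val) { best_val <- v; best <- c(a, b, c) }
  }
  step <- 0.35
  while (step > 2e-4) {
    step <- step / 2
    grid <- expand.grid(a = best[1] + step * (-2:2),
                        b = best[2] + step * (-2:2),
                        c = best[3] + step * (-2:2))
    vals <- apply(grid, 1, obj)
    i <- which.min(vals)
    if (vals[i] < best_val) { best_val <- vals[i]; best <- as.numeric(grid[i, ]) }
  }
  ## final local polish of the grid optimum (still derivative-free and
  ## independent of the SVD solver under test)
  fit <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value < best_val) { best_val <- fit$value; best <- fit$par }
  list(value = best_val, rotation = euler_rotation(best[1], best[2], best[3]))
}

# cyclic Jacobi eigen-decomposition of a symmetric matrix
jacobi_eigen <- function(s, tol = 1e-12, max_sweeps = 100) {
  n <- nrow(s)
  v <- diag(n)
  for (sweep in seq_len(max_sweeps)) {
    off <- sqrt(sum(s[upper.tri(s)]^2))
    if (off < tol) break
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      if (abs(s[p, q]) < tol / n) next
      theta <- 0.5 * atan2(2 * s[p, q], s[q, q] - s[p, p])
      c_ <- cos(theta); s_ <- sin(theta)
      g <- diag(n); g[p, p] <- c_; g[q, q] <- c_; g[p, q] <- s_; g[q, p] <- -s_
      s <- t(g) %*% s %*% g
      v <- v %*% g
    }
  }
  ord <- order(diag(s), decreasing = TRUE)
  list(values = diag(s)[ord], vectors = v[, ord, drop = FALSE])
}

# exact Spearman permutation p by direct looping over permutations,
# independent of the package's vectorized enumeration
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

spearman_perm_oracle <- function(x, y) {
  xr <- rank(x); yr <- rank(y)
  r_obs <- stats::cor(xr, yr)
  rs <- vapply(all_perms(length(y)), function(p) stats::cor(xr, yr[p]),
               numeric(1))
  list(r = r_obs, p = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

# small fixture configurations -----------------------------------------------

toy_tetrahedron <- function(jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  m <- m + matrix(stats::rnorm(12, sd = jitter), 4, 3)
  rownames(m) <- 1:4
  m
}

tiny_configs <- function(n = 2, k = 4, seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rnorm(k * 3, sd = 10), k, 3,
                 dimnames = list(1:k, c("x", "y", "z")))
  lapply(seq_len(n), function(i)
    landmark_config(sprintf("toy%02d", i),
                    base + matrix(stats::rnorm(k * 3, sd = 0.2), k, 3)))
}

# cohort fixture with the allometric signal confined to the juvenile class:
# near-undeformed adults whose sizes vary independently of shape, and a
# size-graded juvenile class carrying the size-linked shape offset
juvenile_allometry_cohort <- function(seed) {
  tpl <- skull_template()
  tiny <- list(dorsoventral_compression = list(weight = 0.5,
                                               magnitude = c(0.95, 1)),
               mediolateral_compression = list(weight = 0.5,
                                               magnitude = c(0.95, 1)))
  co <- simulate_cohort(tpl, cohort_spec(
    mode_mixture = tiny, seed = seed, n_juveniles = 8,
    juvenile_scale = c(0.3, 0.6),
    individual_variation_sd = 0.15, digitizing_noise_sd = 0.05))
  truth <- attr(co, "truth")
  set.seed(seed + 1000)
  for (i in seq_along(co))
    if (truth$age_class[i] == "adult")
      co[[i]]$points <- co[[i]]$points * stats::runif(1, 0.8, 1.25)
  co
}

# a minimal morphospace_model stub for functions that only read scores /
# proportions (confidence bands, component selection)
stub_model <- function(scores = NULL, eigenvalues = NULL) {
  if (is.null(eigenvalues)) {
    scores <- as.matrix(scores)
    eigenvalues <- apply(scores, 2, stats::var)
  }
  if (is.null(scores))
    scores <- matrix(0, 2, length(eigenvalues),
                     dimnames = list(NULL, paste0("PC",
                                                  seq_along(eigenvalues))))
  structure(list(eigenvalues = eigenvalues,
                 proportions = eigenvalues / sum(eigenvalues),
                 cumulative = cumsum(eigenvalues) / sum(eigenvalues),
                 scores = scores, n_specimens = nrow(scores),
                 n_landmarks = NA_integer_),
            class = "morphospace_model")
}
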