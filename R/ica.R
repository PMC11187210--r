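# Robust independent component analysis of an omics compendium.
#
# The compendium X (features x samples) is whitened by PCA to k dimensions
# and decomposed by symmetric FastICA (logcosh contrast) from many random
# starts; pooled components are clustered by absolute-correlation distance
# and clusters reproduced in at least half the runs contribute one robust
# component (the cluster centrotype). Activities come from projecting X on
# the pseudo-inverse of M.

fastica_symmetric <- function(Z, seed, max_iter = 200L, tol = 1e-6) {
  k <- ncol(Z)
  n <- nrow(Z)
  set.seed(seed)
  W <- matrix(stats::rnorm(k * k), k, k)
  sym_decorrelate <- function(W) {
    sv <- svd(W)
    sv$u %*% t(sv$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    S <- Z %*% W
    G <- tanh(S)
    Gp <- 1 - G ^ 2
    W1 <- crossprod(Z, G) / n - sweep(W, 2, colMeans(Gp), "*")
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(colSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) {
      return(list(W = W, converged = TRUE, iterations = it))
    }
  }
  list(W = W, converged = FALSE, iterations = max_iter)
}

# orient so the largest-magnitude weight is positive, unit norm
orient_components <- function(M) {
  M <- sweep(M, 2, sqrt(colSums(M ^ 2)), "/")
  flip <- apply(M, 2, function(w) sign(w[which.max(abs(w))]))
  sweep(M, 2, flip, "*")
}

# classic DBSCAN on a precomputed distance matrix
dbscan_dist <- function(D, eps, min_pts) {
  n <- nrow(D)
  neighbors <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neighbors, length, 0L) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      for (q in neighbors[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Robust ICA decomposition of a compendium
#'
#' Runs FastICA `n_runs` times with distinct sub-seeds after PCA whitening
#' to `k` dimensions, clusters the pooled components by the distance
#' 1 - |Pearson r|, and keeps one centrotype per cluster reproduced in at
#' least half the runs. Component signs are oriented so the
#' largest-magnitude weight is positive, and columns of M have unit norm.
#'
#' @param X features x samples numeric matrix (an `omics_compendium`'s
#'   `values`, or any centered log-scale matrix), or an `omics_compendium`.
#' @param k whitening dimensionality; must be below both matrix dimensions.
#' @param n_runs number of FastICA restarts (default 10; use ~100 for
#'   production compendia).
#' @param seed master seed; all sub-seeds derive from it.
#' @param eps clustering neighborhood radius on 1 - |r| (default 0.1).
#' @param max_retries extra attempts for non-convergent runs.
#' @return object of class `ica_decomposition` with elements `M`
#'   (features x robust components, unit-norm columns), `A` (components x
#'   samples), `k`, `n_robust`, `n_runs`, `seed`, `component_ev`,
#'   `cumulative_ev`.
#' @export
run_robust_ica <- function(X, k, n_runs = 10L, seed = 1L, eps = 0.1,
                           max_retries = 3L) {
  if (inherits(X, "omics_compendium")) X <- X$values
  X <- as.matrix(X)
  stopifnot(k >= 1, k < min(dim(X)), n_runs >= 1)
  col_means <- colMeans(X)
  Xc <- sweep(X, 2, col_means)
  sv <- svd(Xc, nu = k, nv = 0)
  if (sv$d[k] < 1e-12 * sv$d[1]) {
    stop("requested dimensionality exceeds the numerical rank of X")
  }
  Z <- sv$u * sqrt(nrow(Xc))  # whitened: unit-variance, uncorrelated columns

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_runs * (1L + max_retries))
  pool <- vector("list", n_runs)
  run_of <- integer(0)
  next_seed <- n_runs
  for (r in seq_len(n_runs)) {
    fit <- fastica_symmetric(Z, sub_seeds[r])
    tries <- 0L
    while (!fit$converged && tries < max_retries) {
      next_seed <- next_seed + 1L
      fit <- fastica_symmetric(Z, sub_seeds[next_seed])
      tries <- tries + 1L
    }
    if (!fit$converged) {
      warning("FastICA run ", r, " did not converge; excluded")
      next
    }
    pool[[r]] <- orient_components(Z %*% fit$W)
  }
  used <- which(!vapply(pool, is.null, TRUE))
  if (!length(used)) stop("no FastICA run converged")
  comp <- do.call(cbind, pool[used])
  run_of <- rep(used, each = k)

  D <- 1 - abs(stats::cor(comp))
  min_pts <- ceiling(length(used) / 2)
  labels <- dbscan_dist(D, eps, min_pts)
  M_cols <- list()
  for (cl in setdiff(unique(labels), 0L)) {
    idx <- which(labels == cl)
    if (length(unique(run_of[idx])) < ceiling(length(used) / 2)) next
    # centrotype: member most correlated with the rest of its cluster
    sim <- abs(stats::cor(comp[, idx, drop = FALSE]))
    M_cols[[length(M_cols) + 1L]] <- comp[, idx[which.max(colSums(sim))]]
  }
  if (!length(M_cols)) stop("no robust components found at k = ", k)
  M <- orient_components(do.call(cbind, M_cols))
  rownames(M) <- rownames(X)
  colnames(M) <- paste0("IC", seq_len(ncol(M)))
  A <- solve(crossprod(M), crossprod(M, Xc))  # pseudo-inverse projection
  rownames(A) <- colnames(M)
  colnames(A) <- colnames(X)

  out <- structure(list(M = M, A = A, k = k, n_robust = ncol(M),
                        n_runs = n_runs, seed = seed, col_means = col_means),
                   class = "ica_decomposition")
  ev <- component_explained_variance(out, X)
  out$component_ev <- ev$component
  out$cumulative_ev <- ev$cumulative
  out
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("robust ICA decomposition: %d features, %d samples, k = %d\n",
              nrow(x$M), ncol(x$A), x$k))
  cat(sprintf("  %d robust components from %d runs (seed %d); cumulative EV %.3f\n",
              x$n_robust, x$n_runs, x$seed, x$cumulative_ev))
  invisible(x)
}

#' @export
summary.ica_decomposition <- function(object, ...) {
  data.frame(component = colnames(object$M),
             explained_variance = object$component_ev,
             max_abs_weight = apply(abs(object$M), 2, max),
             row.names = NULL)
}

#' Explained variance of each component and of the full decomposition
#'
#' Component j explains `1 - ||X - m_j a_j||^2 / ||X||^2` of the centered
#' matrix; the cumulative value uses the full reconstruction `M A`. Because
#' components are not exactly orthogonal the per-component values need not
#' sum to the cumulative value; both are reported.
#'
#' @param decomp an `ica_decomposition`.
#' @param X the matrix it was fit to (column-centered before comparison).
#' @return list with numeric vector `component` and scalar `cumulative`.
#' @export
component_explained_variance <- function(decomp, X) {
  if (inherits(X, "omics_compendium")) X <- X$values
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  total <- sum(Xc ^ 2)
  if (total == 0) stop("X has zero variance")
  comp_ev <- vapply(seq_len(ncol(decomp$M)), function(j) {
    resid <- Xc - decomp$M[, j, drop = FALSE] %*% decomp$A[j, , drop = FALSE]
    max(0, 1 - sum(resid ^ 2) / total)
  }, 0)
  cum_ev <- max(0, 1 - sum((Xc - decomp$M %*% decomp$A) ^ 2) / total)
  list(component = comp_ev, cumulative = cum_ev)
}

#' Choose the ICA dimensionality by a robust-component plateau
#'
#' Runs robust ICA at each candidate dimensionality and counts robust
#' components with more than one thresholded member. Returns the smallest
#' candidate whose count is within one component of the maximum.
#'
#' @param X features x samples matrix or `omics_compendium`.
#' @param candidate_ks ascending integer vector of dimensionalities.
#' @param n_runs,seed passed to [run_robust_ica()].
#' @param k2_cutoff membership threshold cutoff (see
#'   [threshold_component()]); lower it for feature sets much smaller
#'   than a full compendium.
#' @return selected dimensionality (integer); attribute `counts` carries
#'   the per-candidate robust non-single-feature component counts.
#' @export
select_dimensionality <- function(X, candidate_ks, n_runs = 10L, seed = 1L,
                                  k2_cutoff = 550) {
  stopifnot(!is.unsorted(candidate_ks))
  counts <- vapply(candidate_ks, function(k) {
    dec <- tryCatch(run_robust_ica(X, k, n_runs = n_runs, seed = seed),
                    error = function(e) NULL)
    if (is.null(dec)) return(0L)
    sum(vapply(seq_len(ncol(dec$M)), function(j) {
      length(threshold_component(dec$M[, j], cutoff = k2_cutoff)$members) > 1L
    }, TRUE))
  }, 0L)
  if (all(counts == 0L)) {
    stop("all candidate dimensionalities degenerate; counts: ",
         paste(counts, collapse = ", "))
  }
  k <- candidate_ks[which(counts >= max(counts) - 1L)[1]]
  attr(k, "counts") <- stats::setNames(counts, candidate_ks)
  k
}
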