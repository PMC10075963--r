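# histogram (Freedman-Diaconis) differential entropy of standardized x
hist_negentropy <- function(x) {
  z <- (x - mean(x)) / stats::sd(x)
  n <- length(z)
  h <- 2 * stats::IQR(z) / n^(1 / 3)
  if (h <= 0) h <- 3.49 / n^(1 / 3)  # Scott fallback for tied data
  breaks <- seq(min(z) - h, max(z) + h, by = h)
  cnt <- tabulate(findInterval(z, breaks), nbins = length(breaks))
  p <- cnt[cnt > 0] / n
  H <- -sum(p * log(p)) + log(h)   # differential entropy estimate
  0.5 * log(2 * pi * exp(1)) - H   # negentropy: Gaussian max-entropy gap
}

# k x k rotation acting on columns i, j only
givens <- function(k, i, j, theta) {
  R <- diag(k)
  c_ <- cos(theta); s_ <- sin(theta)
  R[i, i] <- c_; R[j, j] <- c_
  R[i, j] <- -s_; R[j, i] <- s_
  R
}

#' Nonparametric independent component decomposition of response profiles
#'
#' Decomposes a voxels-by-conditions beta matrix into \code{n_components}
#' canonical response profiles with per-voxel weights. The component
#' subspace is fixed by a rank-k singular value decomposition; the rotation
#' within that subspace is then optimized to maximize the summed
#' non-Gaussianity of the voxel-weight distributions, with negentropy
#' estimated nonparametrically (histogram entropy of the standardized
#' weights, Freedman-Diaconis binning). Optimization is by pairwise
#' Jacobi-style angle sweeps with a 1-D line search per component pair,
#' restarted from \code{n_restarts} random rotations; the best solution is
#' returned. Components are ordered by explained variance and sign-flipped
#' so each profile's maximum-magnitude element is positive.
#'
#' Because the rotation is orthogonal, \code{weights \%*\% profiles}
#' reconstructs the data exactly as well as the rank-k SVD does.
#'
#' @param data numeric matrix, voxels x conditions (more voxels than
#'   conditions).
#' @param n_components number of components (study: 3).
#' @param n_restarts random restarts of the rotation search.
#' @param seed integer seed.
#' @param max_sweeps maximum Jacobi sweeps per restart.
#' @param tol convergence tolerance on the objective.
#' @return object of class \code{np_ica}: \code{profiles} (components x
#'   conditions, unit norm rows), \code{weights} (voxels x components),
#'   \code{negentropy} per component, \code{objective},
#'   \code{restart_objectives}, \code{converged}, \code{explained_var}.
#' @export
nonparametric_ica <- function(data, n_components = 3L, n_restarts = 10L,
                              seed = 1L, max_sweeps = 50L, tol = 1e-7) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("data must be finite")
  v <- nrow(data); ccnd <- ncol(data)
  k <- as.integer(n_components)
  if (!(v > ccnd && ccnd >= k)) stop("need voxels > conditions >= n_components")
  sv <- svd(data, nu = k, nv = k)
  if (sum(sv$d > sv$d[1L] * 1e-10) < k)
    stop("data rank is below n_components")
  W0 <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  P0 <- sv$v   # conditions x k, orthonormal columns
  objective <- function(R) {
    W <- W0 %*% R
    sum(apply(W, 2L, hist_negentropy))
  }
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  best <- list(obj = -Inf, R = diag(k), converged = FALSE)
  restart_obj <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    R <- if (r == 1L) diag(k) else qr.Q(qr(matrix(stats::rnorm(k * k), k)))
    obj <- objective(R)
    converged <- FALSE
    if (k > 1L) {
      for (sweep in seq_len(max_sweeps)) {
        obj0 <- obj
        for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
          f <- function(theta) objective(R %*% givens(k, i, j, theta))
          opt <- stats::optimize(f, c(-pi / 4, pi / 4), maximum = TRUE)
          if (opt$objective > obj) {
            R <- R %*% givens(k, i, j, opt$maximum)
            obj <- opt$objective
          }
        }
        if (obj - obj0 < tol) { converged <- TRUE; break }
      }
    } else converged <- TRUE
    restart_obj[r] <- obj
    if (obj > best$obj) best <- list(obj = obj, R = R, converged = converged)
  }
  W <- W0 %*% best$R
  P <- P0 %*% best$R                 # conditions x k, unit-norm columns
  ev <- colSums(W^2)
  ord <- order(ev, decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  P <- P[, ord, drop = FALSE]
  ev <- ev[ord]
  for (j in seq_len(k)) {
    s <- sign(P[which.max(abs(P[, j])), j])
    if (s < 0) { P[, j] <- -P[, j]; W[, j] <- -W[, j] }
  }
  profiles <- t(P)
  rownames(profiles) <- paste0("component", seq_len(k))
  if (!is.null(colnames(data))) colnames(profiles) <- colnames(data)
  colnames(W) <- rownames(profiles)
  structure(list(profiles = profiles, weights = W,
                 negentropy = apply(W, 2L, hist_negentropy),
                 objective = best$obj, restart_objectives = restart_obj,
                 converged = best$converged,
                 explained_var = ev / sum(data^2)),
            class = "np_ica")
}

#' @export
print.np_ica <- function(x, ...) {
  cat("<np_ica>", nrow(x$profiles), "components x", ncol(x$profiles),
      "conditions;", nrow(x$weights), "voxels; objective",
      sprintf("%.4f", x$objective),
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' Back-project component weights onto another condition set
#'
#' Solves \code{other_data ~ weights \%*\% profiles} for the profiles in
#' the least-squares sense (the matrix division of the observed data by
#' the fitted component weights), yielding each component's response
#' profile over a different run's conditions.
#'
#' @param other_data voxels x other-conditions matrix (same voxel order as
#'   the decomposition input).
#' @param weights voxels x components weight matrix.
#' @return components x other-conditions profile matrix.
#' @export
project_weights <- function(other_data, weights) {
  other_data <- as.matrix(other_data)
  weights <- as.matrix(weights)
  if (nrow(other_data) != nrow(weights))
    stop("voxel counts differ between data and weights")
  if (qr(weights)$rank < ncol(weights))
    stop("rank-deficient weights")
  out <- qr.solve(weights, other_data)
  rownames(out) <- colnames(weights) %||%
    paste0("component", seq_len(ncol(weights)))
  out
}

#' Match two sets of component profiles
#'
#' Finds the component permutation and signs maximizing the mean absolute
#' Pearson correlation between matched profiles (exhaustive over
#' permutations; intended for small component counts).
#'
#' @param a,b components x conditions profile matrices with equal
#'   dimensions.
#' @return list: \code{perm} (b's component matched to each of a's),
#'   \code{correlations} (absolute, per matched pair), \code{mean_abs_cor}.
#' @export
match_profiles <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  k <- nrow(a)
  C <- abs(stats::cor(t(a), t(b)))
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) mean(C[cbind(seq_len(k), p)]), 0)
  best <- perms[[which.max(scores)]]
  list(perm = best, correlations = C[cbind(seq_len(k), best)],
       mean_abs_cor = max(scores))
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}

#' Robustness of the decomposition to voxel removal
#'
#' Re-runs the decomposition with a subset of voxels removed and reports
#' the matched-profile correlations against the full-data solution.
#'
#' @param data voxels x conditions matrix.
#' @param mask_to_remove logical or integer index of voxels to drop (must
#'   remove fewer than half).
#' @param n_components components.
#' @param n_restarts,seed passed to \code{\link{nonparametric_ica}}.
#' @return list: \code{full}, \code{reduced} (both \code{np_ica}),
#'   \code{correlations} (matched absolute profile correlations),
#'   \code{mean_abs_cor}.
#' @export
exclusion_robustness <- function(data, mask_to_remove, n_components = 3L,
                                 n_restarts = 10L, seed = 1L) {
  data <- as.matrix(data)
  idx <- if (is.logical(mask_to_remove)) which(mask_to_remove) else
    as.integer(mask_to_remove)
  if (length(idx) >= nrow(data)) stop("mask removes every voxel")
  if (length(idx) >= nrow(data) / 2)
    stop("mask must remove fewer than half of the voxels")
  full <- nonparametric_ica(data, n_components, n_restarts, seed)
  keep <- setdiff(seq_len(nrow(data)), idx)
  reduced <- nonparametric_ica(data[keep, , drop = FALSE], n_components,
                               n_restarts, seed)
  m <- match_profiles(full$profiles, reduced$profiles)
  list(full = full, reduced = reduced, correlations = m$correlations,
       mean_abs_cor = m$mean_abs_cor)
}

#' Write a decomposition to CSV/JSON
#'
#' @param ica an \code{np_ica}.
#' @param dir output directory; writes \code{profiles.csv},
#'   \code{weights.csv}, \code{diagnostics.json}.
#' @return \code{dir}, invisibly.
#' @export
write_ica <- function(ica, dir) {
  stopifnot(inherits(ica, "np_ica"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ica$profiles, file.path(dir, "profiles.csv"))
  utils::write.csv(ica$weights, file.path(dir, "weights.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(objective = ica$objective,
         restart_objectives = ica$restart_objectives,
         negentropy = as.list(ica$negentropy),
         converged = ica$converged,
         explained_var = as.list(ica$explained_var)),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
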