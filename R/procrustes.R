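#' Centre a configuration and optionally scale to unit centroid size
#'
#' Translates the centroid to the origin and, when `do_scale`, divides by the
#' centroid size (the square root of the summed squared distances of all
#' landmarks to their centroid).
#'
#' @param config numeric `p x k` matrix of landmark coordinates.
#' @param do_scale scale to unit centroid size?
#' @return list with `coords` (centred, possibly scaled matrix) and `csize`
#'   (the original centroid size).
#' @export
center_and_scale <- function(config, do_scale = TRUE) {
  stopifnot(is.matrix(config), nrow(config) >= 3L)
  X <- sweep(config, 2, colMeans(config))
  cs <- sqrt(sum(X^2))
  if (cs < 1e-12) stop("degenerate configuration: all points coincident")
  if (do_scale) X <- X / cs
  list(coords = X, csize = cs)
}

#' Centroid size of a configuration
#' @inheritParams center_and_scale
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  X <- sweep(config, 2, colMeans(config))
  sqrt(sum(X^2))
}

#' Optimal proper rotation between two centred configurations
#'
#' Returns the rotation matrix `R` (proper, `det(R) = +1`) minimising
#' `||A - B %*% R||^2` over all rotations — the singular-value-decomposition
#' solution with determinant correction, so reflections are never introduced.
#'
#' @param A,B centred `p x k` matrices with identical dimensions.
#' @return `k x k` rotation matrix.
#' @export
optimal_rotation <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("dimension mismatch between configurations")
  H <- crossprod(B, A)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  k <- ncol(A)
  s$u %*% diag(c(rep(1, k - 1), d), k) %*% t(s$v)
}

# Deterministic orientation: rotate so the consensus lies along its principal
# axes, each axis signed so its largest-|coordinate| entry is positive. The
# construction is equivariant under rotation of the whole solution, which
# makes GPA output invariant to the pose of any input configuration.
canonical_rotation <- function(C) {
  k <- ncol(C)
  E <- eigen(crossprod(C), symmetric = TRUE)
  V <- E$vectors
  Y <- C %*% V
  for (j in seq_len(k)) {
    i <- which.max(abs(Y[, j]))
    if (Y[i, j] < 0) { V[, j] <- -V[, j]; Y[, j] <- -Y[, j] }
  }
  if (det(V) < 0) V[, k] <- -V[, k]
  V
}

# GPA work-horse on a list of raw configurations. Returns list(coords [array],
# csize, consensus, iterations, rss).
gpa_core <- function(Xs, do_scale = TRUE, tol = 1e-6, max_iter = 100L,
                     init_consensus = NULL, canonicalize = TRUE) {
  n <- length(Xs)
  p <- nrow(Xs[[1]]); k <- ncol(Xs[[1]])
  cs <- numeric(n)
  for (i in seq_len(n)) {
    st <- center_and_scale(Xs[[i]], do_scale)
    Xs[[i]] <- st$coords
    cs[i] <- st$csize
  }
  consensus <- init_consensus %||% Xs[[1]]
  it <- 0L
  repeat {
    it <- it + 1L
    for (i in seq_len(n)) Xs[[i]] <- Xs[[i]] %*% optimal_rotation(consensus, Xs[[i]])
    new_cons <- Reduce(`+`, Xs) / n
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    if (do_scale) new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- rms(new_cons - consensus)
    consensus <- new_cons
    if (delta < tol) break
    if (it >= max_iter)
      stop(sprintf("GPA failed to converge after %d iterations (last consensus change %.3g)",
                   max_iter, delta))
  }
  if (canonicalize) {
    V <- canonical_rotation(consensus)
    consensus <- consensus %*% V
    for (i in seq_len(n)) Xs[[i]] <- Xs[[i]] %*% V
  }
  coords <- array(unlist(Xs), dim = c(p, k, n))
  # summed squared deviation from the arithmetic mean of the superimposed
  # coordinates (the GPA objective); the stored consensus is that mean
  # re-standardised to unit centroid size
  xbar <- Reduce(`+`, Xs) / n
  rss <- sum(vapply(seq_len(n), function(i) sum((coords[, , i] - xbar)^2),
                    numeric(1)))
  list(coords = coords, csize = cs, consensus = consensus,
       iterations = it, rss = rss)
}

#' Generalised Procrustes analysis of a configuration set
#'
#' Iterative superimposition: every configuration is centred, optionally
#' scaled to unit centroid size, and rotated (proper rotations only) onto the
#' running consensus; the consensus — the arithmetic mean of the superimposed
#' coordinates, re-standardised — is updated until its root-mean-square change
#' falls below `tol`. The converged solution is put in a deterministic
#' principal-axes orientation, so the output does not depend on the pose or
#' ordering of the inputs.
#'
#' @param set a [configuration_set()] with at least 2 configurations.
#' @param do_scale scale configurations to unit centroid size (full GPA)?
#' @param tol convergence threshold on the consensus RMS change.
#' @param max_iter maximum number of align-to-consensus iterations; exceeding
#'   it is an error carrying the last residual change.
#' @return An object of class `aligned_set`: the superimposed coordinate
#'   array, original centroid sizes, consensus, scheme, metadata and (after
#'   [project_to_tangent()]) tangent-space shape variables.
#' @export
gpa <- function(set, do_scale = TRUE, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(set, "configuration_set"))
  n <- n_configs(set)
  if (n < 2L) stop("GPA needs at least 2 configurations")
  Xs <- lapply(seq_len(n), function(i) set$coords[, , i])
  fit <- gpa_core(Xs, do_scale = do_scale, tol = tol, max_iter = max_iter)
  structure(list(scheme = set$scheme, coords = fit$coords, csize = fit$csize,
                 consensus = fit$consensus, meta = set$meta,
                 do_scale = do_scale, tol = tol, tangent = NULL,
                 iterations = fit$iterations, rss = fit$rss),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("aligned set: %d configurations of %d landmarks in %dD (GPA %s, %d iteration(s))\n",
              dim(x$coords)[3], x$scheme$n_points, x$scheme$dims,
              if (x$do_scale) "with unit-size scaling" else "without scaling",
              x$iterations))
  cat(sprintf("  summed squared deviation from consensus: %.6g\n", x$rss))
  if (!is.null(x$tangent)) cat("  tangent-space shape variables present\n")
  invisible(x)
}

#' Project superimposed configurations to the tangent space
#'
#' Flattens every superimposed configuration and orthogonally projects it to
#' the linear tangent space at the consensus (removing the component along
#' the consensus vector). The consensus itself maps to the zero vector and
#' the projection is idempotent.
#'
#' @param aligned an `aligned_set` from [gpa()], [slide_semilandmarks()] or
#'   [matching_alignment()].
#' @return The same `aligned_set` with `$tangent`, an
#'   `n x (n_points * dims)` matrix of shape variables.
#' @export
project_to_tangent <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_set"))
  n <- dim(aligned$coords)[3]
  cvec <- vec_config(aligned$consensus)
  cc <- sum(cvec^2)
  X <- t(apply(aligned$coords, 3, vec_config))
  if (n == 1L) X <- matrix(X, nrow = 1L)
  proj <- X - tcrossprod(drop(X %*% cvec) / cc, cvec)
  aligned$tangent <- proj
  aligned
}

#' Procrustes distance between two configurations
#'
#' Square root of the summed squared differences after both configurations
#' are centred, scaled to unit centroid size and optimally rotated.
#'
#' @param A,B `p x k` coordinate matrices.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(A, B) {
  A <- center_and_scale(A)$coords
  B <- center_and_scale(B)$coords
  B <- B %*% optimal_rotation(A, B)
  sqrt(sum((A - B)^2))
}
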