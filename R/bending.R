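#' Thin-plate-spline bending-energy matrix
#'
#' Builds the bending-energy matrix of the thin-plate-spline interpolant
#' anchored at a reference configuration: the upper-left `p x p` block of the
#' inverse of the TPS system `L = [[K, Q], [Q', 0]]`, with radial kernel
#' `U(r) = r^2 log r` in 2D and `U(r) = -r` in 3D. The quadratic form
#' `sum_d v_d' B v_d` over the displacement field's coordinate columns is the
#' (nonnegative) bending energy of the deformation; it vanishes exactly on
#' affine displacement fields.
#'
#' @param reference `p x k` matrix (k = 2 or 3) of non-coincident points.
#' @return Object of class `bending_energy`: list with `reference` and the
#'   symmetric positive-semidefinite `matrix`.
#' @export
bending_energy <- function(reference) {
  stopifnot(is.matrix(reference))
  p <- nrow(reference); k <- ncol(reference)
  if (!k %in% c(2L, 3L)) stop("bending energy defined for 2D or 3D references")
  D <- as.matrix(stats::dist(reference))
  if (any(D[upper.tri(D)] < 1e-12))
    stop("coincident reference points make the TPS system singular")
  K <- if (k == 2L) ifelse(D == 0, 0, D^2 * log(D)) else -D
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, k + 1L, k + 1L)))
  Li <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system for this reference configuration"))
  B <- Li[seq_len(p), seq_len(p), drop = FALSE]
  B <- (B + t(B)) / 2
  # fix the sign convention so the quadratic form is nonnegative
  if (sum(diag(B)) < 0) B <- -B
  structure(list(reference = reference, matrix = B), class = "bending_energy")
}

#' @param be a `bending_energy` object.
#' @param displacement `p x k` displacement field.
#' @return `bending_energy_of()`: the scalar bending energy of the field.
#' @rdname bending_energy
#' @export
bending_energy_of <- function(be, displacement) {
  stopifnot(inherits(be, "bending_energy"))
  abs(sum(displacement * (be$matrix %*% displacement)))
}

# tangent direction of each semi-landmark: central difference over its chain
# neighbours (anchors included), normalised to unit length
chain_tangents <- function(X, scheme) {
  semis <- integer(0); tangents <- NULL
  for (ch in scheme$chains) {
    seqidx <- c(ch$start, ch$semis, ch$end)
    for (j in seq_along(ch$semis)) {
      pos <- j + 1L
      t_vec <- X[seqidx[pos + 1L], ] - X[seqidx[pos - 1L], ]
      nrm <- sqrt(sum(t_vec^2))
      if (nrm < 1e-12) t_vec <- rep(0, ncol(X)) else t_vec <- t_vec / nrm
      semis <- c(semis, ch$semis[j])
      tangents <- rbind(tangents, t_vec)
    }
  }
  list(idx = semis, tangents = tangents)
}

# slide one configuration's semi-landmarks along their tangents to minimise
# bending energy relative to the consensus (closed-form quadratic minimum)
slide_one <- function(X, consensus, Bmat, scheme) {
  tg <- chain_tangents(X, scheme)
  s <- tg$idx; Tm <- tg$tangents
  D <- Bmat %*% (X - consensus)              # p x k
  b <- rowSums(Tm * D[s, , drop = FALSE])    # gradient terms per semi-landmark
  M <- Bmat[s, s, drop = FALSE] * tcrossprod(Tm)
  M <- M + diag(1e-10 * max(1, mean(abs(diag(M)))), length(s))
  tau <- tryCatch(drop(solve(M, -b)), error = function(e) rep(0, length(s)))
  X[s, ] <- X[s, ] + tau * Tm
  X
}

#' Slide semi-landmarks by the minimum bending-energy criterion
#'
#' Alternates (a) sliding every configuration's semi-landmarks along their
#' estimated curve tangent directions so as to minimise the thin-plate-spline
#' bending energy of its deviation from the current consensus, with
#' (b) re-superimposition and consensus update, until the total bending
#' energy stabilises or `max_cycles` is reached. Fixed landmarks never move.
#' This removes the arbitrary component of semi-landmark spacing along the
#' outline curves before any shape statistics are computed.
#'
#' @param aligned an `aligned_set` from [gpa()].
#' @param scheme landmark scheme (defaults to the set's); a scheme with no
#'   chains makes this a no-op.
#' @param max_cycles maximum slide/re-superimpose cycles.
#' @param tol relative change in total bending energy below which the
#'   procedure stops.
#' @return The `aligned_set` with slid coordinates, updated consensus, and an
#'   `energy_trace` data frame (per cycle: energy before and after sliding,
#'   measured against that cycle's consensus).
#' @export
slide_semilandmarks <- function(aligned, scheme = aligned$scheme,
                                max_cycles = 5L, tol = 1e-6) {
  stopifnot(inherits(aligned, "aligned_set"))
  if (!length(scheme$chains)) {
    aligned$energy_trace <- data.frame(cycle = integer(0), energy_before = numeric(0),
                                       energy_after = numeric(0))
    return(aligned)
  }
  n <- dim(aligned$coords)[3]
  trace <- NULL
  for (cyc in seq_len(max_cycles)) {
    consensus <- aligned$consensus
    be <- bending_energy(consensus)
    e_before <- sum(vapply(seq_len(n), function(i)
      bending_energy_of(be, aligned$coords[, , i] - consensus), numeric(1)))
    Xs <- lapply(seq_len(n), function(i)
      slide_one(aligned$coords[, , i], consensus, be$matrix, scheme))
    e_after <- sum(vapply(Xs, function(X)
      bending_energy_of(be, X - consensus), numeric(1)))
    trace <- rbind(trace, data.frame(cycle = cyc, energy_before = e_before,
                                     energy_after = e_after))
    fit <- gpa_core(Xs, do_scale = aligned$do_scale, tol = aligned$tol,
                    max_iter = 100L, init_consensus = consensus)
    aligned$coords <- fit$coords
    aligned$consensus <- fit$consensus
    aligned$rss <- fit$rss
    if (e_before - e_after < tol * max(e_before, 1e-12)) break
  }
  aligned$energy_trace <- trace
  if (!is.null(aligned$tangent)) aligned <- project_to_tangent(aligned)
  aligned
}
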