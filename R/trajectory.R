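#' Pairwise phenotypic trajectory comparison of group mean shapes
#'
#' Compares the magnitude and direction of shape differences among groups
#' (biotypes, formula classes, ...). For every pair of groups the
#' mean-difference vector is computed; its Euclidean norm is the magnitude of
#' that contrast. Pairs of contrasts are then compared by (a) the absolute
#' difference of their magnitudes and (b) the angle between the two
#' difference vectors (degrees, from the normalised inner product), each
#' against a permutation null obtained by reshuffling group labels across all
#' observations. When the number of distinct label assignments does not
#' exceed `n_perm`, the null is enumerated completely and the p-values are
#' exact. Homogeneous-subset letters are assigned by single-linkage grouping
#' of contrasts whose comparisons are non-significant at `alpha`.
#'
#' @param tangent observation x variable matrix of shape variables.
#' @param groups factor with >= 2 levels; every group needs n >= 2.
#' @param n_perm number of random permutations (or the enumeration budget).
#' @param seed integer seed (`NULL`: current RNG stream).
#' @param alpha significance level for the subset letters.
#' @return Object of class `trajectory_result`: list with `pairs` (data
#'   frame: pair label, magnitude, letters for size and angle), `theta`,
#'   `P_size`, `P_theta` (matrices over contrasts), `exhaustive` flag.
#' @export
trajectory_analysis <- function(tangent, groups, n_perm = 999L, seed = NULL,
                                alpha = 0.05) {
  Y <- as.matrix(tangent)
  groups <- droplevels(factor(groups))
  g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("every group needs n >= 2 (violated by: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")")
  pair_idx <- utils::combn(g, 2L)
  n_pair <- ncol(pair_idx)
  pair_names <- apply(pair_idx, 2, function(ij)
    paste(levels(groups)[ij], collapse = " vs "))

  contrast_stats <- function(lab) {
    gm <- rowsum(Y, lab) / as.vector(table(lab))
    D <- gm[pair_idx[1, ], , drop = FALSE] - gm[pair_idx[2, ], , drop = FALSE]
    mags <- sqrt(rowSums(D^2))
    list(D = D, mags = mags)
  }
  angle_deg <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu < 1e-15 || nv < 1e-15) return(0)
    cth <- sum(u * v) / (nu * nv)
    acos(max(-1, min(1, cth))) * 180 / pi
  }
  obs <- contrast_stats(groups)
  theta <- matrix(0, n_pair, n_pair, dimnames = list(pair_names, pair_names))
  for (i in seq_len(n_pair)) for (j in seq_len(n_pair))
    theta[i, j] <- angle_deg(obs$D[i, ], obs$D[j, ])

  # permutation (or exhaustive) null over group-label assignments
  n_assign <- round(exp(lgamma(length(groups) + 1) - sum(lgamma(sizes + 1))))
  exhaustive <- is.finite(n_assign) && n_assign <= n_perm
  labelings <- if (exhaustive) enumerate_assignments(as.vector(sizes)) else NULL
  ge_size <- matrix(0, n_pair, n_pair)
  ge_theta <- matrix(0, n_pair, n_pair)
  obs_dmag <- abs(outer(obs$mags, obs$mags, `-`))
  n_draw <- if (exhaustive) ncol(labelings) else n_perm
  run_null <- function() {
    for (d in seq_len(n_draw)) {
      lab <- if (exhaustive) factor(levels(groups)[labelings[, d]],
                                    levels = levels(groups))
             else groups[sample.int(length(groups))]
      st <- contrast_stats(lab)
      dmag <- abs(outer(st$mags, st$mags, `-`))
      ge_size <<- ge_size + (dmag >= obs_dmag - 1e-12)
      for (i in seq_len(n_pair)) for (j in seq_len(n_pair)) {
        if (i >= j) next
        th <- angle_deg(st$D[i, ], st$D[j, ])
        if (th >= theta[i, j] - 1e-12) ge_theta[i, j] <<- ge_theta[i, j] + 1
      }
    }
  }
  local_seed(seed, run_null())
  P_size <- if (exhaustive) ge_size / n_draw else (ge_size + 1) / (n_draw + 1)
  P_theta <- matrix(1, n_pair, n_pair)
  for (i in seq_len(n_pair)) for (j in seq_len(n_pair)) {
    if (i >= j) next
    p <- if (exhaustive) ge_theta[i, j] / n_draw
         else (ge_theta[i, j] + 1) / (n_draw + 1)
    P_theta[i, j] <- P_theta[j, i] <- p
  }
  diag(P_size) <- 1
  dimnames(P_size) <- dimnames(P_theta) <- list(pair_names, pair_names)

  pairs <- data.frame(pair = pair_names, magnitude = obs$mags,
                      letters_size = subset_letters(P_size, alpha),
                      letters_theta = subset_letters(P_theta, alpha),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, theta = theta, P_size = P_size,
                 P_theta = P_theta, exhaustive = exhaustive,
                 n_draw = n_draw, alpha = alpha, seed = seed),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("trajectory analysis over %d contrasts (%s null, %d draws)\n",
              nrow(x$pairs), if (x$exhaustive) "exhaustive" else "permutation",
              x$n_draw))
  y <- x$pairs; y$magnitude <- round(y$magnitude, 5)
  print(y, row.names = FALSE)
  invisible(x)
}

# all distinct assignments of labels 1..k with given group sizes, as an
# integer matrix (one column per assignment)
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(free, k) {
    if (k == length(sizes)) {
      out <- integer(n); out[free] <- k
      return(matrix(out, ncol = 1))
    }
    picks <- utils::combn(free, sizes[k])
    cols <- lapply(seq_len(ncol(picks)), function(j) {
      rest <- rec(setdiff(free, picks[, j]), k + 1L)
      rest[picks[, j], ] <- k
      rest
    })
    do.call(cbind, cols)
  }
  rec(seq_len(n), 1L)
}

# homogeneous-subset letters: single-linkage components of the graph whose
# edges join contrasts with non-significant pairwise P
subset_letters <- function(P, alpha) {
  m <- nrow(P)
  comp <- seq_len(m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    if (P[i, j] > alpha) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  letters[match(comp, unique(comp))]
}
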