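# centered full-rank dummy coding of a factor (or pass-through for matrices)
center_dummies <- function(X) {
  if (is.null(X)) return(NULL)
  if (is.factor(X) || is.character(X)) {
    X <- droplevels(factor(X))
    if (nlevels(X) < 2L) return(matrix(numeric(0), length(X), 0L))
    M <- stats::model.matrix(~X)[, -1, drop = FALSE]
  } else {
    M <- as.matrix(X)
  }
  sweep(M, 2, colMeans(M))
}

# R^2 of Y (centered) on design M, plus the design rank
.rda_fit <- function(Yc, M) {
  if (is.null(M) || ncol(M) == 0L)
    return(list(r2 = 0, rank = 0L, qr = NULL))
  qr_ <- qr(M)
  fit <- qr.fitted(qr_, Yc)
  list(r2 = sum(fit^2) / sum(Yc^2), rank = qr_$rank, qr = qr_)
}

#' Ezekiel-adjusted R-squared
#'
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - p - 1)`. Penalises the number of
#' predictors; negative values are legitimate (a model worse than chance).
#'
#' @param R2 coefficient of determination in `[0, 1]`.
#' @param n number of observations.
#' @param p number of predictors (dummy columns / design rank).
#' @return scalar adjusted R-squared.
#' @export
adjusted_r2 <- function(R2, n, p) {
  stopifnot(R2 >= -1e-12, R2 <= 1 + 1e-12)
  if (n <= p + 1) stop("adjusted R2 needs n > p + 1")
  1 - (1 - R2) * (n - 1) / (n - p - 1)
}

#' Redundancy analysis of a multivariate response on a factor
#'
#' Multivariate least squares of the column-centred response on the
#' dummy-coded constraint: `R2` is the fraction of the total sum of squares
#' captured by the fitted values, `R2_adj` the Ezekiel adjustment, and the
#' permutation p-value comes from shuffling the rows of the response
#' (pseudo-F statistic, `P = (count >= observed + 1)/(n_perm + 1)`).
#'
#' @param Y observation x variable numeric matrix.
#' @param X factor (dummy-coded internally) or numeric design matrix.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed integer seed (`NULL`: current RNG stream).
#' @return Object of class `rda_result`: list with `R2, R2_adj, P, F, n,
#'   p_x, p_z, n_perm, seed`.
#' @export
rda <- function(Y, X, n_perm = 999L, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (sum(Yc^2) < 1e-12) stop("constant response: no variance to explain")
  Xd <- center_dummies(X)
  if (ncol(Xd) == 0L) {
    warning("single-level constraint: R2 = 0")
    return(structure(list(R2 = 0, R2_adj = 0, P = NA_real_, F = NA_real_,
                          n = n, p_x = 0L, p_z = 0L, n_perm = n_perm,
                          seed = seed), class = "rda_result"))
  }
  if (n <= ncol(Xd) + 1L) stop("need n > p_x + 1 observations")
  fit <- .rda_fit(Yc, Xd)
  p_x <- fit$rank
  Fobs <- (fit$r2 / p_x) / ((1 - fit$r2) / (n - p_x - 1L))
  P <- NA_real_
  if (n_perm > 0L) {
    P <- local_seed(seed, {
      stat <- numeric(n_perm)
      for (i in seq_len(n_perm)) {
        fp <- .rda_fit(Yc[sample.int(n), , drop = FALSE], Xd)
        stat[i] <- (fp$r2 / p_x) / ((1 - fp$r2) / (n - p_x - 1L))
      }
      perm_pvalue(Fobs, stat)
    })
  }
  structure(list(R2 = fit$r2, R2_adj = adjusted_r2(fit$r2, n, p_x), P = P,
                 F = Fobs, n = n, p_x = p_x, p_z = 0L, n_perm = n_perm,
                 seed = seed),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA: R2 = %.4f, R2_adj = %.4f, F = %.4f, P = %s (n = %d, p_x = %d, p_z = %d, %d perms)\n",
              x$R2, x$R2_adj, x$F, format(x$P), x$n, x$p_x, x$p_z, x$n_perm))
  invisible(x)
}

#' Partial redundancy analysis
#'
#' Pure (semipartial) effect of the constraint `X` after removing the
#' conditioning factor `Z`: the unadjusted fraction is
#' `R2(X+Z) - R2(Z)`, the adjusted fraction the difference of the
#' Ezekiel-adjusted terms (Peres-Neto convention), and significance comes
#' from permuting the residuals of the Z-only model (Freedman-Lane) with a
#' partial pseudo-F statistic. `Z = NULL` reduces bit-for-bit to [rda()].
#'
#' @inheritParams rda
#' @param Z conditioning factor or design matrix, or `NULL`.
#' @return An `rda_result`; `R2` holds the unadjusted pure fraction.
#' @export
partial_rda <- function(Y, X, Z = NULL, n_perm = 999L, seed = NULL) {
  if (is.null(Z)) return(rda(Y, X, n_perm = n_perm, seed = seed))
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (sum(Yc^2) < 1e-12) stop("constant response: no variance to explain")
  Xd <- center_dummies(X)
  Zd <- center_dummies(Z)
  fz <- .rda_fit(Yc, Zd)
  fxz <- .rda_fit(Yc, cbind(Zd, Xd))
  df_x <- fxz$rank - fz$rank
  frac <- fxz$r2 - fz$r2
  adj <- adjusted_r2(fxz$r2, n, fxz$rank) -
    (if (fz$rank > 0L) adjusted_r2(fz$r2, n, fz$rank) else 0)
  if (df_x == 0L) {
    warning("constraint nested within the conditioning factor: pure fraction 0")
    return(structure(list(R2 = 0, R2_adj = adj, P = NA_real_, F = NA_real_,
                          n = n, p_x = 0L, p_z = fz$rank, n_perm = n_perm,
                          seed = seed), class = "rda_result"))
  }
  Fobs <- (frac / df_x) / ((1 - fxz$r2) / (n - fxz$rank - 1L))
  P <- NA_real_
  if (n_perm > 0L) {
    fit_z <- if (fz$rank > 0L) qr.fitted(fz$qr, Yc) else matrix(0, n, ncol(Yc))
    res_z <- Yc - fit_z
    P <- local_seed(seed, {
      stat <- numeric(n_perm)
      for (i in seq_len(n_perm)) {
        Yp <- fit_z + res_z[sample.int(n), , drop = FALSE]
        Yp <- sweep(Yp, 2, colMeans(Yp))
        fzp <- .rda_fit(Yp, Zd)
        fxzp <- .rda_fit(Yp, cbind(Zd, Xd))
        stat[i] <- ((fxzp$r2 - fzp$r2) / df_x) /
          ((1 - fxzp$r2) / (n - fxz$rank - 1L))
      }
      perm_pvalue(Fobs, stat)
    })
  }
  structure(list(R2 = frac, R2_adj = adj, P = P, F = Fobs, n = n,
                 p_x = df_x, p_z = fz$rank, n_perm = n_perm, seed = seed),
            class = "rda_result")
}

#' Two-factor variance partitioning
#'
#' Partitions the variance of a multivariate response into the pure
#' fractions of two factors, their shared fraction and the residual, on both
#' the unadjusted scale (where the fractions sum exactly to `R2(X1+X2)` plus
#' residual = 1) and the Ezekiel-adjusted scale. The testable pure fractions
#' get permutation p-values via [partial_rda()]; the shared fraction is not
#' permutable and is reported without a p-value.
#'
#' @inheritParams rda
#' @param X1,X2 the two factors (or design matrices).
#' @return Object of class `varpart_result`: data frame with rows
#'   `pure_X1, pure_X2, shared, residual` and columns `R2, R2_adj, P`, plus
#'   attributes `R2_total`, `R2_total_adj`.
#' @export
variance_partition <- function(Y, X1, X2, n_perm = 999L, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  d1 <- center_dummies(X1); d2 <- center_dummies(X2)
  f1 <- .rda_fit(Yc, d1); f2 <- .rda_fit(Yc, d2)
  f12 <- .rda_fit(Yc, cbind(d1, d2))
  a1 <- adjusted_r2(f1$r2, n, f1$rank)
  a2 <- adjusted_r2(f2$r2, n, f2$rank)
  a12 <- adjusted_r2(f12$r2, n, f12$rank)
  frac <- data.frame(
    fraction = c("pure_X1", "pure_X2", "shared", "residual"),
    R2 = c(f12$r2 - f2$r2, f12$r2 - f1$r2,
           f1$r2 + f2$r2 - f12$r2, 1 - f12$r2),
    R2_adj = c(a12 - a2, a12 - a1, a1 + a2 - a12, 1 - a12),
    P = NA_real_, stringsAsFactors = FALSE)
  if (n_perm > 0L) {
    frac$P[1] <- local_seed(seed, partial_rda(Y, X1, X2, n_perm = n_perm)$P)
    frac$P[2] <- local_seed(if (is.null(seed)) NULL else seed + 1L,
                            partial_rda(Y, X2, X1, n_perm = n_perm)$P)
  }
  structure(frac, class = c("varpart_result", "data.frame"),
            R2_total = f12$r2, R2_total_adj = a12, n = n,
            n_perm = n_perm, seed = seed)
}

#' @export
print.varpart_result <- function(x, ...) {
  y <- as.data.frame(x)
  y$R2 <- round(y$R2, 4); y$R2_adj <- round(y$R2_adj, 4)
  print(y, row.names = FALSE)
  cat(sprintf("total R2 = %.4f (adjusted %.4f)\n",
              attr(x, "R2_total"), attr(x, "R2_total_adj")))
  invisible(x)
}

#' Principal component scores of shape variables
#'
#' Centred PCA of the tangent-space shape variables; explained-variance
#' fractions sum to 1 and reconstruction from all components reproduces the
#' input.
#'
#' @param tangent observation x variable matrix (e.g. `aligned$tangent`).
#' @return list with `scores`, `rotation`, `center`, `sdev` and
#'   `explained` (variance fractions).
#' @export
pca_scores <- function(tangent) {
  tangent <- as.matrix(tangent)
  if (nrow(tangent) < 2L) stop("PCA needs at least 2 observations")
  pc <- stats::prcomp(tangent, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, rotation = pc$rotation, center = pc$center,
       sdev = pc$sdev, explained = expl)
}
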