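test_that("RDA matches the explicit hat-matrix projection and vegan", {
  set.seed(20)
  Y <- matrix(rnorm(60), 20, 3)
  g <- factor(rep(c("a", "b"), each = 10))
  r <- rda(Y, g, n_perm = 0)
  # oracle: direct projection formula
  Yc <- sweep(Y, 2, colMeans(Y))
  Xd <- cbind(as.numeric(g == "b") - mean(g == "b"))
  H <- Xd %*% solve(t(Xd) %*% Xd) %*% t(Xd)
  r2_oracle <- sum((H %*% Yc)^2) / sum(Yc^2)
  expect_equal(r$R2, r2_oracle, tolerance = 1e-10)
  # independent implementation: vegan
  v <- vegan::RsquareAdj(vegan::rda(Y ~ g))
  expect_equal(r$R2, v$r.squared, tolerance = 1e-10)
  expect_equal(r$R2_adj, v$adj.r.squared, tolerance = 1e-10)
  # R2 invariant to a full-rank recoding of the dummies
  r_flip <- rda(Y, factor(g, levels = c("b", "a")), n_perm = 0)
  expect_equal(r$R2, r_flip$R2, tolerance = 1e-12)
})

test_that("RDA degenerate inputs behave as documented", {
  Y <- matrix(rnorm(30), 10, 3)
  # group means determine Y exactly -> R2 = 1
  g <- factor(rep(c("a", "b"), each = 5))
  Yg <- rbind(matrix(rep(c(1, 2, 3), 5), 5, byrow = TRUE),
              matrix(rep(c(-1, 0, 4), 5), 5, byrow = TRUE))
  expect_equal(rda(Yg, g, n_perm = 0)$R2, 1, tolerance = 1e-12)
  # single-level constraint
  expect_warning(r0 <- rda(Y, factor(rep("a", 10)), n_perm = 0), "single-level")
  expect_equal(r0$R2, 0)
  expect_error(rda(matrix(1, 10, 3), g, n_perm = 0), "constant")
})

test_that("adjusted R2 follows the Ezekiel formula including negative values", {
  expect_equal(adjusted_r2(0, 20, 3), -0.1875)
  expect_equal(adjusted_r2(1, 20, 3), 1)
  expect_equal(adjusted_r2(0.5, 20, 3), 0.40625)
  expect_error(adjusted_r2(0.5, 4, 3), "n > p")
})

test_that("partial RDA composes two explicit sequential least-squares fits", {
  set.seed(4)
  Y <- matrix(rnorm(24), 12, 2)
  X <- factor(rep(c("a", "b"), 6))
  Z <- factor(rep(c("u", "v", "w"), each = 4))
  pr <- partial_rda(Y, X, Z, n_perm = 0)
  # oracle: direct residualisation
  Yc <- sweep(Y, 2, colMeans(Y))
  mz <- stats::model.matrix(~Z)
  mxz <- stats::model.matrix(~Z + X)
  fit <- function(M) {
    H <- M %*% solve(t(M) %*% M) %*% t(M)
    sum((H %*% Yc)^2) / sum(Yc^2)
  }
  expect_equal(pr$R2, fit(mxz) - fit(mz), tolerance = 1e-10)
  # vegan agrees on the semipartial fraction
  v <- vegan::RsquareAdj(vegan::rda(Y ~ X + Condition(Z)))
  expect_equal(pr$R2, v$r.squared, tolerance = 1e-10)
  # Z = NULL is bit-for-bit rda
  expect_identical(partial_rda(Y, X, NULL, n_perm = 199, seed = 7),
                   rda(Y, X, n_perm = 199, seed = 7))
  # X duplicating Z: pure fraction collapses
  expect_warning(dup <- partial_rda(Y, Z, Z, n_perm = 0), "nested")
  expect_lte(dup$R2_adj, 0)
})

test_that("variance partitioning is additive and matches vegan::varpart", {
  set.seed(6)
  Y <- matrix(rnorm(90), 30, 3)
  X1 <- factor(rep(c("s1", "s2", "s3"), each = 10))
  X2 <- factor(rep(c("f1", "f2"), 15))
  vp <- variance_partition(Y, X1, X2, n_perm = 0)
  # unadjusted fractions sum exactly to 1
  expect_equal(sum(vp$R2), 1, tolerance = 1e-9)
  expect_equal(vp$R2[1] + vp$R2[3], rda(Y, X1, n_perm = 0)$R2, tolerance = 1e-10)
  vv <- vegan::varpart(Y, ~X1, ~X2)$part$indfract$Adj.R.square
  expect_equal(vp$R2_adj, vv, tolerance = 1e-9)
  # X2 identical to X1: pure fractions vanish, shared carries the total
  vp2 <- variance_partition(Y, X1, X1, n_perm = 0)
  expect_equal(vp2$R2[1], 0, tolerance = 1e-10)
  expect_equal(vp2$R2[2], 0, tolerance = 1e-10)
  expect_equal(vp2$R2[3], rda(Y, X1, n_perm = 0)$R2, tolerance = 1e-10)
})

test_that("orthogonal balanced factors share almost no variance", {
  set.seed(9)
  X1 <- factor(rep(c("s1", "s2"), each = 20))
  X2 <- factor(rep(c("f1", "f2"), 20))     # orthogonal to X1
  mu1 <- ifelse(X1 == "s2", 1, 0)
  mu2 <- ifelse(X2 == "f2", 0.8, 0)
  Y <- cbind(mu1 + rnorm(40, sd = .3), mu2 + rnorm(40, sd = .3))
  vp <- variance_partition(Y, X1, X2, n_perm = 0)
  expect_lt(abs(vp$R2[3]), 0.02)
})

test_that("trajectory analysis measures magnitudes, angles and exact enumeration P", {
  set.seed(13)
  # identical group means -> all magnitudes ~ 0
  Y0 <- matrix(rnorm(30, sd = 1e-8), 15, 2)
  g3 <- factor(rep(c("A", "B", "C"), each = 5))
  tr0 <- trajectory_analysis(Y0, g3, n_perm = 99, seed = 1)
  expect_true(all(tr0$pairs$magnitude < 1e-7))

  # collinear difference vectors -> angle 0
  means <- rbind(c(0, 0), c(1, 0), c(3, 0))
  Yc <- means[as.integer(g3), ] + matrix(rnorm(30, sd = 1e-9), 15, 2)
  trc <- trajectory_analysis(Yc, g3, n_perm = 99, seed = 1)
  expect_lt(trc$theta["A vs B", "A vs C"], 1e-4)

  # triangle inequality on group-mean distances
  set.seed(14)
  Yt <- matrix(rnorm(36), 18, 2)
  gt <- factor(rep(c("A", "B", "C"), each = 6))
  trt <- trajectory_analysis(Yt, gt, n_perm = 0, seed = 1)
  m <- trt$pairs$magnitude
  expect_lte(m[1], m[2] + m[3] + 1e-12)

  # exact enumeration P versus an independent oracle (3 groups of 3)
  Y3 <- matrix(rnorm(18), 9, 2)
  g9 <- factor(rep(c("A", "B", "C"), each = 3))
  tr <- trajectory_analysis(Y3, g9, n_perm = 9999, seed = 2)
  expect_true(tr$exhaustive)
  expect_equal(tr$n_draw, 1680L)
  # oracle: enumerate all label assignments independently
  oracle_stat <- function(lab) {
    gm <- rbind(colMeans(Y3[lab == 1, ]), colMeans(Y3[lab == 2, ]),
                colMeans(Y3[lab == 3, ]))
    d <- rbind(gm[1, ] - gm[2, ], gm[1, ] - gm[3, ], gm[2, ] - gm[3, ])
    mags <- sqrt(rowSums(d^2))
    ang <- function(u, v) acos(max(-1, min(1, sum(u * v) /
      (sqrt(sum(u^2)) * sqrt(sum(v^2)))))) * 180 / pi
    list(dmag12 = abs(mags[1] - mags[2]), th12 = ang(d[1, ], d[2, ]))
  }
  obs <- oracle_stat(as.integer(g9))
  picks1 <- utils::combn(9, 3)
  cnt_size <- 0L; cnt_th <- 0L; total <- 0L
  for (i in seq_len(ncol(picks1))) {
    rest <- setdiff(1:9, picks1[, i])
    picks2 <- utils::combn(rest, 3)
    for (j in seq_len(ncol(picks2))) {
      lab <- integer(9)
      lab[picks1[, i]] <- 1L
      lab[picks2[, j]] <- 2L
      lab[lab == 0L] <- 3L
      st <- oracle_stat(lab)
      total <- total + 1L
      if (st$dmag12 >= obs$dmag12 - 1e-12) cnt_size <- cnt_size + 1L
      if (st$th12 >= obs$th12 - 1e-12) cnt_th <- cnt_th + 1L
    }
  }
  expect_equal(total, 1680L)
  expect_equal(tr$P_size["A vs B", "A vs C"], cnt_size / total, tolerance = 1e-12)
  expect_equal(tr$P_theta["A vs B", "A vs C"], cnt_th / total, tolerance = 1e-12)

  expect_error(trajectory_analysis(Y3, factor(c(rep("A", 8), "B")), n_perm = 9),
               "n >= 2")
})

test_that("PCA scores reconstruct the input and order variance", {
  set.seed(15)
  Y <- matrix(rnorm(50), 10, 5)
  pc <- pca_scores(Y)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
  recon <- pc$scores %*% t(pc$rotation) +
    matrix(pc$center, 10, 5, byrow = TRUE)
  expect_equal(recon, Y, tolerance = 1e-9, ignore_attr = TRUE)
  # rank-1 variation -> PC1 carries everything
  v <- rnorm(5)
  Y1 <- outer(rnorm(10), v)
  expect_equal(pca_scores(Y1)$explained[1], 1, tolerance = 1e-9)
})
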