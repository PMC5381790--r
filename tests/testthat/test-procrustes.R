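test_that("centring and scaling follow the centroid-size closed form", {
  # unit square centred at (5,5): half-diagonal distances 1/sqrt(2)*... the
  # centroid size is sqrt(4 * 0.5^2 * 2) = sqrt(2) per unit half-side; for
  # the unit square with corners (±1/2, ±1/2) + 5, size = sqrt(4*(1/4+1/4)) = sqrt(2)...
  sq <- cbind(c(-.5, .5, .5, -.5) + 5, c(-.5, -.5, .5, .5) + 5)
  st <- center_and_scale(sq, do_scale = FALSE)
  expect_equal(colMeans(st$coords), c(0, 0))
  expect_equal(st$csize, sqrt(sum(c(.5, .5, .5, .5, .5, .5, .5, .5)^2)))
  # square with half-diagonal 1 (corners on the unit circle) has size 2
  sq2 <- cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)) + 5
  expect_equal(center_and_scale(sq2)$csize, 2)
  # already centred, unit size: unchanged
  u <- center_and_scale(matrix(rnorm(12), 4, 3))$coords
  st2 <- center_and_scale(u)
  expect_equal(st2$coords, u, tolerance = 1e-12)
  expect_equal(st2$csize, 1)
  expect_error(center_and_scale(matrix(1, 5, 3)), "degenerate")
})

test_that("optimal rotation is proper and matches brute-force minimisation", {
  set.seed(42)
  A <- center_and_scale(matrix(rnorm(30), 10, 3))$coords
  # exact recovery of a known rotation
  Rz <- rotation_z(pi / 2)
  B <- A %*% Rz
  R <- optimal_rotation(A, B)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_lt(sum((A - B %*% R)^2), 1e-20)
  expect_equal(optimal_rotation(A, A), diag(3), tolerance = 1e-10)

  # random pair: residual vs direct numerical minimisation over Euler angles
  B2 <- center_and_scale(matrix(rnorm(30), 10, 3))$coords
  R2 <- optimal_rotation(A, B2)
  res_svd <- sum((A - B2 %*% R2)^2)
  euler <- function(a) rotation_z(a[1]) %*%
    matrix(c(1, 0, 0, 0, cos(a[2]), -sin(a[2]), 0, sin(a[2]), cos(a[2])),
           3, 3, byrow = TRUE) %*% rotation_z(a[3])
  obj <- function(a) sum((A - B2 %*% euler(a))^2)
  starts <- as.matrix(expand.grid(seq(0, 2 * pi, length.out = 5)[-5],
                                  seq(0, pi, length.out = 4),
                                  seq(0, 2 * pi, length.out = 5)[-5]))
  best <- min(apply(starts, 1, function(s)
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$value))
  expect_equal(res_svd, best, tolerance = 1e-6)
  expect_lte(res_svd, best + 1e-8)   # never worse than the numeric optimum
  expect_error(optimal_rotation(A, B2[, 1:2]), "mismatch")
})

test_that("GPA handles identical and similarity-transformed copies", {
  set.seed(1)
  base <- matrix(rnorm(27), 9, 3)
  mats <- list(base, base, base, base)
  coords <- array(unlist(mats), dim = c(9, 3, 4))
  meta <- data.frame(individual = sprintf("i%d", 1:4), side = "L", session = "1")
  set <- configuration_set(coords, meta, flat_scheme(9L))
  al <- gpa(set)
  expect_lt(al$rss, 1e-20)
  expect_equal(al$coords[, , 1], al$consensus, tolerance = 1e-10)

  # rotated/translated/scaled copies align to within 1e-8
  copies <- lapply(1:4, function(i) {
    th <- i * 0.7
    base %*% rotation_z(th) * (0.5 + i) + matrix(rnorm(3), 9, 3, byrow = TRUE)
  })
  set2 <- configuration_set(array(unlist(copies), dim = c(9, 3, 4)), meta,
                            flat_scheme(9L))
  al2 <- gpa(set2)
  for (i in 2:4)
    expect_lt(max(abs(al2$coords[, , i] - al2$coords[, , 1])), 1e-8)
})

test_that("GPA of distinct triangles attains the brute-force joint minimum", {
  t1 <- matrix(c(0, 0, 1, 0, 0.2, 1), 3, 2, byrow = TRUE)
  t2 <- matrix(c(0, 0, 1.3, 0, 0.7, 0.9), 3, 2, byrow = TRUE)
  t3 <- matrix(c(0, 0, 0.8, 0.1, 0.1, 1.4), 3, 2, byrow = TRUE)
  set <- triangle_set(list(t1, t2, t3))
  al <- gpa(set, tol = 1e-10)

  # oracle: generic optimiser over the three rotation angles of the
  # unit-size centred triangles, objective = summed squared deviation from
  # the mean of the rotated configurations
  U <- lapply(list(t1, t2, t3), function(m) center_and_scale(m)$coords)
  obj <- function(th) {
    rot <- Map(function(u, a) u %*% rotation_2d(a), U, as.list(th))
    M <- Reduce(`+`, rot) / 3
    sum(vapply(rot, function(r) sum((r - M)^2), numeric(1)))
  }
  best <- min(vapply(1:25, function(s) {
    stats::optim(runif(3, 0, 2 * pi), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 10000))$value
  }, numeric(1)))
  expect_equal(al$rss, best, tolerance = 1e-6)
})

test_that("GPA deviation from consensus never increases across iterations", {
  # re-run the internal loop manually and track the objective
  set.seed(8)
  set <- quick_bilateral(n = 6L, seed = 2L)
  Xs <- lapply(seq_len(n_configs(set)), function(i)
    center_and_scale(set$coords[, , i])$coords)
  consensus <- Xs[[1]]
  obj_trace <- numeric(0)
  for (it in 1:20) {
    Xs <- lapply(Xs, function(X) X %*% optimal_rotation(consensus, X))
    M <- Reduce(`+`, Xs) / length(Xs)
    obj_trace <- c(obj_trace, sum(vapply(Xs, function(X) sum((X - M)^2),
                                         numeric(1))))
    M <- sweep(M, 2, colMeans(M))
    consensus <- M / sqrt(sum(M^2))
  }
  expect_true(all(diff(obj_trace) <= 1e-12))
})

test_that("tangent projection is idempotent and consistent with Procrustes distance", {
  set <- quick_bilateral(n = 10L, seed = 3L)
  al <- project_to_tangent(gpa(set))
  cvec <- as.vector(al$consensus)
  # consensus maps to zero
  cons_proj <- cvec - cvec * sum(cvec * cvec) / sum(cvec^2)
  expect_equal(max(abs(cons_proj)), 0, tolerance = 1e-12)
  # idempotence
  t2 <- al$tangent - tcrossprod(drop(al$tangent %*% cvec) / sum(cvec^2), cvec)
  expect_equal(t2, al$tangent, tolerance = 1e-12)
  # small-variation regime: tangent distance ~ Procrustes distance
  i <- 1; j <- 2
  td <- sqrt(sum((al$tangent[i, ] - al$tangent[j, ])^2))
  pd <- procrustes_distance(set$coords[, , i], set$coords[, , j])
  expect_lt(abs(td - pd) / pd, 0.01)
})
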