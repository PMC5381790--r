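test_that("reflection is an involution that preserves size and flips chirality", {
  set.seed(5)
  X <- matrix(rnorm(15), 5, 3)
  expect_identical(reflect_side(reflect_side(X)), X)
  expect_equal(centroid_size(reflect_side(X)), centroid_size(X))
  # signed volume of a landmark tetrad changes sign
  vol <- function(M) det(rbind(M[2, ] - M[1, ], M[3, ] - M[1, ], M[4, ] - M[1, ]))
  expect_equal(vol(reflect_side(X)[1:4, ]), -vol(X[1:4, ]))
  expect_error(reflect_side(X, axis = 4), "axis")
})

test_that("matching alignment gives zero asymmetry for mirror-perfect pairs", {
  sc <- quick_scheme()
  pars <- sim_params(scheme = sc, sigma_fa = 0, sigma_me = 0,
                     n_per_site = c(s1 = 5L), seed = 6, n_replicates = 1L)
  set <- simulate_shapes(pars)   # R is the exact mirror of L
  al <- matching_alignment(set)
  side <- al$meta$side
  for (ind in unique(al$meta$individual)) {
    iL <- which(al$meta$individual == ind & side == "L")
    iR <- which(al$meta$individual == ind & side == "R")
    expect_lt(max(abs(al$tangent[iL, ] - al$tangent[iR, ])), 1e-7)
  }
})

test_that("matching alignment is invariant to configuration order and flags missing sides", {
  set <- quick_bilateral(n = 5L, seed = 12L)
  al1 <- matching_alignment(set)
  perm <- sample(n_configs(set))
  al2 <- matching_alignment(subset_configs(set, perm))
  expect_equal(al1$coords, al2$coords, tolerance = 1e-10)
  # drop one individual's R side entirely
  drop <- !(set$meta$individual == "ind002" & set$meta$side == "R")
  expect_error(matching_alignment(subset_configs(set, drop)), "ind002")
})

test_that("Procrustes ANOVA bookkeeping matches the balanced crossed design", {
  set.seed(2)
  # 35 individuals x 2 sides x 2 sessions, q = 6 shape variables
  n <- 35L; q <- 6L
  ind <- factor(rep(sprintf("i%02d", 1:n), each = 4))
  side <- factor(rep(c("L", "L", "R", "R"), n))
  sess <- factor(rep(c("1", "2"), 2 * n))
  Y <- matrix(rnorm(4 * n * q), ncol = q)
  aov <- procrustes_anova(Y, ind, side, sess, n_perm = 0)
  expect_equal(aov$effect, c("Individual", "Side", "Individual × Side",
                             "Measurement error"))
  expect_equal(aov$df, c(34L, 1L, 34L, 70L))
  expect_equal(aov$MS, aov$SS / aov$df)
  # SS additivity at 1e-9 relative
  expect_lt(abs(sum(aov$SS) - attr(aov, "total_SS")) / attr(aov, "total_SS"), 1e-9)
  # unbalanced and single-replicate error paths
  expect_error(procrustes_anova(Y[-1, , drop = FALSE], ind[-1], side[-1],
                                sess[-1], n_perm = 0), "unbalanced")
  one <- sess == "1"
  expect_error(procrustes_anova(Y[one, ], ind[one], side[one], sess[one],
                                n_perm = 0), "2 replicate")
})

test_that("ANOVA results are invariant to individual relabeling", {
  set.seed(3)
  n <- 10L
  ind <- rep(sprintf("i%02d", 1:n), each = 4)
  side <- rep(c("L", "L", "R", "R"), n)
  sess <- rep(c("1", "2"), 2 * n)
  Y <- matrix(rnorm(4 * n * 5), ncol = 5)
  a1 <- procrustes_anova(Y, ind, side, sess, n_perm = 99, seed = 1)
  relabeled <- sprintf("specimen_%s", ind)
  a2 <- procrustes_anova(Y, relabeled, side, sess, n_perm = 99, seed = 1)
  expect_equal(a1$SS, a2$SS, tolerance = 1e-12)
  expect_equal(a1$P, a2$P)
})

test_that("Monte-Carlo mean squares match their expected-MS compositions", {
  # balanced two-way mixed model fed directly to the ANOVA: 500 draws
  s2_ind <- 0.5; s2_fa <- 0.2; s2_me <- 0.1
  n <- 12L; q <- 6L; r <- 2L
  ind <- factor(rep(seq_len(n), each = 2 * r))
  side <- factor(rep(rep(c("L", "R"), each = r), n))
  sess <- factor(rep(seq_len(r), 2 * n))
  set.seed(77)
  ms_sum <- numeric(4)
  nsim <- 500
  for (s in seq_len(nsim)) {
    a_i <- matrix(rnorm(n * q, sd = sqrt(s2_ind)), n, q)
    ab <- matrix(rnorm(n * 2 * q, sd = sqrt(s2_fa)), n * 2, q)
    cell <- (as.integer(ind) - 1L) * 2L + as.integer(side)
    Y <- a_i[as.integer(ind), ] + ab[cell, ] +
      matrix(rnorm(length(ind) * q, sd = sqrt(s2_me)), ncol = q)
    ms_sum <- ms_sum + procrustes_anova(Y, ind, side, sess, n_perm = 0)$MS
  }
  ms_bar <- ms_sum / nsim
  expect_equal(ms_bar[4], q * s2_me, tolerance = 0.05)
  expect_equal(ms_bar[3], q * (s2_me + r * s2_fa), tolerance = 0.05)
  expect_equal(ms_bar[1], q * (s2_me + r * s2_fa + 2 * r * s2_ind),
               tolerance = 0.05)
})

test_that("asymmetry decomposition extracts DA vector and centred FA scores", {
  sc <- default_arch_scheme()
  # strong DA on the 11 inner-margin landmarks, small noise: the injected
  # landmarks dominate the magnitude ranking of the DA vector
  da <- da_inner_margin(sc, magnitude = 0.03)
  pars <- sim_params(scheme = sc, da_vector = da, sigma_ind = 5e-3,
                     sigma_fa = 2e-4, sigma_me = 2e-4, sigma_site = 0,
                     n_per_site = c(s1 = 12L), seed = 21)
  set <- simulate_shapes(pars)
  al <- matching_alignment(set)
  dec <- decompose_asymmetry(al, n_perm = 99, seed = 4)
  expect_equal(colSums(dec$fa_scores), rep(0, ncol(dec$fa_scores)),
               tolerance = 1e-9)
  mag <- sqrt(rowSums(dec$da_vector^2))
  injected <- which(rowSums(abs(da)) > 0)
  top <- order(mag, decreasing = TRUE)[seq_along(injected)]
  expect_gte(sum(top %in% injected), length(injected) - 2L)
  expect_true(dec$flags["DA"])

  # mirror-perfect data (digitising noise only): da_vector ~ noise floor
  # and FA not significant
  pars0 <- sim_params(scheme = quick_scheme(), sigma_fa = 0, sigma_me = 1e-3,
                      n_per_site = c(s1 = 8L), seed = 22)
  al0 <- matching_alignment(simulate_shapes(pars0))
  dec0 <- decompose_asymmetry(al0, n_perm = 99, seed = 5)
  expect_lt(sqrt(sum(dec0$da_vector^2)), 2e-3)
  expect_false(dec0$flags["FA"])
})

test_that("per-landmark asymmetry flags the deviating landmark and respects adjustment", {
  sc <- flat_scheme(p = 8L)
  # deviation injected at landmark 5 only, two sites
  da <- matrix(0, 8, 3); da[5, 3] <- 0.08
  pars <- sim_params(scheme = sc, da_vector = da, sigma_ind = 0.01,
                     sigma_fa = 2e-3, sigma_me = 1e-3,
                     n_per_site = c(a = 10L, b = 10L), seed = 31)
  set <- simulate_shapes(pars)
  al <- matching_alignment(set, slide = FALSE)
  res <- per_landmark_asymmetry(al, n_perm = 199, seed = 9)
  expect_equal(res$landmark, 1:8)
  # the injected landmark attains the smallest P (ties at the permutation
  # floor allowed) and clearly the largest effect size
  expect_equal(res$P[5], min(res$P))
  expect_equal(which.max(res$R2_adj), 5L)
  expect_true(all(res$P_bh >= res$P))

  # zero-deviation data (identical mirrored sides, individual variation
  # only): all adjusted R2 <= 0 (adjustment penalty)
  pars0 <- sim_params(scheme = sc, sigma_ind = 0.02, sigma_fa = 0,
                      sigma_me = 0, sigma_site = 0,
                      n_per_site = c(a = 6L, b = 6L), seed = 32)
  set0 <- simulate_shapes(pars0)
  al0 <- matching_alignment(set0, slide = FALSE)
  res0 <- per_landmark_asymmetry(al0, n_perm = 99, seed = 10)
  expect_true(all(res0$R2_adj <= 1e-10))

  # single site: degrades with a warning record
  single <- subset_configs(set, set$meta$site == "a")
  al1 <- matching_alignment(single, slide = FALSE)
  expect_warning(r1 <- per_landmark_asymmetry(al1, n_perm = 49, seed = 2),
                 "single site")
  expect_false(is.null(attr(r1, "warning")))
})
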