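#' Reflect a configuration across a coordinate plane
#'
#' Multiplies the chosen coordinate of every landmark by -1 (the
#' x-coordinate by default). Used to mirror right-side configurations onto
#' the left before the joint superimposition of the matching-symmetry
#' design. For a `configuration_set`, all configurations are reflected and a
#' `reflected` metadata flag is toggled.
#'
#' @param x a `p x k` matrix or a [configuration_set()].
#' @param axis coordinate index to negate (default 1 = x).
#' @return Same type as `x`, reflected.
#' @export
reflect_side <- function(x, axis = 1L) UseMethod("reflect_side")

#' @export
reflect_side.matrix <- function(x, axis = 1L) {
  if (axis < 1L || axis > ncol(x)) stop("invalid reflection axis ", axis)
  x[, axis] <- -x[, axis]
  x
}

#' @export
reflect_side.configuration_set <- function(x, axis = 1L) {
  if (axis < 1L || axis > x$scheme$dims) stop("invalid reflection axis ", axis)
  x$coords[, axis, ] <- -x$coords[, axis, ]
  refl <- x$meta$reflected %||% rep(FALSE, nrow(x$meta))
  x$meta$reflected <- !refl
  x
}

#' Matching-symmetry alignment of paired left/right configurations
#'
#' Implements the matching-symmetry superimposition for paired bilateral
#' structures: every right-side configuration is reflected (x -> -x) so that
#' its landmarks correspond to the left side, then all left and reflected
#' right configurations are jointly superimposed by GPA, semi-landmarks are
#' slid against the joint consensus (if the scheme has chains), and
#' tangent-space shape variables are computed.
#'
#' @param set a [configuration_set()] in which every individual has both
#'   sides (any number of digitising sessions >= 1).
#' @param do_scale scale to unit centroid size during GPA?
#' @param slide slide semi-landmarks after the joint superimposition?
#' @param axis reflection axis (default 1 = x).
#' @param tol,max_iter GPA convergence settings.
#' @return An `aligned_set` with tangent variables; `meta$side` keeps the
#'   original side labels and `meta$reflected` marks the mirrored
#'   configurations.
#' @export
matching_alignment <- function(set, do_scale = TRUE, slide = TRUE, axis = 1L,
                               tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(set, "configuration_set"))
  sides <- tapply(set$meta$side, set$meta$individual,
                  function(s) length(unique(s)))
  missing_side <- names(sides)[sides < 2L]
  if (length(missing_side))
    stop("individual(s) missing a side: ", paste(missing_side, collapse = ", "))
  set <- sort_configs(set)
  is_r <- set$meta$side == "R"
  set$coords[, axis, is_r] <- -set$coords[, axis, is_r]
  set$meta$reflected <- is_r
  aligned <- gpa(set, do_scale = do_scale, tol = tol, max_iter = max_iter)
  if (slide && length(set$scheme$chains))
    aligned <- slide_semilandmarks(aligned, tol = tol)
  project_to_tangent(aligned)
}

# balanced crossed two-factor decomposition of a multivariate response;
# returns the sums of squares of the sequential (here orthogonal) design
crossed_ss <- function(Y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B)
  ai <- as.integer(A); bi <- as.integer(B)
  ci <- (ai - 1L) * b + bi
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_tot <- sum(Yc^2)
  na <- tabulate(ai, a); nb <- tabulate(bi, b); nc <- tabulate(ci, a * b)
  a_mean <- rowsum(Yc, ai) / na
  b_mean <- rowsum(Yc, bi) / nb
  cm <- rowsum(Yc, ci)
  filled <- as.integer(rownames(cm))
  c_mean <- matrix(0, a * b, ncol(Yc))
  c_mean[filled, ] <- cm / nc[filled]
  ca <- ((seq_len(a * b) - 1L) %/% b) + 1L
  cb <- ((seq_len(a * b) - 1L) %% b) + 1L
  dev <- c_mean - a_mean[ca, , drop = FALSE] - b_mean[cb, , drop = FALSE]
  ss_a <- sum(na * rowSums(a_mean^2))
  ss_b <- sum(nb * rowSums(b_mean^2))
  ss_ab <- sum(nc * rowSums(dev^2))
  ss_e <- sum((Yc - c_mean[ci, , drop = FALSE])^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_e = ss_e, ss_tot = ss_tot)
}

#' Procrustes ANOVA for crossed shape designs
#'
#' Decomposes the summed squared tangent-space (Procrustes) deviations of a
#' balanced crossed design into its effects, with Goodall-style F ratios and
#' permutation p-values. Two designs are supported:
#'
#' * `individual x side` with replicate digitising sessions — the matching
#'   symmetry decomposition: `Individual`, `Side` (directional asymmetry),
#'   `Individual x Side` (fluctuating asymmetry) and `Measurement error`
#'   rows. Individual and Side are tested against the interaction mean
#'   square; the interaction is tested against measurement error.
#' * `individual x session` with one observation per cell — the
#'   measurement-error decomposition: `Individual` and `Session` rows, both
#'   tested against the residual (which is the individual x session
#'   interaction).
#'
#' Degrees of freedom follow the design (e.g. 34/1/34/70 for 35 individuals
#' x 2 sides x 2 sessions); mean squares are SS/df. Permutation inference
#' uses, per term: whole-row shuffling for `Individual`, shuffling of
#' B-labels within individual for `Side`/`Session`, and residual
#' randomisation under the additive model for the interaction. P-values are
#' `(count >= observed + 1) / (n_perm + 1)`; `n_perm = 0` skips permutation.
#'
#' @param Y observation x variable matrix of shape variables, or an
#'   `aligned_set` with tangent variables (then `individual`, `side`,
#'   `replicate` default to its metadata).
#' @param individual,side,replicate factors over the rows of `Y`; `side`
#'   `NULL` selects the individual-x-session design.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations (`NULL`: use current RNG).
#' @return Object of class `anova_table`: a data frame with columns
#'   `effect, df, SS, MS, Rsq, F, P` plus attributes `total_SS`, `n_perm`,
#'   `seed` and the design sizes used by [variance_components()].
#' @export
procrustes_anova <- function(Y, individual = NULL, side = NULL,
                             replicate = NULL, n_perm = 999L, seed = NULL) {
  if (inherits(Y, "aligned_set")) {
    if (is.null(Y$tangent)) Y <- project_to_tangent(Y)
    individual <- individual %||% Y$meta$individual
    side <- if (missing(side)) Y$meta$side else side
    replicate <- replicate %||% Y$meta$session
    Y <- Y$tangent
  }
  stopifnot(is.matrix(Y), !is.null(individual))
  individual <- factor(individual)
  if (is.null(replicate) && is.null(side))
    stop("need at least one of side / replicate besides individual")
  if (is.null(side)) {
    B <- factor(replicate); b_name <- "Session"
    reps_in_cells <- FALSE
  } else {
    side <- factor(side)
    if (nlevels(side) != 2L) stop("side must have exactly 2 levels")
    if (is.null(replicate)) {
      B <- side; b_name <- "Side"; reps_in_cells <- FALSE
    } else {
      B <- side; b_name <- "Side"; reps_in_cells <- TRUE
      replicate <- factor(replicate)
    }
  }
  tab <- table(individual, B)
  if (length(unique(as.vector(tab))) != 1L)
    stop("unbalanced design: every individual x ", tolower(b_name),
         " cell needs the same number of observations")
  r <- unique(as.vector(tab))
  if (reps_in_cells && r < 2L)
    stop("fluctuating asymmetry requires >= 2 replicate sessions per side")
  a <- nlevels(individual); b <- nlevels(B); q <- ncol(Y)

  decomp <- function(Y, A, B) crossed_ss(Y, A, B)
  obs <- decomp(Y, individual, B)

  if (reps_in_cells || r > 1L) {
    effects <- c("Individual", b_name, paste("Individual ×", b_name),
                 "Measurement error")
    df <- c(a - 1L, b - 1L, (a - 1L) * (b - 1L), a * b * (r - 1L))
    SS <- c(obs$ss_a, obs$ss_b, obs$ss_ab, obs$ss_e)
  } else {
    effects <- c("Individual", b_name, "Residual")
    df <- c(a - 1L, b - 1L, (a - 1L) * (b - 1L))
    SS <- c(obs$ss_a, obs$ss_b, obs$ss_ab)
  }
  MS <- SS / df
  n_eff <- length(effects)
  Fv <- rep(NA_real_, n_eff)
  err_of <- rep(NA_integer_, n_eff)
  if (n_eff == 4L) {
    err_of[1:3] <- c(3L, 3L, 4L)   # ind, side -> interaction; interaction -> error
  } else {
    err_of[1:2] <- c(3L, 3L)       # both tested against the residual
  }
  for (i in seq_len(n_eff)) if (!is.na(err_of[i])) Fv[i] <- MS[i] / MS[err_of[i]]

  P <- rep(NA_real_, n_eff)
  if (n_perm > 0L) {
    f_of <- function(d, term) {
      ss <- c(d$ss_a, d$ss_b, d$ss_ab, d$ss_e)[seq_len(n_eff)]
      ms <- ss / df
      ms[term] / ms[err_of[term]]
    }
    P <- local_seed(seed, {
      n_obs <- nrow(Y)
      gm <- colMeans(Y)
      # fitted values of the additive (no-interaction) model, for the
      # interaction term's residual randomisation
      a_mean <- rowsum(Y, individual) / as.vector(table(individual))
      b_mean <- rowsum(Y, B) / as.vector(table(B))
      add_fit <- a_mean[as.character(individual), , drop = FALSE] +
        b_mean[as.character(B), , drop = FALSE] -
        matrix(gm, n_obs, q, byrow = TRUE)
      add_res <- Y - add_fit
      ind_levels <- levels(individual)
      pv <- rep(NA_real_, n_eff)
      for (term in seq_len(n_eff)) {
        if (is.na(err_of[term])) next
        stat_obs <- f_of(obs, term)
        stat_perm <- numeric(n_perm)
        for (pi in seq_len(n_perm)) {
          if (term == 1L) {                       # individuals: shuffle rows
            Yp <- Y[sample.int(n_obs), , drop = FALSE]
            stat_perm[pi] <- f_of(decomp(Yp, individual, B), term)
          } else if (term == 2L) {                # side/session labels within individual
            Bp <- B
            for (lv in ind_levels) {
              rows <- which(individual == lv)
              map <- sample(levels(B))
              Bp[rows] <- factor(map[as.integer(B[rows])], levels = levels(B))
            }
            stat_perm[pi] <- f_of(decomp(Y, individual, Bp), term)
          } else {                                 # interaction: residual randomisation
            Yp <- add_fit + add_res[sample.int(n_obs), , drop = FALSE]
            stat_perm[pi] <- f_of(decomp(Yp, individual, B), term)
          }
        }
        pv[term] <- perm_pvalue(stat_obs, stat_perm)
      }
      pv
    })
  }
  out <- data.frame(effect = effects, df = df, SS = SS, MS = MS,
                    Rsq = SS / obs$ss_tot, F = Fv, P = P,
                    stringsAsFactors = FALSE)
  structure(out, class = c("anova_table", "data.frame"),
            total_SS = obs$ss_tot, n_perm = n_perm, seed = seed,
            design = list(a = a, b = b, r = r, q = q))
}

#' @export
print.anova_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$SS <- round(y$SS, 4); y$MS <- round(y$MS, 4)
  y$Rsq <- round(y$Rsq, 4); y$F <- round(y$F, 4)
  print(y, row.names = FALSE)
  cat(sprintf("Total SS = %.4f; %d permutations\n",
              attr(x, "total_SS"), attr(x, "n_perm")))
  invisible(x)
}

#' Variance components from the expected mean squares
#'
#' Inverts the expected-mean-square composition of the balanced
#' individual x side x replicate design: with per-coordinate components
#' `s2_me` (digitising error), `s2_fa` (individual x side) and `s2_ind`
#' (individual), and q shape variables, `E(MS_err) = q s2_me`,
#' `E(MS_int) = q (s2_me + r s2_fa)` and
#' `E(MS_ind) = q (s2_me + r s2_fa + b r s2_ind)`.
#'
#' @param aov an `anova_table` from the four-row symmetry design.
#' @return named numeric vector `c(sigma2_ind, sigma2_fa, sigma2_me)`.
#' @export
variance_components <- function(aov) {
  stopifnot(inherits(aov, "anova_table"))
  d <- attr(aov, "design")
  if (nrow(aov) != 4L) stop("variance components need the replicate-level design")
  ms <- aov$MS
  q <- d$q; r <- d$r; b <- d$b
  c(sigma2_ind = (ms[1] - ms[3]) / (b * r * q),
    sigma2_fa = (ms[3] - ms[4]) / (r * q),
    sigma2_me = ms[4] / q)
}

#' Directional and fluctuating asymmetry decomposition
#'
#' Runs the matching-symmetry Procrustes ANOVA and extracts the two
#' asymmetry summaries: the directional-asymmetry vector (consensus left
#' minus reflected-right displacement per landmark) and the per-individual
#' fluctuating-asymmetry deviations (centred signed left-right differences,
#' which sum to the zero vector).
#'
#' @param aligned an `aligned_set` from [matching_alignment()] (tangent
#'   variables and L/R metadata present; >= 2 sessions for the FA test).
#' @param n_perm,seed permutation settings passed to [procrustes_anova()].
#' @param alpha significance level for the DA/FA flags.
#' @return Object of class `asymmetry_result`: list with `anova`
#'   (`anova_table`), `da_vector` (`p x k` matrix), `fa_scores`
#'   (`n_individuals x (p*k)` matrix) and `flags` (logical `DA`, `FA`).
#' @export
decompose_asymmetry <- function(aligned, n_perm = 999L, seed = NULL,
                                alpha = 0.05) {
  stopifnot(inherits(aligned, "aligned_set"))
  if (is.null(aligned$tangent)) aligned <- project_to_tangent(aligned)
  aov <- procrustes_anova(aligned, n_perm = n_perm, seed = seed)
  p <- aligned$scheme$n_points; k <- aligned$scheme$dims
  ind <- factor(aligned$meta$individual)
  side <- factor(aligned$meta$side)
  cell <- interaction(ind, side, drop = FALSE)
  cell_mean <- rowsum(aligned$tangent, cell) / as.vector(table(cell))
  lv <- levels(ind)
  lmean <- cell_mean[paste(lv, "L", sep = "."), , drop = FALSE]
  rmean <- cell_mean[paste(lv, "R", sep = "."), , drop = FALSE]
  diffs <- lmean - rmean
  da_vec <- unvec_config(colMeans(diffs), p, k)
  fa <- sweep(diffs, 2, colMeans(diffs))
  rownames(fa) <- lv
  flags <- c(DA = isTRUE(aov$P[2] < alpha), FA = isTRUE(aov$P[3] < alpha))
  structure(list(anova = aov, da_vector = da_vec, fa_scores = fa,
                 flags = flags, alpha = alpha),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat("Matching-symmetry asymmetry decomposition\n")
  print(x$anova)
  cat(sprintf("directional asymmetry: |da| = %.5g, significant: %s (alpha = %g)\n",
              sqrt(sum(x$da_vector^2)), x$flags["DA"], x$alpha))
  cat(sprintf("fluctuating asymmetry significant: %s\n", x$flags["FA"]))
  invisible(x)
}

#' Per-landmark left-right asymmetry tests
#'
#' Tests each landmark (fixed and semi-landmarks alike) for a nonzero mean
#' left-minus-reflected-right displacement while controlling for
#' site-of-origin differences. For landmark j, the response is the
#' session-averaged aligned coordinate triple of every (individual, side)
#' pair; a partial redundancy analysis of that response on side, conditioned
#' on site, yields the semipartial adjusted R-squared, and the permutation
#' null flips the side labels within each individual (respecting the paired
#' structure). Raw and Benjamini-Hochberg-adjusted p-values are reported.
#'
#' @param aligned an `aligned_set` from [matching_alignment()].
#' @param site per-configuration site factor (default: metadata `site`).
#'   With fewer than 2 sites the test degrades to the uncontrolled version
#'   and the result carries a `warning` attribute.
#' @param n_perm,seed permutation settings.
#' @return data frame with one row per landmark: `landmark, R2_adj, P, P_bh`.
#' @export
per_landmark_asymmetry <- function(aligned, site = NULL, n_perm = 999L,
                                   seed = NULL) {
  stopifnot(inherits(aligned, "aligned_set"))
  meta <- aligned$meta
  site <- site %||% meta$site
  p <- aligned$scheme$n_points; k <- aligned$scheme$dims
  ind <- factor(meta$individual)
  sidef <- factor(meta$side)
  cell <- interaction(ind, sidef, drop = FALSE)
  csize_tab <- table(cell)
  # session-averaged coordinates per (individual, side), per landmark
  flat <- t(apply(aligned$coords, 3, vec_config))       # n_config x pk
  cmean <- rowsum(flat, cell) / as.vector(csize_tab)
  cell_ind <- sub("\\.[LR]$", "", rownames(cmean))
  cell_side <- sub("^.*\\.", "", rownames(cmean))
  site_by_ind <- tapply(as.character(site), ind, function(s) s[1])
  cell_site <- factor(site_by_ind[cell_ind])
  degraded <- nlevels(droplevels(cell_site)) < 2L
  Z <- if (degraded) NULL else cell_site
  res <- local_seed(seed, {
    rows <- lapply(seq_len(p), function(j) {
      cols <- j + (seq_len(k) - 1L) * p
      Yj <- cmean[, cols, drop = FALSE]
      fit <- paired_side_rda(Yj, factor(cell_side), Z, factor(cell_ind), n_perm)
      data.frame(landmark = j, R2_adj = fit$R2_adj, P = fit$P)
    })
    do.call(rbind, rows)
  })
  res$P_bh <- stats::p.adjust(res$P, method = "BH")
  if (degraded) {
    attr(res, "warning") <- "single site: per-landmark tests run without site control"
    warning(attr(res, "warning"))
  }
  res
}

# pRDA of Y on side given Z, with side labels flipped within individual as
# the permutation null
paired_side_rda <- function(Y, side, Z, ind, n_perm) {
  Yc <- sweep(Y, 2, colMeans(Y))
  n <- nrow(Yc)
  Xd <- center_dummies(side)
  Zd <- if (is.null(Z)) NULL else center_dummies(Z)
  r2 <- function(M) {
    if (is.null(M) || ncol(M) == 0L) return(list(r2 = 0, rank = 0L))
    qr_ <- qr(M)
    fit <- qr.fitted(qr_, Yc)
    list(r2 = sum(fit^2) / sum(Yc^2), rank = qr_$rank)
  }
  fz <- r2(Zd)
  stat <- function(Xd) {
    fxz <- r2(cbind(Zd, Xd))
    dfx <- fxz$rank - fz$rank
    if (dfx == 0L) return(list(f = 0, r2xz = fxz$r2, rxz = fxz$rank))
    f <- ((fxz$r2 - fz$r2) / dfx) / ((1 - fxz$r2) / (n - fxz$rank - 1L))
    list(f = f, r2xz = fxz$r2, rxz = fxz$rank)
  }
  obs <- stat(Xd)
  R2_adj <- adjusted_r2(obs$r2xz, n, obs$rxz) -
    (if (fz$rank > 0L) adjusted_r2(fz$r2, n, fz$rank) else 0)
  lv <- levels(ind)
  stat_perm <- numeric(n_perm)
  for (pi in seq_len(n_perm)) {
    flip <- sample(c(FALSE, TRUE), length(lv), replace = TRUE)
    names(flip) <- lv
    s2 <- as.character(side)
    swap <- flip[as.character(ind)]
    s2[swap] <- ifelse(s2[swap] == levels(side)[1], levels(side)[2], levels(side)[1])
    stat_perm[pi] <- stat(center_dummies(factor(s2, levels = levels(side))))$f
  }
  list(R2_adj = R2_adj, P = perm_pvalue(obs$f, stat_perm))
}
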