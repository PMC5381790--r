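#' Simulation parameters for bilateral landmark datasets
#'
#' Collects everything the generator needs: the landmark scheme, the
#' crescent-arch template parameters, the variance components of the
#' bilateral mixed model (individual, individual x side, digitising error),
#' an optional directional-asymmetry offset, per-site mean-shape shifts,
#' site-specific formula frequencies and the design sizes. All standard
#' deviations are per coordinate, in the raw units of the template (whose
#' centroid size is about 5.6 with defaults); a fixed seed makes the output
#' byte-identical.
#'
#' The default magnitudes (`sigma_ind` 0.02, `sigma_fa` 5e-4, `sigma_me`
#' 0.002, DA offset 0.0012 on 11 inner-margin landmarks) were calibrated once
#' so that the directional- and fluctuating-asymmetry tests have roughly 0.8
#' power at 35 individuals x 2 sides x 2 sessions — the sample size of the
#' largest single-group analyses this design emulates.
#'
#' @param scheme a [landmark_scheme()].
#' @param base_shape named list of template parameters (see
#'   [mean_arch_shape()]).
#' @param sigma_ind individual-level shape SD.
#' @param da_vector `p x dims` directional offset added to the left side
#'   (`NULL` = zero; see [da_inner_margin()]).
#' @param sigma_fa individual x side (fluctuating asymmetry) SD.
#' @param sigma_me digitising-replicate (measurement error) SD.
#' @param sigma_site SD of randomly drawn per-site mean-shape shifts, used
#'   when `site_effects` is `NULL`.
#' @param site_effects named list of `p x dims` matrices per site, or `NULL`.
#' @param formula_model named per-site probability of the alternative dental
#'   formula, or `NULL` for no formula records.
#' @param coupling add `da_vector` only to alternative-formula individuals?
#' @param basal_formula,alternative_formula formula strings for the records.
#' @param n_per_site named integer vector of individuals per site.
#' @param n_replicates digitising sessions per configuration.
#' @param seed integer seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(scheme = default_arch_scheme(), base_shape = list(),
                       sigma_ind = 0.02, da_vector = NULL, sigma_fa = 5e-4,
                       sigma_me = 0.002, sigma_site = 0.01,
                       site_effects = NULL, formula_model = NULL,
                       coupling = FALSE, basal_formula = "1,5–5,1",
                       alternative_formula = "1,5–4,1",
                       n_per_site = c(site01 = 35L), n_replicates = 2L,
                       seed = 1L) {
  stopifnot(sigma_ind >= 0, sigma_fa >= 0, sigma_me >= 0, sigma_site >= 0,
            n_replicates >= 1L, all(n_per_site >= 1L))
  if (is.null(names(n_per_site)))
    names(n_per_site) <- sprintf("site%02d", seq_along(n_per_site))
  if (!is.null(formula_model)) {
    if (any(formula_model < 0 | formula_model > 1))
      stop("formula probabilities must lie in [0, 1]")
    miss <- setdiff(names(n_per_site), names(formula_model))
    if (length(miss))
      stop("formula_model lacks probabilities for site(s): ",
           paste(miss, collapse = ", "))
  }
  if (!is.null(da_vector))
    stopifnot(all(dim(da_vector) == c(scheme$n_points, scheme$dims)))
  structure(list(scheme = scheme, base_shape = base_shape,
                 sigma_ind = sigma_ind, da_vector = da_vector,
                 sigma_fa = sigma_fa, sigma_me = sigma_me,
                 sigma_site = sigma_site, site_effects = site_effects,
                 formula_model = formula_model, coupling = coupling,
                 basal_formula = basal_formula,
                 alternative_formula = alternative_formula,
                 n_per_site = n_per_site, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Deterministic crescent-arch template configuration
#'
#' Builds the mean left-side configuration: each semi-landmark chain is laid
#' along a circular arc (the outer ridge on the larger radius, the inner
#' tooth-bearing curve on the smaller one, offset in z and bowed out of
#' plane), anchors at the arc ends, and any remaining fixed landmarks placed
#' at deterministic positions beyond the arc span (the tips anchoring the
#' arch in the pharyngeal cavity). The right-side template is this shape
#' mirrored in x.
#'
#' @param scheme a [landmark_scheme()].
#' @param base_shape named list overriding any of `r_outer` (1), `r_inner`
#'   (0.65), `arc_span` (2.2 rad), `z_sep` (0.12), `z_bow` (0.15).
#' @return `p x dims` coordinate matrix.
#' @export
mean_arch_shape <- function(scheme, base_shape = list()) {
  bp <- utils::modifyList(list(r_outer = 1, r_inner = 0.65, arc_span = 2.2,
                               z_sep = 0.12, z_bow = 0.15), base_shape)
  if (bp$arc_span <= 1e-6) stop("degenerate template: arc_span must be > 0")
  if (bp$r_outer <= 0 || bp$r_inner <= 0) stop("degenerate template: radii must be > 0")
  p <- scheme$n_points; k <- scheme$dims
  X <- matrix(NA_real_, p, k)
  nch <- length(scheme$chains)
  radii <- if (nch <= 1L) bp$r_outer else
    seq(bp$r_outer, bp$r_inner, length.out = nch)
  zoff <- if (nch <= 1L) 0 else seq(0, bp$z_sep, length.out = nch)
  for (c_i in seq_along(scheme$chains)) {
    ch <- scheme$chains[[c_i]]
    idx <- c(ch$start, ch$semis, ch$end)
    ang <- seq(-bp$arc_span / 2, bp$arc_span / 2, length.out = length(idx))
    X[idx, 1] <- radii[c_i] * cos(ang)
    X[idx, 2] <- radii[c_i] * sin(ang)
    if (k == 3L) X[idx, 3] <- zoff[c_i] + bp$z_bow * sin(ang)
  }
  loose <- setdiff(scheme$fixed, unlist(lapply(scheme$chains, function(ch)
    c(ch$start, ch$end))))
  if (length(loose)) {
    ang <- bp$arc_span / 2 + 0.35 * seq_along(loose)
    r <- 1.12 * bp$r_outer
    X[loose, 1] <- r * cos(ang)
    X[loose, 2] <- r * sin(ang)
    if (k == 3L) X[loose, 3] <- 0.08 * (-1)^(seq_along(loose))
  }
  if (anyNA(X)) {  # scheme without chains: spread all points on the arc
    todo <- which(is.na(X[, 1]))
    ang <- seq(-bp$arc_span / 2, bp$arc_span / 2, length.out = length(todo))
    X[todo, 1] <- bp$r_outer * cos(ang)
    X[todo, 2] <- bp$r_outer * sin(ang)
    if (k == 3L) X[todo, 3] <- bp$z_bow * sin(ang)
  }
  X
}

#' Directional-asymmetry offset on the inner tooth-bearing margin
#'
#' Builds a `p x dims` offset matrix displacing landmarks of the inner
#' (tooth-bearing) semi-landmark chain — where a missing right-side tooth
#' shows up — by `magnitude` along the out-of-plane axis.
#'
#' @param scheme a [landmark_scheme()].
#' @param magnitude per-landmark displacement (raw template units).
#' @param n_landmarks how many central landmarks of the last chain to move.
#' @return `p x dims` matrix (zero elsewhere).
#' @export
da_inner_margin <- function(scheme, magnitude = 0.0012, n_landmarks = 11L) {
  p <- scheme$n_points; k <- scheme$dims
  D <- matrix(0, p, k)
  if (!length(scheme$chains)) stop("scheme has no chains to carry the offset")
  ch <- scheme$chains[[length(scheme$chains)]]
  semis <- ch$semis
  n_landmarks <- min(n_landmarks, length(semis))
  mid <- seq(from = floor((length(semis) - n_landmarks) / 2) + 1L,
             length.out = n_landmarks)
  D[semis[mid], k] <- magnitude
  D
}

# Bernoulli formula draws for one vector of site labels (uses current RNG)
draw_formulae <- function(sites, params) {
  pr <- params$formula_model[sites]
  alt <- stats::runif(length(sites)) < pr
  data.frame(alternative = alt,
             formula = ifelse(alt, params$alternative_formula,
                              params$basal_formula),
             stringsAsFactors = FALSE)
}

# per-site mean-shape displacement matrices (uses current RNG when random)
site_effect_list <- function(params) {
  sites <- names(params$n_per_site)
  if (!is.null(params$site_effects)) {
    miss <- setdiff(sites, names(params$site_effects))
    if (length(miss)) stop("site_effects missing site(s): ", paste(miss, collapse = ", "))
    return(params$site_effects[sites])
  }
  p <- params$scheme$n_points; k <- params$scheme$dims
  stats::setNames(lapply(sites, function(s)
    matrix(stats::rnorm(p * k, sd = params$sigma_site), p, k)), sites)
}

#' Simulate dental-formula records
#'
#' One Bernoulli draw per individual of basal vs alternative formula with
#' the site-specific probability of `params$formula_model`. The draws use
#' the same seeded stream position as [simulate_shapes()], so shapes and
#' records generated from the same `sim_params` agree.
#'
#' @param params a [sim_params()] with a `formula_model`.
#' @return data frame `individual, site, lineage, biotype, formula,
#'   alternative`.
#' @export
simulate_formulae <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(params$formula_model))
    stop("params carry no formula_model")
  sites <- rep(names(params$n_per_site), params$n_per_site)
  ids <- sprintf("ind%03d", seq_along(sites))
  local_seed(params$seed, {
    fm <- draw_formulae(sites, params)
    data.frame(individual = ids, site = sites, lineage = "B-01",
               biotype = "hybrid", formula = fm$formula,
               alternative = fm$alternative, stringsAsFactors = FALSE)
  })
}

#' Simulate a bilateral landmark dataset
#'
#' Generates, for each individual: shape = template + site shift +
#' individual deviation; the left side additionally carries the directional
#' offset (for all individuals, or only alternative-formula individuals when
#' `coupling` is on) and its own individual x side deviation; the right side
#' is the mirrored shape with an independent individual x side deviation;
#' every digitising session adds independent error. All deviations are
#' isotropic Gaussian per landmark coordinate.
#'
#' @param params a [sim_params()].
#' @return A [configuration_set()]; when `params$formula_model` is set, the
#'   per-individual records are attached as attribute `records`.
#' @export
simulate_shapes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  scheme <- params$scheme
  p <- scheme$n_points; k <- scheme$dims
  base <- mean_arch_shape(scheme, params$base_shape)
  da <- params$da_vector
  sites <- rep(names(params$n_per_site), params$n_per_site)
  n_ind <- length(sites)
  ids <- sprintf("ind%03d", seq_len(n_ind))
  nr <- params$n_replicates
  local_seed(params$seed, {
    records <- NULL
    if (!is.null(params$formula_model)) {
      fm <- draw_formulae(sites, params)
      records <- data.frame(individual = ids, site = sites, lineage = "B-01",
                            biotype = "hybrid", formula = fm$formula,
                            alternative = fm$alternative,
                            stringsAsFactors = FALSE)
    }
    eff <- site_effect_list(params)
    n_cfg <- n_ind * 2L * nr
    coords <- array(NA_real_, dim = c(p, k, n_cfg))
    meta <- vector("list", n_cfg)
    ci <- 0L
    for (i in seq_len(n_ind)) {
      S <- base + eff[[sites[i]]] +
        matrix(stats::rnorm(p * k, sd = params$sigma_ind), p, k)
      add_da <- !is.null(da) &&
        (!params$coupling || isTRUE(records$alternative[i]))
      core <- list(L = S + if (add_da) da else 0,
                   R = reflect_side(S, 1L))
      for (side in c("L", "R")) {
        cell <- core[[side]] +
          matrix(stats::rnorm(p * k, sd = params$sigma_fa), p, k)
        for (r in seq_len(nr)) {
          ci <- ci + 1L
          coords[, , ci] <- cell +
            matrix(stats::rnorm(p * k, sd = params$sigma_me), p, k)
          meta[[ci]] <- data.frame(
            individual = ids[i], biotype = "hybrid", lineage = "B-01",
            site = sites[i],
            dental_formula = if (is.null(records)) NA_character_
                             else records$formula[i],
            session = as.character(r), side = side, stringsAsFactors = FALSE)
        }
      }
    }
    set <- configuration_set(coords, do.call(rbind, meta), scheme)
    attr(set, "records") <- records
    set
  })
}

#' Synthetic dataset mimicking the full shape-study design
#'
#' A packaged fixture generator reproducing the design dimensions of the
#' shape analysis — 66 clonal hybrid individuals of one lineage spread over
#' 7 sites, 2 sides, 2 digitising sessions, 33 landmarks in 3D, with
#' site-dependent alternative-formula frequencies and the directional offset
#' coupled to the alternative formula — with the generator's default
#' magnitudes. Optionally appends parental-species groups (43 + 14
#' individuals with biotype-specific mean shapes and stable formulae) so the
#' biotype-level ordination and trajectory stages can be exercised.
#'
#' @param seed integer seed.
#' @param include_parentals add the two parental-species groups?
#' @return list with `configs` (a [configuration_set()]) and `records` (the
#'   per-individual formula data frame).
#' @export
study_mimic_dataset <- function(seed = 1L, include_parentals = FALSE) {
  n_hyb <- c("AS-3" = 10L, "AS-8" = 9L, "AS-13" = 19L, "NO-1" = 9L,
             "NO-5" = 11L, "NO-7" = 2L, "NO-10" = 6L)
  p_alt <- c("AS-3" = 0.5, "AS-8" = 0.4, "AS-13" = 0.3, "NO-1" = 0.6,
             "NO-5" = 0.9, "NO-7" = 0.5, "NO-10" = 0.45)
  scheme <- default_arch_scheme()
  pars <- sim_params(scheme = scheme,
                     da_vector = da_inner_margin(scheme),
                     formula_model = p_alt, coupling = TRUE,
                     n_per_site = n_hyb, seed = seed)
  set <- simulate_shapes(pars)
  records <- attr(set, "records")
  if (include_parentals) {
    p <- scheme$n_points; k <- scheme$dims
    wave <- function(f, a) {
      M <- matrix(0, p, k)
      t <- seq_len(p) / p
      M[, 2] <- a * sin(2 * pi * f * t)
      M[, k] <- M[, k] + a * cos(2 * pi * f * t)
      M
    }
    make_parent <- function(biotype, lineage, formula, n_site, shift, seed_off) {
      pp <- sim_params(scheme = scheme, n_per_site = n_site,
                       seed = seed + seed_off)
      ps <- simulate_shapes(pp)
      for (i in seq_len(dim(ps$coords)[3])) {
        sgn <- if (ps$meta$side[i] == "R") reflect_side(shift, 1L) else shift
        ps$coords[, , i] <- ps$coords[, , i] + sgn
      }
      ps$meta$biotype <- biotype
      ps$meta$lineage <- lineage
      ps$meta$dental_formula <- formula
      ps$meta$individual <- paste0(biotype, "_", ps$meta$individual)
      ps
    }
    eos <- make_parent("eos", "EOS", "0,5–5,0",
                       c("AS-3" = 28L, "AS-13" = 6L, "NO-10" = 9L),
                       wave(1.5, 0.03), 101L)
    neo <- make_parent("neogaeus", "NEO", "2,5–4,2",
                       c("AS-3" = 14L), wave(2.5, 0.05), 202L)
    coords <- array(c(set$coords, eos$coords, neo$coords),
                    dim = c(p, k, dim(set$coords)[3] + dim(eos$coords)[3] +
                              dim(neo$coords)[3]))
    meta <- rbind(set$meta, eos$meta, neo$meta)
    set <- configuration_set(coords, meta, scheme)
    par_rec <- unique(rbind(
      data.frame(individual = eos$meta$individual, site = eos$meta$site,
                 lineage = "EOS", biotype = "eos",
                 formula = "0,5–5,0", alternative = FALSE,
                 stringsAsFactors = FALSE),
      data.frame(individual = neo$meta$individual, site = neo$meta$site,
                 lineage = "NEO", biotype = "neogaeus",
                 formula = "2,5–4,2", alternative = FALSE,
                 stringsAsFactors = FALSE)))
    records <- rbind(records, par_rec)
  }
  list(configs = set, records = records)
}
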