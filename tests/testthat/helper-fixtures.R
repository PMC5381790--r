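# small schemes and datasets shared across tests (all generated in code)

# 9-point 3D scheme with one 6-semi-landmark chain
quick_scheme <- function() {
  landmark_scheme(n_points = 9L, dims = 3L, fixed = c(1L, 2L, 9L),
                  chains = list(list(start = 2L, semis = 3:8, end = 9L)))
}

# chainless scheme (no sliding): all landmarks fixed
flat_scheme <- function(p = 6L, dims = 3L) {
  landmark_scheme(n_points = p, dims = dims, fixed = seq_len(p),
                  chains = list())
}

# small bilateral simulated set
quick_bilateral <- function(n = 8L, seed = 1L, scheme = quick_scheme(), ...) {
  simulate_shapes(sim_params(scheme = scheme, n_per_site = c(s1 = n),
                             seed = seed, ...))
}

# planar triangle configurations (2D) as a configuration_set
triangle_set <- function(mats) {
  coords <- array(unlist(mats), dim = c(3L, 2L, length(mats)))
  meta <- data.frame(individual = sprintf("t%d", seq_along(mats)),
                     side = "L", session = "1", stringsAsFactors = FALSE)
  configuration_set(coords, meta,
                    landmark_scheme(3L, 2L, fixed = 1:3, chains = list()))
}

rotation_z <- function(th) {
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

rotation_2d <- function(th) {
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
}

sort_configs_for_test <- function(set) archasym:::sort_configs(set)
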