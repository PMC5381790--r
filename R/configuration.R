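#' Sets of landmark configurations with specimen metadata
#'
#' A `configuration_set` bundles an array of landmark coordinates with the
#' specimen metadata the downstream analyses need: individual id, biotype,
#' clonal lineage, sampling site, dental formula, digitising session
#' (replicate) and side (L/R). Coordinates are stored as a
#' `n_points x dims x n_configs` array; one slice per configuration.
#'
#' @param coords numeric array `p x k x n` (or a `p x k` matrix for a single
#'   configuration). All values must be finite.
#' @param meta data frame with one row per configuration. Required columns:
#'   `individual`, `side` (values "L"/"R"), `session`. Optional columns
#'   `biotype`, `lineage`, `site`, `dental_formula` are filled with `NA`
#'   when absent. `(individual, side, session)` triples must be unique.
#' @param scheme a [landmark_scheme()] matching the first two array dims.
#' @return An object of class `configuration_set`.
#' @export
configuration_set <- function(coords, meta, scheme) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  if (!inherits(scheme, "landmark_scheme")) stop("scheme must be a landmark_scheme")
  if (dim(coords)[1] != scheme$n_points || dim(coords)[2] != scheme$dims)
    stop(sprintf("coords are %d x %d but scheme expects %d x %d",
                 dim(coords)[1], dim(coords)[2], scheme$n_points, scheme$dims))
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  n <- dim(coords)[3]
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n) stop("meta must have one row per configuration")
  req <- c("individual", "side", "session")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("meta lacks required column(s): ", paste(miss, collapse = ", "))
  if (!all(meta$side %in% c("L", "R"))) stop("side must be 'L' or 'R'")
  for (opt in c("biotype", "lineage", "site", "dental_formula"))
    if (is.null(meta[[opt]])) meta[[opt]] <- NA_character_
  key <- paste(meta$individual, meta$side, meta$session, sep = "|")
  if (anyDuplicated(key))
    stop("duplicated (individual, side, session): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(meta) <- NULL
  structure(list(scheme = scheme, coords = coords, meta = meta),
            class = "configuration_set")
}

#' @export
print.configuration_set <- function(x, ...) {
  cat(sprintf("configuration set: %d configurations of %d landmarks in %dD\n",
              n_configs(x), x$scheme$n_points, x$scheme$dims))
  cat(sprintf("  %d individual(s), sides: %s, sessions: %s\n",
              length(unique(x$meta$individual)),
              paste(sort(unique(x$meta$side)), collapse = "/"),
              paste(sort(unique(x$meta$session)), collapse = "/")))
  invisible(x)
}

#' @param set a `configuration_set`.
#' @return `n_configs()`: number of configurations in the set.
#' @rdname configuration_set
#' @export
n_configs <- function(set) dim(set$coords)[3]

#' @param idx integer or logical index over configurations.
#' @return `subset_configs()`: a `configuration_set` restricted to `idx`.
#' @rdname configuration_set
#' @export
subset_configs <- function(set, idx) {
  configuration_set(set$coords[, , idx, drop = FALSE],
                    set$meta[idx, , drop = FALSE], set$scheme)
}

# canonical ordering: individual, side, session (reader output must not
# depend on input row order)
sort_configs <- function(set) {
  o <- order(set$meta$individual, set$meta$side, set$meta$session)
  subset_configs(set, o)
}
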