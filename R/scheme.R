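#' Landmark scheme for one side of a bilateral structure
#'
#' Bookkeeping for a landmark configuration made of fixed (discrete,
#' homologous) landmarks and ordered chains of sliding semi-landmarks, each
#' chain delimited by two fixed anchor landmarks. The default scheme is the
#' 33-point, 3D pharyngeal-arch template: seven fixed landmarks and two
#' 13-point semi-landmark chains, the outer ridge running from landmark 4 to
#' 18 and the inner (tooth-bearing) curve from 19 to 33.
#'
#' All indices are 1-based. Fixed and semi-landmark indices must be disjoint,
#' lie in `1..n_points`, and jointly cover every point; chain anchors must be
#' fixed landmarks.
#'
#' @param n_points number of landmarks per side.
#' @param dims spatial dimension (2 or 3).
#' @param fixed integer vector of fixed-landmark indices.
#' @param chains list of semi-landmark chains; each chain is a list with
#'   elements `start` (anchor index), `semis` (ordered semi-landmark
#'   indices) and `end` (anchor index). May be empty (no sliding).
#' @return An object of class `landmark_scheme`.
#' @examples
#' sc <- landmark_scheme()          # the 33-point arch scheme
#' sc$fixed
#' semilandmarks(sc)
#' @export
landmark_scheme <- function(n_points = 33L, dims = 3L,
                            fixed = c(1L, 2L, 3L, 4L, 18L, 19L, 33L),
                            chains = list(
                              list(start = 4L, semis = 5:17, end = 18L),
                              list(start = 19L, semis = 20:32, end = 33L))) {
  n_points <- as.integer(n_points)
  dims <- as.integer(dims)
  fixed <- as.integer(sort(unique(fixed)))
  if (n_points < 3L) stop("a scheme needs at least 3 points")
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  chains <- lapply(chains, function(ch) {
    ch <- list(start = as.integer(ch$start), semis = as.integer(ch$semis),
               end = as.integer(ch$end))
    if (length(ch$semis) < 1L) stop("each chain needs at least one semi-landmark")
    ch
  })
  semis <- unlist(lapply(chains, `[[`, "semis"))
  if (anyDuplicated(semis)) stop("semi-landmark indices duplicated across chains")
  if (length(intersect(fixed, semis)))
    stop("fixed and semi-landmark indices must be disjoint")
  idx <- c(fixed, semis)
  if (any(idx < 1L | idx > n_points)) stop("landmark index outside 1..n_points")
  if (length(idx) != n_points || !setequal(idx, seq_len(n_points)))
    stop("fixed landmarks and chains must jointly cover all points")
  for (ch in chains)
    if (!all(c(ch$start, ch$end) %in% fixed))
      stop("chain anchors must be fixed landmarks")
  structure(list(n_points = n_points, dims = dims, fixed = fixed,
                 chains = chains),
            class = "landmark_scheme")
}

#' @rdname landmark_scheme
#' @export
default_arch_scheme <- function() landmark_scheme()

#' @param scheme a `landmark_scheme`.
#' @return `semilandmarks()`: sorted integer vector of all semi-landmark
#'   indices in the scheme.
#' @rdname landmark_scheme
#' @export
semilandmarks <- function(scheme) {
  sort(unlist(lapply(scheme$chains, `[[`, "semis")))
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat(sprintf("landmark scheme: %d points in %dD; %d fixed, %d semi-landmarks in %d chain(s)\n",
              x$n_points, x$dims, length(x$fixed),
              length(semilandmarks(x)), length(x$chains)))
  invisible(x)
}
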