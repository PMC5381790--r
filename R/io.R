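#' Read a long-format landmark coordinate table
#'
#' Reads the canonical long CSV layout: one row per
#' individual x side x digitising session x landmark, with X/Y/Z coordinates
#' and specimen metadata, and assembles a [configuration_set()]. Row order in
#' the file is irrelevant; configurations are sorted canonically by
#' (individual, side, session) and landmark rows by index.
#'
#' @param path path to a comma-separated text file with a header.
#' @param scheme optional [landmark_scheme()]; when `NULL` a chainless scheme
#'   is inferred (`n_points` from the largest landmark index, `dims` 3 when a
#'   z column is mapped and non-empty, else 2).
#' @param columns named character vector mapping the canonical roles
#'   `individual, biotype, lineage, site, dental_formula, session, side,
#'   landmark, x, y, z` to the file's column names. Roles absent from the
#'   file may be dropped from the mapping (metadata roles become `NA`; a
#'   missing `z` gives 2D data).
#' @return A `configuration_set`.
#' @section Errors:
#' Duplicated (individual, side, session, landmark) rows, non-numeric
#' coordinates (reported with file row numbers) and landmark-count mismatches
#' against the scheme are hard errors.
#' @seealso [write_long_table()], [read_tps()]
#' @export
read_long_table <- function(path, scheme = NULL, columns = long_table_columns()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE)
  need <- c("individual", "session", "side", "landmark", "x", "y")
  for (role in need)
    if (is.na(columns[role] %||% NA) || !columns[[role]] %in% names(raw))
      stop("input lacks a column for role '", role, "'")
  get_col <- function(role) {
    nm <- columns[role]
    if (is.na(nm) || !nm %in% names(raw)) rep(NA_character_, nrow(raw)) else raw[[nm]]
  }
  num_col <- function(role) {
    v <- get_col(role)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v) & nzchar(trimws(v)))
    if (length(bad))
      stop(sprintf("non-numeric %s coordinate at file row(s) %s", role,
                   paste(bad + 1L, collapse = ", ")))  # +1 for header line
    out
  }
  d <- data.frame(individual = get_col("individual"),
                  biotype = get_col("biotype"), lineage = get_col("lineage"),
                  site = get_col("site"), dental_formula = get_col("dental_formula"),
                  session = get_col("session"), side = get_col("side"),
                  landmark = as.integer(get_col("landmark")),
                  x = num_col("x"), y = num_col("y"),
                  stringsAsFactors = FALSE)
  has_z <- !is.na(columns["z"] %||% NA) && columns[["z"]] %in% names(raw)
  if (has_z) {
    d$z <- num_col("z")
    if (all(is.na(d$z))) has_z <- FALSE
  }
  if (anyNA(d$landmark)) stop("non-integer landmark index in input")
  key <- paste(d$individual, d$side, d$session, d$landmark, sep = "|")
  if (anyDuplicated(key))
    stop("duplicated (individual, side, session, landmark) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (is.null(scheme)) {
    p <- max(d$landmark)
    scheme <- landmark_scheme(n_points = p, dims = if (has_z) 3L else 2L,
                              fixed = seq_len(p), chains = list())
  }
  cfg_key <- paste(d$individual, d$side, d$session, sep = "|")
  groups <- split(seq_len(nrow(d)), cfg_key)
  p <- scheme$n_points
  counts <- lengths(groups)
  if (any(counts != p))
    stop("landmark count mismatch (expected ", p, ") for configuration(s): ",
         paste(names(groups)[counts != p], collapse = "; "))
  ids <- names(groups)
  coords <- array(NA_real_, dim = c(p, scheme$dims, length(groups)))
  meta <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- d[groups[[i]], , drop = FALSE]
    if (!setequal(g$landmark, seq_len(p)))
      stop("landmark indices for configuration ", ids[i],
           " do not cover 1..", p)
    g <- g[order(g$landmark), , drop = FALSE]
    coords[, 1, i] <- g$x
    coords[, 2, i] <- g$y
    if (scheme$dims == 3L) coords[, 3, i] <- g$z
    meta[[i]] <- g[1, c("individual", "biotype", "lineage", "site",
                        "dental_formula", "session", "side")]
  }
  meta <- do.call(rbind, meta)
  sort_configs(configuration_set(coords, meta, scheme))
}

#' @return `long_table_columns()`: the default identity column mapping.
#' @rdname read_long_table
#' @export
long_table_columns <- function() {
  roles <- c("individual", "biotype", "lineage", "site", "dental_formula",
             "session", "side", "landmark", "x", "y", "z")
  stats::setNames(roles, roles)
}

#' Write a configuration set as a long-format CSV
#'
#' Inverse of [read_long_table()]: one row per landmark, stable column order
#' (`individual,biotype,lineage,site,dental_formula,session,side,landmark,x,y,z`),
#' coordinates printed with 17 significant digits so that a read/write round
#' trip is bit-exact.
#'
#' @param set a non-empty [configuration_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(set, path) {
  stopifnot(inherits(set, "configuration_set"))
  if (n_configs(set) == 0L) stop("cannot write an empty configuration set")
  set <- sort_configs(set)
  p <- set$scheme$n_points
  k <- set$scheme$dims
  n <- n_configs(set)
  meta <- set$meta[rep(seq_len(n), each = p), , drop = FALSE]
  out <- data.frame(meta[c("individual", "biotype", "lineage", "site",
                           "dental_formula", "session", "side")],
                    landmark = rep(seq_len(p), n),
                    stringsAsFactors = FALSE)
  fmt <- function(v) sprintf("%.17g", v)
  out$x <- fmt(as.vector(set$coords[, 1, ]))
  out$y <- fmt(as.vector(set$coords[, 2, ]))
  if (k == 3L) out$z <- fmt(as.vector(set$coords[, 3, ]))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a TPS landmark file
#'
#' Minimal reader for the classic TPS dialect used for 2D fixtures: `LM=n`
#' starts a block of `n` coordinate lines; an optional `ID=label` line (before
#' or after the coordinates of its block) names the specimen. All blocks must
#' have the same landmark count.
#'
#' @param path path to a TPS text file.
#' @return A [configuration_set()] of 2D configurations (side "L",
#'   session "1"), with a chainless scheme inferred from the first block.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  blocks <- list(); cur <- NULL
  for (ln in lines) {
    if (grepl("^LM\\s*=", ln, ignore.case = TRUE)) {
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- list(n = as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE)),
                  coords = list(), id = NA_character_)
    } else if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
      if (is.null(cur)) stop("ID= line before any LM= block")
      cur$id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
    } else if (grepl("^[A-Za-z]+\\s*=", ln)) {
      next  # other TPS keys (IMAGE=, SCALE=, ...) ignored
    } else {
      if (is.null(cur)) stop("coordinate line before any LM= block")
      cur$coords[[length(cur$coords) + 1L]] <- as.numeric(strsplit(ln, "\\s+")[[1]])
    }
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
  if (!length(blocks)) stop("no LM= blocks found in ", path)
  ns <- vapply(blocks, `[[`, integer(1), "n")
  if (length(unique(ns)) != 1L)
    stop("inconsistent LM counts across blocks: ", paste(unique(ns), collapse = ", "))
  p <- ns[1]
  coords <- array(NA_real_, dim = c(p, 2L, length(blocks)))
  ids <- character(length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (length(b$coords) != b$n)
      stop("block ", i, " declares LM=", b$n, " but has ", length(b$coords),
           " coordinate lines")
    m <- do.call(rbind, b$coords)
    if (ncol(m) < 2L || anyNA(m[, 1:2])) stop("malformed coordinates in block ", i)
    coords[, , i] <- m[, 1:2]
    ids[i] <- if (is.na(b$id)) sprintf("specimen_%03d", i) else b$id
  }
  scheme <- landmark_scheme(n_points = p, dims = 2L, fixed = seq_len(p),
                            chains = list())
  meta <- data.frame(individual = ids, side = "L", session = "1",
                     stringsAsFactors = FALSE)
  configuration_set(coords, meta, scheme)
}
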