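HABITATS <- c("natural", "agricultural", "urban")

#' Filter occurrence records on year and coordinate precision
#'
#' Keeps records whose year lies in `[min_year, max_year]` (inclusive) and
#' whose latitude and longitude both carry at least `min_decimals` decimal
#' places. Precision is judged on the original textual coordinates when the
#' record carries them (`lat_text`/`lon_text` columns), because trailing zeros
#' are invisible once a coordinate is a float; otherwise the shortest
#' round-trip rendering of the numeric value is used.
#'
#' @param records data frame with columns `species`, `lat`, `lon`, `year` and
#'   optionally `lat_text`, `lon_text`.
#' @param min_year,max_year inclusive year bounds.
#' @param min_decimals minimum decimal places required of both coordinates.
#' @return the retained records, with a `"filter_counts"` attribute recording
#'   counts before/after each criterion.
#' @export
filter_records <- function(records, min_year = 1990, max_year = 2022,
                           min_decimals = 2) {
  validate_records(records)
  n0 <- nrow(records)
  ok_year <- records$year >= min_year & records$year <= max_year
  lat_txt <- if ("lat_text" %in% names(records)) records$lat_text else records$lat
  lon_txt <- if ("lon_text" %in% names(records)) records$lon_text else records$lon
  ok_dec <- n_decimals(lat_txt) >= min_decimals & n_decimals(lon_txt) >= min_decimals
  out <- records[ok_year & ok_dec, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(input = n0, year_pass = sum(ok_year),
                                  decimals_pass = sum(ok_dec),
                                  retained = nrow(out))
  out
}

validate_records <- function(records) {
  req <- c("species", "lat", "lon", "year")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (any(records$lat < -90 | records$lat > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]")
  }
  if (any(records$lon < -180 | records$lon > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]")
  }
  invisible(records)
}

#' Read occurrence records from CSV
#'
#' Accepts either the package's native column names (`species`, `lat`, `lon`,
#' `year`) or GBIF "simple CSV" names (`species`, `decimalLatitude`,
#' `decimalLongitude`, `year`), or an explicit `col_map`. Coordinate columns
#' are additionally kept as text (`lat_text`, `lon_text`) so decimal-precision
#' filtering can see trailing zeros.
#'
#' @param file CSV path with a header.
#' @param col_map optional named character vector mapping native names to the
#'   file's column names, e.g. `c(lat = "decimalLatitude")`.
#' @return a records data frame.
#' @export
read_records_csv <- function(file, col_map = NULL) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
  gbif <- c(lat = "decimalLatitude", lon = "decimalLongitude")
  map <- c(species = "species", lat = "lat", lon = "lon", year = "year")
  for (k in names(gbif)) if (gbif[[k]] %in% names(raw)) map[[k]] <- gbif[[k]]
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  missing <- map[!map %in% names(raw)]
  if (length(missing)) stop("missing column(s) in ", file, ": ",
                            paste(missing, collapse = ", "))
  out <- data.frame(species = raw[[map[["species"]]]],
                    lat = as.numeric(raw[[map[["lat"]]]]),
                    lon = as.numeric(raw[[map[["lon"]]]]),
                    year = as.integer(raw[[map[["year"]]]]),
                    lat_text = raw[[map[["lat"]]]],
                    lon_text = raw[[map[["lon"]]]],
                    stringsAsFactors = FALSE)
  validate_records(out)
  out
}

#' Construct a habitat grid
#'
#' A regular lat/lon grid whose cells each carry one of the three habitat
#' classes (natural, agricultural, urban). Row 1 is the *minimum*-latitude
#' edge; cells are closed on their lower edge and open on the upper in both
#' axes, so boundary points resolve deterministically to the lower-index cell.
#'
#' @param classes character matrix (`n_rows` x `n_cols`) of habitat classes,
#'   or integer cover codes if `reclass` is supplied.
#' @param bbox numeric vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param reclass optional data frame `code`, `class` mapping raw cover codes
#'   to the three classes; must cover every code present.
#' @return an object of class `"habitat_grid"`.
#' @export
habitat_grid <- function(classes, bbox, reclass = NULL) {
  if (!is.null(reclass)) {
    if (!all(c("code", "class") %in% names(reclass))) {
      stop("reclass needs columns `code` and `class`")
    }
    idx <- match(as.vector(classes), reclass$code)
    if (anyNA(idx)) {
      stop("cover code(s) missing from reclass table: ",
           paste(unique(as.vector(classes)[is.na(idx)]), collapse = ", "))
    }
    classes <- matrix(reclass$class[idx], nrow(classes), ncol(classes))
  }
  if (!all(classes %in% HABITATS)) {
    stop("grid classes must all be one of: ", paste(HABITATS, collapse = ", "))
  }
  stopifnot(length(bbox) == 4, bbox[1] < bbox[2], bbox[3] < bbox[4])
  structure(list(classes = classes, bbox = as.numeric(bbox),
                 n_rows = nrow(classes), n_cols = ncol(classes)),
            class = "habitat_grid")
}

#' @export
print.habitat_grid <- function(x, ...) {
  cat("habitat_grid:", x$n_rows, "x", x$n_cols, "cells, bbox [",
      paste(format(x$bbox, digits = 6), collapse = ", "), "]\n")
  print(table(factor(x$classes, HABITATS)))
  invisible(x)
}

grid_cell <- function(grid, lat, lon) {
  dy <- (grid$bbox[2] - grid$bbox[1]) / grid$n_rows
  dx <- (grid$bbox[4] - grid$bbox[3]) / grid$n_cols
  row <- floor((lat - grid$bbox[1]) / dy) + 1   # row 1 = minimum-latitude edge
  col <- floor((lon - grid$bbox[3]) / dx) + 1
  inside <- lat >= grid$bbox[1] & lat < grid$bbox[2] &
    lon >= grid$bbox[3] & lon < grid$bbox[4]
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  cbind(row = row, col = col)
}

#' Assign a habitat class to each occurrence record
#'
#' Looks each record's point up in the grid ([closed, open) cells, boundary
#' points to the lower-index cell). Points outside the grid are dropped and
#' counted (default) or raise an error in strict mode.
#'
#' @param records a records data frame.
#' @param grid a `"habitat_grid"`.
#' @param strict logical; error on out-of-grid points instead of dropping.
#' @return records with an added `habitat` column and a `"dropped_outside"`
#'   attribute giving the number of out-of-grid records removed.
#' @export
assign_habitat <- function(records, grid, strict = FALSE) {
  validate_records(records)
  stopifnot(inherits(grid, "habitat_grid"))
  rc <- grid_cell(grid, records$lat, records$lon)
  outside <- is.na(rc[, 1])
  if (any(outside) && strict) {
    stop(sum(outside), " record(s) fall outside the habitat grid")
  }
  keep <- which(!outside)
  out <- records[keep, , drop = FALSE]
  out$habitat <- grid$classes[cbind(rc[keep, 1], rc[keep, 2])]
  rownames(out) <- NULL
  attr(out, "dropped_outside") <- sum(outside)
  out
}

#' Build the species-by-habitat occurrence matrix
#'
#' @param records habitat-labelled records (from [assign_habitat()]).
#' @return integer matrix, species rows (alphabetical) by the three habitat
#'   columns in the fixed order natural, agricultural, urban.
#' @export
build_matrix <- function(records) {
  if (!"habitat" %in% names(records)) stop("records must carry a `habitat` column")
  tab <- table(factor(records$species), factor(records$habitat, HABITATS))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), HABITATS))
  m
}

#' Drop species with too few records
#'
#' @param mat occurrence matrix (species x habitat counts).
#' @param min_records minimum row total (inclusive) for a species to be kept.
#' @return the filtered matrix.
#' @export
apply_min_records <- function(mat, min_records = 50) {
  keep <- rowSums(mat) >= min_records
  if (!any(keep)) stop("no species with at least ", min_records, " records")
  mat[keep, , drop = FALSE]
}

#' Random contingency table with fixed margins (Patefield sampler)
#'
#' Draws tables from the conditional distribution of independent counts given
#' the margins (probability proportional to
#' `prod(r_i!) prod(c_j!) / (N! prod(t_ij!))`), via Patefield's AS 159
#' algorithm as implemented in [stats::r2dtable()]. Deterministic per seed.
#'
#' @param row_margins,col_margins nonnegative integer margins with equal sums.
#' @param n number of tables to draw.
#' @param seed optional integer seed.
#' @return a list of `n` integer matrices.
#' @export
patefield_sample <- function(row_margins, col_margins, n = 1, seed = NULL) {
  if (any(row_margins < 0) || any(col_margins < 0)) stop("negative margin")
  if (sum(row_margins) != sum(col_margins)) {
    stop("row and column margin sums differ (", sum(row_margins), " vs ",
         sum(col_margins), ")")
  }
  if (sum(row_margins) == 0) stop("empty table: margin total is zero")
  if (!is.null(seed)) set.seed(seed)
  # a single row or column admits exactly one margin-consistent table
  if (length(row_margins) == 1) {
    return(replicate(n, matrix(as.integer(col_margins), 1), simplify = FALSE))
  }
  if (length(col_margins) == 1) {
    return(replicate(n, matrix(as.integer(row_margins), ncol = 1), simplify = FALSE))
  }
  stats::r2dtable(n, as.integer(row_margins), as.integer(col_margins))
}

#' Degree-of-habitat-occupancy percentiles from the fixed-margin null model
#'
#' For every species-habitat cell, generates `n_sim` randomized matrices with
#' the observed margins (Patefield sampler) and scores the percentage of
#' simulated counts lying below the observed count. A simulated count equal to
#' the observed one counts as not-below under the default `ties = "strict"`;
#' `ties = "half"` credits half of each tie.
#'
#' @param mat observed occurrence matrix.
#' @param n_sim number of randomized matrices.
#' @param seed integer seed (recorded in the result).
#' @param ties `"strict"` or `"half"`.
#' @param high,low classification thresholds passed to [classify_occupancy()].
#' @return an object of class `"occupancy_result"`: a data frame with one row
#'   per species-habitat cell (`species`, `habitat`, `observed`, `percentile`,
#'   `class`) plus attributes `n_sim`, `seed`, `ties`.
#' @export
occupancy_percentiles <- function(mat, n_sim = 10000, seed = 1,
                                  ties = c("strict", "half"),
                                  high = 80, low = 20) {
  ties <- match.arg(ties)
  if (nrow(mat) < 1 || n_sim < 1) stop("nonempty matrix and n_sim >= 1 required")
  # canonicalize row/column order by label before sampling: the sequential
  # Patefield fill depends on cell order, so sorting on the dimnames (which
  # travel with their counts) makes the scores exactly equivariant under row
  # or column permutations of the input matrix
  ro <- if (!is.null(rownames(mat))) order(rownames(mat)) else seq_len(nrow(mat))
  co <- if (!is.null(colnames(mat))) order(colnames(mat)) else seq_len(ncol(mat))
  cmat <- mat[ro, co, drop = FALSE]
  sims <- patefield_sample(rowSums(cmat), colSums(cmat), n = n_sim, seed = seed)
  below <- matrix(0, nrow(cmat), ncol(cmat))
  ties_n <- matrix(0, nrow(cmat), ncol(cmat))
  for (s in sims) {
    below <- below + (s < cmat)
    if (ties == "half") ties_n <- ties_n + (s == cmat)
  }
  pct <- matrix(0, nrow(mat), ncol(mat))
  pct[ro, co] <- 100 * (below + 0.5 * ties_n) / n_sim
  out <- data.frame(
    species = rep(rownames(mat), times = ncol(mat)),
    habitat = rep(colnames(mat), each = nrow(mat)),
    observed = as.vector(mat),
    percentile = as.vector(pct),
    stringsAsFactors = FALSE
  )
  out$class <- classify_occupancy(out$percentile, high = high, low = low)
  structure(out, n_sim = n_sim, seed = seed, ties = ties,
            class = c("occupancy_result", "data.frame"))
}

#' Classify occupancy percentiles into low / intermediate / high
#'
#' Strict thresholds: a percentile must *exceed* `high` for "high" and fall
#' *below* `low` for "low"; values at either boundary are intermediate.
#'
#' @param percentile numeric vector in `[0, 100]`.
#' @param high,low thresholds with `0 <= low < high <= 100`.
#' @return character vector in `{low, intermediate, high}`.
#' @export
classify_occupancy <- function(percentile, high = 80, low = 20) {
  if (!(low >= 0 && high <= 100 && low < high)) {
    stop("thresholds must satisfy 0 <= low < high <= 100")
  }
  ifelse(percentile > high, "high", ifelse(percentile < low, "low", "intermediate"))
}

#' Write an occupancy result to CSV
#'
#' @param x an `"occupancy_result"`.
#' @param file output path.
#' @export
write_occupancy_csv <- function(x, file) {
  df <- as.data.frame(x)
  df$n_sim <- attr(x, "n_sim")
  df$seed <- attr(x, "seed")
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read / write a habitat grid as plain text
#'
#' The grid is stored as a whitespace-separated matrix of integer cover codes,
#' a JSON sidecar (`<file>.json`) with the bounding box, and the
#' reclassification table as CSV.
#'
#' @param file path of the code-matrix file.
#' @param reclass_file CSV with columns `code`, `class`.
#' @return a `"habitat_grid"`.
#' @export
read_grid <- function(file, reclass_file) {
  codes <- as.matrix(utils::read.table(file))
  dimnames(codes) <- NULL
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  reclass <- utils::read.csv(reclass_file, stringsAsFactors = FALSE)
  habitat_grid(codes, bbox = unlist(meta$bbox), reclass = reclass)
}

#' @rdname read_grid
#' @param grid a `"habitat_grid"` to write; classes are written as codes
#'   1 = natural, 2 = agricultural, 3 = urban with a matching reclass CSV.
#' @export
write_grid <- function(grid, file, reclass_file) {
  codes <- matrix(match(grid$classes, HABITATS), grid$n_rows, grid$n_cols)
  utils::write.table(codes, file, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(bbox = grid$bbox), paste0(file, ".json"),
                       auto_unbox = FALSE, digits = NA)
  utils::write.csv(data.frame(code = 1:3, class = HABITATS), reclass_file,
                   row.names = FALSE)
  invisible(file)
}
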