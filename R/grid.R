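# Raster data model: a single co-registered layer ("egrid") and an aligned
# multi-layer stack ("egridstack"). Grids follow the usual raster convention:
# row 1 is the northernmost row, column 1 the westernmost column; cell centers
# sit at (xmin + (col - 0.5) * cell_size, ymax - (row - 0.5) * cell_size).
# Nodata cells are stored as NA in the value matrix; the `nodata` field is the
# sentinel used for file I/O only.

#' Construct an environmental grid
#'
#' A lightweight single-layer raster: a numeric matrix plus a geotransform
#' (top-left corner, square cell size), a nodata sentinel used on file
#' input/output, and a free-text coordinate-system label. Nodata cells are
#' represented as `NA` in `values`.
#'
#' @param values Numeric matrix (rows = north to south, columns = west to
#'   east). `NA` marks nodata.
#' @param xmin Map x-coordinate of the grid's west (left) edge.
#' @param ymax Map y-coordinate of the grid's north (top) edge.
#' @param cell_size Cell edge length in map units; cells are square.
#' @param nodata Sentinel value written for `NA` cells on output.
#' @param crs_label Free-text coordinate-system tag (not interpreted).
#' @return An object of class `egrid`.
#' @examples
#' g <- egrid(matrix(1:6, 2, 3), xmin = 0, ymax = 2, cell_size = 1)
#' grid_lat(g)
#' @export
egrid <- function(values, xmin = 0, ymax = nrow(values), cell_size = 1,
                  nodata = -9999, crs_label = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-nodata grid values must be finite", call. = FALSE)
  storage.mode(values) <- "double"
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         cell_size = as.numeric(cell_size), nodata = as.numeric(nodata),
         crs_label = as.character(crs_label)),
    class = "egrid")
}

#' @export
print.egrid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<egrid> %d x %d cells, cell size %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$xmin, x$ymax))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  values: [%g, %g], nodata cells: %d\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  else cat("  all cells nodata\n")
  invisible(x)
}

#' @export
dim.egrid <- function(x) dim(x$values)

is_egrid <- function(x) inherits(x, "egrid")

#' Cell-center coordinates
#'
#' @param g An `egrid`.
#' @return `grid_lon()`: vector of cell-center x (longitude) per column;
#'   `grid_lat()`: vector of cell-center y (latitude) per row.
#' @export
grid_lon <- function(g) g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$cell_size

#' @rdname grid_lon
#' @export
grid_lat <- function(g) g$ymax - (seq_len(nrow(g$values)) - 0.5) * g$cell_size

# Point -> (row, col). Half-open cell intervals [edge, edge + cell_size) in
# both axes, so a point on a shared edge belongs to exactly one cell.
# Returns NA row/col for points outside the extent.
point_to_cell <- function(g, lon, lat) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  ymin <- g$ymax - nr * g$cell_size
  col <- floor((lon - g$xmin) / g$cell_size) + 1L
  row <- nr - floor((lat - ymin) / g$cell_size)
  bad <- col < 1L | col > nc | row < 1L | row > nr |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# Geometry equality used by every aligned-grid operation.
grids_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) <= tol && abs(a$ymax - b$ymax) <= tol &&
    abs(a$cell_size - b$cell_size) <= tol
}

stopifnot_aligned <- function(a, b) {
  if (!grids_aligned(a, b))
    stop("grids are not aligned (dimensions or geotransform differ)",
         call. = FALSE)
  invisible(TRUE)
}

# Carry geometry, swap values; intersect nodata masks of any extra grids.
grid_like <- function(template, values) {
  egrid(values, xmin = template$xmin, ymax = template$ymax,
        cell_size = template$cell_size, nodata = template$nodata,
        crs_label = template$crs_label)
}

#' Read an Esri ASCII grid
#'
#' Parses the conventional six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by one whitespace-
#' separated row of values per line, north to south. Cells equal to the
#' nodata sentinel become `NA`.
#'
#' @param path Path to the file.
#' @param crs_label Coordinate-system tag attached to the result.
#' @return An `egrid`.
#' @seealso [write_ascii_grid()] for the complementary writer; the pair
#'   round-trips exactly under the writer's declared numeric format.
#' @export
read_ascii_grid <- function(path, crs_label = "unspecified") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 6L)
    stop("malformed ASCII grid: fewer than 6 header lines in ", path,
         call. = FALSE)
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "NODATA_value")
  hdr <- numeric(6)
  for (i in seq_along(keys)) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(parts) != 2L || tolower(parts[[1]]) != tolower(keys[[i]]))
      stop(sprintf("malformed ASCII grid header: expected key '%s' on line %d",
                   keys[[i]], i), call. = FALSE)
    val <- suppressWarnings(as.numeric(parts[[2]]))
    if (is.na(val))
      stop(sprintf("malformed ASCII grid header: non-numeric value for '%s'",
                   keys[[i]]), call. = FALSE)
    hdr[[i]] <- val
  }
  ncols <- as.integer(hdr[[1]]); nrows <- as.integer(hdr[[2]])
  body <- lines[-(1:6)]
  if (length(body) != nrows)
    stop(sprintf("malformed ASCII grid: expected %d data rows, found %d",
                 nrows, length(body)), call. = FALSE)
  vals <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[[r]]), "\\s+")[[1]]))
    if (length(row) != ncols || anyNA(row))
      stop(sprintf("malformed ASCII grid: ragged or non-numeric data row %d", r),
           call. = FALSE)
    vals[r, ] <- row
  }
  nodata <- hdr[[6]]
  vals[vals == nodata] <- NA_real_
  egrid(vals, xmin = hdr[[3]], ymax = hdr[[4]] + nrows * hdr[[5]],
        cell_size = hdr[[5]], nodata = nodata, crs_label = crs_label)
}

#' Write an Esri ASCII grid
#'
#' Values are formatted with `sprintf("%.*g", digits, value)`; with the
#' default 15 significant digits, `write_ascii_grid(read_ascii_grid(f))`
#' reproduces `f` byte-for-byte for files this writer produced.
#'
#' @param g An `egrid`.
#' @param path Output path.
#' @param digits Significant digits used for formatting values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path, digits = 15) {
  stopifnot(is_egrid(g))
  v <- g$values
  v[is.na(v)] <- g$nodata
  fmt <- function(x) sprintf("%.*g", digits, x)
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", fmt(g$xmin)),
    paste("yllcorner", fmt(g$ymax - nrow(v) * g$cell_size)),
    paste("cellsize", fmt(g$cell_size)),
    paste("NODATA_value", fmt(g$nodata)))
  rows <- apply(v, 1L, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Rescale grid values to the unit interval
#'
#' Linear map of the non-nodata cells so the minimum becomes 0 and the
#' maximum 1. A constant grid maps to all zeros with a warning rather than
#' erroring, so batch pipelines survive degenerate layers.
#'
#' @param g An `egrid` with at least one non-nodata cell.
#' @return An `egrid` with values in `[0, 1]`; nodata preserved.
#' @export
rescale01 <- function(g) {
  stopifnot(is_egrid(g))
  v <- g$values
  ok <- !is.na(v)
  if (!any(ok)) stop("cannot rescale an all-nodata grid", call. = FALSE)
  lo <- min(v[ok]); hi <- max(v[ok])
  if (hi == lo) {
    warning("constant grid: rescale01 maps all cells to 0", call. = FALSE)
    v[ok] <- 0
  } else {
    v[ok] <- (v[ok] - lo) / (hi - lo)
  }
  grid_like(g, v)
}

#' Proximity component of the invasion-risk score
#'
#' For every cell of `target_mask` equal to 1, computes the planar Euclidean
#' distance (map units, cell center to point) to the nearest occurrence, then
#' inverts the rescaled distance so the closest masked cell scores 1 and the
#' furthest scores 0. Cells with mask 0 (or nodata) are nodata in the output.
#'
#' @param target_mask An `egrid` of 0/1 defining where proximity is evaluated
#'   (e.g. crop-suitable cells).
#' @param occ Occurrence data frame with `lon` and `lat` columns.
#' @return An `egrid` in `[0, 1]` over masked cells.
#' @export
proximity_component <- function(target_mask, occ) {
  stopifnot(is_egrid(target_mask))
  occ <- as_occurrences(occ)
  if (nrow(occ) == 0L) stop("empty occurrence set", call. = FALSE)
  v <- target_mask$values
  idx <- which(!is.na(v) & v == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  if (nrow(idx) == 0L) return(grid_like(target_mask, out))
  cx <- target_mask$xmin + (idx[, "col"] - 0.5) * target_mask$cell_size
  cy <- target_mask$ymax - (idx[, "row"] - 0.5) * target_mask$cell_size
  # nearest-occurrence distance per masked cell
  d2 <- outer(cx, occ$lon, "-")^2 + outer(cy, occ$lat, "-")^2
  dmin <- sqrt(apply(d2, 1L, min))
  if (max(dmin) == min(dmin)) {
    out[idx] <- 1  # equidistant cells are all "closest"
  } else {
    out[idx] <- 1 - (dmin - min(dmin)) / (max(dmin) - min(dmin))
  }
  grid_like(target_mask, out)
}

#' Count cells per latitude band
#'
#' Assigns every non-nodata cell to the latitude band containing its cell
#' center and tabulates counts per band and cell value. Bands are half-open
#' `[k * band_width, (k + 1) * band_width)`.
#'
#' @param g A georeferenced `egrid` (values typically 0/1 or categories).
#' @param band_width Band height in degrees; must be positive.
#' @return A data frame with columns `band` (southern edge of the band),
#'   `value`, and `count`; counts partition the non-nodata cells.
#' @export
latitude_band_counts <- function(g, band_width = 1) {
  stopifnot(is_egrid(g))
  if (!is.numeric(band_width) || band_width <= 0)
    stop("`band_width` must be positive", call. = FALSE)
  lat <- grid_lat(g)
  v <- g$values
  ok <- which(!is.na(v), arr.ind = TRUE)
  if (nrow(ok) == 0L)
    return(data.frame(band = numeric(0), value = numeric(0),
                      count = integer(0)))
  band <- floor(lat[ok[, "row"]] / band_width) * band_width
  val <- v[ok]
  tab <- aggregate(list(count = rep(1L, length(val))),
                   by = list(band = band, value = val), FUN = sum)
  tab <- tab[order(tab$band, tab$value), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# ---- stacks ----------------------------------------------------------------

#' Construct an aligned multi-layer stack
#'
#' @param layers Named list of `egrid` objects sharing geometry and nodata
#'   mask.
#' @return An object of class `egridstack`.
#' @export
egridstack <- function(layers) {
  if (length(layers) == 0L) stop("stack needs at least one layer", call. = FALSE)
  if (is.null(names(layers)) || any(!nzchar(names(layers))) ||
      anyDuplicated(names(layers)))
    stop("layers must have unique non-empty names", call. = FALSE)
  if (!all(vapply(layers, is_egrid, logical(1))))
    stop("all layers must be egrid objects", call. = FALSE)
  ref <- layers[[1L]]
  for (nm in names(layers)) {
    stopifnot_aligned(ref, layers[[nm]])
    if (!identical(is.na(ref$values), is.na(layers[[nm]]$values)))
      stop("layer '", nm, "' has a different nodata mask", call. = FALSE)
  }
  structure(list(layers = layers), class = "egridstack")
}

#' @export
print.egridstack <- function(x, ...) {
  ref <- x$layers[[1L]]
  cat(sprintf("<egridstack> %d layers, %d x %d cells: %s\n",
              length(x$layers), nrow(ref$values), ncol(ref$values),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.egridstack <- function(x) names(x$layers)

stack_ref <- function(stack) stack$layers[[1L]]

# Cell values as an (n_complete_cells x n_layers) matrix plus the linear cell
# indices (column-major into the value matrix) the rows correspond to.
stack_values <- function(stack, cells = NULL) {
  mats <- lapply(stack$layers, function(g) g$values)
  if (is.null(cells)) cells <- which(!is.na(mats[[1L]]))
  out <- vapply(mats, function(m) m[cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(NULL, names(mats)))
  colnames(out) <- names(stack$layers)
  list(cells = cells, values = out)
}

# Linear (column-major) index of a lon/lat point's cell in the stack grid,
# NA outside the extent.
cell_index_of_points <- function(g, lon, lat) {
  rc <- point_to_cell(g, lon, lat)
  idx <- (rc$col - 1L) * nrow(g$values) + rc$row
  idx[is.na(rc$row)] <- NA_integer_
  idx
}

# ---- occurrences -----------------------------------------------------------

#' Coerce to an occurrence table
#'
#' @param x A data frame with columns `species`, `lon`, `lat` (or just
#'   `lon`/`lat`; species defaults to `"unknown"`).
#' @return A data frame with columns `species`, `lon`, `lat`.
#' @export
as_occurrences <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("lon", "lat") %in% names(x)))
    stop("occurrences need `lon` and `lat` columns", call. = FALSE)
  if (is.null(x$species)) x$species <- "unknown"
  x[, c("species", "lon", "lat")]
}

#' Read occurrence points from delimited text
#'
#' Expects a header `species,lon,lat` (comma- or tab-delimited).
#'
#' @param path Path to the file.
#' @return An occurrence data frame.
#' @export
read_occurrences <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  as_occurrences(utils::read.table(path, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE))
}

#' @rdname read_occurrences
#' @param occ Occurrence data frame.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as_occurrences(occ), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Thin occurrences to one point per grid cell
#'
#' Points falling outside the grid or on nodata cells are dropped with a
#' warning. The first point encountered in each cell is kept and snapped to
#' the cell center.
#'
#' @param occ Occurrence data frame.
#' @param g Reference `egrid`.
#' @return Thinned occurrence data frame (cell-center coordinates).
#' @export
thin_occurrences <- function(occ, g) {
  occ <- as_occurrences(occ)
  idx <- cell_index_of_points(g, occ$lon, occ$lat)
  outside <- is.na(idx)
  onnodata <- !outside & is.na(g$values[idx])
  if (any(outside | onnodata))
    warning(sum(outside | onnodata),
            " occurrence(s) outside the grid or on nodata cells dropped",
            call. = FALSE)
  keep <- !(outside | onnodata)
  idx <- idx[keep]
  occ <- occ[keep, , drop = FALSE]
  dup <- duplicated(idx)
  occ <- occ[!dup, , drop = FALSE]
  idx <- idx[!dup]
  nr <- nrow(g$values)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  occ$lon <- g$xmin + (col - 0.5) * g$cell_size
  occ$lat <- g$ymax - (row - 0.5) * g$cell_size
  rownames(occ) <- NULL
  occ
}
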