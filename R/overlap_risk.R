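# Habitat-overlap statistics between two species' binary suitability maps
# and the three-component invasion-risk score (suitability of the invader on
# crop-suitable cells + land-cover transformation + proximity to invader
# occurrences, summed and rescaled to [0, 1]).

#' Cellwise intersection of two binary maps
#'
#' @param a,b Aligned `egrid`s of 0/1.
#' @return An `egrid` of 0/1; nodata where either input is nodata.
#' @export
overlap_map <- function(a, b) {
  stopifnot(is_egrid(a), is_egrid(b))
  stopifnot_aligned(a, b)
  v <- ifelse(is.na(a$values) | is.na(b$values), NA_real_,
              (a$values == 1 & b$values == 1) * 1)
  grid_like(a, v)
}

#' Proportional overlap of two binary maps
#'
#' Number of shared suitable cells divided by the maximum overlap possible,
#' i.e. the suitable-cell count of the smaller map.
#'
#' @param a,b Aligned `egrid`s of 0/1; at least one must have a suitable
#'   cell.
#' @return A proportion in `[0, 1]`.
#' @export
proportional_overlap <- function(a, b) {
  stopifnot_aligned(a, b)
  na <- sum(a$values == 1, na.rm = TRUE)
  nb <- sum(b$values == 1, na.rm = TRUE)
  if (na == 0L && nb == 0L)
    stop("proportional overlap undefined: both maps empty", call. = FALSE)
  nab <- sum(a$values == 1 & b$values == 1, na.rm = TRUE)
  nab / min(na[na > 0], nb[nb > 0])
}

#' Binary land-cover transformation map
#'
#' Maps the listed forest class codes to 1 and every other class to 0;
#' class codes absent from `forest_classes` and not otherwise known trigger
#' a warning (and map to 0).
#'
#' @param landcover `egrid` of integer class codes.
#' @param forest_classes Numeric vector of class codes treated as forest.
#' @param known_classes Optional vector of all expected codes; codes outside
#'   it are reported.
#' @return An `egrid` of 0/1.
#' @export
landcover_component <- function(landcover, forest_classes,
                                known_classes = NULL) {
  stopifnot(is_egrid(landcover))
  v <- landcover$values
  if (!is.null(known_classes)) {
    seen <- unique(v[!is.na(v)])
    unknown <- setdiff(seen, known_classes)
    if (length(unknown) > 0L)
      warning("unseen land-cover class code(s) mapped to 0: ",
              paste(unknown, collapse = ", "), call. = FALSE)
  }
  grid_like(landcover, ifelse(is.na(v), NA_real_,
                              (v %in% forest_classes) * 1))
}

#' Three-component invasion-risk score
#'
#' Adds the invader-suitability component (categorical suitability of the
#' invader rescaled to `[0, 1]` on crop-suitable cells), the binary
#' land-cover transformation component, and the proximity (inverted
#' distance) component, then rescales the sum to `[0, 1]`. Risk is defined
#' only where all three components are defined (crop-suitable cells).
#'
#' @param suitability_component `egrid`, invader suitability over
#'   crop-suitable cells (categorical 0-3 or continuous; rescaled
#'   internally to `[0, 1]`).
#' @param landcover_component `egrid` of 0/1.
#' @param distance_component `egrid` in `[0, 1]` (see
#'   [proximity_component()]).
#' @return An `egrid` of risk in `[0, 1]` (0 low, 1 high).
#' @export
invasion_risk <- function(suitability_component, landcover_component,
                          distance_component) {
  stopifnot_aligned(suitability_component, landcover_component)
  stopifnot_aligned(suitability_component, distance_component)
  d <- distance_component$values
  if (any(d < 0 | d > 1, na.rm = TRUE))
    stop("distance component must lie in [0, 1]", call. = FALSE)
  s <- suppressWarnings(rescale01(suitability_component))$values
  total <- s + landcover_component$values + d
  rescale01(grid_like(suitability_component, total))
}

#' High/low risk counts per latitude band
#'
#' @param risk `egrid` of risk in `[0, 1]`.
#' @param high_threshold Cells at or above it count as high risk
#'   (default 0.5).
#' @param band_width Band height in degrees.
#' @return Data frame `band`, `n_high`, `n_low`; rows partition the
#'   non-nodata cells.
#' @export
risk_by_latitude <- function(risk, high_threshold = 0.5, band_width = 1) {
  stopifnot(is_egrid(risk))
  high <- binarize(risk, high_threshold)
  tab <- latitude_band_counts(high, band_width)
  if (nrow(tab) == 0L)
    return(data.frame(band = numeric(0), n_high = integer(0),
                      n_low = integer(0)))
  bands <- sort(unique(tab$band))
  data.frame(
    band = bands,
    n_high = vapply(bands, function(b)
      sum(tab$count[tab$band == b & tab$value == 1]), integer(1)),
    n_low = vapply(bands, function(b)
      sum(tab$count[tab$band == b & tab$value == 0]), integer(1)))
}

#' Future overlap/risk series under dispersal constraints
#'
#' Per period, intersects each replicate's dispersal-constrained occupancy
#' with the crop-suitability map and averages across replicates into a
#' consensus frequency map, rescaled to percent.
#'
#' @param snail_occupancy_series For a single run: list (periods) of 0/1
#'   `egrid`s; for replicate consensus: list (periods) of lists
#'   (replicates) of 0/1 `egrid`s or matrices.
#' @param crop_suitability_series List of 0/1 `egrid`s, same length.
#' @return List of `egrid`s, values in `[0, 100]` (percent of replicates
#'   in which the cell is overlapping occupied crop-suitable habitat).
#' @export
future_risk_series <- function(snail_occupancy_series,
                               crop_suitability_series) {
  if (length(snail_occupancy_series) != length(crop_suitability_series))
    stop("series lengths differ", call. = FALSE)
  lapply(seq_along(crop_suitability_series), function(k) {
    crop <- crop_suitability_series[[k]]
    occ <- snail_occupancy_series[[k]]
    reps <- if (is_egrid(occ) || is.matrix(occ)) list(occ) else occ
    mats <- lapply(reps, function(o) {
      m <- if (is_egrid(o)) o$values else o
      ifelse(is.na(m) | is.na(crop$values), NA_real_,
             (m == 1 & crop$values == 1) * 1)
    })
    grid_like(crop, 100 * Reduce(`+`, mats) / length(mats))
  })
}
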