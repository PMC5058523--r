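# Synthetic landscapes with known ground truth. Spatially autocorrelated
# predictor layers are built by convolving white noise with a uniform square
# kernel, inducing cross-layer correlation with a mixing matrix, and
# standardizing each layer. All generators are deterministic given their seed.

#' Landscape specification
#'
#' @param nrows,ncols Grid dimensions in cells.
#' @param n_vars Number of predictor layers to generate.
#' @param smoothing_radius Radius (in cells) of the uniform smoothing kernel;
#'   0 yields white noise. Larger radii increase spatial autocorrelation.
#' @param mixing `n_vars x n_vars` matrix; generated independent fields are
#'   linearly combined as `mixing %*% fields`, planting cross-layer
#'   correlation. Defaults to the identity (independent layers).
#' @param seed Integer seed; every generated quantity is a pure function of
#'   the spec including this seed.
#' @param xmin,ymax,cell_size Geotransform of the generated grids. The
#'   defaults place the landscape in geographic-style coordinates with
#'   `cell_size` degrees per cell.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(nrows = 60, ncols = 60, n_vars = 6,
                           smoothing_radius = 3, mixing = diag(n_vars),
                           seed = 1L, xmin = 75, ymax = 15,
                           cell_size = 0.05) {
  if (n_vars < 2L) stop("`n_vars` must be at least 2", call. = FALSE)
  if (smoothing_radius < 0) stop("`smoothing_radius` must be >= 0", call. = FALSE)
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != n_vars || ncol(mixing) != n_vars)
    stop("`mixing` must be an n_vars x n_vars matrix", call. = FALSE)
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 n_vars = as.integer(n_vars),
                 smoothing_radius = as.integer(smoothing_radius),
                 mixing = mixing, seed = as.integer(seed),
                 xmin = xmin, ymax = ymax, cell_size = cell_size),
            class = "landscape_spec")
}

# Uniform-kernel smoothing of a matrix, reflecting at the edges so border
# cells keep comparable variance.
smooth_uniform <- function(m, radius) {
  if (radius <= 0L) return(m)
  k <- 2L * radius + 1L
  pad_reflect <- function(x, r) {
    n <- length(x)
    c(x[r:1], x, x[n:(n - r + 1L)])
  }
  run_mean <- function(x, r) {
    xp <- pad_reflect(x, r)
    cs <- cumsum(c(0, xp))
    (cs[(k + 1):(length(xp) + 1)] - cs[1:(length(xp) - k + 1)]) / k
  }
  m <- apply(m, 2L, run_mean, r = radius)
  t(apply(t(m), 2L, run_mean, r = radius))
}

#' Generate a correlated, autocorrelated environmental stack
#'
#' Each layer is white Gaussian noise smoothed with a uniform kernel of the
#' spec's radius; layers are then linearly mixed with the spec's mixing
#' matrix (planting pairwise correlation) and standardized to mean 0,
#' standard deviation 1 over the grid.
#'
#' @param spec A [landscape_spec()].
#' @param names Optional layer names; default `env1..envK`.
#' @return An `egridstack` with `spec$n_vars` layers.
#' @export
gen_env_stack <- function(spec, names = NULL) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (is.null(names)) names <- paste0("env", seq_len(spec$n_vars))
  if (length(names) != spec$n_vars)
    stop("`names` must have length n_vars", call. = FALSE)
  set.seed(spec$seed)
  nr <- spec$nrows; nc <- spec$ncols
  fields <- lapply(seq_len(spec$n_vars), function(i)
    smooth_uniform(matrix(rnorm(nr * nc), nr, nc), spec$smoothing_radius))
  flat <- vapply(fields, as.numeric, numeric(nr * nc))   # cells x vars
  mixed <- flat %*% t(spec$mixing)
  mixed <- scale(mixed)                                   # standardize layers
  layers <- lapply(seq_len(spec$n_vars), function(i)
    egrid(matrix(mixed[, i], nr, nc), xmin = spec$xmin, ymax = spec$ymax,
          cell_size = spec$cell_size))
  names(layers) <- names
  egridstack(layers)
}

#' Ground-truth suitability model
#'
#' Linear and quadratic coefficients per layer plus an intercept; suitability
#' at a cell is `plogis(intercept + sum(linear * x + quadratic * x^2))`.
#'
#' @param linear,quadratic Named numeric vectors of coefficients (names are
#'   layer names; layers not named get coefficient 0).
#' @param intercept Intercept on the logit scale.
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(linear, quadratic = NULL, intercept = 0) {
  if (length(linear) == 0L && length(quadratic) == 0L)
    stop("truth model needs at least one coefficient", call. = FALSE)
  if (all(c(unlist(linear), unlist(quadratic)) == 0))
    stop("truth model needs at least one nonzero coefficient", call. = FALSE)
  structure(list(linear = unlist(linear), quadratic = unlist(quadratic),
                 intercept = intercept),
            class = "truth_model")
}

#' Evaluate the true suitability surface of a landscape
#'
#' @param stack An `egridstack`.
#' @param truth A [truth_model()] referencing only layers present in `stack`.
#' @return An `egrid` with values in `(0, 1)`.
#' @export
true_suitability <- function(stack, truth) {
  stopifnot(inherits(stack, "egridstack"), inherits(truth, "truth_model"))
  refd <- union(names(truth$linear), names(truth$quadratic))
  missing <- setdiff(refd, names(stack$layers))
  if (length(missing) > 0L)
    stop("truth model references unknown layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ref <- stack_ref(stack)
  eta <- matrix(truth$intercept, nrow(ref$values), ncol(ref$values))
  for (nm in names(truth$linear))
    eta <- eta + truth$linear[[nm]] * stack$layers[[nm]]$values
  for (nm in names(truth$quadratic))
    eta <- eta + truth$quadratic[[nm]] * stack$layers[[nm]]$values^2
  grid_like(ref, stats::plogis(eta))
}

#' Sample occurrence points from a suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' `suitability * bias` (bias 1 everywhere when absent), emulating
#' effort-biased collection; points are placed at cell centers (one per
#' cell).
#'
#' @param truth_surface An `egrid` with values in `[0, 1]`.
#' @param n Number of occurrence cells to draw.
#' @param bias Optional nonnegative `egrid` of relative sampling effort.
#' @param seed Integer seed.
#' @param species Species label attached to the points.
#' @return An occurrence data frame (`species`, `lon`, `lat`).
#' @export
sample_occurrences <- function(truth_surface, n, bias = NULL, seed = 1L,
                               species = "synthetic") {
  stopifnot(is_egrid(truth_surface))
  v <- truth_surface$values
  w <- v
  if (!is.null(bias)) {
    stopifnot_aligned(truth_surface, bias)
    if (any(bias$values < 0, na.rm = TRUE))
      stop("bias must be nonnegative", call. = FALSE)
    w <- w * bias$values
  }
  w[is.na(w)] <- 0
  pos <- which(w > 0)
  if (n > length(pos))
    stop("`n` exceeds the number of cells with positive sampling weight",
         call. = FALSE)
  set.seed(seed)
  if (n == 0L)
    return(data.frame(species = character(0), lon = numeric(0),
                      lat = numeric(0)))
  cells <- pos[sample.int(length(pos), n, replace = FALSE, prob = w[pos])]
  nr <- nrow(v)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  data.frame(
    species = species,
    lon = truth_surface$xmin + (col - 0.5) * truth_surface$cell_size,
    lat = truth_surface$ymax - (row - 0.5) * truth_surface$cell_size)
}

#' Generate a future environmental series by additive drift
#'
#' Period `k` of layer `v` equals the base layer plus `k * trends[[v]]`
#' (layers without a stated trend stay constant).
#'
#' @param stack Base `egridstack`.
#' @param trends Named numeric vector: additive drift per period for each
#'   drifting layer.
#' @param periods Number of future periods (>= 1).
#' @return A list of `egridstack`, one per period.
#' @export
gen_future_series <- function(stack, trends, periods = 4L) {
  stopifnot(inherits(stack, "egridstack"))
  if (periods < 1L) stop("`periods` must be >= 1", call. = FALSE)
  unknown <- setdiff(names(trends), names(stack$layers))
  if (length(unknown) > 0L)
    stop("trend given for unknown layer(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  lapply(seq_len(periods), function(k) {
    layers <- stack$layers
    for (nm in names(trends)) {
      g <- layers[[nm]]
      g$values <- g$values + k * trends[[nm]]
      layers[[nm]] <- g
    }
    egridstack(layers)
  })
}

#' Generate a blob-structured binary land-cover map
#'
#' Smoothed Gaussian noise thresholded at the `1 - forest_fraction` quantile,
#' giving spatially clumped forest patches whose share of the landscape
#' matches `forest_fraction` (to quantile granularity).
#'
#' @param spec A [landscape_spec()] (its dimensions, smoothing radius and
#'   seed are used; the seed is offset so land cover is independent of the
#'   environmental stack).
#' @param forest_fraction Target proportion of forest (value 1) cells.
#' @return An `egrid` of 0/1.
#' @export
gen_landcover <- function(spec, forest_fraction = 0.5) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (forest_fraction < 0 || forest_fraction > 1)
    stop("`forest_fraction` must lie in [0, 1]", call. = FALSE)
  set.seed(spec$seed + 104729L)  # decoupled stream from gen_env_stack
  nr <- spec$nrows; nc <- spec$ncols
  field <- smooth_uniform(matrix(rnorm(nr * nc), nr, nc),
                          max(1L, spec$smoothing_radius))
  if (forest_fraction == 0) {
    lc <- matrix(0, nr, nc)
  } else if (forest_fraction == 1) {
    lc <- matrix(1, nr, nc)
  } else {
    cut <- stats::quantile(field, probs = 1 - forest_fraction, names = FALSE)
    lc <- (field >= cut) * 1
  }
  egrid(lc, xmin = spec$xmin, ymax = spec$ymax, cell_size = spec$cell_size)
}

#' Generate site-level demographic counts
#'
#' Adult and juvenile densities per site are drawn from normal distributions
#' whose means increase linearly with the site's suitability (slope
#' `effect`), truncated at zero; the juveniles-per-adult ratio is derived.
#'
#' @param sites Data frame with `site_id`, `lon`, `lat` (ids generated when
#'   absent).
#' @param suitability An `egrid` in `[0, 1]`.
#' @param effect Increase in mean density across the full suitability range
#'   (0 to 1), in individuals per quadrat.
#' @param noise_sd Standard deviation of the density noise.
#' @param baseline Mean density at suitability 0.
#' @param seed Integer seed.
#' @return Data frame with columns `site_id`, `lon`, `lat`, `suitability`,
#'   `adults`, `juveniles`, `juv_per_adult` (NA where adults = 0).
#' @export
gen_demography <- function(sites, suitability, effect = 10, noise_sd = 2,
                           baseline = 5, seed = 1L) {
  stopifnot(is_egrid(suitability))
  sites <- as.data.frame(sites)
  if (is.null(sites$site_id)) sites$site_id <- paste0("site", seq_len(nrow(sites)))
  idx <- cell_index_of_points(suitability, sites$lon, sites$lat)
  if (anyNA(idx) || anyNA(suitability$values[idx]))
    stop("site outside the grid extent or on a nodata cell", call. = FALSE)
  s <- suitability$values[idx]
  set.seed(seed)
  n <- nrow(sites)
  adults <- pmax(0, baseline + effect * s + stats::rnorm(n, 0, noise_sd))
  juveniles <- pmax(0, 0.6 * (baseline + effect * s) +
                      stats::rnorm(n, 0, noise_sd))
  data.frame(site_id = sites$site_id, lon = sites$lon, lat = sites$lat,
             suitability = s, adults = adults, juveniles = juveniles,
             juv_per_adult = ifelse(adults > 0, juveniles / adults, NA_real_))
}
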