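# Demographic validation: assign field sites to predicted suitability
# categories and test whether population parameters (adults, juveniles,
# juveniles per adult) differ between category groups.

#' Assign sites to suitability categories
#'
#' Looks up each site's suitability value and four-class category (via
#' [categorize()]) at its grid cell. Sites outside the grid or on nodata
#' cells are excluded with a warning.
#'
#' @param sites Data frame with `site_id`, `lon`, `lat` and optionally
#'   demographic columns (carried through).
#' @param suitability `egrid` in `[0, 1]`.
#' @param mtss MTSS threshold for the categorization.
#' @return Data frame of the retained sites with added `suitability_value`
#'   and `category` columns.
#' @export
assign_sites <- function(sites, suitability, mtss) {
  stopifnot(is_egrid(suitability))
  sites <- as.data.frame(sites)
  idx <- cell_index_of_points(suitability, sites$lon, sites$lat)
  bad <- is.na(idx)
  bad[!bad] <- is.na(suitability$values[idx[!bad]])
  if (any(bad))
    warning(sum(bad), " site(s) outside the grid or on nodata cells excluded",
            call. = FALSE)
  sites <- sites[!bad, , drop = FALSE]
  idx <- idx[!bad]
  cat_grid <- categorize(suitability, mtss)
  sites$suitability_value <- suitability$values[idx]
  sites$category <- cat_grid$values[idx]
  rownames(sites) <- NULL
  sites
}

#' Compare a demographic parameter between category groups
#'
#' Welch two-sample t-test (unequal variances) of site-level values of the
#' chosen parameter between two sets of suitability categories. Sites with
#' an undefined value of the parameter (e.g. juveniles per adult where no
#' adults were recorded) are excluded; the exclusion count is reported.
#'
#' @param records Output of [assign_sites()] joined with demographic columns
#'   (`adults`, `juveniles`, `juv_per_adult`).
#' @param group_a,group_b Vectors of category codes (subsets of 0:3)
#'   defining the two groups.
#' @param parameter One of `"adults"`, `"juveniles"`, `"juv_per_adult"`.
#' @return List: `mean_a`, `mean_b`, `t`, `df`, `p`, `n_a`, `n_b`,
#'   `n_excluded`.
#' @export
compare_groups <- function(records, group_a = c(2, 3), group_b = c(0, 1),
                           parameter = c("adults", "juveniles",
                                         "juv_per_adult")) {
  parameter <- match.arg(parameter)
  x <- records[[parameter]][records$category %in% group_a]
  y <- records[[parameter]][records$category %in% group_b]
  n_excl <- sum(is.na(x)) + sum(is.na(y))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 records with a defined value",
         call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    # identical degenerate groups: no evidence of a difference
    return(list(mean_a = mean(x), mean_b = mean(y), t = 0,
                df = length(x) + length(y) - 2, p = 1,
                n_a = length(x), n_b = length(y), n_excluded = n_excl))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(mean_a = mean(x), mean_b = mean(y),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_a = length(x), n_b = length(y),
       n_excluded = n_excl)
}
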