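# MIGCLIM-style cellular automaton: stepwise colonization of suitable cells
# from mature occupied neighbors through a distance-indexed kernel, optional
# rare long-distance dispersal (LDD), strong barriers, decolonization of
# cells that fall below the suitability threshold, and environmental-change
# periods that swap the suitability surface. Suitability is on the 0-1000
# integer scale (round(1000 * logistic output)).

#' Dispersal automaton parameters
#'
#' Defaults follow the conventional parameterization for a poor disperser:
#' colonization threshold 600 on the 0-1000 suitability scale, 4
#' environmental-change periods of 20 dispersal steps each, maturity after 1
#' step, certain propagule production, LDD attempted with probability 0.05
#' per mature cell and step at cell distances in `[lddMinDist, lddMaxDist]`.
#' A `lddMaxDist` smaller than `lddMinDist` disables LDD with a warning
#' (fail-soft on an inconsistent setting).
#'
#' @param rcThreshold Suitability cut in `[0, 1000]`; cells at or above it
#'   are colonizable, occupied cells below it are decolonized.
#' @param encChgSteps Number of environmental-change periods.
#' @param dispSteps Dispersal steps per period.
#' @param iniMatAge Steps since colonization before a cell emits propagules.
#' @param propagule_prod Probability a mature source emits propagules in a
#'   step (scales the kernel).
#' @param lddFreq Per-step LDD attempt probability per mature cell.
#' @param lddMinDist,lddMaxDist Rounded cell-distance bounds for LDD targets.
#' @param kernel Numeric vector of colonization probabilities indexed by
#'   rounded source-target distance in cells (`kernel[d]`); default certain
#'   colonization at distance 1, nothing beyond.
#' @param replicates Number of stochastic replicate runs.
#' @param seed Integer seed.
#' @return An object of class `dispersal_params`.
#' @export
dispersal_params <- function(rcThreshold = 600, encChgSteps = 4L,
                             dispSteps = 20L, iniMatAge = 1L,
                             propagule_prod = 1.0, lddFreq = 0.05,
                             lddMinDist = 2L, lddMaxDist = 0L,
                             kernel = c(1.0), replicates = 5L, seed = 1L) {
  if (rcThreshold < 0 || rcThreshold > 1000)
    stop("`rcThreshold` must lie in [0, 1000]", call. = FALSE)
  for (p in list(propagule_prod = propagule_prod, lddFreq = lddFreq))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (dispSteps < 1L) stop("`dispSteps` must be >= 1", call. = FALSE)
  if (any(kernel < 0 | kernel > 1))
    stop("kernel values must lie in [0, 1]", call. = FALSE)
  ldd_enabled <- lddFreq > 0 && lddMaxDist >= lddMinDist
  if (lddFreq > 0 && lddMaxDist < lddMinDist)
    warning("lddMaxDist < lddMinDist: long-distance dispersal disabled",
            call. = FALSE)
  structure(list(rcThreshold = rcThreshold,
                 encChgSteps = as.integer(encChgSteps),
                 dispSteps = as.integer(dispSteps),
                 iniMatAge = as.integer(iniMatAge),
                 propagule_prod = propagule_prod, lddFreq = lddFreq,
                 lddMinDist = as.integer(lddMinDist),
                 lddMaxDist = as.integer(lddMaxDist),
                 kernel = as.numeric(kernel),
                 ldd_enabled = ldd_enabled,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "dispersal_params")
}

# Offsets (dr, dc) whose rounded Euclidean distance d satisfies
# dmin <= d <= dmax, with the probability attached to each offset.
kernel_offsets <- function(kernel, propagule_prod) {
  rng <- length(kernel)
  out <- list()
  for (dr in -rng:rng) for (dc in -rng:rng) {
    if (dr == 0L && dc == 0L) next
    d <- round(sqrt(dr^2 + dc^2))
    if (d >= 1L && d <= rng && kernel[d] > 0)
      out[[length(out) + 1L]] <- c(dr, dc, propagule_prod * kernel[d])
  }
  if (length(out) == 0L)
    return(matrix(numeric(0), 0L, 3L,
                  dimnames = list(NULL, c("dr", "dc", "p"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("dr", "dc", "p")
  m
}

ring_offsets <- function(dmin, dmax) {
  out <- list()
  for (dr in -dmax:dmax) for (dc in -dmax:dmax) {
    d <- round(sqrt(dr^2 + dc^2))
    if (d >= dmin && d <= dmax)
      out[[length(out) + 1L]] <- c(dr, dc)
  }
  do.call(rbind, out)
}

#' Initialize the dispersal state
#'
#' Initial cells falling on barriers are removed (barriers take precedence);
#' surviving initial cells are treated as mature (`age = iniMatAge`).
#'
#' @param initial `egrid` of 0/1 initial occupancy.
#' @param barrier `egrid` of 0/1; 1 = strong barrier, never occupiable.
#' @param params A [dispersal_params()].
#' @return An object of class `dispersal_state` with matrices `occupied`,
#'   `age`, `barrier`, counters, and an empty history table.
#' @export
init_state <- function(initial, barrier, params) {
  stopifnot(is_egrid(initial), is_egrid(barrier),
            inherits(params, "dispersal_params"))
  stopifnot_aligned(initial, barrier)
  occ <- !is.na(initial$values) & initial$values == 1
  bar <- !is.na(barrier$values) & barrier$values == 1
  occ <- occ & !bar
  age <- matrix(0L, nrow(occ), ncol(occ))
  age[occ] <- params$iniMatAge
  structure(list(occupied = occ, age = age, barrier = bar,
                 step_index = 0L, period_index = 0L,
                 history = data.frame(step = integer(0), period = integer(0),
                                      colonized = integer(0),
                                      decolonized = integer(0),
                                      occupied = integer(0)),
                 geometry = initial[c("xmin", "ymax", "cell_size", "nodata",
                                      "crs_label")]),
            class = "dispersal_state")
}

# Shift a logical/numeric matrix by (dr, dc), zero-filling exposed edges.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) == 0L || length(cs) == 0L) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Advance the automaton one dispersal step
#'
#' In order: (a) occupied cells whose suitability fell below `rcThreshold`
#' are decolonized; (b) every unoccupied, non-barrier, suitable cell is
#' colonized with probability `1 - prod(1 - propagule_prod * kernel(d))`
#' over the mature sources in kernel range; (c) each mature cell attempts
#' long-distance dispersal with probability `lddFreq`, colonizing one
#' uniformly chosen eligible cell at rounded distance in
#' `[lddMinDist, lddMaxDist]`; (d) ages increment, new colonists start at
#' age 1. Sources are the mature cells as of the start of the step.
#'
#' @param state A `dispersal_state`.
#' @param suitability `egrid` on the 0-1000 scale.
#' @param params A [dispersal_params()].
#' @return The updated `dispersal_state`. Uses the current RNG stream;
#'   seed at the level of [run_dispersal()].
#' @export
step_dispersal <- function(state, suitability, params) {
  stopifnot(inherits(state, "dispersal_state"), is_egrid(suitability))
  sv <- suitability$values
  if (any(sv < 0 | sv > 1000, na.rm = TRUE))
    stop("suitability must lie on the 0-1000 scale", call. = FALSE)
  suit <- !is.na(sv) & sv >= params$rcThreshold
  occ <- state$occupied
  age <- state$age

  # (a) decolonization
  decol <- occ & !suit
  occ[decol] <- FALSE
  age[decol] <- 0L

  mature <- occ & (age >= params$iniMatAge)

  # (b) short-distance colonization
  eligible <- !occ & !state$barrier & suit
  newcol <- matrix(FALSE, nrow(occ), ncol(occ))
  off <- kernel_offsets(params$kernel, params$propagule_prod)
  if (nrow(off) > 0L && any(mature) && any(eligible)) {
    log_miss <- matrix(0, nrow(occ), ncol(occ))
    for (k in seq_len(nrow(off))) {
      p <- off[k, "p"]
      src <- shift_matrix(mature, off[k, "dr"], off[k, "dc"])
      if (p >= 1) {
        log_miss[src > 0] <- -Inf
      } else {
        log_miss <- log_miss + src * log1p(-p)
      }
    }
    pcol <- 1 - exp(log_miss)
    el <- which(eligible)
    hit <- el[stats::runif(length(el)) < pcol[el]]
    newcol[hit] <- TRUE
  }

  # (c) long-distance dispersal
  if (params$ldd_enabled && any(mature)) {
    srcs <- which(mature)
    fire <- srcs[stats::runif(length(srcs)) < params$lddFreq]
    if (length(fire) > 0L) {
      ring <- ring_offsets(params$lddMinDist, params$lddMaxDist)
      nr <- nrow(occ)
      for (s in fire) {
        r0 <- (s - 1L) %% nr + 1L
        c0 <- (s - 1L) %/% nr + 1L
        tr <- r0 + ring[, 1L]; tc <- c0 + ring[, 2L]
        okc <- tr >= 1L & tr <= nr & tc >= 1L & tc <= ncol(occ)
        tgt <- (tc[okc] - 1L) * nr + tr[okc]
        tgt <- tgt[eligible[tgt] & !occ[tgt] & !newcol[tgt]]
        if (length(tgt) > 0L)
          newcol[tgt[sample.int(length(tgt), 1L)]] <- TRUE
      }
    }
  }

  # (d) bookkeeping
  age[occ] <- age[occ] + 1L
  occ[newcol] <- TRUE
  age[newcol] <- 1L
  state$occupied <- occ
  state$age <- age
  state$step_index <- state$step_index + 1L
  state$history <- rbind(state$history, data.frame(
    step = state$step_index, period = state$period_index,
    colonized = sum(newcol), decolonized = sum(decol),
    occupied = sum(occ)))
  state
}

occupancy_grid <- function(state) {
  g <- state$geometry
  egrid(state$occupied * 1, xmin = g$xmin, ymax = g$ymax,
        cell_size = g$cell_size, nodata = g$nodata, crs_label = g$crs_label)
}

#' Run the dispersal simulation over an environmental series
#'
#' Three scenarios:
#' \describe{
#'   \item{unlimited}{per period, occupancy is every cell at or above
#'     `rcThreshold` (any suitable cell can be reached; barriers ignored).}
#'   \item{none}{no dispersal: an initially occupied cell persists while it
#'     stays suitable and is never recovered once lost
#'     (occupancy is cumulative-intersection over periods).}
#'   \item{constrained}{`dispSteps` automaton steps per period with barriers
#'     and the kernel; `replicates` stochastic runs averaged into a
#'     consensus occupancy-frequency map per period.}
#' }
#'
#' @param initial,barrier `egrid`s of 0/1.
#' @param suitability_series List of `egrid`s on the 0-1000 scale, one per
#'   period; length must equal `params$encChgSteps`.
#' @param params A [dispersal_params()].
#' @param scenario One of `"constrained"`, `"unlimited"`, `"none"`.
#' @return A list of class `dispersal_run`: `occupancy` (list per period of
#'   consensus `egrid`s, values in `[0, 1]`), `replicate_occupancy` (list of
#'   lists of 0/1 matrices, constrained scenario), `history` (per-replicate
#'   step history), `params`, `scenario`.
#' @export
run_dispersal <- function(initial, barrier, suitability_series, params,
                          scenario = c("constrained", "unlimited", "none")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(params, "dispersal_params"))
  if (length(suitability_series) != params$encChgSteps)
    stop("suitability series length must equal encChgSteps", call. = FALSE)
  for (s in suitability_series) stopifnot_aligned(initial, s)

  suit_masks <- lapply(suitability_series, function(s)
    !is.na(s$values) & s$values >= params$rcThreshold)

  mk_grid <- function(vals) grid_like(initial, vals * 1)

  if (scenario == "unlimited") {
    occ <- lapply(suit_masks, mk_grid)
    return(structure(list(occupancy = occ, replicate_occupancy = NULL,
                          history = NULL, params = params,
                          scenario = scenario), class = "dispersal_run"))
  }
  if (scenario == "none") {
    # barrier cells are uninhabitable: same effective initial population
    # as the automaton scenarios
    occ0 <- !is.na(initial$values) & initial$values == 1 &
      !(!is.na(barrier$values) & barrier$values == 1)
    out <- vector("list", length(suit_masks))
    cur <- occ0
    for (k in seq_along(suit_masks)) {
      cur <- cur & suit_masks[[k]]
      out[[k]] <- mk_grid(cur)
    }
    return(structure(list(occupancy = out, replicate_occupancy = NULL,
                          history = NULL, params = params,
                          scenario = scenario), class = "dispersal_run"))
  }

  # constrained
  set.seed(params$seed)
  n_per <- params$encChgSteps
  rep_occ <- vector("list", params$replicates)
  histories <- vector("list", params$replicates)
  for (r in seq_len(params$replicates)) {
    state <- init_state(initial, barrier, params)
    per <- vector("list", n_per)
    for (k in seq_len(n_per)) {
      state$period_index <- k
      for (s in seq_len(params$dispSteps))
        state <- step_dispersal(state, suitability_series[[k]], params)
      per[[k]] <- state$occupied
    }
    rep_occ[[r]] <- per
    h <- state$history; h$replicate <- r
    histories[[r]] <- h
  }
  consensus <- lapply(seq_len(n_per), function(k) {
    m <- Reduce(`+`, lapply(rep_occ, function(p) p[[k]] * 1))
    mk_grid(m / params$replicates)
  })
  structure(list(occupancy = consensus, replicate_occupancy = rep_occ,
                 history = do.call(rbind, histories), params = params,
                 scenario = scenario),
            class = "dispersal_run")
}

#' @export
print.dispersal_run <- function(x, ...) {
  cat(sprintf("<dispersal_run> scenario '%s', %d period(s)\n", x$scenario,
              length(x$occupancy)))
  for (k in seq_along(x$occupancy)) {
    v <- x$occupancy[[k]]$values
    cat(sprintf("  period %d: mean occupancy %.3f\n", k, mean(v, na.rm = TRUE)))
  }
  invisible(x)
}
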