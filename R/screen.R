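# Collinearity screening of predictor layers: pairwise Pearson correlation
# over a common random sample of cells, then greedy pruning of pairs whose
# |r| exceeds a threshold, resolving each pair by a biological-relevance
# priority ordering.

#' Pairwise Pearson correlation matrix over sampled cells
#'
#' All layers are evaluated at one common random sample of non-nodata cells,
#' so every pairwise coefficient is computed on identical cases. A layer
#' with zero variance in the sample has undefined correlations; these are
#' flagged with a warning and treated as r = 0.
#'
#' @param stack An `egridstack`.
#' @param sample_n Number of cells to sample (capped at the number of
#'   non-nodata cells).
#' @param seed Integer seed for the cell sample.
#' @return Symmetric correlation matrix with unit diagonal, layer names on
#'   both dimensions.
#' @export
corr_matrix <- function(stack, sample_n = 10000L, seed = 1L) {
  stopifnot(inherits(stack, "egridstack"))
  sv <- stack_values(stack)
  ncell <- length(sv$cells)
  if (ncell < 3L) stop("need at least 3 non-nodata cells", call. = FALSE)
  set.seed(seed)
  take <- if (sample_n >= ncell) seq_len(ncell) else
    sample.int(ncell, sample_n)
  x <- sv$values[take, , drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning("zero-variance layer(s) in sample: ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            "; correlations treated as 0", call. = FALSE)
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r
}

#' Prune correlated predictors by priority
#'
#' Greedy removal: repeatedly take the retained pair with the largest `|r|`
#' strictly exceeding `threshold` and drop its lower-priority member, until
#' no retained pair exceeds the threshold. Ties in `|r|` are broken by
#' priority, then lexicographic name, making the pass deterministic. The
#' priority ordering formalizes the usual expert judgment of biological
#' relevance (earlier = more relevant = kept).
#'
#' @param corr Symmetric correlation matrix with dimnames.
#' @param threshold Absolute-correlation cut in `(0, 1)`; pairs with
#'   `|r| > threshold` (strict) are broken up. Default 0.7.
#' @param priority Character vector covering all layer names, most relevant
#'   first. Defaults to the matrix order.
#' @return A list of class `screen_result`: `corr`, `retained` (ordered by
#'   priority), `dropped` (data frame `name`, `partner`, `r`), `threshold`.
#' @export
prune_correlated <- function(corr, threshold = 0.7,
                             priority = rownames(corr)) {
  nm <- rownames(corr)
  if (is.null(nm) || !identical(nm, colnames(corr)))
    stop("`corr` must have matching row/column names", call. = FALSE)
  if (!setequal(priority, nm) || anyDuplicated(priority))
    stop("`priority` must be a permutation of the correlation matrix names",
         call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  rank_of <- stats::setNames(seq_along(priority), priority)
  retained <- nm
  dropped <- data.frame(name = character(0), partner = character(0),
                        r = numeric(0))
  repeat {
    sub <- abs(corr[retained, retained, drop = FALSE])
    diag(sub) <- 0
    if (all(sub <= threshold)) break
    # candidate pairs over the threshold, worst |r| first; deterministic ties
    idx <- which(sub > threshold, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    pr <- data.frame(a = retained[idx[, 1L]], b = retained[idx[, 2L]],
                     absr = sub[idx])
    pr$lo <- pmin(rank_of[pr$a], rank_of[pr$b])
    ord <- order(-pr$absr, pr$lo, pmin(pr$a, pr$b))
    top <- pr[ord[1L], ]
    victim <- if (rank_of[top$a] <= rank_of[top$b]) top$b else top$a
    keeper <- setdiff(c(top$a, top$b), victim)
    dropped <- rbind(dropped, data.frame(
      name = victim, partner = keeper,
      r = corr[victim, keeper]))
    retained <- setdiff(retained, victim)
  }
  retained <- priority[priority %in% retained]
  rownames(dropped) <- NULL
  structure(list(corr = corr, retained = retained, dropped = dropped,
                 threshold = threshold),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> |r| threshold %g: retained %d of %d layers\n",
              x$threshold, length(x$retained), nrow(x$corr)))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped) > 0L)
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  dropped %s (r = %.3f with %s)\n", x$dropped$name[i],
                  x$dropped$r[i], x$dropped$partner[i]))
  invisible(x)
}

#' Write a screening report as delimited text
#'
#' @param result A `screen_result`.
#' @param corr_path,report_path Output paths for the correlation matrix and
#'   the retained/dropped report.
#' @export
write_screen_report <- function(result, corr_path, report_path) {
  utils::write.csv(result$corr, corr_path)
  rep <- rbind(
    data.frame(name = result$retained, status = "retained",
               partner = NA_character_, r = NA_real_),
    if (nrow(result$dropped) > 0L)
      data.frame(name = result$dropped$name, status = "dropped",
                 partner = result$dropped$partner, r = result$dropped$r))
  utils::write.csv(rep, report_path, row.names = FALSE)
  invisible(report_path)
}
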