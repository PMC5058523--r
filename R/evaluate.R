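# Threshold-free and threshold-based evaluation of suitability predictions:
# rank-based AUC, the maximum sensitivity-plus-specificity (MTSS) threshold
# search, the true skill statistic, and binary / four-class map conversion.

#' Rank-based AUC
#'
#' Mann-Whitney formulation: the probability that a random positive score
#' exceeds a random negative score, ties counted one half. Equivalent to
#' exhaustive pair counting.
#'
#' @param pos_scores,neg_scores Nonempty numeric vectors of predicted scores
#'   for the positive (presence) and negative (background/absence) class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("both score vectors must be nonempty", call. = FALSE)
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Sensitivity, specificity and TSS at a threshold
#'
#' Prediction rule: present when `score >= threshold`. TSS = sensitivity +
#' specificity - 1.
#'
#' @param pos_scores,neg_scores Nonempty numeric score vectors.
#' @param threshold Decision threshold.
#' @return For [tss_at()], the scalar TSS.
#' @export
tss_at <- function(pos_scores, neg_scores, threshold) {
  cm <- confusion_at(pos_scores, neg_scores, threshold)
  cm$sensitivity + cm$specificity - 1
}

confusion_at <- function(pos_scores, neg_scores, threshold) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("both score vectors must be nonempty", call. = FALSE)
  sens <- mean(pos_scores >= threshold)
  spec <- mean(neg_scores < threshold)
  list(sensitivity = sens, specificity = spec)
}

#' Maximum sensitivity plus specificity threshold search
#'
#' Evaluates sensitivity + specificity at every unique observed score used
#' as a `>=` threshold and returns the maximizer; ties resolve to the
#' smallest threshold (the more inclusive suitable area, conservative for
#' risk screening).
#'
#' @param pos_scores,neg_scores Nonempty numeric score vectors.
#' @return An object of class `threshold_search`: data frame `table` with
#'   columns `threshold`, `sensitivity`, `specificity`, `tss`, plus the
#'   selected `mtss_threshold` and its `tss`.
#' @export
mtss_threshold <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("both score vectors must be nonempty", call. = FALSE)
  cand <- sort(unique(c(pos_scores, neg_scores)))
  sens <- vapply(cand, function(t) mean(pos_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg_scores < t), numeric(1))
  tss <- sens + spec - 1
  best <- which(tss == max(tss))[1L]  # cand sorted: first max = smallest
  structure(list(
    table = data.frame(threshold = cand, sensitivity = sens,
                       specificity = spec, tss = tss),
    mtss_threshold = cand[best],
    tss = tss[best]),
    class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("<threshold_search> %d candidate thresholds; MTSS = %g (TSS %.3f)\n",
              nrow(x$table), x$mtss_threshold, x$tss))
  invisible(x)
}

#' Binarize a suitability grid at a threshold
#'
#' @param suitability An `egrid` (typically in `[0, 1]`).
#' @param threshold Cells with value `>= threshold` become 1, others 0;
#'   nodata preserved.
#' @return An `egrid` of 0/1.
#' @export
binarize <- function(suitability, threshold) {
  stopifnot(is_egrid(suitability))
  v <- suitability$values
  grid_like(suitability, ifelse(is.na(v), NA_real_, (v >= threshold) * 1))
}

#' Four-class suitability categorization
#'
#' Class 0 (unsuitable) below the MTSS threshold; the interval
#' `[mtss, 1]` is split into three equal-width classes: 1 poor, 2 medium,
#' 3 highly suitable. The equal-width split above MTSS is the package's
#' declared convention for the usual poor/medium/high map classes.
#'
#' @param suitability An `egrid` in `[0, 1]`.
#' @param mtss MTSS threshold in `(0, 1)`.
#' @return An `egrid` of classes `{0, 1, 2, 3}`.
#' @export
categorize <- function(suitability, mtss) {
  stopifnot(is_egrid(suitability))
  if (mtss <= 0 || mtss >= 1)
    stop("`mtss` must lie in (0, 1)", call. = FALSE)
  v <- suitability$values
  w <- (1 - mtss) / 3
  cls <- ifelse(v < mtss, 0, pmin(3, floor((v - mtss) / w) + 1))
  cls[is.na(v)] <- NA_real_
  grid_like(suitability, cls)
}
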