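# Shared fixture builders. Everything is generated in code at test time;
# the strong-signal landscape mirrors a sharply delimited endemic niche
# (two active predictors, suitable area ~8% of the landscape).

make_grid <- function(values, ...) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  egrid(values, ...)
}

# Small landscape for fast unit tests.
small_landscape <- function(seed = 7, nrows = 50, ncols = 50, n_vars = 4) {
  spec <- landscape_spec(nrows = nrows, ncols = ncols, n_vars = n_vars,
                         smoothing_radius = 3, seed = seed)
  stack <- gen_env_stack(spec)
  truth <- truth_model(c(env1 = 4, env2 = -3), intercept = -7)
  surface <- true_suitability(stack, truth)
  list(spec = spec, stack = stack, truth = truth, surface = surface)
}

# Strong-signal landscape at the scale used for recovery checks:
# 2 active + 3 inactive predictors.
strong_landscape <- function(seed = 42) {
  spec <- landscape_spec(nrows = 100, ncols = 100, n_vars = 5,
                         smoothing_radius = 3, seed = seed)
  stack <- gen_env_stack(spec)
  truth <- truth_model(c(env1 = 4, env2 = -3), intercept = -7)
  surface <- true_suitability(stack, truth)
  list(spec = spec, stack = stack, truth = truth, surface = surface)
}

# O(n^2) pair-counting AUC oracle (ties half).
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# Exhaustive MTSS oracle: evaluate every unique score as a >= threshold.
mtss_oracle <- function(pos, neg) {
  cand <- sort(unique(c(pos, neg)))
  tss <- vapply(cand, function(t)
    mean(pos >= t) + mean(neg < t) - 1, numeric(1))
  list(threshold = cand[which(tss == max(tss))[1L]], tss = max(tss))
}

# Brute-force retained-set oracle for correlation pruning: all subsets,
# keep feasible ones (no retained pair with |r| > threshold), maximize
# size, tie-break by earliest priority ranks (lexicographic on the sorted
# rank vector).
prune_oracle <- function(corr, threshold, priority) {
  nm <- rownames(corr)
  rank_of <- setNames(seq_along(priority), priority)
  best <- NULL; best_key <- NULL
  for (mask in 0:(2^length(nm) - 1)) {
    sel <- nm[bitwAnd(mask, 2^(seq_along(nm) - 1)) > 0]
    if (length(sel) > 1L) {
      sub <- abs(corr[sel, sel, drop = FALSE]); diag(sub) <- 0
      if (any(sub > threshold)) next
    }
    key <- c(-length(sel), sort(rank_of[sel]))
    if (is.null(best)) { best <- sel; best_key <- key; next }
    # lexicographic comparison, shorter key padded
    n <- max(length(key), length(best_key))
    a <- c(key, rep(Inf, n - length(key)))
    b <- c(best_key, rep(Inf, n - length(best_key)))
    cmp <- a - b
    first <- which(cmp != 0)[1L]
    if (!is.na(first) && cmp[first] < 0) { best <- sel; best_key <- key }
  }
  priority[priority %in% best]
}

# Clique-structured planted correlation matrix: layers in the same block
# are mutually over-correlated, cross-block correlations are low.
planted_corr <- function(blocks, r_within = 0.85, r_between = 0.2) {
  nm <- unlist(blocks)
  k <- length(nm)
  corr <- matrix(r_between, k, k, dimnames = list(nm, nm))
  for (b in blocks)
    corr[b, b] <- r_within
  diag(corr) <- 1
  corr
}

# All set partitions of a vector (Bell number sized; fine for n = 5).
set_partitions <- function(items) {
  if (length(items) == 0L) return(list(list()))
  first <- items[[1L]]
  rest <- set_partitions(items[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

# 8-neighborhood reachability (BFS) over non-barrier cells from a set of
# start cells; oracle for barrier confinement.
reachable_cells <- function(start, barrier) {
  nr <- nrow(barrier); nc <- ncol(barrier)
  seen <- matrix(FALSE, nr, nc)
  queue <- start[!barrier[start]]
  seen[queue] <- TRUE
  while (length(queue) > 0L) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    r <- (cur - 1L) %% nr + 1L; c <- (cur - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      idx <- (cc - 1L) * nr + rr
      if (!seen[idx] && !barrier[idx]) {
        seen[idx] <- TRUE
        queue <- c(queue, idx)
      }
    }
  }
  seen
}
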