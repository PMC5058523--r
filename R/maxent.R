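# Presence-background maximum-entropy suitability model. The model is the
# Gibbs distribution q(x) = exp(lambda . f(x)) / Z over the background
# sample, fitted by minimizing the L1-penalized presence log-loss
#
#   J(lambda) = -mean_presence(lambda . f) + log Z(lambda)
#               + reg_beta * sum_j |lambda_j|
#
# with features standardized over the background (so the per-feature penalty
# scale is the background SD of the raw feature, folded into the
# standardization) and the penalty weight scaled by 1/sqrt(n_presences), the
# usual lasso-style calibration that keeps the default multiplier meaningful
# across sample sizes. J is convex; a cyclic prox-Newton coordinate descent
# with a backtracking safeguard converges to the unique optimum and records
# a per-update gain trace used for percent-contribution diagnostics.

#' Feature specification for the suitability model
#'
#' @param types Subset of `c("linear", "quadratic", "product")`; at least
#'   one. Products are all unordered pairs of distinct predictors.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(types = c("linear", "quadratic", "product")) {
  types <- match.arg(types, c("linear", "quadratic", "product"),
                     several.ok = TRUE)
  structure(list(types = types), class = "feature_spec")
}

# Expand an (n x nvar) raw environment matrix into the model's feature
# matrix. Returns the matrix plus per-feature metadata (parent variables,
# used for attributing gains and importances back to predictors).
build_features <- function(env, spec) {
  vars <- colnames(env)
  mats <- list(); meta <- list()
  if ("linear" %in% spec$types) {
    mats$linear <- env
    meta$linear <- data.frame(feature = vars, var1 = vars, var2 = NA)
  }
  if ("quadratic" %in% spec$types) {
    q <- env^2
    colnames(q) <- paste0(vars, "^2")
    mats$quadratic <- q
    meta$quadratic <- data.frame(feature = colnames(q), var1 = vars,
                                 var2 = NA)
  }
  if ("product" %in% spec$types && length(vars) >= 2L) {
    pairs <- utils::combn(vars, 2L)
    p <- apply(pairs, 2L, function(ab) env[, ab[1L]] * env[, ab[2L]])
    if (is.null(dim(p))) p <- matrix(p, nrow = nrow(env))
    colnames(p) <- paste0(pairs[1L, ], "*", pairs[2L, ])
    mats$product <- p
    meta$product <- data.frame(feature = colnames(p), var1 = pairs[1L, ],
                               var2 = pairs[2L, ])
  }
  X <- do.call(cbind, unname(mats))
  meta <- do.call(rbind, unname(meta))
  rownames(meta) <- NULL
  list(X = X, meta = meta)
}

# Standardize a feature matrix with given (or freshly computed) background
# moments; zero-variance features get scale 1 so they stay inert.
standardize_features <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(X = sweep(sweep(X, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

#' Sample background cells
#'
#' Cells are drawn without replacement from the non-nodata cells,
#' with probability proportional to an optional bias grid (uniform when
#' absent), the standard device for matching background effort to
#' presence-sampling effort.
#'
#' @param stack An `egridstack`.
#' @param n Number of background cells (must not exceed the cells with
#'   positive weight).
#' @param bias Optional nonnegative `egrid` of relative effort.
#' @param seed Integer seed.
#' @return Integer vector of linear (column-major) cell indices.
#' @export
sample_background <- function(stack, n = 10000L, bias = NULL, seed = 1L) {
  stopifnot(inherits(stack, "egridstack"))
  ref <- stack_ref(stack)
  ok <- which(!is.na(ref$values))
  w <- rep(1, length(ok))
  if (!is.null(bias)) {
    stopifnot_aligned(ref, bias)
    if (any(bias$values < 0, na.rm = TRUE))
      stop("bias must be nonnegative", call. = FALSE)
    w <- bias$values[ok]
    w[is.na(w)] <- 0
  }
  pos <- ok[w > 0]
  if (n > length(pos))
    stop("`n` exceeds the number of cells with positive weight", call. = FALSE)
  set.seed(seed)
  if (n == length(pos)) return(sort(pos))
  sort(pos[sample.int(length(pos), n, replace = FALSE, prob = w[w > 0])])
}

# Penalized objective at eta = X_bg lambda (log-sum-exp stabilized).
maxent_objective <- function(lambda, eta_bg, mean_pr_f, reg_beta) {
  m <- max(eta_bg)
  logZ <- m + log(sum(exp(eta_bg - m)))
  -sum(mean_pr_f * lambda) + logZ + reg_beta * sum(abs(lambda))
}

#' Fit the presence-background suitability model
#'
#' Presences are thinned to one per cell, features built from the predictor
#' stack, standardized over the background, and the penalized convex
#' objective minimized by cyclic prox-Newton coordinate descent. The fit
#' records a gain trace (objective drop per coordinate update, attributed to
#' parent predictors) consumed by [percent_contribution()].
#'
#' @param presences Occurrence data frame (`lon`, `lat`).
#' @param background Integer vector of background cell indices (from
#'   [sample_background()]).
#' @param stack Predictor `egridstack`.
#' @param spec A [feature_spec()].
#' @param reg_beta L1 regularization multiplier (default 1).
#' @param init Optional starting vector of feature weights (defaults to 0);
#'   the optimum is independent of the start because the objective is
#'   strictly convex in the active features.
#' @param max_iter Cycle cap; `tol` relative objective-change tolerance.
#' @param tol Convergence tolerance on the relative objective change per
#'   full cycle.
#' @return An object of class `suitability_model` with elements `lambdas`,
#'   `feature_meta`, `center`, `scale`, `spec`, `reg_beta`, `log_partition`
#'   (log Z over the background at the optimum, standardized features),
#'   `entropy_H` (entropy of the fitted background distribution), `n_bg`,
#'   `trace` (per-update gains), `objective`, `converged`, `layer_names`.
#' @export
fit_maxent <- function(presences, background, stack, spec = feature_spec(),
                       reg_beta = 1.0, init = NULL, max_iter = 10000L,
                       tol = 1e-8) {
  stopifnot(inherits(stack, "egridstack"), inherits(spec, "feature_spec"))
  ref <- stack_ref(stack)
  pres <- thin_occurrences(presences, ref)
  if (nrow(pres) < 5L)
    stop("need at least 5 presence cells after thinning", call. = FALSE)
  pres_cells <- cell_index_of_points(ref, pres$lon, pres$lat)
  sv_bg <- stack_values(stack, background)
  sv_pr <- stack_values(stack, pres_cells)
  if (any(!is.finite(sv_bg$values)) || any(!is.finite(sv_pr$values)))
    stop("non-finite predictor values in feature matrix", call. = FALSE)

  fb <- build_features(sv_bg$values, spec)
  fp <- build_features(sv_pr$values, spec)
  std <- standardize_features(fb$X)
  Xb <- std$X
  Xp <- standardize_features(fp$X, std$center, std$scale)$X
  p <- ncol(Xb)
  mean_pr_f <- colMeans(Xp)
  # effective penalty: global multiplier x unit feature SD / sqrt(m)
  beta_eff <- reg_beta / sqrt(nrow(Xp))

  lambda <- if (is.null(init)) numeric(p) else as.numeric(init)
  if (length(lambda) != p) stop("`init` has wrong length", call. = FALSE)
  eta <- as.numeric(Xb %*% lambda)
  obj <- maxent_objective(lambda, eta, mean_pr_f, beta_eff)
  trace_feat <- integer(0); trace_gain <- numeric(0)
  converged <- FALSE

  for (cycle in seq_len(max_iter)) {
    obj_start <- obj
    for (j in seq_len(p)) {
      m <- max(eta)
      w <- exp(eta - m); w <- w / sum(w)
      xj <- Xb[, j]
      qx <- sum(w * xj)
      g <- qx - mean_pr_f[j]
      h <- max(sum(w * xj^2) - qx^2, 1e-10)
      # prox-Newton coordinate step with soft threshold
      target <- lambda[j] - g / h
      lam_new <- sign(target) * max(0, abs(target) - beta_eff / h)
      delta <- lam_new - lambda[j]
      if (delta == 0) next
      # backtracking safeguard on the exact objective
      step <- 1
      repeat {
        cand <- lambda[j] + step * delta
        eta_cand <- eta + (cand - lambda[j]) * xj
        obj_cand <- {
          lam_tmp <- lambda; lam_tmp[j] <- cand
          maxent_objective(lam_tmp, eta_cand, mean_pr_f, beta_eff)
        }
        if (obj_cand <= obj + 1e-12 || step < 1e-8) break
        step <- step / 2
      }
      if (obj_cand < obj) {
        trace_feat <- c(trace_feat, j)
        trace_gain <- c(trace_gain, obj - obj_cand)
        lambda[j] <- cand
        eta <- eta_cand
        obj <- obj_cand
      }
    }
    if (abs(obj_start - obj) <= tol * (abs(obj_start) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf(
      "coordinate descent hit the %d-cycle cap (last objective %.8g)",
      max_iter, obj), call. = FALSE)

  m <- max(eta)
  logZ <- m + log(sum(exp(eta - m)))
  q <- exp(eta - logZ)
  H <- -sum(q * ifelse(q > 0, log(q), 0))

  structure(list(
    lambdas = stats::setNames(lambda, fb$meta$feature),
    feature_meta = fb$meta, center = std$center, scale = std$scale,
    spec = spec, reg_beta = reg_beta, log_partition = logZ,
    entropy_H = H, n_bg = length(background), background = background,
    presence_cells = sv_pr$cells,
    trace = data.frame(feature = fb$meta$feature[trace_feat],
                       var1 = fb$meta$var1[trace_feat],
                       var2 = fb$meta$var2[trace_feat],
                       gain = trace_gain),
    objective = obj, converged = converged,
    layer_names = names(stack$layers)),
    class = "suitability_model")
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf(
    "<suitability_model> %d features over %d predictors; %d active (nonzero)\n",
    length(x$lambdas), length(x$layer_names), sum(x$lambdas != 0)))
  cat(sprintf("  reg_beta %g, objective %.6g, entropy H %.4f, converged: %s\n",
              x$reg_beta, x$objective, x$entropy_H, x$converged))
  invisible(x)
}

# Linear predictor (standardized features) for arbitrary cells.
model_eta <- function(model, env) {
  fx <- build_features(env, model$spec)
  X <- standardize_features(fx$X, model$center, model$scale)$X
  as.numeric(X %*% model$lambdas)
}

#' Predict suitability over a stack
#'
#' `raw` output is the Gibbs density normalized to sum to 1 over the
#' model's background sample; `logistic` output applies the entropy-based
#' transform `raw * exp(H) / (1 + raw * exp(H))`, bounded in `[0, 1]`.
#'
#' @param object A fitted `suitability_model`.
#' @param stack An `egridstack` containing all the model's predictors.
#' @param output `"logistic"` (default) or `"raw"`.
#' @param ... Unused.
#' @return An `egrid` of predictions (nodata preserved).
#' @export
predict.suitability_model <- function(object, stack, output = c("logistic", "raw"),
                                      ...) {
  output <- match.arg(output)
  stopifnot(inherits(stack, "egridstack"))
  missing <- setdiff(object$layer_names, names(stack$layers))
  if (length(missing) > 0L)
    stop("stack lacks model layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sv <- stack_values(stack)
  env <- sv$values[, object$layer_names, drop = FALSE]
  eta <- model_eta(object, env)
  raw <- exp(eta - object$log_partition)
  out <- if (output == "raw") raw else {
    re <- raw * exp(object$entropy_H)
    re / (1 + re)
  }
  ref <- stack_ref(stack)
  v <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  v[sv$cells] <- out
  grid_like(ref, v)
}

# Scores (linear predictor; monotone in both outputs) at given cell indices.
score_cells <- function(model, stack, cells) {
  sv <- stack_values(stack, cells)
  model_eta(model, sv$values[, model$layer_names, drop = FALSE])
}

#' Replicate model evaluation
#'
#' Repeats: random presence split into train/test, fresh background sample,
#' fit on the training presences, then train and test AUC against the
#' background, MTSS threshold from the training scores, and TSS of the test
#' presences at that threshold. Summaries are means and standard deviations
#' across replicates.
#'
#' @param presences Occurrence data frame.
#' @param stack Predictor `egridstack`.
#' @param spec A [feature_spec()].
#' @param reg_beta L1 multiplier.
#' @param n_replicates Number of replicate models.
#' @param test_fraction Proportion of presences held out per replicate.
#' @param n_background Background sample size per replicate (capped at the
#'   available cells).
#' @param bias Optional bias grid for the background sample.
#' @param seed Integer seed; replicate r uses derived seeds so the whole
#'   evaluation is deterministic.
#' @return An object of class `replicate_evaluation`: data frame
#'   `replicates` (auc_train, auc_test, tss, mtss_threshold) and a `summary`
#'   data frame of means and SDs.
#' @export
replicate_evaluate <- function(presences, stack, spec = feature_spec(),
                               reg_beta = 1.0, n_replicates = 10L,
                               test_fraction = 0.3, n_background = 10000L,
                               bias = NULL, seed = 1L) {
  ref <- stack_ref(stack)
  pres <- thin_occurrences(presences, ref)
  n <- nrow(pres)
  n_test <- max(1L, round(test_fraction * n))
  if (n - n_test < 5L || n_test < 3L)
    stop("not enough presences for the requested split", call. = FALSE)
  n_bg <- min(n_background, sum(!is.na(ref$values)))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- seed + 1000L * r
    set.seed(rs)
    test_idx <- sample.int(n, n_test)
    train <- pres[-test_idx, , drop = FALSE]
    test <- pres[test_idx, , drop = FALSE]
    bg <- sample_background(stack, n_bg, bias = bias, seed = rs + 1L)
    model <- fit_maxent(train, bg, stack, spec, reg_beta)
    s_bg <- score_cells(model, stack, bg)
    s_train <- score_cells(model, stack,
                           cell_index_of_points(ref, train$lon, train$lat))
    s_test <- score_cells(model, stack,
                          cell_index_of_points(ref, test$lon, test$lat))
    ts <- mtss_threshold(s_train, s_bg)
    # report the threshold on the logistic output scale, as map products use it
    thr_logistic <- {
      raw <- exp(ts$mtss_threshold - model$log_partition)
      re <- raw * exp(model$entropy_H); re / (1 + re)
    }
    rows[[r]] <- data.frame(
      replicate = r,
      auc_train = auc(s_train, s_bg),
      auc_test = auc(s_test, s_bg),
      tss = tss_at(s_test, s_bg, ts$mtss_threshold),
      mtss_threshold = thr_logistic)
  }
  reps <- do.call(rbind, rows)
  summ <- data.frame(
    statistic = c("auc_train", "auc_test", "tss", "mtss_threshold"),
    mean = c(mean(reps$auc_train), mean(reps$auc_test), mean(reps$tss),
             mean(reps$mtss_threshold)),
    sd = c(stats::sd(reps$auc_train), stats::sd(reps$auc_test),
           stats::sd(reps$tss), stats::sd(reps$mtss_threshold)))
  summ$sd[is.na(summ$sd)] <- 0
  structure(list(replicates = reps, summary = summ),
            class = "replicate_evaluation")
}

#' @export
print.replicate_evaluation <- function(x, ...) {
  cat(sprintf("<replicate_evaluation> %d replicates\n", nrow(x$replicates)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-15s %.3f (%.3f)\n", s$statistic[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Percent contribution of each predictor
#'
#' Sums the objective gains of the fit's coordinate updates per predictor
#' (a product feature's gain is split equally between its two parents) and
#' normalizes to 100.
#'
#' @param model A fitted `suitability_model` with a nonempty gain trace.
#' @return Data frame `variable`, `percent`, descending.
#' @export
percent_contribution <- function(model) {
  tr <- model$trace
  if (nrow(tr) == 0L)
    stop("model has no recorded fit trace", call. = FALSE)
  gains <- stats::setNames(numeric(length(model$layer_names)),
                           model$layer_names)
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$var2[i])) {
      gains[tr$var1[i]] <- gains[tr$var1[i]] + tr$gain[i]
    } else {
      gains[tr$var1[i]] <- gains[tr$var1[i]] + tr$gain[i] / 2
      gains[tr$var2[i]] <- gains[tr$var2[i]] + tr$gain[i] / 2
    }
  }
  total <- sum(gains)
  pct <- if (total > 0) 100 * gains / total else gains * 0
  out <- data.frame(variable = names(pct), percent = as.numeric(pct))
  out[order(-out$percent), , drop = FALSE]
}

#' Permutation importance of each predictor
#'
#' For each predictor, its raw values are permuted across the evaluation
#' cells (training presences plus background), features rebuilt, and the
#' drop in training AUC measured; drops (clamped at 0) are normalized to
#' sum to 100.
#'
#' @param model A fitted `suitability_model`.
#' @param stack The predictor `egridstack` used for fitting.
#' @param seed Integer seed for the permutations.
#' @return Data frame `variable`, `importance`, descending.
#' @export
permutation_importance <- function(model, stack, seed = 1L) {
  cells <- c(model$presence_cells, model$background)
  n_pr <- length(model$presence_cells)
  sv <- stack_values(stack, cells)
  env <- sv$values[, model$layer_names, drop = FALSE]
  eta <- model_eta(model, env)
  auc_full <- auc(eta[seq_len(n_pr)], eta[-seq_len(n_pr)])
  set.seed(seed)
  drops <- vapply(model$layer_names, function(v) {
    ep <- env
    ep[, v] <- ep[sample.int(nrow(ep)), v]
    s <- model_eta(model, ep)
    max(0, auc_full - auc(s[seq_len(n_pr)], s[-seq_len(n_pr)]))
  }, numeric(1))
  total <- sum(drops)
  imp <- if (total > 0) 100 * drops / total else drops * 0
  out <- data.frame(variable = names(imp), importance = as.numeric(imp))
  out[order(-out$importance), , drop = FALSE]
}

# Training gain of a fitted model relative to the null (uniform) model:
# log(n_bg) - [ -mean_pr(eta) + log Z ].
model_gain <- function(model, stack, presences_cells = model$presence_cells) {
  sv <- stack_values(stack, presences_cells)
  eta <- model_eta(model, sv$values[, model$layer_names, drop = FALSE])
  log(model$n_bg) - (-mean(eta) + model$log_partition)
}

#' Jackknife variable gains
#'
#' Refits the model with each predictor alone and with each predictor
#' excluded, reporting training gain, test gain and test AUC per condition
#' alongside the full model.
#'
#' @param presences Occurrence data frame.
#' @param stack Predictor `egridstack` (at least 2 layers).
#' @param spec,reg_beta Passed to [fit_maxent()].
#' @param test_fraction Held-out presence fraction for test gain/AUC.
#' @param n_background Background sample size.
#' @param seed Integer seed.
#' @return List with `full` (gain_train, gain_test, auc_test of the full
#'   model) and `table` (per variable: gain_only, gain_without,
#'   test_auc_only).
#' @export
jackknife_gains <- function(presences, stack, spec = feature_spec(),
                            reg_beta = 1.0, test_fraction = 0.3,
                            n_background = 10000L, seed = 1L) {
  vars <- names(stack$layers)
  if (length(vars) < 2L)
    stop("jackknife needs at least 2 predictor layers", call. = FALSE)
  ref <- stack_ref(stack)
  pres <- thin_occurrences(presences, ref)
  set.seed(seed)
  n <- nrow(pres)
  test_idx <- sample.int(n, max(1L, round(test_fraction * n)))
  train <- pres[-test_idx, , drop = FALSE]
  test <- pres[test_idx, , drop = FALSE]
  n_bg <- min(n_background, sum(!is.na(ref$values)))
  bg <- sample_background(stack, n_bg, seed = seed + 1L)

  eval_subset <- function(sub_vars) {
    sub <- egridstack(stack$layers[sub_vars])
    # single-layer stacks cannot carry product features
    sp <- if (length(sub_vars) == 1L)
      feature_spec(setdiff(spec$types, "product")) else spec
    m <- fit_maxent(train, bg, sub, sp, reg_beta)
    tr_cells <- cell_index_of_points(ref, train$lon, train$lat)
    te_cells <- cell_index_of_points(ref, test$lon, test$lat)
    s_te <- score_cells(m, sub, te_cells)
    s_bg <- score_cells(m, sub, bg)
    list(gain_train = model_gain(m, sub, tr_cells),
         gain_test = model_gain(m, sub, te_cells),
         auc_test = auc(s_te, s_bg))
  }

  full <- eval_subset(vars)
  tab <- do.call(rbind, lapply(vars, function(v) {
    only <- eval_subset(v)
    without <- eval_subset(setdiff(vars, v))
    data.frame(variable = v,
               gain_only = only$gain_train,
               gain_without = without$gain_train,
               test_auc_only = only$auc_test)
  }))
  list(full = full, table = tab)
}

#' Marginal response curve of one predictor
#'
#' Sweeps the predictor over its background range at `n_points` while
#' holding every other predictor at its background mean; returns the
#' logistic prediction along the sweep.
#'
#' @param model A fitted `suitability_model`.
#' @param stack The predictor `egridstack`.
#' @param variable Predictor name.
#' @param n_points Sweep resolution.
#' @return Data frame `value`, `prediction`.
#' @export
response_curve <- function(model, stack, variable, n_points = 100L) {
  if (!variable %in% model$layer_names)
    stop("unknown variable: ", variable, call. = FALSE)
  sv <- stack_values(stack, model$background)
  env_bg <- sv$values[, model$layer_names, drop = FALSE]
  sweep_vals <- seq(min(env_bg[, variable]), max(env_bg[, variable]),
                    length.out = n_points)
  env <- matrix(rep(colMeans(env_bg), each = n_points), nrow = n_points,
                dimnames = list(NULL, model$layer_names))
  env[, variable] <- sweep_vals
  eta <- model_eta(model, env)
  raw <- exp(eta - model$log_partition)
  re <- raw * exp(model$entropy_H)
  data.frame(value = sweep_vals, prediction = re / (1 + re))
}

#' Serialize / restore a fitted model as plain text
#'
#' The lambdas file holds a small header (`reg_beta`, `log_partition`,
#' `entropy_H`, feature types, layer names) followed by one row per feature
#' (name, lambda, center, scale).
#'
#' @param model A `suitability_model`.
#' @param path Output path.
#' @export
write_lambdas <- function(model, path) {
  hdr <- c(
    paste0("# reg_beta ", format(model$reg_beta, digits = 17)),
    paste0("# log_partition ", format(model$log_partition, digits = 17)),
    paste0("# entropy_H ", format(model$entropy_H, digits = 17)),
    paste0("# n_bg ", model$n_bg),
    paste0("# types ", paste(model$spec$types, collapse = ",")),
    paste0("# layers ", paste(model$layer_names, collapse = ",")))
  tab <- data.frame(feature = names(model$lambdas),
                    lambda = as.numeric(model$lambdas),
                    center = as.numeric(model$center),
                    scale = as.numeric(model$scale))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
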