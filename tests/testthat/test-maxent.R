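land <- small_landscape()

test_that("background sampling honors size and bias contracts", {
  st <- land$stack
  ref <- invasim:::stack_ref(st)
  n_all <- sum(!is.na(ref$values))
  bg_all <- sample_background(st, n_all, seed = 1)
  expect_equal(bg_all, which(!is.na(ref$values)))  # every cell exactly once

  bias <- ref
  bias$values[] <- 1
  bias$values[, 26:50] <- 0
  bg <- sample_background(st, 500, bias = bias, seed = 2)
  cols <- (bg - 1) %/% 50 + 1
  expect_true(all(cols <= 25))

  bias$values[, 26:50] <- 1 / 3  # 3:1 left:right weight
  # a ~10% draw keeps weighted without-replacement inclusion near the weights
  bg2 <- sample_background(st, 250, bias = bias, seed = 3)
  left <- mean(((bg2 - 1) %/% 50 + 1) <= 25)
  se <- sqrt(0.75 * 0.25 / 250)
  expect_lt(abs(left - 0.75), 3 * se)
  expect_error(sample_background(st, n_all + 1, seed = 1), "exceeds")
})

test_that("heavy regularization recovers the null model", {
  occ <- sample_occurrences(egrid(matrix(1, 50, 50),
                                  xmin = land$spec$xmin,
                                  ymax = land$spec$ymax,
                                  cell_size = land$spec$cell_size),
                            100, seed = 4)
  bg <- sample_background(land$stack, 1000, seed = 5)
  m <- fit_maxent(occ, bg, land$stack, reg_beta = 100)
  expect_true(all(m$lambdas == 0))
  pred <- predict(m, land$stack, output = "raw")
  expect_equal(max(pred$values) - min(pred$values), 0)
})

test_that("the fitted surface recovers the generating suitability", {
  occ <- sample_occurrences(land$surface, 200, seed = 6)
  bg <- sample_background(land$stack, 2000, seed = 7)
  m <- fit_maxent(occ, bg, land$stack)
  pred <- predict(m, land$stack)
  expect_gt(cor(as.numeric(pred$values), as.numeric(land$surface$values),
                method = "spearman"), 0.9)
  expect_true(all(pred$values >= 0 & pred$values <= 1))

  # raw output normalizes over the background sample
  raw <- predict(m, land$stack, output = "raw")
  expect_equal(sum(raw$values[m$background]), 1, tolerance = 1e-6)

  # duplicated presence rows collapse to the identical model
  m2 <- fit_maxent(rbind(occ, occ), bg, land$stack)
  expect_equal(m2$lambdas, m$lambdas)
})

test_that("the penalized objective is convex: optima agree across starts", {
  occ <- sample_occurrences(land$surface, 150, seed = 8)
  bg <- sample_background(land$stack, 1500, seed = 9)
  m0 <- fit_maxent(occ, bg, land$stack)
  set.seed(10)
  m1 <- fit_maxent(occ, bg, land$stack,
                   init = rnorm(length(m0$lambdas), 0, 0.2))
  m2 <- fit_maxent(occ, bg, land$stack,
                   init = rnorm(length(m0$lambdas), 0, 0.2))
  expect_lt(abs(m1$objective - m2$objective) / (abs(m1$objective) + 1e-12),
            1e-6)
  expect_lt(abs(m0$objective - m1$objective) / (abs(m0$objective) + 1e-12),
            1e-6)
})

test_that("a single-signal model tracks its driving layer", {
  tm <- truth_model(c(env1 = 5), intercept = -2)
  surf <- true_suitability(land$stack, tm)
  occ <- sample_occurrences(surf, 200, seed = 11)
  bg <- sample_background(land$stack, 2000, seed = 12)
  m <- fit_maxent(occ, bg, land$stack, feature_spec("linear"))
  pred <- predict(m, land$stack)
  expect_gt(cor(as.numeric(pred$values),
                as.numeric(land$stack$layers$env1$values),
                method = "spearman"), 0.95)

  # linear-only positive effect: monotone response curve
  rc <- response_curve(m, land$stack, "env1")
  expect_true(all(diff(rc$prediction) >= -1e-12))

  # contribution concentrates on the driving variable
  pc <- percent_contribution(m)
  expect_equal(sum(pc$percent), 100, tolerance = 1e-6)
  expect_equal(pc$variable[1], "env1")
  expect_gt(pc$percent[1], 50)

  pi <- permutation_importance(m, land$stack, seed = 1)
  expect_equal(sum(pi$importance), 100, tolerance = 1e-6)
  expect_equal(pi$variable[1], "env1")
})

test_that("replicate evaluation summarizes train/test discrimination", {
  occ <- sample_occurrences(land$surface, 150, seed = 13)
  ev <- replicate_evaluate(occ, land$stack, n_replicates = 3,
                           n_background = 1500, seed = 14)
  expect_equal(nrow(ev$replicates), 3L)
  expect_true(all(ev$replicates$auc_train >= 0 & ev$replicates$auc_train <= 1))
  expect_true(all(ev$replicates$tss >= -1 & ev$replicates$tss <= 1))
  expect_true(all(ev$summary$sd >= 0))
  expect_gt(ev$summary$mean[ev$summary$statistic == "auc_test"], 0.8)

  ev1 <- replicate_evaluate(occ, land$stack, n_replicates = 1,
                            n_background = 1500, seed = 15)
  expect_equal(ev1$summary$sd, rep(0, 4))
  expect_equal(ev1$summary$mean[1], ev1$replicates$auc_train[1])
})

test_that("jackknife gains isolate informative variables", {
  tm <- truth_model(c(env1 = 4), intercept = -3)
  surf <- true_suitability(land$stack, tm)
  occ <- sample_occurrences(surf, 250, seed = 16)
  jk <- jackknife_gains(occ, land$stack, n_background = 1500, seed = 17)
  tab <- jk$table
  expect_true(all(tab$gain_only >= -1e-9))
  # the informative variable alone nearly matches the full model
  g1 <- tab$gain_only[tab$variable == "env1"]
  expect_gt(g1, 0.9 * jk$full$gain_train)
  # excluding an uninformative variable barely moves the gain
  g_wo <- tab$gain_without[tab$variable == "env4"]
  expect_gt(g_wo, 0.95 * jk$full$gain_train)
  expect_error(jackknife_gains(occ, egridstack(land$stack$layers[1]),
                               n_background = 500, seed = 1),
               "at least 2")
})

test_that("quadratic-only response curves peak at the analytic vertex", {
  # fit a quadratic-only model on data whose optimum sits inside the range
  tm <- truth_model(c(env1 = 0), quadratic = c(env1 = -3), intercept = 1)
  surf <- true_suitability(land$stack, tm)
  occ <- sample_occurrences(surf, 300, seed = 18)
  bg <- sample_background(land$stack, 2000, seed = 19)
  m <- fit_maxent(occ, bg, land$stack, feature_spec(c("linear", "quadratic")))
  rc <- response_curve(m, land$stack, "env1", n_points = 201)
  # unimodal with an interior maximum near the planted optimum (0)
  peak <- rc$value[which.max(rc$prediction)]
  expect_lt(abs(peak - 0), 0.5)
  expect_error(response_curve(m, land$stack, "nope"), "unknown variable")
})

test_that("models serialize to a readable lambdas file", {
  occ <- sample_occurrences(land$surface, 100, seed = 20)
  bg <- sample_background(land$stack, 1000, seed = 21)
  m <- fit_maxent(occ, bg, land$stack)
  f <- withr::local_tempfile(fileext = ".txt")
  write_lambdas(m, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# entropy_H", lines)))
  tab <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), length(m$lambdas))
  expect_equal(tab$lambda, unname(m$lambdas))
})
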