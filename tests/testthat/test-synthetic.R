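test_that("environmental stacks are deterministic and honor the mixing matrix", {
  spec <- landscape_spec(nrows = 100, ncols = 100, n_vars = 3,
                         smoothing_radius = 0, seed = 9)
  s1 <- gen_env_stack(spec)
  s2 <- gen_env_stack(spec)
  expect_identical(s1$layers$env1$values, s2$layers$env1$values)

  # identity mixing, no smoothing: layers essentially uncorrelated
  v <- sapply(s1$layers, function(g) as.numeric(g$values))
  r <- cor(v)
  expect_true(all(abs(r[upper.tri(r)]) < 0.1))

  # duplicating layer 1 into layer 2 forces near-perfect correlation
  mix <- diag(3)
  mix[2, ] <- c(1, 0, 0)
  spec2 <- landscape_spec(nrows = 50, ncols = 50, n_vars = 3,
                          smoothing_radius = 2, mixing = mix, seed = 9)
  sd2 <- gen_env_stack(spec2)
  expect_gt(cor(as.numeric(sd2$layers$env1$values),
                as.numeric(sd2$layers$env2$values)), 0.99)

  expect_error(landscape_spec(n_vars = 3, mixing = diag(2)), "mixing")
})

test_that("true suitability is the logistic of the planted linear predictor", {
  land <- small_landscape()
  flat <- true_suitability(land$stack,
                           structure(list(linear = c(env1 = 0),
                                          quadratic = NULL, intercept = 0),
                                     class = "truth_model"))
  expect_true(all(flat$values == 0.5))

  # a dominant positive weight makes suitability track that layer
  tm <- truth_model(c(env1 = 5), intercept = 0)
  s <- true_suitability(land$stack, tm)
  expect_gt(cor(as.numeric(s$values),
                as.numeric(land$stack$layers$env1$values),
                method = "spearman"), 0.95)

  # deeply negative intercept drives suitability into the logistic tail
  tm2 <- truth_model(c(env1 = 0.001), intercept = -20)
  s2 <- true_suitability(land$stack, tm2)
  expect_true(all(s2$values < 1e-7))

  expect_error(true_suitability(land$stack,
                                truth_model(c(nosuch = 1))), "unknown layer")
})

test_that("occurrence sampling follows suitability-times-bias weights", {
  v <- matrix(0, 4, 4); v[2, 3] <- 1
  g <- egrid(v, xmin = 0, ymax = 4, cell_size = 1)
  occ <- sample_occurrences(g, 1, seed = 1)
  expect_equal(occ$lon, 2.5)
  expect_equal(occ$lat, 2.5)

  expect_equal(nrow(sample_occurrences(g, 0, seed = 1)), 0L)
  expect_error(sample_occurrences(g, 5, seed = 1), "positive sampling weight")

  # strong left-half bias concentrates sampling even under flat suitability
  u <- egrid(matrix(1, 40, 40), xmin = 0, ymax = 40, cell_size = 1)
  b <- u
  b$values[, 21:40] <- 1 / 9  # 9:1 left:right effort
  occ2 <- sample_occurrences(u, 200, bias = b, seed = 2)
  expect_gte(mean(occ2$lon < 20), 0.7)

  # sampling frequencies match normalized weights (with-replacement harness)
  set.seed(4)
  w <- runif(50)
  draws <- sample.int(50, 10000, replace = TRUE, prob = w)
  gof <- suppressWarnings(chisq.test(tabulate(draws, 50), p = w / sum(w)))
  expect_gt(gof$p.value, 0.01)
})

test_that("future series apply additive drift linearly", {
  land <- small_landscape()
  base_mean <- mean(land$stack$layers$env1$values)

  same <- gen_future_series(land$stack, c(env1 = 0), periods = 3)
  expect_identical(same[[3]]$layers$env1$values,
                   land$stack$layers$env1$values)

  fut <- gen_future_series(land$stack, c(env1 = 1), periods = 4)
  expect_equal(mean(fut[[4]]$layers$env1$values), base_mean + 4)

  mixed <- gen_future_series(land$stack, c(env1 = 0.5, env2 = -0.25),
                             periods = 3)
  for (k in 1:3) {
    expect_equal(mean(mixed[[k]]$layers$env1$values),
                 mean(land$stack$layers$env1$values) + k * 0.5)
    expect_equal(mean(mixed[[k]]$layers$env2$values),
                 mean(land$stack$layers$env2$values) - k * 0.25)
  }
  expect_error(gen_future_series(land$stack, c(bogus = 1)), "unknown layer")
})

test_that("land-cover maps hit the requested forest share", {
  spec <- landscape_spec(nrows = 200, ncols = 200, n_vars = 2,
                         smoothing_radius = 3, seed = 6)
  expect_true(all(gen_landcover(spec, 1)$values == 1))
  expect_true(all(gen_landcover(spec, 0)$values == 0))
  lc <- gen_landcover(spec, 0.5)
  expect_true(abs(mean(lc$values) - 0.5) < 0.05)
  expect_error(gen_landcover(spec, 1.2), "forest_fraction")
})

test_that("demographic counts scale with suitability as specified", {
  land <- small_landscape()
  set.seed(2)
  ref <- land$surface
  cells <- sample(which(!is.na(ref$values)), 12)
  nr <- nrow(ref$values)
  sites <- data.frame(
    lon = ref$xmin + ((cells - 1) %/% nr + 0.5) * ref$cell_size,
    lat = ref$ymax - ((cells - 1) %% nr + 0.5) * ref$cell_size)

  # zero noise: densities exactly linear in suitability
  d0 <- gen_demography(sites, ref, effect = 10, noise_sd = 0, baseline = 5,
                       seed = 1)
  expect_equal(d0$adults, 5 + 10 * d0$suitability)
  expect_equal(d0$juveniles, 0.6 * (5 + 10 * d0$suitability))

  # determinism
  d1 <- gen_demography(sites, ref, seed = 3)
  d2 <- gen_demography(sites, ref, seed = 3)
  expect_identical(d1, d2)

  expect_error(gen_demography(data.frame(lon = 999, lat = 999), ref),
               "outside")
})
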