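# helper: uniform grids on a shared geometry
dgrid <- function(v, nr = 10, nc = 10) {
  if (length(v) == 1L) v <- matrix(v, nr, nc)
  egrid(v, xmin = 0, ymax = nrow(v), cell_size = 1)
}

test_that("parameter validation and the inconsistent-LDD rule", {
  expect_warning(p <- dispersal_params(lddFreq = 0.05, lddMinDist = 2,
                                       lddMaxDist = 0), "disabled")
  expect_s3_class(p, "dispersal_params")
  expect_false(p$ldd_enabled)  # lddMaxDist 0 < lddMinDist 2 disables LDD
  p2 <- suppressWarnings(dispersal_params(lddMinDist = 2, lddMaxDist = 4))
  expect_true(p2$ldd_enabled)
  expect_error(dispersal_params(rcThreshold = 2000), "rcThreshold")
  expect_error(dispersal_params(propagule_prod = 1.5), "probabilities")
})

test_that("initialization respects barriers and tallies occupancy", {
  init <- dgrid(0); init$values[5, 5] <- 1; init$values[2, 2] <- 1
  bar <- dgrid(0); bar$values[2, 2] <- 1
  p <- suppressWarnings(dispersal_params())
  st <- init_state(init, bar, p)
  expect_false(st$occupied[2, 2])   # barrier precedence
  expect_true(st$occupied[5, 5])
  expect_equal(sum(st$occupied), 1)
  expect_equal(st$age[5, 5], p$iniMatAge)

  st0 <- init_state(dgrid(0), bar, p)
  expect_equal(sum(st0$occupied), 0)

  set.seed(41)
  ri <- dgrid(matrix(rbinom(100, 1, 0.3), 10, 10))
  rb <- dgrid(matrix(rbinom(100, 1, 0.2), 10, 10))
  sr <- init_state(ri, rb, p)
  expect_equal(sum(sr$occupied), sum(ri$values == 1 & rb$values == 0))
})

test_that("stepping decolonizes, colonizes neighbors, and stays local", {
  p <- suppressWarnings(dispersal_params(lddFreq = 0))
  suit <- dgrid(1000)

  # certain colonization of an adjacent suitable cell
  init <- dgrid(0); init$values[5, 5] <- 1
  st <- init_state(init, dgrid(0), p)
  set.seed(42)
  st <- step_dispersal(st, suit, p)
  expect_true(all(st$occupied[4:6, 4:6]))  # all 8 neighbors colonized
  expect_equal(sum(st$occupied), 9)

  # zero kernel and no LDD: occupancy can only shrink
  p0 <- suppressWarnings(dispersal_params(kernel = c(0), lddFreq = 0))
  suit_drop <- dgrid(1000); suit_drop$values[5, 5] <- 0
  st2 <- init_state(dgrid(1), dgrid(0), p0)
  n0 <- sum(st2$occupied)
  set.seed(43)
  st2 <- step_dispersal(st2, suit_drop, p0)
  expect_equal(sum(st2$occupied), n0 - 1)
  expect_false(st2$occupied[5, 5])
  expect_equal(st2$age[5, 5], 0L)

  # locality: with lddFreq 0 nothing colonizes beyond the kernel range
  init3 <- dgrid(0); init3$values[1, 1] <- 1
  st3 <- init_state(init3, dgrid(0), p)
  set.seed(44)
  st3 <- step_dispersal(st3, suit, p)
  d <- sqrt(outer((1:10 - 1)^2, (1:10 - 1)^2, "+"))
  expect_true(all(!st3$occupied[round(d) > 1]))

  expect_error(step_dispersal(st3, dgrid(2000), p), "0-1000")
})

test_that("per-step colonization counts match the analytic probability oracle", {
  p <- suppressWarnings(dispersal_params(propagule_prod = 0.4,
                                         kernel = c(0.5), lddFreq = 0))
  suit <- dgrid(1000)
  set.seed(45)
  init <- dgrid(matrix(rbinom(100, 1, 0.25), 10, 10))
  st0 <- init_state(init, dgrid(0), p)

  # closed-form expected colonizations: per eligible cell,
  # 1 - prod(1 - p*k) over mature sources at rounded distance 1
  mature <- st0$occupied
  expected <- 0
  for (r in 1:10) for (c in 1:10) {
    if (mature[r, c]) next
    miss <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= 10 && cc >= 1 && cc <= 10 && mature[rr, cc])
        miss <- miss * (1 - 0.4 * 0.5)
    }
    expected <- expected + (1 - miss)
  }

  counts <- replicate(200, {
    st <- step_dispersal(st0, suit, p)
    tail(st$history$colonized, 1)
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("scenario runs honor their dispersal assumptions", {
  p <- suppressWarnings(dispersal_params(encChgSteps = 2, dispSteps = 5,
                                         replicates = 2, seed = 11))
  all_suit <- list(dgrid(1000), dgrid(1000))
  init <- dgrid(0); init$values[5, 5] <- 1

  run_u <- run_dispersal(init, dgrid(0), all_suit, p, "unlimited")
  expect_true(all(run_u$occupancy[[1]]$values == 1))  # full from period 1

  # collapsing suitability empties the no-dispersal scenario for good
  collapse <- list(dgrid(1000), dgrid(0))
  run_n <- run_dispersal(init, dgrid(0), collapse, p, "none")
  expect_equal(sum(run_n$occupancy[[1]]$values), 1)
  expect_equal(sum(run_n$occupancy[[2]]$values), 0)

  expect_error(run_dispersal(init, dgrid(0), all_suit[1], p, "none"),
               "encChgSteps")

  # determinism: identical seeds give identical consensus maps
  r1 <- run_dispersal(init, dgrid(0), all_suit, p, "constrained")
  r2 <- run_dispersal(init, dgrid(0), all_suit, p, "constrained")
  expect_identical(lapply(r1$occupancy, `[[`, "values"),
                   lapply(r2$occupancy, `[[`, "values"))
})

test_that("a closed barrier ring confines spread to the reachable set", {
  p <- suppressWarnings(dispersal_params(encChgSteps = 2, dispSteps = 10,
                                         replicates = 3, seed = 12))
  bar <- dgrid(0, 15, 15)
  bar$values[5, 5:11] <- 1; bar$values[11, 5:11] <- 1
  bar$values[5:11, 5] <- 1; bar$values[5:11, 11] <- 1
  init <- dgrid(0, 15, 15); init$values[8, 8] <- 1
  suit <- list(dgrid(1000, 15, 15), dgrid(1000, 15, 15))
  run <- run_dispersal(init, bar, suit, p, "constrained")

  reach <- reachable_cells(which(init$values == 1), bar$values == 1)
  for (k in 1:2) for (r in seq_along(run$replicate_occupancy)) {
    occ <- run$replicate_occupancy[[r]][[k]]
    expect_true(all(!occ[!reach]))          # confinement
    expect_true(all(!occ[bar$values == 1])) # barrier impermeability
  }
})

test_that("scenario occupancies nest on random landscapes", {
  set.seed(46)
  p <- suppressWarnings(dispersal_params(encChgSteps = 3, dispSteps = 8,
                                         replicates = 2, seed = 13))
  for (i in 1:3) {
    suit <- lapply(1:3, function(k)
      dgrid(matrix(sample(c(0, 700, 1000), 400, TRUE), 20, 20)))
    init <- dgrid(matrix(rbinom(400, 1, 0.1), 20, 20))
    bar <- dgrid(matrix(rbinom(400, 1, 0.15), 20, 20))
    run_n <- run_dispersal(init, bar, suit, p, "none")
    run_c <- run_dispersal(init, bar, suit, p, "constrained")
    run_u <- run_dispersal(init, bar, suit, p, "unlimited")
    for (k in 1:3) {
      none_k <- run_n$occupancy[[k]]$values == 1
      unlim_k <- run_u$occupancy[[k]]$values == 1
      for (r in seq_along(run_c$replicate_occupancy)) {
        con_k <- run_c$replicate_occupancy[[r]][[k]]
        expect_true(all(!none_k | con_k))   # none subset of constrained
        expect_true(all(!con_k | unlim_k))  # constrained subset of unlimited
      }
    }
  }
})
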