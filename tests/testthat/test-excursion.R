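test_that("manifold dimension follows cumulative variance exactly on
           noiseless planted factors", {
  # rank-2 data in 6 ROIs: d = 2, all variance explained
  sim <- simulate_neural(neural_sim_config(n_rois = 6, manifold_dim = 2,
                                           n_volumes_rest = 100,
                                           n_volumes_task = 10,
                                           noise_sd = 0, seed = 1))
  m <- fit_manifold(sim$rest)
  expect_equal(m$d, 2)
  expect_equal(m$var_explained, 1.0, tolerance = 1e-10)
  # rest sample covariance has exactly rank 2
  ev <- eigen(stats::cov(sim$rest), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[3] / ev[1], 1e-12)
  # planted variances (4, 2, 1, 0.5): cumulative fractions 0.533, 0.8,
  # 0.933, 1 -> smallest count reaching 75% is 2; reaching 90% is 3
  set.seed(2)
  w <- rand_frame(8, 4)
  z <- matrix(rnorm(4000 * 4), 4000, 4) %*% diag(sqrt(c(4, 2, 1, 0.5)))
  x <- z %*% t(w)
  colnames(x) <- sprintf("ROI%03d", 1:8)
  expect_equal(fit_manifold(x, 0.75)$d, 2)
  expect_equal(fit_manifold(x, 0.9)$d, 3)
})

test_that("isotropic white noise needs roughly threshold x n_rois
           components", {
  ds <- sapply(1:6, function(s) {
    set.seed(s)
    x <- matrix(rnorm(400 * 10), 400, 10)
    colnames(x) <- sprintf("ROI%03d", 1:10)
    fit_manifold(x, 0.75)$d
  })
  expect_true(all(ds %in% 7:9))
})

test_that("constant ROI raises an error naming it", {
  x <- cbind(ROIA = rnorm(50), ROIB = rep(2, 50))
  expect_error(fit_manifold(x), "ROIB")
})

test_that("manifold basis is orthonormal and projectors behave", {
  sim <- simulate_neural(neural_sim_config(seed = 3))
  m <- fit_manifold(sim$rest)
  v <- m$basis
  expect_lt(max(abs(crossprod(v) - diag(m$d))), 1e-10)
  p_on <- v %*% t(v)
  p_off <- diag(nrow(p_on)) - p_on
  expect_lt(max(abs(p_on %*% p_on - p_on)), 1e-10)   # idempotent
  expect_lt(max(abs(p_off %*% p_off - p_off)), 1e-10)
  expect_lt(max(abs(p_on - t(p_on))), 1e-10)          # symmetric
  expect_lt(max(abs(p_on + p_off - diag(nrow(p_on)))), 1e-12)
})

test_that("excursion is the off-manifold share of the centered signal", {
  # V = span{(1,0)}: x = (3,4) has e = 4, r = 0.8
  m <- structure(list(basis = matrix(c(1, 0), 2, 1), center = c(0, 0),
                      d = 1L, var_explained = 1, sdev = c(1, 0),
                      var_threshold = 0.75, roi_labels = NULL),
                 class = "rest_manifold")
  out <- excursion_series(m, matrix(c(3, 4), 1, 2))
  expect_equal(out$excursion, 0.8, tolerance = 1e-12)
  # on-manifold vector: r = 0; orthogonal vector: r = 1
  expect_equal(excursion_series(m, matrix(c(5, 0), 1, 2))$excursion, 0)
  expect_equal(excursion_series(m, matrix(c(0, 2), 1, 2))$excursion, 1)
  # near-zero norm flagged with r = 0
  z <- excursion_series(m, matrix(c(1e-14, 0), 1, 2))
  expect_true(z$near_zero)
  expect_equal(z$excursion, 0)
  # r invariant to positive rescaling, bounded in [0, 1]
  set.seed(4)
  x <- matrix(rnorm(20), 10, 2)
  r1 <- excursion_series(m, x)$excursion
  r2 <- excursion_series(m, 7 * x)$excursion
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_true(all(r1 >= 0 & r1 <= 1))
})

test_that("projector route equals least-squares regression on the basis", {
  sim <- simulate_neural(neural_sim_config(n_rois = 15, manifold_dim = 4,
                                           n_volumes_task = 50, seed = 5))
  m <- fit_manifold(sim$rest)
  out <- excursion_series(m, sim$task)
  xc <- sweep(sim$task, 2, m$center)
  oracle <- sapply(seq_len(nrow(xc)), function(t) {
    fit <- lm.fit(m$basis, xc[t, ])
    sqrt(sum(fit$residuals^2)) / sqrt(sum(xc[t, ]^2))
  })
  expect_lt(max(abs(out$excursion - oracle)), 1e-8)
})

test_that("noiseless task data lie on the planted manifold; a step leaves
           it exactly at the step", {
  sched <- c(rep(0, 60), rep(1.5, 40))
  sim <- simulate_neural(neural_sim_config(n_rois = 10, manifold_dim = 3,
                                           n_volumes_rest = 300,
                                           n_volumes_task = 100,
                                           off_manifold_schedule = sched,
                                           noise_sd = 0, seed = 6))
  # threshold high enough to retain every planted factor
  # off-manifold norm relative to planted basis: 0 before, 1.5 after
  w <- sim$ground_truth$W
  xc <- sweep(sim$task, 2, sim$ground_truth$mu)
  off <- xc - xc %*% w %*% t(w)
  offn <- sqrt(rowSums(off^2))
  expect_lt(max(offn[1:60]), 1e-10)
  expect_equal(offn[61:100], rep(1.5, 40), tolerance = 1e-10)
  # excursion from the fitted manifold is positive exactly from the step on
  m <- fit_manifold(sim$rest, var_threshold = 0.999)
  r <- excursion_series(m, sim$task)$excursion
  expect_lt(max(r[1:60]), 1e-8)
  expect_true(all(r[61:100] > 1e-3))
})

test_that("baseline standardization matches hand z-scores and is shift
           invariant", {
  curve <- tibble::tibble(volume = 1:3, excursion = c(0.2, 0.4, 0.4))
  out <- standardize_to_baseline(curve, 1:2)
  expect_equal(out$standardized[3], 0.1 / stats::sd(c(0.2, 0.4)),
               tolerance = 1e-12)
  expect_equal(out$standardized[3], 0.7071, tolerance = 1e-3)
  # degenerate baseline errors
  flat <- tibble::tibble(volume = 1:4, excursion = rep(0.3, 4))
  expect_error(standardize_to_baseline(flat, 1:2), "SD is zero")
  # adding a constant to the raw curve leaves z unchanged
  shifted <- dplyr::mutate(curve, excursion = excursion + 0.5)
  expect_equal(standardize_to_baseline(shifted, 1:2)$standardized,
               out$standardized, tolerance = 1e-10)
})

test_that("early excursion averages the first 4 blocks and recovers a
           planted step height", {
  curve <- tibble::tibble(volume = 1:200,
                          excursion = 0,
                          standardized = c(rep(0, 100), rep(2, 100)))
  # defaults: 8 trials x 4 blocks x 2 volumes = 64 volumes
  expect_equal(early_excursion(curve, 101), 2.0)
  expect_error(early_excursion(curve, 180), "exceeds")
  # noiseless planted step: post-onset standardized excursion is flat at
  # the step height in baseline-SD units... baseline SD is 0 without noise,
  # so recovery is asserted on the raw curve instead
  sched <- c(rep(0, 100), rep(2, 100))
  sim <- simulate_neural(neural_sim_config(n_rois = 12, manifold_dim = 3,
                                           n_volumes_rest = 400,
                                           n_volumes_task = 200,
                                           off_manifold_schedule = sched,
                                           noise_sd = 1e-4, seed = 7))
  m <- fit_manifold(sim$rest, var_threshold = 0.999)
  st <- standardize_to_baseline(excursion_series(m, sim$task), 1:100)
  ee <- early_excursion(st, 101)
  # mean post-onset raw excursion matches the planted geometry within 10%
  raw <- st$excursion
  xc <- sweep(sim$task, 2, m$center)
  expected_r <- mean(2 / sqrt(rowSums(xc[101:164, ]^2)))
  expect_equal(mean(raw[101:164]), expected_r, tolerance = 0.1)
  expect_gt(ee, 10)  # far outside baseline variability
})
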