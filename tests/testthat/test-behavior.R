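test_that("circular mean handles wrap-around and is rotation equivariant", {
  expect_equal(circular_mean(rep(45, 10)), 45)
  expect_equal(circular_mean(c(-10, 10, -10, 10)), 0, tolerance = 1e-12)
  # vector-sum oracle: {170, -170} sum to a resultant pointing at 180
  expect_equal(circular_mean(c(170, -170)), 180, tolerance = 1e-9)
  set.seed(1)
  x <- runif(50, -180, 180)
  for (delta in c(20, 150, 300)) {
    m0 <- circular_mean(x)
    m1 <- circular_mean(x + delta)
    r <- (m1 - m0 - delta) %% 360
    expect_lt(min(r, 360 - r), 1e-8)
  }
})

test_that("reaction-time filters flag trials without altering good ones", {
  tr <- make_trials(rep(10, 40))
  tr$rt_s[5] <- 2.5   # too slow
  tr$rt_s[9] <- 0.05  # anticipatory
  out <- preprocess_trials(tr)
  expect_false(out$valid[5])
  expect_false(out$valid[9])
  # constant error curve: zero residuals, nothing interpolated, values intact
  expect_equal(sum(out$interpolated), 0)
  expect_equal(out$error_deg, tr$error_deg)
})

test_that("spline detrending interpolates exactly a planted spike", {
  t <- 0:119
  decay <- 45 * exp(-t / 30)  # smooth 45 -> 5 degree decay
  tr <- make_trials(decay)
  tr$error_deg[61] <- tr$error_deg[61] + 90
  out <- preprocess_trials(tr)
  expect_true(out$interpolated[61])
  expect_equal(sum(out$interpolated), 1)
  # replaced by the spline fit, i.e. close to the uncontaminated curve
  expect_lt(abs(out$error_deg[61] - decay[61]), 10)
  # all other trials untouched
  expect_equal(out$error_deg[-61], tr$error_deg[-61])
})

test_that("tiny blocks pass through undetrended with a warning", {
  tr <- make_trials(c(10, 20, 100))
  expect_warning(out <- preprocess_trials(tr), "valid trials")
  expect_equal(out$error_deg, tr$error_deg)
})

test_that("early error is the circular mean of the first 32 learning trials", {
  tr <- make_trials(rep(45, 40))
  expect_equal(early_error(tr, 1), 45)
  # window is exactly 32 trials: trial 33+ must not matter
  tr2 <- make_trials(c(rep(10, 32), rep(-170, 8)))
  expect_equal(early_error(tr2, 1), 10, tolerance = 1e-10)
  expect_error(early_error(make_trials(rep(1, 10)), 1), ">= 32")
  tr3 <- make_trials(rep(10, 32))
  tr3$valid <- FALSE
  expect_error(early_error(tr3, 1), "invalid")
})

test_that("features give savings = day1 - day2 and n-1 standardization", {
  tr <- dplyr::bind_rows(
    make_trials(rep(30, 32), day = 1, subject = "a"),
    make_trials(rep(12, 32), day = 2, subject = "a"),
    make_trials(rep(20, 32), day = 1, subject = "b"),
    make_trials(rep(18, 32), day = 2, subject = "b"))
  f <- compute_features(tr)
  expect_equal(f$savings[f$subject == "a"], 18)
  # two-subject standardization: {0, 2} -> -/+ 1/sqrt(2)
  expect_equal(sort(f$savings_z), c(-1, 1) / sqrt(2), tolerance = 1e-10)
  # identical subjects: zero SD is an error
  tr_same <- dplyr::bind_rows(
    make_trials(rep(30, 32), day = 1, subject = "a"),
    make_trials(rep(12, 32), day = 2, subject = "a"),
    make_trials(rep(30, 32), day = 1, subject = "b"),
    make_trials(rep(12, 32), day = 2, subject = "b"))
  expect_error(compute_features(tr_same), "zero SD")
})

test_that("noiseless generator follows the planted exponential exactly", {
  cfg <- behavior_sim_config(n_subjects_per_group = 1, error_noise_sd = 0,
                             rt_violation_rate = 0,
                             learn_rate_day1 = c(FF = 10, SS = 120, SF = 120),
                             learn_rate_day2 = c(FF = 10, SS = 120, SF = 10),
                             seed = 4)
  tr <- simulate_behavior(cfg)
  ff1 <- dplyr::filter(tr, group == "FF", day == 1, epoch == "learning")
  expect_equal(ff1$error_deg[1], 45)                 # error at rotation onset
  expect_lt(abs(ff1$error_deg[61]), 0.12)            # 45 e^{-6} < 0.12
  # SS has identical rates both days: savings exactly 0
  f <- compute_features(tr)
  expect_equal(f$savings[f$group == "SS"], 0, tolerance = 1e-10)
  # SF shows large positive savings; FF little
  expect_gt(f$savings[f$group == "SF"], 15)
  expect_lt(abs(f$savings[f$group == "FF"]), 1e-10)
})

test_that("generator is deterministic and separates phenotypes beyond noise", {
  cfg <- behavior_sim_config(seed = 1)
  expect_identical(simulate_behavior(cfg), simulate_behavior(cfg))
  tr <- suppressWarnings(preprocess_trials(simulate_behavior(cfg)))
  f <- compute_features(tr)
  gm <- tapply(f$early_error_day1, f$group, mean)
  # SE of a 32-trial mean at the configured noise, for a group of n subjects
  se <- cfg$error_noise_sd / sqrt(32) / sqrt(cfg$n_subjects_per_group)
  expect_gt(abs(gm[["SS"]] - gm[["FF"]]), 3 * se)
})

test_that("complete-linkage/Manhattan clustering matches small enumerable
           cases and is order invariant", {
  f <- tibble::tibble(subject = c("a", "b", "c"), x = c(0, 1, 10))
  cl <- cluster_learners(f, k = 2)
  expect_equal(cl$labels$cluster, c(1, 1, 2))
  # hand sums of squares: within 0.5, total 182/3
  expect_equal(cl$ss_ratio, 0.5 / (182 / 3), tolerance = 1e-12)
  # duplicated points always share a cluster
  f2 <- tibble::tibble(subject = letters[1:4], x = c(0, 0, 5, 9))
  cl2 <- cluster_learners(f2, k = 2)
  expect_equal(cl2$labels$cluster[1], cl2$labels$cluster[2])
  # subject order must not change the partition
  perm <- c(3, 1, 2)
  cl3 <- cluster_learners(f[perm, ], k = 2)
  relabel <- cl3$labels$cluster[match(f$subject, cl3$labels$subject)]
  expect_equal(adjusted_rand_index(relabel, cl$labels$cluster), 1)
  expect_error(cluster_learners(f, k = 5), "exceeds")
})

test_that("clustering recovers planted phenotypes and ss_ratio decreases
           in k", {
  tr <- suppressWarnings(preprocess_trials(
    simulate_behavior(behavior_sim_config(seed = 1))))
  f <- compute_features(tr)
  cl <- cluster_learners(f, k = 3)
  expect_equal(adjusted_rand_index(cl$labels$cluster, f$group), 1)
  ratios <- sapply(2:8, function(k) cluster_learners(f, k)$ss_ratio)
  expect_true(all(diff(ratios) <= 1e-12))
  # ARI agrees with the independent mclust implementation
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(cl$labels$cluster, f$group),
               mclust::adjustedRandIndex(cl$labels$cluster, f$group))
})

test_that("clustering is invariant to pre-standardization affine rescaling", {
  tr <- suppressWarnings(preprocess_trials(
    simulate_behavior(behavior_sim_config(n_subjects_per_group = 5,
                                          seed = 3))))
  f <- compute_features(tr)
  f2 <- dplyr::mutate(f,
    early_error_day1 = 10 * early_error_day1 + 5,
    early_error_day2 = -2 * early_error_day2,
    savings = 0.5 * savings - 1)
  for (v in c("early_error_day1", "early_error_day2", "savings")) {
    f2[[paste0(v, "_z")]] <-
      (f2[[v]] - mean(f2[[v]])) / stats::sd(f2[[v]])
  }
  c1 <- cluster_learners(f, 3)$labels$cluster
  c2 <- cluster_learners(f2, 3)$labels$cluster
  # sign flips can permute merge heights; partitions must still agree up to
  # labels for same-shape features
  expect_equal(abs(adjusted_rand_index(c1, c2)), 1)
})

test_that("bootstrap validity flags planted structure and handles
           degeneracy", {
  f <- tibble::tibble(subject = c("a", "b", "c"), x = c(0, 1, 10))
  bv <- bootstrap_cluster_validity(f, k_range = 2:2, n_boot = 100, seed = 1)
  expect_equal(bv$ss_ratio_observed, 0.5 / (182 / 3), tolerance = 1e-9)
  # all-identical points: ratio 0 by convention
  m <- matrix(rep(1, 6), ncol = 2)
  expect_equal(neuroexcursion:::ss_ratio(m, c(1, 1, 2)), 0)
  # planted 3 groups: observed k=3 ratio below the null 5th percentile
  tr <- suppressWarnings(preprocess_trials(
    simulate_behavior(behavior_sim_config(seed = 2))))
  ft <- compute_features(tr)
  bv3 <- suppressWarnings(
    bootstrap_cluster_validity(ft, k_range = 2:4, n_boot = 200, seed = 2))
  row3 <- bv3[bv3$k == 3, ]
  expect_lt(row3$ss_ratio_observed, row3$null_q05)
})
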