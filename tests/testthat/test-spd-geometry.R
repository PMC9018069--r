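test_that("log/exp maps invert each other and match scalar closed forms", {
  # scalar closed forms: log-map r*log(s/r); exp-map r*exp(t/r)
  expect_equal(spd_log(matrix(4), matrix(4 * exp(2)))[1, 1], 8,
               tolerance = 1e-12)
  expect_equal(spd_exp(matrix(1), matrix(1))[1, 1], exp(1),
               tolerance = 1e-12)
  # log at the reference itself is zero
  a <- rand_spd(6, seed = 1)
  expect_lt(frob(spd_log(a, a)), 1e-10)
  # roundtrips both ways on random 10x10 pairs
  for (s in 1:5) {
    ref <- rand_spd(10, seed = 10 + s)
    spd <- rand_spd(10, seed = 60 + s)
    expect_lt(frob(spd_exp(ref, spd_log(ref, spd)) - spd), 1e-8)
    tan <- rand_sym(10, seed = 110 + s)
    expect_lt(frob(spd_log(ref, spd_exp(ref, tan)) - tan), 1e-8)
  }
})

test_that("inputs must be SPD and symmetric", {
  expect_error(spd_log(diag(2), matrix(c(1, 2, 3, 4), 2)), "symmetric")
  neg <- diag(c(1, -1))
  expect_error(spd_log(neg, diag(2)), "positive definite")
  expect_error(spd_distance(diag(2), diag(3)), "mismatch")
  expect_error(shrinkage_covariance(cbind(a = rnorm(10), b = rep(1, 10))),
               "Constant")
})

test_that("parallel transport matches the scalar case and is an isometry", {
  expect_equal(spd_transport(matrix(1), matrix(4), matrix(2))[1, 1], 8,
               tolerance = 1e-12)
  from <- rand_spd(8, seed = 2); to <- rand_spd(8, seed = 3)
  tan <- rand_sym(8, seed = 4)
  expect_lt(frob(spd_transport(from, from, tan) - tan), 1e-10)
  moved <- spd_transport(from, to, tan)
  norm_at <- function(ref, t) {
    ih <- neuroexcursion:::spd_invsqrt(ref)
    frob(ih %*% t %*% ih)
  }
  expect_equal(norm_at(to, moved), norm_at(from, tan), tolerance = 1e-8)
})

test_that("geodesic distance is symmetric, zero on the diagonal, and
           congruence invariant", {
  s1 <- rand_spd(7, seed = 5); s2 <- rand_spd(7, seed = 6)
  expect_equal(spd_distance(s1, s1), 0, tolerance = 1e-10)
  expect_equal(spd_distance(s1, s2), spd_distance(s2, s1),
               tolerance = 1e-10)
  expect_equal(spd_distance(matrix(1), matrix(exp(2))), 2,
               tolerance = 1e-12)
  set.seed(7)
  a <- matrix(rnorm(49), 7, 7)  # invertible w.p. 1
  expect_equal(spd_distance(a %*% s1 %*% t(a), a %*% s2 %*% t(a)),
               spd_distance(s1, s2), tolerance = 1e-8)
})

test_that("Frechet mean: identity cases, geometric mean, first-order
           condition", {
  a <- rand_spd(5, seed = 8)
  expect_equal(spd_frechet_mean(list(a)), a, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(spd_frechet_mean(list(a, a)), a, tolerance = 1e-7,
               ignore_attr = TRUE)
  # scalar sets: geometric mean
  expect_equal(spd_frechet_mean(list(matrix(1), matrix(exp(2))))[1, 1],
               exp(1), tolerance = 1e-10)
  set.seed(9)
  vals <- runif(6, 0.2, 5)
  fm <- spd_frechet_mean(lapply(vals, matrix))[1, 1]
  expect_equal(fm, exp(mean(log(vals))), tolerance = 1e-10)
  # first-order condition at the solution
  mats <- lapply(1:4, function(i) rand_spd(6, seed = 20 + i))
  m <- spd_frechet_mean(mats, tol = 1e-10)
  mih <- neuroexcursion:::spd_invsqrt(m)
  mean_log <- Reduce(`+`, lapply(mats, function(s) {
    neuroexcursion:::spd_logm(mih %*% s %*% mih)
  })) / length(mats)
  expect_lt(frob(mean_log), 1e-9)
})

test_that("centering maps the subject's own rest to the grand mean and
           preserves shared relative shifts", {
  rest <- rand_spd(6, seed = 30); grand <- rand_spd(6, seed = 31)
  out <- spd_center(rest, list(rest), grand)
  expect_lt(frob(out$tangents[[1]]), 1e-8)
  expect_lt(frob(out$centered[[1]] - grand), 1e-8)
  # scalar chain: rest 1, grand 4, task e^2 -> T = 2, Tc = 8, Sc = 4 e^2
  out1 <- spd_center(matrix(1), list(matrix(exp(2))), matrix(4))
  expect_equal(out1$tangents[[1]][1, 1], 8, tolerance = 1e-10)
  expect_equal(out1$centered[[1]][1, 1], 4 * exp(2), tolerance = 1e-10)
  # two subjects with identical relative shift get identical centered tangents
  rel <- rand_spd(6, seed = 32)  # common R^{-1/2} S R^{-1/2}
  r1 <- rand_spd(6, seed = 33); r2 <- rand_spd(6, seed = 34)
  mk_task <- function(r) {
    rh <- neuroexcursion:::spd_sqrt(r)
    rh %*% rel %*% rh
  }
  t1 <- spd_center(r1, list(mk_task(r1)), grand)$tangents[[1]]
  t2 <- spd_center(r2, list(mk_task(r2)), grand)$tangents[[1]]
  expect_equal(t1, t2, tolerance = 1e-8)
})

test_that("centering removes subject identity on planted shared task shifts", {
  # subjects share one task tangent pattern but have very different bases
  p <- 8
  set.seed(40)
  h <- rnorm(p); h <- h / sqrt(sum(h^2))
  shared <- 1.5 * tcrossprod(h)
  rests <- lapply(1:6, function(i) rand_spd(p, seed = 40 + i) * runif(1, .5, 3))
  tasks <- lapply(rests, function(r) {
    rh <- neuroexcursion:::spd_sqrt(r)
    rh %*% neuroexcursion:::spd_expm(shared) %*% rh
  })
  grand <- spd_frechet_mean(rests)
  centered <- mapply(function(r, s) spd_center(r, list(s), grand)$centered[[1]],
                     rests, tasks, SIMPLIFY = FALSE)
  pair_dist <- function(lst) {
    d <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      d <- c(d, spd_distance(lst[[i]], lst[[j]]))
    }
    mean(d)
  }
  expect_gt(pair_dist(tasks) / pair_dist(centered), 10)
})

test_that("shrinkage covariance is SPD in p > n regimes, consistent, and
           matches the scalar case", {
  # scalar: estimate equals the 1/n sample variance
  x <- matrix(c(1, -1, 1, -1), ncol = 1)
  est <- shrinkage_covariance(x)
  expect_equal(est[1, 1], 1, tolerance = 1e-12)
  expect_lte(est[1, 1], 1)
  # p = 60 > n = 50 stays positive definite
  set.seed(50)
  wide <- matrix(rnorm(50 * 60), 50, 60)
  ev <- eigen(shrinkage_covariance(wide), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # consistency: Frobenius error roughly halves when n quadruples
  p <- 6
  sigma <- rand_spd(p, seed = 51)
  err_at <- function(n, seed) {
    set.seed(seed)
    xs <- MASS::mvrnorm(n, rep(0, p), sigma)
    frob(shrinkage_covariance(xs) - sigma)
  }
  e_small <- mean(sapply(1:10, function(s) err_at(200, 100 + s)))
  e_big <- mean(sapply(1:10, function(s) err_at(800, 200 + s)))
  expect_lt(e_big / e_small, 0.65)
})
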