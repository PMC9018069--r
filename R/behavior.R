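#' Clean visuomotor-rotation trial data
#'
#' Applies the standard filters to per-trial angular errors: trials with
#' reaction times above 2 s or below 100 ms are flagged invalid; within each
#' scan block (epoch x day x subject) the error curve is detrended by an
#' unpenalized cubic B-spline least-squares fit with one interior knot per
#' 40 trials (`ceiling(n / 40)` knots, evenly spaced), and trials whose
#' residual exceeds 3 SD of the block residuals are replaced by the fitted
#' value and flagged `interpolated`. Valid non-outlier trials are never
#' altered. Blocks with fewer than 4 valid trials pass through undetrended
#' with a warning.
#'
#' @param trials tibble with at least `subject`, `day`, `epoch`, `trial`,
#'   `error_deg`, `rt_s` (as produced by [simulate_behavior()]).
#' @param rt_max,rt_min reaction-time validity bounds in seconds.
#' @param sd_threshold residual outlier threshold in block-residual SDs.
#' @param trials_per_knot trials per interior spline knot.
#' @return the input tibble with added logical columns `valid` and
#'   `interpolated`, `error_deg` replaced by the spline fit on interpolated
#'   trials, and attributes `n_invalid` / `n_interpolated`.
#' @export
preprocess_trials <- function(trials, rt_max = 2, rt_min = 0.1,
                              sd_threshold = 3, trials_per_knot = 40) {
  needed <- c("subject", "day", "epoch", "trial", "error_deg", "rt_s")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  trials <- dplyr::mutate(trials,
    valid = .data$rt_s <= rt_max & .data$rt_s >= rt_min,
    interpolated = FALSE)

  detrend_block <- function(df) {
    ok <- df$valid
    n_ok <- sum(ok)
    if (n_ok < 4L) {
      warn(sprintf("Block %s/day %s/%s: only %d valid trials; not detrended.",
                   df$subject[1], df$day[1], df$epoch[1], n_ok))
      return(df)
    }
    x <- df$trial[ok]; y <- df$error_deg[ok]
    n_knots <- ceiling(n_ok / trials_per_knot)
    knots <- seq(min(x), max(x), length.out = n_knots + 2L)
    knots <- knots[-c(1L, length(knots))]
    basis <- splines::bs(x, knots = knots, degree = 3, intercept = TRUE)
    fit <- stats::lm.fit(basis, y)
    resid <- y - fit$fitted.values
    rsd <- stats::sd(resid)
    # guard against numerically-zero residual spread (e.g. constant blocks)
    if (is.na(rsd) || rsd < 1e-8 * max(1, max(abs(y)))) return(df)
    out_idx <- which(abs(resid) > sd_threshold * rsd)
    if (length(out_idx)) {
      rows <- which(ok)[out_idx]
      df$error_deg[rows] <- wrap_degrees(fit$fitted.values[out_idx])
      df$interpolated[rows] <- TRUE
    }
    df
  }

  parts <- trials %>%
    dplyr::group_by(.data$subject, .data$day, .data$epoch) %>%
    dplyr::group_split()
  out <- purrr::map_dfr(parts, detrend_block) %>%
    dplyr::arrange(.data$subject, .data$day, .data$trial)
  attr(out, "n_invalid") <- sum(!out$valid)
  attr(out, "n_interpolated") <- sum(out$interpolated)
  out
}

#' Early error: circular mean over the first four 8-trial learning blocks
#'
#' The circular mean of the signed angular error over learning trials 1-32
#' (the first four sets of eight trials after rotation onset), using valid
#' trials only. Interpolated trials count as valid.
#'
#' @param trials preprocessed tibble for one subject (see
#'   [preprocess_trials()]); must contain a `learning` epoch.
#' @param day which day to evaluate.
#' @param n_trials number of learning trials in the window (default 32).
#' @return early error in degrees, in (-180, 180].
#' @export
early_error <- function(trials, day, n_trials = 32) {
  d <- day
  learn <- trials %>%
    dplyr::filter(.data$day == d, .data$epoch == "learning") %>%
    dplyr::arrange(.data$trial)
  if (nrow(learn) < n_trials) {
    abort(sprintf("Need >= %d learning trials on day %s.", n_trials, day))
  }
  win <- learn[seq_len(n_trials), ]
  if ("valid" %in% names(win)) win <- win[win$valid, ]
  if (nrow(win) == 0L) abort("All early-learning trials are invalid.")
  circular_mean(win$error_deg)
}

#' Per-subject learning features: early errors and savings
#'
#' Computes day-1 and day-2 early error per subject, savings as their
#' difference (day 1 minus day 2), and feature-wise standardized copies
#' (mean 0, SD 1 across subjects, sample SD with the n-1 denominator).
#'
#' @param trials preprocessed trial tibble covering all subjects, both days.
#' @return tibble with one row per subject: `subject`, `group` (if
#'   present), `early_error_day1`, `early_error_day2`, `savings`, and `_z`
#'   standardized versions of the three features.
#' @export
compute_features <- function(trials) {
  feats <- trials %>%
    dplyr::group_by(.data$subject) %>%
    dplyr::group_modify(function(df, key) {
      tibble(early_error_day1 = early_error(df, 1),
             early_error_day2 = early_error(df, 2))
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(savings = .data$early_error_day1 - .data$early_error_day2)
  if ("group" %in% names(trials)) {
    feats <- dplyr::left_join(feats,
      dplyr::distinct(trials, .data$subject, .data$group), by = "subject")
  }
  if (nrow(feats) < 2L) abort("Standardization needs >= 2 subjects.")
  for (v in c("early_error_day1", "early_error_day2", "savings")) {
    s <- stats::sd(feats[[v]])
    if (s == 0) abort(sprintf("Feature `%s` has zero SD across subjects.", v))
    feats[[paste0(v, "_z")]] <- (feats[[v]] - mean(feats[[v]])) / s
  }
  feats
}

feature_matrix <- function(features) {
  zc <- grep("_z$", names(features), value = TRUE)
  if (length(zc)) {
    m <- as.matrix(features[zc])
  } else {
    m <- as.matrix(features[vapply(features, is.numeric, logical(1))])
  }
  rownames(m) <- features$subject
  m
}

# Within-cluster over total sum of squares for a labelled matrix.
ss_ratio <- function(m, labels) {
  total <- sum(sweep(m, 2, colMeans(m))^2)
  if (total == 0) return(0)
  within <- sum(vapply(unique(labels), function(l) {
    sub <- m[labels == l, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
  within / total
}

#' Cluster learners by complete linkage on Manhattan distance
#'
#' Agglomerative complete-linkage clustering of the standardized features
#' (day-1 early error, day-2 early error, savings) under the L1 metric,
#' with the tree cut at `k` clusters. Cluster ids are renumbered in order
#' of first appearance, so the result is deterministic given the input
#' order; `stats::hclust` breaks merge ties by lowest pair index.
#'
#' @param features tibble from [compute_features()], or any tibble with a
#'   `subject` column plus `_z` feature columns (falls back to all numeric
#'   columns when no `_z` columns exist — useful for fixtures).
#' @param k number of clusters (2 <= k <= n subjects).
#' @return object of class `learner_clusters`: list with `labels` tibble
#'   (subject, cluster), `k`, `linkage`, `ss_ratio`, and the `hclust` tree.
#' @export
cluster_learners <- function(features, k = 3) {
  m <- feature_matrix(features)
  if (k < 2) abort("k must be >= 2.")
  if (k > nrow(m)) abort("k exceeds the number of subjects.")
  hc <- stats::hclust(stats::dist(m, method = "manhattan"),
                      method = "complete")
  raw <- stats::cutree(hc, k = k)
  labels <- match(raw, unique(raw))  # renumber by order of appearance
  structure(
    list(labels = tibble(subject = rownames(m), cluster = labels),
         k = k, linkage = "complete",
         ss_ratio = ss_ratio(m, labels),
         tree = hc, features = m),
    class = "learner_clusters")
}

#' @export
print.learner_clusters <- function(x, ...) {
  cat(sprintf("Learner clustering: %d subjects, k = %d (%s linkage, L1)\n",
              nrow(x$labels), x$k, x$linkage))
  cat(sprintf("Within/total SS ratio: %.5f\n", x$ss_ratio))
  print(table(x$labels$cluster))
  invisible(x)
}

#' Parametric-bootstrap validation of the cluster count
#'
#' Draws `n_boot` samples of n subjects from a single multivariate normal
#' with the observed feature mean and covariance (the null of no cluster
#' structure), reruns the complete-linkage clustering for each candidate
#' `k`, and records the within/total sum-of-squares ratio. A `k` whose
#' observed ratio falls below the null distribution's lower quantiles is
#' better separated than a homogeneous Gaussian would produce.
#'
#' @param features tibble as for [cluster_learners()].
#' @param k_range candidate cluster counts (default 2:8).
#' @param n_boot bootstrap draws (>= 100; 5000 for final analyses, 500 is a
#'   reasonable fast mode).
#' @param seed RNG seed.
#' @return tibble with one row per `k`: `k`, `ss_ratio_observed`,
#'   `null_q05`, `null_q50`, `null_q95`, and `p_value` (fraction of null
#'   draws with ratio <= observed). The full null draws are kept in the
#'   `null_draws` attribute (matrix, draws x k).
#' @export
bootstrap_cluster_validity <- function(features, k_range = 2:8,
                                       n_boot = 500, seed = 1L) {
  if (n_boot < 100) abort("n_boot must be >= 100.")
  m <- feature_matrix(features)
  n <- nrow(m)
  if (max(k_range) > n) abort("k_range exceeds the number of subjects.")
  mu <- colMeans(m)
  sigma <- stats::cov(m)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    warn("Feature covariance is singular; ridge-stabilizing.")
    sigma <- sigma + diag(1e-8 * max(ev), ncol(m))
  }
  ratios_for <- function(mm) {
    hc <- stats::hclust(stats::dist(mm, method = "manhattan"),
                        method = "complete")
    vapply(k_range, function(k) ss_ratio(mm, stats::cutree(hc, k = k)),
           numeric(1))
  }
  observed <- ratios_for(m)
  set.seed(as.integer(seed))
  null_draws <- vapply(seq_len(n_boot), function(b) {
    ratios_for(MASS::mvrnorm(n, mu, sigma))
  }, numeric(length(k_range)))
  null_draws <- t(matrix(null_draws, nrow = length(k_range)))
  colnames(null_draws) <- paste0("k", k_range)
  out <- tibble(
    k = k_range,
    ss_ratio_observed = observed,
    null_q05 = apply(null_draws, 2, stats::quantile, probs = 0.05),
    null_q50 = apply(null_draws, 2, stats::quantile, probs = 0.50),
    null_q95 = apply(null_draws, 2, stats::quantile, probs = 0.95),
    p_value = vapply(seq_along(k_range), function(i) {
      mean(null_draws[, i] <= observed[i])
    }, numeric(1)))
  attr(out, "null_draws") <- null_draws
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- as.integer(seed)
  out
}
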