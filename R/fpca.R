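#' Smooth a sampled curve with a GCV-penalized cubic smoothing spline
#'
#' Fits a cubic smoothing spline with knots at the observations and the
#' roughness penalty chosen by generalized cross-validation,
#' `GCV(lambda) = n RSS / (n - tr(S_lambda))^2` (the criterion minimized by
#' `stats::smooth.spline` with `cv = FALSE`). Constant input returns a
#' constant curve.
#'
#' @param values numeric samples (>= 10).
#' @param grid sample positions (default regular unit spacing).
#' @return object of class `functional_curve`: list with `grid`, `fitted`,
#'   `lambda`, `df` (effective degrees of freedom), and the underlying
#'   `smooth.spline` fit (`NULL` for the degenerate constant case).
#' @export
smooth_curve <- function(values, grid = seq_along(values)) {
  if (length(values) < 10L) abort("Need at least 10 samples.")
  if (length(grid) != length(values)) abort("grid/values length mismatch.")
  if (stats::sd(values) == 0) {
    return(structure(list(grid = grid, fitted = values, lambda = Inf,
                          df = 1, fit = NULL), class = "functional_curve"))
  }
  fit <- stats::smooth.spline(grid, values, cv = FALSE, all.knots = TRUE,
                              keep.data = FALSE)
  structure(list(grid = grid,
                 fitted = stats::predict(fit, grid)$y,
                 lambda = fit$lambda,
                 df = fit$df,
                 fit = fit),
            class = "functional_curve")
}

#' Evaluate a smoothed curve on new positions
#' @param curve a [smooth_curve()] result.
#' @param at positions to evaluate.
#' @return numeric vector.
#' @export
eval_curve <- function(curve, at = curve$grid) {
  if (is.null(curve$fit)) return(rep(curve$fitted[1], length(at)))
  stats::predict(curve$fit, at)$y
}

# Trapezoid quadrature weights on a grid.
quad_weights <- function(grid) {
  n <- length(grid)
  if (n == 1L) return(1)
  h <- diff(grid)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

#' Multivariate functional PCA of per-subject curve tuples
#'
#' Each subject contributes a tuple of curves sharing a common grid (here:
#' excursion for each network on each day, four elements). The multivariate
#' covariance operator eigenproblem is solved by quadrature-weighted PCA of
#' the concatenated discretized curves: with trapezoid weights `w`, the
#' eigenvectors of the weighted covariance give component functions
#' normalized to unit norm under the multivariate inner product
#' `sum_e integral phi_e^2`, and subject scores are the weighted inner
#' products of the centered data with each component. Elements are equally
#' weighted. The component sign is fixed so its largest-magnitude value is
#' positive.
#'
#' @param curves tibble with columns `subject`, `element` (curve label,
#'   e.g. network x day), `grid`, `value` — one row per sample; every
#'   subject must carry the same elements on the same grid.
#' @param n_components number of components K to extract (K <= subjects-1).
#' @return object of class `mfpca_result`: `mean` (tibble element/grid/
#'   value), `components` (tibble element/grid/component/value), `scores`
#'   (tibble subject x component), `var_explained` (per-component fraction
#'   of total variance), `elements`, `grid`.
#' @export
mfpca <- function(curves, n_components = 3) {
  needed <- c("subject", "element", "grid", "value")
  if (!all(needed %in% names(curves))) {
    abort(paste0("curves must have columns: ", paste(needed, collapse = ", ")))
  }
  curves <- dplyr::select(curves, dplyr::all_of(needed))
  elements <- unique(curves$element)
  grid <- sort(unique(curves$grid))
  wide <- curves %>%
    dplyr::arrange(match(.data$element, elements), .data$grid) %>%
    tidyr::pivot_wider(names_from = c("element", "grid"),
                       values_from = "value")
  subjects <- wide$subject
  x <- as.matrix(wide[, -1])
  n <- nrow(x)
  if (ncol(x) != length(elements) * length(grid) || anyNA(x)) {
    abort("Subjects differ in elements or grid (ragged curve set).")
  }
  if (n_components > n - 1L) abort("n_components must be <= subjects - 1.")
  mean_vec <- colMeans(x)
  xc <- sweep(x, 2, mean_vec)
  if (all(xc == 0)) abort("All subjects identical: variance undefined.")
  w <- rep(quad_weights(grid), times = length(elements))
  sw <- sqrt(w)
  xw <- sweep(xc, 2, sw, `*`)
  sv <- svd(xw / sqrt(n - 1))
  ev <- sv$d^2
  var_explained <- (ev / sum(ev))[seq_len(n_components)]
  comps <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 1, sw, `/`)
  # sign convention: largest-|loading| point positive
  signs <- apply(comps, 2, function(v) sign(v[which.max(abs(v))]))
  comps <- sweep(comps, 2, signs, `*`)
  scores <- xc %*% sweep(comps, 1, w, `*`)   # weighted inner products
  idx <- tidyr::expand_grid(element = elements, grid = grid)
  comp_tbl <- purrr::map_dfr(seq_len(n_components), function(k) {
    dplyr::mutate(idx, component = k, value = comps[, k])
  })
  score_tbl <- tibble(subject = subjects)
  for (k in seq_len(n_components)) {
    score_tbl[[paste0("score", k)]] <- scores[, k]
  }
  structure(
    list(mean = dplyr::mutate(idx, value = mean_vec),
         components = comp_tbl,
         scores = score_tbl,
         var_explained = var_explained,
         elements = elements, grid = grid, weights = w),
    class = "mfpca_result")
}

#' @export
print.mfpca_result <- function(x, ...) {
  cat(sprintf("mfPCA: %d subjects, %d elements, %d components\n",
              nrow(x$scores), length(x$elements),
              length(x$var_explained)))
  cat("Variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Kruskal-Wallis rank test of group differences
#'
#' Tie-corrected H statistic with a chi-square reference on g-1 degrees of
#' freedom (via `stats::kruskal.test`). When all values are identical the
#' tie correction degenerates (0/0); by convention H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return one-row tibble: `statistic` (H), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) abort("Need >= 2 nonempty groups.")
  if (length(values) != length(groups)) abort("Length mismatch.")
  if (stats::sd(values) == 0) {
    return(tibble(statistic = 0, df = nlevels(droplevels(groups)) - 1L,
                  p_value = 1, n = length(values)))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n = length(values))
}

#' Conover-Iman pairwise post hoc comparisons on ranks
#'
#' Follows a Kruskal-Wallis test: pairwise t-type statistics on the pooled
#' ranks, with the pooled rank variance scaled by `(N - 1 - H)/(N - g)` and
#' a t reference on `N - g` degrees of freedom; two-sided p values are
#' Benjamini-Hochberg adjusted across the pairs.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return tibble with one row per unordered pair: `group1`, `group2`,
#'   `statistic`, `p_value`, `p_adjusted`.
#' @export
conover_iman <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  if (g < 2L) abort("Need >= 2 groups.")
  n_total <- length(values)
  r <- rank(values)
  h <- kruskal_wallis(values, groups)$statistic
  mean_ranks <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  s2 <- (sum(r^2) - n_total * (n_total + 1)^2 / 4) / (n_total - 1)
  scale2 <- s2 * (n_total - 1 - h) / (n_total - g)
  pairs <- utils::combn(levels(groups), 2)
  stat <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(scale2 * (1 / n_g[[a]] + 1 / n_g[[b]]))
    if (se == 0) {
      stat[i] <- 0; p[i] <- 1
    } else {
      stat[i] <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
      p[i] <- 2 * stats::pt(-abs(stat[i]), df = n_total - g)
    }
  }
  tibble(group1 = pairs[1, ], group2 = pairs[2, ],
         statistic = stat, p_value = p,
         p_adjusted = stats::p.adjust(p, method = "BH"))
}
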