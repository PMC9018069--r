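#' Estimate a resting-state manifold by PCA
#'
#' Column-mean-centered PCA of the resting ROI time series; the manifold is
#' the affine subspace through the resting mean spanned by the smallest
#' number of principal components whose cumulative variance reaches
#' `var_threshold` (default 75%).
#'
#' @param rest volumes x ROIs numeric matrix (ROI names as column names).
#' @param var_threshold cumulative variance fraction to retain, in (0, 1).
#' @return object of class `rest_manifold`: list with `basis` (ROIs x d,
#'   orthonormal columns), `center` (resting mean), `d`, `var_explained`
#'   (cumulative fraction at `d`), `sdev` (all singular values / sqrt(n-1)),
#'   `roi_labels`.
#' @export
fit_manifold <- function(rest, var_threshold = 0.75) {
  rest <- as.matrix(rest)
  if (var_threshold <= 0 || var_threshold >= 1) {
    abort("var_threshold must be in (0, 1).")
  }
  vars <- apply(rest, 2, stats::var)
  if (any(vars == 0)) {
    bad <- colnames(rest)[vars == 0]
    if (is.null(bad)) bad <- which(vars == 0)
    abort(paste0("Constant (zero-variance) ROI(s): ",
                 paste(bad, collapse = ", ")))
  }
  pc <- stats::prcomp(rest, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  d <- which(cum >= var_threshold)[1]
  structure(
    list(basis = pc$rotation[, seq_len(d), drop = FALSE],
         center = pc$center,
         d = d,
         var_explained = cum[d],
         sdev = pc$sdev,
         var_threshold = var_threshold,
         roi_labels = colnames(rest)),
    class = "rest_manifold")
}

#' @export
print.rest_manifold <- function(x, ...) {
  cat(sprintf(
    "Resting-state manifold: %d ROIs, d = %d (%.1f%% variance, threshold %.0f%%)\n",
    length(x$center), x$d, 100 * x$var_explained, 100 * x$var_threshold))
  invisible(x)
}

#' Per-volume off-manifold excursion of task activity
#'
#' For each task volume, the activation vector is centered (by default at
#' the resting mean, so the manifold is treated as an affine subspace
#' through rest), split into its on-manifold projection `V V' x` and
#' off-manifold remainder, and the excursion is the ratio of the
#' off-manifold norm to the total norm: `r_t = ||(I - VV')x|| / ||x||`,
#' always in \[0, 1\]. Volumes with near-zero centered norm get `r = 0` and
#' are flagged.
#'
#' @param manifold a [fit_manifold()] result.
#' @param task volumes x ROIs matrix with the same ROI order as the rest
#'   scan used to fit the manifold.
#' @param centering `"rest-mean"` (default), `"task-mean"`, or `"none"`.
#' @param tol near-zero norm tolerance.
#' @return tibble with columns `volume`, `excursion` (raw `r_t`), and
#'   `near_zero` (logical flag).
#' @export
excursion_series <- function(manifold, task,
                             centering = c("rest-mean", "task-mean", "none"),
                             tol = 1e-12) {
  centering <- match.arg(centering)
  task <- as.matrix(task)
  if (anyNA(task)) abort("Task data contain NA.")
  if (ncol(task) != length(manifold$center)) {
    abort("ROI count mismatch between task data and manifold.")
  }
  if (!is.null(colnames(task)) && !is.null(manifold$roi_labels) &&
      !identical(colnames(task), manifold$roi_labels)) {
    abort("ROI labels/order differ between task data and manifold.")
  }
  ctr <- switch(centering,
    "rest-mean" = manifold$center,
    "task-mean" = colMeans(task),
    "none" = rep(0, ncol(task)))
  xc <- sweep(task, 2, ctr)
  v <- manifold$basis
  on_part <- xc %*% v %*% t(v)
  off <- xc - on_part
  total <- sqrt(rowSums(xc^2))
  off_norm <- sqrt(rowSums(off^2))
  near_zero <- total < tol
  r <- ifelse(near_zero, 0, pmin(off_norm / pmax(total, tol), 1))
  tibble(volume = seq_len(nrow(task)), excursion = r, near_zero = near_zero)
}

#' Standardize an excursion curve to its pre-rotation baseline
#'
#' Expresses the excursion in baseline-variability units:
#' `z_t = (r_t - mean(baseline)) / sd(baseline)` with the sample SD (n-1
#' denominator) over the baseline volumes.
#'
#' @param curve tibble from [excursion_series()] (columns `volume`,
#'   `excursion`).
#' @param baseline_window integer vector of baseline volume indices.
#' @return the input tibble with an added `standardized` column and
#'   attributes `baseline_mean` / `baseline_sd`.
#' @export
standardize_to_baseline <- function(curve, baseline_window) {
  if (length(baseline_window) == 0L) abort("Empty baseline window.")
  if (any(!baseline_window %in% curve$volume)) {
    abort("Baseline window exceeds the curve.")
  }
  base <- curve$excursion[match(baseline_window, curve$volume)]
  m <- mean(base); s <- stats::sd(base)
  if (is.na(s) || s == 0) abort("Baseline excursion SD is zero.")
  out <- dplyr::mutate(curve, standardized = (.data$excursion - m) / s)
  attr(out, "baseline_mean") <- m
  attr(out, "baseline_sd") <- s
  out
}

#' Early excursion: mean standardized excursion after rotation onset
#'
#' The neural analogue of behavioral early error: the mean of the
#' standardized excursion over the volumes spanning the first
#' `n_blocks x trials_per_block` trials after rotation onset (with the
#' default 8-trial blocks, 4 blocks and 2 volumes per trial, a 64-volume
#' window).
#'
#' @param curve standardized curve from [standardize_to_baseline()].
#' @param rotation_onset volume index of the first post-rotation volume.
#' @param trials_per_block,n_blocks window size in trials.
#' @param volumes_per_trial trial-to-volume conversion (trial spacing / TR;
#'   default 2).
#' @return scalar mean standardized excursion.
#' @export
early_excursion <- function(curve, rotation_onset, trials_per_block = 8,
                            n_blocks = 4, volumes_per_trial = 2) {
  if (!"standardized" %in% names(curve)) {
    abort("Curve must be standardized first (standardize_to_baseline()).")
  }
  n_vol <- trials_per_block * n_blocks * volumes_per_trial
  window <- seq(rotation_onset, length.out = n_vol)
  if (max(window) > max(curve$volume)) {
    abort("Early-excursion window exceeds the scan length.")
  }
  mean(curve$standardized[match(window, curve$volume)])
}
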