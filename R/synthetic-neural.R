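#' Configuration for the neural time-series simulator
#'
#' Emulates ROI-level BOLD with a planted low-dimensional structure: each
#' volume is `x_t = mu + W z_t + s_t * u + noise`, where `W` is an
#' orthonormal `n_rois x manifold_dim` loading matrix (the subject's
#' intrinsic manifold), `z_t` are independent Gaussian latent factors with
#' geometrically decaying variances, `u` is a unit vector orthogonal to the
#' columns of `W` (fixed per subject), and `s_t` is the off-manifold
#' schedule — zero during rest, and during task whatever perturbation
#' magnitude is planted at each volume (e.g. a step at rotation onset).
#'
#' @param n_rois number of ROIs.
#' @param manifold_dim latent dimension `k` (< `n_rois`).
#' @param n_volumes_rest,n_volumes_task scan lengths in volumes.
#' @param tr_seconds sampling interval (default 2 s).
#' @param off_manifold_schedule numeric vector of length `n_volumes_task`;
#'   per-volume magnitude of the perturbation along `u`.
#' @param factor_variance_decay geometric decay ratio of latent factor
#'   variances (first factor has variance 1).
#' @param noise_sd isotropic Gaussian noise SD.
#' @param seed RNG seed.
#' @return a `neural_sim_config` list.
#' @export
neural_sim_config <- function(n_rois = 20,
                              manifold_dim = 4,
                              n_volumes_rest = 180,
                              n_volumes_task = 880,
                              tr_seconds = 2,
                              off_manifold_schedule = rep(0, n_volumes_task),
                              factor_variance_decay = 0.6,
                              noise_sd = 0.1,
                              seed = 1L) {
  if (manifold_dim >= n_rois) abort("manifold_dim must be < n_rois.")
  if (length(off_manifold_schedule) != n_volumes_task) {
    abort("off_manifold_schedule length must equal n_volumes_task.")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  if (factor_variance_decay <= 0 || factor_variance_decay > 1) {
    abort("factor_variance_decay must be in (0, 1].")
  }
  structure(
    list(n_rois = n_rois, manifold_dim = manifold_dim,
         n_volumes_rest = n_volumes_rest, n_volumes_task = n_volumes_task,
         tr_seconds = tr_seconds,
         off_manifold_schedule = off_manifold_schedule,
         factor_variance_decay = factor_variance_decay,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "neural_sim_config")
}

# Orthonormal basis plus one orthogonal unit vector, from a Gaussian draw.
planted_basis <- function(p, k) {
  q <- qr.Q(qr(matrix(stats::rnorm(p * (k + 1)), p, k + 1)))
  list(W = q[, seq_len(k), drop = FALSE], u = q[, k + 1])
}

#' Simulate rest and task ROI time series for one subject
#'
#' Draws the planted orthonormal basis `W`, its orthogonal unit
#' perturbation direction `u`, latent factors with geometrically decaying
#' variances, and isotropic noise, and returns rest and task volumes-by-ROI
#' matrices along with the ground truth needed by recovery tests.
#'
#' @param config a [neural_sim_config()].
#' @param planted optional list with `W`, `u`, `mu` to reuse a previously
#'   drawn subject manifold (e.g. for a second session of the same
#'   subject); drawn fresh when `NULL`.
#' @return list with `rest` and `task` (volumes x ROIs matrices with ROI
#'   column names), `ground_truth` (list: `W`, `u`, `mu`, `schedule`,
#'   `factor_variances`), and the `config`.
#' @export
simulate_neural <- function(config = neural_sim_config(), planted = NULL) {
  if (!inherits(config, "neural_sim_config")) {
    abort("`config` must come from neural_sim_config().")
  }
  set.seed(config$seed)
  p <- config$n_rois; k <- config$manifold_dim
  if (is.null(planted)) {
    basis <- planted_basis(p, k)
    mu <- stats::rnorm(p, 0, 1)
  } else {
    basis <- list(W = planted$W, u = planted$u)
    mu <- planted$mu
  }
  fvar <- config$factor_variance_decay^(seq_len(k) - 1)

  draw <- function(n, schedule) {
    z <- matrix(stats::rnorm(n * k), n, k) %*% diag(sqrt(fvar), k)
    x <- matrix(mu, n, p, byrow = TRUE) + z %*% t(basis$W) +
      outer(schedule, basis$u)
    if (config$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    }
    colnames(x) <- sprintf("ROI%03d", seq_len(p))
    x
  }

  rest <- draw(config$n_volumes_rest, rep(0, config$n_volumes_rest))
  task <- draw(config$n_volumes_task, config$off_manifold_schedule)
  list(rest = rest, task = task,
       ground_truth = list(W = basis$W, u = basis$u, mu = mu,
                           schedule = config$off_manifold_schedule,
                           factor_variances = fvar),
       config = config)
}

#' Simulate covariance matrices with planted rank-one tangent structure
#'
#' For each subject `i` a base SPD matrix `R_i` is drawn by jittering a
#' common base on the manifold, and each observation's covariance is
#' `S_ij = Exp_{R_i}(sum_k lambda_ijk h_k h_k')`, i.e. the exp-map at `R_i`
#' of a planted sum of rank-one symmetric tangent components with known
#' scores. This is the exact generative model assumed by the joint
#' embedding, so recovery can be tested against the returned ground truth.
#'
#' @param n_subjects number of subjects.
#' @param n_epochs observations per subject.
#' @param components p x K matrix whose columns are the planted unit loading
#'   vectors `h_k`.
#' @param scores (n_subjects * n_epochs) x K matrix of planted `lambda`
#'   scores, observations ordered subject-major; if `NULL`, drawn Gaussian
#'   with SD `score_sd`.
#' @param score_sd per-component score SD used when `scores` is `NULL`.
#' @param base common base SPD matrix (default identity).
#' @param jitter scale of the per-subject symmetric log-space perturbation
#'   of `base`; 0 gives all subjects the same base.
#' @param seed RNG seed.
#' @return list with `covariances` (list of SPD matrices), `design` (tibble
#'   subject/epoch per observation), `bases` (per-subject `R_i`), and
#'   `ground_truth` (`components`, `scores`).
#' @export
simulate_covariance_set <- function(n_subjects, n_epochs, components,
                                    scores = NULL,
                                    score_sd = NULL,
                                    base = NULL, jitter = 0, seed = 1L) {
  components <- as.matrix(components)
  p <- nrow(components); K <- ncol(components)
  if (is.null(base)) base <- diag(p)
  base <- check_spd(base, "base")
  if (nrow(base) != p) abort("base dimension must match components.")
  set.seed(as.integer(seed))
  components <- apply(components, 2, function(h) h / sqrt(sum(h^2)))
  components <- matrix(components, p, K)
  n_obs <- n_subjects * n_epochs
  if (is.null(scores)) {
    if (is.null(score_sd)) score_sd <- 2 / seq_len(K)
    scores <- sapply(seq_len(K),
                     function(k) stats::rnorm(n_obs, 0, score_sd[[k]]))
    scores <- matrix(scores, n_obs, K)
  } else {
    scores <- as.matrix(scores)
    if (nrow(scores) != n_obs || ncol(scores) != K) {
      abort("scores must be (n_subjects * n_epochs) x K.")
    }
  }
  bases <- lapply(seq_len(n_subjects), function(i) {
    if (jitter == 0) return(base)
    z <- matrix(stats::rnorm(p * p, 0, jitter), p, p)
    spd_exp(base, (z + t(z)) / 2)
  })
  design <- tidyr::expand_grid(subject = seq_len(n_subjects),
                               epoch = seq_len(n_epochs))
  covs <- purrr::map(seq_len(n_obs), function(i) {
    tangent <- Reduce(`+`, lapply(seq_len(K), function(k) {
      scores[i, k] * tcrossprod(components[, k])
    }))
    spd_exp(bases[[design$subject[i]]], tangent)
  })
  list(covariances = covs, design = design, bases = bases,
       ground_truth = list(components = components, scores = scores))
}
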