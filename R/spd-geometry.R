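#' Affine-invariant geometry on symmetric positive-definite matrices
#'
#' Covariance matrices live on the SPD manifold, and differences between a
#' task covariance and a resting reference are naturally expressed as tangent
#' vectors at the reference point under the affine-invariant metric. These
#' functions implement the matrix log/exp maps, parallel transport, geodesic
#' distance, the Frechet (geometric) mean, and the full subject-centering
#' procedure that re-expresses each subject's task covariances relative to
#' the group grand-mean rest covariance.
#'
#' All matrix functions go through the symmetric eigendecomposition; inputs
#' are symmetrized first and eigenvalues below `1e-12` raise an error rather
#' than being clipped silently.
#'
#' @name spd-geometry
NULL

EIG_FLOOR <- 1e-12

# Symmetrize, checking the asymmetry is numerical noise only.
sym_part <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("Expected a square matrix.")
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    abort("Matrix is not symmetric.")
  }
  (m + t(m)) / 2
}

# Apply f to the eigenvalues of a symmetric matrix.
spd_fun <- function(m, f, require_spd = TRUE) {
  m <- sym_part(m)
  e <- eigen(m, symmetric = TRUE)
  if (require_spd && min(e$values) <= EIG_FLOOR) {
    abort(sprintf("Matrix is not positive definite (min eigenvalue %.3e).",
                  min(e$values)))
  }
  v <- e$vectors
  out <- v %*% (f(e$values) * t(v))
  (out + t(out)) / 2
}

spd_sqrt    <- function(m) spd_fun(m, sqrt)
spd_invsqrt <- function(m) spd_fun(m, function(x) 1 / sqrt(x))
spd_logm    <- function(m) spd_fun(m, log)
spd_expm    <- function(m) spd_fun(m, exp, require_spd = FALSE)

check_spd <- function(m, arg = "matrix") {
  m <- sym_part(m)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= EIG_FLOOR) {
    abort(sprintf("%s is not positive definite (min eigenvalue %.3e).",
                  arg, min(ev)))
  }
  m
}

#' Log map: project an SPD matrix onto the tangent space at a reference
#'
#' `T = R^{1/2} logm(R^{-1/2} S R^{-1/2}) R^{1/2}`. The result is a symmetric
#' matrix encoding the difference of `S` from `ref` under the
#' affine-invariant metric; `spd_exp(ref, T)` inverts it.
#'
#' @param ref reference SPD matrix.
#' @param s SPD matrix to project.
#' @return symmetric matrix of the same dimension.
#' @export
spd_log <- function(ref, s) {
  ref <- check_spd(ref, "ref"); s <- check_spd(s, "s")
  if (!all(dim(ref) == dim(s))) abort("Dimension mismatch between ref and s.")
  rh <- spd_sqrt(ref); rih <- spd_invsqrt(ref)
  out <- rh %*% spd_logm(rih %*% s %*% rih) %*% rh
  (out + t(out)) / 2
}

#' Exp map: project a tangent vector back onto the SPD manifold
#'
#' `S = R^{1/2} expm(R^{-1/2} T R^{-1/2}) R^{1/2}`; inverse of [spd_log()].
#'
#' @param ref reference SPD matrix.
#' @param tangent symmetric matrix anchored at `ref`.
#' @return SPD matrix.
#' @export
spd_exp <- function(ref, tangent) {
  ref <- check_spd(ref, "ref"); tangent <- sym_part(tangent)
  if (!all(dim(ref) == dim(tangent))) abort("Dimension mismatch.")
  rh <- spd_sqrt(ref); rih <- spd_invsqrt(ref)
  out <- rh %*% spd_expm(rih %*% tangent %*% rih) %*% rh
  (out + t(out)) / 2
}

#' Parallel transport of a tangent vector between reference points
#'
#' `T^c = G T G'` with `G = to^{1/2} from^{-1/2}`: the tangent vector is
#' carried from the tangent space at `from_ref` to the one at `to_ref`
#' preserving its affine-invariant norm.
#'
#' @param from_ref,to_ref SPD reference matrices.
#' @param tangent symmetric matrix anchored at `from_ref`.
#' @return symmetric matrix anchored at `to_ref`.
#' @export
spd_transport <- function(from_ref, to_ref, tangent) {
  from_ref <- check_spd(from_ref, "from_ref")
  to_ref <- check_spd(to_ref, "to_ref")
  tangent <- sym_part(tangent)
  g <- spd_sqrt(to_ref) %*% spd_invsqrt(from_ref)
  out <- g %*% tangent %*% t(g)
  (out + t(out)) / 2
}

#' Affine-invariant geodesic distance between SPD matrices
#'
#' `d(S1, S2) = ||logm(S1^{-1/2} S2 S1^{-1/2})||_F`; symmetric in its
#' arguments and invariant under congruence `S -> A S A'`.
#'
#' @param s1,s2 SPD matrices of equal dimension.
#' @return non-negative scalar.
#' @export
spd_distance <- function(s1, s2) {
  s1 <- check_spd(s1, "s1"); s2 <- check_spd(s2, "s2")
  if (!all(dim(s1) == dim(s2))) abort("Dimension mismatch.")
  ih <- spd_invsqrt(s1)
  fnorm(spd_logm(ih %*% s2 %*% ih))
}

#' Frechet mean of a set of SPD matrices
#'
#' The point minimizing summed squared geodesic distances, computed by the
#' standard fixed-point iteration
#' `M <- M^{1/2} expm(mean_i logm(M^{-1/2} R_i M^{-1/2})) M^{1/2}`,
#' initialized at the arithmetic mean, until the Frobenius norm of the mean
#' log falls below `tol`. For 1x1 inputs this is the geometric mean.
#'
#' @param mats list of SPD matrices of common dimension.
#' @param tol convergence tolerance on the mean-log norm.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return SPD matrix with attributes `iterations` and `converged`.
#' @export
spd_frechet_mean <- function(mats, tol = 1e-8, max_iter = 200) {
  if (!is.list(mats) || length(mats) == 0L) {
    abort("spd_frechet_mean() needs a nonempty list of SPD matrices.")
  }
  mats <- lapply(mats, check_spd, arg = "element")
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1L) abort("Matrices differ in dimension.")
  m <- Reduce(`+`, mats) / length(mats)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mh <- spd_sqrt(m); mih <- spd_invsqrt(m)
    logs <- lapply(mats, function(s) spd_logm(mih %*% s %*% mih))
    mean_log <- Reduce(`+`, logs) / length(logs)
    if (fnorm(mean_log) < tol) { converged <- TRUE; break }
    m <- mh %*% spd_expm(mean_log) %*% mh
    m <- (m + t(m)) / 2
  }
  if (!converged) {
    abort(sprintf("Frechet mean did not converge in %d iterations.", max_iter))
  }
  attr(m, "iterations") <- it
  attr(m, "converged") <- TRUE
  m
}

#' Center a subject's task covariances at the grand-mean rest covariance
#'
#' Removes static subject differences in covariance: each task covariance
#' `S_ij` is expressed as a tangent vector at the subject's own rest
#' covariance (`spd_log`), transported to the grand mean (`spd_transport`
#' with `G = grand^{1/2} rest^{-1/2}`), and mapped back to the manifold at
#' the grand mean (`spd_exp`). A subject's own rest covariance centers to
#' the grand mean exactly.
#'
#' @param rest the subject's rest SPD covariance.
#' @param tasks list of task-epoch SPD covariances for the same subject.
#' @param grand grand-mean rest covariance (see [spd_frechet_mean()]).
#' @return list with `tangents` (centered tangent vectors at `grand`) and
#'   `centered` (centered SPD matrices), both lists parallel to `tasks`.
#' @export
spd_center <- function(rest, tasks, grand) {
  rest <- check_spd(rest, "rest"); grand <- check_spd(grand, "grand")
  if (!is.list(tasks)) tasks <- list(tasks)
  tangents <- vector("list", length(tasks))
  centered <- vector("list", length(tasks))
  for (j in seq_along(tasks)) {
    tj <- spd_log(rest, tasks[[j]])
    tc <- spd_transport(rest, grand, tj)
    tangents[[j]] <- tc
    centered[[j]] <- spd_exp(grand, tc)
  }
  list(tangents = tangents, centered = centered)
}

#' Well-conditioned shrinkage estimator of a covariance matrix
#'
#' Linear shrinkage of the sample covariance (1/n denominator) toward the
#' scaled identity `mu I`, with the data-driven intensity of Ledoit & Wolf's
#' well-conditioned estimator. The result is positive definite even when
#' there are fewer observations than variables, which is what makes equal
#' epoch lengths matter: the shrinkage intensity depends on the sample size.
#'
#' @param x numeric matrix, observations in rows, variables in columns; or a
#'   data frame of numeric columns.
#' @return SPD covariance matrix with attribute `shrinkage` (intensity in
#'   \[0, 1\]).
#' @export
shrinkage_covariance <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("shrinkage_covariance() needs a numeric matrix.")
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) abort("Need at least 2 observations.")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    abort(paste0("Constant column(s): ", paste(bad, collapse = ", ")))
  }
  xc <- sweep(x, 2, colMeans(x))
  s <- crossprod(xc) / n
  mu <- sum(diag(s)) / p
  d2 <- sum((s - mu * diag(p))^2) / p
  # average distance of per-observation outer products from s
  b2_sum <- 0
  for (t in seq_len(n)) {
    dev <- tcrossprod(xc[t, ]) - s
    b2_sum <- b2_sum + sum(dev^2) / p
  }
  b2 <- min(b2_sum / n^2, d2)
  rho <- if (d2 > 0) b2 / d2 else 1
  est <- rho * mu * diag(p) + (1 - rho) * s
  est <- (est + t(est)) / 2
  dimnames(est) <- list(colnames(x), colnames(x))
  attr(est, "shrinkage") <- rho
  est
}
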