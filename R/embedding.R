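#' Joint rank-one embedding of symmetric matrices
#'
#' Approximates a set of symmetric matrices (here: centered covariance
#' tangent vectors, read as weighted signed graphs over ROIs) by a shared
#' set of rank-one connectivity patterns with per-observation scores:
#' `T_i ~ sum_k lambda_ik h_k h_k'` with unit loading vectors `h_k`. Fit by
#' greedy deflation: for each component, alternate the exact coordinate
#' updates `lambda_ik = h' R_i h` (for unit `h`) and `h` = leading
#' eigenvector of `sum_i lambda_ik R_i`, each of which cannot increase the
#' residual objective `sum_i ||R_i - lambda_ik h h'||_F^2`; then deflate
#' and fit the next component on the residuals. Scores are unconstrained in
#' sign (tangent vectors encode both increases and decreases in
#' connectivity relative to rest).
#'
#' Components are ordered by decreasing score variance and each `h_k` has
#' its largest-magnitude loading positive (`h` and `-h` give the same
#' pattern).
#'
#' @param tangents list of symmetric p x p matrices.
#' @param n_components number of patterns K (1 <= K <= p).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter per-component iteration cap.
#' @return object of class `joint_embedding`: `components` (p x K matrix,
#'   unit columns), `scores` (observations x K), `residual_norms`,
#'   `fit_history` (objective per iteration, non-increasing), `degenerate`
#'   flag (TRUE when all inputs are zero), `roi_labels`.
#' @export
joint_embed <- function(tangents, n_components = 2, tol = 1e-8,
                        max_iter = 500) {
  if (!is.list(tangents) || !length(tangents)) {
    abort("tangents must be a nonempty list of symmetric matrices.")
  }
  tangents <- lapply(tangents, sym_part)
  p <- nrow(tangents[[1]])
  if (any(vapply(tangents, nrow, integer(1)) != p)) {
    abort("Matrices differ in dimension.")
  }
  if (n_components < 1 || n_components > p) abort("Need 1 <= K <= p.")
  n <- length(tangents)
  labels <- rownames(tangents[[1]])
  res <- tangents
  comps <- matrix(0, p, n_components)
  scores <- matrix(0, n, n_components)
  history <- tibble(component = integer(0), iteration = integer(0),
                    objective = numeric(0))
  degenerate <- all(vapply(res, function(m) all(m == 0), logical(1)))
  obj <- function(rr, h, lam) {
    sum(vapply(seq_len(n),
               function(i) sum((rr[[i]] - lam[i] * tcrossprod(h))^2),
               numeric(1)))
  }
  for (k in seq_len(n_components)) {
    norms <- vapply(res, fnorm, numeric(1))
    if (max(norms) == 0) {
      # residuals exhausted; remaining components get unit basis vectors
      h <- numeric(p); h[min(k, p)] <- 1
      comps[, k] <- h
      next
    }
    mean_res <- Reduce(`+`, res) / n
    init_from <- if (fnorm(mean_res) > 0) mean_res else res[[which.max(norms)]]
    e <- eigen(init_from, symmetric = TRUE)
    h <- e$vectors[, which.max(abs(e$values))]
    lam <- vapply(res, function(m) drop(crossprod(h, m %*% h)), numeric(1))
    last <- obj(res, h, lam)
    history <- dplyr::bind_rows(history,
      tibble(component = k, iteration = 0L, objective = last))
    for (it in seq_len(max_iter)) {
      m_w <- Reduce(`+`, purrr::map2(res, lam, `*`)) / n
      e <- eigen(m_w, symmetric = TRUE)
      h_new <- e$vectors[, which.max(e$values)]
      lam_new <- vapply(res, function(m) drop(crossprod(h_new, m %*% h_new)),
                        numeric(1))
      cur <- obj(res, h_new, lam_new)
      if (cur > last) break  # numerically flat; keep previous iterate
      h <- h_new; lam <- lam_new
      history <- dplyr::bind_rows(history,
        tibble(component = k, iteration = it, objective = cur))
      if (last - cur <= tol * max(last, 1e-300)) { last <- cur; break }
      last <- cur
    }
    s <- sign(h[which.max(abs(h))]); if (s == 0) s <- 1
    comps[, k] <- s * h
    scores[, k] <- lam
    res <- purrr::map2(res, lam, function(m, l) m - l * tcrossprod(h))
  }
  ord <- order(apply(scores, 2, stats::var), decreasing = TRUE)
  comps <- comps[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  rownames(comps) <- labels
  residual_norms <- vapply(res, fnorm, numeric(1))
  structure(
    list(components = comps, scores = scores,
         residual_norms = residual_norms,
         fit_history = history,
         degenerate = degenerate,
         roi_labels = labels,
         n_components = n_components),
    class = "joint_embedding")
}

#' @export
print.joint_embedding <- function(x, ...) {
  cat(sprintf("Joint embedding: %d observations, %d ROIs, K = %d\n",
              nrow(x$scores), nrow(x$components), x$n_components))
  cat(sprintf("Mean residual Frobenius norm: %.4g\n",
              mean(x$residual_norms)))
  if (x$degenerate) cat("(degenerate: all input matrices were zero)\n")
  invisible(x)
}

#' Reconstruct an observation from its embedding
#'
#' `sum_k lambda_ik h_k h_k'` for observation `i`.
#'
#' @param embedding a [joint_embed()] result.
#' @param i observation index.
#' @return symmetric p x p matrix.
#' @export
reconstruct <- function(embedding, i) {
  if (i < 1 || i > nrow(embedding$scores)) abort("Index out of range.")
  out <- Reduce(`+`, lapply(seq_len(ncol(embedding$components)), function(k) {
    embedding$scores[i, k] * tcrossprod(embedding$components[, k])
  }))
  dimnames(out) <- list(embedding$roi_labels, embedding$roi_labels)
  out
}

#' Mixed-design ANOVA on embedding (or component) scores
#'
#' Repeated-measures F tests with subject as the blocking factor: epoch and
#' day are within-subject factors, group (learner phenotype) is between
#' subjects. Fit with `stats::aov` using error strata
#' `Error(subject/(day + epoch))`; main-effect F and p for group, day and
#' epoch are reported with Benjamini-Hochberg adjustment across the three
#' effects. The design must be balanced (complete crossing of day x epoch
#' within every subject); zero-variance strata return F = 0, p = 1.
#'
#' @param scores tibble with columns `subject`, `group`, `day`, `epoch`,
#'   `score` (one row per subject x day x epoch).
#' @return tibble with one row per effect: `effect`, `df1`, `df2`,
#'   `statistic`, `p_value`, `p_adjusted`.
#' @export
score_anova <- function(scores) {
  needed <- c("subject", "group", "day", "epoch", "score")
  if (!all(needed %in% names(scores))) {
    abort(paste0("scores must have columns: ", paste(needed, collapse = ", ")))
  }
  counts <- scores %>%
    dplyr::count(.data$subject, .data$day, .data$epoch)
  if (any(counts$n != 1L) ||
      length(unique(table(counts$subject))) != 1L ||
      nrow(counts) != length(unique(scores$subject)) *
        length(unique(scores$day)) * length(unique(scores$epoch))) {
    abort("Unbalanced design: need one score per subject x day x epoch.")
  }
  df <- dplyr::mutate(scores,
    subject = factor(.data$subject), group = factor(.data$group),
    day = factor(.data$day), epoch = factor(.data$epoch))
  single_day <- nlevels(df$day) < 2L
  form <- if (single_day) {
    score ~ group + epoch + Error(subject / epoch)
  } else {
    score ~ group + day + epoch + Error(subject / (day + epoch))
  }
  fit <- stats::aov(form, data = df)
  smry <- summary(fit)
  rows <- purrr::map_dfr(smry, function(stratum) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    keep <- terms %in% c("group", "day", "epoch")
    if (!any(keep)) return(tibble())
    resid_row <- which(terms == "Residuals")
    df2 <- if (length(resid_row)) tab$Df[resid_row] else NA_real_
    ms_resid <- if (length(resid_row)) tab$`Mean Sq`[resid_row] else NA_real_
    purrr::map_dfr(which(keep), function(i) {
      f <- tab$`F value`[i]; p <- tab$`Pr(>F)`[i]
      if (is.na(f) || is.nan(f)) {
        if (!is.na(tab$`Mean Sq`[i]) && tab$`Mean Sq`[i] < 1e-20) {
          f <- 0; p <- 1
        }
      }
      if (!is.na(ms_resid) && ms_resid < 1e-20 && tab$`Mean Sq`[i] < 1e-20) {
        f <- 0; p <- 1
      }
      tibble(effect = terms[i], df1 = tab$Df[i], df2 = df2,
             statistic = f, p_value = p)
    })
  })
  dplyr::mutate(rows, p_adjusted = stats::p.adjust(.data$p_value, "BH"))
}
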