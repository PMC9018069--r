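#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a learner clustering
#' @param x a `learner_clusters` object.
#' @param ... unused.
#' @return tibble with one row per subject: `subject`, `cluster`.
#' @method tidy learner_clusters
#' @export
tidy.learner_clusters <- function(x, ...) x$labels

#' @rdname tidy.learner_clusters
#' @return for `glance`: one-row tibble with `k`, `n`, `linkage`,
#'   `ss_ratio`.
#' @method glance learner_clusters
#' @export
glance.learner_clusters <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$labels), linkage = x$linkage,
         ss_ratio = x$ss_ratio)
}

#' Tidy an mfPCA fit
#' @param x an `mfpca_result`.
#' @param what `"scores"` (default) or `"components"`.
#' @param ... unused.
#' @return tibble of subject scores (long) or component curves.
#' @method tidy mfpca_result
#' @export
tidy.mfpca_result <- function(x, what = c("scores", "components"), ...) {
  what <- match.arg(what)
  if (what == "components") return(x$components)
  tidyr::pivot_longer(x$scores, -"subject", names_to = "component",
                      names_prefix = "score", values_to = "score") %>%
    dplyr::mutate(component = as.integer(.data$component))
}

#' @rdname tidy.mfpca_result
#' @method glance mfpca_result
#' @export
glance.mfpca_result <- function(x, ...) {
  tibble(n_subjects = nrow(x$scores),
         n_elements = length(x$elements),
         n_components = length(x$var_explained),
         var_explained_total = sum(x$var_explained))
}

#' Tidy a joint embedding
#' @param x a `joint_embedding`.
#' @param what `"scores"` (default) or `"components"` (loading vectors).
#' @param ... unused.
#' @return long tibble of observation scores, or ROI loadings.
#' @method tidy joint_embedding
#' @export
tidy.joint_embedding <- function(x, what = c("scores", "components"), ...) {
  what <- match.arg(what)
  if (what == "components") {
    labels <- x$roi_labels %||% sprintf("ROI%03d", seq_len(nrow(x$components)))
    return(purrr::map_dfr(seq_len(ncol(x$components)), function(k) {
      tibble(roi = labels, component = k, loading = x$components[, k])
    }))
  }
  purrr::map_dfr(seq_len(ncol(x$scores)), function(k) {
    tibble(observation = seq_len(nrow(x$scores)), component = k,
           score = x$scores[, k])
  })
}

#' @rdname tidy.joint_embedding
#' @method glance joint_embedding
#' @export
glance.joint_embedding <- function(x, ...) {
  tibble(n_observations = nrow(x$scores),
         n_rois = nrow(x$components),
         n_components = ncol(x$components),
         mean_residual_norm = mean(x$residual_norms),
         degenerate = x$degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
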