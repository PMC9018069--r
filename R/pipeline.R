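#' Configuration for the full synthetic-analysis pipeline
#'
#' Bundles the study conditions for an end-to-end run: a two-day
#' visuomotor-rotation experiment with three learner phenotypes, ROI time
#' series for a cognitive (62 ROIs) and a sensorimotor (51 ROIs) network,
#' 2-s TR with 4-s trial spacing (2 volumes per trial), and
#' equal-length 177-volume covariance epochs (rest, end of baseline, early
#' rotation, late rotation) — the equal length matters because the
#' covariance shrinkage intensity depends on the sample size.
#'
#' @param n_subjects_per_group subjects per phenotype (default 10).
#' @param behavior a [behavior_sim_config()]; its seed is overridden by
#'   `seed`.
#' @param network_sizes named integer vector of ROIs per network.
#' @param manifold_dim planted latent dimension per network.
#' @param noise_sd isotropic BOLD noise SD.
#' @param excursion_height named list per phenotype of length-2 numeric
#'   vectors: planted off-manifold step height on day 1 and day 2 (in
#'   latent-signal units). FF and SF learners engage off-manifold activity
#'   more strongly than SS learners.
#' @param var_threshold PCA variance threshold for the manifold (0.75).
#' @param k_clusters behavioral cluster count (3).
#' @param n_mfpca mfPCA components (3).
#' @param n_embed embedding components (2).
#' @param epoch_length covariance epoch length in volumes (177).
#' @param volumes_per_trial trial-to-volume conversion (2 = 4 s / 2 s TR).
#' @param n_boot bootstrap draws for cluster validation; 0 skips it.
#' @param seed master seed; all stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects_per_group = 10,
                            behavior = behavior_sim_config(
                              n_subjects_per_group = n_subjects_per_group),
                            network_sizes = c(cognitive = 62,
                                              sensorimotor = 51),
                            manifold_dim = 8,
                            noise_sd = 0.1,
                            excursion_height = list(FF = c(1.2, 0.9),
                                                    SF = c(1.2, 0.9),
                                                    SS = c(0.4, 0.3)),
                            var_threshold = 0.75,
                            k_clusters = 3,
                            n_mfpca = 3,
                            n_embed = 2,
                            epoch_length = 177,
                            volumes_per_trial = 2,
                            n_boot = 0,
                            seed = 1L) {
  behavior$n_subjects_per_group <- n_subjects_per_group
  behavior$seed <- as.integer(seed)
  n_task <- volumes_per_trial *
    (behavior$n_baseline_trials + behavior$n_learning_trials)
  n_baseline_vol <- volumes_per_trial * behavior$n_baseline_trials
  if (epoch_length > n_baseline_vol) {
    abort("epoch_length exceeds the baseline period.")
  }
  if (is.null(names(network_sizes)) || any(!nzchar(names(network_sizes)))) {
    abort("network_sizes must be named.")
  }
  structure(
    list(n_subjects_per_group = n_subjects_per_group,
         behavior = behavior,
         network_sizes = network_sizes,
         manifold_dim = manifold_dim,
         noise_sd = noise_sd,
         excursion_height = excursion_height,
         var_threshold = var_threshold,
         k_clusters = k_clusters,
         n_mfpca = n_mfpca,
         n_embed = n_embed,
         epoch_length = epoch_length,
         volumes_per_trial = volumes_per_trial,
         n_task_volumes = n_task,
         n_baseline_volumes = n_baseline_vol,
         rotation_onset = n_baseline_vol + 1L,
         n_rest_volumes = 180L,
         n_boot = n_boot,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

# Covariance epoch windows: rest handled separately; task epochs are the
# end of baseline and the beginning and end of the rotation period.
epoch_windows <- function(config) {
  len <- config$epoch_length
  onset <- config$rotation_onset
  n <- config$n_task_volumes
  list(
    baseline = seq(onset - len, onset - 1L),
    early = seq(onset, onset + len - 1L),
    late = seq(n - len + 1L, n))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates behavior and neural data for three learner phenotypes and runs
#' every analysis stage: trial preprocessing, learning features and
#' complete-linkage clustering (with optional parametric-bootstrap
#' validation), per-network resting-manifold estimation and task excursion,
#' mfPCA of the four standardized excursion curves per subject with
#' Kruskal-Wallis / Conover-Iman group tests, shrinkage covariance
#' estimation over equal-length epochs, Riemannian centering at the
#' grand-mean rest covariance, joint rank-one embedding of the centered
#' tangent vectors, and a mixed-design ANOVA on the embedding scores.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, per-stage tables are
#'   written as tab-delimited text plus a JSON sidecar recording the seed
#'   and configuration.
#' @param verbose print stage progress.
#' @return object of class `excursion_pipeline`; see the elements
#'   `features`, `clusters`, `cluster_ari`, `bootstrap`, `early_excursion`,
#'   `mfpca`, `mfpca_tests`, `embedding`, `embedding_anova`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  ## -- behavior ------------------------------------------------------------
  say("stage behavior: simulate + preprocess + cluster")
  trials <- stage("simulate_behavior", simulate_behavior(config$behavior))
  clean <- stage("preprocess_trials", suppressWarnings(
    preprocess_trials(trials)))
  features <- stage("compute_features", compute_features(clean))
  clusters <- stage("cluster_learners",
                    cluster_learners(features, k = config$k_clusters))
  truth <- features$group
  ari <- adjusted_rand_index(clusters$labels$cluster, truth)
  boot <- NULL
  if (config$n_boot > 0) {
    say("stage bootstrap: %d draws", config$n_boot)
    boot <- stage("bootstrap_cluster_validity",
                  bootstrap_cluster_validity(features, n_boot = config$n_boot,
                                             seed = child_seed(config$seed, 7)))
  }

  ## -- neural simulation + excursion ---------------------------------------
  say("stage excursion: %d subjects x %d networks x 2 days",
      nrow(features), length(config$network_sizes))
  subjects <- features$subject
  groups <- stats::setNames(features$group, subjects)
  networks <- names(config$network_sizes)
  wins <- epoch_windows(config)

  excursion_curves <- list()
  early_exc <- list()
  cov_sets <- stats::setNames(
    replicate(length(networks), list(rest = list(), task = list()),
              simplify = FALSE), networks)
  idx <- 0L
  for (s in seq_along(subjects)) {
    sub <- subjects[s]; grp <- groups[[sub]]
    for (net in networks) {
      planted <- NULL
      rest_d1 <- NULL
      for (day in 1:2) {
        idx <- idx + 1L
        h <- config$excursion_height[[grp]][day]
        schedule <- c(rep(0, config$n_baseline_volumes),
                      rep(h, config$n_task_volumes -
                            config$n_baseline_volumes))
        ncfg <- neural_sim_config(
          n_rois = config$network_sizes[[net]],
          manifold_dim = config$manifold_dim,
          n_volumes_rest = config$n_rest_volumes,
          n_volumes_task = config$n_task_volumes,
          off_manifold_schedule = schedule,
          noise_sd = config$noise_sd,
          seed = child_seed(config$seed, 100 + idx))
        sim <- stage("simulate_neural", simulate_neural(ncfg, planted))
        planted <- sim$ground_truth[c("W", "u", "mu")]
        if (day == 1) rest_d1 <- sim$rest
        if (day == 1) {
          manifold <- stage("fit_manifold",
                            fit_manifold(rest_d1, config$var_threshold))
        }
        curve <- stage("excursion_series",
                       excursion_series(manifold, sim$task)) %>%
          standardize_to_baseline(seq_len(config$n_baseline_volumes))
        excursion_curves[[length(excursion_curves) + 1L]] <-
          dplyr::mutate(curve, subject = sub, group = grp,
                        network = net, day = day)
        early_exc[[length(early_exc) + 1L]] <- tibble(
          subject = sub, group = grp, network = net, day = day,
          early_excursion = early_excursion(
            curve, config$rotation_onset,
            volumes_per_trial = config$volumes_per_trial))
        ## covariance epochs (equal length)
        rest_win <- seq_len(config$epoch_length)
        cov_sets[[net]]$task[[paste(sub, day, sep = ".")]] <-
          lapply(wins, function(w) {
            stage("shrinkage_covariance",
                  shrinkage_covariance(sim$task[w, , drop = FALSE]))
          })
        if (day == 1) {
          cov_sets[[net]]$rest[[sub]] <- stage(
            "shrinkage_covariance",
            shrinkage_covariance(rest_d1[rest_win, , drop = FALSE]))
        }
      }
    }
  }
  curves_tbl <- dplyr::bind_rows(excursion_curves)
  early_tbl <- dplyr::bind_rows(early_exc)

  ## -- mfPCA of excursion curves -------------------------------------------
  say("stage mfpca: smoothing %d curves", 2L * length(networks) *
        length(subjects))
  smooth_tbl <- curves_tbl %>%
    dplyr::group_by(.data$subject, .data$network, .data$day) %>%
    dplyr::group_modify(function(df, key) {
      sm <- smooth_curve(df$standardized, df$volume)
      tibble(grid = df$volume, value = sm$fitted)
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(element = paste(.data$network, .data$day, sep = "_day"))
  fp <- stage("mfpca", mfpca(smooth_tbl, n_components = config$n_mfpca))
  grp_by_subject <- groups[fp$scores$subject]
  fp_tests <- purrr::map_dfr(seq_len(config$n_mfpca), function(k) {
    sc <- fp$scores[[paste0("score", k)]]
    kw <- kruskal_wallis(sc, grp_by_subject)
    dplyr::mutate(kw, component = k, .before = 1)
  })
  fp_posthoc <- purrr::map_dfr(seq_len(config$n_mfpca), function(k) {
    sc <- fp$scores[[paste0("score", k)]]
    dplyr::mutate(conover_iman(sc, grp_by_subject), component = k,
                  .before = 1)
  })

  ## -- covariance centering + embedding ------------------------------------
  embeddings <- list()
  anovas <- list()
  for (net in networks) {
    say("stage centering/embedding: %s network", net)
    rests <- cov_sets[[net]]$rest
    grand <- stage("frechet_mean", spd_frechet_mean(unname(rests)))
    design <- tidyr::expand_grid(subject = subjects, day = 1:2,
                                 epoch = c("baseline", "early", "late"))
    tangents <- purrr::pmap(design, function(subject, day, epoch) {
      tasks <- cov_sets[[net]]$task[[paste(subject, day, sep = ".")]]
      stage("spd_center",
            spd_center(rests[[subject]], tasks[[epoch]], grand)$tangents[[1]])
    })
    emb <- stage("joint_embed",
                 joint_embed(tangents, n_components = config$n_embed))
    emb_design <- dplyr::mutate(design, group = groups[.data$subject])
    score_tbls <- purrr::map(seq_len(config$n_embed), function(k) {
      dplyr::mutate(emb_design, score = emb$scores[, k], component = k)
    })
    anova_tbl <- purrr::map_dfr(score_tbls, function(st) {
      dplyr::mutate(stage("score_anova", score_anova(st)),
                    component = st$component[1], .before = 1)
    })
    embeddings[[net]] <- list(embedding = emb, design = emb_design,
                              grand_mean = grand)
    anovas[[net]] <- anova_tbl
  }

  result <- structure(
    list(config = config,
         trials = clean,
         features = features,
         clusters = clusters,
         cluster_ari = ari,
         bootstrap = boot,
         excursion_curves = curves_tbl,
         early_excursion = early_tbl,
         mfpca = fp,
         mfpca_tests = fp_tests,
         mfpca_posthoc = fp_posthoc,
         embedding = embeddings,
         embedding_anova = anovas),
    class = "excursion_pipeline")

  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.excursion_pipeline <- function(x, ...) {
  cat("Sensorimotor-adaptation analysis pipeline\n")
  cat(sprintf("  subjects: %d (%d per phenotype), seed %d\n",
              nrow(x$features), x$config$n_subjects_per_group,
              x$config$seed))
  cat(sprintf("  behavioral clusters: k = %d, ARI vs ground truth = %.3f\n",
              x$clusters$k, x$cluster_ari))
  cat(sprintf("  mfPCA variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$mfpca$var_explained),
                    collapse = ", ")))
  for (net in names(x$embedding)) {
    cat(sprintf("  %s embedding mean residual norm: %.3f\n", net,
                mean(x$embedding[[net]]$embedding$residual_norms)))
  }
  invisible(x)
}

# Write the machine-readable pipeline outputs.
write_pipeline <- function(result, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    abort("Output directory is not empty; pass force = TRUE to overwrite.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  tsv(result$features, "features.tsv")
  tsv(result$clusters$labels, "cluster_labels.tsv")
  tsv(result$early_excursion, "early_excursion.tsv")
  tsv(result$mfpca$scores, "mfpca_scores.tsv")
  tsv(result$mfpca_tests, "mfpca_tests.tsv")
  if (!is.null(result$bootstrap)) tsv(result$bootstrap, "bootstrap.tsv")
  for (net in names(result$embedding)) {
    tsv(as.data.frame(result$embedding[[net]]$embedding$scores),
        sprintf("embedding_scores_%s.tsv", net))
    tsv(result$embedding_anova[[net]], sprintf("embedding_anova_%s.tsv", net))
  }
  cfg <- result$config
  sidecar <- list(
    seed = cfg$seed,
    n_subjects = 3L * cfg$n_subjects_per_group,
    network_sizes = as.list(cfg$network_sizes),
    var_threshold = cfg$var_threshold,
    epoch_length = cfg$epoch_length,
    config_hash = sum(utf8ToInt(paste(
      vapply(cfg[!vapply(cfg, is.list, logical(1))], paste,
             character(1), collapse = ","), collapse = ";"))))
  jsonlite::write_json(sidecar, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
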