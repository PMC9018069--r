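#' Configuration for the behavioral simulator
#'
#' Describes a two-day visuomotor-rotation experiment with three learner
#' phenotypes. On each day subjects perform baseline trials (no rotation),
#' learning trials under a fixed cursor rotation, and washout trials
#' (rotation removed). Angular error during learning decays exponentially
#' from the rotation magnitude with a per-phenotype time constant:
#' FF learners adapt fast on both days, SS slow on both days, and SF slow on
#' day 1 but fast on day 2 (pronounced savings). Washout shows an
#' aftereffect of opposite sign decaying back to zero.
#'
#' @param n_subjects_per_group subjects per phenotype.
#' @param n_baseline_trials,n_learning_trials,n_washout_trials trial counts
#'   per day (defaults 120 / 320 / 120).
#' @param rotation_deg imposed cursor rotation in degrees (default 45,
#'   clockwise).
#' @param learn_rate_day1,learn_rate_day2 named numeric vectors
#'   (`FF`, `SS`, `SF`) of exponential time constants, in trials.
#' @param washout_rate washout decay time constant in trials.
#' @param rt_mean,rt_sd named per-phenotype reaction-time mean and SD in
#'   seconds (lognormal distribution, parameterized by its own mean/sd).
#' @param error_noise_sd trial-to-trial Gaussian error noise, degrees.
#' @param rt_violation_rate fraction of trials given out-of-range reaction
#'   times (> 2 s or < 0.1 s) to exercise the preprocessing filters.
#' @param seed RNG seed.
#' @return a `behavior_sim_config` list.
#' @export
behavior_sim_config <- function(n_subjects_per_group = 10,
                                n_baseline_trials = 120,
                                n_learning_trials = 320,
                                n_washout_trials = 120,
                                rotation_deg = 45,
                                learn_rate_day1 = c(FF = 12, SS = 120, SF = 120),
                                learn_rate_day2 = c(FF = 12, SS = 120, SF = 12),
                                washout_rate = 20,
                                rt_mean = c(FF = 0.7, SS = 0.45, SF = 0.6),
                                rt_sd = c(FF = 0.15, SS = 0.1, SF = 0.15),
                                error_noise_sd = 8,
                                rt_violation_rate = 0.02,
                                seed = 1L) {
  groups <- c("FF", "SS", "SF")
  counts <- c(n_subjects_per_group, n_baseline_trials,
              n_learning_trials, n_washout_trials)
  if (any(counts <= 0)) abort("All counts must be positive.")
  for (r in list(learn_rate_day1, learn_rate_day2, washout_rate)) {
    if (any(r <= 0)) abort("Learning/washout rates must be positive.")
  }
  if (error_noise_sd < 0) abort("error_noise_sd must be >= 0.")
  for (nm in c("learn_rate_day1", "learn_rate_day2", "rt_mean", "rt_sd")) {
    v <- get(nm)
    if (!all(groups %in% names(v))) {
      abort(sprintf("`%s` must name all of FF, SS, SF.", nm))
    }
  }
  structure(
    list(n_subjects_per_group = n_subjects_per_group,
         n_baseline_trials = n_baseline_trials,
         n_learning_trials = n_learning_trials,
         n_washout_trials = n_washout_trials,
         rotation_deg = rotation_deg,
         learn_rate_day1 = learn_rate_day1,
         learn_rate_day2 = learn_rate_day2,
         washout_rate = washout_rate,
         rt_mean = rt_mean, rt_sd = rt_sd,
         error_noise_sd = error_noise_sd,
         rt_violation_rate = rt_violation_rate,
         seed = as.integer(seed)),
    class = "behavior_sim_config")
}

# Lognormal parameters from a target mean/sd on the natural scale.
lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Simulate two-day visuomotor-rotation trial tables
#'
#' Generates one row per trial per subject per day, with the phenotype
#' stored as ground truth in the `group` column. During learning the signed
#' angular error follows `rotation_deg * exp(-t / rate)` plus Gaussian
#' noise (`t` counted from 0 at rotation onset); during washout the
#' aftereffect, proportional to the amount adapted, decays toward zero with
#' the washout time constant. A small configurable fraction of trials gets
#' out-of-range reaction times so that downstream filters have work to do.
#'
#' @param config a [behavior_sim_config()].
#' @return tibble with columns `subject`, `group`, `day`, `trial`, `block`,
#'   `epoch`, `target_deg`, `error_deg`, `rt_s`. Deterministic given
#'   `config$seed`.
#' @export
simulate_behavior <- function(config = behavior_sim_config()) {
  if (!inherits(config, "behavior_sim_config")) {
    abort("`config` must come from behavior_sim_config().")
  }
  set.seed(config$seed)
  groups <- c("FF", "SS", "SF")
  n_per <- config$n_subjects_per_group
  subjects <- tibble(
    subject = sprintf("sub%02d", seq_len(3 * n_per)),
    group = rep(groups, each = n_per))
  targets <- seq(0, 315, by = 45)

  one_day <- function(group, day) {
    nb <- config$n_baseline_trials
    nl <- config$n_learning_trials
    nw <- config$n_washout_trials
    rate <- if (day == 1) config$learn_rate_day1[[group]] else
      config$learn_rate_day2[[group]]
    t_learn <- seq_len(nl) - 1
    mean_err <- c(
      rep(0, nb),
      config$rotation_deg * exp(-t_learn / rate),
      -config$rotation_deg * (1 - exp(-(nl - 1) / rate)) *
        exp(-(seq_len(nw) - 1) / config$washout_rate))
    n <- nb + nl + nw
    err <- wrap_degrees(mean_err + stats::rnorm(n, 0, config$error_noise_sd))
    lp <- lnorm_params(config$rt_mean[[group]], config$rt_sd[[group]])
    rt <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
    viol <- stats::runif(n) < config$rt_violation_rate
    rt[viol] <- ifelse(stats::runif(sum(viol)) < 0.5,
                       stats::runif(sum(viol), 2.05, 2.6),
                       stats::runif(sum(viol), 0.01, 0.09))
    tibble(
      day = day,
      trial = seq_len(n),
      block = (seq_len(n) - 1) %/% 8 + 1,
      epoch = rep(c("baseline", "learning", "washout"), c(nb, nl, nw)),
      target_deg = targets[(seq_len(n) - 1) %% 8 + 1],
      error_deg = err,
      rt_s = rt)
  }

  trials <- purrr::pmap_dfr(subjects, function(subject, group) {
    dplyr::bind_rows(
      dplyr::mutate(one_day(group, 1), subject = subject, group = group),
      dplyr::mutate(one_day(group, 2), subject = subject, group = group))
  })
  dplyr::select(trials, "subject", "group", "day", "trial", "block",
                "epoch", "target_deg", "error_deg", "rt_s")
}
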