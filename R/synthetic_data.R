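#' Configuration of the synthetic visual-search trial generator
#'
#' Builds the generative-model configuration used by [generate_dataset()].
#' Subject effects follow a logistic-normal model: subject `i` draws an
#' intercept `b_i ~ N(0, sigma_b^2)` and a condition effect
#' `d_i ~ N(delta, tau^2)` on the log-odds scale, and the probability that a
#' trial's first saccade is captured is
#' `plogis(mu + b_i + d_i * [condition == critical])`.  `tau` — the
#' between-subject SD of the condition effect — is the knob that controls
#' the true reliability of the difference-score measure: `tau = 0` (with
#' `sigma_b = 0`) means no true individual differences and split-half
#' reliability of approximately zero.
#'
#' Target-fixation latencies are a subject offset plus a condition offset
#' (applied to the critical condition) plus right-skewed lognormal trial
#' noise, truncated at the paradigm time limit: truncated trials are scored
#' `first_fixation = "none"` with missing latency.
#'
#' Three presets mirror common paradigm designs:
#' \describe{
#'   \item{`statistical_learning`}{high- vs low-probability distractor
#'     location; set size 6, time limit 1500 ms; the distractor appears at
#'     the high-probability location on 45% of distractor-present trials;
#'     difference = low - high.}
#'   \item{`conditioned_distractor`}{previously conditioned (CS+) vs neutral
#'     distractor, equal trial counts; set size 6, time limit 1000 ms;
#'     difference = CS+ - neutral.}
#'   \item{`search_mode`}{distractor-present vs -absent trials, equally
#'     often; set size 4, time limit 2000 ms; on absent trials the capture
#'     event is a first fixation on any non-target, scored with the
#'     proxy-distractor rate; difference = present - absent.}
#' }
#'
#' @param paradigm preset name (see Details).
#' @param n_subjects,n_runs,trials_per_condition_per_run design sizes.  For
#'   the `statistical_learning` preset `trials_per_condition_per_run` is half
#'   the distractor-present trials per run, which are then split 45%/55%
#'   between the high- and low-probability conditions.
#' @param mu baseline capture log-odds.
#' @param sigma_b between-subject SD of the capture intercept (log-odds).
#' @param delta mean condition effect on capture log-odds (applied to the
#'   critical condition; negative = suppression).
#' @param tau between-subject SD of the condition effect — the
#'   reliability-controlling knob.
#' @param latency_mean_ms,latency_subject_sd_ms base target-fixation latency
#'   and the SD of its subject offset.
#' @param latency_effect_mean_ms,latency_effect_sd_ms mean and
#'   between-subject SD of the latency condition offset (critical condition).
#' @param latency_trial_noise lognormal `sdlog` of the trial noise (the noise
#'   scale is fixed at a 150 ms mean).
#' @param nontarget_share probability that a non-captured first saccade on a
#'   distractor-present trial lands on a non-target rather than the target
#'   (exercises the proxy-distractor measure).
#' @param high_prob_share share of distractor-present trials at the
#'   high-probability location (`statistical_learning` preset only).
#' @param seed integer seed; [generate_dataset()] is deterministic given the
#'   full configuration.
#' @return Object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(paradigm = c("statistical_learning",
                                    "conditioned_distractor", "search_mode"),
                       n_subjects = 40, n_runs = 2,
                       trials_per_condition_per_run = 30,
                       mu = -1.0, sigma_b = 0.6, delta = NULL, tau = 0.5,
                       latency_mean_ms = 350, latency_subject_sd_ms = 60,
                       latency_effect_mean_ms = NULL,
                       latency_effect_sd_ms = 25,
                       latency_trial_noise = 0.45,
                       nontarget_share = 0.3, high_prob_share = 0.45,
                       seed = 1) {
  paradigm <- match.arg(paradigm)
  preset <- switch(paradigm,
    statistical_learning = list(
      critical = "high_prob", baseline = "low_prob",
      direction = c("low_prob", "high_prob"),
      set_size = 6L, time_limit_ms = 1500,
      delta = -0.8, latency_effect = -40, absent_baseline = FALSE),
    conditioned_distractor = list(
      critical = "CS_plus", baseline = "neutral",
      direction = c("CS_plus", "neutral"),
      set_size = 6L, time_limit_ms = 1000,
      delta = -0.6, latency_effect = -30, absent_baseline = FALSE),
    search_mode = list(
      critical = "present", baseline = "absent",
      direction = c("present", "absent"),
      set_size = 4L, time_limit_ms = 2000,
      delta = 0.5, latency_effect = 40, absent_baseline = TRUE))
  if (is.null(delta)) delta <- preset$delta
  if (is.null(latency_effect_mean_ms))
    latency_effect_mean_ms <- preset$latency_effect

  cfg <- structure(
    list(paradigm = paradigm,
         n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
         trials_per_condition_per_run =
           as.integer(trials_per_condition_per_run),
         mu = mu, sigma_b = sigma_b, delta = delta, tau = tau,
         latency_mean_ms = latency_mean_ms,
         latency_subject_sd_ms = latency_subject_sd_ms,
         latency_effect_mean_ms = latency_effect_mean_ms,
         latency_effect_sd_ms = latency_effect_sd_ms,
         latency_trial_noise = latency_trial_noise,
         nontarget_share = nontarget_share,
         high_prob_share = high_prob_share,
         critical_condition = preset$critical,
         baseline_condition = preset$baseline,
         direction = preset$direction,
         set_size = preset$set_size,
         time_limit_ms = preset$time_limit_ms,
         absent_baseline = preset$absent_baseline,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (n_subjects < 1L || n_runs < 1L)
      stop("n_subjects and n_runs must be >= 1", call. = FALSE)
    if (trials_per_condition_per_run < 2L)
      stop("trials_per_condition_per_run must be >= 2", call. = FALSE)
    if (sigma_b < 0 || tau < 0 || latency_subject_sd_ms < 0 ||
        latency_effect_sd_ms < 0 || latency_trial_noise < 0)
      stop("standard deviations must be >= 0", call. = FALSE)
    if (nontarget_share < 0 || nontarget_share > 1 ||
        high_prob_share <= 0 || high_prob_share >= 1)
      stop("shares must be proportions", call. = FALSE)
    # the logistic link keeps probabilities in (0,1); reject configurations
    # whose central probabilities are numerically degenerate
    p0 <- stats::plogis(mu + c(-3, 3) * max(sigma_b, tau) + c(min(delta, 0),
                                                              max(delta, 0)))
    if (any(p0 < 1e-10) || any(p0 > 1 - 1e-10))
      stop("configuration implies capture probabilities numerically at 0 ",
           "or 1", call. = FALSE)
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %s preset\n", x$paradigm))
  cat(sprintf("  %d subjects, %d run(s), %d trials/condition/run\n",
              x$n_subjects, x$n_runs, x$trials_per_condition_per_run))
  cat(sprintf("  capture: mu = %g, sigma_b = %g, delta = %g, tau = %g\n",
              x$mu, x$sigma_b, x$delta, x$tau))
  cat(sprintf("  latency: %g +/- %g ms, effect %g +/- %g ms, sdlog %g\n",
              x$latency_mean_ms, x$latency_subject_sd_ms,
              x$latency_effect_mean_ms, x$latency_effect_sd_ms,
              x$latency_trial_noise))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Per-run trial counts for the two conditions.  The statistical-learning
# preset splits the distractor-present trials 45/55 between the high- and
# low-probability locations; the other presets use equal counts.
condition_counts <- function(cfg) {
  t <- cfg$trials_per_condition_per_run
  if (cfg$paradigm == "statistical_learning") {
    total <- 2L * t
    n_crit <- as.integer(round(cfg$high_prob_share * total))
    c(stats::setNames(n_crit, cfg$critical_condition),
      stats::setNames(total - n_crit, cfg$baseline_condition))
  } else {
    c(stats::setNames(t, cfg$critical_condition),
      stats::setNames(t, cfg$baseline_condition))
  }
}

# Draw one cohort's subject-level effects from the current RNG stream.
draw_subjects <- function(cfg) {
  n <- cfg$n_subjects
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    b = stats::rnorm(n, 0, cfg$sigma_b),
    d = stats::rnorm(n, cfg$delta, cfg$tau),
    lat_b = stats::rnorm(n, 0, cfg$latency_subject_sd_ms),
    lat_d = stats::rnorm(n, cfg$latency_effect_mean_ms,
                         cfg$latency_effect_sd_ms),
    stringsAsFactors = FALSE)
}

# Simulate a trial table for the given cohort from the current RNG stream.
# counts: named per-run trial counts for (critical, baseline).
simulate_trials <- function(cfg, subj, counts) {
  per_run <- sum(counts)
  n_trials <- cfg$n_subjects * cfg$n_runs * per_run
  si <- rep(seq_len(cfg$n_subjects), each = cfg$n_runs * per_run)
  run <- rep(rep(seq_len(cfg$n_runs) - 1L, each = per_run), cfg$n_subjects)
  cond_block <- rep(names(counts), counts)

  # randomized presentation order within each subject x run
  cond <- as.vector(vapply(seq_len(cfg$n_subjects * cfg$n_runs),
                           function(i) sample(cond_block),
                           character(per_run)))
  trial_index <- rep(seq_len(per_run) - 1L, cfg$n_subjects * cfg$n_runs)

  is_crit <- cond == cfg$critical_condition
  absent <- cfg$absent_baseline & !is_crit
  p <- stats::plogis(cfg$mu + subj$b[si] + subj$d[si] * is_crit)
  event <- stats::runif(n_trials) < p

  ff <- character(n_trials)
  ff[event & !absent] <- "distractor"
  ff[event & absent] <- "nontarget"
  noncap <- which(!event)
  nt <- stats::runif(length(noncap)) < cfg$nontarget_share
  ff[noncap] <- ifelse(!absent[noncap] & nt, "nontarget", "target")

  sdlog <- cfg$latency_trial_noise
  noise <- stats::rlnorm(n_trials, meanlog = log(150) - sdlog^2 / 2,
                         sdlog = sdlog)
  lat <- cfg$latency_mean_ms + subj$lat_b[si] + subj$lat_d[si] * is_crit +
    noise
  timeout <- lat > cfg$time_limit_ms | lat <= 0
  ff[timeout] <- "none"
  lat[timeout] <- NA_real_

  data.frame(subject_id = subj$subject_id[si], run_index = run,
             trial_index = trial_index, condition = cond,
             first_fixation = ff, latency_ms = round(lat, 1),
             distractor_present = !absent, stringsAsFactors = FALSE)
}

#' Generate a synthetic trial dataset with known generative parameters
#'
#' Simulates a full cohort under the logistic-normal capture model and the
#' lognormal latency model described in [sim_config()], and returns it as a
#' validated [trial_dataset()] with the preset's condition pair, set size,
#' time limit and difference-score direction.  Deterministic given the
#' configuration (including its seed).
#'
#' @param config a [sim_config()].
#' @return A [trial_dataset()].
#' @examples
#' d <- generate_dataset(sim_config("search_mode", n_subjects = 8, seed = 3))
#' summary(d)
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  subj <- draw_subjects(config)
  trials <- simulate_trials(config, subj, condition_counts(config))
  trial_dataset(trials,
                critical_condition = config$critical_condition,
                baseline_condition = config$baseline_condition,
                set_size = config$set_size,
                time_limit_ms = config$time_limit_ms,
                direction = config$direction,
                paradigm = config$paradigm)
}

#' Ground-truth split-half reliability of a simulated design
#'
#' Monte-Carlo oracle for the expected half-vs-half Pearson correlation of
#' difference scores under the generative model: for each of `n_mc`
#' replicate cohorts, two *independent* halves are simulated afresh at the
#' per-half trial counts the stratified split would produce
#' (`floor(m / 2)` per condition per run), per-subject difference scores are
#' computed on each half, and the two vectors are correlated.  The average
#' over replicates is the value the split engine is expected to recover.
#'
#' @param config a [sim_config()].
#' @param measure `"capture"` or `"fixation_time"`.
#' @param n_mc number of replicate cohorts (default 500).
#' @param seed integer seed (independent of `config$seed`).
#' @return Mean half-vs-half correlation (scalar).
#' @export
true_split_reliability <- function(config, measure = c("capture",
                                                       "fixation_time"),
                                   n_mc = 500, seed = 1) {
  measure <- match.arg(measure)
  validate_sim_config(config)
  half_counts <- condition_counts(config) %/% 2L
  if (any(half_counts < 1L))
    stop("design too small: a half would hold no trials", call. = FALSE)
  set.seed(seed)
  meta <- list(critical_condition = config$critical_condition,
               baseline_condition = config$baseline_condition,
               set_size = config$set_size,
               time_limit_ms = config$time_limit_ms,
               direction = config$direction, paradigm = config$paradigm)
  r <- vapply(seq_len(n_mc), function(i) {
    subj <- draw_subjects(config)
    halves <- lapply(1:2, function(h) {
      d <- do.call(trial_dataset,
                   c(list(trials = simulate_trials(config, subj,
                                                   half_counts)), meta))
      difference_scores(d, measure)
    })
    ids <- intersect(halves[[1]]$subject_id, halves[[2]]$subject_id)
    if (length(ids) < 3L) return(NA_real_)
    x <- halves[[1]]$value[match(ids, halves[[1]]$subject_id)]
    y <- halves[[2]]$value[match(ids, halves[[2]]$subject_id)]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
  mean(r, na.rm = TRUE)
}
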