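#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with the argument checks the split
#' engine relies on: equal lengths of at least 3 and nonzero variance in both
#' vectors.  Returns `NA` (rather than erroring) on zero variance, the
#' "undefined" signal the permutation loop records and excludes from the
#' mean.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` if either vector is constant.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Spearman-Brown correction of a split-half correlation
#'
#' Estimates full-length-test reliability from the correlation between two
#' half-length tests: `r_SB = 2 r / (1 + r)`.  Monotone increasing on
#' (-1, 1\], fixing 0 and 1.
#'
#' @param r split-half correlation, > -1.
#' @return The corrected coefficient (vectorised).
#' @examples
#' spearman_brown(0.802)  # 0.890
#' @export
spearman_brown <- function(r) {
  if (any(r <= -1, na.rm = TRUE))
    stop("Spearman-Brown correction is undefined for r <= -1", call. = FALSE)
  2 * r / (1 + r)
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' Normal-theory interval on the Fisher z scale: `z = atanh(r)` with standard
#' error `1 / sqrt(n - 3)`, back-transformed with `tanh`.  The interval
#' contains `r` and its width strictly decreases with `n`.
#'
#' @param r correlation, |r| <= 1.
#' @param n number of independent pairs, >= 4.
#' @param level confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.  For |r| = 1 the degenerate
#'   interval `(r, r)` is returned with a warning.
#' @examples
#' fisher_ci(0.802, 36)  # c(0.643, 0.895)
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  stopifnot(length(r) == 1L, abs(r) <= 1, n >= 4L, level > 0, level < 1)
  if (abs(r) == 1) {
    warning("|r| = 1: degenerate confidence interval")
    return(c(lower = r, upper = r))
  }
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  c(lower = tanh(z - hw), upper = tanh(z + hw))
}

#' z-score outlier screening of per-subject difference scores
#'
#' Standardises the scores to mean 0 and SD 1 and flags subjects whose
#' absolute z-score meets the threshold.  Diagnostic only: no subject is
#' removed by the pipeline.
#'
#' @param scores named numeric vector of per-subject scores, or the
#'   data.frame returned by [difference_scores()].
#' @param threshold flag subjects with `|z| >= threshold` (default 3).
#' @return Object of class `outlier_report`: list with `z` (named z-scores),
#'   `flagged` (subject IDs) and `threshold`.
#' @export
outlier_zscores <- function(scores, threshold = 3) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$value, scores$subject_id)
  stopifnot(is.numeric(scores), length(scores) >= 3L)
  s <- stats::sd(scores)
  if (s == 0) {
    warning("zero variance in scores: z-scores undefined, nothing flagged")
    z <- rep(NA_real_, length(scores))
    names(z) <- names(scores)
    return(structure(list(z = z, flagged = character(0),
                          threshold = threshold),
                     class = "outlier_report"))
  }
  z <- (scores - mean(scores)) / s
  structure(list(z = z,
                 flagged = names(z)[abs(z) >= threshold],
                 threshold = threshold),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier screen (|z| >= %g): %d of %d subjects flagged\n",
              x$threshold, length(x$flagged), length(x$z)))
  if (length(x$flagged) > 0L)
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

# Derive one reproducible sub-seed per permutation from the master seed.
# sample.int draws sequentially, so the first k sub-seeds do not change when
# n_perm grows: earlier permutations are never reshuffled.
perm_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Randomly split a trial dataset into two condition/run-balanced halves
#'
#' Every subject x condition x run stratum contributes an equal number of
#' trials to each half; when a stratum holds an odd number of trials one
#' uniformly random trial is dropped for this split only.  Strata with fewer
#' than 2 trials contribute nothing to either half.  Within each run the
#' retained trials keep their presentation order, and halves are concatenated
#' over runs.
#'
#' @param dataset a [trial_dataset()].
#' @param seed integer seed making the split reproducible.
#' @return List with elements `half_A` and `half_B` (both [trial_dataset()]s)
#'   and `dropped` (number of trials left out of both halves).
#' @export
stratified_split <- function(dataset, seed) {
  validate_trialdata(dataset)
  tr <- dataset$trials
  set.seed(seed)
  assign_half <- split_assignment(
    interaction(tr$subject_id, tr$condition, tr$run_index, drop = TRUE))
  out <- lapply(1:2, function(h) {
    d <- dataset
    d$trials <- tr[assign_half == h, , drop = FALSE]
    d$trials <- d$trials[order(d$trials$run_index, d$trials$trial_index), ,
                         drop = FALSE]
    rownames(d$trials) <- NULL
    d
  })
  list(half_A = out[[1]], half_B = out[[2]],
       dropped = sum(assign_half == 0L))
}

# One random half assignment: 1 = half A, 2 = half B, 0 = dropped.
# Consumes length(stratum) uniforms from the current RNG stream.
split_assignment <- function(stratum) {
  stratum <- as.integer(factor(stratum))
  o <- order(stratum, stats::runif(length(stratum)))
  m <- tabulate(stratum)
  h <- m %/% 2L
  pos <- sequence(m)
  lab <- ifelse(pos <= rep(h, m), 1L, ifelse(pos <= rep(2L * h, m), 2L, 0L))
  out <- integer(length(stratum))
  out[o] <- lab
  out
}

#' Permuted split-half reliability of a difference-score measure
#'
#' The package's core estimator.  On each of `n_perm` permutations the
#' trials are randomly split into two halves with an equal number of
#' observations per subject x condition x run (see [stratified_split()]),
#' the per-subject difference score of the chosen measure is computed on each
#' half, and the two per-subject vectors are Pearson-correlated.  The
#' coefficients are averaged into the reported split-half reliability `r`,
#' which is Spearman-Brown-corrected to full-test length
#' (`r_SB = 2r / (1 + r)`); both estimates carry Fisher-z confidence
#' intervals.
#'
#' Permutations on which a correlation is undefined (fewer than 3 subjects
#' with usable data in both halves, or zero variance in a half) are recorded
#' as `NA`, excluded from the mean, and counted in `n_undefined`.  Subjects
#' without usable data in both conditions of the full dataset are excluded
#' up front and listed in `excluded_subjects`.
#'
#' @inheritParams difference_scores
#' @param n_perm number of random splits (default 1000).
#' @param seed integer master seed; each permutation consumes an independent
#'   sub-stream, so enlarging `n_perm` does not reshuffle earlier
#'   permutations.
#' @param level confidence level for the Fisher-z intervals.
#' @return Object of class `split_half` with components `measure`,
#'   `direction`, `n_subjects`, `permutation_r` (length `n_perm`, `NA` where
#'   undefined), `mean_r`, `sb_r`, `ci_r`, `ci_sb`, `n_undefined`,
#'   `excluded_subjects`, `n_perm`, `seed`, `level`.  Methods: `print`,
#'   `summary`, `coef`, `confint`, `plot`.
#' @examples
#' cfg <- sim_config("statistical_learning", n_subjects = 12,
#'                   trials_per_condition_per_run = 10, seed = 7)
#' d <- generate_dataset(cfg)
#' fit <- split_half(d, "capture", n_perm = 50, seed = 1)
#' fit
#' coef(fit)
#' @export
split_half <- function(dataset, measure = c("capture", "fixation_time"),
                       direction = NULL, n_perm = 1000, seed,
                       timeout_policy = c("exclude_none", "count_none"),
                       summary_fun = c("mean", "median"), level = 0.95) {
  measure <- match.arg(measure)
  timeout_policy <- match.arg(timeout_policy)
  summary_fun <- match.arg(summary_fun)
  stopifnot(n_perm >= 1L)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  validate_trialdata(dataset)
  if (is.null(direction)) direction <- dataset$direction

  # subjects usable on the full dataset (both conditions scored)
  full <- difference_scores(dataset, measure, direction, timeout_policy,
                            summary_fun)
  keep_ids <- full$subject_id
  if (length(keep_ids) < 4L)
    stop("fewer than 4 subjects with usable data in both conditions",
         call. = FALSE)

  tr <- dataset$trials
  keep <- tr$subject_id %in% keep_ids & tr$condition %in% direction
  sub <- dataset
  sub$trials <- tr[keep, , drop = FALSE]
  enc <- measure_encoding(sub, measure, timeout_policy, summary_fun)
  st <- sub$trials
  n <- nrow(st)

  subj <- factor(st$subject_id, levels = sort(keep_ids))
  cond <- factor(st$condition, levels = direction)
  stratum <- as.integer(interaction(subj, cond, st$run_index, drop = TRUE))
  S <- nlevels(subj)
  # group = subject x condition cell, minuend cells odd, subtrahend even
  g <- (as.integer(subj) - 1L) * 2L + as.integer(cond)
  G <- 2L * S
  yd <- ifelse(enc$scored, enc$y / enc$divisor, 0)
  sc <- as.numeric(enc$scored)
  use_median <- identical(summary_fun, "median") &&
    measure == "fixation_time"

  half_diffs <- function(idx) {
    if (use_median) {
      agg <- tapply(seq_along(g[idx]), g[idx], function(i) {
        ii <- idx[i][enc$scored[idx[i]]]
        if (length(ii) == 0L) NA_real_ else stats::median(enc$y[ii])
      })
      v <- rep(NA_real_, G)
      v[as.integer(names(agg))] <- as.numeric(agg)
    } else {
      num <- as.numeric(rowsum(c(yd[idx], numeric(G)),
                               c(g[idx], seq_len(G))))
      den <- as.numeric(rowsum(c(sc[idx], numeric(G)),
                               c(g[idx], seq_len(G))))
      v <- num / den
      v[den == 0] <- NA_real_
    }
    v[seq(1L, G, 2L)] - v[seq(2L, G, 2L)]
  }

  seeds <- perm_seeds(seed, n_perm)
  r <- rep(NA_real_, n_perm)
  for (p in seq_len(n_perm)) {
    set.seed(seeds[p])
    a <- split_assignment(stratum)
    dA <- half_diffs(which(a == 1L))
    dB <- half_diffs(which(a == 2L))
    ok <- !is.na(dA) & !is.na(dB)
    if (sum(ok) >= 3L && stats::sd(dA[ok]) > 0 && stats::sd(dB[ok]) > 0)
      r[p] <- stats::cor(dA[ok], dB[ok])
  }

  mean_r <- mean(r, na.rm = TRUE)
  if (!is.finite(mean_r))
    stop("all permutations produced undefined correlations", call. = FALSE)
  sb_r <- if (mean_r > -1) spearman_brown(mean_r) else NA_real_
  ci_for <- function(est) {
    if (is.na(est)) c(lower = NA_real_, upper = NA_real_)
    else if (abs(est) == 1) c(lower = est, upper = est)
    else fisher_ci(est, length(keep_ids), level)
  }
  structure(
    list(measure = measure, direction = direction,
         n_subjects = length(keep_ids),
         permutation_r = r, mean_r = mean_r, sb_r = sb_r,
         ci_r = ci_for(mean_r),
         ci_sb = ci_for(sb_r),
         n_undefined = sum(is.na(r)),
         excluded_subjects = attr(full, "excluded"),
         n_perm = n_perm, seed = seed, level = level,
         paradigm = dataset$paradigm),
    class = "split_half")
}

#' @export
print.split_half <- function(x, digits = 3, ...) {
  cat(sprintf("Permuted split-half reliability (%s", x$measure))
  if (nzchar(x$paradigm)) cat(", ", x$paradigm, sep = "")
  cat(sprintf("; %d permutations, n = %d)\n", x$n_perm, x$n_subjects))
  cat(sprintf("  r    = %.*f [%.*f, %.*f]\n", digits, x$mean_r,
              digits, x$ci_r[1], digits, x$ci_r[2]))
  cat(sprintf("  r_SB = %.*f [%.*f, %.*f]\n", digits, x$sb_r,
              digits, x$ci_sb[1], digits, x$ci_sb[2]))
  if (x$n_undefined > 0L)
    cat(sprintf("  (%d permutation(s) undefined and excluded)\n",
                x$n_undefined))
  invisible(x)
}

#' @export
summary.split_half <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  q <- stats::quantile(object$permutation_r, c(0.025, 0.25, 0.5, 0.75, 0.975),
                       na.rm = TRUE)
  cat("\nPermutation coefficient distribution:\n")
  print(round(q, digits))
  if (length(object$excluded_subjects) > 0L)
    cat("Excluded subjects:",
        paste(object$excluded_subjects, collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.split_half <- function(object, ...) {
  c(r = object$mean_r, r_sb = object$sb_r)
}

#' @export
confint.split_half <- function(object, parm = c("r", "r_sb"), level = NULL,
                               ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  if (is.null(level)) level <- object$level
  n <- object$n_subjects
  out <- rbind(r = fisher_ci(object$mean_r, n, level),
               r_sb = fisher_ci(object$sb_r, n, level))
  out[parm, , drop = FALSE]
}

#' @export
plot.split_half <- function(x, ...) {
  graphics::hist(x$permutation_r, breaks = 30,
                 main = sprintf("Split-half coefficients (%s)", x$measure),
                 xlab = "Pearson r per permutation", ...)
  graphics::abline(v = x$mean_r, lwd = 2)
  invisible(x)
}

#' Average reliability over several split-half analyses
#'
#' Unweighted arithmetic means of the split-half correlations and of their
#' Spearman-Brown corrections across a collection of results — the summary
#' used to report the overall reliability of a measure across datasets.
#'
#' @param results a list of [split_half()] fits, or a numeric vector of
#'   split-half correlations (whose Spearman-Brown corrections are then
#'   computed per element before averaging).
#' @return Named numeric vector `c(mean_r, mean_sb)`.
#' @examples
#' aggregate_mean_reliability(c(0.802, 0.609, 0.692, 0.458,
#'                              0.656, 0.765, 0.815, 0.890))
#' @export
aggregate_mean_reliability <- function(results) {
  if (is.numeric(results)) {
    stopifnot(length(results) >= 1L)
    return(c(mean_r = mean(results),
             mean_sb = mean(spearman_brown(results))))
  }
  stopifnot(is.list(results), length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "split_half")))
  c(mean_r = mean(vapply(results, `[[`, 0, "mean_r")),
    mean_sb = mean(vapply(results, `[[`, 0, "sb_r")))
}
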