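#' Randomization test comparing two split-half reliability estimates
#'
#' Non-parametric test of whether the split-half reliability of two measures
#' (or two groups) differs.  The observed statistic is the difference of the
#' two mean split-half correlations.  Under the null hypothesis the
#' permutation coefficients are exchangeable between measures, so the pooled
#' coefficients are repeatedly re-partitioned at the original pool sizes
#' (without replacement) and the difference of group means recomputed;
#' the `p` value is the two-tailed normal tail probability of
#' `z = (observed - mean(null)) / sd(null)`.
#'
#' An empirical permutation p (rank of the observed difference among the
#' null differences, with +1 smoothing) is also reported as a robustness
#' check; it is secondary to the z-based p.
#'
#' @param coeffs_a,coeffs_b numeric vectors of per-permutation split-half
#'   coefficients (e.g. the `permutation_r` component of [split_half()]
#'   fits; `NA`s are dropped).  Sizes may differ; re-partitions preserve
#'   them.
#' @param n_iter number of random re-partitions (default 1000).
#' @param seed integer seed.
#' @param tail `"two_sided"` (default) or `"one_sided"` (upper tail of |z|
#'   direction observed).
#' @return Object of class `rel_compare`: list with `observed_diff`,
#'   `null_diffs`, `z_stat`, `p_value`, `p_empirical`, `n_iter`, `seed`,
#'   `tail`, `degenerate`.
#' @examples
#' set.seed(1)
#' a <- rnorm(200, 0.7, 0.05); b <- rnorm(200, 0.5, 0.05)
#' randomization_test(a, b, n_iter = 500, seed = 2)
#' @export
randomization_test <- function(coeffs_a, coeffs_b, n_iter = 1000, seed,
                               tail = c("two_sided", "one_sided")) {
  tail <- match.arg(tail)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  coeffs_a <- coeffs_a[!is.na(coeffs_a)]
  coeffs_b <- coeffs_b[!is.na(coeffs_b)]
  stopifnot(length(coeffs_a) >= 1L, length(coeffs_b) >= 1L, n_iter >= 1L)

  na <- length(coeffs_a)
  pool <- c(coeffs_a, coeffs_b)
  ntot <- length(pool)
  observed <- mean(coeffs_a) - mean(coeffs_b)

  set.seed(seed)
  total <- sum(pool)
  null_diffs <- vapply(seq_len(n_iter), function(i) {
    sa <- sum(pool[sample.int(ntot, na)])
    sa / na - (total - sa) / (ntot - na)
  }, 0)

  s <- stats::sd(null_diffs)
  # identical pools (as multisets) make the comparison vacuous: any
  # reassignment is as extreme as the observation, so p is 1 by construction
  degenerate <- !is.finite(s) || s == 0 ||
    (na == ntot - na && isTRUE(all.equal(sort(coeffs_a), sort(coeffs_b))))
  if (degenerate) {
    warning("degenerate comparison (zero-variance null or identical pools); ",
            "p set to 1")
    z <- 0
    p <- 1
  } else {
    z <- (observed - mean(null_diffs)) / s
    p <- if (tail == "two_sided") 2 * stats::pnorm(-abs(z))
         else stats::pnorm(-abs(z))
    p <- min(p, 1)
  }
  centered <- abs(null_diffs - mean(null_diffs))
  p_emp <- (1 + sum(centered >= abs(observed - mean(null_diffs)))) /
    (n_iter + 1)

  structure(list(observed_diff = observed, null_diffs = null_diffs,
                 z_stat = z, p_value = p, p_empirical = p_emp,
                 n_iter = n_iter, seed = seed, tail = tail,
                 degenerate = degenerate),
            class = "rel_compare")
}

#' @export
print.rel_compare <- function(x, digits = 3, ...) {
  cat("Randomization test on pooled split-half coefficients\n")
  cat(sprintf("  observed difference of mean r: %.*f\n", digits,
              x$observed_diff))
  if (x$degenerate) {
    cat("  degenerate null distribution (zero variance): p = 1\n")
  } else {
    cat(sprintf("  z = %.*f, p = %s (%s; %d re-partitions)\n", digits,
                x$z_stat, format.pval(x$p_value, digits = digits),
                sub("_", "-", x$tail), x$n_iter))
    cat(sprintf("  empirical permutation p = %.*f\n", digits, x$p_empirical))
  }
  invisible(x)
}

#' @export
plot.rel_compare <- function(x, ...) {
  graphics::hist(x$null_diffs, breaks = 30,
                 main = "Null distribution of reassigned mean-r differences",
                 xlab = "difference of group mean r", ...)
  graphics::abline(v = x$observed_diff, lwd = 2)
  invisible(x)
}

#' Compare split-half reliability between two measures, fits or datasets
#'
#' Convenience wrapper around [randomization_test()].  Accepts either two
#' fitted [split_half()] objects (their permutation coefficient pools are
#' compared directly) or two [trial_dataset()]s, for which the split engine
#' is run first — e.g. to compare the same measure across two cohorts.
#'
#' @param a,b [split_half()] fits, or [trial_dataset()]s.
#' @param measure,n_perm,split_seed passed to [split_half()] when `a`/`b`
#'   are datasets (`split_seed` seeds both engine runs).
#' @param ... passed on to [randomization_test()] (e.g. `n_iter`, `tail`).
#' @param seed seed for the randomization test.
#' @return A `rel_compare` object (see [randomization_test()]).
#' @export
compare_reliability <- function(a, b, seed, measure = "capture",
                                n_perm = 1000, split_seed = NULL, ...) {
  if (inherits(a, "trialdata")) {
    if (is.null(split_seed))
      stop("split_seed is required when comparing datasets", call. = FALSE)
    a <- split_half(a, measure, n_perm = n_perm, seed = split_seed)
  }
  if (inherits(b, "trialdata")) {
    b <- split_half(b, measure, n_perm = n_perm, seed = split_seed)
  }
  stopifnot(inherits(a, "split_half"), inherits(b, "split_half"))
  randomization_test(a$permutation_r, b$permutation_r, seed = seed, ...)
}
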