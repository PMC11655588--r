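test_that("pearson_r matches the product-moment formula and handles edge cases", {
  expect_equal(pearson_r(1:3, 1:3), 1)
  expect_equal(pearson_r(1:3, 3:1), -1)
  set.seed(2)
  x <- rnorm(10); y <- rnorm(10)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), manual)
  expect_true(is.na(pearson_r(rep(1, 5), rnorm(5))))
  expect_error(pearson_r(1:2, 1:2))
})

test_that("Spearman-Brown correction reproduces published worked examples", {
  expect_equal(round(spearman_brown(0.802), 3), 0.890)
  expect_equal(round(spearman_brown(0.698), 3), 0.822)
  expect_equal(round(spearman_brown(0.890), 3), 0.942)
  expect_equal(round(spearman_brown(0.272), 3), 0.428)
  expect_equal(spearman_brown(0), 0)    # fixed points
  expect_equal(spearman_brown(1), 1)
  r <- seq(-0.9, 0.95, by = 0.05)
  expect_true(all(diff(spearman_brown(r)) > 0))  # monotone
  expect_error(spearman_brown(-1), "undefined")
})

test_that("Fisher-z intervals reproduce published intervals and shrink with n", {
  expect_equal(round(unname(fisher_ci(0.802, 36)), 3), c(0.643, 0.895))
  expect_equal(round(unname(fisher_ci(0.609, 38)), 3), c(0.359, 0.777))
  # interval of the Spearman-Brown point estimate reproduces printed bounds
  sb <- spearman_brown(0.802)
  expect_equal(round(unname(fisher_ci(sb, 36)), 3), c(0.794, 0.943))

  ci0 <- fisher_ci(0, 30)
  expect_equal(ci0[["lower"]], -ci0[["upper"]])  # symmetric about 0
  w <- sapply(c(10, 30, 100, 500), function(n) diff(fisher_ci(0.5, n)))
  expect_true(all(diff(w) < 0))  # width strictly decreasing in n
  ci <- fisher_ci(0.5, 20)
  expect_true(ci[1] < 0.5 && 0.5 < ci[2])
  expect_warning(d <- fisher_ci(1, 10), "degenerate")
  expect_equal(unname(d), c(1, 1))
})

test_that("z-score outlier screen standardises and flags without removing", {
  rep1 <- outlier_zscores(c(a = 0, b = 0, c = 0, d = 10), threshold = 1.5)
  expect_identical(rep1$flagged, "d")
  expect_equal(mean(rep1$z), 0)
  expect_equal(sd(rep1$z), 1)

  sym <- outlier_zscores(c(-2, -1, 0, 1, 2), threshold = 3)
  expect_length(sym$flagged, 0)

  set.seed(11)
  x <- rnorm(100)
  names(x) <- paste0("s", 1:100)
  rep2 <- outlier_zscores(x, threshold = 2)
  expect_identical(rep2$flagged,
                   names(x)[abs((x - mean(x)) / sd(x)) >= 2])
  expect_warning(z0 <- outlier_zscores(rep(1, 5)), "zero variance")
  expect_length(z0$flagged, 0)
})

test_that("stratified split balances every subject x condition x run stratum", {
  # mixed odd/even strata: n_per 5 and 8 across two runs
  d5 <- toy_dataset(n_subjects = 4, n_per = 5, n_runs = 1, seed = 2)
  d8 <- toy_dataset(n_subjects = 4, n_per = 8, n_runs = 1, seed = 3)
  d8$trials$run_index <- 1L
  d <- d5
  d$trials <- rbind(d5$trials, d8$trials)

  key <- function(tr) paste(tr$subject_id, tr$condition, tr$run_index)
  for (s in 1:50) {
    halves <- stratified_split(d, seed = s)
    ta <- table(key(halves$half_A$trials))
    tb <- table(key(halves$half_B$trials))
    expect_identical(names(ta), names(tb))
    expect_true(all(ta == tb))  # exact balance in every stratum
    # odd strata (5 trials) drop exactly one trial each
    expect_identical(halves$dropped, 4L * 2L)
    # halves are disjoint subsets of the original trials
    ids <- function(tr) paste(tr$subject_id, tr$condition, tr$run_index,
                              tr$trial_index)
    expect_length(intersect(ids(halves$half_A$trials),
                            ids(halves$half_B$trials)), 0)
    expect_true(all(ids(halves$half_A$trials) %in% ids(d$trials)))
  }
})

test_that("constant strata give r = 1 on every permutation", {
  d <- constant_strata_dataset(n_subjects = 8, n_per = 6)
  for (m in c("capture", "fixation_time")) {
    fit <- split_half(d, m, n_perm = 25, seed = 42)
    expect_equal(fit$permutation_r, rep(1, 25))
    expect_equal(fit$mean_r, 1)
    expect_equal(fit$sb_r, 1)
  }
})

test_that("engine is reproducible and permutation sub-streams are stable", {
  d <- toy_dataset(n_subjects = 8, n_per = 10, n_runs = 2, seed = 5)
  f1 <- split_half(d, "capture", n_perm = 40, seed = 7)
  f2 <- split_half(d, "capture", n_perm = 40, seed = 7)
  expect_identical(f1$permutation_r, f2$permutation_r)

  # enlarging n_perm must not reshuffle earlier permutations
  f3 <- split_half(d, "capture", n_perm = 60, seed = 7)
  expect_identical(f3$permutation_r[1:40], f1$permutation_r)

  f4 <- split_half(d, "capture", n_perm = 40, seed = 8)
  expect_false(identical(f4$permutation_r, f1$permutation_r))

  # invariants of the result object
  expect_equal(f1$mean_r, mean(f1$permutation_r, na.rm = TRUE))
  expect_equal(f1$sb_r, 2 * f1$mean_r / (1 + f1$mean_r))
  expect_true(f1$ci_r[1] < f1$mean_r && f1$mean_r < f1$ci_r[2])
})

test_that("undefined permutations are excluded from the mean and counted", {
  # 4 subjects, 2 trials per stratum: halves hold 1 trial each, so
  # zero-variance halves occur often in a small homogeneous dataset
  rows <- list()
  for (s in 1:4)
    for (cond in c("high_prob", "low_prob"))
      rows[[length(rows) + 1L]] <-
        trial_block(paste0("s", s), cond,
                    c("distractor", "target")[c(1, 2)])
  d <- trial_dataset(do.call(rbind, rows), "high_prob", "low_prob", 6, 1500,
                     direction = c("low_prob", "high_prob"))
  fit <- split_half(d, "capture", n_perm = 30, seed = 3)
  expect_identical(fit$n_undefined, sum(is.na(fit$permutation_r)))
  expect_equal(fit$mean_r, mean(fit$permutation_r, na.rm = TRUE))
})

test_that("aggregate reliability averages coefficients and corrections", {
  caps <- c(0.802, 0.609, 0.692, 0.458, 0.656, 0.765, 0.815, 0.890)
  agg <- aggregate_mean_reliability(caps)
  expect_equal(round(agg[["mean_r"]], 3), 0.711)
  expect_equal(round(agg[["mean_sb"]], 3), 0.824)

  expect_equal(aggregate_mean_reliability(0.5)[["mean_r"]], 0.5)
  expect_equal(aggregate_mean_reliability(c(0.3, -0.3))[["mean_r"]], 0)

  d <- constant_strata_dataset()
  fits <- list(split_half(d, "capture", n_perm = 5, seed = 1),
               split_half(d, "fixation_time", n_perm = 5, seed = 1))
  agg2 <- aggregate_mean_reliability(fits)
  expect_equal(unname(agg2), c(1, 1))
})
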