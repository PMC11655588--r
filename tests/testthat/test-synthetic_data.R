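test_that("generation is deterministic given the configuration", {
  cfg <- sim_config("conditioned_distractor", n_subjects = 10, seed = 13)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$trials, d2$trials)
  cfg2 <- sim_config("conditioned_distractor", n_subjects = 10, seed = 14)
  expect_false(identical(generate_dataset(cfg2)$trials, d1$trials))
  validate_trialdata(d1)
})

test_that("degenerate homogeneous configs behave as expected", {
  # tau = 0, sigma_b = 0: every subject shares one capture-probability pair
  cfg <- sim_config("conditioned_distractor", n_subjects = 20,
                    trials_per_condition_per_run = 150, n_runs = 1,
                    tau = 0, sigma_b = 0, mu = -1, delta = -0.6, seed = 8)
  d <- generate_dataset(cfg)
  sm <- subject_measures(d, "capture")
  p_crit <- plogis(-1 - 0.6)
  p_base <- plogis(-1)
  expect_lt(abs(mean(sm$value[sm$condition == "CS_plus"]) - p_crit), 0.03)
  expect_lt(abs(mean(sm$value[sm$condition == "neutral"]) - p_base), 0.03)

  # delta = 0, tau = 0: expected difference score is 0
  cfg0 <- sim_config("conditioned_distractor", n_subjects = 30,
                     trials_per_condition_per_run = 80, n_runs = 1,
                     tau = 0, sigma_b = 0, delta = 0, seed = 9)
  ds <- difference_scores(generate_dataset(cfg0), "capture")
  expect_equal(mean(ds$value), 0, tolerance = 0.03)
})

test_that("grand-mean capture matches integration over the random effects", {
  cfg <- sim_config("conditioned_distractor", n_subjects = 40,
                    trials_per_condition_per_run = 30, n_runs = 2,
                    mu = -1, sigma_b = 0.6, delta = -0.8, tau = 0.5,
                    seed = 20)
  d <- generate_dataset(cfg)
  sm <- subject_measures(d, "capture")
  # population-averaged inverse-logit: E[plogis(mu + B)] with
  # B ~ N(0, sigma_b^2) (baseline) or N(delta, sigma_b^2 + tau^2) (critical)
  pop_mean <- function(m, s)
    integrate(function(x) plogis(x) * dnorm(x, m, s), -Inf, Inf)$value
  expect_lt(abs(mean(sm$value[sm$condition == "CS_plus"]) -
                  pop_mean(-1 - 0.8, sqrt(0.6^2 + 0.5^2))), 0.05)
  expect_lt(abs(mean(sm$value[sm$condition == "neutral"]) -
                  pop_mean(-1, 0.6)), 0.05)
})

test_that("presets honor the declared trial schedules and designs", {
  # statistical learning: critical (high-probability) share 45%
  cfg <- sim_config("statistical_learning", n_subjects = 4, seed = 2)
  d <- generate_dataset(cfg)
  tab <- table(d$trials$condition)
  expect_equal(unname(tab["high_prob"] / sum(tab)), 0.45, tolerance = 0.01)
  expect_true(all(d$trials$distractor_present))
  expect_identical(d$set_size, 6L)
  expect_identical(d$time_limit_ms, 1500)

  # conditioned distractor: equal counts, 1000 ms limit
  dc <- generate_dataset(sim_config("conditioned_distractor",
                                    n_subjects = 4, seed = 2))
  tc <- table(dc$trials$condition)
  expect_equal(unname(tc[1]), unname(tc[2]))
  expect_identical(dc$time_limit_ms, 1000)

  # search mode: present/absent equally often, absent trials distractor-free
  dm <- generate_dataset(sim_config("search_mode", n_subjects = 4, seed = 2))
  tm <- table(dm$trials$condition)
  expect_equal(unname(tm["present"]), unname(tm["absent"]))
  expect_true(all(!dm$trials$distractor_present[dm$trials$condition ==
                                                  "absent"]))
  expect_identical(dm$set_size, 4L)
  expect_identical(dm$n_nontargets, 3L)

  # latencies respect the time limit; timeouts are coded none/NA
  for (dd in list(d, dc, dm)) {
    lat <- dd$trials$latency_ms
    expect_true(all(is.na(lat) | (lat > 0 & lat <= dd$time_limit_ms)))
    expect_true(all(is.na(lat[dd$trials$first_fixation == "none"])))
  }
})

test_that("true reliability oracle responds to tau and trial count", {
  base <- function(tau, tpc)
    sim_config("conditioned_distractor", n_subjects = 30, n_runs = 1,
               trials_per_condition_per_run = tpc, tau = tau, sigma_b = 0,
               seed = 1)
  r_tau <- sapply(c(0, 0.5, 1.2), function(tau)
    true_split_reliability(base(tau, 20), "capture", n_mc = 60, seed = 5))
  expect_equal(r_tau[1], 0, tolerance = 0.1)  # no individual differences
  expect_true(all(diff(r_tau) > 0))           # non-decreasing in tau

  r_tpc <- sapply(c(8, 30, 90), function(tpc)
    true_split_reliability(base(0.6, tpc), "capture", n_mc = 60, seed = 5))
  expect_true(all(diff(r_tpc) > 0))           # non-decreasing in trials

  # large tau, many trials: approaches 1
  r_big <- true_split_reliability(base(2.5, 150), "capture", n_mc = 40,
                                  seed = 5)
  expect_gt(r_big, 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config("statistical_learning", tau = -1),
               "standard deviations")
  expect_error(sim_config("statistical_learning",
                          trials_per_condition_per_run = 1),
               ">= 2")
  expect_error(sim_config("statistical_learning", mu = 40),
               "numerically at 0 or 1")
  expect_error(sim_config("statistical_learning", high_prob_share = 1.2),
               "proportions")
})
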