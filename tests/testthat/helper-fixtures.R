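# Hand-built fixtures used across test files.

# One subject x condition trial block.
trial_block <- function(subject, condition, first_fixation,
                        latency = 400, run = 0L,
                        distractor_present = TRUE) {
  n <- length(first_fixation)
  data.frame(subject_id = subject, run_index = run,
             trial_index = seq_len(n) - 1L, condition = condition,
             first_fixation = first_fixation,
             latency_ms = rep_len(latency, n),
             distractor_present = rep_len(distractor_present, n),
             stringsAsFactors = FALSE)
}

# Small two-condition dataset: n_per trials per subject x condition x run,
# capture outcomes drawn per supplied probabilities.
toy_dataset <- function(n_subjects = 6, n_per = 8, n_runs = 1,
                        p_crit = 0.5, p_base = 0.2, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (r in seq_len(n_runs) - 1L) {
      for (cond in c("high_prob", "low_prob")) {
        p <- if (cond == "high_prob") p_crit else p_base
        ff <- ifelse(runif(n_per) < p, "distractor", "target")
        rows[[length(rows) + 1L]] <-
          trial_block(sprintf("s%02d", s), cond, ff,
                      latency = round(runif(n_per, 300, 900), 1), run = r)
      }
    }
  }
  trial_dataset(do.call(rbind, rows),
                critical_condition = "high_prob",
                baseline_condition = "low_prob",
                set_size = 6, time_limit_ms = 1500,
                direction = c("low_prob", "high_prob"))
}

# Dataset in which all trials within a subject x condition stratum are
# identical (same outcome, same latency), so every balanced split produces
# two identical halves: split-half r is exactly 1 on every permutation as
# long as the difference scores vary between subjects.
constant_strata_dataset <- function(n_subjects = 8, n_per = 6) {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    cap_high <- s <= n_subjects / 2
    for (cond in c("high_prob", "low_prob")) {
      ff <- rep(if (cond == "high_prob" && cap_high) "distractor"
                else "target", n_per)
      rows[[length(rows) + 1L]] <-
        trial_block(sprintf("s%02d", s), cond, ff,
                    latency = rep(300 + 17 * s +
                                    (cond == "high_prob") * (30 + 7 * s),
                                  n_per))
    }
  }
  trial_dataset(do.call(rbind, rows),
                critical_condition = "high_prob",
                baseline_condition = "low_prob",
                set_size = 6, time_limit_ms = 1500,
                direction = c("low_prob", "high_prob"))
}
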