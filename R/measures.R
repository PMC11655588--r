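#' Oculomotor capture rate for one subject x condition cell
#'
#' The probability that the first saccade of a trial landed on the salient
#' distractor, computed over distractor-present trials of a single subject in
#' a single condition.
#'
#' Trials on which no eye movement reached the target within the time limit
#' (`first_fixation == "none"`) are excluded from the denominator under the
#' default `"exclude_none"` policy; set `timeout_policy = "count_none"` to
#' count them as non-capture trials instead.
#'
#' @param trials data.frame of trials (rows of a [trial_dataset()]) all
#'   sharing one subject and condition, with `distractor_present` true.
#' @param timeout_policy how to treat trials with `first_fixation == "none"`.
#' @return list with `value` (capture probability in \[0, 1\]) and
#'   `n_trials_used` (the denominator).  `value` is `NA` with zero scored
#'   trials ("insufficient data"; the split engine drops such subjects).
#' @export
capture_rate <- function(trials, timeout_policy = c("exclude_none",
                                                    "count_none")) {
  timeout_policy <- match.arg(timeout_policy)
  stopifnot(nrow(trials) > 0L, all(trials$distractor_present))
  scored <- if (timeout_policy == "exclude_none")
    trials$first_fixation != "none" else rep(TRUE, nrow(trials))
  n <- sum(scored)
  if (n == 0L) return(list(value = NA_real_, n_trials_used = 0L))
  list(value = sum(trials$first_fixation[scored] == "distractor") / n,
       n_trials_used = n)
}

#' Proxy-distractor capture rate on distractor-absent trials
#'
#' On distractor-absent trials there is no distractor to capture the eyes, so
#' the baseline against capture is the probability of first-fixating any one
#' non-target: the proportion of trials whose first fixation landed on a
#' non-target, divided by the number of non-targets in the search array.
#' The result therefore lies in \[0, 1/n_nontargets\].
#'
#' @param trials data.frame of distractor-absent trials of one subject.
#' @param n_nontargets number of non-target items in the array (>= 1).
#' @inheritParams capture_rate
#' @return list with `value` and `n_trials_used`, as [capture_rate()].
#' @export
proxy_capture_rate <- function(trials, n_nontargets,
                               timeout_policy = c("exclude_none",
                                                  "count_none")) {
  timeout_policy <- match.arg(timeout_policy)
  stopifnot(nrow(trials) > 0L, !any(trials$distractor_present),
            n_nontargets >= 1L)
  scored <- if (timeout_policy == "exclude_none")
    trials$first_fixation != "none" else rep(TRUE, nrow(trials))
  n <- sum(scored)
  if (n == 0L) return(list(value = NA_real_, n_trials_used = 0L))
  list(value = (sum(trials$first_fixation[scored] == "nontarget") / n) /
         n_nontargets,
       n_trials_used = n)
}

#' Mean target-fixation latency for one subject x condition cell
#'
#' The arithmetic mean (or, optionally, median) of the latency to fixate the
#' target, over trials on which a target fixation was registered.  Trials
#' whose first saccade went to the distractor still contribute their later
#' target-fixation latency: the measure is time to reach the target,
#' unconditionally.
#'
#' @param trials data.frame of trials of one subject x condition.
#' @param summary_fun `"mean"` (default) or `"median"`.
#' @return list with `value` (milliseconds) and `n_trials_used` (trials with
#'   a recorded latency).  `value` is `NA` when no latency was recorded.
#' @export
fixation_time <- function(trials, summary_fun = c("mean", "median")) {
  summary_fun <- match.arg(summary_fun)
  stopifnot(nrow(trials) > 0L)
  lat <- trials$latency_ms[!is.na(trials$latency_ms)]
  if (length(lat) == 0L) return(list(value = NA_real_, n_trials_used = 0L))
  f <- if (summary_fun == "mean") mean else stats::median
  list(value = f(lat), n_trials_used = length(lat))
}

# Per-trial encoding of a measure: outcome y, scored flag, and an optional
# per-condition divisor (the proxy rate divides by n_nontargets).  All
# engine-level aggregation works from these three vectors so the permutation
# loop never dispatches on measure type row by row.
measure_encoding <- function(dataset, measure,
                             timeout_policy = "exclude_none",
                             summary_fun = "mean") {
  tr <- dataset$trials
  if (measure == "capture") {
    scored <- if (timeout_policy == "exclude_none")
      tr$first_fixation != "none" else rep(TRUE, nrow(tr))
    # distractor-absent conditions are scored with the proxy-distractor rate
    absent <- !tr$distractor_present
    y <- ifelse(absent, tr$first_fixation == "nontarget",
                tr$first_fixation == "distractor")
    divisor <- ifelse(absent, dataset$n_nontargets, 1)
    list(y = as.numeric(y), scored = scored, divisor = divisor)
  } else if (measure == "fixation_time") {
    scored <- !is.na(tr$latency_ms)
    y <- ifelse(scored, tr$latency_ms, 0)
    list(y = as.numeric(y), scored = scored,
         divisor = rep(1, nrow(tr)), summary_fun = summary_fun)
  } else stop("unknown measure: ", measure, call. = FALSE)
}

# Aggregate an encoded measure over groups (subject or subject x half).
# Returns value and n per group; NA value where no scored trials.
aggregate_measure <- function(enc, group, summary_fun = "mean") {
  if (identical(summary_fun, "median")) {
    n <- tapply(enc$scored, group, sum)
    v <- tapply(seq_along(group), group, function(i) {
      ii <- i[enc$scored[i]]
      if (length(ii) == 0L) NA_real_
      else stats::median(enc$y[ii] / enc$divisor[ii])
    })
    return(list(value = as.numeric(v), n = as.integer(n),
                levels = names(n)))
  }
  num <- rowsum(ifelse(enc$scored, enc$y / enc$divisor, 0), group)
  den <- rowsum(as.numeric(enc$scored), group)
  v <- as.numeric(num) / as.numeric(den)
  v[as.numeric(den) == 0] <- NA_real_
  list(value = v, n = as.integer(den), levels = rownames(num))
}

#' Per-subject measure values for both conditions of the contrast
#'
#' Computes the selected measure for every subject in each of the dataset's
#' two contrast conditions.  For the capture measure, distractor-absent
#' conditions are scored with the proxy-distractor rate
#' ([proxy_capture_rate()]); all other condition cells use [capture_rate()]
#' or [fixation_time()].
#'
#' @param dataset a [trial_dataset()].
#' @param measure `"capture"` or `"fixation_time"`.
#' @param timeout_policy,summary_fun see [capture_rate()] and
#'   [fixation_time()].
#' @return data.frame with columns `subject_id`, `condition`, `value`,
#'   `n_trials_used` (one row per subject x contrast condition; `value` `NA`
#'   when that cell has no scored trials).
#' @export
subject_measures <- function(dataset, measure = c("capture", "fixation_time"),
                             timeout_policy = c("exclude_none", "count_none"),
                             summary_fun = c("mean", "median")) {
  measure <- match.arg(measure)
  timeout_policy <- match.arg(timeout_policy)
  summary_fun <- match.arg(summary_fun)
  validate_trialdata(dataset)
  tr <- dataset$trials
  keep <- tr$condition %in% c(dataset$critical_condition,
                              dataset$baseline_condition)
  sub <- dataset
  sub$trials <- tr[keep, , drop = FALSE]
  enc <- measure_encoding(sub, measure, timeout_policy, summary_fun)
  group <- paste(sub$trials$subject_id, sub$trials$condition, sep = "\r")
  agg <- aggregate_measure(enc, group, summary_fun)
  parts <- strsplit(agg$levels, "\r", fixed = TRUE)
  data.frame(
    subject_id = vapply(parts, `[`, "", 1L),
    condition = vapply(parts, `[`, "", 2L),
    value = agg$value,
    n_trials_used = agg$n,
    stringsAsFactors = FALSE)
}

#' Per-subject difference scores of a measure between two conditions
#'
#' The individual-differences measure whose reliability the split-half engine
#' estimates: for each subject, the measure value under the minuend condition
#' minus the value under the subtrahend condition (e.g. capture probability
#' on low- minus high-probability distractor-location trials).
#'
#' Subjects lacking scored trials in either condition are omitted from the
#' result and listed in the `"excluded"` attribute.
#'
#' @inheritParams subject_measures
#' @param direction length-2 character vector `(minuend, subtrahend)`;
#'   defaults to the dataset's declared direction.
#' @return data.frame with columns `subject_id`, `measure`, `value`; attribute
#'   `"excluded"` holds the IDs of omitted subjects.
#' @export
difference_scores <- function(dataset, measure = c("capture", "fixation_time"),
                              direction = NULL,
                              timeout_policy = c("exclude_none", "count_none"),
                              summary_fun = c("mean", "median")) {
  measure <- match.arg(measure)
  timeout_policy <- match.arg(timeout_policy)
  summary_fun <- match.arg(summary_fun)
  if (is.null(direction)) direction <- dataset$direction
  stopifnot(length(direction) == 2L)

  sm <- subject_measures(dataset, measure, timeout_policy, summary_fun)
  a <- sm[sm$condition == direction[1], ]
  b <- sm[sm$condition == direction[2], ]
  ids <- union(a$subject_id, b$subject_id)
  va <- a$value[match(ids, a$subject_id)]
  vb <- b$value[match(ids, b$subject_id)]
  d <- va - vb
  ok <- !is.na(d)
  if (!any(ok))
    stop("no subject has usable data in both conditions", call. = FALSE)
  out <- data.frame(subject_id = ids[ok], measure = measure, value = d[ok],
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- ids[!ok]
  out
}
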