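#' Trial-level datasets for oculomotor visual-search reliability analysis
#'
#' A `trialdata` object bundles a long-format table of scored visual-search
#' trials (one row per trial) with the paradigm metadata the reliability
#' analysis needs: the pair of critical/baseline distractor conditions being
#' contrasted, the search-array set size, and the trial time limit.
#'
#' Each trial records where the first saccade went (`first_fixation`, one of
#' `"distractor"`, `"target"`, `"nontarget"`, `"none"`) and the latency in
#' milliseconds until the target was fixated (`latency_ms`, `NA` when no
#' target fixation was registered within the time limit).  `run_index`
#' identifies the experimental block or phase; random splits are balanced
#' within each subject x condition x run stratum, so datasets that pool
#' several phases (e.g. training and test) must encode them as distinct runs.
#'
#' @param trials data.frame with columns `subject_id` (character),
#'   `run_index` (non-negative integer), `trial_index` (non-negative integer,
#'   presentation order within run), `condition` (character), `first_fixation`
#'   (character), `latency_ms` (positive numeric or `NA`), and
#'   `distractor_present` (logical).
#' @param critical_condition,baseline_condition the two condition labels whose
#'   per-subject contrast defines the difference-score measure.  Must differ
#'   and both occur in `trials`.
#' @param set_size number of stimuli in the search array.
#' @param time_limit_ms trial time limit in milliseconds; recorded latencies
#'   must not exceed it.
#' @param n_nontargets number of non-target items a first saccade could land
#'   on in a distractor-absent display; used by the proxy-distractor capture
#'   rate.  Defaults to `set_size - 1`.
#' @param conditions declared set of admissible condition labels.  Defaults to
#'   the critical/baseline pair.
#' @param direction length-2 character vector `(minuend, subtrahend)` giving
#'   the sign convention of the difference score.  Defaults to
#'   `c(critical_condition, baseline_condition)`.
#' @param paradigm free-text tag describing the paradigm.
#'
#' @return An object of class `trialdata`.
#' @seealso [read_trials()], [write_trials()], [difference_scores()],
#'   [split_half()]
#' @examples
#' tr <- data.frame(
#'   subject_id = "s1", run_index = 0L, trial_index = 0:3,
#'   condition = c("high_prob", "low_prob", "high_prob", "low_prob"),
#'   first_fixation = c("target", "distractor", "target", "target"),
#'   latency_ms = c(410.5, 702.0, 390.1, 515.3),
#'   distractor_present = TRUE)
#' d <- trial_dataset(tr, critical_condition = "high_prob",
#'                    baseline_condition = "low_prob",
#'                    set_size = 6, time_limit_ms = 1500)
#' d
#' @export
trial_dataset <- function(trials, critical_condition, baseline_condition,
                          set_size, time_limit_ms,
                          n_nontargets = set_size - 1L,
                          conditions = NULL,
                          direction = c(critical_condition, baseline_condition),
                          paradigm = "") {
  stopifnot(is.data.frame(trials))
  required <- c("subject_id", "run_index", "trial_index", "condition",
                "first_fixation", "latency_ms", "distractor_present")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0L)
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  trials <- trials[required]
  trials$subject_id <- as.character(trials$subject_id)
  trials$run_index <- as.integer(trials$run_index)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$condition <- as.character(trials$condition)
  trials$first_fixation <- as.character(trials$first_fixation)
  trials$latency_ms <- as.numeric(trials$latency_ms)
  trials$distractor_present <- as.logical(trials$distractor_present)
  rownames(trials) <- NULL

  if (is.null(conditions))
    conditions <- unique(c(critical_condition, baseline_condition,
                           trials$condition))
  x <- structure(
    list(trials = trials,
         conditions = as.character(conditions),
         critical_condition = as.character(critical_condition),
         baseline_condition = as.character(baseline_condition),
         set_size = as.integer(set_size),
         n_nontargets = as.integer(n_nontargets),
         time_limit_ms = as.numeric(time_limit_ms),
         direction = as.character(direction),
         paradigm = as.character(paradigm)),
    class = "trialdata")
  validate_trialdata(x)
  x
}

#' Validate a trialdata object
#'
#' Checks every dataset invariant and reports *all* violating rows, not just
#' the first: latencies positive and within the time limit, condition labels
#' inside the declared set, `first_fixation` categories admissible,
#' distractor-first fixations only on distractor-present trials, and the
#' critical/baseline pair well-formed.
#'
#' @param x a [trial_dataset()].
#' @return `x` invisibly; errors with a message listing offending rows
#'   otherwise.
#' @export
validate_trialdata <- function(x) {
  stopifnot(inherits(x, "trialdata"))
  tr <- x$trials
  problems <- character(0)

  if (length(x$critical_condition) != 1L || length(x$baseline_condition) != 1L ||
      x$critical_condition == x$baseline_condition)
    problems <- c(problems,
                  "critical_condition and baseline_condition must be two distinct labels")
  if (length(x$direction) != 2L ||
      !all(x$direction %in% x$conditions))
    problems <- c(problems,
                  "direction must name two declared conditions (minuend, subtrahend)")
  if (!all(c(x$critical_condition, x$baseline_condition) %in% x$conditions))
    problems <- c(problems, "critical/baseline pair must be in the declared condition set")
  if (!is.na(x$time_limit_ms) && x$time_limit_ms <= 0)
    problems <- c(problems, "time_limit_ms must be positive")
  if (x$n_nontargets < 1L)
    problems <- c(problems, "n_nontargets must be >= 1")

  if (nrow(tr) > 0L) {
    bad_rows <- function(mask, what) {
      mask[is.na(mask)] <- FALSE
      if (any(mask))
        sprintf("%s (rows %s)", what,
                paste(utils::head(which(mask), 25L), collapse = ", "))
      else character(0)
    }
    problems <- c(
      problems,
      bad_rows(!(tr$condition %in% x$conditions),
               "condition label not in declared set"),
      bad_rows(!(tr$first_fixation %in%
                   c("distractor", "target", "nontarget", "none")),
               "invalid first_fixation category"),
      bad_rows(!is.na(tr$latency_ms) & tr$latency_ms <= 0,
               "latency_ms must be > 0 when present"),
      bad_rows(!is.na(tr$latency_ms) & tr$latency_ms > x$time_limit_ms,
               "latency_ms exceeds the paradigm time limit"),
      bad_rows(tr$first_fixation == "distractor" & !tr$distractor_present,
               "first_fixation = distractor on a distractor-absent trial"),
      bad_rows(is.na(tr$run_index) | tr$run_index < 0L,
               "run_index must be a non-negative integer"),
      bad_rows(is.na(tr$trial_index) | tr$trial_index < 0L,
               "trial_index must be a non-negative integer"),
      bad_rows(grepl(",", tr$subject_id, fixed = TRUE),
               "subject_id must not contain commas"))

    for (cc in c(x$critical_condition, x$baseline_condition))
      if (!any(tr$condition == cc))
        problems <- c(problems,
                      sprintf("declared condition '%s' has no trials", cc))
  }

  if (length(problems) > 0L)
    stop("invalid trial dataset:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(x)
}

#' @export
print.trialdata <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("Trial dataset [%s]\n",
              if (nzchar(x$paradigm)) x$paradigm else "unlabelled"))
  cat(sprintf("  %d trials, %d subjects, %d run(s)\n",
              nrow(tr), length(unique(tr$subject_id)),
              length(unique(tr$run_index))))
  cat(sprintf("  contrast: %s vs %s (difference = %s - %s)\n",
              x$critical_condition, x$baseline_condition,
              x$direction[1], x$direction[2]))
  cat(sprintf("  set size %d, time limit %g ms\n",
              x$set_size, x$time_limit_ms))
  invisible(x)
}

#' @export
summary.trialdata <- function(object, ...) {
  tr <- object$trials
  tab <- table(condition = tr$condition, first_fixation = tr$first_fixation)
  print(object)
  cat("\nFirst-fixation counts by condition:\n")
  print(tab)
  cat(sprintf("\nMissing latency (no target fixation): %d trials (%.1f%%)\n",
              sum(is.na(tr$latency_ms)),
              100 * mean(is.na(tr$latency_ms))))
  invisible(tab)
}

trial_columns <- c("subject_id", "run_index", "trial_index", "condition",
                   "first_fixation", "latency_ms", "distractor_present")

#' Read scored trials from the tidy CSV interchange format
#'
#' Reads a UTF-8, comma-separated, headered file with one scored trial per
#' row and the fixed column order written by [write_trials()].  Paradigm
#' metadata (the critical/baseline pair, set size, time limit) comes either
#' from a JSON sidecar written alongside the CSV (`<path>.json`) or from the
#' arguments, which override the sidecar.
#'
#' A missing latency (no target fixation within the time limit) is encoded by
#' an empty field.  Unknown condition labels, non-numeric latencies and other
#' invariant violations raise validation errors listing all offending rows.
#'
#' @param path CSV file path.
#' @param conditions optional declared condition set.
#' @inheritParams trial_dataset
#' @param ... further metadata passed to [trial_dataset()].
#' @return A validated [trial_dataset()]; row order is preserved.
#' @export
read_trials <- function(path, critical_condition = NULL,
                        baseline_condition = NULL, set_size = NULL,
                        time_limit_ms = NULL, conditions = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(trial_columns, names(raw))
  if (length(missing_cols) > 0L)
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  lat <- raw$latency_ms
  lat[!nzchar(trimws(lat))] <- NA_character_
  lat_num <- suppressWarnings(as.numeric(lat))
  bad_lat <- which(!is.na(lat) & is.na(lat_num))
  if (length(bad_lat) > 0L)
    stop("non-numeric latency_ms at data row(s): ",
         paste(utils::head(bad_lat, 25L), collapse = ", "), call. = FALSE)

  meta <- list(critical_condition = critical_condition,
               baseline_condition = baseline_condition,
               set_size = set_size, time_limit_ms = time_limit_ms,
               conditions = conditions)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (nm in names(meta))
      if (is.null(meta[[nm]]) && !is.null(side[[nm]]))
        meta[[nm]] <- side[[nm]]
    meta$n_nontargets <- side$n_nontargets
    meta$direction <- side$direction
    meta$paradigm <- side$paradigm
  }
  dots <- list(...)
  meta[names(dots)] <- dots
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (is.null(meta$critical_condition) || is.null(meta$baseline_condition) ||
      is.null(meta$set_size) || is.null(meta$time_limit_ms))
    stop("paradigm metadata (critical_condition, baseline_condition, ",
         "set_size, time_limit_ms) must be supplied as arguments or via a ",
         "'<path>.json' sidecar", call. = FALSE)

  trials <- data.frame(
    subject_id = raw$subject_id,
    run_index = as.integer(raw$run_index),
    trial_index = as.integer(raw$trial_index),
    condition = raw$condition,
    first_fixation = raw$first_fixation,
    latency_ms = lat_num,
    distractor_present = toupper(trimws(raw$distractor_present)) %in%
      c("TRUE", "T", "1"),
    stringsAsFactors = FALSE)

  bad_cond <- which(!(trials$condition %in%
                        unique(c(meta$conditions, meta$critical_condition,
                                 meta$baseline_condition))))
  if (!is.null(meta$conditions) && length(bad_cond) > 0L)
    stop("condition label not in declared set {",
         paste(meta$conditions, collapse = ", "), "} at data row(s): ",
         paste(utils::head(bad_cond, 25L), collapse = ", "), call. = FALSE)

  do.call(trial_dataset, c(list(trials = trials), meta))
}

#' Write scored trials to the tidy CSV interchange format
#'
#' Writes one trial per row with the fixed column order
#' `subject_id, run_index, trial_index, condition, first_fixation,
#' latency_ms, distractor_present`; latency is formatted to 1 decimal place
#' and missing latency becomes an empty field, so a read/write round trip is
#' byte-identical.  Unless `sidecar = FALSE`, the paradigm metadata is
#' written to `<path>.json` so the file is self-describing.
#'
#' @param dataset a [trial_dataset()].
#' @param path output CSV path.
#' @param sidecar write the metadata sidecar JSON next to the CSV?
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path, sidecar = TRUE) {
  validate_trialdata(dataset)
  tr <- dataset$trials
  lat <- ifelse(is.na(tr$latency_ms), "",
                sprintf("%.1f", tr$latency_ms))
  body <- data.frame(
    subject_id = tr$subject_id,
    run_index = tr$run_index,
    trial_index = tr$trial_index,
    condition = tr$condition,
    first_fixation = tr$first_fixation,
    latency_ms = lat,
    distractor_present = ifelse(tr$distractor_present, "TRUE", "FALSE"),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(trial_columns, collapse = ","), con)
  if (nrow(body) > 0L)
    writeLines(do.call(paste, c(unname(body), sep = ",")), con)
  if (isTRUE(sidecar)) {
    meta <- dataset[c("conditions", "critical_condition",
                      "baseline_condition", "set_size", "n_nontargets",
                      "time_limit_ms", "direction", "paradigm")]
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
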