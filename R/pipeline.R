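pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("ocureliab")),
           error = function(e) "unknown")
}

split_half_record <- function(fit, precision = 3) {
  list(measure = fit$measure,
       direction = fit$direction,
       n_subjects = fit$n_subjects,
       mean_r = round(fit$mean_r, precision),
       sb_r = round(fit$sb_r, precision),
       ci_r = round(unname(fit$ci_r), precision),
       ci_sb = round(unname(fit$ci_sb), precision),
       level = fit$level,
       n_perm = fit$n_perm,
       n_undefined = fit$n_undefined,
       excluded_subjects = as.character(fit$excluded_subjects),
       seed = fit$seed,
       version = pkg_version(),
       permutation_r = fit$permutation_r)
}

#' Simulate a dataset and write it to disk
#'
#' Generates a synthetic cohort from a [sim_config()] and writes the trial
#' CSV (with its metadata sidecar) plus the fully resolved configuration as
#' `<path>.config.json`, so the file records exactly how it was produced.
#'
#' @param config a [sim_config()].
#' @param path output CSV path.
#' @return The generated [trial_dataset()], invisibly.
#' @export
run_simulate <- function(config, path) {
  d <- generate_dataset(config)
  write_trials(d, path)
  cfg <- unclass(config)
  cfg$version <- pkg_version()
  jsonlite::write_json(cfg, paste0(path, ".config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(d)
}

#' Run the split-half reliability pipeline and write JSON results
#'
#' End-to-end driver: reads (or accepts) a trial dataset, runs the permuted
#' split-half engine for each requested measure, logs excluded subjects and
#' undefined-permutation counts to `stderr`, and writes one JSON result
#' record per measure (including the raw permutation-coefficient vector,
#' which [run_compare()] consumes).
#'
#' @param input a [trial_dataset()] or a CSV path readable by
#'   [read_trials()].
#' @param measures measures to analyse.
#' @param n_perm,seed,level passed to [split_half()].
#' @param outdir output directory (created if needed); files are named
#'   `reliability_<measure>.json`.
#' @param precision decimals for reported r-type quantities (default 3).
#' @param ... further arguments to [split_half()].
#' @return Named list of [split_half()] fits, invisibly.
#' @export
run_reliability <- function(input, measures = c("capture", "fixation_time"),
                            n_perm = 1000, seed, outdir, precision = 3,
                            level = 0.95, ...) {
  dataset <- if (inherits(input, "trialdata")) input else read_trials(input)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fits <- lapply(measures, function(m) {
    fit <- split_half(dataset, m, n_perm = n_perm, seed = seed,
                      level = level, ...)
    if (length(fit$excluded_subjects) > 0L)
      message(sprintf("[%s] excluded subjects: %s", m,
                      paste(fit$excluded_subjects, collapse = ", ")))
    if (fit$n_undefined > 0L)
      message(sprintf("[%s] %d undefined permutation(s) excluded", m,
                      fit$n_undefined))
    jsonlite::write_json(split_half_record(fit, precision),
                         file.path(outdir,
                                   sprintf("reliability_%s.json", m)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fit
  })
  names(fits) <- measures
  invisible(fits)
}

#' Run the reliability-comparison randomization test and write JSON
#'
#' Compares two split-half analyses — given as [split_half()] fits, as JSON
#' result files written by [run_reliability()], or as datasets — with
#' [randomization_test()] / [compare_reliability()], and writes the result
#' record.
#'
#' @param a,b [split_half()] fits, paths to `reliability_*.json` files, or
#'   [trial_dataset()]s.
#' @param seed seed for the randomization test.
#' @param n_iter number of re-partitions.
#' @param path output JSON path.
#' @param precision decimals for reported quantities.
#' @param ... passed to [compare_reliability()].
#' @return The `rel_compare` result, invisibly.
#' @export
run_compare <- function(a, b, seed, n_iter = 1000, path, precision = 3,
                        ...) {
  load_pool <- function(x) {
    if (is.character(x)) {
      rec <- jsonlite::read_json(x, simplifyVector = TRUE)
      if (is.null(rec$permutation_r))
        stop("not a reliability result file: ", x, call. = FALSE)
      return(rec$permutation_r)
    }
    x
  }
  a <- load_pool(a)
  b <- load_pool(b)
  res <- if (is.numeric(a) && is.numeric(b))
    randomization_test(a, b, n_iter = n_iter, seed = seed)
  else compare_reliability(a, b, seed = seed, n_iter = n_iter, ...)
  rec <- list(observed_diff = round(res$observed_diff, precision),
              z_stat = round(res$z_stat, precision),
              p_value = res$p_value,
              p_empirical = res$p_empirical,
              null_mean = round(mean(res$null_diffs), precision + 2),
              null_sd = round(stats::sd(res$null_diffs), precision + 2),
              n_iter = res$n_iter,
              degenerate = res$degenerate,
              seed = res$seed,
              version = pkg_version())
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(res)
}
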