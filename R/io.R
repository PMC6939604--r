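#' Write and read trial-level CPT-AX data as CSV
#'
#' One row per trial with columns `child_id`, `block_index`, `trial_index`,
#' `stimulus_role`, `trial_type`, `responded` (0/1) and `rt_ms` (empty when
#' no response was made); UTF-8 with a header row.
#'
#' @param trials trial-level data frame (see [simulate_cohort_trials()]; a
#'   single session without a `child_id` column is also accepted by
#'   `write_trials_csv()` and given the id `"s01"`).
#' @param path file path.
#' @return `write_trials_csv()` returns `path` invisibly;
#'   `read_trials_csv()` returns the trial-level data frame with logical
#'   `responded` and numeric `rt_ms`.
#' @export
write_trials_csv <- function(trials, path) {
  d <- as.data.frame(trials)
  if (!"child_id" %in% names(d)) d <- cbind(child_id = "s01", d)
  d <- d[c("child_id", "block_index", "trial_index", "stimulus_role",
           "trial_type", "responded", "rt_ms")]
  d$responded <- as.integer(d$responded)
  utils::write.csv(d, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  d$responded <- d$responded == 1L
  d$rt_ms <- as.numeric(d$rt_ms)
  d
}

#' Write a cohort table as CSV
#'
#' Demographic columns first, then any latent generator columns (already
#' prefixed `synthetic_` to flag their provenance).
#'
#' @param cohort data frame from [generate_cohort()] (or any per-child
#'   table with a `child_id` column).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' A hand-constructed toy session with documented scoring answers
#'
#' Loads the deterministic 400-trial fixture stored with the package. The
#' fixture follows a regular within-block layout (go pairs at positions
#' 1-2, 11-12, ..., cue-only at 5, 15, ..., uncued targets at 8, 18, ...)
#' and carries hand-scored responses:
#' \itemize{
#'   \item 36 go trials answered at 400, 410, ..., 750 ms (in-window hits),
#'   \item 2 go trials answered at 150 ms (anticipations, scored as misses),
#'   \item 2 go trials with no response,
#'   \item 9 no-go responses at 500 ms.
#' }
#' Hand-counted ground truth: hit rate 90% (36/40), commissions 2.5%
#' (9/360), mean hit RT 575 ms, SD of hit RT 105.3565 ms (sample SD of an
#' arithmetic 400..750 grid).
#'
#' @return A `"cpt_session"` data frame.
#' @export
fixture_toy_session <- function() {
  path <- system.file("extdata", "toy_session.csv", package = "cptddm",
                      mustWork = TRUE)
  d <- read_trials_csv(path)
  d$child_id <- NULL
  attr(d, "stimulus_duration_ms") <- CPT_STIMULUS_MS
  attr(d, "isi_ms") <- CPT_ISI_MS
  attr(d, "deadline_ms") <- CPT_DEADLINE_MS
  class(d) <- c("cpt_session", "data.frame")
  validate_session(d)
  d
}
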