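#' Standard task-performance measures for a scored session
#'
#' Computes the four conventional CPT-AX outcome measures. A *hit* is a go
#' trial with a response between 200 and 1650 ms from stimulus onset;
#' responses faster than 200 ms are treated as anticipations and count as
#' misses (they are excluded from the accuracy numerator, not merely from
#' the RT pool). A *commission error* is any response on a no-go trial.
#'
#' @param session a scored `"cpt_session"` data frame (responses filled in).
#' @param rt_window numeric length-2: the valid response window in ms
#'   (default `c(200, 1650)`).
#' @return A list of class `"cpt_measures"`: `hit_rate_pct` (percent of the
#'   40 go trials hit), `commission_pct` (percent of the 360 no-go trials
#'   with a response), `mrt_ms` and `sdrt_ms` (mean and sample SD of hit
#'   RTs; `NA` when fewer than one / two hits exist) and `n_hits`.
#' @examples
#' s <- generate_trial_sequence(seed = 1)
#' s$responded[s$trial_type == "go"] <- TRUE
#' s$rt_ms[s$trial_type == "go"] <- 500
#' score_session(s)
#' @export
score_session <- function(session, rt_window = c(200, 1650)) {
  validate_session(session)
  go <- session$trial_type == "go"
  hit <- go & session$responded &
    !is.na(session$rt_ms) &
    session$rt_ms >= rt_window[1] & session$rt_ms <= rt_window[2]
  n_go <- sum(go)
  n_nogo <- sum(!go)
  hit_rts <- session$rt_ms[hit]
  structure(list(
    hit_rate_pct = 100 * sum(hit) / n_go,
    commission_pct = 100 * sum(session$responded[!go]) / n_nogo,
    mrt_ms = if (length(hit_rts) >= 1L) mean(hit_rts) else NA_real_,
    sdrt_ms = if (length(hit_rts) >= 2L) stats::sd(hit_rts) else NA_real_,
    n_hits = sum(hit)
  ), class = "cpt_measures")
}

#' @export
print.cpt_measures <- function(x, ...) {
  cat(sprintf("hit rate %.1f%% (%d hits), commissions %.2f%%, MRT %s ms, SDRT %s ms\n",
              x$hit_rate_pct, x$n_hits, x$commission_pct,
              if (is.na(x$mrt_ms)) "NA" else sprintf("%.0f", x$mrt_ms),
              if (is.na(x$sdrt_ms)) "NA" else sprintf("%.0f", x$sdrt_ms)))
  invisible(x)
}

#' EZ-model input moments from a scored session
#'
#' Derives the three summary statistics the EZ transform consumes, using
#' the same hit definition as [score_session()] (so `pc` equals the hit
#' rate divided by 100): proportion correct over the 40 go trials, mean hit
#' RT in seconds, and the sample variance of hit RT in seconds squared.
#' Sub-200 ms responses contribute to neither the accuracy numerator nor
#' the RT moments.
#'
#' @inheritParams score_session
#' @return A list with `pc`, `mrt` (s), `vrt` (s^2) and `n_hits`.
#'   Fewer than two hits is an error (the RT variance is undefined);
#'   `pc = 1` is returned as-is and triggers exclusion downstream in
#'   [ez_fit()].
#' @export
ez_inputs_from_session <- function(session, rt_window = c(200, 1650)) {
  m <- score_session(session, rt_window)
  if (m$n_hits <= 1L)
    stop("ez_inputs_from_session: insufficient data (", m$n_hits,
         " hits); RT variance undefined", call. = FALSE)
  go <- session$trial_type == "go"
  hit_rts <- session$rt_ms[go & session$responded &
                             !is.na(session$rt_ms) &
                             session$rt_ms >= rt_window[1] &
                             session$rt_ms <= rt_window[2]] / 1000
  list(pc = m$n_hits / sum(go), mrt = mean(hit_rts),
       vrt = stats::var(hit_rts), n_hits = m$n_hits)
}
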