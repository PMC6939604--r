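# Build a deterministic scored session: go trials get the supplied RTs in
# order (NA = no response), no-go responses placed on the first
# `n_commissions` no-go trials at `commission_rt` ms.
scored_session <- function(go_rts, n_commissions = 0, commission_rt = 500,
                           seed = 1) {
  s <- generate_trial_sequence(seed)
  go <- which(s$trial_type == "go")
  stopifnot(length(go_rts) <= length(go))
  rts <- rep(NA_real_, length(go))
  rts[seq_along(go_rts)] <- go_rts
  s$responded[go] <- !is.na(rts)
  s$rt_ms[go] <- rts
  if (n_commissions > 0) {
    nogo <- which(s$trial_type != "go")[seq_len(n_commissions)]
    s$responded[nogo] <- TRUE
    s$rt_ms[nogo] <- commission_rt
  }
  s
}

# Small per-child analysis table with the structure cohort_table() yields,
# drawn directly from distributions (no diffusion simulation); `r_vy`
# controls how strongly v tracks the response.
toy_analysis_table <- function(n_vp = 33, n_term = 32, seed = 1,
                               r_vy = -0.5) {
  set.seed(seed)
  n <- n_vp + n_term
  grp <- c(rep("VP", n_vp), rep("term", n_term))
  v <- rnorm(n, 0.2, 0.09)
  swan <- r_vy * scale(v)[, 1] * 10 + rnorm(n, 0, 10 * sqrt(1 - r_vy^2))
  data.frame(
    child_id = sprintf("c%02d", seq_len(n)), group = grp,
    age_years = rnorm(n, 9.4, 1), swan_inattention = swan,
    commission_pct = pmax(0, rnorm(n, 2.4, 1.5)),
    hit_rate_pct = pmin(97.5, 100 * plogis(rnorm(n, 2, 0.8))),
    mrt_ms = rnorm(n, 480, 60), sdrt_ms = pmax(50, rnorm(n, 168, 40)),
    v = v, a = pmax(0.03, rnorm(n, 0.112, 0.02)),
    ter = pmax(0.05, rnorm(n, 0.26, 0.07)),
    stringsAsFactors = FALSE)
}

# One full synthetic replicate: cohort -> trials -> EZ fit -> analysis table
pipeline_replicate <- function(seed, config = cohort_config()) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 2)
  coh <- generate_cohort(config, seed = seeds[1])
  fit <- ezddm(simulate_cohort_trials(coh, seed = seeds[2]), cohort = coh)
  cohort_table(fit)
}
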