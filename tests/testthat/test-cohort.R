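test_that("default cohorts have the configured two-group structure", {
  coh <- generate_cohort(cohort_config(), seed = 7)
  expect_identical(nrow(coh), 65L)
  expect_identical(sum(coh$group == "VP"), 33L)
  expect_identical(sum(coh$group == "term"), 32L)
  expect_true(all(coh$synthetic_v > 0))
  expect_true(all(coh$synthetic_a > 0))
  expect_true(all(coh$synthetic_ter >= 0.05))
  expect_true(all(coh$synthetic_commission_rate >= 0 &
                    coh$synthetic_commission_rate <= 1))
  expect_identical(sum(is.na(coh$swan_inattention)), 1L)
  expect_true(all(coh$group[is.na(coh$swan_inattention)] == "term"))
  expect_identical(coh, generate_cohort(cohort_config(), seed = 7))
})

test_that("degenerate and invalid configurations behave as specified", {
  cfg <- cohort_config(swan_sd = c(vp = 0, term = 0), n_swan_missing_term = 0L)
  coh <- generate_cohort(cfg, seed = 1)
  expect_true(all(coh$swan_inattention[coh$group == "VP"] == -0.70))
  expect_true(all(coh$swan_inattention[coh$group == "term"] == -6.58))
  expect_error(cohort_config(n_vp = 0L), "group sizes")
  expect_error(cohort_config(a_sd = -1), "SDs")
  expect_error(cohort_config(frobnicate = 2), "unknown")
})

test_that("replicate cohorts match the configured SWAN moments", {
  cfg <- cohort_config(n_swan_missing_term = 0L)
  means <- vapply(1:200, function(i) {
    coh <- generate_cohort(cfg, seed = 1000 + i)
    mean(coh$swan_inattention[coh$group == "VP"])
  }, numeric(1))
  se <- 9.89 / sqrt(33 * 200)
  expect_lt(abs(mean(means) - (-0.70)), 2 * se)
})

test_that("simulated sessions respect the response mechanisms", {
  template <- generate_trial_sequence(1)
  child <- generate_cohort(cohort_config(), seed = 2)[1, ]
  child$synthetic_commission_rate <- 0
  s <- simulate_child_session(child, template, seed = 3)
  expect_silent(validate_session(s))
  expect_identical(sum(s$responded[s$trial_type != "go"]), 0L)

  # overwhelming drift: essentially certain hits well inside the deadline
  child$synthetic_v <- 2.11; child$synthetic_ter <- 0.25
  s2 <- simulate_child_session(child, template, seed = 4)
  expect_identical(sum(s2$responded[s2$trial_type == "go"]), 40L)

  child$synthetic_v <- NA
  expect_error(simulate_child_session(child, template, seed = 5), "latent")
})

test_that("child-session hit proportion matches the analytic forward rate", {
  child <- data.frame(synthetic_v = 0.211, synthetic_a = 0.112,
                      synthetic_ter = 0.253, synthetic_commission_rate = 0)
  template <- generate_trial_sequence(1)
  n_sessions <- 200                       # 8000 go trials
  hits <- vapply(seq_len(n_sessions), function(i) {
    s <- simulate_child_session(child, template, seed = 100 + i)
    sum(s$responded[s$trial_type == "go"])
  }, numeric(1))
  p_hat <- sum(hits) / (40 * n_sessions)
  pc <- ez_forward(0.211, 0.112, 0.253)$pc
  se <- sqrt(pc * (1 - pc) / (40 * n_sessions))
  # deadline censoring removes a sliver of slow hits; allow it alongside
  # Monte-Carlo error and Euler bias
  expect_lt(abs(p_hat - pc), 3 * se + 0.015 * pc)
})

test_that("cohort trial data are reproducible and analysis-clean", {
  cfg <- cohort_config(n_vp = 3L, n_term = 3L)
  coh <- generate_cohort(cfg, seed = 5)
  t1 <- simulate_cohort_trials(coh, seed = 6)
  t2 <- simulate_cohort_trials(coh, seed = 6)
  expect_identical(t1, t2)
  expect_identical(nrow(t1), 6L * 400L)
  fit <- ezddm(t1, cohort = coh)
  tab <- cohort_table(fit, drop_excluded = FALSE)
  expect_false(any(grepl("^synthetic_", names(tab))))
})
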