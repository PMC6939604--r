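small_fit <- local({
  cfg <- cohort_config(n_vp = 5L, n_term = 5L)
  coh <- generate_cohort(cfg, seed = 31)
  ezddm(simulate_cohort_trials(coh, seed = 32), cohort = coh)
})

test_that("ezddm fits every child and flags perfect scorers", {
  p <- small_fit$parameters
  expect_identical(nrow(p), 10L)
  ok <- !p$excluded
  expect_true(all(is.finite(p$v[ok])))
  expect_true(all(p$exclusion_reason[p$excluded] %in%
                    c("perfect_accuracy", "null_accuracy",
                      "insufficient_hits", "chance_accuracy")))
  expect_true(all(is.na(p$v[p$excluded])))
  # per-child estimates invert the per-child observed moments exactly
  i <- which(ok)[1]
  fw <- ez_forward(p$v[i], p$a[i], p$ter[i])
  expect_equal(fw$pc, p$pc[i], tolerance = 1e-12)
  expect_equal(fw$mrt, p$mrt_s[i], tolerance = 1e-12)
  expect_equal(fw$vrt, p$vrt_s2[i], tolerance = 1e-12)
})

test_that("a child with a perfect session is excluded with the spec reason", {
  trials <- cbind(child_id = "kid", as.data.frame(scored_session(rep(500, 40))))
  fit <- ezddm(trials)
  expect_true(fit$parameters$excluded)
  expect_identical(fit$parameters$exclusion_reason, "perfect_accuracy")
})

test_that("the S3 surface behaves: print, summary, coef, predict, simulate", {
  expect_output(print(small_fit), "EZ diffusion model fit")
  sm <- summary(small_fit)
  expect_true(all(c("group", "n", "v", "a", "ter") %in% names(sm)))
  cm <- coef(small_fit)
  expect_identical(colnames(cm), c("v", "a", "ter"))
  pr <- predict(small_fit)
  ok <- !small_fit$parameters$excluded
  expect_equal(pr$pc[ok], small_fit$parameters$pc[ok], tolerance = 1e-12)
  tr <- simulate(small_fit, nsim = 50, seed = 1)
  expect_identical(nrow(tr), 50L * length(unique(tr$group)))
  expect_identical(tr, simulate(small_fit, nsim = 50, seed = 1))
})

test_that("supersubject averaging equals each child when children coincide", {
  s1 <- scored_session(seq(420, 800, by = 10), seed = 3)   # identical kids, 39 hits
  trials <- rbind(cbind(child_id = "a", as.data.frame(s1)),
                  cbind(child_id = "b", as.data.frame(s1)))
  fit <- ezddm(trials)
  avg <- cptddm:::supersubject_parameters(fit)
  expect_equal(avg$v, fit$parameters$v[1])
  expect_equal(avg$a, fit$parameters$a[1])
  expect_equal(avg$ter, fit$parameters$ter[1])
})

test_that("goodness of fit returns per-group tables with sane quantiles", {
  gof <- goodness_of_fit(small_fit, n_trials = 400, seed = 9)
  expect_setequal(gof$group, c("VP", "term"))
  expect_true(all(gof$sim_accuracy_pct >= 0 & gof$sim_accuracy_pct <= 100))
  q <- as.matrix(gof[paste0("q", c(10, 30, 50, 70, 90))])
  expect_true(all(apply(q, 1, function(x) all(diff(x) >= 0))))
  expect_identical(gof, goodness_of_fit(small_fit, n_trials = 400, seed = 9))
})

test_that("supersubject accuracy converges to the forward prediction", {
  gof <- goodness_of_fit(small_fit, n_trials = 100000, seed = 10)
  avg <- cptddm:::supersubject_parameters(small_fit)
  for (i in seq_len(nrow(gof))) {
    pc <- ez_forward(avg$v[i], avg$a[i], avg$ter[i])$pc
    se <- sqrt(pc * (1 - pc) / 100000)
    expect_lt(abs(gof$sim_accuracy_pct[i] / 100 - pc), 3 * se + 0.015 * pc)
  }
})

test_that("plot method runs headlessly and returns the GoF table", {
  pdf(NULL)
  on.exit(dev.off())
  gof <- plot(small_fit, n_trials = 200, seed = 2)
  expect_s3_class(gof, "ezddm_gof")
})
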