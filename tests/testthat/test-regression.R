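# independent stepwise oracle: greedy forward/backward selection computed
# from raw R-squared increments and the partial-F distribution, no add1()
stepwise_oracle <- function(d, response, forced, candidates,
                            p_enter = 0.05, p_remove = 0.10) {
  r2 <- function(preds) summary(lm(reformulate(preds, response), d))$r.squared
  partial_p <- function(base, extra) {
    n <- nrow(d)
    k_full <- length(base) + 1
    f <- (r2(c(base, extra)) - r2(base)) /
      ((1 - r2(c(base, extra))) / (n - k_full - 1))
    pf(f, 1, n - k_full - 1, lower.tail = FALSE)
  }
  entered <- character(0)
  remaining <- candidates
  repeat {
    changed <- FALSE
    if (length(remaining)) {
      ps <- vapply(remaining, function(cnd)
        partial_p(c(forced, entered), cnd), numeric(1))
      if (min(ps) <= p_enter) {
        entered <- c(entered, remaining[which.min(ps)])
        remaining <- setdiff(remaining, entered)
        changed <- TRUE
      }
    }
    if (length(entered)) {
      ps <- vapply(entered, function(cnd)
        partial_p(c(forced, setdiff(entered, cnd)), cnd), numeric(1))
      if (max(ps) >= p_remove) {
        worst <- entered[which.max(ps)]
        entered <- setdiff(entered, worst)
        remaining <- union(remaining, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  entered
}

test_that("stepwise selection matches the independent partial-F oracle", {
  for (seed in c(11, 12, 13, 14)) {
    tab <- toy_analysis_table(33, 31, seed = seed)
    res <- hierarchical_stepwise_regression(tab)
    d <- tab
    d$group <- as.numeric(d$group != "term")
    sel <- stepwise_oracle(d, "swan_inattention", c("group", "age_years"),
                           c("hit_rate_pct", "sdrt_ms", "v"))
    expect_setequal(attr(res, "selected"), sel)
  }
})

test_that("regression degrees of freedom track the analysis sample size", {
  tab <- toy_analysis_table(33, 31, seed = 11)   # N = 64 complete rows
  res <- hierarchical_stepwise_regression(tab)
  m1 <- res[[1]]
  expect_identical(m1$n, 64L)
  expect_equal(unname(c(m1$df1, m1$df2)), c(2, 61))
  if (length(res) > 1) {
    m2 <- res[[2]]
    expect_equal(m2$df2, 64 - length(m2$predictors) - 1)
    expect_gte(m2$delta_r_squared, 0)
  }
})

test_that("an orthogonal candidate is never entered", {
  tab <- toy_analysis_table(30, 30, seed = 5, r_vy = -0.6)
  set.seed(99)
  # residualise noise against everything so it carries no partial signal
  noise <- rnorm(nrow(tab))
  tab$noise <- resid(lm(noise ~ swan_inattention + group0 + age_years +
                          hit_rate_pct + sdrt_ms + v,
                        data = transform(tab,
                                         group0 = as.numeric(group != "term"))))
  res <- hierarchical_stepwise_regression(
    tab, candidates = c("hit_rate_pct", "sdrt_ms", "v", "noise"))
  expect_false("noise" %in% attr(res, "selected"))
})

test_that("coefficients are standardized betas on z-scored variables", {
  tab <- toy_analysis_table(33, 31, seed = 21, r_vy = -0.6)
  res <- hierarchical_stepwise_regression(tab)
  d <- tab[complete.cases(tab[c("swan_inattention", "group", "age_years",
                                "hit_rate_pct", "sdrt_ms", "v")]), ]
  d$group <- as.numeric(d$group != "term")
  zd <- as.data.frame(scale(d[c("swan_inattention", "group", "age_years")]))
  ref <- coef(lm(swan_inattention ~ group + age_years, data = zd))
  co <- res[[1]]$coefficients
  expect_equal(co$beta[co$term == "group"], unname(ref["group"]),
               tolerance = 1e-12)
  expect_equal(co$beta[co$term == "age_years"], unname(ref["age_years"]),
               tolerance = 1e-12)
})

test_that("collinear designs are rejected with the offending column named", {
  tab <- toy_analysis_table(20, 20, seed = 6)
  tab$v_copy <- tab$v
  expect_error(
    hierarchical_stepwise_regression(
      tab, forced = c("group", "age_years", "v", "v_copy"),
      candidates = "hit_rate_pct"),
    "v_copy")
})

test_that("interaction step is invariant to measure location shifts", {
  tab <- toy_analysis_table(32, 32, seed = 7, r_vy = -0.5)
  r1 <- interaction_regression(tab)
  shifted <- tab
  shifted$v <- shifted$v + 100
  shifted$hit_rate_pct <- shifted$hit_rate_pct - 55
  r2 <- interaction_regression(shifted)
  expect_equal(r1[[3]]$delta_r_squared, r2[[3]]$delta_r_squared,
               tolerance = 1e-10)
  expect_equal(r1[[3]]$delta_p, r2[[3]]$delta_p, tolerance = 1e-10)
})

test_that("interaction step 1 equals stepwise Model 1 on the same rows", {
  tab <- toy_analysis_table(33, 31, seed = 8)
  a <- hierarchical_stepwise_regression(tab)[[1]]
  b <- interaction_regression(tab)[[1]]
  expect_equal(a$r_squared, b$r_squared)
  expect_equal(a$coefficients$beta, b$coefficients$beta)
  expect_equal(unname(c(a$F, a$df1, a$df2)), unname(c(b$F, b$df1, b$df2)))
})

test_that("with ample power the stepwise procedure retains drift rate", {
  # drift-mediated coupling at a cohort size where entry power is high:
  # drift should be retained in the large majority of replicates
  cfg <- cohort_config(n_vp = 150L, n_term = 150L)
  hits <- vapply(1:20, function(i) {
    tab <- pipeline_replicate(seed = 800 + i, config = cfg)
    "v" %in% attr(hierarchical_stepwise_regression(tab), "selected")
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("under a group-homogeneous data law the interaction adds nothing", {
  set.seed(42)
  n <- 5000
  grp <- rep(c("VP", "term"), each = n / 2)
  v <- rnorm(n, 0.2, 0.09)
  tab <- data.frame(
    group = grp, age_years = rnorm(n, 9.4, 1),
    swan_inattention = -40 * v + rnorm(n, 0, 8),   # identical slope per group
    hit_rate_pct = rnorm(n, 86, 8), sdrt_ms = rnorm(n, 168, 40), v = v)
  r <- interaction_regression(tab)
  expect_lt(r[[3]]$delta_r_squared, 0.002)
  expect_gt(r[[3]]$delta_p, 0.001)
})
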