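test_that("partial correlation reduces to Pearson and to the textbook formula", {
  set.seed(1)
  n <- 10000
  z <- rnorm(n); x <- z + rnorm(n); y <- z + rnorm(n)
  expect_equal(partial_correlation(x, y)$r, cor(x, y))
  expect_equal(partial_correlation(x, x)$r, 1)
  res <- partial_correlation(x, y, controls = z)
  # closed-form first-order partial correlation on the same sample
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(res$r, oracle, tolerance = 1e-12)
  expect_lt(abs(res$r), 3 / sqrt(n))      # true partial correlation is 0
  expect_identical(res$k, 1L)
})

test_that("partial correlation handles missing rows and degenerate input", {
  x <- c(1, 2, 3, 4, 5, NA, 7, 8)
  y <- c(2, 1, 4, 3, 6, 5, NA, 7)
  res <- partial_correlation(x, y)
  expect_identical(res$n, 6L)
  expect_error(partial_correlation(rep(1, 10), rnorm(10)), "zero residual")
  expect_error(partial_correlation(1:4, 1:4, controls = rnorm(4)), "at least")
})

test_that("partial-correlation p-values follow the t reference distribution", {
  res <- partial_correlation(rnorm(30) + 1:30, rnorm(30) + 1:30,
                             controls = 1:30)
  t_manual <- res$r * sqrt((res$n - 2 - res$k) / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(t_manual), res$n - 3))
})

test_that("Fisher comparison reproduces the published worked examples", {
  hit <- fisher_compare(-0.369, 33, -0.418, 31)
  expect_equal(round(hit$z, 2), 0.22)
  expect_equal(round(hit$p, 2), 0.83)
  drift <- fisher_compare(-0.364, 33, -0.435, 31)
  expect_equal(round(drift$z, 2), 0.32)
  expect_equal(round(drift$p, 2), 0.75)
})

test_that("Fisher comparison is antisymmetric and guards its domain", {
  a <- fisher_compare(0.3, 40, 0.5, 35)
  b <- fisher_compare(0.5, 35, 0.3, 40)
  expect_equal(a$z, -b$z)
  expect_equal(fisher_compare(0.4, 20, 0.4, 50)$z, 0)
  expect_error(fisher_compare(1, 20, 0.4, 50), "atanh")
  expect_error(fisher_compare(0.2, 3, 0.4, 50), "n1 > 3")
})

test_that("MANCOVA degrees of freedom follow the Pillai approximation", {
  tab <- toy_analysis_table(33, 32, seed = 2)
  res <- mancova_pillai(tab[c("commission_pct", "hit_rate_pct", "mrt_ms",
                              "sdrt_ms", "v", "a", "ter")],
                        tab$group, tab$age_years)
  expect_identical(res$df1, c(7, 7))
  expect_identical(res$df2, c(56, 56))
  expect_true(all(res$pillai >= 0 & res$pillai <= 1))
})

test_that("a single outcome reduces Pillai to the univariate ANCOVA F", {
  tab <- toy_analysis_table(20, 20, seed = 3)
  res <- mancova_pillai(tab["v"], tab$group, tab$age_years)
  fit <- lm(v ~ group + age_years, data = tab)
  dr <- drop1(fit, test = "F")
  expect_equal(res$F[res$effect == "group"], dr["group", "F value"])
  expect_equal(res$F[res$effect == "covariate"], dr["age_years", "F value"])
  expect_equal(res$F, (res$pillai / (1 - res$pillai)) * (res$df2 / res$df1))
})

test_that("Pillai statistics match an independent Type-III computation", {
  skip_if_not_installed("car")
  tab <- toy_analysis_table(12, 8, seed = 4)
  Y <- as.matrix(tab[c("v", "mrt_ms", "sdrt_ms")])
  res <- mancova_pillai(Y, tab$group, tab$age_years)
  fit <- lm(Y ~ group + age_years, data = tab)
  ca <- car::Anova(fit, type = "III", test.statistic = "Pillai")
  sm <- summary(ca, multivariate = TRUE)$multivariate.tests
  for (eff in c("group", "age_years")) {
    st <- sm[[eff]]
    V <- sum(diag(st$SSPH %*% solve(st$SSPH + st$SSPE)))
    mine <- res[res$effect == ifelse(eff == "group", "group", "covariate"), ]
    expect_equal(mine$pillai, V, tolerance = 1e-10)
  }
})
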