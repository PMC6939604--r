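#' Per-child analysis table from a fitted EZ model
#'
#' Merges the per-child standard measures and diffusion estimates with the
#' cohort covariates into the flat table consumed by the inferential stage.
#' Latent `synthetic_*` generator columns, if present, are dropped: the
#' analysis never reads ground truth.
#'
#' @param object an `"ezddm"` fit with a cohort attached.
#' @param drop_excluded drop children with undefined parameters
#'   (default `TRUE`).
#' @return A data frame, one row per child.
#' @export
cohort_table <- function(object, drop_excluded = TRUE) {
  stopifnot(inherits(object, "ezddm"))
  tab <- merge_cohort(object)
  tab <- tab[!grepl("^synthetic_", names(tab))]
  if (drop_excluded) tab <- tab[!tab$excluded, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Partial correlation by the residual method
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares projection onto an intercept and the control covariates.
#' With no controls this is the plain Pearson correlation. The two-sided
#' p-value uses \eqn{t = r\sqrt{(n-2-k)/(1-r^2)}} on \eqn{n-2-k} degrees of
#' freedom, `k` the number of controls.
#'
#' Rows with missing values in `x`, `y` or any control are dropped
#' (listwise).
#'
#' @param x,y numeric vectors of equal length.
#' @param controls optional numeric vector, matrix or data frame of control
#'   covariates.
#' @return A list of class `"partial_correlation"`: `r`, `n`, `k`, `t`, `p`.
#' @examples
#' set.seed(1)
#' z <- rnorm(200); x <- z + rnorm(200); y <- z + rnorm(200)
#' partial_correlation(x, y, controls = z)$r  # near zero
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  ctl <- if (is.null(controls)) NULL else as.matrix(controls)
  stopifnot(length(x) == length(y),
            is.null(ctl) || nrow(ctl) == length(x))
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(ctl)) ok <- ok & !apply(is.na(ctl), 1L, any)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- if (is.null(ctl)) 0L else ncol(ctl)
  if (n < k + 4L)
    stop("partial_correlation: need at least k + 4 complete rows",
         call. = FALSE)
  if (k > 0L) {
    ctl <- ctl[ok, , drop = FALSE]
    x <- stats::lm.fit(cbind(1, ctl), x)$residuals
    y <- stats::lm.fit(cbind(1, ctl), y)$residuals
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("partial_correlation: zero residual variance", call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - 2L - k
  t <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, n = n, k = k, t = t,
                 p = 2 * stats::pt(-abs(t), df)),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("partial r = %.3f (n = %d, %d control%s), p = %.4g\n",
              x$r, x$n, x$k, if (x$k == 1) "" else "s", x$p))
  invisible(x)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' Tests the equality of two correlation coefficients estimated in
#' independent samples using the arctanh (Fisher z) transform:
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'   {\sqrt{1/(n_1-3) + 1/(n_2-3)}}.}
#'
#' @param r1,r2 the two correlations, strictly inside (-1, 1).
#' @param n1,n2 the two sample sizes (> 3). For partial correlations the
#'   raw group sizes are used with the n - 3 variance term.
#' @return A list of class `"fisher_comparison"`: `z` and the two-sided
#'   normal `p`.
#' @examples
#' fisher_compare(-0.369, 33, -0.418, 31)  # z approx 0.22
#' @export
fisher_compare <- function(r1, n1, r2, n2) {
  stopifnot(n1 > 3, n2 > 3)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("fisher_compare: |r| must be < 1 (atanh infinite at 1)",
         call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z))),
            class = "fisher_comparison")
}

#' @export
print.fisher_comparison <- function(x, ...) {
  cat(sprintf("Fisher comparison: z = %.2f, p = %.2g\n", x$z, x$p))
  invisible(x)
}

#' MANCOVA with Pillai's trace and unique (Type-III) sums of squares
#'
#' Multivariate analysis of covariance of a set of outcome measures on a
#' between-subjects factor with a covariate. For each effect the hypothesis
#' cross-product matrix is formed as the increase in the error
#' cross-product when that term is dropped from the full model (unique /
#' Type-III sums of squares), Pillai's trace is
#' \eqn{V = \mathrm{tr}\,[H (H + E)^{-1}]}, and the standard F
#' approximation is applied: with `p` outcomes, `q` hypothesis df,
#' `s = min(p, q)`, `m = (|p - q| - 1)/2`, `u = (df_e - p - 1)/2`,
#' \deqn{F = \frac{2u + s + 1}{2m + s + 1} \cdot \frac{V/s}{1 - V/s}}
#' on \eqn{(s(2m + s + 1),\; s(2u + s + 1))} degrees of freedom. For a
#' single-df effect this gives df \eqn{(p,\; N - \mathrm{rank} - p + 1)}.
#'
#' @param outcomes data frame or matrix of numeric outcome measures (one
#'   column per measure).
#' @param group between-subjects factor (coerced to factor).
#' @param covariate numeric covariate (e.g. age); may be `NULL`.
#' @return A data frame of class `"mancova"`, one row per effect: `effect`,
#'   `pillai`, `F`, `df1`, `df2`, `p`.
#' @examples
#' d <- generate_cohort(cohort_config(), seed = 5)
#' mancova_pillai(d[c("swan_inattention", "synthetic_v")],
#'                d$group, d$age_years)
#' @export
mancova_pillai <- function(outcomes, group, covariate = NULL) {
  Y <- as.matrix(outcomes)
  if (anyNA(Y)) stop("mancova_pillai: outcomes contain missing values",
                     call. = FALSE)
  storage.mode(Y) <- "double"
  group <- factor(group)
  n <- nrow(Y)
  p <- ncol(Y)
  X_full <- stats::model.matrix(
    if (is.null(covariate)) ~ group else ~ group + covariate)
  terms <- list(group = grep("^group", colnames(X_full)))
  if (!is.null(covariate)) terms$covariate <- grep("^covariate", colnames(X_full))

  rss <- function(X) {
    fit <- stats::lm.fit(X, Y)
    crossprod(as.matrix(fit$residuals))
  }
  E <- rss(X_full)
  rank_full <- qr(X_full)$rank
  df_e <- n - rank_full
  if (df_e < p) stop("mancova_pillai: too few rows for ", p, " outcomes",
                     call. = FALSE)

  out <- do.call(rbind, lapply(names(terms), function(tm) {
    cols <- terms[[tm]]
    H <- rss(X_full[, -cols, drop = FALSE]) - E
    q <- length(cols)
    HE <- H + E
    if (rcond(HE) < .Machine$double.eps * 100)
      stop("mancova_pillai: singular cross-product matrix", call. = FALSE)
    V <- sum(diag(H %*% solve(HE)))
    s <- min(p, q)
    m <- (abs(p - q) - 1) / 2
    u <- (df_e - p - 1) / 2
    df1 <- s * (2 * m + s + 1)
    df2 <- s * (2 * u + s + 1)
    Fst <- ((2 * u + s + 1) / (2 * m + s + 1)) * (V / s) / (1 - V / s)
    data.frame(effect = tm, pillai = V, F = Fst, df1 = df1, df2 = df2,
               p = stats::pf(Fst, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("mancova", "data.frame")
  out
}
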