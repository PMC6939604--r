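#' Hierarchical regression with stepwise entry of task measures
#'
#' Regresses parent-rated inattention on a forced block (group, age) in
#' Model 1 and then lets the candidate task measures compete for entry by
#' the classic p-to-enter / p-to-remove stepwise rule: at each iteration the
#' candidate with the smallest partial-F p-value enters if that p-value is
#' at most `p_enter`; after each entry any previously entered candidate
#' whose partial-F p-value has risen to `p_remove` or above is removed.
#' Forced predictors are never removed. This isolates which of a set of
#' highly intercorrelated measures carries unique variance.
#'
#' All variables (response and predictors, including the 0/1 group dummy
#' with term-born children coded 0) are z-scored on the listwise-complete
#' analysis sample before fitting, so reported coefficients are
#' standardized betas; entry decisions are scale-invariant.
#'
#' @param data per-child data frame (e.g. [cohort_table()] output).
#' @param response name of the response column
#'   (default `"swan_inattention"`).
#' @param forced character vector of predictors forced into Model 1.
#' @param candidates character vector of stepwise candidate predictors.
#' @param p_enter,p_remove stepwise thresholds (defaults 0.05 / 0.10).
#' @param group_var name of the grouping column to dummy-code (skipped if
#'   absent from `forced`).
#' @return A list of class `"hierarchical_regression"`: one element per
#'   model step with `label`, `predictors`, `coefficients` (term,
#'   standardized `beta`, `p`), `r_squared`, `delta_r_squared`, overall `F`
#'   with `df1`, `df2`, `p_model`, and `n`. Attribute `"selected"` names
#'   the candidates retained at the final step.
#' @examples
#' coh <- generate_cohort(cohort_config(), seed = 11)
#' fit <- ezddm(simulate_cohort_trials(coh, seed = 11), cohort = coh)
#' hierarchical_stepwise_regression(cohort_table(fit))
#' @export
hierarchical_stepwise_regression <- function(
    data, response = "swan_inattention",
    forced = c("group", "age_years"),
    candidates = c("hit_rate_pct", "sdrt_ms", "v"),
    p_enter = 0.05, p_remove = 0.10, group_var = "group") {

  d <- prepare_regression_frame(data, c(response, forced, candidates),
                                group_var)
  n <- nrow(d)
  models <- list()
  fit <- stats::lm(reformulate(forced, response), data = d)
  check_collinearity(fit)
  models[[1]] <- describe_model("Model 1", fit, n, prev_r2 = 0)

  entered <- character(0)
  remaining <- candidates
  repeat {
    changed <- FALSE
    if (length(remaining)) {
      a1 <- stats::add1(
        fit,
        scope = reformulate(c(attr(stats::terms(fit), "term.labels"),
                              remaining)),
        test = "F")
      pv <- a1[remaining, "Pr(>F)"]
      if (any(!is.na(pv) & pv <= p_enter)) {
        best <- remaining[which.min(pv)]
        entered <- c(entered, best)
        remaining <- setdiff(remaining, best)
        fit <- stats::lm(reformulate(c(forced, entered), response), data = d)
        check_collinearity(fit)
        changed <- TRUE
      }
    }
    if (length(entered)) {
      d1 <- stats::drop1(fit, scope = reformulate(entered), test = "F")
      pv <- d1[entered, "Pr(>F)"]
      worst <- entered[which.max(pv)]
      if (max(pv, na.rm = TRUE) >= p_remove) {
        entered <- setdiff(entered, worst)
        remaining <- union(remaining, worst)
        fit <- stats::lm(reformulate(c(forced, entered), response), data = d)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(entered))
    models[[2]] <- describe_model("Model 2", fit, n,
                                  prev_r2 = models[[1]]$r_squared)
  structure(models, class = "hierarchical_regression",
            selected = entered)
}

#' Forced-entry regression with group-interaction terms
#'
#' The companion analysis to [hierarchical_stepwise_regression()]: three
#' forced-entry steps with no data-driven selection — (1) group and age,
#' (2) plus all task measures, (3) plus group x measure product terms —
#' testing whether the measure-inattention relationships differ between
#' groups. Measures are mean-centered on the analysis sample before the
#' products are formed, so the interaction block's contribution is
#' invariant to measure location shifts; the change-in-R-squared F test at
#' each step is reported.
#'
#' @inheritParams hierarchical_stepwise_regression
#' @param measures task-measure predictors entered at step 2 and
#'   interacted with group at step 3.
#' @return A list of class `"hierarchical_regression"` with one element per
#'   step (fields as in [hierarchical_stepwise_regression()], plus
#'   `delta_F`, `delta_df1`, `delta_df2`, `delta_p` for the block test).
#' @export
interaction_regression <- function(
    data, response = "swan_inattention",
    forced = c("group", "age_years"),
    measures = c("hit_rate_pct", "sdrt_ms", "v"),
    group_var = "group") {

  d <- prepare_regression_frame(data, c(response, forced, measures),
                                group_var)
  n <- nrow(d)
  for (m in measures) d[[m]] <- d[[m]] - mean(d[[m]])  # center before products
  inter <- paste0("group_x_", measures)
  for (i in seq_along(measures))
    d[[inter[i]]] <- d[[forced[1]]] * d[[measures[i]]]

  steps <- list(forced, c(forced, measures), c(forced, measures, inter))
  labels <- c("Step 1 (group, age)", "Step 2 (+ measures)",
              "Step 3 (+ group interactions)")
  models <- list()
  prev_fit <- NULL
  prev_r2 <- 0
  for (k in seq_along(steps)) {
    fit <- stats::lm(reformulate(steps[[k]], response), data = d)
    check_collinearity(fit)
    models[[k]] <- describe_model(labels[k], fit, n, prev_r2 = prev_r2)
    if (!is.null(prev_fit)) {
      cmp <- stats::anova(prev_fit, fit)
      models[[k]]$delta_F <- cmp$F[2]
      models[[k]]$delta_df1 <- cmp$Df[2]
      models[[k]]$delta_df2 <- cmp$Res.Df[2]
      models[[k]]$delta_p <- cmp$`Pr(>F)`[2]
    }
    prev_fit <- fit
    prev_r2 <- models[[k]]$r_squared
  }
  structure(models, class = "hierarchical_regression", selected = NULL)
}

# listwise deletion, group dummy coding (term = 0), z-scoring
prepare_regression_frame <- function(data, vars, group_var) {
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("regression: columns not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- data[vars]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (group_var %in% vars) {
    g <- d[[group_var]]
    d[[group_var]] <- as.numeric(!(g %in% c("term", "Term", 0, "0")))
  }
  for (v in vars) {
    if (!is.numeric(d[[v]]))
      stop("regression: column '", v, "' is not numeric", call. = FALSE)
    s <- stats::sd(d[[v]])
    if (s == 0) stop("regression: column '", v, "' is constant",
                     call. = FALSE)
    d[[v]] <- (d[[v]] - mean(d[[v]])) / s
  }
  d
}

check_collinearity <- function(fit) {
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("regression: collinear design; aliased terms: ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

describe_model <- function(label, fit, n, prev_r2) {
  sm <- summary(fit)
  ct <- sm$coefficients
  terms <- setdiff(rownames(ct), "(Intercept)")
  list(label = label,
       predictors = terms,
       coefficients = data.frame(term = terms,
                                 beta = ct[terms, "Estimate"],
                                 p = ct[terms, "Pr(>|t|)"],
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
       r_squared = sm$r.squared,
       delta_r_squared = sm$r.squared - prev_r2,
       F = unname(sm$fstatistic["value"]),
       df1 = unname(sm$fstatistic["numdf"]),
       df2 = unname(sm$fstatistic["dendf"]),
       p_model = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                           sm$fstatistic["dendf"], lower.tail = FALSE),
       n = n)
}

#' @export
print.hierarchical_regression <- function(x, digits = 3, ...) {
  for (m in x) {
    cat(sprintf("%s: R2 = %.3f (dR2 = %.3f), F(%d, %d) = %.3f, p = %.4g, n = %d\n",
                m$label, m$r_squared, m$delta_r_squared, m$df1, m$df2, m$F,
                m$p_model, m$n))
    co <- m$coefficients
    for (i in seq_len(nrow(co)))
      cat(sprintf("    %-16s beta = %+.3f  p = %.4g\n",
                  co$term[i], co$beta[i], co$p[i]))
    if (!is.null(m$delta_p))
      cat(sprintf("    block test: F(%d, %d) = %.3f, p = %.4g\n",
                  m$delta_df1, m$delta_df2, m$delta_F, m$delta_p))
  }
  sel <- attr(x, "selected")
  if (!is.null(sel))
    cat("stepwise-retained candidates:",
        if (length(sel)) paste(sel, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
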