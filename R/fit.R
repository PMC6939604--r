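#' Fit the EZ diffusion model to CPT-AX trial data
#'
#' The package's central fitting function. Takes trial-level go/no-go data
#' for one or more children, scores each child's session (hit rate,
#' commission errors, RT moments, with responses outside the 200-1650 ms
#' window rejected), and estimates drift rate, boundary separation and
#' nondecision time per child by the closed-form EZ transform of
#' [ez_fit()].
#'
#' Children whose go-trial accuracy is 1 (or 0) have undefined EZ
#' parameters: they are retained in the result with `excluded = TRUE` and
#' reason `"perfect_accuracy"` (`"null_accuracy"`), mirroring the standard
#' practice of excluding perfect scorers rather than applying an edge
#' correction. Children with fewer than two hits are excluded with reason
#' `"insufficient_hits"`; chance-level accuracy with reason
#' `"chance_accuracy"`.
#'
#' @param trials a data frame of trial-level data with columns `child_id`,
#'   `trial_type`, `responded`, `rt_ms` (plus the structural columns of
#'   [generate_trial_sequence()]), e.g. from [simulate_cohort_trials()].
#' @param cohort optional data frame of per-child covariates keyed by
#'   `child_id` (e.g. from [generate_cohort()]); carried into the result
#'   and used by `summary()` and [goodness_of_fit()] for group splits.
#' @param s noise scaling constant (default 0.1).
#' @param rt_window valid response window in ms.
#' @return An object of class `"ezddm"`: a list with `parameters` (one row
#'   per child: moments `pc`, `mrt_s`, `vrt_s2`, `n_hits`; standard
#'   measures `hit_rate_pct`, `commission_pct`, `mrt_ms`, `sdrt_ms`;
#'   estimates `v`, `a`, `ter`; `excluded`, `exclusion_reason`), `cohort`,
#'   `s`, `rt_window` and `call`. Methods: [print.ezddm()],
#'   [summary.ezddm()], [coef.ezddm()], [predict.ezddm()],
#'   [simulate.ezddm()], [plot.ezddm()].
#' @examples
#' coh <- generate_cohort(cohort_config(n_vp = 3, n_term = 3))
#' fit <- ezddm(simulate_cohort_trials(coh, seed = 2), cohort = coh)
#' coef(fit)
#' @export
ezddm <- function(trials, cohort = NULL, s = 0.1, rt_window = c(200, 1650)) {
  stopifnot(is.data.frame(trials),
            all(c("child_id", "trial_type", "responded", "rt_ms") %in%
                  names(trials)))
  ids <- unique(trials$child_id)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sess <- trials[trials$child_id == ids[i], , drop = FALSE]
    m <- score_session(sess, rt_window)
    row <- data.frame(
      child_id = ids[i], n_hits = m$n_hits, pc = m$n_hits / 40,
      mrt_s = m$mrt_ms / 1000, vrt_s2 = (m$sdrt_ms / 1000)^2,
      hit_rate_pct = m$hit_rate_pct, commission_pct = m$commission_pct,
      mrt_ms = m$mrt_ms, sdrt_ms = m$sdrt_ms,
      v = NA_real_, a = NA_real_, ter = NA_real_,
      excluded = FALSE, exclusion_reason = NA_character_,
      stringsAsFactors = FALSE)
    if (m$n_hits == 40L) {
      row$excluded <- TRUE; row$exclusion_reason <- "perfect_accuracy"
    } else if (m$n_hits == 0L) {
      row$excluded <- TRUE; row$exclusion_reason <- "null_accuracy"
    } else if (m$n_hits < 2L) {
      row$excluded <- TRUE; row$exclusion_reason <- "insufficient_hits"
    } else if (row$pc == 0.5) {
      row$excluded <- TRUE; row$exclusion_reason <- "chance_accuracy"
    } else {
      p <- withCallingHandlers(
        ez_fit(row$pc, row$mrt_s, row$vrt_s2, s = s),
        warning = function(w) invokeRestart("muffleWarning"))
      row$v <- p$v; row$a <- p$a; row$ter <- p$ter
    }
    rows[[i]] <- row
  }
  params <- do.call(rbind, rows)
  rownames(params) <- NULL
  structure(list(parameters = params, cohort = cohort, s = s,
                 rt_window = rt_window, call = match.call()),
            class = "ezddm")
}

#' @export
print.ezddm <- function(x, ...) {
  p <- x$parameters
  cat("EZ diffusion model fit:", nrow(p), "children,",
      sum(p$excluded), "excluded",
      if (any(p$excluded))
        paste0("(", paste(unique(stats::na.omit(p$exclusion_reason)),
                          collapse = ", "), ")") else "", "\n")
  ok <- !p$excluded
  if (any(ok))
    cat(sprintf("  mean v = %.3f, a = %.3f, Ter = %.3f s (s = %s)\n",
                mean(p$v[ok]), mean(p$a[ok]), mean(p$ter[ok]), format(x$s)))
  invisible(x)
}

#' Group-level summary of an EZ diffusion fit
#'
#' @param object an `"ezddm"` fit.
#' @param ... unused.
#' @return A data frame of per-group means and SDs of the standard measures
#'   and diffusion parameters over non-excluded children (one pooled row if
#'   no cohort with a `group` column was supplied).
#' @export
summary.ezddm <- function(object, ...) {
  p <- merge_cohort(object)
  p <- p[!p$excluded, , drop = FALSE]
  grp <- if ("group" %in% names(p)) p$group else rep("all", nrow(p))
  vars <- c("hit_rate_pct", "commission_pct", "mrt_ms", "sdrt_ms",
            "v", "a", "ter")
  out <- do.call(rbind, lapply(split(p, grp), function(d) {
    data.frame(group = d$group[1] %||% "all", n = nrow(d),
               t(vapply(d[vars], mean, numeric(1))),
               t(stats::setNames(vapply(d[vars], stats::sd, numeric(1)),
                                 paste0("sd_", vars))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_cohort <- function(object) {
  p <- object$parameters
  if (is.null(object$cohort)) return(p)
  keep <- setdiff(names(object$cohort), names(p))
  merge(p, object$cohort[c("child_id", keep)], by = "child_id", sort = FALSE)
}

#' @export
coef.ezddm <- function(object, ...) {
  p <- object$parameters
  m <- as.matrix(p[c("v", "a", "ter")])
  rownames(m) <- p$child_id
  m
}

#' Forward-predicted observables from a fitted EZ model
#'
#' Applies [ez_forward()] at each child's fitted parameters, giving the
#' model-implied accuracy, mean RT and RT variance. Because EZ is exactly
#' identified, for non-excluded children these reproduce the observed
#' moments; the method is chiefly useful with `newdata` (e.g.
#' group-averaged parameters).
#'
#' @param object an `"ezddm"` fit.
#' @param newdata optional data frame or matrix with columns `v`, `a`,
#'   `ter`; defaults to the fitted per-child parameters.
#' @param ... unused.
#' @return A data frame with columns `pc`, `mrt`, `vrt`, `mdt`.
#' @export
predict.ezddm <- function(object, newdata = NULL, ...) {
  pars <- if (is.null(newdata)) object$parameters else as.data.frame(newdata)
  keep <- !is.na(pars$v)
  out <- data.frame(pc = NA_real_, mrt = NA_real_, vrt = NA_real_,
                    mdt = NA_real_)[rep(1L, nrow(pars)), , drop = FALSE]
  for (i in which(keep))
    out[i, ] <- unlist(ez_forward(pars$v[i], pars$a[i], pars$ter[i],
                                  s = object$s))
  rownames(out) <- if (!is.null(pars$child_id)) pars$child_id else NULL
  out
}

#' Simulate supersubject trials from a fitted EZ model
#'
#' Simulates Wiener first-passage trials at the group-averaged fitted
#' parameters (one "supersubject" per group), the construction used for
#' simulation-based goodness of fit.
#'
#' @param object an `"ezddm"` fit (with a cohort carrying `group` for
#'   per-group supersubjects; otherwise one pooled supersubject).
#' @param nsim number of trials per supersubject (default 1000).
#' @param seed integer seed.
#' @param dt Euler step in seconds.
#' @param ... unused.
#' @return A data frame of simulated trials with a `group` column.
#' @export
simulate.ezddm <- function(object, nsim = 1000, seed = NULL, dt = 0.001, ...) {
  if (!is.null(seed)) set.seed(seed)
  avg <- supersubject_parameters(object)
  out <- do.call(rbind, lapply(seq_len(nrow(avg)), function(i) {
    tr <- simulate_diffusion_trials(avg$v[i], avg$a[i], avg$ter[i],
                                    s = object$s, n_trials = nsim, dt = dt)
    cbind(group = avg$group[i], tr)
  }))
  rownames(out) <- NULL
  out
}

supersubject_parameters <- function(object) {
  p <- merge_cohort(object)
  p <- p[!p$excluded, , drop = FALSE]
  if (nrow(p) == 0L) stop("no non-excluded children to average", call. = FALSE)
  grp <- if ("group" %in% names(p)) p$group else rep("all", nrow(p))
  pieces <- split(p, grp)
  out <- do.call(rbind, lapply(names(pieces), function(g) {
    d <- pieces[[g]]
    data.frame(group = g, n_children = nrow(d),
               v = mean(d$v), a = mean(d$a), ter = mean(d$ter),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
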