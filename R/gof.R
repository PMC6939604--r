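#' Simulation-based goodness of fit via group-averaged supersubjects
#'
#' For each group, averages the fitted diffusion parameters arithmetically
#' across (non-excluded) children, simulates one supersubject of `n_trials`
#' Wiener trials at the averaged parameters, and compares the simulated
#' accuracy and mean correct RT with the observed group means. Simulated
#' correct-RT quantiles (10/30/50/70/90%) are returned for quantile-plot
#' style comparison. Trials whose simulated RT exceeds the response
#' deadline count as misses, matching the scoring of real sessions.
#'
#' @param object an `"ezddm"` fit whose cohort carries a `group` column
#'   (otherwise a single pooled group is used).
#' @param n_trials trials per supersubject (default 1000).
#' @param seed integer seed.
#' @param dt Euler step in seconds.
#' @param deadline_ms censoring deadline in ms (default 1650).
#' @return A data frame of class `"ezddm_gof"`, one row per group:
#'   `group`, `n_children`, `mean_v`, `mean_a`, `mean_ter`,
#'   `sim_accuracy_pct`, `sim_mrt_ms`, `obs_accuracy_pct`, `obs_mrt_ms`,
#'   `q10` ... `q90` (simulated correct-RT quantiles, ms).
#' @examples
#' coh <- generate_cohort(cohort_config(n_vp = 4, n_term = 4))
#' fit <- ezddm(simulate_cohort_trials(coh, seed = 3), cohort = coh)
#' goodness_of_fit(fit, n_trials = 200, seed = 1)
#' @export
goodness_of_fit <- function(object, n_trials = 1000, seed = NULL, dt = 0.001,
                            deadline_ms = 1650) {
  stopifnot(inherits(object, "ezddm"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  avg <- supersubject_parameters(object)
  p <- merge_cohort(object)
  p <- p[!p$excluded, , drop = FALSE]
  grp <- if ("group" %in% names(p)) p$group else rep("all", nrow(p))

  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  out <- avg
  names(out)[match(c("v", "a", "ter"), names(out))] <-
    c("mean_v", "mean_a", "mean_ter")
  for (nm in c("sim_accuracy_pct", "sim_mrt_ms", "obs_accuracy_pct",
               "obs_mrt_ms", paste0("q", qs * 100)))
    out[[nm]] <- NA_real_

  for (i in seq_len(nrow(out))) {
    tr <- simulate_diffusion_trials(out$mean_v[i], out$mean_a[i],
                                    out$mean_ter[i], s = object$s,
                                    n_trials = n_trials, dt = dt)
    rt_ms <- tr$total_rt * 1000
    correct <- tr$boundary == "upper" & rt_ms <= deadline_ms
    out$sim_accuracy_pct[i] <- 100 * mean(correct)
    out$sim_mrt_ms[i] <- mean(rt_ms[correct])
    out[i, paste0("q", qs * 100)] <-
      as.list(stats::quantile(rt_ms[correct], qs, names = FALSE))
    d <- p[grp == out$group[i], , drop = FALSE]
    out$obs_accuracy_pct[i] <- mean(d$hit_rate_pct)
    out$obs_mrt_ms[i] <- mean(d$mrt_ms)
  }
  class(out) <- c("ezddm_gof", "data.frame")
  out
}

#' Observed versus supersubject-simulated performance
#'
#' Plots, per group, the observed group-mean accuracy and mean correct RT
#' against the values simulated at group-averaged parameters, plus the
#' simulated correct-RT quantiles.
#'
#' @param x an `"ezddm"` fit.
#' @param n_trials,seed,dt passed to [goodness_of_fit()].
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, the [goodness_of_fit()] table that was plotted.
#' @export
plot.ezddm <- function(x, n_trials = 1000, seed = NULL, dt = 0.001, ...) {
  gof <- goodness_of_fit(x, n_trials = n_trials, seed = seed, dt = dt)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  rng <- range(gof$sim_mrt_ms, gof$obs_mrt_ms)
  graphics::plot(gof$obs_mrt_ms, gof$sim_mrt_ms, xlim = rng, ylim = rng,
                 xlab = "observed mean RT (ms)",
                 ylab = "simulated mean RT (ms)", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::text(gof$obs_mrt_ms, gof$sim_mrt_ms, gof$group, pos = 3)
  qcols <- grep("^q[0-9]+$", names(gof), value = TRUE)
  qprob <- as.numeric(sub("q", "", qcols))
  graphics::matplot(qprob, t(as.matrix(gof[qcols])), type = "b", pch = 19,
                    xlab = "quantile (%)", ylab = "simulated correct RT (ms)",
                    lty = 1)
  graphics::legend("topleft", legend = gof$group, bty = "n",
                   col = seq_len(nrow(gof)), lty = 1, pch = 19)
  invisible(gof)
}
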