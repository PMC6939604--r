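#' Run the full synthetic-cohort analysis pipeline
#'
#' End-to-end orchestration: generate a cohort, simulate trial-level CPT-AX
#' responses, score sessions and fit the EZ diffusion model (excluding
#' perfect scorers), run the supersubject goodness-of-fit simulation, and
#' perform the inferential stage — Pillai-trace MANCOVA of the seven
#' performance measures on group with age as covariate, age-partialed
#' correlations with parent-rated inattention (pooled and per group),
#' Fisher r-to-z comparisons of the group correlations, the hierarchical
#' stepwise regression and the forced-entry interaction regression. All
#' tables are written as CSV together with a JSON manifest; everything is
#' regenerable from `config` and `seed` alone, and repeated runs with the
#' same inputs produce byte-identical outputs.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stage seed derives from it.
#' @param n_gof_trials supersubject trials for goodness of fit.
#' @param dt Euler step in seconds.
#' @param p_enter,p_remove stepwise thresholds.
#' @param verbose print per-stage progress messages.
#' @return Invisibly, a list with the fitted objects and result tables
#'   (`cohort`, `fit`, `gof`, `mancova`, `partial_correlations`, `fisher`,
#'   `stepwise`, `interaction`, `manifest`) and `out_dir`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         seed = config$seed, n_gof_trials = 1000,
                         dt = 0.001, p_enter = 0.05, p_remove = 0.10,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[cptddm] ", ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  say("generating cohort (n = ", config$n_vp + config$n_term, ")")
  cohort <- generate_cohort(config, seed = stage_seeds[1])
  say("simulating sessions")
  trials <- simulate_cohort_trials(cohort, seed = stage_seeds[2], dt = dt)
  say("scoring and fitting EZ model")
  fit <- ezddm(trials, cohort = cohort)
  excl <- fit$parameters[fit$parameters$excluded, , drop = FALSE]
  say(nrow(excl), " children excluded (",
      paste(excl$exclusion_reason, collapse = ", "), ")")
  tab <- cohort_table(fit)

  say("goodness of fit (", n_gof_trials, " trials per supersubject)")
  gof <- goodness_of_fit(fit, n_trials = n_gof_trials,
                         seed = stage_seeds[3], dt = dt)

  say("inference stage")
  measures <- c("commission_pct", "hit_rate_pct", "mrt_ms", "sdrt_ms",
                "v", "a", "ter")
  manc <- mancova_pillai(tab[measures], tab$group, tab$age_years)

  pc_rows <- list()
  fisher_rows <- list()
  for (m in measures) {
    scopes <- list(pooled = tab, VP = tab[tab$group == "VP", ],
                   term = tab[tab$group == "term", ])
    rs <- lapply(scopes, function(d)
      partial_correlation(d[[m]], d$swan_inattention, controls = d$age_years))
    for (sc in names(rs))
      pc_rows[[paste(m, sc)]] <- data.frame(
        measure = m, scope = sc, r = rs[[sc]]$r, n = rs[[sc]]$n,
        p = rs[[sc]]$p, stringsAsFactors = FALSE)
    fc <- fisher_compare(rs$VP$r, sum(tab$group == "VP"),
                         rs$term$r, sum(tab$group == "term"))
    fisher_rows[[m]] <- data.frame(measure = m, z = fc$z, p = fc$p,
                                   stringsAsFactors = FALSE)
  }
  pcors <- do.call(rbind, pc_rows); rownames(pcors) <- NULL
  fisher <- do.call(rbind, fisher_rows); rownames(fisher) <- NULL

  stepwise <- hierarchical_stepwise_regression(tab, p_enter = p_enter,
                                               p_remove = p_remove)
  interact <- interaction_regression(tab)

  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  write_trials_csv(trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(fit$parameters, file.path(out_dir, "parameters.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(gof), file.path(out_dir, "gof.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(manc), file.path(out_dir, "mancova.csv"),
                   row.names = FALSE)
  utils::write.csv(pcors, file.path(out_dir, "partial_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(fisher, file.path(out_dir, "fisher_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(regression_table(stepwise),
                   file.path(out_dir, "regression_stepwise.csv"),
                   row.names = FALSE)
  utils::write.csv(regression_table(interact),
                   file.path(out_dir, "regression_interaction.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "cptddm",
    version = as.character(utils::packageVersion("cptddm")),
    master_seed = as.integer(seed),
    stage_seeds = as.integer(stage_seeds),
    config = unclass(config),
    config_hash = config_hash(config),
    n_children = nrow(cohort),
    n_excluded = nrow(excl),
    exclusions = if (nrow(excl)) stats::setNames(
      as.list(excl$exclusion_reason), excl$child_id) else list(),
    n_mancova = nrow(tab),
    n_regression = sum(stats::complete.cases(
      tab[c("swan_inattention", "group", "age_years", "hit_rate_pct",
            "sdrt_ms", "v")])),
    stepwise_selected = as.list(attr(stepwise, "selected"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("MANCOVA N = ", manifest$n_mancova,
      "; regression N = ", manifest$n_regression)
  say("done; outputs in ", out_dir)
  invisible(list(cohort = cohort, fit = fit, gof = gof, mancova = manc,
                 partial_correlations = pcors, fisher = fisher,
                 stepwise = stepwise, interaction = interact,
                 manifest = manifest, out_dir = out_dir))
}

# flat one-row-per-term view of a hierarchical_regression for CSV export
regression_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(model = m$label, n = m$n, r_squared = m$r_squared,
               delta_r_squared = m$delta_r_squared,
               F = m$F, df1 = m$df1, df2 = m$df2, p_model = m$p_model,
               term = m$coefficients$term, beta = m$coefficients$beta,
               p_term = m$coefficients$p, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

# deterministic hash of the configuration (djb2 over its deparsed form)
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(txt)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
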