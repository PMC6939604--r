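#' Configuration for the synthetic two-group cohort generator
#'
#' Returns the default generator settings, optionally overridden. The
#' defaults emulate a cohort of 33 very-preterm (VP) and 32 term-born
#' children aged about 8-11 years with a wide spread of parent-rated
#' inattention (SWAN raw scores; higher = more inattentive), whose go-trial
#' behaviour arises from a Wiener diffusion process with drift rate
#' negatively coupled to inattention, and whose no-go false alarms follow a
#' small per-trial Bernoulli process.
#'
#' Group-level diffusion means (drift 0.211 / 0.191, boundary 0.112,
#' nondecision time 0.253 / 0.267 s for VP / term) and demographic moments
#' are the generator's calibration defaults. Between-child SDs are 0.092
#' (drift, total), 0.023 (boundary) and 0.075 s (nondecision time). The
#' drift-inattention coupling `swan_v_slope` is the change in true drift per
#' within-group SD of SWAN inattention; its default is calibrated so that
#' the pooled age-partialed correlation between inattention and *fitted*
#' drift in a 40-go-trial session is about -0.37. Latent drift and boundary
#' are truncated at 0 and nondecision time at 0.05 s for physical validity.
#' `n_swan_missing_term` term-born children (default 1) have their SWAN
#' score set missing, reproducing the listwise-deletion structure typical of
#' parent questionnaires.
#'
#' @param ... name-value overrides of any default listed above.
#' @return A list of class `"cohort_config"`.
#' @examples
#' cohort_config(n_vp = 10, n_term = 10)
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_vp = 33L, n_term = 32L,
    age_mean = c(vp = 9.6, term = 9.1),
    age_sd = c(vp = 1.0, term = 1.1),
    swan_mean = c(vp = -0.70, term = -6.58),
    swan_sd = c(vp = 9.89, term = 12.23),
    prop_female = c(vp = 0.455, term = 0.406),
    v_mean = c(vp = 0.211, term = 0.191),
    v_sd_total = 0.092,
    swan_v_slope = -0.050,
    a_mean = c(vp = 0.112, term = 0.112),
    a_sd = 0.023,
    ter_mean = c(vp = 0.253, term = 0.267),
    ter_sd = 0.075,
    commission_mean = 0.024,
    commission_shape1 = 2,
    n_swan_missing_term = 1L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("cohort_config: unknown settings: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_vp < 1L || cfg$n_term < 1L)
    stop("cohort_config: group sizes must be >= 1", call. = FALSE)
  sds <- c(cfg$age_sd, cfg$swan_sd, cfg$v_sd_total, cfg$a_sd, cfg$ter_sd)
  if (any(sds < 0)) stop("cohort_config: SDs must be >= 0", call. = FALSE)
  if (abs(cfg$swan_v_slope) > cfg$v_sd_total)
    stop("cohort_config: |swan_v_slope| cannot exceed v_sd_total ",
         "(the coupling cannot explain more than the total drift variance)",
         call. = FALSE)
  if (cfg$commission_mean < 0 || cfg$commission_mean > 1)
    stop("cohort_config: commission_mean must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

# rejection-sampled truncated normal; vectorised, deterministic under seed
rtnorm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower))
    x[bad] <- stats::rnorm(sum(bad), mean[bad], if (length(sd) > 1) sd[bad] else sd)
  x
}

#' Generate a synthetic cohort of children with latent diffusion parameters
#'
#' Draws demographics (age, sex, SWAN inattention) from group-specific
#' normals and latent diffusion parameters from the model
#' `true_v = group mean + slope * z(SWAN) + noise`, with `z(SWAN)` the SWAN
#' score standardised by the group's configured mean and SD, plus
#' independently drawn boundary separation and nondecision time, and a
#' Beta-distributed per-no-go-trial commission probability. Latent columns
#' are prefixed `synthetic_`: they exist only so that validation studies can
#' compare estimates to ground truth, and no analysis stage reads them.
#'
#' @param config a [cohort_config()] list.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A data frame with one row per child: `child_id`, `group`
#'   (`"VP"`/`"term"`), `age_years`, `sex`, `swan_inattention`, and the
#'   latent `synthetic_v`, `synthetic_a`, `synthetic_ter`,
#'   `synthetic_commission_rate`.
#' @examples
#' head(generate_cohort(cohort_config(), seed = 7))
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  set.seed(as.integer(seed))
  grp <- c(rep("VP", config$n_vp), rep("term", config$n_term))
  key <- ifelse(grp == "VP", "vp", "term")
  n <- length(grp)

  age <- stats::rnorm(n, config$age_mean[key], config$age_sd[key])
  sex <- ifelse(stats::runif(n) < config$prop_female[key], "F", "M")
  swan <- stats::rnorm(n, config$swan_mean[key], config$swan_sd[key])
  z_swan <- ifelse(config$swan_sd[key] > 0,
                   (swan - config$swan_mean[key]) / config$swan_sd[key], 0)

  v_resid_sd <- sqrt(config$v_sd_total^2 - config$swan_v_slope^2)
  v <- rtnorm(n, config$v_mean[key] + config$swan_v_slope * z_swan,
              v_resid_sd, lower = 0)
  a <- rtnorm(n, config$a_mean[key], config$a_sd, lower = 0)
  ter <- rtnorm(n, config$ter_mean[key], config$ter_sd, lower = 0.05)
  shape1 <- config$commission_shape1
  shape2 <- shape1 * (1 - config$commission_mean) / config$commission_mean
  cr <- stats::rbeta(n, shape1, shape2)

  if (config$n_swan_missing_term > 0L) {
    term_rows <- which(grp == "term")
    swan[sample(term_rows, min(config$n_swan_missing_term,
                               length(term_rows)))] <- NA_real_
  }

  data.frame(
    child_id = sprintf("%s%02d", ifelse(grp == "VP", "vp", "tb"),
                       stats::ave(seq_len(n), grp, FUN = seq_along)),
    group = grp, age_years = age, sex = sex, swan_inattention = swan,
    synthetic_v = v, synthetic_a = a, synthetic_ter = ter,
    synthetic_commission_rate = cr,
    stringsAsFactors = FALSE
  )
}

#' Simulate one child's responses on a CPT-AX session
#'
#' Fills the response columns of a session template. Each go trial runs one
#' Wiener diffusion trial at the child's latent parameters: upper-boundary
#' absorption is a response with RT `(Ter + decision time) * 1000` ms,
#' lower-boundary absorption is a withheld response (miss), and any
#' simulated RT beyond the response deadline is censored to a miss. Each
#' no-go trial draws a Bernoulli false alarm at the child's commission rate,
#' with commission RT uniform on 300-1650 ms.
#'
#' @param child one row of a [generate_cohort()] data frame (latent
#'   `synthetic_*` columns required).
#' @param session_template an unanswered session from
#'   [generate_trial_sequence()].
#' @param seed integer seed.
#' @param dt Euler step for the diffusion simulation, seconds.
#' @return The session with `responded` and `rt_ms` filled in.
#' @export
simulate_child_session <- function(child, session_template, seed,
                                   dt = 0.001) {
  need <- c("synthetic_v", "synthetic_a", "synthetic_ter",
            "synthetic_commission_rate")
  if (!all(need %in% names(child)) || anyNA(child[need]))
    stop("simulate_child_session: child lacks latent diffusion parameters",
         call. = FALSE)
  session <- session_template
  deadline <- attr(session, "deadline_ms")
  if (is.null(deadline)) deadline <- CPT_DEADLINE_MS
  set.seed(as.integer(seed))

  go <- which(session$trial_type == "go")
  tr <- .euler_diffusion(length(go), child$synthetic_v, child$synthetic_a,
                         child$synthetic_ter, 0.1, dt)
  rt <- tr$total_rt * 1000
  hit <- tr$boundary == 1L & rt <= deadline
  session$responded[go] <- hit
  session$rt_ms[go] <- ifelse(hit, rt, NA_real_)

  nogo <- which(session$trial_type != "go")
  fa <- stats::runif(length(nogo)) < child$synthetic_commission_rate
  session$responded[nogo] <- fa
  session$rt_ms[nogo] <- ifelse(fa, stats::runif(length(nogo), 300, deadline),
                                NA_real_)
  session
}

#' Simulate trial-level data for a whole cohort
#'
#' Generates one session template from the master seed (all children see
#' the same pseudorandomised stimulus order, as in a fixed-order task
#' administration) and simulates each child's responses on it using a
#' per-child substream seed derived from the master seed.
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param seed master integer seed.
#' @param dt Euler step in seconds.
#' @return A data frame of 400 rows per child: `child_id` plus the session
#'   columns of [generate_trial_sequence()].
#' @examples
#' coh <- generate_cohort(cohort_config(n_vp = 2, n_term = 2))
#' trials <- simulate_cohort_trials(coh, seed = 1)
#' nrow(trials)  # 1600
#' @export
simulate_cohort_trials <- function(cohort, seed, dt = 0.001) {
  template <- generate_trial_sequence(seed)
  set.seed(as.integer(seed))
  child_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cohort))
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    s <- simulate_child_session(cohort[i, ], template, seed = child_seeds[i],
                                dt = dt)
    out[[i]] <- cbind(child_id = cohort$child_id[i], as.data.frame(s))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "deadline_ms") <- attr(template, "deadline_ms")
  res
}
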