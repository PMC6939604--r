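#' Simulate first-passage trials of the Wiener diffusion process
#'
#' Simulates `n_trials` independent decision trials of the two-boundary
#' Wiener process underlying the EZ model, by Euler-Maruyama discretisation:
#' evidence starts unbiased at `a/2` and evolves in steps
#' \eqn{\Delta x = v\,dt + s\sqrt{dt}\,\epsilon} with standard-normal
#' \eqn{\epsilon} until it is absorbed at `a` (the "respond" boundary) or 0
#' (withhold). Decision time is the number of steps times `dt`; total RT adds
#' the nondecision time.
#'
#' The discretisation overestimates decision times slightly (the process can
#' cross and return between grid points); at the default `dt = 0.001` s the
#' bias on mean decision time is below about one percent for parameter values
#' typical of child go/no-go data, and halving `dt` halves it.
#'
#' Randomness comes from R's RNG: pass `seed` (or call `set.seed()` yourself)
#' for reproducible draws.
#'
#' @param v,a,ter,s diffusion parameters as in [ez_fit()]; may also be given
#'   as a single `"ddm_parameters"` object via `params`.
#' @param n_trials number of trials to simulate (>= 1).
#' @param dt Euler step in seconds, in (0, 0.005].
#' @param seed optional integer seed.
#' @param params optional `"ddm_parameters"` list overriding `v, a, ter, s`.
#' @return A data frame with one row per trial: `boundary` (`"upper"` or
#'   `"lower"`), `decision_time` and `total_rt` in seconds.
#' @examples
#' tr <- simulate_diffusion_trials(v = 0.211, a = 0.112, ter = 0.253,
#'                                 n_trials = 500, seed = 1)
#' mean(tr$boundary == "upper")   # close to ez_forward(...)$pc
#' @export
simulate_diffusion_trials <- function(v, a, ter, s = 0.1, n_trials = 1000,
                                      dt = 0.001, seed = NULL, params = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "ddm_parameters"))
    v <- params$v; a <- params$a; ter <- params$ter; s <- params$s
  }
  if (any(is.na(c(v, a, ter))))
    stop("simulate_diffusion_trials: missing diffusion parameters",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- .euler_diffusion(as.integer(n_trials), v, a, ter, s, dt)
  out$boundary <- ifelse(out$boundary == 1L, "upper", "lower")
  out
}
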