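#' Closed-form EZ diffusion-model estimation
#'
#' Transforms a participant's go-trial summary statistics -- proportion
#' correct `pc`, mean correct response time `mrt` (seconds) and variance of
#' correct response time `vrt` (seconds squared) -- into the three EZ
#' diffusion parameters: drift rate `v`, boundary separation `a` and
#' nondecision time `ter`. The transform is exact (the model is exactly
#' identified), with the starting point fixed at `a/2` and all cross-trial
#' variabilities at zero.
#'
#' With \eqn{L = \mathrm{logit}(P_c)} the estimates are
#' \deqn{v = \mathrm{sign}(P_c - 1/2)\, s\,
#'   \left[ \frac{L (L P_c^2 - L P_c + P_c - 1/2)}{V_{RT}} \right]^{1/4},}
#' \deqn{a = s^2 L / v,} and \eqn{T_{er} = M_{RT} - \mathrm{MDT}} where
#' \eqn{\mathrm{MDT} = \frac{a}{2v}\,\frac{1 - y}{1 + y}},
#' \eqn{y = \exp(-v a / s^2)}.
#'
#' Perfect accuracy (`pc` of 0 or 1) makes the logit infinite and the
#' parameters undefined: the function throws an error and the participant
#' must be excluded upstream (no edge correction is applied). Chance
#' accuracy (`pc == 0.5`) makes `L = 0` and the boundary indeterminate and
#' is likewise an error. Below-chance accuracy yields a negative drift and a
#' warning; a negative fitted `ter` is returned as-is with a warning rather
#' than clamped.
#'
#' @param pc proportion correct on go trials, strictly between 0 and 1 and
#'   not equal to 0.5.
#' @param mrt mean correct-response RT in seconds.
#' @param vrt variance of correct-response RT in seconds squared; must be
#'   positive.
#' @param s within-trial noise scaling constant (default 0.1, the
#'   conventional scaling under which boundary separations near 0.1 and
#'   drifts near 0.2 arise for second-scale RTs).
#' @return A list of class `"ddm_parameters"` with elements `v`, `a`, `ter`
#'   and `s`.
#' @seealso [ez_forward()] for the analytic inverse,
#'   [simulate_diffusion_trials()] for trial-level simulation.
#' @examples
#' p <- ez_fit(pc = 0.914, mrt = 0.473, vrt = 0.0272)
#' unlist(p)
#' @export
ez_fit <- function(pc, mrt, vrt, s = 0.1) {
  stopifnot(is.numeric(pc), length(pc) == 1L, is.numeric(mrt), is.numeric(vrt),
            is.numeric(s), s > 0)
  if (is.na(pc) || is.na(mrt) || is.na(vrt))
    stop("ez_fit: missing summary statistics", call. = FALSE)
  if (pc <= 0 || pc >= 1)
    stop("ez_fit: parameters undefined at pc = ", pc,
         " (perfect or null accuracy); exclude this participant",
         call. = FALSE)
  if (pc == 0.5)
    stop("ez_fit: degenerate at pc = 0.5 (logit is zero, boundary ",
         "separation indeterminate)", call. = FALSE)
  if (vrt <= 0)
    stop("ez_fit: vrt must be positive", call. = FALSE)
  if (pc < 0.5)
    warning("ez_fit: below-chance accuracy (pc < 0.5); fitted drift is negative",
            call. = FALSE)

  L <- stats::qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^0.25
  a <- s^2 * L / v
  y <- exp(-v * a / s^2)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  ter <- mrt - mdt
  if (ter < 0)
    warning("ez_fit: negative nondecision time (", signif(ter, 4),
            " s); reported unclamped", call. = FALSE)
  structure(list(v = v, a = a, ter = ter, s = s), class = "ddm_parameters")
}

#' Analytic forward prediction of the EZ diffusion model
#'
#' Maps diffusion parameters to the go-trial observables the EZ transform
#' consumes: proportion correct, mean correct RT and variance of correct RT.
#' This is the exact inverse of [ez_fit()], so
#' `ez_fit(ez_forward(v, a, ter))` recovers `(v, a, ter)` to machine
#' precision; it also serves as the closed-form oracle against which the
#' trial-level simulator is validated.
#'
#' @param v drift rate (evidence per second); must be nonzero.
#' @param a boundary separation; must be positive.
#' @param ter nondecision time in seconds.
#' @param s noise scaling constant (default 0.1).
#' @return A list with elements `pc`, `mrt` (s), `vrt` (s^2) and `mdt`, the
#'   mean decision time in seconds.
#' @examples
#' ez_forward(v = 0.211, a = 0.112, ter = 0.253)
#' @export
ez_forward <- function(v, a, ter, s = 0.1) {
  stopifnot(is.numeric(v), is.numeric(a), is.numeric(ter), s > 0)
  if (v == 0)
    stop("ez_forward: degenerate at v = 0", call. = FALSE)
  if (a <= 0)
    stop("ez_forward: boundary separation must be positive", call. = FALSE)
  L <- v * a / s^2
  pc <- stats::plogis(L)
  y <- exp(-L)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  vrt <- s^4 * L * (L * pc^2 - L * pc + pc - 0.5) / v^4
  list(pc = pc, mrt = ter + mdt, vrt = vrt, mdt = mdt)
}

#' @export
print.ddm_parameters <- function(x, digits = 4, ...) {
  cat("EZ diffusion parameters (s =", format(x$s), ")\n")
  cat(sprintf("  drift rate v          : %s\n", format(x$v, digits = digits)))
  cat(sprintf("  boundary separation a : %s\n", format(x$a, digits = digits)))
  cat(sprintf("  nondecision time Ter  : %s s\n", format(x$ter, digits = digits)))
  invisible(x)
}
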