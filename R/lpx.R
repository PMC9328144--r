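#' Lethal profile multiplication factor (LPx)
#'
#' The factor by which an exposure profile must be multiplied so that the
#' model predicts x% toxicant-attributable mortality at the end of the
#' profile window: the returned \code{f} solves
#' \eqn{S_{end}(f \cdot C_w) = 1 - x/100} with background mortality set to
#' zero (the convention used in profile-based risk assessment: LPx measures
#' the toxicant, not test-specific background survival).
#'
#' Damage is linear in the exposure, so the damage trajectory is computed
#' once at factor 1 and rescaled. For IT the solution is closed-form:
#' \eqn{f = (m_w / D_{max,1}) (x/(100-x))^{1/\beta}} with \eqn{D_{max,1}}
#' the running-max damage at factor 1. For SD the factor is found by
#' bisection (survival at profile end is monotone non-increasing in the
#' factor) to a relative tolerance of 1e-4, starting from the bracket
#' [1e-6, 1e6].
#'
#' @param params \code{\link{sd_params}} or \code{\link{it_params}} (the
#'   \code{hb} component is ignored — treated as 0).
#' @param profile an \code{\link{exposure_profile}}.
#' @param x effect level in percent, strictly between 0 and 100.
#' @return The multiplication factor (scalar, > 0).
#' @examples
#' p <- exposure_profile(c(0, 1, 2), c(0, 10, 0))
#' lpx(it_params(kD = 1, mw = 8, beta = 2), p, x = 50)
#' @export
lpx <- function(params, profile, x = 50) {
  stopifnot(inherits(params, "guts_params"),
            inherits(profile, "exposure_profile"))
  x <- as.numeric(x)[1L]
  if (!is.finite(x) || x <= 0 || x >= 100)
    stop("'x' must lie strictly between 0 and 100")
  t_end <- max(profile$times)
  traj <- guts_damage(profile, params[["kD"]], eval_times = t_end)
  dmax1 <- traj$running_max[1L]
  if (dmax1 <= 0)
    stop("profile carries no exposure; LPx undefined")
  if (inherits(params, "it_params")) {
    return((params[["mw"]] / dmax1) *
             (x / (100 - x))^(1 / params[["beta"]]))
  }
  # SD: survival at t_end for scaled exposure f*Cw; hb := 0
  zw <- params[["zw"]]; bw <- params[["bw"]]
  if (bw <= 0) stop("killing rate bw = 0: no factor produces mortality")
  dam_fun <- function(t) damage_eval(profile, params[["kD"]],
                                     traj$node_damage, t)
  base_grid <- c(profile$times, traj$stationary_times)
  s_end <- function(f) {
    H <- cum_excess_hazard(t_end, t_end,
                           function(t) f * dam_fun(t),
                           zw = zw, bw = bw, base_grid = base_grid)
    exp(-H)
  }
  target <- 1 - x / 100
  f_lo <- 1e-6; f_hi <- 1e6
  if (s_end(f_lo) < target)
    stop("profile already exceeds the effect level at factor 1e-6")
  if (s_end(f_hi) > target)
    stop("bracket exhausted: effect level not reachable (threshold too ",
         "high relative to the profile)")
  # bisection on log10(f)
  l_lo <- log10(f_lo); l_hi <- log10(f_hi)
  while ((l_hi - l_lo) > 1e-4 / log(10)) {
    l_mid <- (l_lo + l_hi) / 2
    if (s_end(10^l_mid) > target) l_lo <- l_mid else l_hi <- l_mid
  }
  10^((l_lo + l_hi) / 2)
}

#' Likelihood-region uncertainty interval for LPx
#'
#' Propagates calibration uncertainty into LPx: parameter sets are drawn
#' (log10-uniform) from a box spanned by the per-parameter 95% profile
#' intervals (widened by a 10% log-range margin and clipped to the search
#' bounds) and accepted when their log-likelihood lies within
#' \eqn{\chi^2_{1,0.95}/2 = 1.92} of the maximum; the interval is the range
#' of LPx over the accepted draws together with the best-fit value.
#'
#' @param fit a converged \code{\link{guts_fit}}.
#' @param profile an \code{\link{exposure_profile}}.
#' @param x effect level in percent.
#' @param n_draws number of accepted parameter draws aimed for.
#' @param seed integer seed; the interval is reproducible.
#' @param ci optional matrix from \code{\link{confint}} (computed if
#'   missing).
#' @param max_tries cap on candidate draws.
#' @return Object of class \code{"lpx_result"}: list with \code{factor}
#'   (best fit), \code{ci} = c(lower, upper), \code{x}, \code{variant},
#'   \code{profile_label}, \code{n_accepted}, \code{flagged} (TRUE when
#'   fewer than 20 draws were accepted and the interval is unreliable).
#' @export
lpx_uncertainty <- function(fit, profile, x = 50, n_draws = 200L,
                            seed = 1L, ci = NULL, max_tries = 20000L) {
  stopifnot(inherits(fit, "guts_fit"))
  if (!fit$converged) stop("uncertainty propagation requires a converged fit")
  if (is.null(ci)) ci <- confint(fit)
  best <- lpx(fit$params, profile, x = x)
  lo_b <- fit$bounds[, 1L]; hi_b <- fit$bounds[, 2L]
  lo <- log10(ci[, "lower"]); hi <- log10(ci[, "upper"])
  # widen each marginal interval a little: corners of the joint likelihood
  # region can lie outside the box of marginal intervals
  margin <- 0.25 * (hi - lo)
  lo <- pmax(lo - margin, lo_b); hi <- pmin(hi + margin, hi_b)
  cutoff <- fit$logLik - stats::qchisq(0.95, df = 1) / 2
  set.seed(as.integer(seed))
  accepted <- numeric(0)
  tries <- 0L
  batch <- max(4L * n_draws, 400L)
  while (length(accepted) < n_draws && tries < max_tries) {
    m <- matrix(stats::runif(batch * length(lo)), ncol = length(lo))
    th <- sweep(sweep(m, 2L, hi - lo, `*`), 2L, lo, `+`)
    for (r in seq_len(nrow(th))) {
      tries <- tries + 1L
      if (tries > max_tries || length(accepted) >= n_draws) break
      pars <- make_params(th[r, ], fit$variant)
      ll <- tryCatch(as.numeric(log_likelihood(pars, fit$data)),
                     error = function(e) -Inf)
      if (ll >= cutoff)
        accepted <- c(accepted, lpx(pars, profile, x = x))
    }
  }
  flagged <- length(accepted) < 20L
  rng <- range(c(best, accepted))
  structure(list(factor = best,
                 ci = c(lower = rng[1L], upper = rng[2L]),
                 x = x, variant = fit$variant,
                 profile_label = profile$label,
                 n_accepted = length(accepted), flagged = flagged),
            class = "lpx_result")
}

#' @export
print.lpx_result <- function(x, ...) {
  cat("LP", format(x$x), " (GUTS-RED-", x$variant, ")",
      if (nzchar(x$profile_label)) paste0(" on ", sQuote(x$profile_label)),
      ": ", format(signif(x$factor, 4)),
      "  [", format(signif(x$ci[1L], 4)), ", ",
      format(signif(x$ci[2L], 4)), "]",
      if (x$flagged) "  (unreliable: too few accepted draws)",
      "\n", sep = "")
  invisible(x)
}
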