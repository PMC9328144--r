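#' GUTS-RED parameter vectors
#'
#' Parameters of the two reduced GUTS variants. Stochastic death (SD):
#' dominant rate constant \code{kD} (1/d), effect threshold \code{zw}
#' (ug/L), killing rate \code{bw} (L/(ug d)) and background hazard
#' \code{hb} (1/d). Individual tolerance (IT): \code{kD}, median \code{mw}
#' (ug/L) and shape \code{beta} of the log-logistic threshold distribution,
#' and \code{hb}.
#'
#' @param kD dominant rate constant, 1/day; > 0.
#' @param zw effect threshold, ug/L; >= 0.
#' @param bw killing rate constant, L/(ug day); >= 0.
#' @param hb background hazard rate, 1/day; >= 0.
#' @return A named numeric vector of class \code{"sd_params"} or
#'   \code{"it_params"} (both inherit \code{"guts_params"}).
#' @export
sd_params <- function(kD, zw, bw, hb = 0) {
  p <- c(kD = as.numeric(kD), zw = as.numeric(zw),
         bw = as.numeric(bw), hb = as.numeric(hb))
  if (anyNA(p) || any(!is.finite(p))) stop("parameters must be finite")
  if (p[["kD"]] <= 0) stop("kD must be > 0")
  if (p[["zw"]] < 0 || p[["bw"]] < 0 || p[["hb"]] < 0)
    stop("zw, bw and hb must be >= 0")
  structure(p, class = c("sd_params", "guts_params"))
}

#' @rdname sd_params
#' @param mw median of the individual threshold distribution, ug/L; > 0.
#' @param beta shape of the log-logistic threshold distribution; > 0.
#' @export
it_params <- function(kD, mw, beta, hb = 0) {
  p <- c(kD = as.numeric(kD), mw = as.numeric(mw),
         beta = as.numeric(beta), hb = as.numeric(hb))
  if (anyNA(p) || any(!is.finite(p))) stop("parameters must be finite")
  if (p[["kD"]] <= 0) stop("kD must be > 0")
  if (p[["mw"]] <= 0) stop("mw must be > 0")
  if (p[["beta"]] <= 0) stop("beta must be > 0")
  if (p[["hb"]] < 0) stop("hb must be >= 0")
  structure(p, class = c("it_params", "guts_params"))
}

#' @export
print.guts_params <- function(x, ...) {
  cat("GUTS-RED-", if (inherits(x, "sd_params")) "SD" else "IT",
      " parameters:\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

variant_of <- function(params) {
  if (inherits(params, "sd_params")) "SD"
  else if (inherits(params, "it_params")) "IT"
  else stop("not a GUTS parameter vector")
}

## ---- scaled damage --------------------------------------------------------
## dDw/dt = kD (Cw(t) - Dw), Dw(0) = 0, solved exactly on every linear
## exposure segment Cw(t) = c0 + s (t - t0):
##   Dw(t0 + tau) = c0 + s tau - s/kD + exp(-kD tau) (D0 - c0 + s/kD)

# damage at all profile nodes (sequential exact recurrence)
damage_at_nodes <- function(profile, kD) {
  tt <- profile$times; cc <- profile$conc
  n <- length(tt)
  D <- numeric(n)
  for (i in seq_len(n - 1L)) {
    h <- tt[i + 1L] - tt[i]
    s <- (cc[i + 1L] - cc[i]) / h
    A <- D[i] - cc[i] + s / kD
    D[i + 1L] <- cc[i] + s * h - s / kD + exp(-kD * h) * A
  }
  D
}

# vectorized analytic damage at arbitrary times, given node damages
damage_eval <- function(profile, kD, node_damage, t) {
  tt <- profile$times; cc <- profile$conc
  seg <- findInterval(t, tt, rightmost.closed = TRUE)
  seg[seg >= length(tt)] <- length(tt) - 1L
  seg[seg < 1L] <- 1L
  h <- tt[seg + 1L] - tt[seg]
  s <- (cc[seg + 1L] - cc[seg]) / h
  tau <- t - tt[seg]
  A <- node_damage[seg] - cc[seg] + s / kD
  cc[seg] + s * tau - s / kD + exp(-kD * tau) * A
}

# interior stationary points of Dw within each segment (exact closed form:
# Dw'(tau) = s - kD A e^(-kD tau) = 0  =>  tau* = -log(s / (kD A)) / kD)
damage_stationary_times <- function(profile, kD, node_damage) {
  tt <- profile$times; cc <- profile$conc
  n <- length(tt)
  i <- seq_len(n - 1L)
  h <- tt[i + 1L] - tt[i]
  s <- (cc[i + 1L] - cc[i]) / h
  A <- node_damage[i] - cc[i] + s / kD
  ratio <- s / (kD * A)
  ok <- is.finite(ratio) & ratio > 0 & ratio < 1
  tau <- rep(NA_real_, n - 1L)
  tau[ok] <- -log(ratio[ok]) / kD
  ok <- ok & !is.na(tau) & tau > 0 & tau < h
  tt[i][ok] + tau[ok]
}

#' Scaled damage trajectory for an exposure profile
#'
#' Integrates the reduced-GUTS damage state
#' \eqn{dD_w/dt = k_D (C_w(t) - D_w)}, \eqn{D_w(0) = 0}, exactly on each
#' linear segment of the profile, and records the running maximum of the
#' damage. Interior damage extrema within a segment are located in closed
#' form from the analytic solution, so the running maximum is exact (up to
#' floating point), not grid-limited.
#'
#' @param profile an \code{\link{exposure_profile}}.
#' @param kD dominant rate constant, 1/day; > 0.
#' @param eval_times times (days) at which the trajectory is reported;
#'   default: the profile nodes. Must lie inside the profile window.
#' @return An object of class \code{"damage_trajectory"}: list with
#'   \code{times}, \code{damage}, \code{running_max} (all at
#'   \code{eval_times}) plus the \code{profile}, \code{kD} and internal
#'   node solution used for further evaluation.
#' @examples
#' p <- exposure_profile(c(0, 4), c(10, 10))
#' guts_damage(p, kD = 1, eval_times = log(2))$damage  # 5 ug/L
#' @export
guts_damage <- function(profile, kD, eval_times = NULL) {
  stopifnot(inherits(profile, "exposure_profile"))
  kD <- as.numeric(kD)[1L]
  if (!is.finite(kD) || kD <= 0) stop("kD must be > 0")
  if (is.null(eval_times)) eval_times <- profile$times
  eval_times <- as.numeric(eval_times)
  t_max <- max(profile$times)
  if (any(eval_times < 0) || any(eval_times > t_max))
    stop("evaluation times outside the profile window")
  nd <- damage_at_nodes(profile, kD)
  ts <- damage_stationary_times(profile, kD, nd)
  # exact running max: cumulative max over nodes, stationary points and
  # eval times
  grid <- sort(unique(c(profile$times, ts, eval_times)))
  dg <- damage_eval(profile, kD, nd, grid)
  rmax <- cummax(dg)
  idx <- match(eval_times, grid)
  structure(list(times = eval_times,
                 damage = dg[idx],
                 running_max = rmax[idx],
                 profile = profile, kD = kD,
                 node_damage = nd, stationary_times = ts),
            class = "damage_trajectory")
}

#' @export
print.damage_trajectory <- function(x, ...) {
  cat("Damage trajectory (kD = ", format(x$kD), " 1/d) over [0, ",
      format(max(x$profile$times)), "] d; max damage ",
      format(max(x$running_max)), " ug/L\n", sep = "")
  invisible(x)
}

## ---- survival -------------------------------------------------------------

# cumulative integral of bw * max(0, dam(t) - zw) at eval_t, by trapezoid on
# a grid refined (midpoint insertion) until change < tol relative, with
# threshold-crossing points inserted each pass. dam_fun must be vectorized.
cum_excess_hazard <- function(eval_t, t_end, dam_fun, zw, bw, base_grid,
                              tol = 1e-6, max_pass = 14L) {
  if (bw == 0) return(numeric(length(eval_t)))
  grid <- sort(unique(c(0, base_grid, eval_t, t_end)))
  grid <- grid[grid >= 0 & grid <= t_end]
  prev <- NULL
  for (pass in seq_len(max_pass)) {
    d <- dam_fun(grid)
    ex <- d - zw
    # insert linear-interpolated crossing points of the threshold
    sgn <- sign(ex)
    cross <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
    if (length(cross)) {
      tc <- grid[cross] + (grid[cross + 1L] - grid[cross]) *
        (-ex[cross]) / (ex[cross + 1L] - ex[cross])
      grid <- sort(unique(c(grid, tc)))
      d <- dam_fun(grid)
      ex <- d - zw
    }
    ex <- pmax(ex, 0)
    dh <- diff(grid)
    cum <- c(0, cumsum(dh * (ex[-1L] + ex[-length(ex)]) / 2))
    at <- stats::approx(grid, cum, xout = eval_t, ties = "ordered")$y
    if (!is.null(prev) && all(abs(at - prev) <= tol * (1 + abs(at))))
      return(bw * at)
    prev <- at
    grid <- sort(c(grid, (grid[-1L] + grid[-length(grid)]) / 2))
  }
  bw * prev
}

#' Survival under the stochastic-death (SD) variant
#'
#' Hazard \eqn{h(t) = b_w \max(0, D_w(t) - z_w) + h_b};
#' \eqn{S(t) = \exp(-\int_0^t h)}. The excess-hazard integral is computed
#' by trapezoid on a grid refined until convergence, with the
#' threshold-crossing times inserted as grid points.
#'
#' @param traj a \code{\link{guts_damage}} trajectory.
#' @param params an \code{\link{sd_params}} vector.
#' @return An object of class \code{"survival_curve"}: list with
#'   \code{times} and \code{survival}.
#' @export
survival_sd <- function(traj, params) {
  stopifnot(inherits(traj, "damage_trajectory"), inherits(params, "sd_params"))
  tt <- traj$times
  dam_fun <- function(t) damage_eval(traj$profile, traj$kD, traj$node_damage, t)
  H <- cum_excess_hazard(tt, max(traj$profile$times), dam_fun,
                         zw = params[["zw"]], bw = params[["bw"]],
                         base_grid = c(traj$profile$times,
                                       traj$stationary_times))
  survival_curve(tt, exp(-(H + params[["hb"]] * tt)))
}

#' Survival under the individual-tolerance (IT) variant
#'
#' Individual thresholds follow a log-logistic distribution with median
#' \code{mw} and shape \code{beta}:
#' \eqn{F(d) = (1 + (d/m_w)^{-\beta})^{-1}}, \eqn{F(0) = 0}. An individual
#' dies as soon as its threshold is exceeded, so
#' \eqn{S(t) = (1 - F(\max_{u \le t} D_w(u))) e^{-h_b t}}.
#'
#' @param traj a \code{\link{guts_damage}} trajectory.
#' @param params an \code{\link{it_params}} vector.
#' @return A \code{"survival_curve"}.
#' @export
survival_it <- function(traj, params) {
  stopifnot(inherits(traj, "damage_trajectory"), inherits(params, "it_params"))
  Fm <- loglogistic_cdf(traj$running_max, params[["mw"]], params[["beta"]])
  survival_curve(traj$times, (1 - Fm) * exp(-params[["hb"]] * traj$times))
}

loglogistic_cdf <- function(d, mw, beta) {
  ifelse(d <= 0, 0, 1 / (1 + (d / mw)^(-beta)))
}

survival_curve <- function(times, survival) {
  survival <- pmin(pmax(survival, 0), 1)
  structure(list(times = as.numeric(times), survival = as.numeric(survival)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Survival curve: S(", format(max(x$times)), " d) = ",
      format(min(x$survival)), "\n", sep = "")
  invisible(x)
}

#' Model survival for a parameter set and exposure profile
#'
#' Convenience wrapper: damage trajectory plus the variant-appropriate
#' survival function, dispatched on the class of \code{params}.
#'
#' @param params \code{\link{sd_params}} or \code{\link{it_params}}.
#' @param profile an \code{\link{exposure_profile}}.
#' @param times evaluation times in days (default: profile nodes).
#' @return A \code{"survival_curve"}.
#' @export
guts_survival <- function(params, profile, times = NULL) {
  traj <- guts_damage(profile, params[["kD"]], eval_times = times)
  if (inherits(params, "sd_params")) survival_sd(traj, params)
  else survival_it(traj, params)
}

#' Simulate survivor counts from a survival curve
#'
#' Conditional-binomial death process: survivors at \eqn{t_i} are drawn
#' binomial with size the survivors at \eqn{t_{i-1}} and probability
#' \eqn{S(t_i)/S(t_{i-1})} — exactly the sampling model behind the
#' interval-censored multinomial likelihood used for calibration.
#'
#' @param curve a \code{"survival_curve"} containing all \code{obs_times}.
#' @param n0 initial number of organisms.
#' @param obs_times observation times (days); subset of the curve's times.
#'   Times after the survival probability reaches 0 yield 0 survivors.
#' @param seed integer seed; the draw is reproducible.
#' @return Integer survivor counts at \code{obs_times} (count at a time-0
#'   observation equals \code{n0}).
#' @export
simulate_survivors <- function(curve, n0, obs_times, seed = NULL) {
  stopifnot(inherits(curve, "survival_curve"))
  idx <- match(obs_times, curve$times)
  if (anyNA(idx)) stop("'obs_times' must be a subset of the curve's times")
  S <- curve$survival[idx]
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- integer(length(obs_times))
  alive <- as.integer(n0)
  S_prev <- 1
  for (i in seq_along(obs_times)) {
    if (obs_times[i] == 0) {
      out[i] <- alive; S_prev <- S[i]; next
    }
    if (S_prev <= 0) {
      if (alive > 0)
        stop("survival already 0 with ", alive, " organisms still alive")
      out[i] <- 0L; S_prev <- S[i]; next
    }
    p <- S[i] / S_prev
    alive <- stats::rbinom(1L, alive, min(max(p, 0), 1))
    out[i] <- alive
    S_prev <- S[i]
  }
  out
}
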