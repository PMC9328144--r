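## Calibration of GUTS-RED-SD / -IT by maximum likelihood.
##
## The likelihood is the interval-censored multinomial death likelihood:
## within each treatment the deaths in each observation interval are
## multinomial with probabilities S(t_{i-1}) - S(t_i), plus the survivors
## remaining at the final observation with probability S(t_end).

# closed-form survival under constant exposure c over [0, t] (fast path for
# toxicity-test treatments; the general trapezoid path handles arbitrary
# profiles and is cross-checked against this in the tests)
surv_constant <- function(conc, params, t) {
  kD <- params[["kD"]]; hb <- params[["hb"]]
  if (inherits(params, "sd_params")) {
    zw <- params[["zw"]]; bw <- params[["bw"]]
    Hex <- numeric(length(t))
    if (bw > 0 && conc > zw) {
      tstar <- if (zw <= 0) 0 else -log(1 - zw / conc) / kD
      on <- t > tstar
      Hex[on] <- (conc - zw) * (t[on] - tstar) +
        (conc / kD) * (exp(-kD * t[on]) - exp(-kD * tstar))
      Hex <- bw * Hex
    }
    exp(-(Hex + hb * t))
  } else {
    dmax <- conc * (1 - exp(-kD * t))
    (1 - loglogistic_cdf(dmax, params[["mw"]], params[["beta"]])) *
      exp(-hb * t)
  }
}

is_constant_profile <- function(p) {
  length(p$times) == 2L && p$conc[1L] == p$conc[2L]
}

model_survival_matrix <- function(params, data) {
  vapply(data$treatments, function(tr) {
    if (is_constant_profile(tr$exposure))
      surv_constant(tr$exposure$conc[1L], params, data$times)
    else
      guts_survival(params, tr$exposure, times = data$times)$survival
  }, numeric(length(data$times)))
}

#' Interval-censored multinomial log-likelihood of a GUTS-RED model
#'
#' For each treatment with survivor counts \eqn{y_0 \ge y_1 \ge \dots} at
#' times \eqn{t_0 = 0 < t_1 < \dots}, the contribution is
#' \eqn{\sum_i d_i \log(S(t_{i-1}) - S(t_i)) + y_{end} \log S(t_{end})}
#' with \eqn{d_i = y_{i-1} - y_i} deaths in interval \eqn{i} (multinomial
#' coefficient omitted; it does not depend on the parameters). Interval
#' probabilities are floored at \code{floor} before taking logs; the number
#' of floored cells is attached as attribute \code{"n_floored"} so a fit
#' that leans on the guard can be flagged.
#'
#' @param params \code{\link{sd_params}} or \code{\link{it_params}}.
#' @param data a prepared \code{\link{survival_dataset}} (counts
#'   non-increasing in time).
#' @param floor lower bound on interval probabilities before log.
#' @return Log-likelihood (scalar) with attribute \code{n_floored}.
#' @export
log_likelihood <- function(params, data, floor = 1e-30) {
  stopifnot(inherits(params, "guts_params"),
            inherits(data, "survival_dataset"))
  S <- model_survival_matrix(params, data)
  if (any(!is.finite(S))) stop("non-finite model survival")
  ll <- 0
  n_floored <- 0L
  for (j in seq_along(data$treatments)) {
    y <- data$treatments[[j]]$survivors
    if (any(diff(y) > 0))
      stop("survivor counts increase over time; prepare the data first")
    Sj <- S[, j]
    d <- -diff(y)
    p <- -diff(Sj)
    n_floored <- n_floored + sum(d > 0 & p < floor) +
      sum(y[length(y)] > 0 & Sj[length(Sj)] < floor)
    p <- pmax(p, floor)
    ll <- ll + sum(d * log(p)) +
      y[length(y)] * log(max(Sj[length(Sj)], floor))
  }
  structure(ll, n_floored = n_floored)
}

#' Control settings for \code{\link{guts_fit}}
#'
#' @param n_screen number of Latin-hypercube screening points in log10
#'   parameter space.
#' @param n_top number of screening points refined by Nelder-Mead.
#' @param maxit maximum Nelder-Mead iterations per refinement.
#' @param floor interval-probability floor in the likelihood.
#' @param ci_step_frac initial profiling step, as a fraction of the log10
#'   search range of the parameter.
#' @param ci_maxit Nelder-Mead iterations per profiling re-optimization.
#' @return A list of class \code{"guts_control"}.
#' @export
guts_control <- function(n_screen = 200L, n_top = 10L, maxit = 400L,
                         floor = 1e-30, ci_step_frac = 0.04,
                         ci_maxit = 200L) {
  structure(list(n_screen = as.integer(n_screen), n_top = as.integer(n_top),
                 maxit = as.integer(maxit), floor = floor,
                 ci_step_frac = ci_step_frac,
                 ci_maxit = as.integer(ci_maxit)),
            class = "guts_control")
}

# data-scaled default log10 search bounds (openGUTS-style heuristics)
default_bounds <- function(data, variant) {
  t_end <- max(data$times)
  cpeak <- vapply(data$treatments, function(tr) max(tr$exposure$conc), 0)
  pos <- cpeak[cpeak > 0]
  if (!length(pos)) stop("calibration needs at least one exposed treatment")
  thr <- c(min(pos) / 1000, 2 * max(pos))
  b <- rbind(
    kD = c(log(20) / t_end / 100, 1000),
    if (variant == "SD") rbind(zw = thr, bw = c(1e-4, 1e4))
    else rbind(mw = thr, beta = c(0.5, 100)),
    hb = c(1e-6, 0.1))
  colnames(b) <- c("lower", "upper")
  log10(b)
}

make_params <- function(theta, variant) {
  v <- 10^theta
  if (variant == "SD") sd_params(v[1L], v[2L], v[3L], v[4L])
  else it_params(v[1L], v[2L], v[3L], v[4L])
}

#' Fit a GUTS-RED model to toxicity-test survival data
#'
#' Maximum-likelihood calibration of all four parameters jointly (including
#' background mortality) in log10 parameter space, within data-scaled
#' default bounds: a seeded Latin-hypercube screen followed by Nelder-Mead
#' refinement of the best screening points. Estimates within 1% (log scale)
#' of a search bound are flagged, mirroring the "edge of the calibration
#' search space" diagnostic familiar from openGUTS.
#'
#' @param data a prepared \code{\link{survival_dataset}} with a control and
#'   at least one exposed treatment.
#' @param variant \code{"SD"} (stochastic death) or \code{"IT"} (individual
#'   tolerance).
#' @param control a \code{\link{guts_control}} list.
#' @param seed integer seed for the multi-start screen (the fit is
#'   deterministic given data, variant, control and seed).
#' @param hb_control_only if \code{TRUE}, background mortality is first
#'   fitted to the control treatment alone and then held fixed; the default
#'   (\code{FALSE}) fits all parameters together.
#' @param bounds optional 4x2 matrix of log10 bounds overriding the
#'   defaults (rows kD, zw|mw, bw|beta, hb).
#' @return An object of class \code{"guts_fit"} with components
#'   \code{params} (best-fit \code{guts_params}), \code{variant},
#'   \code{logLik}, \code{boundary} (per-parameter bound flags),
#'   \code{converged}, \code{n_starts}, \code{n_floored}, \code{bounds},
#'   \code{data}, \code{seed}, \code{control}. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{logLik}, \code{confint},
#'   \code{predict}, \code{simulate}, \code{residuals}, \code{plot},
#'   \code{gof}.
#' @examples
#' \donttest{
#' des <- test_design(c(0, 1.8, 3.2, 5.6, 10, 18), n0 = 40,
#'                    times = 0:4)
#' dat <- generate_test(sd_params(0.7, 2, 0.3, 0.01), des, seed = 1)
#' fit <- guts_fit(dat, "SD", seed = 1)
#' coef(fit)
#' }
#' @export
guts_fit <- function(data, variant = c("SD", "IT"),
                     control = guts_control(), seed = 1L,
                     hb_control_only = FALSE, bounds = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  variant <- match.arg(variant)
  if (length(data$treatments) < 2L)
    stop("calibration needs at least 2 treatments including a control")
  cl <- match.call()
  if (is.null(bounds)) bounds <- default_bounds(data, variant)
  lo <- bounds[, 1L]; hi <- bounds[, 2L]
  k <- length(lo)

  hb_fixed <- NULL
  if (hb_control_only) {
    hb_fixed <- fit_hb_control(data)
    lo[k] <- hi[k] <- log10(max(hb_fixed, 1e-10))
  }

  negll <- function(theta) {
    thc <- pmin(pmax(theta, lo), hi)
    pen <- sum((theta - thc)^2) * 1e4
    val <- tryCatch(
      -as.numeric(log_likelihood(make_params(thc, variant), data,
                                 floor = control$floor)),
      error = function(e) Inf)
    if (!is.finite(val)) val <- 1e12
    val + pen
  }

  set.seed(as.integer(seed))
  U <- lhs::randomLHS(control$n_screen, k)
  starts <- sweep(sweep(U, 2L, hi - lo, `*`), 2L, lo, `+`)
  screen_val <- apply(starts, 1L, negll)
  ord <- order(screen_val)[seq_len(min(control$n_top, nrow(starts)))]

  best <- NULL
  for (i in ord) {
    opt <- stats::optim(starts[i, ], negll, method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = 1e-10))
    # polish from the incumbent
    opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(maxit = control$maxit,
                                        reltol = 1e-10))
    if (opt2$value < opt$value) opt <- opt2
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta <- pmin(pmax(best$par, lo), hi)
  params <- make_params(theta, variant)
  ll <- log_likelihood(params, data, floor = control$floor)
  rng <- hi - lo
  boundary <- (theta - lo < 0.01 * rng) | (hi - theta < 0.01 * rng)
  if (!is.null(hb_fixed)) boundary[k] <- FALSE
  names(boundary) <- names(params)
  structure(list(params = params, variant = variant,
                 logLik = as.numeric(ll),
                 theta = stats::setNames(theta, names(params)),
                 bounds = bounds, boundary = boundary,
                 converged = is.finite(ll) && best$convergence %in% c(0L, 1L),
                 n_starts = length(ord), n_floored = attr(ll, "n_floored"),
                 hb_fixed = hb_fixed,
                 data = data, seed = as.integer(seed), control = control,
                 call = cl),
            class = "guts_fit")
}

# background hazard from the control treatment only (exponential survival MLE
# via 1-d likelihood search)
fit_hb_control <- function(data) {
  conc <- vapply(data$treatments, function(tr) max(tr$exposure$conc), 0)
  ctrl <- which(conc == 0)
  if (!length(ctrl)) stop("no control treatment found")
  y <- data$treatments[[ctrl[1L]]]$survivors
  tt <- data$times
  nll <- function(log_hb) {
    S <- exp(-10^log_hb * tt)
    d <- -diff(y); p <- pmax(-diff(S), 1e-30)
    -(sum(d * log(p)) + y[length(y)] * log(max(S[length(S)], 1e-30)))
  }
  opt <- stats::optimize(nll, c(-8, log10(0.5)))
  10^opt$minimum
}

#' Profile-likelihood confidence interval for one fitted parameter
#'
#' Walks the parameter away from its estimate (log10 scale), re-optimizing
#' the remaining parameters at every step, until the profiled log-likelihood
#' drops \eqn{\chi^2_{1,0.95}/2 = 1.9207} below the maximum, then refines
#' the crossing by bisection. Intervals that run into a search bound are
#' clipped there and flagged.
#'
#' @param fit a converged \code{\link{guts_fit}}.
#' @param parm parameter name (\code{"kD"}, \code{"zw"}/\code{"mw"},
#'   \code{"bw"}/\code{"beta"}, \code{"hb"}).
#' @param level confidence level.
#' @return Named numeric \code{c(lower, upper)} on the natural scale, with
#'   attribute \code{"at_bound"} = logical(2).
#' @export
profile_ci <- function(fit, parm, level = 0.95) {
  stopifnot(inherits(fit, "guts_fit"))
  if (!fit$converged) stop("profiling requires a converged fit")
  nm <- names(fit$params)
  j <- match(parm, nm)
  if (is.na(j)) stop("unknown parameter ", parm, "; have: ",
                     paste(nm, collapse = ", "))
  lo <- fit$bounds[, 1L]; hi <- fit$bounds[, 2L]
  ctl <- fit$control
  drop_ll <- stats::qchisq(level, df = 1) / 2
  target <- fit$logLik - drop_ll
  data <- fit$data; variant <- fit$variant
  theta_hat <- fit$theta

  prof_ll <- function(v, start_rest) {
    negll_rest <- function(rest) {
      th <- numeric(length(theta_hat)); th[j] <- v; th[-j] <- rest
      thc <- pmin(pmax(th, lo), hi)
      pen <- sum((th - thc)^2) * 1e4
      val <- tryCatch(
        -as.numeric(log_likelihood(make_params(thc, variant), data,
                                   floor = ctl$floor)),
        error = function(e) Inf)
      if (!is.finite(val)) val <- 1e12
      val + pen
    }
    opt <- stats::optim(start_rest, negll_rest, method = "Nelder-Mead",
                        control = list(maxit = ctl$ci_maxit, reltol = 1e-9))
    list(ll = -opt$value, rest = opt$par)
  }

  one_side <- function(dir) {  # dir = -1 lower, +1 upper
    step <- ctl$ci_step_frac * (hi[j] - lo[j])
    v_in <- theta_hat[j]; ll_in <- fit$logLik
    rest <- theta_hat[-j]
    v <- v_in
    at_bound <- FALSE
    repeat {
      v_new <- v + dir * step
      hit <- (dir < 0 && v_new <= lo[j]) || (dir > 0 && v_new >= hi[j])
      if (hit) v_new <- if (dir < 0) lo[j] else hi[j]
      pr <- prof_ll(v_new, rest)
      rest <- pr$rest
      if (pr$ll < target) { v_out <- v_new; ll_out <- pr$ll; break }
      v_in <- v_new; ll_in <- pr$ll
      if (hit) { at_bound <- TRUE; v_out <- v_new; break }
      v <- v_new
      step <- step * 1.5
    }
    if (at_bound) return(list(v = v_out, at_bound = TRUE))
    # bisect the crossing between v_in (inside) and v_out (outside)
    for (it in seq_len(20L)) {
      if (abs(v_out - v_in) < 1e-3 * (hi[j] - lo[j])) break
      v_mid <- (v_in + v_out) / 2
      pr <- prof_ll(v_mid, rest)
      rest <- pr$rest
      if (pr$ll < target) v_out <- v_mid else v_in <- v_mid
    }
    list(v = (v_in + v_out) / 2, at_bound = FALSE)
  }

  lo_side <- one_side(-1)
  hi_side <- one_side(+1)
  out <- c(lower = 10^lo_side$v, upper = 10^hi_side$v)
  attr(out, "at_bound") <- c(lower = lo_side$at_bound,
                             upper = hi_side$at_bound)
  out
}

#' Goodness-of-fit metrics for a calibrated GUTS-RED model
#'
#' \code{nrmse}: root-mean-square of (observed - predicted survivors) over
#' all treatment-by-time cells, divided by the mean observed survivor count
#' (dimensionless; EFSA screening reads < 0.5 as acceptable).
#' \code{sppe}: survival probability prediction error per treatment,
#' \eqn{100 (y_{obs,end} - y_{pred,end}) / n_0} in percentage points
#' (screening band |sppe| < 50).
#'
#' @param fit a converged \code{\link{guts_fit}}.
#' @return List of class \code{"guts_gof"} with \code{nrmse} and the
#'   per-treatment \code{sppe} vector.
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "guts_fit"))
  data <- fit$data
  S <- model_survival_matrix(fit$params, data)
  obs <- vapply(data$treatments, function(tr) as.numeric(tr$survivors),
                numeric(length(data$times)))
  obs <- matrix(obs, nrow = length(data$times))
  n0 <- obs[1L, ]
  pred <- sweep(S, 2L, n0, `*`)
  nrmse <- sqrt(mean((obs - pred)^2)) / mean(obs)
  last <- nrow(obs)
  sppe <- 100 * (obs[last, ] - pred[last, ]) / n0
  names(sppe) <- vapply(data$treatments, function(tr) tr$label, "")
  structure(list(nrmse = nrmse, sppe = sppe), class = "guts_gof")
}

#' @export
print.guts_gof <- function(x, ...) {
  cat("NRMSE:", format(x$nrmse, digits = 4), "\nSPPE [% pts]:\n")
  print(round(x$sppe, 2))
  invisible(x)
}
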