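# Independent oracles and fixture builders used across the test files.

# random piecewise-linear exposure profile
random_profile <- function(n_seg = NULL, t_end = NULL, c_max = 20) {
  n_seg <- n_seg %||% sample(3:8, 1)
  t_end <- t_end %||% stats::runif(1, 2, 10)
  repeat {
    tt <- sort(c(0, stats::runif(n_seg - 1, 0, t_end), t_end))
    if (all(diff(tt) > 1e-4)) break
  }
  exposure_profile(tt, stats::runif(n_seg + 1, 0, c_max))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adaptive numeric ODE integration of dD/dt = kD (Cw(t) - D), D(0) = 0
ode_damage_oracle <- function(profile, kD, times) {
  cw <- stats::approxfun(profile$times, profile$conc, rule = 2)
  tt <- sort(unique(c(0, times)))
  out <- deSolve::ode(y = c(D = 0), times = tt,
                      func = function(t, y, p) list(kD * (cw(t) - y)),
                      rtol = 1e-10, atol = 1e-12)
  out[match(times, tt), "D"]
}

# brute-force grid evaluation of IT survival at profile end (oracle for the
# closed-form LPx): running max on a very dense grid
it_surv_end_brute <- function(params, profile, factor, n_grid = 20001L) {
  tt <- seq(0, max(profile$times), length.out = n_grid)
  tr <- guts_damage(scale_profile(profile, factor), params[["kD"]],
                    eval_times = tt)
  dmax <- max(tr$damage)
  1 - 1 / (1 + (dmax / params[["mw"]])^(-params[["beta"]]))
}

# generic bisection LPx on the IT survival function (does not use the
# closed form under test)
it_lpx_bisect <- function(params, profile, x) {
  t_end <- max(profile$times)
  s_end <- function(f) {
    tr <- guts_damage(scale_profile(profile, f), params[["kD"]],
                      eval_times = t_end)
    1 - 1 / (1 + (tr$running_max[1L] / params[["mw"]])^(-params[["beta"]]))
  }
  target <- 1 - x / 100
  lo <- 1e-6; hi <- 1e6
  for (i in 1:80) {
    mid <- sqrt(lo * hi)
    if (s_end(mid) > target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# standard synthetic recovery design (40 fish, 5 concentrations + control,
# daily observation over 4 days)
recovery_design <- function() {
  test_design(c(0, 1.8, 3.2, 5.6, 10, 18), n0 = 40L, times = 0:4)
}

sd_truth <- function() sd_params(kD = 0.7, zw = 2.0, bw = 0.3, hb = 0.01)
it_truth <- function() it_params(kD = 0.7, mw = 5.0, beta = 3.0, hb = 0.01)

# raw 3-replicate ELS fixture: times incl. a prehatch phase, one replicate
# with a scoring error (count going up), two control groups
els_fixture <- function() {
  times <- c(0, 2, 5, 8, 14, 21, 28)
  tr <- function(conc, reps, is_control = FALSE)
    list(exposure = constant_profile_pub(conc, 28), replicates = reps,
         survivors = reps[[1L]], label = format(conc),
         is_control = is_control)
  survival_dataset(
    times,
    list(
      tr(0, list(c(20, 20, 18, 18, 17, 17, 17),
                 c(20, 19, 19, 20, 18, 18, 17)), is_control = TRUE),
      tr(0, list(c(20, 20, 19, 19, 19, 18, 18)), is_control = TRUE),
      tr(3, list(c(20, 19, 17, 16, 17, 15, 14),
                 c(20, 20, 18, 17, 16, 14, 13)))),
    species = "els-fixture", study_type = "ELS", check_monotone = FALSE)
}

constant_profile_pub <- function(conc, t_end) {
  exposure_profile(c(0, t_end), c(conc, conc))
}

survival_curve_pub <- function(times, survival) {
  gutsred:::survival_curve(times, survival)
}
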