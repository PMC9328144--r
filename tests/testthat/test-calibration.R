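# one-treatment dataset with a model whose S(1) = 0.6 exactly:
# IT with kD -> inf so Dmax = conc, mw = 7.5, beta = 1:
# F(5) = 1 / (1 + (5/7.5)^-1) = 0.4
ll_example <- function() {
  data <- survival_dataset(c(0, 1),
                           list(list(exposure = 5, survivors = c(10, 6))))
  params <- it_params(kD = 1e9, mw = 7.5, beta = 1, hb = 0)
  list(data = data, params = params)
}

test_that("multinomial interval likelihood matches the hand-computed example", {
  ex <- ll_example()
  expect_equal(as.numeric(log_likelihood(ex$params, ex$data)),
               4 * log(0.4) + 6 * log(0.6), tolerance = 1e-9)
})

test_that("likelihood is 0 for a perfect no-death model and floors impossible cells", {
  data <- survival_dataset(0:2, list(list(exposure = 2,
                                          survivors = c(10, 10, 10))))
  no_effect <- sd_params(kD = 1, zw = 10, bw = 0.5, hb = 0)  # S identically 1
  ll <- log_likelihood(no_effect, data)
  expect_equal(as.numeric(ll), 0)
  expect_equal(attr(ll, "n_floored"), 0L)
  deaths <- survival_dataset(0:2, list(list(exposure = 2,
                                            survivors = c(10, 7, 7))))
  ll2 <- log_likelihood(no_effect, deaths)
  expect_equal(as.numeric(ll2), 3 * log(1e-30), tolerance = 1e-6)
  expect_gt(attr(ll2, "n_floored"), 0L)
})

test_that("likelihood is invariant to treatment ordering", {
  dat <- generate_test(sd_truth(), recovery_design(), seed = 3)
  perm <- dat
  perm$treatments <- rev(perm$treatments)
  p <- sd_params(0.5, 1.5, 0.2, 0.02)
  expect_equal(as.numeric(log_likelihood(p, dat)),
               as.numeric(log_likelihood(p, perm)))
})

test_that("fitting is deterministic under a seed and beats its start points", {
  dat <- generate_test(sd_truth(), recovery_design(), seed = 21)
  ctl <- guts_control(n_screen = 40, n_top = 3)
  f1 <- guts_fit(dat, "SD", control = ctl, seed = 5)
  f2 <- guts_fit(dat, "SD", control = ctl, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$logLik, f2$logLik)
  # the returned optimum beats the likelihood at scattered probe points
  set.seed(1)
  for (i in 1:10) {
    probe <- sd_params(10^stats::runif(1, -2, 2), stats::runif(1, 0.1, 30),
                       10^stats::runif(1, -3, 2), stats::runif(1, 0, 0.08))
    expect_gte(f1$logLik, as.numeric(log_likelihood(probe, dat)))
  }
})

test_that("parameters are recovered from synthetic data (both variants)", {
  ctl <- guts_control(n_screen = 80, n_top = 5)
  for (variant in c("SD", "IT")) {
    truth <- if (variant == "SD") sd_truth() else it_truth()
    dat <- generate_test(truth, recovery_design(), seed = 2)
    fit <- guts_fit(dat, variant, control = ctl, seed = 2)
    expect_true(fit$converged)
    tox <- names(truth)[1:3]
    ci <- confint(fit, parm = tox)
    expect_true(all(ci[, 1] <= as.numeric(truth)[1:3] &
                      as.numeric(truth)[1:3] <= ci[, 2]))
    # every profiled interval contains the point estimate
    expect_true(all(ci[, 1] <= coef(fit)[tox] + 1e-9 &
                      coef(fit)[tox] <= ci[, 2] + 1e-9))
    g <- gof(fit)
    expect_lt(g$nrmse, 0.5)
    expect_true(all(abs(g$sppe) < 50))
  }
})

test_that("the true-parameter likelihood is not above the fitted optimum", {
  dat <- generate_test(sd_truth(), recovery_design(), seed = 9)
  fit <- guts_fit(dat, "SD", control = guts_control(n_screen = 80), seed = 9)
  expect_gte(fit$logLik + 1e-6,
             as.numeric(log_likelihood(sd_truth(), dat)))
})

test_that("a dataset without deaths pushes the threshold to the upper bound", {
  des <- test_design(c(0, 1, 3, 10), n0 = 20, times = 0:3)
  no_death <- generate_test(sd_params(1, 1e5, 0.1, 0), des, seed = 1)
  fit <- guts_fit(no_death, "SD", control = guts_control(n_screen = 60),
                  seed = 1)
  # the likelihood is flat in the threshold above the top concentration's
  # damage, so its profiled upper limit runs into the search bound
  ci_zw <- profile_ci(fit, "zw")
  expect_true(attr(ci_zw, "at_bound")[["upper"]])
  expect_true(any(fit$boundary))  # hb collapses onto its lower bound
})

test_that("all-or-nothing mortality leaves the killing rate unbounded above", {
  # deaths jump from none at 3.2 to complete by day 1 at 5.6: any large bw
  # explains the data equally well once zw sits between the two levels
  times <- 0:4
  mk <- function(conc, surv) list(exposure = conc, survivors = surv)
  dat <- survival_dataset(times, list(
    mk(0, c(20, 20, 20, 20, 20)),
    mk(1.8, c(20, 20, 20, 20, 20)),
    mk(3.2, c(20, 20, 20, 20, 20)),
    mk(5.6, c(20, 0, 0, 0, 0)),
    mk(10, c(20, 0, 0, 0, 0))))
  fit <- guts_fit(dat, "SD", control = guts_control(n_screen = 60), seed = 1)
  ci_bw <- profile_ci(fit, "bw")
  expect_true(attr(ci_bw, "at_bound")[["upper"]])
})

test_that("goodness-of-fit metrics match their definitions", {
  # observed {10, 6}, predicted {10, 8}: sppe = 100 (6 - 8)/10 = -20
  data <- survival_dataset(c(0, 1),
                           list(list(exposure = 5, survivors = c(10, 6))))
  pred_params <- it_params(kD = 1e9, mw = 20, beta = 1, hb = 0)  # S(1)=0.8
  fit <- structure(list(params = pred_params, data = data),
                   class = "guts_fit")
  g <- gof(fit)
  expect_equal(unname(g$sppe), -20, tolerance = 1e-6)
  expect_equal(g$nrmse, sqrt(mean(c(0, 4))) / mean(c(10, 6)),
               tolerance = 1e-6)
  # perfect predictions: both metrics vanish
  perfect <- survival_dataset(c(0, 1),
                              list(list(exposure = 5,
                                        survivors = c(10, 8))))
  fit2 <- structure(list(params = pred_params, data = perfect),
                    class = "guts_fit")
  g2 <- gof(fit2)
  expect_equal(g2$nrmse, 0, tolerance = 1e-9)
  expect_equal(unname(g2$sppe), 0, tolerance = 1e-9)
})

test_that("control-only background-mortality fit is available", {
  dat <- generate_test(sd_truth(), recovery_design(), seed = 13)
  fit <- guts_fit(dat, "SD", control = guts_control(n_screen = 40),
                  seed = 1, hb_control_only = TRUE)
  expect_true(fit$converged)
  expect_equal(coef(fit)[["hb"]], fit$hb_fixed, tolerance = 1e-6)
})

test_that("fit methods expose the classic modelling surface", {
  dat <- generate_test(it_truth(), recovery_design(), seed = 4)
  fit <- guts_fit(dat, "IT", control = guts_control(n_screen = 40), seed = 4)
  expect_named(coef(fit), c("kD", "mw", "beta", "hb"))
  expect_s3_class(logLik(fit), "logLik")
  S <- predict(fit)
  expect_equal(dim(S), c(5L, 6L))
  expect_true(all(S >= 0 & S <= 1))
  r <- residuals(fit)
  expect_equal(dim(r), dim(S))
  sim <- simulate(fit, seed = 1)
  expect_s3_class(sim, "survival_dataset")
  expect_identical(simulate(fit, seed = 1)$treatments[[3L]]$survivors,
                   sim$treatments[[3L]]$survivors)
  rep <- fit_report(fit)
  expect_true(all(c("species", "variant", "estimate", "loglik",
                    "boundary", "nrmse", "sppe") %in% names(rep)))
})
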