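test_that("damage matches closed forms under constant exposure", {
  p <- constant_profile_pub(10, 25)
  expect_equal(guts_damage(p, 1, log(2))$damage, 5, tolerance = 1e-12)
  expect_equal(guts_damage(p, 1, 20)$damage, 10, tolerance = 1e-6)
  # general closed form C (1 - exp(-kD t)) at several times/rates
  for (kD in c(0.2, 2, 30)) {
    tt <- c(0.3, 1.7, 6)
    expect_equal(guts_damage(p, kD, tt)$damage,
                 10 * (1 - exp(-kD * tt)), tolerance = 1e-10)
  }
})

test_that("damage is linear in the exposure profile", {
  set.seed(5)
  for (i in 1:10) {
    p <- random_profile()
    kD <- 10^stats::runif(1, -1, 2)
    tt <- sort(stats::runif(6, 0, max(p$times)))
    k <- stats::runif(1, 0, 4)
    d1 <- guts_damage(p, kD, tt)
    d2 <- guts_damage(scale_profile(p, k), kD, tt)
    expect_equal(d2$damage, k * d1$damage, tolerance = 1e-10)
    expect_equal(d2$running_max, k * d1$running_max, tolerance = 1e-10)
  }
})

test_that("analytic damage agrees with an adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(17)
  for (i in 1:20) {
    p <- random_profile()
    kD <- 10^stats::runif(1, -1, 2)
    tt <- sort(stats::runif(8, 0.05, max(p$times)))
    ana <- guts_damage(p, kD, tt)$damage
    num <- ode_damage_oracle(p, kD, tt)
    expect_equal(ana, unname(num), tolerance = 1e-6)
  }
})

test_that("running max is non-decreasing and catches interior peaks", {
  # pulse then zero: the damage maximum sits inside the decay segment only
  # if exposure crosses damage; here max is at the end of the rising limb
  p <- exposure_profile(c(0, 1, 5), c(0, 12, 0))
  tr <- guts_damage(p, 2, seq(0, 5, by = 0.25))
  expect_true(all(diff(tr$running_max) >= -1e-12))
  expect_true(all(tr$running_max >= tr$damage - 1e-12))
  # oracle: dense-grid maximum
  dense <- guts_damage(p, 2, seq(0, 5, length.out = 40001))
  expect_equal(max(tr$running_max), max(dense$damage), tolerance = 1e-8)
})

test_that("SD survival reproduces hand-integrated constant-excess hazard", {
  # damage ~ constant 10 (kD huge): hazard bw (10 - zw) = 0.6/d, t = 2
  p <- constant_profile_pub(10, 2)
  tr <- guts_damage(p, 1e8, c(0, 2))
  s <- survival_sd(tr, sd_params(1e8, 4, 0.1, 0))
  expect_equal(s$survival[1L], 1)
  expect_equal(s$survival[2L], exp(-1.2), tolerance = 1e-3)
})

test_that("SD survival reduces to background when damage stays sub-threshold or bw = 0", {
  p <- constant_profile_pub(3, 4)
  tr <- guts_damage(p, 2, 0:4)
  s <- survival_sd(tr, sd_params(2, 10, 0.5, 0.05))  # zw above any damage
  expect_equal(s$survival, exp(-0.05 * (0:4)), tolerance = 1e-9)
  s0 <- survival_sd(tr, sd_params(2, 0.1, 0, 0.05))  # bw = 0
  expect_equal(s0$survival, exp(-0.05 * (0:4)), tolerance = 1e-9)
})

test_that("IT survival follows the log-logistic threshold distribution", {
  p <- constant_profile_pub(4, 3)
  tr <- guts_damage(p, 1e8, c(1, 3))  # running max = median for t > 0
  s <- survival_it(tr, it_params(1e8, 4, 2, 0.02))
  expect_equal(s$survival, 0.5 * exp(-0.02 * c(1, 3)),
               tolerance = 1e-6)
  tr4 <- guts_damage(constant_profile_pub(4, 3), 1e8, 3)
  expect_equal(survival_it(tr4, it_params(1e8, 2, 2, 0))$survival,
               0.2, tolerance = 1e-6)  # 1 - 1/(1 + (4/2)^-2)
  z <- guts_damage(constant_profile_pub(0, 3), 1, c(0, 1, 3))
  expect_equal(survival_it(z, it_params(1, 5, 2, 0.03))$survival,
               exp(-0.03 * c(0, 1, 3)))
})

test_that("both variants are non-increasing in time and in exposure", {
  set.seed(23)
  sdp <- sd_params(1.5, 2, 0.3, 0.01)
  itp <- it_params(1.5, 3, 2.5, 0.01)
  for (i in 1:5) {
    p <- random_profile()
    tt <- seq(0, max(p$times), length.out = 25)
    tr1 <- guts_damage(p, 1.5, tt)
    tr2 <- guts_damage(scale_profile(p, 1.7), 1.5, tt)  # pointwise higher
    for (params in list(sdp, itp)) {
      f <- if (inherits(params, "sd_params")) survival_sd else survival_it
      s1 <- f(tr1, params)$survival
      s2 <- f(tr2, params)$survival
      expect_true(all(diff(s1) <= 1e-9))
      expect_true(all(s2 <= s1 + 1e-9))
      expect_equal(s1[1L], 1)
    }
  }
})

test_that("closed-form constant-exposure survival matches the general path", {
  tt <- c(0, 0.5, 1, 2, 4)
  for (conc in c(0, 1.8, 5.6, 18)) {
    tr <- guts_damage(constant_profile_pub(conc, 4), 0.7, tt)
    sdp <- sd_params(0.7, 2, 0.3, 0.01)
    itp <- it_params(0.7, 5, 3, 0.01)
    expect_equal(gutsred:::surv_constant(conc, sdp, tt),
                 survival_sd(tr, sdp)$survival, tolerance = 2e-6)
    expect_equal(gutsred:::surv_constant(conc, itp, tt),
                 survival_it(tr, itp)$survival, tolerance = 1e-9)
  }
})

test_that("simulated survivors follow the curve (degenerate and Monte-Carlo)", {
  tt <- 0:3
  all_live <- survival_curve_pub(tt, c(1, 1, 1, 1))
  expect_equal(simulate_survivors(all_live, 40, tt, seed = 1),
               rep(40L, 4))
  dead_end <- survival_curve_pub(tt, c(1, 0.5, 0.2, 0))
  expect_equal(simulate_survivors(dead_end, 40, tt, seed = 1)[4L], 0L)
  # mean over replicates within 3 standard errors of n0 * S(t)
  S <- c(1, 0.8, 0.55, 0.4)
  curve <- survival_curve_pub(tt, S)
  n0 <- 40; reps <- 3000
  sims <- vapply(seq_len(reps),
                 function(r) simulate_survivors(curve, n0, tt, seed = r),
                 integer(4))
  m <- rowMeans(sims)
  se <- sqrt(n0 * S * (1 - S)) / sqrt(reps)
  expect_true(all(abs(m - n0 * S) <= 3 * se + 1e-9))
  # reproducible under seed
  expect_identical(simulate_survivors(curve, n0, tt, seed = 99),
                   simulate_survivors(curve, n0, tt, seed = 99))
})
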