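test_that("laminar Green's function: causality, envelope, pole-branch oracle", {
  t <- seq(-2, 10, by = 0.05)
  g <- delta_response(1.5, 0.2, t)
  expect_true(all(g[t < 0] == 0))
  pos <- t >= 0
  expect_lt(max(abs(Mod(g[pos]) - exp(-0.2 * t[pos] / 2) / 1.5)), 1e-13)
  expect_error(delta_response(0, 0.1, t), "positive")
  expect_error(delta_response(1, -0.1, t), "nonnegative")

  # ODE oracle at m = 1: initialize on the decaying (retarded rotating-wave)
  # pole of s^2 + m^2 + iC and integrate ten carrier periods at weak damping
  m <- 1; C <- 0.01
  tt <- seq(0, 10 * 2 * pi / m, by = 0.02)
  num <- ode_oracle_2nd(
    (1 + 0i) / m, (1i * m - C / 2) / m,
    function(y, t) -(m^2 + 1i * C) * y, tt, rtol = 1e-12
  )
  g2 <- delta_response(m, C, tt)
  expect_lt(max(Mod(g2 - as.vector(num))) / max(Mod(num)), 1e-3)
})

test_that("two-layer response transfers amplitude and conserves layer power", {
  m <- 1.2; C <- 0.15; alpha <- 0.05
  t <- seq(0, 80, by = 0.05)
  rec <- two_layer_response(m, C, alpha, stim_layer = 2, t)
  # t -> 0+: all response on the stimulated layer
  expect_equal(Mod(rec$traces[2, 1]), 1 / m, tolerance = 1e-12)
  expect_equal(Mod(rec$traces[1, 1]), 0, tolerance = 1e-12)
  # alpha t = pi/2: fully transferred to the other layer
  i_half <- which.min(abs(alpha * t - pi / 2))
  expect_lt(Mod(rec$traces[2, i_half]) / Mod(rec$traces[1, i_half]), 2e-3)
  # layer power sum decays exactly as e^{-Ct} / m^2
  en <- colSums(Mod(rec$traces)^2)
  expect_lt(max(abs(en - exp(-C * t) / m^2)), 1e-12)
})

test_that("three-layer response respects the generator block structure", {
  t <- seq(0, 60, by = 0.1)
  # zero coefficients: response confined to the stimulated layer
  rec0 <- three_layer_response(1, 0.1, c(0, 0, 0), stim_layer = 2, t)
  expect_true(all(Mod(rec0$traces[c(1, 3), ]) == 0))
  expect_equal(Mod(rec0$traces[2, 1]), 1, tolerance = 1e-12)
  # only the 1-2 coupling active: layer 3 never responds
  rec12 <- three_layer_response(1, 0.1, c(0.07, 0, 0), stim_layer = 1, t)
  expect_true(all(Mod(rec12$traces[3, ]) == 0))
  expect_gt(max(Mod(rec12$traces[2, ])), 0.1)
  # orthogonality: layer energies sum to the carrier envelope exactly
  rec <- three_layer_response(0.8, 0.12, c(0.05, 0.02, 0.03), 1, t)
  en <- colSums(Mod(rec$traces)^2)
  expect_lt(max(abs(en - exp(-0.12 * t) / 0.8^2)), 1e-12)
})

test_that("synthetic LFP: exactness at zero noise, determinism, calibrated noise", {
  t <- seq(0, 30, by = 0.05)
  pars <- list(m = 1, C = 0.1, alpha = 0.05)
  clean <- make_synthetic_lfp("two_layer", pars, t, noise_sd = 0)
  fwd <- two_layer_response(1, 0.1, 0.05, 1, t)
  expect_identical(clean$traces, fwd$traces)
  r1 <- make_synthetic_lfp("two_layer", pars, t, noise_sd = 0.05, seed = 11)
  r2 <- make_synthetic_lfp("two_layer", pars, t, noise_sd = 0.05, seed = 11)
  expect_identical(r1$traces, r2$traces)
  expect_false(identical(
    r1$traces,
    make_synthetic_lfp("two_layer", pars, t, noise_sd = 0.05, seed = 12)$traces
  ))
  # empirical noise sd within 3% of requested over >= 1e4 samples
  tl <- seq(0, 500, by = 0.05)   # 2 layers x 10001 samples
  rn <- make_synthetic_lfp("two_layer", pars, tl, noise_sd = 0.04, seed = 3)
  fwd <- two_layer_response(1, 0.1, 0.05, 1, tl)
  noise <- Re(rn$traces - fwd$traces)
  expect_lt(abs(stats::sd(as.vector(noise)) - 0.04) / 0.04, 0.03)
  expect_error(make_synthetic_lfp("two_layer", pars, t, noise_sd = -1),
               "nonnegative")
  # real-observation mode keeps imaginary parts exactly zero
  rr <- make_synthetic_lfp("two_layer", pars, t, noise_sd = 0.02, seed = 1,
                           real_observations = TRUE)
  expect_true(all(Im(rr$traces) == 0))
  expect_true(isTRUE(rr$meta$real_observations))
})

test_that("noiseless two-layer records invert to within 1%", {
  t <- seq(0, 60, by = 0.1)
  truth <- c(m = 1, C = 0.1, alpha = 0.05)
  rec <- make_synthetic_lfp("two_layer", as.list(truth), t, noise_sd = 0)
  # init within +-50% of the truth
  fit <- fit_lfp(rec, "two_layer", init = c(m = 1.4, C = 0.06, alpha = 0.07))
  expect_true(fit$converged)
  expect_true(all(abs(fit$estimates - truth) / truth < 0.01))
  expect_true(all(fit$standard_errors >= 0))
})

test_that("noisy records invert to within 10% and a null rotation is not detected", {
  t <- seq(0, 60, by = 0.1)
  truth <- c(m = 1, C = 0.1, alpha = 0.05)
  rec <- make_synthetic_lfp("two_layer", as.list(truth), t,
                            noise_sd = 0.05 * 1, seed = 17)  # 5% of the peak 1/m
  fit <- fit_lfp(rec, "two_layer", init = c(m = 1.2, C = 0.12, alpha = 0.06),
                 n_restarts = 3)
  expect_true(all(abs(fit$estimates - truth) / truth < 0.10))
  # alpha = 0 data: estimate within 2 standard errors of zero
  rec0 <- make_synthetic_lfp("two_layer", list(m = 1, C = 0.1, alpha = 0), t,
                             noise_sd = 0.05, seed = 5)
  fit0 <- fit_lfp(rec0, "two_layer", init = c(m = 1.1, C = 0.12, alpha = 0.03),
                  n_restarts = 3)
  expect_lt(abs(fit0$estimates[["alpha"]]),
            2 * fit0$standard_errors[["alpha"]])
})

test_that("three-layer inversion recovers the generator coefficients", {
  t <- seq(0, 60, by = 0.1)
  truth <- c(m = 1, C = 0.1, c12 = 0.04, c13 = 0, c23 = 0.02)
  rec <- make_synthetic_lfp("three_layer", as.list(truth), t,
                            noise_sd = 0.02, seed = 2)
  fit <- fit_lfp(rec, "three_layer",
                 init = c(m = 1.2, C = 0.12, c12 = 0.05, c13 = 0.01, c23 = 0.03))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["m"]] - 1), 0.02)
  expect_lt(abs(fit$estimates[["c12"]] - 0.04), 0.005)
  expect_lt(abs(fit$estimates[["c23"]] - 0.02), 0.005)
})

test_that("short records are rejected before fitting", {
  t <- seq(0, 0.5, by = 0.1)
  rec <- make_synthetic_lfp("two_layer", list(m = 1, C = 0.1, alpha = 0), t)
  expect_error(fit_lfp(rec, "two_layer", init = c(m = 1, C = 0.1, alpha = 0)),
               "too short")
})
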