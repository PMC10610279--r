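ref_params <- function() {
  structural_params(Tlag = 0.17, Tk0 = 1.35, CL = 56.15, V1 = 208.34,
                    Q = 14.63, V2 = 76.15)
}

irt_params <- function() {
  # immediate-release-tablet covariate level applied to Tk0 and V1
  structural_params(Tlag = 0.17, Tk0 = 1.35 * exp(-0.4), CL = 56.15,
                    V1 = 208.34 * exp(-1.26), Q = 14.63, V2 = 76.15)
}

test_that("micro constants follow the clearance/volume reparameterization", {
  k <- micro_constants(ref_params())
  expect_equal(k$k10, 56.15 / 208.34, tolerance = 1e-12)
  expect_equal(k$k10, 0.2695, tolerance = 1e-3)
  expect_equal(k$k21, 14.63 / 76.15, tolerance = 1e-12)
  expect_equal(k$k21, 0.1921, tolerance = 1e-3)

  k2 <- micro_constants(irt_params())
  expect_equal(k2$k10, 0.9501, tolerance = 1e-4)

  ident <- structural_params(0.1, 1, CL = 30, V1 = 30, Q = 50, V2 = 50)
  ki <- micro_constants(ident)
  expect_equal(ki$k10, 1)
  expect_equal(ki$k21, 1)

  expect_error(structural_params(-0.1, 1.35, 56.15, 208.34, 14.63, 76.15),
               "positive")
  expect_error(structural_params(0.17, 1.35, NA, 208.34, 14.63, 76.15),
               "finite")
})

test_that("derived metrics match an independent polynomial root-finder", {
  p <- irt_params()
  k <- micro_constants(p)
  # roots of x^2 - (k10+k12+k21) x + k10*k21 via polyroot
  rts <- sort(Re(polyroot(c(k$k10 * k$k21, -(k$k10 + k$k12 + k$k21), 1))))
  d <- derived_metrics(p)
  expect_equal(d$beta_macro, rts[1], tolerance = 1e-10)
  expect_equal(d$alpha, rts[2], tolerance = 1e-10)
  expect_equal(d$t_half_term, 4.72, tolerance = 1e-3)
  expect_equal(d$t_half_dist, 0.558, tolerance = 1e-3)
  expect_equal(d$Vss, 135.25, tolerance = 1e-4)
  expect_true(d$t_half_dist < d$t_half_term)
  # invariants of the quadratic
  expect_equal(d$alpha * d$beta_macro, k$k10 * k$k21, tolerance = 1e-12)
  expect_equal(d$alpha + d$beta_macro, k$k10 + k$k12 + k$k21, tolerance = 1e-12)
})

test_that("one-compartment limit: solution converges as Q -> 0", {
  # The terminal exponential's rate tends to k21 -> 0 but its coefficient
  # vanishes with it: the curve converges to the one-compartment zero-order
  # solution and the dominant (alpha) rate to CL/V1.
  p <- structural_params(0.17, 1.35, CL = 56.15, V1 = 208.34, Q = 1e-7, V2 = 76.15)
  d <- derived_metrics(p)
  expect_equal(log(2) / d$alpha, log(2) * 208.34 / 56.15, tolerance = 1e-4)
  v <- model_variant(1L, "zero-order", lag = TRUE)
  tt <- c(0.5, 1, 2, 4, 8, 12)
  one_cpt <- conc_variant(v, list(Tlag = 0.17, Tk0 = 1.35, CL = 56.15, V1 = 208.34),
                          20, tt)
  expect_equal(conc_single_dose(p, 20, tt), one_cpt, tolerance = 1e-6)
})

test_that("degenerate (coincident-rate) parameters use the critically damped form", {
  # k10 == k21 with k12 vanishing collapses the discriminant:
  # choose Q so k12 = Q/V1 is ~1e-11 * k10 and V2 so k21 = k10
  V1 <- 100; CL <- 50
  k10 <- CL / V1
  Q <- k10 * 1e-11 * V1
  p <- structural_params(0.1, 0.5, CL, V1, Q, V2 = Q / k10)
  d <- derived_metrics(p)
  expect_true(d$degenerate)
  tt <- c(0.2, 0.5, 1, 2, 4)
  oc <- ode_conc_oracle(p, 20, tt)
  expect_equal(conc_single_dose(p, 20, tt), oc, tolerance = 1e-6)
})

test_that("single-dose solution is piecewise with exact continuity", {
  p <- irt_params()
  expect_equal(conc_single_dose(p, 20, c(0, 0.05, p$Tlag)), c(0, 0, 0))
  expect_equal(conc_single_dose(p, 0, c(0, 1, 5)), c(0, 0, 0))
  expect_error(conc_single_dose(p, 20, c(-1, 2)), "negative")

  cmax <- exposure_metrics(p, regimen(20, 24, 1L))$Cmax
  eps <- 1e-9
  for (brk in c(p$Tlag, p$Tlag + p$Tk0)) {
    gap <- abs(conc_single_dose(p, 20, brk - eps) -
               conc_single_dose(p, 20, brk + eps))
    expect_lt(gap, 1e-6 * cmax)
  }
})

test_that("closed form agrees with the ODE oracle over random parameter sets", {
  tt <- c(0.1, 0.25, 0.5, 1, 2, 4, 8, 12, 24, 48)
  for (p in random_params(100, seed = 11)) {
    oc <- ode_conc_oracle(p, 20, tt)
    cf <- conc_single_dose(p, 20, tt)
    expect_equal(cf, oc, tolerance = 1e-6)
  }
})

test_that("profiles are dose-linear and superpose across doses", {
  p <- irt_params()
  tt <- seq(0.25, 40, by = 0.25)
  r <- regimen(5, 8, 5L)
  prof <- conc_profile(p, r, tt)
  expect_identical(conc_profile(p, regimen(10, 8, 5L), tt), 2 * prof)
  manual <- Reduce(`+`, lapply(0:4, function(j) {
    td <- tt - j * 8
    out <- numeric(length(tt))
    out[td >= 0] <- conc_single_dose(p, 5, td[td >= 0])
    out
  }))
  expect_identical(prof, manual)
  expect_identical(conc_profile(p, regimen(5, 8, 1L), tt),
                   conc_single_dose(p, 5, tt))
  expect_identical(conc_profile(p, r, numeric(0)), numeric(0))
})

test_that("multi-dose profile matches the ODE oracle integrating all doses", {
  p <- irt_params()
  r <- regimen(5, 8, 21L)
  tt <- seq(160, 168, by = 0.5)
  oc <- ode_conc_oracle(p, 5, tt, dose_times = (0:20) * 8)
  expect_equal(conc_profile(p, r, tt), oc, tolerance = 1e-6)
})

test_that("total single-dose AUC equals dose/CL for random parameter sets", {
  for (p in random_params(10, seed = 3)) {
    expect_equal(auc_single_dose(p, 20), 20 * 1000 / p$CL, tolerance = 1e-3)
  }
})

test_that("exposure metrics: boundary minimum and steady-state maximum", {
  p <- irt_params()
  # single dose on an effectively infinite interval: minimum at the boundary
  m1 <- exposure_metrics(p, regimen(20, 1000, 1L))
  expect_equal(m1$Cmin, 0)
  expect_gt(m1$Cmax, 0)
  expect_lt(m1$Tmax, 2)

  # steady state 5 mg q8h: Cmax matches a brute-force dense grid
  nss <- max(10L, ceiling(5 * derived_metrics(p)$t_half_term / 8))
  r <- regimen(5, 8, nss)
  m <- exposure_metrics(p, r)
  grid <- seq((nss - 1) * 8, nss * 8, by = 1e-3)
  # the peak sits on the input-end kink, so a 1e-3 h grid resolves it only
  # to first order in the step
  expect_equal(m$Cmax, max(conc_profile(p, r, grid)), tolerance = 1e-3)
  expect_gte(m$Cmax, max(conc_profile(p, r, grid)))
  expect_gte(m$Cmax, m$Cmin)
  expect_gte(m$Cmin, 0)
  expect_true(m$Tmax >= (nss - 1) * 8 && m$Tmax <= nss * 8)
  # trough change between successive intervals below 0.1% at steady state
  tr1 <- conc_profile(p, r, (nss - 1) * 8)
  tr2 <- conc_profile(p, r, nss * 8)
  expect_lt(abs(tr2 - tr1) / tr1, 1e-3)
})

test_that("comparator variants agree with their own ODE systems", {
  skip_if_not_installed("deSolve")
  # one-compartment, first-order absorption, no lag
  v1 <- model_variant(1L, "first-order", lag = FALSE)
  pars <- list(ka = 1.2, CL = 40, V1 = 150)
  tt <- c(0.25, 0.5, 1, 2, 4, 8)
  ode1 <- function(t, y, parms) {
    list(c(-1.2 * y[1], 1.2 * y[1] - 40 / 150 * y[2]))
  }
  sol <- deSolve::lsoda(c(20000, 0), c(0, tt), ode1, rtol = 1e-11, atol = 1e-11)
  expect_equal(conc_variant(v1, pars, 20, tt), sol[-1, 3] / 150,
               tolerance = 1e-6, ignore_attr = TRUE)

  # two-compartment, first-order absorption, with lag
  v2 <- model_variant(2L, "first-order", lag = TRUE)
  pars2 <- list(Tlag = 0.3, ka = 0.9, CL = 56, V1 = 60, Q = 15, V2 = 76)
  ode2 <- function(t, y, parms) {
    k10 <- 56 / 60; k12 <- 15 / 60; k21 <- 15 / 76
    list(c(-0.9 * y[1],
           0.9 * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  tau <- tt  # integrate in lag-shifted time
  sol2 <- deSolve::lsoda(c(20000, 0, 0), c(0, tau), ode2, rtol = 1e-11, atol = 1e-11)
  expect_equal(conc_variant(v2, pars2, 20, tt + 0.3), sol2[-1, 3] / 60,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(conc_variant(v2, pars2, 20, c(0, 0.29)), c(0, 0))

  expect_error(conc_variant(v1, list(ka = 1), 20, 1), "params must provide")
  expect_error(model_variant(3L), "1 or 2")
})
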