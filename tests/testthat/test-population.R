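test_that("typical parameters apply formulation coefficients multiplicatively", {
  m <- ava_model()
  p1 <- typical_params(m, "#1")
  expect_equal(unlist(p1[c("Tlag", "Tk0", "CL", "V1", "Q", "V2")]),
               c(Tlag = 0.17, Tk0 = 1.35, CL = 56.15, V1 = 208.34,
                 Q = 14.63, V2 = 76.15))
  p2 <- typical_params(m, "#2")
  expect_equal(p2$V1, 208.34 * exp(-1.26), tolerance = 1e-12)
  expect_equal(p2$V1, 59.10, tolerance = 1e-3)
  expect_equal(p2$Tk0, 0.905, tolerance = 1e-3)
  expect_equal(p2$CL, 56.15)  # unaffected parameter untouched
  # the steady-state volume for the immediate-release tablet
  expect_equal(p2$V1 + p2$V2, 135.25, tolerance = 1e-3)
  p3 <- typical_params(m, "#3")
  expect_equal(p3$Tk0, 0.684, tolerance = 1e-3)
  expect_equal(p3$V1, 60.29, tolerance = 1e-3)
  expect_error(typical_params(m, "#9"), "unknown formulation")
})

test_that("model construction enforces the hierarchical-layer invariants", {
  expect_error(fixed_effects(c(Tlag = -1, Tk0 = 1)), "positive")
  expect_error(fixed_effects(c(Tlag = 0.2), beta = list(Tk0 = c("#2" = 1))),
               "unknown parameter")
  expect_error(fixed_effects(c(Tk0 = 1), beta = list(Tk0 = c("#1" = 1))),
               "non-reference")
  expect_error(random_effects_spec(c(Tlag = -0.1)), "non-negative")
  expect_error(random_effects_spec(
    c(A = 0.3, B = 0.3, C = 0.3),
    correlations = list(list(pair = c("A", "B"), rho = 0.9),
                        list(pair = c("B", "C"), rho = 0.9),
                        list(pair = c("A", "C"), rho = -0.9))),
    "positive definite")
  expect_error(error_model(-0.1), "non-negative")
  # fixed/random parameter sets must agree with the variant
  expect_error(population_model(
    fixed_effects(c(Tlag = 0.2, Tk0 = 1, CL = 50, V1 = 200, Q = 15, V2 = 76)),
    random_effects_spec(c(Tlag = 0.3)),
    error_model(0.1)), "must cover exactly")
})

test_that("sampled individuals recover the population law", {
  m <- ava_model()
  # degenerate: all omegas zero returns the typical values exactly
  m0 <- m
  m0$random <- random_effects_spec(
    stats::setNames(rep(0, 6), names(m$random$omega)))
  s0 <- sample_individual(m0, "#2", n = 3, seed = 1)
  p2 <- unlist(typical_params(m, "#2")[colnames(s0$params)])
  for (i in 1:3) expect_equal(s0$params[i, ], p2)
  expect_true(all(s0$eta == 0))

  s <- sample_individual(m, "#1", n = 1e5, seed = 42)
  # correlation of the (V1, CL) random effects
  expect_equal(cor(s$eta[, "V1"], s$eta[, "CL"]), 0.72, tolerance = 0.015)
  # lognormal median equals the typical value
  expect_equal(median(s$params[, "CL"]), 56.15, tolerance = 0.01)
  # empirical omegas within 2%, other pairs uncorrelated
  for (nm in colnames(s$eta)) {
    expect_equal(sd(s$eta[, nm]), m$random$omega[[nm]], tolerance = 0.02)
  }
  expect_lt(abs(cor(s$eta[, "Tlag"], s$eta[, "Q"])), 0.02)
  # lognormal closure: log realized parameter is normal with the stated moments
  lcl <- log(s$params[, "CL"])
  expect_equal(mean(lcl), log(56.15), tolerance = 0.01)
  expect_equal(sd(lcl), 0.21, tolerance = 0.01)
  expect_gt(shapiro.test(sample(lcl, 5000))$p.value, 1e-4)
})

test_that("proportional residual error has the stated moments", {
  e <- error_model(0.14)
  expect_identical(apply_residual_error(c(0, 0, 0), e, seed = 1), c(0, 0, 0))
  e0 <- error_model(0)
  expect_identical(apply_residual_error(c(5, 50), e0), c(5, 50))
  set.seed(7)
  y <- apply_residual_error(rep(100, 1e5), e)
  expect_equal(mean(y), 100, tolerance = 0.002)
  expect_equal(sd(y), 14, tolerance = 0.022)
  # negative observations are possible but rare at b = 0.14
  expect_gte(mean(y >= 0), 0.999)
  expect_error(apply_residual_error(-1, e), "non-negative")
})

test_that("simulated observations are deterministic and match the model", {
  m <- ava_model()
  d <- default_design()
  t1 <- simulate_observations(m, d, seed = 5)
  t2 <- simulate_observations(m, d, seed = 5)
  expect_identical(t1, t2)
  # noise-free, variability-free simulation equals typical predictions
  m0 <- m
  m0$random <- random_effects_spec(
    stats::setNames(rep(0, 6), names(m$random$omega)))
  m0$error <- error_model(0)
  t0 <- simulate_observations(m0, d, seed = 1)
  obs <- t0[t0$EVID == 0, ]
  for (f in ava_formulations()) {
    sub <- obs[obs$FORM == f & obs$ID == 1, ]
    expect_equal(sub$DV,
                 conc_single_dose(typical_params(m, f), d$dose_per_period, sub$TIME),
                 tolerance = 1e-12)
  }
  # grand-mean profile close to the typical curve (Monte-Carlo agreement)
  big <- simulate_observations(m, study_design(
    n_subjects = 200,
    periods = rep(list("#2"), 200),
    dose_per_period = 20,
    sampling_times = d$sampling_times), seed = 9)
  bo <- big[big$EVID == 0, ]
  typ <- conc_single_dose(typical_params(m, "#2"), 20, d$sampling_times)
  for (j in c(4, 8, 12)) {
    tt <- d$sampling_times[j]
    x <- bo$DV[bo$TIME == tt]
    mc_se <- sd(x) / sqrt(length(x))
    # lognormal skew puts the mean a bit above the typical curve; allow 3 SE
    # around the simulated mean of the model itself rather than equality
    expect_lt(abs(mean(x) - typ[j]), max(4 * mc_se, 0.25 * typ[j]))
  }
})
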