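# Builds one small noise-free-ish single-subject dataset reused across blocks.
rich_single_subject <- function(seed = 4) {
  m0 <- ava_model()
  m0$random <- random_effects_spec(
    stats::setNames(rep(0, 6), names(m0$random$omega)))
  m0$error <- error_model(0.01)
  d <- study_design(1, list("#1"), 20, seq(0.1, 24, by = 0.1))
  simulate_observations(m0, d, seed = seed)
}

# manual cohort with known random effects, one period of formulation #1
cohort_known_etas <- function(n, times, b = 0.14, seed = 31) {
  m <- ava_model()
  s <- sample_individual(m, "#1", n = n, seed = seed)
  rows <- lapply(seq_len(n), function(i) {
    p <- structural_params(s$params[i, "Tlag"], s$params[i, "Tk0"],
                           s$params[i, "CL"], s$params[i, "V1"],
                           s$params[i, "Q"], s$params[i, "V2"])
    cc <- conc_single_dose(p, 20, times)
    dv <- if (b > 0) cc * (1 + b * stats::rnorm(length(cc))) else cc
    data.frame(ID = i, TIME = c(0, times),
               AMT = c(20, rep(NA_real_, length(cc))),
               DV = c(NA_real_, dv),
               EVID = c(1L, rep(0L, length(cc))),
               MDV = c(1L, rep(0L, length(cc))),
               FORM = "#1", PERIOD = 1L,
               BLQ = c(NA, dv < 5), stringsAsFactors = FALSE)
  })
  list(tab = event_table(do.call(rbind, rows)), eta = s$eta)
}

test_that("Wald test matches the reported covariate z-statistics", {
  expect_equal(wald_test(0, 2), 1)
  expect_error(wald_test(1, 0), "positive")
  # V1 coefficient for the immediate-release tablet: |z| ~ 18.5
  expect_lt(wald_test(-1.26, 0.068), 1e-15)
  expect_equal(abs(-1.26 / 0.068), 18.53, tolerance = 1e-3)
  # Tk0 coefficient: |z| ~ 3.33, p ~ 8.6e-4
  expect_equal(wald_test(-0.4, 0.12), 8.59e-4, tolerance = 1e-2)
})

test_that("BICc applies the hybrid subject/observation penalty", {
  expect_equal(bicc(100, 12, 36, 0, 0), 100)
  expect_equal(bicc(100, 12, 36, 2, 1), 100 + 2 * log(12) + log(36))
})

test_that("importance-sampling OFV degenerates to the fixed-effect likelihood", {
  m0 <- ava_model()
  m0$random <- random_effects_spec(
    stats::setNames(rep(0, 6), names(m0$random$omega)))
  d <- study_design(2, list(c("#1", "#2"), c("#2", "#1")), 20,
                    c(0.5, 1, 2, 4, 8))
  tab <- simulate_observations(ava_model(), d, seed = 6)
  got <- ofv_importance_sampling(m0, tab, n_mc = 200, seed = 1)
  # independent closed form: no random effects means no integral
  obs <- tab[tab$EVID == 0, ]
  expected <- 0
  for (i in unique(obs$ID)) for (per in unique(obs$PERIOD)) {
    sub <- obs[obs$ID == i & obs$PERIOD == per, ]
    f <- conc_single_dose(typical_params(m0, sub$FORM[1]), 20, sub$TIME)
    expected <- expected - 2 * sum(dnorm(sub$DV, f, sqrt((0.14 * f)^2 + 0.01^2),
                                         log = TRUE))
  }
  expect_equal(got, expected, tolerance = 1e-8)
})

test_that("OFV orders the generating model above a mis-specified one", {
  tab <- generate_study(ava_model(), seed = 12)
  m <- ava_model()
  m_bad <- m
  pop <- m$fixed$pop; pop["CL"] <- pop["CL"] * 2
  m_bad$fixed <- fixed_effects(pop, m$fixed$beta, m$fixed$reference_category)
  o_true <- ofv_importance_sampling(m, tab, n_mc = 400, seed = 3)
  o_bad <- ofv_importance_sampling(m_bad, tab, n_mc = 400, seed = 3)
  expect_lt(o_true, o_bad)
})

test_that("quadrupling the Monte-Carlo size shrinks the OFV estimator variance", {
  d <- study_design(3, list("#1", "#2", "#3"), 20, c(0.5, 1, 2, 4, 8))
  tab <- simulate_observations(ava_model(), d, seed = 15)
  m <- ava_model()
  o_small <- vapply(1:20, function(s)
    ofv_importance_sampling(m, tab, n_mc = 100, seed = s), numeric(1))
  o_big <- vapply(1:20, function(s)
    ofv_importance_sampling(m, tab, n_mc = 400, seed = 100 + s), numeric(1))
  expect_gt(var(o_small) / var(o_big), 1.8)
  expect_error(ofv_importance_sampling(m, tab, n_mc = 50), "at least 100")
})

test_that("empirical Bayes modes recover known effects and shrink under sparsity", {
  m <- ava_model()
  # noiseless recovery on a rich grid
  ck <- cohort_known_etas(1, seq(0.25, 24, by = 0.25), b = 0, seed = 51)
  m_tight <- m; m_tight$error <- error_model(0.02)
  eta_hat <- ebe_estimate(m_tight, ck$tab, id = 1, sigma_floor = 1e-4)
  expect_equal(unname(eta_hat), unname(ck$eta[1, names(eta_hat)]),
               tolerance = 0.02)

  # prior-only limit: observations in the pre-lag window carry no parameter
  # information (prediction identically zero nearby), so the mode is the
  # prior mode at zero
  flat_tab <- event_table(data.frame(
    ID = 1L, TIME = c(0, 0.05), AMT = c(20, NA), DV = c(NA, 0),
    EVID = c(1L, 0L), MDV = c(1L, 0L), FORM = "#1", PERIOD = 1L,
    BLQ = c(NA, TRUE)))
  eta_flat <- ebe_estimate(m, flat_tab, id = 1)
  expect_equal(unname(eta_flat), rep(0, 6))

  # shrinkage towards zero with sparse sampling
  ck2 <- cohort_known_etas(100, c(1, 4, 10), b = 0.14, seed = 52)
  eh <- t(vapply(1:100, function(i) ebe_estimate(m, ck2$tab, id = i),
                 numeric(6)))
  for (nm in c("CL", "V1", "Tk0")) {
    expect_lt(mean(abs(eh[, nm])), mean(abs(ck2$eta[, nm])))
  }
})

test_that("SAEM with zero iterations returns the initial model unchanged", {
  tab <- rich_single_subject()
  init <- ava_model()
  fit0 <- saem_fit(tab, init = init,
                   settings = fit_settings(burn_in = 0, n_explore = 0,
                                           n_smooth = 0, n_mc_ofv = 300))
  expect_identical(fit0$estimates, init)
})

test_that("SAEM pins structural parameters on near-noiseless rich data", {
  tab <- rich_single_subject()
  fit <- saem_fit(tab, settings = fit_settings(seed = 2, n_mc_ofv = 300))
  truth <- c(Tlag = 0.17, Tk0 = 1.35, CL = 56.15, V1 = 208.34,
             Q = 14.63, V2 = 76.15)
  est <- fit$estimates$fixed$pop[names(truth)]
  expect_true(all(abs(est / truth - 1) < 0.02))
})

test_that("a crossover fit is stable, stochastic-error calibrated, and rejects bad input", {
  m <- ava_model()
  tab <- generate_study(m, seed = 2)
  fit <- saem_fit(tab, settings = fit_settings(burn_in = 10, n_explore = 150,
                                               n_smooth = 100, n_mc_ofv = 300,
                                               seed = 2))
  expect_true(fit$converged)
  expect_true(is.finite(fit$ofv))
  expect_true(is.finite(fit$bicc))
  expect_equal(fit$n_subjects, 12L)
  # trace path: fixed effects stable over the last 50 smoothing iterations
  last <- tail(fit$trace[, 1:6], 50)
  rel <- apply(last, 2, sd) / colMeans(last)
  expect_true(all(rel < 0.01))
  # error coefficient recovered closely (it is the best-identified parameter)
  expect_equal(fit$estimates$error$b, 0.14, tolerance = 0.15)
  # linearized standard errors on the reported scale: same order as a
  # small-study population fit (roughly 1-100% RSE)
  expect_true(all(is.finite(fit$rse)))
  expect_true(all(fit$rse[1:6] > 0.5 & fit$rse[1:6] < 100))
  # the correlated pair is estimated with the right sign and rough size
  rho <- fit$estimates$random$correlations[[1]]
  expect_setequal(rho$pair, c("V1", "CL"))
  expect_gt(rho$rho, 0.2)

  # subjects without observations are rejected up front
  bad <- tab[!(tab$ID == 3 & tab$EVID == 0), ]
  expect_error(saem_fit(bad, settings = fit_settings(n_explore = 5, n_smooth = 5)),
               "without observations")
})

test_that("covariate screening is calibrated and detects planted signal", {
  set.seed(77)
  ebes <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("CL", "V1")))
  # planted: covariate equal to an eta column has correlation one
  sc <- covariate_screen(ebes, data.frame(copyCL = ebes[, "CL"]))
  expect_equal(sc$statistic[sc$eta == "CL"], 1, tolerance = 1e-12)
  expect_lt(sc$p_value[sc$eta == "CL"], 1e-10)

  # null calibration: independent covariates give uniform p-values
  pvals <- vapply(1:100, function(i) {
    covariate_screen(ebes, data.frame(x = rnorm(30)))$p_value[1]
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  # constant covariate reported as not applicable
  scc <- covariate_screen(ebes, data.frame(k = rep(1, 30)))
  expect_true(all(is.na(scc$p_value)))
  expect_error(covariate_screen(ebes[1:2, ], data.frame(x = rnorm(2))),
               "at least 3")
})

test_that("formulation already in the model leaves no residual EBE association", {
  # parallel-group design: each subject receives a single formulation, the
  # model carries the formulation coefficients, so EBEs under the true model
  # must be free of formulation effects
  m <- ava_model()
  n_sig <- 0L
  for (r in 1:10) {
    d <- study_design(12, as.list(rep(ava_formulations(), 4)), 20,
                      default_design()$sampling_times)
    tab <- simulate_observations(m, d, seed = 300 + r)
    eh <- t(vapply(1:12, function(i) ebe_estimate(m, tab, id = i), numeric(6)))
    colnames(eh) <- names(m$fixed$pop)
    forms <- vapply(d$periods, `[`, character(1), 1)
    sc <- covariate_screen(eh[, c("Tk0", "V1")], data.frame(form = forms))
    if (any(sc$p_value < 0.05, na.rm = TRUE)) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2L)
})
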