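#' SAEM fit settings
#'
#' Controls for the stochastic approximation EM estimator. The step-size
#' schedule is the standard two-phase regime: step 1 during the exploratory
#' phase (`n_explore` iterations), then `1 / iter^step_alpha` during the
#' smoothing phase (`n_smooth` iterations), with `step_alpha` in (0.5, 1].
#'
#' @param burn_in MCMC equilibration iterations before any parameter update.
#' @param n_explore Exploratory (step size 1) iterations, K1.
#' @param n_smooth Smoothing (decreasing step) iterations, K2.
#' @param n_kernel MCMC kernel sweeps per iteration.
#' @param step_alpha Exponent of the smoothing-phase step-size decay.
#' @param n_mc_ofv Monte-Carlo size of the importance-sampling likelihood.
#' @param tol Relative-stability tolerance used for the convergence flag.
#' @param seed Integer seed driving the whole fit.
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(burn_in = 20L, n_explore = 300L, n_smooth = 200L,
                         n_kernel = 2L, step_alpha = 0.7, n_mc_ofv = 1000L,
                         tol = 0.01, seed = 1L) {
  stopifnot(burn_in >= 0, n_explore >= 0, n_smooth >= 0, n_kernel >= 1,
            step_alpha > 0.5, step_alpha <= 1, n_mc_ofv >= 100, tol > 0)
  structure(list(burn_in = as.integer(burn_in), n_explore = as.integer(n_explore),
                 n_smooth = as.integer(n_smooth), n_kernel = as.integer(n_kernel),
                 step_alpha = step_alpha, n_mc_ofv = as.integer(n_mc_ofv),
                 tol = tol, seed = as.integer(seed)),
            class = "fit_settings")
}

## ---- internal data layout ---------------------------------------------
## Observations are flattened to one row per (subject, period, time):
##   subj, dose, time, y, form. The covariate design X (n_obs x n_beta)
## holds the indicator of each beta entry; SH = X beta gives the log-scale
## covariate shift, mapped to parameters via bpar (the parameter index of
## each beta entry).
flatten_data <- function(data, variant) {
  validate_event_table(data)
  obs <- data[data$EVID == 0L, , drop = FALSE]
  doses <- data[data$EVID == 1L, , drop = FALSE]
  ids <- sort(unique(data$ID))
  no_obs <- setdiff(ids, unique(obs$ID))
  if (length(no_obs)) {
    stop("subjects without observations: ", paste(no_obs, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(doses$ID, doses$PERIOD)
  dose_of <- stats::setNames(doses$AMT, key)
  okey <- paste(obs$ID, obs$PERIOD)
  if (!all(okey %in% key)) stop("observation rows without a dose event", call. = FALSE)
  list(subj = match(obs$ID, ids), ids = ids,
       dose = unname(dose_of[okey]), time = obs$TIME, y = obs$DV,
       form = obs$FORM, n = nrow(obs), N = length(ids))
}

## fast unchecked concentration kernels used inside the estimator; theta is a
## matrix with one row per observation row
pred_rows <- function(variant, theta, dose, time) {
  if (variant$absorption == "zero-order") {
    Tlag <- if (variant$lag) theta[, "Tlag"] else 0
    Tk0 <- theta[, "Tk0"]
    V1 <- theta[, "V1"]
    k10 <- theta[, "CL"] / V1
    if (variant$n_compartments == 2L) {
      k12 <- theta[, "Q"] / V1; k21 <- theta[, "Q"] / theta[, "V2"]
      s <- k10 + k12 + k21
      d <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
      al <- (s + d) / 2; be <- pmax((s - d) / 2, 1e-12)
      A <- (al - k21) / (al - be); B <- (k21 - be) / (al - be)
      cum <- function(x) {
        pos <- x > 0
        out <- numeric(length(x))
        out[pos] <- A[pos] * (1 - exp(-al[pos] * x[pos])) / al[pos] +
          B[pos] * (1 - exp(-be[pos] * x[pos])) / be[pos]
        out
      }
    } else {
      cum <- function(x) {
        pos <- x > 0
        out <- numeric(length(x))
        out[pos] <- (1 - exp(-k10[pos] * x[pos])) / k10[pos]
        out
      }
    }
    tau <- time - Tlag
    R0 <- dose * 1000 / Tk0
    return((R0 / V1) * (cum(tau) - cum(tau - Tk0)))
  }
  ## first-order absorption
  Tlag <- if (variant$lag) theta[, "Tlag"] else 0
  ka <- theta[, "ka"]; V1 <- theta[, "V1"]
  k10 <- theta[, "CL"] / V1
  tau <- pmax(time - Tlag, 0)
  D <- dose * 1000
  if (variant$n_compartments == 1L) {
    ka <- ifelse(abs(ka - k10) < 1e-9 * pmax(ka, k10), ka * (1 + 1e-6), ka)
    f <- D * ka / (V1 * (ka - k10)) * (exp(-k10 * tau) - exp(-ka * tau))
    return(ifelse(time > Tlag, f, 0))
  }
  k12 <- theta[, "Q"] / V1; k21 <- theta[, "Q"] / theta[, "V2"]
  s <- k10 + k12 + k21
  d <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  al <- (s + d) / 2; be <- pmax((s - d) / 2, 1e-12)
  ka <- ifelse(abs(ka - al) < 1e-9 * pmax(ka, al), ka * (1 + 1e-6), ka)
  ka <- ifelse(abs(ka - be) < 1e-9 * pmax(ka, be), ka * (1 + 1e-6), ka)
  f <- D * ka / V1 * ((k21 - al) / ((ka - al) * (be - al)) * exp(-al * tau) +
                      (k21 - be) / ((ka - be) * (al - be)) * exp(-be * tau) +
                      (k21 - ka) / ((al - ka) * (be - ka)) * exp(-ka * tau))
  ifelse(time > Tlag, f, 0)
}

## log density of the proportional-error observation model with a small
## additive floor that regularizes the zero-prediction region
obs_logdens <- function(y, f, b, sigma_floor) {
  stats::dnorm(y, f, sqrt((b * f)^2 + sigma_floor^2), log = TRUE)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## covariate design for the flattened rows
build_design <- function(fd, covariate_spec, parnames, reference) {
  bpar <- integer(0); bcat <- character(0)
  for (nm in names(covariate_spec)) {
    for (ct in covariate_spec[[nm]]) {
      if (ct == reference) next
      bpar <- c(bpar, match(nm, parnames)); bcat <- c(bcat, ct)
    }
  }
  Q <- length(bpar)
  X <- matrix(0, fd$n, Q)
  if (Q) for (q in seq_len(Q)) X[, q] <- as.numeric(fd$form == bcat[q])
  list(X = X, bpar = bpar, bcat = bcat, Q = Q)
}

## SH (n_obs x P) log-scale shift implied by beta
shift_matrix <- function(des, beta, P) {
  SH <- matrix(0, nrow(des$X), P)
  if (des$Q) for (q in seq_len(des$Q)) {
    SH[, des$bpar[q]] <- SH[, des$bpar[q]] + des$X[, q] * beta[q]
  }
  SH
}

#' Fit a population PK model by SAEM
#'
#' Maximum-likelihood estimation of the hierarchical model by stochastic
#' approximation EM: a component-wise random-walk Metropolis kernel (with
#' scales adapted towards roughly 30% acceptance) samples the subject-level
#' log-parameters; sufficient statistics of the Gaussian layer (population
#' log-means, the structured random-effect covariance and the proportional
#' error coefficient) are stochastically averaged, while covariate
#' coefficients are updated by a short warm-started quasi-Newton M-step each
#' iteration. Fixed effects are estimated on the log scale and the covariance
#' through its structured blocks, guaranteeing positivity/positive
#' definiteness. With zero iterations the initial model is returned unchanged.
#'
#' @param data An `event_table` (every subject needs at least one
#'   observation).
#' @param variant Structural [model_variant()].
#' @param covariate_spec Named list mapping parameter names to the
#'   non-reference formulation categories carrying a coefficient; default is
#'   the final model's structure (formulation on `Tk0` and `V1`) restricted to
#'   categories present in the data.
#' @param init Initial [population_model()]; default [init_pooled()].
#' @param settings A [fit_settings()] object.
#' @param sigma_floor Additive floor (ug/L) on the observation SD that
#'   regularizes zero predictions.
#' @return A `fit_result` list: `estimates` (a [population_model()]), `se`,
#'   `rse` (%), `ofv`, `bicc`, `ebes`, `trace`, `converged`, plus bookkeeping.
#' @export
saem_fit <- function(data, variant = model_variant(), covariate_spec = NULL,
                     init = NULL, settings = fit_settings(), sigma_floor = 0.01) {
  stopifnot(inherits(settings, "fit_settings"))
  fd <- flatten_data(data, variant)
  parnames <- variant_param_names(variant)
  P <- length(parnames)
  if (is.null(covariate_spec)) {
    cats <- setdiff(intersect(unique(fd$form), ava_formulations()), "#1")
    covariate_spec <- list()
    if (length(cats)) {
      for (nm in intersect(c("Tk0", "V1"), parnames)) covariate_spec[[nm]] <- cats
    }
  }
  if (is.null(init)) init <- init_pooled(data, variant, covariate_spec)
  reference <- init$fixed$reference_category
  des <- build_design(fd, covariate_spec, parnames, reference)

  set.seed(settings$seed)
  mu <- log(init$fixed$pop[parnames])
  beta <- numeric(des$Q)
  if (des$Q) for (q in seq_len(des$Q)) {
    nm <- parnames[des$bpar[q]]
    bb <- init$fixed$beta[[nm]]
    if (!is.null(bb) && des$bcat[q] %in% names(bb)) beta[q] <- bb[[des$bcat[q]]]
  }
  Omega <- omega_matrix(init$random)[parnames, parnames]
  act <- init$random$omega[parnames] > 0
  blocks <- cor_blocks(init$random, parnames)
  b <- init$error$b
  N <- fd$N

  n_iter <- settings$n_explore + settings$n_smooth
  trace_names <- c(paste0(parnames, "_pop"),
                   if (des$Q) paste0("beta_", parnames[des$bpar], "_", des$bcat),
                   paste0("omega_", parnames), cor_names(blocks, parnames), "b")
  trace <- matrix(NA_real_, n_iter, length(trace_names),
                  dimnames = list(NULL, trace_names))

  ## latent state
  psi <- matrix(mu, N, P, byrow = TRUE, dimnames = list(NULL, parnames))
  sc <- matrix(pmax(sqrt(diag(Omega)), 0.05), N, P, byrow = TRUE)
  SH <- shift_matrix(des, beta, P)

  rowpred <- function(psi_mat) {
    theta <- exp(psi_mat[fd$subj, , drop = FALSE] + SH)
    colnames(theta) <- parnames
    pred_rows(variant, theta, fd$dose, fd$time)
  }
  ll_by_subj <- function(f) {
    as.numeric(rowsum(obs_logdens(fd$y, f, b, sigma_floor), fd$subj))
  }
  prior_chol <- function() chol(Omega[act, act, drop = FALSE] +
                                diag(1e-10, sum(act)))
  prior_ll <- function(psi_mat, U) {
    dev <- sweep(psi_mat[, act, drop = FALSE], 2L, mu[act], "-")
    z <- dev %*% backsolve(U, diag(sum(act)))
    -0.5 * rowSums(z^2) - sum(log(diag(U)))
  }

  cur_f <- rowpred(psi)
  cur_ll <- ll_by_subj(cur_f)
  U <- prior_chol()
  cur_pr <- prior_ll(psi, U)

  ## SA accumulators
  T1 <- colMeans(psi)
  T2 <- crossprod(psi) / N
  T3 <- b^2

  mstep_obj <- function(bvec) {
    SHb <- shift_matrix(des, bvec, P)
    theta <- exp(psi[fd$subj, , drop = FALSE] + SHb)
    colnames(theta) <- parnames
    f <- pred_rows(variant, theta, fd$dose, fd$time)
    -sum(obs_logdens(fd$y, f, b, sigma_floor))
  }

  total_iter <- settings$burn_in + n_iter
  for (it in seq_len(total_iter)) {
    adapt <- it <= settings$burn_in + settings$n_explore
    for (sweep_i in seq_len(settings$n_kernel)) {
      for (j in which(act)) {
        prop <- psi
        prop[, j] <- prop[, j] + sc[, j] * stats::rnorm(N)
        f_p <- rowpred(prop)
        ll_p <- ll_by_subj(f_p)
        pr_p <- prior_ll(prop, U)
        loga <- (ll_p + pr_p) - (cur_ll + cur_pr)
        ## overflowing proposals (non-finite predictions) are rejected
        loga[!is.finite(loga)] <- -Inf
        accept <- log(stats::runif(N)) < loga
        if (any(accept)) {
          psi[accept, j] <- prop[accept, j]
          rows <- fd$subj %in% which(accept)
          cur_f[rows] <- f_p[rows]
          cur_ll[accept] <- ll_p[accept]
          cur_pr[accept] <- pr_p[accept]
        }
        if (adapt) {
          delta <- min(0.5, 5 / it)
          sc[, j] <- sc[, j] * exp(delta * ((accept + 0) - 0.3))
        }
      }
    }
    if (it <= settings$burn_in) next
    k <- it - settings$burn_in
    gam <- if (k <= settings$n_explore) 1 else (k - settings$n_explore)^(-settings$step_alpha)

    ## stochastic approximation of the Gaussian-layer statistics
    T1 <- T1 + gam * (colMeans(psi) - T1)
    T2 <- T2 + gam * (crossprod(psi) / N - T2)
    mu_new <- T1
    C <- T2 - tcrossprod(T1)
    Omega_new <- project_structure(C, blocks, act, P)

    ## covariate coefficients: short warm-started quasi-Newton M-step,
    ## relaxed by the SA step size
    if (des$Q) {
      opt <- stats::optim(beta, mstep_obj, method = "BFGS",
                          control = list(maxit = 2, reltol = 1e-8))
      beta <- beta + gam * (opt$par - beta)
    }
    mu <- mu_new
    Omega <- Omega_new
    SH <- shift_matrix(des, beta, P)
    cur_f <- rowpred(psi)
    resid2 <- ((fd$y - cur_f) / pmax(cur_f, 1))^2
    T3 <- T3 + gam * (mean(resid2) - T3)
    b <- sqrt(T3)
    U <- prior_chol()
    cur_ll <- ll_by_subj(cur_f)
    cur_pr <- prior_ll(psi, U)

    om <- sqrt(diag(Omega))
    trace[k, ] <- c(exp(mu), if (des$Q) beta, om,
                    cor_values(Omega, blocks), b)
  }

  est <- assemble_model(mu, beta, des, Omega, blocks, b, variant, parnames, reference,
                        covariate_spec)
  if (n_iter == 0L) est <- init

  ## convergence: relative stability of the fixed-effect path over the last
  ## smoothing iterations
  converged <- FALSE
  if (settings$n_smooth >= 20L) {
    last <- trace[(n_iter - min(50L, settings$n_smooth) + 1L):n_iter,
                  seq_len(P), drop = FALSE]
    rel <- apply(last, 2L, stats::sd) / pmax(abs(colMeans(last)), 1e-12)
    converged <- all(rel < settings$tol)
  }

  ebes <- ebe_all(est, fd, variant, parnames, des, sigma_floor)
  seinfo <- tryCatch(
    fim_se(est, fd, variant, parnames, des, ebes, sigma_floor),
    error = function(e) NULL)
  ofv <- tryCatch(
    ofv_internal(est, fd, variant, parnames, des, ebes, settings$n_mc_ofv,
                 seed = settings$seed + 1L, sigma_floor = sigma_floor),
    error = function(e) NA_real_)
  n_random_linked <- P + des$Q + sum(act) + length(cor_values(Omega, blocks))
  bic <- if (is.finite(ofv)) bicc(ofv, N, fd$n, n_random_linked, 1L) else NA_real_

  structure(list(estimates = est, se = if (!is.null(seinfo)) seinfo$se,
                 rse = if (!is.null(seinfo)) seinfo$rse,
                 ofv = ofv, bicc = bic, ebes = ebes, trace = trace,
                 converged = converged, settings = settings,
                 n_subjects = N, n_obs = fd$n, ids = fd$ids),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("SAEM fit:", x$n_subjects, "subjects,", x$n_obs, "observations\n")
  cat(sprintf("  OFV %.2f | BICc %.2f | converged: %s\n", x$ofv, x$bicc, x$converged))
  print(x$estimates)
  invisible(x)
}

## correlation-block bookkeeping: parameters joined by a correlation share a
## block; everything else is independent (the structured covariance MLE is
## then the blockwise empirical covariance)
cor_blocks <- function(re, parnames) {
  comp <- seq_along(parnames)
  for (cr in re$correlations) {
    i <- match(cr$pair[1], parnames); j <- match(cr$pair[2], parnames)
    ci <- comp[i]; cj <- comp[j]
    comp[comp == cj] <- ci
  }
  comp
}

cor_names <- function(blocks, parnames) {
  out <- character(0)
  for (bl in unique(blocks)) {
    idx <- which(blocks == bl)
    if (length(idx) > 1L) {
      pairs <- utils::combn(idx, 2L)
      out <- c(out, apply(pairs, 2L, function(pp)
        paste0("corr_", parnames[pp[1]], "_", parnames[pp[2]])))
    }
  }
  out
}

cor_values <- function(Omega, blocks) {
  out <- numeric(0)
  for (bl in unique(blocks)) {
    idx <- which(blocks == bl)
    if (length(idx) > 1L) {
      pairs <- utils::combn(idx, 2L)
      out <- c(out, apply(pairs, 2L, function(pp)
        Omega[pp[1], pp[2]] / sqrt(Omega[pp[1], pp[1]] * Omega[pp[2], pp[2]])))
    }
  }
  out
}

project_structure <- function(C, blocks, act, P) {
  Om <- matrix(0, P, P)
  ## the diagonal keeps a small floor (SD 0.02 on the log scale) so the
  ## sampler retains mobility when a variance estimate collapses; true
  ## between-subject SDs in this domain sit an order of magnitude above it
  diag(Om) <- pmax(diag(C), 4e-4)
  for (bl in unique(blocks)) {
    idx <- which(blocks == bl)
    if (length(idx) > 1L) {
      for (a in idx) for (bb in idx) {
        if (a != bb) {
          den <- sqrt(C[a, a] * C[bb, bb])
          r <- if (is.finite(den) && den > 1e-12) C[a, bb] / den else 0
          r <- max(min(r, 0.98), -0.98)
          Om[a, bb] <- r * sqrt(Om[a, a] * Om[bb, bb])
        }
      }
    }
  }
  Om[!act, ] <- 0; Om[, !act] <- 0
  Om
}

assemble_model <- function(mu, beta, des, Omega, blocks, b, variant, parnames,
                           reference, covariate_spec) {
  pop <- stats::setNames(exp(mu), parnames)
  beta_list <- list()
  if (des$Q) for (q in seq_len(des$Q)) {
    nm <- parnames[des$bpar[q]]
    beta_list[[nm]] <- c(beta_list[[nm]], stats::setNames(beta[q], des$bcat[q]))
  }
  om <- stats::setNames(sqrt(diag(Omega)), parnames)
  correlations <- list()
  for (bl in unique(blocks)) {
    idx <- which(blocks == bl)
    if (length(idx) > 1L) {
      pairs <- utils::combn(idx, 2L)
      for (cc in seq_len(ncol(pairs))) {
        i <- pairs[1, cc]; j <- pairs[2, cc]
        if (om[i] > 0 && om[j] > 0) {
          correlations[[length(correlations) + 1L]] <-
            list(pair = parnames[c(i, j)], rho = Omega[i, j] / (om[i] * om[j]))
        }
      }
    }
  }
  population_model(
    fixed = fixed_effects(pop, beta_list, reference_category = reference),
    random = random_effects_spec(om, correlations),
    error = error_model(b), variant = variant)
}

#' Naive-pooled initial estimates
#'
#' Pools all observations and minimizes a log-scale least-squares criterion
#' over the structural parameters (covariate coefficients start at zero) to
#' produce starting values for [saem_fit()]; random-effect SDs start at 0.3
#' and the error coefficient at 0.2.
#'
#' @param data An `event_table`.
#' @param variant Structural [model_variant()].
#' @param covariate_spec Covariate structure (see [saem_fit()]).
#' @return A [population_model()].
#' @export
init_pooled <- function(data, variant = model_variant(), covariate_spec = list()) {
  fd <- flatten_data(data, variant)
  parnames <- variant_param_names(variant)
  ## crude heuristics from the pooled profile
  pos <- fd$y > 0
  tmx <- if (any(pos)) fd$time[pos][which.max(fd$y[pos])] else 1
  cmx <- max(fd$y, 1)
  dmed <- stats::median(fd$dose)
  ## AUC of the pooled mean profile, extended by a crude tail
  mt <- sort(unique(fd$time))
  mbar <- vapply(mt, function(tt) mean(fd$y[fd$time == tt]), numeric(1))
  auc <- sum(diff(mt) * (utils::head(mbar, -1) + utils::tail(mbar, -1)) / 2)
  auc <- max(auc, cmx)
  cl0 <- dmed * 1000 / (1.5 * auc)
  start <- c(Tlag = 0.1, Tk0 = max(tmx / 2, 0.2), ka = 2 / max(tmx, 0.5),
             CL = cl0, V1 = dmed * 1000 / (2 * cmx), Q = cl0 / 4,
             V2 = dmed * 1000 / (4 * cmx))
  th0 <- log(start[parnames])
  obj <- function(lt) {
    theta <- matrix(exp(lt), fd$n, length(lt), byrow = TRUE,
                    dimnames = list(NULL, parnames))
    f <- pred_rows(variant, theta, fd$dose, fd$time)
    sum((log(pmax(fd$y, 0.5)) - log(pmax(f, 0.5)))^2)
  }
  opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-8))
  pop <- stats::setNames(exp(opt$par), parnames)
  beta <- list()
  for (nm in names(covariate_spec)) {
    beta[[nm]] <- stats::setNames(rep(0, length(covariate_spec[[nm]])),
                                  covariate_spec[[nm]])
  }
  ## the final model's single correlated pair enters the structure here with a
  ## zero starting value
  correlations <- if (all(c("V1", "CL") %in% parnames)) {
    list(list(pair = c("V1", "CL"), rho = 0))
  } else list()
  population_model(
    fixed = fixed_effects(pop, beta, reference_category = "#1"),
    random = random_effects_spec(stats::setNames(rep(0.3, length(parnames)), parnames),
                                 correlations = correlations),
    error = error_model(0.2), variant = variant)
}

## ---- EBE, OFV, SE ------------------------------------------------------

subject_rows <- function(fd, i) which(fd$subj == i)

subj_negloglik <- function(eta_act, i, rows, mdl, fd, variant, parnames, des,
                           act, Oinv_act, sigma_floor) {
  eta <- numeric(length(parnames)); eta[act] <- eta_act
  SHr <- shift_matrix(des, mdl$betavec, length(parnames))[rows, , drop = FALSE]
  theta <- exp(matrix(mdl$mu + eta, length(rows), length(parnames), byrow = TRUE) + SHr)
  colnames(theta) <- parnames
  f <- pred_rows(variant, theta, fd$dose[rows], fd$time[rows])
  -(sum(obs_logdens(fd$y[rows], f, mdl$b, sigma_floor)) -
      0.5 * drop(eta_act %*% Oinv_act %*% eta_act))
}

unpack_model <- function(m, parnames, des) {
  betavec <- numeric(des$Q)
  if (des$Q) for (q in seq_len(des$Q)) {
    nm <- parnames[des$bpar[q]]
    betavec[q] <- m$fixed$beta[[nm]][[des$bcat[q]]]
  }
  list(mu = log(m$fixed$pop[parnames]), betavec = betavec,
       Omega = omega_matrix(m$random)[parnames, parnames],
       b = m$error$b)
}

ebe_all <- function(m, fd, variant, parnames, des, sigma_floor) {
  mdl <- unpack_model(m, parnames, des)
  act <- m$random$omega[parnames] > 0
  E <- matrix(0, fd$N, length(parnames), dimnames = list(fd$ids, parnames))
  if (!any(act)) return(E)
  Oinv <- solve(mdl$Omega[act, act, drop = FALSE])
  for (i in seq_len(fd$N)) {
    rows <- subject_rows(fd, i)
    opt <- tryCatch(
      stats::optim(numeric(sum(act)), subj_negloglik, method = "BFGS",
                   i = i, rows = rows, mdl = mdl, fd = fd, variant = variant,
                   parnames = parnames, des = des, act = act, Oinv_act = Oinv,
                   sigma_floor = sigma_floor, control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(opt)) {
      warning("EBE optimization failed for subject ", fd$ids[i], "; using eta = 0")
    } else {
      E[i, act] <- opt$par
    }
  }
  E
}

#' Empirical Bayes estimate for one subject
#'
#' Mode of the conditional distribution of the subject's random effects given
#' the data, found by quasi-Newton search from `eta = 0`. With no informative
#' observations the mode is the prior mode, zero.
#'
#' @param m A [population_model()].
#' @param data An `event_table` restricted to (or containing) the subject.
#' @param id Subject identifier within `data`.
#' @param sigma_floor Observation-SD floor (ug/L).
#' @return Named vector of log-scale random-effect modes.
#' @export
ebe_estimate <- function(m, data, id = NULL, sigma_floor = 0.01) {
  stopifnot(inherits(m, "population_model"))
  if (!is.null(id)) data <- data[data$ID %in% c(id), , drop = FALSE]
  fd <- flatten_data(data, m$variant)
  parnames <- variant_param_names(m$variant)
  cats <- setdiff(intersect(unique(fd$form), ava_formulations()),
                  m$fixed$reference_category)
  spec <- lapply(m$fixed$beta, function(bb) intersect(names(bb), cats))
  des <- build_design(fd, spec, parnames, m$fixed$reference_category)
  E <- ebe_all(m, fd, m$variant, parnames, des, sigma_floor)
  drop(E[1L, ])
}

ofv_internal <- function(m, fd, variant, parnames, des, ebes, n_mc, seed,
                         sigma_floor) {
  mdl <- unpack_model(m, parnames, des)
  act <- m$random$omega[parnames] > 0
  set.seed(seed)
  if (!any(act)) {
    SHr <- shift_matrix(des, mdl$betavec, length(parnames))
    theta <- exp(matrix(mdl$mu, fd$n, length(parnames), byrow = TRUE) + SHr)
    colnames(theta) <- parnames
    f <- pred_rows(variant, theta, fd$dose, fd$time)
    return(-2 * sum(obs_logdens(fd$y, f, mdl$b, sigma_floor)))
  }
  Pa <- sum(act)
  Oa <- mdl$Omega[act, act, drop = FALSE]
  Oinv <- solve(Oa)
  ldetO <- determinant(Oa, logarithm = TRUE)$modulus
  total <- 0
  for (i in seq_len(fd$N)) {
    rows <- subject_rows(fd, i)
    mode_i <- ebes[i, act]
    nll <- function(e) subj_negloglik(e, i, rows, mdl, fd, variant, parnames,
                                      des, act, Oinv, sigma_floor)
    H <- tryCatch(stats::optimHess(mode_i, nll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(V)) || any(eigen(V, TRUE, TRUE)$values <= 0)) {
      V <- Oa
    }
    V <- 1.3 * V
    L <- chol(V)
    Z <- matrix(stats::rnorm(n_mc * Pa), n_mc, Pa) %*% L
    Es <- sweep(Z, 2L, mode_i, "+")
    ldetV <- determinant(V, logarithm = TRUE)$modulus
    logw <- vapply(seq_len(n_mc), function(s) {
      e <- Es[s, ]
      joint <- -nll(e) - 0.5 * (Pa * log(2 * pi) + ldetO)
      z <- Es[s, ] - mode_i
      prop <- -0.5 * drop(z %*% solve(V, z)) - 0.5 * (Pa * log(2 * pi) + ldetV)
      joint - prop
    }, numeric(1))
    li <- logsumexp(logw) - log(n_mc)
    if (!is.finite(li)) stop("non-finite subject likelihood", call. = FALSE)
    total <- total + li
  }
  -2 * total
}

#' Importance-sampling objective function value
#'
#' Monte-Carlo estimate of minus twice the log marginal likelihood of a
#' population model for an event table. Each subject's integral over the
#' random effects uses an importance proposal centred at the empirical Bayes
#' mode with a covariance from the local curvature.
#'
#' @param m A [population_model()].
#' @param data An `event_table`.
#' @param n_mc Monte-Carlo sample size per subject (>= 100).
#' @param seed Integer seed.
#' @param sigma_floor Observation-SD floor (ug/L).
#' @return The estimated OFV (-2 log-likelihood).
#' @export
ofv_importance_sampling <- function(m, data, n_mc = 1000L, seed = 1L,
                                    sigma_floor = 0.01) {
  stopifnot(inherits(m, "population_model"))
  if (n_mc < 100L) stop("n_mc must be at least 100", call. = FALSE)
  fd <- flatten_data(data, m$variant)
  parnames <- variant_param_names(m$variant)
  cats <- setdiff(intersect(unique(fd$form), ava_formulations()),
                  m$fixed$reference_category)
  spec <- lapply(m$fixed$beta, function(bb) intersect(names(bb), cats))
  des <- build_design(fd, spec, parnames, m$fixed$reference_category)
  ebes <- ebe_all(m, fd, m$variant, parnames, des, sigma_floor)
  ofv_internal(m, fd, m$variant, parnames, des, ebes, n_mc, seed, sigma_floor)
}

#' Corrected Bayesian information criterion
#'
#' Hybrid-penalty BIC for nonlinear mixed-effects models: parameters tied to
#' subject-level random effects are penalized by `log(n_subjects)`, the
#' remaining (residual-error and purely fixed) parameters by `log(n_obs)`.
#'
#' @param ofv -2 log-likelihood.
#' @param n_subjects Number of subjects.
#' @param n_obs Total number of observations.
#' @param n_random_linked_params Count of parameters tied to the random-effect
#'   structure (population values and covariate coefficients of random
#'   parameters, plus variance/correlation parameters).
#' @param n_residual_and_fixed_params Count of the remaining parameters.
#' @return The BICc value.
#' @export
bicc <- function(ofv, n_subjects, n_obs, n_random_linked_params,
                 n_residual_and_fixed_params) {
  stopifnot(n_subjects >= 1, n_obs >= 1, n_random_linked_params >= 0,
            n_residual_and_fixed_params >= 0)
  ofv + n_random_linked_params * log(n_subjects) +
    n_residual_and_fixed_params * log(n_obs)
}

#' Two-sided Wald test
#'
#' @param estimate Parameter estimate.
#' @param se Its standard error (> 0).
#' @return Two-sided normal p-value of `estimate / se`.
#' @export
wald_test <- function(estimate, se) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  2 * stats::pnorm(-abs(estimate / se))
}

#' Covariate screening against empirical Bayes estimates
#'
#' The usual EBE-based screen: Pearson correlation tests for continuous
#' covariates, a one-way location (Kruskal-Wallis) test across groups for
#' categorical covariates. Constant covariates are reported as not applicable.
#'
#' @param ebes Matrix or data frame of per-subject random-effect estimates
#'   (columns named per parameter), e.g. `fit$ebes`.
#' @param covariates Data frame of subject-level covariates (one row per
#'   subject, aligned with `ebes`).
#' @return Data frame with columns `eta`, `covariate`, `type`, `statistic`,
#'   `p_value`.
#' @export
covariate_screen <- function(ebes, covariates) {
  ebes <- as.matrix(ebes)
  if (nrow(ebes) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (nrow(ebes) != nrow(covariates)) {
    stop("ebes and covariates must align by subject", call. = FALSE)
  }
  out <- list()
  for (ej in colnames(ebes)) {
    for (cv in names(covariates)) {
      x <- covariates[[cv]]
      if (is.numeric(x)) {
        if (stats::sd(x) == 0 || stats::sd(ebes[, ej]) == 0) {
          res <- c(NA_real_, NA_real_); type <- "pearson"
        } else {
          ct <- stats::cor.test(ebes[, ej], x, method = "pearson")
          res <- c(unname(ct$estimate), ct$p.value); type <- "pearson"
        }
      } else {
        g <- factor(x)
        if (nlevels(g) < 2L) {
          res <- c(NA_real_, NA_real_); type <- "kruskal"
        } else {
          kt <- stats::kruskal.test(ebes[, ej], g)
          res <- c(unname(kt$statistic), kt$p.value); type <- "kruskal"
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        eta = ej, covariate = cv, type = type,
        statistic = res[1], p_value = res[2], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## ---- linearization-based standard errors -------------------------------
## Jacobian of a subject's predictions w.r.t. the log-scale random effects,
## by central differences at the EBE; reused for both the fixed-effect
## gradient (chain rule through log pop) and the marginal covariance.
fim_se <- function(m, fd, variant, parnames, des, ebes, sigma_floor, h = 1e-4) {
  mdl <- unpack_model(m, parnames, des)
  P <- length(parnames)
  act <- m$random$omega[parnames] > 0
  om <- m$random$omega[parnames]
  rho_n <- cor_values(mdl$Omega, cor_blocks(m$random, parnames))
  n_mean <- P + des$Q
  vnames <- c(paste0("omega_", parnames[act]),
              if (length(rho_n)) cor_names(cor_blocks(m$random, parnames), parnames),
              "b")
  n_var <- length(vnames)
  Fm <- matrix(0, n_mean, n_mean)
  Fv <- matrix(0, n_var, n_var)
  SHfull <- shift_matrix(des, mdl$betavec, P)
  dOm <- dOmega_list(m, parnames, act)
  for (i in seq_len(fd$N)) {
    rows <- subject_rows(fd, i)
    SHr <- SHfull[rows, , drop = FALSE]
    predfun <- function(eta) {
      theta <- exp(matrix(mdl$mu + eta, length(rows), P, byrow = TRUE) + SHr)
      colnames(theta) <- parnames
      pred_rows(variant, theta, fd$dose[rows], fd$time[rows])
    }
    e0 <- ebes[i, ]
    f0 <- predfun(e0)
    J <- matrix(0, length(rows), P)
    for (j in seq_len(P)) {
      ep <- e0; em <- e0
      ep[j] <- ep[j] + h; em[j] <- em[j] - h
      J[, j] <- (predfun(ep) - predfun(em)) / (2 * h)
    }
    Sig <- J[, act, drop = FALSE] %*% mdl$Omega[act, act] %*% t(J[, act, drop = FALSE]) +
      diag((mdl$b * f0)^2 + sigma_floor^2, length(rows))
    Sinv <- tryCatch(solve(Sig), error = function(e)
      solve(Sig + diag(1e-8 * mean(diag(Sig)), nrow(Sig))))
    ## gradient of the mean w.r.t. natural-scale pop values and betas
    G <- cbind(sweep(J, 2L, m$fixed$pop[parnames], "/"),
               if (des$Q) sapply(seq_len(des$Q), function(q)
                 J[, des$bpar[q]] * des$X[rows, q]))
    G <- matrix(G, nrow = length(rows))
    Fm <- Fm + t(G) %*% Sinv %*% G
    ## variance parameters
    dS <- c(lapply(dOm, function(dO)
      J[, act, drop = FALSE] %*% dO %*% t(J[, act, drop = FALSE])),
      list(diag(2 * mdl$b * f0^2, length(rows))))
    for (u in seq_len(n_var)) for (v in u:n_var) {
      val <- 0.5 * sum(diag(Sinv %*% dS[[u]] %*% Sinv %*% dS[[v]]))
      Fv[u, v] <- Fv[u, v] + val
      if (u != v) Fv[v, u] <- Fv[v, u] + val
    }
  }
  inv_safe <- function(A) {
    tryCatch(solve(A), error = function(e)
      solve(A + diag(1e-6 * mean(abs(diag(A))) + 1e-12, nrow(A))))
  }
  se_mean <- sqrt(pmax(diag(inv_safe(Fm)), 0))
  se_var <- sqrt(pmax(diag(inv_safe(Fv)), 0))
  est <- c(m$fixed$pop[parnames],
           if (des$Q) mdl$betavec,
           om[act], rho_n, mdl$b)
  nm <- c(paste0(parnames, "_pop"),
          if (des$Q) paste0("beta_", parnames[des$bpar], "_", des$bcat),
          vnames)
  se <- stats::setNames(c(se_mean, se_var), nm)
  rse <- 100 * se / pmax(abs(est), 1e-12)
  names(rse) <- nm
  list(se = se, rse = rse)
}

## derivatives of the structured covariance w.r.t. each omega (active) and
## each correlation
dOmega_list <- function(m, parnames, act) {
  om <- m$random$omega[parnames]
  acti <- which(act)
  R <- diag(length(parnames))
  for (cr in m$random$correlations) {
    i <- match(cr$pair[1], parnames); j <- match(cr$pair[2], parnames)
    R[i, j] <- R[j, i] <- cr$rho
  }
  out <- list()
  for (j in acti) {
    E <- matrix(0, length(parnames), length(parnames)); E[j, j] <- 1
    D <- diag(om, length(parnames))
    dO <- E %*% R %*% D + D %*% R %*% E
    out[[length(out) + 1L]] <- dO[acti, acti, drop = FALSE]
  }
  for (cr in m$random$correlations) {
    i <- match(cr$pair[1], parnames); j <- match(cr$pair[2], parnames)
    dR <- matrix(0, length(parnames), length(parnames))
    dR[i, j] <- dR[j, i] <- 1
    D <- diag(om, length(parnames))
    dO <- D %*% dR %*% D
    out[[length(out) + 1L]] <- dO[acti, acti, drop = FALSE]
  }
  out
}
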