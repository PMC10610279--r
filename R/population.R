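#' Fixed effects of the population model
#'
#' Typical (population) values for each structural parameter plus the
#' formulation covariate coefficients. Covariates act additively on the log of
#' the parameter (multiplicatively, `exp(beta)`, on the natural scale), the
#' usual convention for categorical covariates in lognormal NLME models.
#'
#' @param pop Named numeric vector of positive typical values; names must
#'   match the structural parameter set of the model variant.
#' @param beta Named list mapping a parameter name to a named numeric vector of
#'   coefficients per non-reference formulation category, e.g.
#'   `list(Tk0 = c("#2" = -0.4, "#3" = -0.68))`.
#' @param reference_category Formulation label acting as reference (its
#'   coefficients are identically zero).
#' @return An object of class `fixed_effects`.
#' @export
fixed_effects <- function(pop, beta = list(), reference_category = "#1") {
  if (is.null(names(pop)) || any(!nzchar(names(pop)))) {
    stop("pop must be a named vector", call. = FALSE)
  }
  if (any(!is.finite(pop)) || any(pop <= 0)) {
    stop("population values must be positive and finite", call. = FALSE)
  }
  reference_category <- match.arg(reference_category, ava_formulations())
  for (nm in names(beta)) {
    if (!nm %in% names(pop)) {
      stop("beta defined for unknown parameter: ", nm, call. = FALSE)
    }
    cats <- names(beta[[nm]])
    if (is.null(cats) || reference_category %in% cats) {
      stop("beta for ", nm, " must be named by non-reference categories", call. = FALSE)
    }
  }
  structure(list(pop = pop, beta = beta, reference_category = reference_category),
            class = "fixed_effects")
}

#' Random-effects specification
#'
#' Lognormal inter-individual variability: each parameter carries a log-scale
#' normal random effect with standard deviation `omega`; selected pairs may be
#' correlated.
#'
#' @param omega Named non-negative numeric vector of log-scale SDs, one per
#'   structural parameter.
#' @param correlations List of correlated pairs, each a
#'   `list(pair = c("V1", "CL"), rho = 0.72)`.
#' @return An object of class `random_effects_spec`.
#' @export
random_effects_spec <- function(omega, correlations = list()) {
  if (is.null(names(omega))) stop("omega must be named", call. = FALSE)
  if (any(!is.finite(omega)) || any(omega < 0)) {
    stop("omega values must be non-negative and finite", call. = FALSE)
  }
  for (cr in correlations) {
    if (!all(c("pair", "rho") %in% names(cr)) || length(cr$pair) != 2L) {
      stop("each correlation must be list(pair = c(p1, p2), rho = r)", call. = FALSE)
    }
    if (!all(cr$pair %in% names(omega))) {
      stop("correlation names unknown: ", paste(cr$pair, collapse = ","), call. = FALSE)
    }
    if (abs(cr$rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  }
  re <- structure(list(omega = omega, correlations = correlations),
                  class = "random_effects_spec")
  ## positive-definiteness (on the active block) is checked at construction
  om <- omega_matrix(re)
  act <- omega > 0
  if (any(act)) {
    ev <- eigen(om[act, act, drop = FALSE], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("implied random-effects covariance is not positive definite",
                           call. = FALSE)
  }
  re
}

#' Covariance matrix implied by a random-effects specification
#'
#' @param re A [random_effects_spec()].
#' @return The log-scale covariance matrix `D R D` (D diagonal of omegas, R the
#'   correlation matrix).
#' @export
omega_matrix <- function(re) {
  stopifnot(inherits(re, "random_effects_spec"))
  om <- re$omega
  R <- diag(length(om))
  dimnames(R) <- list(names(om), names(om))
  for (cr in re$correlations) {
    R[cr$pair[1], cr$pair[2]] <- R[cr$pair[2], cr$pair[1]] <- cr$rho
  }
  D <- diag(om, nrow = length(om))
  out <- D %*% R %*% D
  dimnames(out) <- dimnames(R)
  out
}

#' Proportional residual-error model
#'
#' Observations follow `y = C * (1 + b * eps)` with `eps ~ N(0, 1)`: the error
#' SD is proportional to the predicted concentration.
#'
#' @param b Proportional-error coefficient (dimensionless, >= 0).
#' @return An object of class `error_model`.
#' @export
error_model <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0) {
    stop("b must be a single non-negative number", call. = FALSE)
  }
  structure(list(b = b), class = "error_model")
}

#' Population pharmacokinetic model
#'
#' Combines fixed effects, random-effects specification, residual-error model
#' and structural variant into the full hierarchical model.
#'
#' @param fixed A [fixed_effects()] object.
#' @param random A [random_effects_spec()] object.
#' @param error An [error_model()] object.
#' @param variant A [model_variant()]; defaults to the final two-compartment
#'   zero-order-input model with lag.
#' @return An object of class `population_model`.
#' @export
population_model <- function(fixed, random, error, variant = model_variant()) {
  stopifnot(inherits(fixed, "fixed_effects"), inherits(random, "random_effects_spec"),
            inherits(error, "error_model"), inherits(variant, "model_variant"))
  need <- variant_param_names(variant)
  if (!setequal(names(fixed$pop), need) || !setequal(names(random$omega), need)) {
    stop("fixed and random effects must cover exactly: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ## align ordering
  fixed$pop <- fixed$pop[need]
  random$omega <- random$omega[need]
  structure(list(fixed = fixed, random = random, error = error, variant = variant),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (", x$variant$n_compartments, "-cpt, ",
      x$variant$absorption, if (x$variant$lag) ", lag" else "", ")\n", sep = "")
  cat("  pop:   ", paste(sprintf("%s=%.4g", names(x$fixed$pop), x$fixed$pop),
                         collapse = ", "), "\n")
  for (nm in names(x$fixed$beta)) {
    cat("  beta[", nm, "]: ",
        paste(sprintf("%s=%.3g", names(x$fixed$beta[[nm]]), x$fixed$beta[[nm]]),
              collapse = ", "), "\n", sep = "")
  }
  cat("  omega: ", paste(sprintf("%s=%.3g", names(x$random$omega), x$random$omega),
                         collapse = ", "), "\n")
  for (cr in x$random$correlations) {
    cat(sprintf("  corr(%s, %s) = %.3g\n", cr$pair[1], cr$pair[2], cr$rho))
  }
  cat(sprintf("  error: proportional, b = %.3g\n", x$error$b))
  invisible(x)
}

#' Typical-value parameters for a formulation
#'
#' Applies the formulation covariate coefficients to the population values:
#' the reference category returns them unchanged; other categories multiply
#' the affected parameters by `exp(beta)`.
#'
#' @param x A [population_model()] or [fixed_effects()] object.
#' @param formulation Formulation label.
#' @return A [structural_params()] object (for the final model variant) or a
#'   named numeric vector for other variants.
#' @export
typical_params <- function(x, formulation = NULL) {
  fe <- if (inherits(x, "population_model")) x$fixed else x
  stopifnot(inherits(fe, "fixed_effects"))
  if (is.null(formulation)) formulation <- fe$reference_category
  if (!formulation %in% ava_formulations()) {
    stop("unknown formulation category: ", formulation, call. = FALSE)
  }
  th <- fe$pop
  for (nm in names(fe$beta)) {
    bb <- fe$beta[[nm]]
    if (formulation %in% names(bb)) th[nm] <- th[nm] * exp(bb[[formulation]])
  }
  as_structural(th, if (inherits(x, "population_model")) x$variant else model_variant())
}

as_structural <- function(th, variant) {
  if (variant$n_compartments == 2L && variant$absorption == "zero-order" && variant$lag) {
    structural_params(th[["Tlag"]], th[["Tk0"]], th[["CL"]], th[["V1"]],
                      th[["Q"]], th[["V2"]])
  } else {
    th
  }
}

## Draw n log-scale random-effect vectors via the triangular (Cholesky)
## factorization of the structured covariance. Parameters with omega = 0
## receive exactly zero.
sample_eta <- function(m, n) {
  om <- omega_matrix(m$random)
  P <- ncol(om)
  eta <- matrix(0, n, P, dimnames = list(NULL, colnames(om)))
  act <- m$random$omega > 0
  if (any(act)) {
    L <- chol(om[act, act, drop = FALSE])
    z <- matrix(stats::rnorm(n * sum(act)), n, sum(act))
    eta[, act] <- z %*% L
  }
  eta
}

#' Sample individual parameters from the population model
#'
#' Draws log-scale random effects from the multivariate normal implied by the
#' omegas and correlations and realizes individual parameters as
#' `exp(log(pop) + beta[formulation] + eta)`.
#'
#' @param m A [population_model()].
#' @param formulation Formulation label for the covariate contribution.
#' @param n Number of individuals.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `eta` (n x P matrix of log-scale random effects) and
#'   `params` (n x P matrix of realized individual parameters), plus the
#'   formulation label.
#' @export
sample_individual <- function(m, formulation = NULL, n = 1L, seed = NULL) {
  stopifnot(inherits(m, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  fe <- m$fixed
  if (is.null(formulation)) formulation <- fe$reference_category
  typ <- fe$pop
  for (nm in names(fe$beta)) {
    bb <- fe$beta[[nm]]
    if (formulation %in% names(bb)) typ[nm] <- typ[nm] * exp(bb[[formulation]])
  }
  eta <- sample_eta(m, n)
  pars <- sweep(exp(eta), 2L, typ, "*")
  list(eta = eta, params = pars, formulation = formulation)
}

#' Apply proportional residual error
#'
#' @param true_conc Non-negative model-predicted concentrations (ug/L).
#' @param e An [error_model()].
#' @param seed Optional integer seed.
#' @return Observed concentrations `true_conc * (1 + b * eps)`. Values may be
#'   negative when `b * eps < -1`; they are deliberately not truncated, since
#'   below-quantification values are retained uncensored in this workflow.
#' @export
apply_residual_error <- function(true_conc, e, seed = NULL) {
  stopifnot(inherits(e, "error_model"))
  if (any(true_conc < 0)) stop("true_conc must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  true_conc * (1 + e$b * stats::rnorm(length(true_conc)))
}

## Deterministic child seed per subject so per-subject results are invariant
## to subject ordering. Kept below 2^31 - 1.
child_seed <- function(root, i) {
  as.integer((as.numeric(root) * 48271 + i * 2654435) %% 2147483629)
}

#' Simulate a study's observations from the population model
#'
#' Composes individual sampling, the structural model and the residual-error
#' model over a crossover study design. One random-effect vector is drawn per
#' subject and shared across periods (no inter-occasion variability); period
#' differences arise only through the formulation coefficients. Each subject
#' uses an independent child random stream derived from `seed`, so results are
#' invariant to subject ordering.
#'
#' @param m A [population_model()].
#' @param design A [study_design()].
#' @param seed Integer root seed.
#' @return An `event_table` data frame (see [event_table()]).
#' @export
simulate_observations <- function(m, design, seed = 1L) {
  stopifnot(inherits(m, "population_model"), inherits(design, "study_design"))
  rows <- vector("list", design$n_subjects)
  P <- length(m$fixed$pop)
  for (i in seq_len(design$n_subjects)) {
    set.seed(child_seed(seed, i))
    eta <- drop(sample_eta(m, 1L))
    forms <- design$periods[[i]]
    sub <- vector("list", length(forms))
    for (per in seq_along(forms)) {
      typ <- m$fixed$pop
      for (nm in names(m$fixed$beta)) {
        bb <- m$fixed$beta[[nm]]
        if (forms[per] %in% names(bb)) typ[nm] <- typ[nm] * exp(bb[[forms[per]]])
      }
      th <- typ * exp(eta)
      p <- as_structural(th, m$variant)
      cc <- conc_single_dose(p, design$dose_per_period, design$sampling_times)
      dv <- apply_residual_error(cc, m$error)
      sub[[per]] <- data.frame(
        ID = i,
        TIME = c(0, design$sampling_times),
        AMT = c(design$dose_per_period, rep(NA_real_, length(cc))),
        DV = c(NA_real_, dv),
        EVID = c(1L, rep(0L, length(cc))),
        MDV = c(1L, rep(0L, length(cc))),
        FORM = forms[per], PERIOD = per,
        BLQ = c(NA, dv < design$lloq),
        stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}
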