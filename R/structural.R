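#' Structural PK parameters of the two-compartment AVA model
#'
#' Bundles the six apparent disposition/absorption parameters of the
#' two-compartment model with zero-order input and lag time: lag `Tlag` (h),
#' input duration `Tk0` (h), apparent clearance `CL` (L/h), apparent central
#' volume `V1` (L), apparent intercompartmental clearance `Q` (L/h) and
#' apparent peripheral volume `V2` (L). All parameters are "apparent", i.e.
#' scaled by the unknown bioavailability (and metabolite conversion) factor F.
#'
#' @param Tlag Lag before input starts (h).
#' @param Tk0 Duration of the zero-order (constant-rate) input (h).
#' @param CL Apparent clearance CL/F (L/h).
#' @param V1 Apparent central volume V1/F (L).
#' @param Q Apparent intercompartmental clearance Q/F (L/h).
#' @param V2 Apparent peripheral volume V2/F (L).
#' @return An object of class `structural_params`.
#' @export
structural_params <- function(Tlag, Tk0, CL, V1, Q, V2) {
  p <- c(Tlag = Tlag, Tk0 = Tk0, CL = CL, V1 = V1, Q = Q, V2 = V2)
  if (length(p) != 6L || anyNA(p) || any(!is.finite(p))) {
    stop("all six structural parameters must be finite numbers", call. = FALSE)
  }
  if (any(p <= 0)) {
    bad <- names(p)[p <= 0]
    stop("structural parameters must be strictly positive; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(as.list(p), class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Structural PK parameters (2-cpt, zero-order input with lag):\n")
  cat(sprintf("  Tlag %.4g h | Tk0 %.4g h | CL/F %.4g L/h | V1/F %.4g L | Q/F %.4g L/h | V2/F %.4g L\n",
              x$Tlag, x$Tk0, x$CL, x$V1, x$Q, x$V2))
  invisible(x)
}

#' Micro rate constants of the two-compartment model
#'
#' Reparameterizes clearances/volumes into first-order micro constants:
#' `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`.
#'
#' @param p A [structural_params()] object.
#' @return A list of class `micro_constants` with elements `k10`, `k12`, `k21` (1/h).
#' @export
micro_constants <- function(p) {
  stopifnot(inherits(p, "structural_params"))
  structure(list(k10 = p$CL / p$V1, k12 = p$Q / p$V1, k21 = p$Q / p$V2),
            class = "micro_constants")
}

## Biexponential disposition roots and bolus coefficients.
## alpha, beta are the roots of x^2 - (k10+k12+k21) x + k10*k21 = 0.
## When the discriminant collapses (alpha == beta within tolerance) the
## critically damped closed form applies; `degenerate` flags that branch.
disposition <- function(k, tol = 1e-10) {
  s <- k$k10 + k$k12 + k$k21
  pr <- k$k10 * k$k21
  disc2 <- s^2 - 4 * pr
  if (disc2 < tol * s^2) {
    lam <- s / 2
    return(list(alpha = lam, beta = lam, A = NA_real_, B = NA_real_,
                degenerate = TRUE, lambda = lam))
  }
  d <- sqrt(disc2)
  alpha <- (s + d) / 2
  beta <- (s - d) / 2
  list(alpha = alpha, beta = beta,
       A = (alpha - k$k21) / (alpha - beta),
       B = (k$k21 - beta) / (alpha - beta),
       degenerate = FALSE, lambda = NA_real_)
}

#' Derived disposition metrics
#'
#' Computes the biexponential disposition rates and the quantities usually
#' reported from them: distribution half-life `ln 2 / alpha`, terminal
#' half-life `ln 2 / beta`, and the apparent steady-state volume
#' `Vss = V1 + V2`.
#'
#' @param p A [structural_params()] object.
#' @return A list of class `derived_pk` with `alpha`, `beta_macro` (1/h),
#'   `t_half_dist`, `t_half_term` (h), `Vss` (L) and a `degenerate` flag set
#'   when the two rates coincide (parameters collapse to one compartment
#'   kinetics).
#' @export
derived_metrics <- function(p) {
  stopifnot(inherits(p, "structural_params"))
  d <- disposition(micro_constants(p))
  structure(list(alpha = d$alpha, beta_macro = d$beta,
                 t_half_dist = log(2) / d$alpha,
                 t_half_term = log(2) / d$beta,
                 Vss = p$V1 + p$V2,
                 degenerate = d$degenerate),
            class = "derived_pk")
}

#' @export
print.derived_pk <- function(x, ...) {
  cat(sprintf("Disposition: alpha %.4g /h, beta %.4g /h | t1/2 dist %.3g h, term %.3g h | Vss %.4g L%s\n",
              x$alpha, x$beta_macro, x$t_half_dist, x$t_half_term, x$Vss,
              if (x$degenerate) " [degenerate: rates coincide]" else ""))
  invisible(x)
}

#' Dosing regimen
#'
#' @param dose Amount per administration (mg vinpocetine-equivalent).
#' @param interval Inter-dose interval (h).
#' @param n_doses Number of administrations.
#' @param formulation Formulation label, one of `"#1"` (sustained-release
#'   tablet), `"#2"` (immediate-release tablet), `"#3"` (oral solution).
#' @return An object of class `regimen`.
#' @export
regimen <- function(dose, interval = 24, n_doses = 1L, formulation = "#2") {
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("dose must be a single non-negative number (mg)", call. = FALSE)
  }
  if (!is.numeric(interval) || length(interval) != 1L || !is.finite(interval) || interval <= 0) {
    stop("interval must be a single positive number (h)", call. = FALSE)
  }
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) stop("n_doses must be >= 1", call. = FALSE)
  formulation <- match.arg(formulation, ava_formulations())
  structure(list(dose = dose, interval = interval, n_doses = n_doses,
                 formulation = formulation), class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Regimen: %g mg q%gh x %d (formulation %s)\n",
              x$dose, x$interval, x$n_doses, x$formulation))
  invisible(x)
}

#' Formulation labels used throughout the package
#'
#' `"#1"` sustained-release tablet (reference category), `"#2"`
#' immediate-release tablet, `"#3"` oral solution.
#' @return Character vector of the three labels.
#' @export
ava_formulations <- function() c("#1", "#2", "#3")

## Concentration at time tau (h, relative to start of input) produced by an
## infusion at rate 1 ug/h into the central compartment running from 0 to
## infinity. Single-dose solutions are differences of this cumulative
## response, which makes continuity at the input breakpoints exact by
## construction.
infusion_cum <- function(tau, k, d) {
  out <- numeric(length(tau))
  pos <- tau > 0
  if (!any(pos)) return(out)
  tp <- tau[pos]
  V1inv <- 1  # caller divides by V1
  if (!d$degenerate) {
    out[pos] <- V1inv * (d$A * (1 - exp(-d$alpha * tp)) / d$alpha +
                         d$B * (1 - exp(-d$beta * tp)) / d$beta)
  } else {
    lam <- d$lambda
    a <- k$k10 + k$k12
    E <- exp(-lam * tp)
    out[pos] <- V1inv * ((1 - E) / lam + (lam - a) * (1 - E * (1 + lam * tp)) / lam^2)
  }
  out
}

#' Concentration after a single dose
#'
#' Closed-form central-compartment concentration of the two-compartment model
#' with zero-order input of duration `Tk0` after a lag `Tlag` and linear
#' elimination. The solution is piecewise: zero up to `Tlag`, the
#' constant-rate-input solution on `(Tlag, Tlag + Tk0]`, and biexponential
#' decay afterwards; it is continuous at both breakpoints.
#'
#' @param p A [structural_params()] object.
#' @param dose_mg Dose (mg); converted internally to micrograms so that with
#'   volumes in litres the result is in ug/L.
#' @param t Time(s) since dosing (h); must be non-negative.
#' @return Numeric vector of concentrations (ug/L), same length as `t`.
#' @export
conc_single_dose <- function(p, dose_mg, t) {
  stopifnot(inherits(p, "structural_params"))
  if (!is.numeric(t)) stop("t must be numeric", call. = FALSE)
  if (length(t) && any(t < 0, na.rm = TRUE)) {
    stop("negative times are not allowed", call. = FALSE)
  }
  if (dose_mg < 0) stop("dose must be non-negative", call. = FALSE)
  if (dose_mg == 0 || !length(t)) return(numeric(length(t)))
  k <- micro_constants(p)
  d <- disposition(k)
  R0 <- dose_mg * 1000 / p$Tk0  # ug/h
  tau <- t - p$Tlag
  (R0 / p$V1) * (infusion_cum(tau, k, d) - infusion_cum(tau - p$Tk0, k, d))
}

#' Concentration profile under a multiple-dose regimen
#'
#' Superposition of time-shifted single-dose solutions, valid because
#' elimination is linear. Doses are administered at
#' `0, interval, ..., (n_doses - 1) * interval`.
#'
#' @param p A [structural_params()] object.
#' @param r A [regimen()].
#' @param times Sorted, non-negative time grid (h, from the first dose).
#' @return Numeric vector of concentrations (ug/L), one per element of `times`.
#' @export
conc_profile <- function(p, r, times) {
  stopifnot(inherits(p, "structural_params"), inherits(r, "regimen"))
  if (!length(times)) return(numeric(0))
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  if (any(times < 0)) stop("negative times are not allowed", call. = FALSE)
  out <- numeric(length(times))
  for (j in seq_len(r$n_doses) - 1L) {
    td <- times - j * r$interval
    idx <- td >= 0
    if (!any(idx)) next
    out[idx] <- out[idx] + conc_single_dose(p, r$dose, td[idx])
  }
  out
}

## Locate the maximum of the concentration curve on [lo, hi] for the given
## regimen. The peak of the last dose lies at its input-end time; the residual
## of earlier doses decays monotonically, so the true maximum is bracketed by
## the input-end time. A bounded scalar maximization refines it; a dense grid
## (1e-3 h) is the fallback. Ties resolve to the earliest time.
profile_max <- function(p, r, lo, hi) {
  f <- function(tt) conc_profile(p, r, tt)
  cand_t <- unique(pmin(pmax(c(
    lo, hi,
    (seq_len(r$n_doses) - 1L) * r$interval + p$Tlag + p$Tk0), lo), hi))
  cand_c <- f(sort(cand_t))
  cand_t <- sort(cand_t)
  best <- which.max(cand_c)
  span <- hi - lo
  bl <- max(lo, cand_t[best] - 0.05 * span)
  bu <- min(hi, cand_t[best] + 0.05 * span)
  opt <- tryCatch(stats::optimize(function(tt) f(tt), c(bl, bu),
                                  maximum = TRUE, tol = 1e-8),
                  error = function(e) NULL)
  tmax <- cand_t[best]; cmax <- cand_c[best]
  if (!is.null(opt) && opt$objective > cmax) {
    tmax <- opt$maximum; cmax <- opt$objective
  }
  ## dense-grid fallback guards against a peak outside the refined bracket
  grid <- seq(lo, hi, by = min(1e-3, span / 100))
  gc_ <- f(grid)
  gi <- which.max(gc_)
  if (gc_[gi] > cmax + 1e-12 * max(cmax, 1)) {
    tmax <- grid[gi]; cmax <- gc_[gi]
  }
  list(tmax = tmax, cmax = cmax)
}

## Trapezoid AUC on [lo, hi], refined by doubling until stable.
auc_trapz <- function(p, r, lo, hi, rel_tol = 1e-7) {
  n <- 256L
  prev <- NA_real_
  repeat {
    tt <- seq(lo, hi, length.out = n + 1L)
    cc <- conc_profile(p, r, tt)
    a <- sum((cc[-1] + cc[-length(cc)]) / 2) * (hi - lo) / n
    if (!is.na(prev) && abs(a - prev) <= rel_tol * max(abs(a), 1e-12)) return(a)
    prev <- a
    n <- n * 2L
    if (n > 2^17) return(a)
  }
}

#' Exposure metrics over the last dosing interval
#'
#' Computes `Cmax`, its time `Tmax`, the minimum concentration `Cmin` and the
#' interval AUC over the last dosing interval of the regimen, i.e. on
#' `[(n_doses - 1) * interval, n_doses * interval]`. `Cmax` is located by
#' analytic bracketing around the input-end time refined by bounded scalar
#' maximization (dense-grid fallback); the AUC uses a refined trapezoid rule.
#' For a single dose evaluated over its (possibly infinite) interval the
#' minimum is attained at the boundary, e.g. zero at `t = 0`.
#'
#' @param p A [structural_params()] object.
#' @param r A [regimen()].
#' @return A list with `Cmax`, `Tmax` (absolute time, h), `Cmin`, `Ctrough`
#'   (the end-of-interval concentration) and `AUC_tau` (ug*h/L).
#' @export
exposure_metrics <- function(p, r) {
  stopifnot(inherits(p, "structural_params"), inherits(r, "regimen"))
  lo <- (r$n_doses - 1L) * r$interval
  hi <- r$n_doses * r$interval
  mx <- profile_max(p, r, lo, hi)
  ends <- conc_profile(p, r, c(lo, hi))
  cmin <- min(ends)
  ## within the interval the curve dips lowest just before the last input
  ## starts (residual decay) or at the interval ends
  dip <- lo + p$Tlag
  if (dip < hi) cmin <- min(cmin, conc_profile(p, r, dip))
  list(Cmax = mx$cmax, Tmax = mx$tmax, Cmin = cmin, Ctrough = ends[2],
       AUC_tau = auc_trapz(p, r, lo, hi))
}

#' Total AUC of a single dose
#'
#' Numerical AUC to a long horizon with the terminal tail added analytically
#' (`C(T)/beta`). For linear kinetics this equals `dose / CL` exactly, which
#' the test-suite uses as an oracle.
#'
#' @param p A [structural_params()] object.
#' @param dose_mg Dose (mg).
#' @return AUC from zero to infinity (ug*h/L).
#' @export
auc_single_dose <- function(p, dose_mg) {
  d <- derived_metrics(p)
  Tend <- p$Tlag + p$Tk0 + 12 / d$beta_macro * log(2)
  r <- regimen(dose_mg, interval = Tend, n_doses = 1L)
  auc_trapz(p, r, 0, Tend) + conc_single_dose(p, dose_mg, Tend) / d$beta_macro
}

#' Structural model variant
#'
#' Describes the comparator structural models explored during model
#' development: number of compartments, absorption type and presence of a lag.
#' The final AVA model is `model_variant(2, "zero-order", lag = TRUE)`.
#'
#' @param n_compartments 1 or 2.
#' @param absorption `"zero-order"` (input of duration `Tk0`) or
#'   `"first-order"` (rate constant `ka`).
#' @param lag Logical; is there a lag time before absorption?
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(n_compartments = 2L, absorption = c("zero-order", "first-order"),
                          lag = TRUE) {
  n_compartments <- as.integer(n_compartments)
  if (!n_compartments %in% c(1L, 2L)) stop("n_compartments must be 1 or 2", call. = FALSE)
  absorption <- match.arg(absorption)
  structure(list(n_compartments = n_compartments, absorption = absorption,
                 lag = isTRUE(lag)), class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("Model variant: %d-compartment, %s absorption, %s\n",
              x$n_compartments, x$absorption,
              if (x$lag) "with lag" else "no lag"))
  invisible(x)
}

#' Parameter names required by a model variant
#'
#' @param v A [model_variant()].
#' @return Character vector of structural parameter names.
#' @export
variant_param_names <- function(v) {
  stopifnot(inherits(v, "model_variant"))
  nm <- if (v$absorption == "zero-order") "Tk0" else "ka"
  if (v$lag) nm <- c("Tlag", nm)
  nm <- c(nm, "CL", "V1")
  if (v$n_compartments == 2L) nm <- c(nm, "Q", "V2")
  nm
}

#' Single-dose concentration for an arbitrary model variant
#'
#' Closed-form solutions for the comparator variants used in model-selection
#' demonstrations (one- or two-compartment, zero- or first-order absorption,
#' with or without lag).
#'
#' @param v A [model_variant()].
#' @param params Named numeric vector or list with the entries of
#'   [variant_param_names()] (all positive).
#' @param dose_mg Dose (mg).
#' @param t Times since dosing (h).
#' @return Concentrations (ug/L).
#' @export
conc_variant <- function(v, params, dose_mg, t) {
  stopifnot(inherits(v, "model_variant"))
  params <- as.list(params)
  need <- variant_param_names(v)
  if (!all(need %in% names(params))) {
    stop("params must provide: ", paste(need, collapse = ", "), call. = FALSE)
  }
  th <- lapply(params[need], as.numeric)
  if (any(unlist(th) <= 0)) stop("variant parameters must be positive", call. = FALSE)
  tlag <- if (v$lag) th$Tlag else 0
  if (any(t < 0)) stop("negative times are not allowed", call. = FALSE)
  if (v$absorption == "zero-order") {
    if (v$n_compartments == 2L) {
      p <- structural_params(max(tlag, 1e-12), th$Tk0, th$CL, th$V1, th$Q, th$V2)
      return(conc_single_dose(p, dose_mg, t))
    }
    k10 <- th$CL / th$V1
    R0 <- dose_mg * 1000 / th$Tk0
    tau <- t - tlag
    cum <- function(x) ifelse(x > 0, (1 - exp(-k10 * x)) / k10, 0)
    return((R0 / th$V1) * (cum(tau) - cum(tau - th$Tk0)))
  }
  ## first-order absorption
  D <- dose_mg * 1000
  ka <- th$ka
  tau <- pmax(t - tlag, 0)
  if (v$n_compartments == 1L) {
    k10 <- th$CL / th$V1
    if (abs(ka - k10) < 1e-9 * max(ka, k10)) {
      return(ifelse(t > tlag, D / th$V1 * k10 * tau * exp(-k10 * tau), 0))
    }
    return(ifelse(t > tlag,
                  D * ka / (th$V1 * (ka - k10)) * (exp(-k10 * tau) - exp(-ka * tau)), 0))
  }
  k <- list(k10 = th$CL / th$V1, k12 = th$Q / th$V1, k21 = th$Q / th$V2)
  d <- disposition(k)
  if (d$degenerate) stop("degenerate disposition not supported for first-order variant",
                         call. = FALSE)
  al <- d$alpha; be <- d$beta
  for (lam in c(al, be)) {
    if (abs(ka - lam) < 1e-9 * max(ka, lam)) ka <- ka * (1 + 1e-7)
  }
  co <- D * ka / th$V1
  C <- co * ((k$k21 - al) / ((ka - al) * (be - al)) * exp(-al * tau) +
             (k$k21 - be) / ((ka - be) * (al - be)) * exp(-be * tau) +
             (k$k21 - ka) / ((al - ka) * (be - ka)) * exp(-ka * tau))
  ifelse(t > tlag, C, 0)
}
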