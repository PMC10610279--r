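#' The final population PK model of apovincaminic acid
#'
#' The published population estimates for AVA after single oral doses of
#' vinpocetine: a two-compartment model with zero-order input and lag,
#' linear elimination and proportional residual error; formulation acts
#' multiplicatively (`exp(beta)`) on `Tk0` and `V1`, random effects are
#' lognormal on all six parameters with a single correlation between the
#' `V1` and `CL` effects. The sustained-release tablet (`"#1"`) is the
#' reference category.
#'
#' @return A [population_model()].
#' @export
ava_model <- function() {
  population_model(
    fixed = fixed_effects(
      pop = c(Tlag = 0.17, Tk0 = 1.35, CL = 56.15, V1 = 208.34, Q = 14.63, V2 = 76.15),
      beta = list(Tk0 = c("#2" = -0.4, "#3" = -0.68),
                  V1 = c("#2" = -1.26, "#3" = -1.24)),
      reference_category = "#1"),
    random = random_effects_spec(
      omega = c(Tlag = 0.38, Tk0 = 0.24, CL = 0.21, V1 = 0.15, Q = 0.47, V2 = 0.24),
      correlations = list(list(pair = c("V1", "CL"), rho = 0.72))),
    error = error_model(0.14),
    variant = model_variant(2L, "zero-order", lag = TRUE))
}

#' Standard errors reported with the final AVA model
#'
#' @return An [uncertainty_spec()] carrying the reported standard errors of
#'   the fixed effects and covariate coefficients.
#' @export
ava_uncertainty <- function() {
  uncertainty_spec(
    se_pop = c(Tlag = 0.013, Tk0 = 0.12, CL = 2.15, V1 = 11.07, Q = 1.7, V2 = 11.38),
    se_beta = list(Tk0 = c("#2" = 0.12, "#3" = 0.13),
                   V1 = c("#2" = 0.068, "#3" = 0.071)))
}

#' Dosing regimens of the simulation study
#'
#' The commonly suggested vinpocetine regimens compared in the simulation
#' study: 5/10/15 mg every 8 h and 15/30/60 mg once daily, all as
#' immediate-release tablets. `n_doses` spans `days` days of dosing.
#'
#' @param days Days of dosing covered by each regimen.
#' @return Named list of [regimen()] objects.
#' @export
ava_regimens <- function(days = 1) {
  mk <- function(dose, ii) regimen(dose, ii, n_doses = max(1L, ceiling(days * 24 / ii)),
                                   formulation = "#2")
  list("5mg q8h" = mk(5, 8), "10mg q8h" = mk(10, 8), "15mg q8h" = mk(15, 8),
       "15mg q24h" = mk(15, 24), "30mg q24h" = mk(30, 24), "60mg q24h" = mk(60, 24))
}

## config key helpers: the flat key naming mirrors the usual estimates-table
## layout ("Tlag_pop", "beta_Tk0_Formulation#2", "omega_Tlag", "corr_V1_Cl",
## "b"). "Cl" is accepted as an alias of "CL".
canon_par <- function(x) ifelse(toupper(x) == "CL", "CL", x)

#' Write a population model to a flat config file
#'
#' @param m A [population_model()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(m, path) {
  stopifnot(inherits(m, "population_model"))
  kv <- list()
  for (nm in names(m$fixed$pop)) kv[[paste0(nm, "_pop")]] <- unname(m$fixed$pop[[nm]])
  for (nm in names(m$fixed$beta)) {
    for (ct in names(m$fixed$beta[[nm]])) {
      kv[[sprintf("beta_%s_Formulation%s", nm, ct)]] <- unname(m$fixed$beta[[nm]][[ct]])
    }
  }
  for (nm in names(m$random$omega)) kv[[paste0("omega_", nm)]] <- unname(m$random$omega[[nm]])
  for (cr in m$random$correlations) {
    kv[[sprintf("corr_%s_%s", cr$pair[1], cr$pair[2])]] <- cr$rho
  }
  kv[["b"]] <- m$error$b
  kv[["reference_category"]] <- m$fixed$reference_category
  jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a population model from a flat config file
#'
#' Parses the flat key = value JSON layout written by [write_model_config()].
#' Missing required entries and invalid values raise errors naming the
#' offending key; omitting all correlation entries defaults them to zero with
#' a warning.
#'
#' @param path JSON config path.
#' @param variant Structural [model_variant()] the parameters belong to.
#' @return A [population_model()].
#' @export
read_model_config <- function(path, variant = model_variant()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  kv <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- variant_param_names(variant)
  keys <- names(kv)
  pop <- numeric(0)
  for (nm in need) {
    hit <- keys[canon_par(sub("_pop$", "", keys)) == nm & grepl("_pop$", keys)]
    if (!length(hit)) stop("config is missing required key: ", nm, "_pop", call. = FALSE)
    pop[nm] <- as.numeric(kv[[hit[1]]])
  }
  omega <- numeric(0)
  for (nm in need) {
    hit <- keys[grepl("^omega_", keys) & canon_par(sub("^omega_", "", keys)) == nm]
    if (!length(hit)) stop("config is missing required key: omega_", nm, call. = FALSE)
    val <- as.numeric(kv[[hit[1]]])
    if (is.na(val) || val < 0) stop("invalid value for key ", hit[1], call. = FALSE)
    omega[nm] <- val
  }
  beta <- list()
  for (key in keys[grepl("^beta_", keys)]) {
    mres <- regmatches(key, regexec("^beta_(.+)_Formulation(#[0-9]+)$", key))[[1]]
    if (length(mres) != 3L) stop("cannot parse covariate key: ", key, call. = FALSE)
    par <- canon_par(mres[2]); ct <- mres[3]
    if (!par %in% need) stop("covariate key refers to unknown parameter: ", key, call. = FALSE)
    beta[[par]] <- c(beta[[par]], stats::setNames(as.numeric(kv[[key]]), ct))
  }
  correlations <- list()
  ckeys <- keys[grepl("^corr_", keys)]
  if (!length(ckeys)) {
    warning("no correlation entries in config; random effects assumed independent")
  }
  for (key in ckeys) {
    parts <- canon_par(strsplit(sub("^corr_", "", key), "_")[[1]])
    if (length(parts) != 2L || !all(parts %in% need)) {
      stop("cannot parse correlation key: ", key, call. = FALSE)
    }
    correlations[[length(correlations) + 1L]] <-
      list(pair = parts, rho = as.numeric(kv[[key]]))
  }
  if (is.null(kv[["b"]])) stop("config is missing required key: b", call. = FALSE)
  ref <- if (!is.null(kv[["reference_category"]])) kv[["reference_category"]] else "#1"
  population_model(
    fixed = fixed_effects(pop, beta, reference_category = ref),
    random = random_effects_spec(omega, correlations),
    error = error_model(as.numeric(kv[["b"]])),
    variant = variant)
}
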