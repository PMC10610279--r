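#' Goodness-of-fit table
#'
#' One row per observation with the population prediction (random effects at
#' zero), the individual prediction (at the empirical Bayes estimates) and
#' the individual weighted residual `IWRES = (obs - ipred) / (b * ipred)`
#' (reported where `ipred > 0`).
#'
#' @param fit A `fit_result` from [saem_fit()], or a [population_model()]
#'   (in which case EBEs are taken from `ebes` or computed on the fly).
#' @param data An `event_table` containing the same subjects the fit used.
#' @param ebes Optional matrix of per-subject random-effect estimates (rows
#'   named/ordered by subject id) when `fit` is a bare model.
#' @return Data frame with columns `ID`, `PERIOD`, `FORM`, `TIME`, `DV`,
#'   `PRED`, `IPRED`, `IWRES`.
#' @export
gof <- function(fit, data, ebes = NULL) {
  if (inherits(fit, "fit_result")) {
    m <- fit$estimates; ebes <- fit$ebes; fit_ids <- fit$ids
  } else if (inherits(fit, "population_model")) {
    m <- fit; fit_ids <- NULL
  } else stop("fit must be a fit_result or population_model", call. = FALSE)
  fd <- flatten_data(data, m$variant)
  if (!is.null(fit_ids) && !all(fd$ids %in% fit_ids)) {
    stop("data contains subjects absent from the fit: ",
         paste(setdiff(fd$ids, fit_ids), collapse = ", "), call. = FALSE)
  }
  parnames <- variant_param_names(m$variant)
  cats <- setdiff(intersect(unique(fd$form), ava_formulations()),
                  m$fixed$reference_category)
  spec <- lapply(m$fixed$beta, function(bb) intersect(names(bb), cats))
  des <- build_design(fd, spec, parnames, m$fixed$reference_category)
  if (is.null(ebes)) {
    ebes <- ebe_all(m, fd, m$variant, parnames, des, sigma_floor = 0.01)
  } else {
    ebes <- as.matrix(ebes)
    if (!is.null(rownames(ebes))) {
      if (!all(as.character(fd$ids) %in% rownames(ebes))) {
        stop("ebes rows do not cover the data's subjects", call. = FALSE)
      }
      ebes <- ebes[as.character(fd$ids), parnames, drop = FALSE]
    }
  }
  mdl <- unpack_model(m, parnames, des)
  SH <- shift_matrix(des, mdl$betavec, length(parnames))
  th_pop <- exp(matrix(mdl$mu, fd$n, length(parnames), byrow = TRUE) + SH)
  colnames(th_pop) <- parnames
  pred <- pred_rows(m$variant, th_pop, fd$dose, fd$time)
  th_ind <- exp(matrix(mdl$mu, fd$n, length(parnames), byrow = TRUE) +
                  ebes[fd$subj, , drop = FALSE] + SH)
  colnames(th_ind) <- parnames
  ipred <- pred_rows(m$variant, th_ind, fd$dose, fd$time)
  iwres <- ifelse(ipred > 0, (fd$y - ipred) / (m$error$b * ipred), NA_real_)
  obs <- data[data$EVID == 0L, , drop = FALSE]
  data.frame(ID = obs$ID, PERIOD = obs$PERIOD, FORM = obs$FORM, TIME = obs$TIME,
             DV = obs$DV, PRED = pred, IPRED = ipred, IWRES = iwres,
             stringsAsFactors = FALSE)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets on the observed design (same
#' subjects, doses, sampling times and formulations; fresh random effects and
#' residual errors) and compares observed concentration percentiles with the
#' simulation-based prediction intervals, per time bin. Binning is one bin per
#' nominal sampling time; bins holding fewer than three observations are
#' merged with their neighbour.
#'
#' @param m A [population_model()].
#' @param data An `event_table` supplying the design and the observations.
#' @param n_sim Number of simulation replicates (>= 200).
#' @param percentiles Percentiles to track (defaults 10/50/90).
#' @param stratify_by_formulation If `TRUE`, a stratum per formulation is
#'   produced in addition to the pooled one.
#' @param seed Integer seed.
#' @param conf Confidence level of the prediction-interval envelopes.
#' @return An object of class `vpc_result`: a data frame with columns
#'   `stratum`, `bin_time`, `n_obs`, `percentile`, `observed`, `lower`,
#'   `upper`.
#' @export
vpc <- function(m, data, n_sim = 500L, percentiles = c(10, 50, 90),
                stratify_by_formulation = FALSE, seed = 1L, conf = 0.95) {
  stopifnot(inherits(m, "population_model"))
  if (n_sim < 200L) stop("n_sim must be at least 200", call. = FALSE)
  percentiles <- sort(percentiles)
  fd <- flatten_data(data, m$variant)
  parnames <- variant_param_names(m$variant)
  cats <- setdiff(intersect(unique(fd$form), ava_formulations()),
                  m$fixed$reference_category)
  spec <- lapply(m$fixed$beta, function(bb) intersect(names(bb), cats))
  des <- build_design(fd, spec, parnames, m$fixed$reference_category)
  mdl <- unpack_model(m, parnames, des)
  SH <- shift_matrix(des, mdl$betavec, length(parnames))

  ## time bins: one per nominal time, merged up to >= 3 observations
  ut <- sort(unique(fd$time))
  cnt <- vapply(ut, function(tt) sum(fd$time == tt), integer(1))
  bin_id <- integer(length(ut)); cur <- 1L; acc <- 0L
  for (j in seq_along(ut)) {
    bin_id[j] <- cur; acc <- acc + cnt[j]
    if (acc >= 3L && j < length(ut)) { cur <- cur + 1L; acc <- 0L }
  }
  if (acc > 0L && acc < 3L && cur > 1L) bin_id[bin_id == cur] <- cur - 1L
  obs_bin <- bin_id[match(fd$time, ut)]
  bin_time <- vapply(split(fd$time, obs_bin), stats::median, numeric(1))

  strata <- list(pooled = rep(TRUE, fd$n))
  if (stratify_by_formulation) {
    for (f in sort(unique(fd$form))) strata[[f]] <- fd$form == f
  }

  sim_mat <- matrix(NA_real_, n_sim, fd$n)
  for (r in seq_len(n_sim)) {
    set.seed(child_seed(seed, 200000L + r))
    eta <- sample_eta(m, fd$N)[, parnames, drop = FALSE]
    theta <- exp(matrix(mdl$mu, fd$n, length(parnames), byrow = TRUE) +
                   eta[fd$subj, , drop = FALSE] + SH)
    colnames(theta) <- parnames
    f <- pred_rows(m$variant, theta, fd$dose, fd$time)
    sim_mat[r, ] <- f * (1 + m$error$b * stats::rnorm(fd$n))
  }

  qlo <- (1 - conf) / 2; qhi <- 1 - qlo
  out <- list()
  for (st in names(strata)) {
    sel <- strata[[st]]
    for (bi in sort(unique(obs_bin[sel]))) {
      idx <- which(sel & obs_bin == bi)
      obs_q <- stats::quantile(fd$y[idx], percentiles / 100, names = FALSE)
      simq <- vapply(seq_len(n_sim), function(r)
        stats::quantile(sim_mat[r, idx], percentiles / 100, names = FALSE),
        numeric(length(percentiles)))
      simq <- matrix(simq, nrow = length(percentiles))
      for (pi in seq_along(percentiles)) {
        env <- stats::quantile(simq[pi, ], c(qlo, qhi), names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          stratum = st, bin_time = unname(bin_time[as.character(bi)]),
          n_obs = length(idx), percentile = percentiles[pi],
          observed = obs_q[pi], lower = env[1], upper = env[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("vpc_result", "data.frame")
  attr(res, "n_sim") <- n_sim
  attr(res, "conf") <- conf
  res
}

#' Plot a visual predictive check
#'
#' Percentile curves of the observations overlaid on the simulation
#' envelopes, one panel per stratum, with an optional log concentration axis.
#'
#' @param v A `vpc_result`.
#' @param log_y Use a log10 concentration axis.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_vpc <- function(v, log_y = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  v <- as.data.frame(v)
  v$percentile <- factor(v$percentile)
  gg <- ggplot2::ggplot(v, ggplot2::aes(x = .data$bin_time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$percentile), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$percentile)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$percentile)) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (µg/L)")
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Plot goodness-of-fit diagnostics
#'
#' Observed versus individual predictions with the identity line, alongside
#' individual weighted residuals over time.
#'
#' @param g A [gof()] table.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_gof <- function(g) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(g, ggplot2::aes(x = .data$IPRED, y = .data$DV)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Individual prediction (µg/L)",
                  y = "Observed (µg/L)")
}
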