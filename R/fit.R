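#' Prior specification for the hierarchical models
#'
#' The overall interaction `alpha` (full model) and the drug mean `beta`
#' (single-drug model) get zero-mean normal priors with SD
#' `location_prior_sd`; the default 2 encodes the assumption that large
#' covariate-treatment interactions are uncommon on a standardized scale.
#' All hierarchy SDs (`zeta`, each `sigma_c`, each `tau_d`) get independent
#' half-normal priors with scale `scale_prior_sd` (default 1), weakly
#' informative relative to generating values of 0.05-0.25.
#'
#' @param location_prior_sd positive SD of the normal prior on the top-level
#'   location parameter.
#' @param scale_prior_sd positive scale of the half-normal priors on the
#'   hierarchy SDs.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(location_prior_sd = 2, scale_prior_sd = 1) {
  stopifnot(location_prior_sd > 0, scale_prior_sd > 0)
  structure(list(location_prior_sd = location_prior_sd,
                 scale_prior_sd = scale_prior_sd),
            class = "prior_spec")
}

#' Inference settings for the Gibbs sampler
#'
#' Defaults run 2 chains of 5500 iterations each with the first 500
#' discarded (10,000 retained draws in total, 1000 burn-in across chains).
#' Convergence is flagged against split-chain potential scale reduction
#' (`rhat_max`, default 1.01) and total effective sample size (`ess_min`,
#' default 400) for every reported parameter.
#'
#' @param chains number of chains (>= 2 for split-Rhat to be meaningful).
#' @param iter total iterations per chain, including burn-in.
#' @param burn burn-in iterations discarded per chain.
#' @param thin thinning interval.
#' @param seed optional integer seed for the sampler.
#' @param rhat_max,ess_min convergence-flag thresholds.
#' @return an object of class `inference_settings`.
#' @export
inference_settings <- function(chains = 2L, iter = 5500L, burn = 500L,
                               thin = 1L, seed = NULL,
                               rhat_max = 1.01, ess_min = 400) {
  stopifnot(chains >= 1, iter > burn, burn >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn = as.integer(burn), thin = as.integer(thin),
                 seed = seed, rhat_max = rhat_max, ess_min = ess_min),
            class = "inference_settings")
}

# split-chain potential scale reduction factor; draws is iterations x chains
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2L) return(NA_real_)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  cm <- colMeans(split)
  cv <- apply(split, 2, stats::var)
  W <- mean(cv)
  B <- half * stats::var(cm)
  if (W < .Machine$double.eps) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# total effective sample size across chains (coda's spectral estimator)
ess_total <- function(draws) {
  draws <- as.matrix(draws)
  sum(apply(draws, 2, function(x) {
    if (stats::var(x) < .Machine$double.eps) return(length(x))
    unname(coda::effectiveSize(coda::mcmc(x)))
  }))
}

# one posterior summary row from an iterations x chains draw matrix
summarize_draws <- function(draws, param, unit) {
  x <- as.vector(draws)
  q <- unname(stats::quantile(x, c(0.025, 0.5, 0.975), type = 7))
  ess <- ess_total(draws)
  data.frame(param = param, unit = unit,
             mean = mean(x), sd = stats::sd(x),
             q025 = q[1], q50 = q[2], q975 = q[3],
             ess = ess, rhat = split_rhat(draws),
             mc_error = stats::sd(x) / sqrt(max(ess, 1)),
             stringsAsFactors = FALSE)
}

summarize_block <- function(arr, param, units) {
  # arr: n_keep x K x chains
  do.call(rbind, lapply(seq_along(units), function(k)
    summarize_draws(arr[, k, , drop = TRUE], param, units[k])))
}

check_input_ys <- function(dataset) {
  if (!all(c("y", "s") %in% names(dataset)))
    stop("dataset must contain columns y and s")
  if (any(!is.finite(dataset$y))) stop("non-finite y")
  if (any(!is.finite(dataset$s) | dataset$s <= 0))
    stop("every trial must have s > 0")
}

#' Fit the full ontology-structured hierarchical model
#'
#' Fits the three-level Bayesian hierarchical model
#' `y_z ~ N(mu_z, s_z^2)`, `mu_z ~ N(beta_d, tau_d^2)`,
#' `beta_d ~ N(gamma_c, sigma_c^2)`, `gamma_c ~ N(alpha, zeta^2)` with
#' `alpha ~ N(0, location_prior_sd^2)` and independent half-normal priors on
#' `zeta`, each `sigma_c` and each `tau_d`, by a collapsed conjugate Gibbs
#' sampler: the trial-level means are integrated out analytically
#' (`y_z ~ N(beta_d, s_z^2 + tau_d^2)`), each sweep draws all location
#' parameters jointly from their exact Gaussian conditional given the scales
#' (one message pass up the tree, ancestral sampling back down), and the
#' scale parameters are slice-updated on the log scale. The drug-level
#' `beta` posteriors are the unit of downstream performance evaluation.
#'
#' @param dataset a [simulate_dataset()] result, or any data frame with
#'   columns `y`, `s`, `drug_code`, `class_code`.
#' @param priors a [prior_spec()].
#' @param settings an [inference_settings()].
#' @param fix_scales optional list with elements `tau` (named by drug or
#'   scalar), `sigma` (named by class or scalar) and `zeta`; when supplied
#'   the scale parameters are held at these values and only locations are
#'   sampled (the conjugate-Gaussian special case used for validation).
#' @return an object of class `ontopool_fit` with elements `summary` (one
#'   row per parameter: `param`, `unit`, `mean`, `sd`, `q025`, `q50`,
#'   `q975`, `ess`, `rhat`, `mc_error`), `draws` (named list of draw
#'   arrays), and `diagnostics` (see [check_convergence()]).
#' @export
fit_full <- function(dataset, priors = prior_spec(),
                     settings = inference_settings(), fix_scales = NULL) {
  check_input_ys(dataset)
  stopifnot(all(c("drug_code", "class_code") %in% names(dataset)))
  drugs <- unique(dataset[, c("drug_code", "class_code")])
  drugs <- drugs[order(drugs$class_code, drugs$drug_code), , drop = FALSE]
  classes <- sort(unique(drugs$class_code))
  drug_idx <- match(dataset$drug_code, drugs$drug_code)
  class_of_drug <- match(drugs$class_code, classes)

  fs <- !is.null(fix_scales)
  if (fs) {
    tau0 <- rep_len(fix_scales$tau, nrow(drugs))
    if (!is.null(names(fix_scales$tau)))
      tau0 <- unname(fix_scales$tau[drugs$drug_code])
    sigma0 <- rep_len(fix_scales$sigma, length(classes))
    if (!is.null(names(fix_scales$sigma)))
      sigma0 <- unname(fix_scales$sigma[classes])
    zeta0 <- fix_scales$zeta
    stopifnot(all(tau0 >= 0), all(sigma0 >= 0), zeta0 >= 0)
    tau0 <- pmax(tau0, 1e-4); sigma0 <- pmax(sigma0, 1e-4)
    zeta0 <- max(zeta0, 1e-4)
  } else {
    tau0 <- numeric(0); sigma0 <- numeric(0); zeta0 <- NA_real_
  }

  n_keep <- (settings$iter - settings$burn) %/% settings$thin
  if (!is.null(settings$seed)) {
    old <- local_seed(settings$seed)
    on.exit(restore_seed(old))
  }
  draws <- .gibbs_full(dataset$y, dataset$s, drug_idx - 1L,
                       class_of_drug - 1L, length(classes),
                       priors$location_prior_sd, priors$scale_prior_sd,
                       n_keep, settings$burn, settings$chains,
                       settings$thin, fs, tau0, sigma0, zeta0)
  dimnames(draws$beta) <- list(NULL, drugs$drug_code, NULL)
  dimnames(draws$gamma) <- list(NULL, classes, NULL)
  dimnames(draws$tau) <- list(NULL, drugs$drug_code, NULL)
  dimnames(draws$sigma) <- list(NULL, classes, NULL)

  summ <- rbind(
    summarize_draws(draws$alpha, "alpha", ""),
    summarize_block(draws$gamma, "gamma", classes),
    summarize_block(draws$beta, "beta", drugs$drug_code)
  )
  if (!fs) {
    summ <- rbind(summ,
      summarize_draws(draws$zeta, "zeta", ""),
      summarize_block(draws$sigma, "sigma", classes),
      summarize_block(draws$tau, "tau", drugs$drug_code))
  }
  summ$level <- c(alpha = "overall", gamma = "class", beta = "drug",
                  zeta = "overall", sigma = "class", tau = "drug")[summ$param]
  rownames(summ) <- NULL

  fit <- structure(
    list(model = "full", summary = summ, draws = draws,
         drugs = drugs, classes = classes, priors = priors,
         settings = settings, fixed_scales = if (fs) fix_scales else NULL),
    class = "ontopool_fit")
  fit$diagnostics <- check_convergence(fit)
  fit
}

#' Fit a single-drug random-effects meta-analysis model
#'
#' The comparator model: the lowest two levels of the hierarchy applied to
#' the trials of one drug only, `y_z ~ N(mu_z, s_z^2)`,
#' `mu_z ~ N(beta, tau^2)`, with `beta ~ N(0, location_prior_sd^2)` and
#' `tau ~ halfN(0, scale_prior_sd^2)`. With a single trial, `tau` is
#' informed almost entirely by its prior; no special-casing is applied.
#'
#' @param dataset data frame with columns `y`, `s` (and `drug_code` if
#'   `drug` is given).
#' @param drug optional drug code used to subset `dataset`; if omitted the
#'   dataset must contain trials of exactly one drug.
#' @inheritParams fit_full
#' @return an `ontopool_fit` with summaries for `beta` and `tau`.
#' @export
fit_single <- function(dataset, drug = NULL, priors = prior_spec(),
                       settings = inference_settings()) {
  if (!is.null(drug)) {
    dataset <- dataset[dataset$drug_code == drug, , drop = FALSE]
    if (nrow(dataset) == 0L) stop("no trials for drug ", drug)
  } else if ("drug_code" %in% names(dataset) &&
             length(unique(dataset$drug_code)) != 1L) {
    stop("dataset contains more than one drug; pass `drug`")
  }
  check_input_ys(dataset)

  n_keep <- (settings$iter - settings$burn) %/% settings$thin
  if (!is.null(settings$seed)) {
    old <- local_seed(settings$seed)
    on.exit(restore_seed(old))
  }
  draws <- .gibbs_single(dataset$y, dataset$s,
                         priors$location_prior_sd, priors$scale_prior_sd,
                         n_keep, settings$burn, settings$chains,
                         settings$thin)
  unit <- if ("drug_code" %in% names(dataset)) dataset$drug_code[1] else ""
  summ <- rbind(summarize_draws(draws$beta, "beta", unit),
                summarize_draws(draws$tau, "tau", unit))
  summ$level <- "drug"
  rownames(summ) <- NULL
  fit <- structure(
    list(model = "single", summary = summ, draws = draws,
         drug = unit, priors = priors, settings = settings),
    class = "ontopool_fit")
  fit$diagnostics <- check_convergence(fit)
  fit
}

#' @export
print.ontopool_fit <- function(x, ...) {
  cat(sprintf("<ontopool_fit> %s model, %d parameters, converged: %s\n",
              x$model, nrow(x$summary), x$diagnostics$converged))
  print(utils::head(x$summary[, c("param", "unit", "mean", "sd",
                                  "q025", "q975", "rhat", "ess")], 12))
  invisible(x)
}

#' Convergence diagnostics for a fitted model
#'
#' Recomputes split-chain potential scale reduction and total effective
#' sample size for every reported parameter and flags any parameter
#' exceeding the thresholds. A flagged fit is never silently accepted
#' downstream: [run_study()] counts flagged fits and aborts when their
#' fraction exceeds its tolerance.
#'
#' @param fit an `ontopool_fit`.
#' @param rhat_max,ess_min thresholds; default to those in the fit's
#'   [inference_settings()].
#' @return list with `converged` (logical), `flagged` (character vector of
#'   `param[unit]` labels), `max_rhat`, `min_ess`.
#' @export
check_convergence <- function(fit, rhat_max = NULL, ess_min = NULL) {
  if (is.null(rhat_max)) rhat_max <- fit$settings$rhat_max
  if (is.null(ess_min)) ess_min <- fit$settings$ess_min
  s <- fit$summary
  bad <- (!is.na(s$rhat) & s$rhat > rhat_max) | s$ess < ess_min
  list(converged = !any(bad),
       flagged = paste0(s$param, "[", s$unit, "]")[bad],
       max_rhat = max(s$rhat, na.rm = TRUE),
       min_ess = min(s$ess))
}

#' Drug-level estimates from a fit
#'
#' Extracts the posterior mean and equal-tailed 95% credible interval of the
#' drug-level interaction `beta` for each drug — the quantities compared
#' across models by the performance measures.
#'
#' @param fit an `ontopool_fit` (full or single).
#' @return data frame with columns `drug_code`, `est`, `ci_low`, `ci_high`.
#' @export
drug_estimates <- function(fit) {
  s <- fit$summary[fit$summary$param == "beta", , drop = FALSE]
  data.frame(drug_code = s$unit, est = s$mean,
             ci_low = s$q025, ci_high = s$q975,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize posterior summaries
#'
#' Writes the flat parameter-summary table
#' (`param,level,unit,mean,sd,q025,q50,q975,ess,rhat,mc_error`) as CSV.
#'
#' @param fit an `ontopool_fit`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  cols <- c("param", "level", "unit", "mean", "sd", "q025", "q50", "q975",
            "ess", "rhat", "mc_error")
  utils::write.csv(fit$summary[, cols], path, row.names = FALSE)
  invisible(path)
}
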