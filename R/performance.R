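#' Assemble estimate records from a fitted model
#'
#' One estimate record per drug: the posterior mean and 95% equal-tailed
#' credible interval of the drug-level interaction `beta`, paired with the
#' generating (true) drug effect from the simulated dataset. Stacked records
#' across replicates are the input to all performance measures.
#'
#' @param fit an `ontopool_fit` (full model, or single-drug).
#' @param dataset the [simulate_dataset()] the fit was run on (source of
#'   `beta_true`).
#' @param rep replicate index.
#' @return data frame with columns `rep`, `drug_code`, `model`, `est`,
#'   `ci_low`, `ci_high`, `truth`.
#' @export
estimate_records <- function(fit, dataset, rep = 1L) {
  est <- drug_estimates(fit)
  truth <- attr(dataset, "beta_by_drug")
  if (is.null(truth)) {
    first <- !duplicated(dataset$drug_code)
    truth <- stats::setNames(dataset$beta_true[first],
                             dataset$drug_code[first])
  }
  data.frame(rep = as.integer(rep), drug_code = est$drug_code,
             model = fit$model, est = est$est,
             ci_low = est$ci_low, ci_high = est$ci_high,
             truth = unname(truth[est$drug_code]),
             stringsAsFactors = FALSE)
}

check_records <- function(records, min_n = 2L) {
  if (is.null(records) || nrow(records) < min_n)
    stop("need at least ", min_n, " estimate records")
  stopifnot(all(c("est", "truth") %in% names(records)))
  if (any(!is.finite(records$truth))) stop("non-finite truth")
  invisible(records)
}

#' Simulation-study performance measures
#'
#' Performance of a model's drug-level estimates pooled over drugs and
#' replicates, each with its Monte Carlo standard error:
#' \describe{
#'   \item{`measure_bias`}{mean of `est - truth`; MCSE
#'     `sd(est - truth)/sqrt(N)`.}
#'   \item{`measure_mse`}{mean of `(est - truth)^2`; MCSE
#'     `sd((est - truth)^2)/sqrt(N)`.}
#'   \item{`measure_rmse`}{`sqrt(MSE)`, with the MCSE by the delta method,
#'     `mcse(MSE) / (2 * sqrt(MSE))`.}
#'   \item{`measure_coverage`}{proportion of 95% credible intervals
#'     containing the truth; binomial MCSE `sqrt(c * (1 - c) / N)`.}
#' }
#'
#' @param records stacked [estimate_records()] for one scenario and model.
#' @return list with elements `estimate` and `mcse`.
#' @export
measure_bias <- function(records) {
  check_records(records)
  err <- records$est - records$truth
  list(estimate = mean(err), mcse = stats::sd(err) / sqrt(length(err)))
}

#' @rdname measure_bias
#' @export
measure_mse <- function(records) {
  check_records(records)
  sq <- (records$est - records$truth)^2
  list(estimate = mean(sq), mcse = stats::sd(sq) / sqrt(length(sq)))
}

#' @rdname measure_bias
#' @export
measure_rmse <- function(records) {
  m <- measure_mse(records)
  if (m$estimate == 0) return(list(estimate = 0, mcse = 0))
  list(estimate = sqrt(m$estimate),
       mcse = m$mcse / (2 * sqrt(m$estimate)))
}

#' @rdname measure_bias
#' @export
measure_coverage <- function(records) {
  check_records(records, min_n = 1L)
  stopifnot(all(c("ci_low", "ci_high") %in% names(records)))
  hit <- records$ci_low <= records$truth & records$truth <= records$ci_high
  c_hat <- mean(hit)
  list(estimate = c_hat,
       mcse = sqrt(c_hat * (1 - c_hat) / length(hit)))
}

# empirical SE of the point estimates across stacked records
emp_se <- function(records, errors_based = FALSE) {
  x <- if (errors_based) records$est - records$truth else records$est
  stats::sd(x)
}

#' Relative precision of the full model versus the single-drug model
#'
#' Percentage gain in precision of the full model over the single-drug
#' model, `100 * ((empSE_single / empSE_full)^2 - 1)`, where the empirical
#' SE is the standard deviation of the point estimates across stacked
#' drug-replicate records (the rsimsum convention; set
#' `errors_based = TRUE` to use the SD of `est - truth` instead, relevant
#' because each drug-replicate has its own truth). The MCSE is a jackknife
#' over replicates: each replicate's records are deleted from both models
#' jointly, preserving the pairing.
#'
#' @param records_single,records_full paired [estimate_records()] for the
#'   two models on the same replicates (same `rep` values).
#' @param errors_based use SD of errors rather than of estimates.
#' @return list with `estimate` (percent) and `mcse`.
#' @export
relative_precision <- function(records_single, records_full,
                               errors_based = FALSE) {
  check_records(records_single); check_records(records_full)
  reps <- sort(unique(records_full$rep))
  if (!setequal(reps, unique(records_single$rep)))
    stop("replicates are not paired between models")
  rp <- function(sgl, ful) {
    if (nrow(ful) < 2L) return(NA_real_)
    ef <- emp_se(ful, errors_based)
    if (is.na(ef)) return(NA_real_)
    if (ef == 0) stop("empirical SE of the full model is zero")
    100 * ((emp_se(sgl, errors_based) / ef)^2 - 1)
  }
  est <- rp(records_single, records_full)
  R <- length(reps)
  if (R < 3L) return(list(estimate = est, mcse = NA_real_))
  loo <- vapply(reps, function(r)
    rp(records_single[records_single$rep != r, , drop = FALSE],
       records_full[records_full$rep != r, , drop = FALSE]),
    numeric(1))
  list(estimate = est,
       mcse = sqrt((R - 1) / R * sum((loo - mean(loo))^2)))
}

#' Detection of true subgroup effects by model
#'
#' A drug's interaction is "detected" in a replicate when the 95% credible
#' interval excludes zero. For each drug, over the (paired) replicates in
#' which the generating drug effect is at least as large as the detection
#' threshold in the simulated direction (`truth <= truth_threshold`,
#' default -0.10; set `condition = FALSE` to use all replicates), this
#' returns the proportions detected by both models, the single-drug model
#' only, the full model only, and neither.
#'
#' @param records_single,records_full paired [estimate_records()].
#' @param truth_threshold detection conditioning threshold (default -0.10).
#' @param condition whether to restrict to replicates with
#'   `truth <= truth_threshold`.
#' @return data frame with columns `drug_code`, `n_eligible`, `p_both`,
#'   `p_single_only`, `p_full_only`, `p_neither` (rows with no eligible
#'   replicates are dropped).
#' @export
detection_classes <- function(records_single, records_full,
                              truth_threshold = -0.10, condition = TRUE) {
  check_records(records_single, 1L); check_records(records_full, 1L)
  key <- function(r) paste(r$rep, r$drug_code)
  m <- match(key(records_full), key(records_single))
  if (anyNA(m) || nrow(records_full) != nrow(records_single))
    stop("records are not paired by replicate and drug")
  sgl <- records_single[m, , drop = FALSE]
  ful <- records_full
  if (condition) {
    keep <- ful$truth <= truth_threshold
    sgl <- sgl[keep, , drop = FALSE]
    ful <- ful[keep, , drop = FALSE]
  }
  if (nrow(ful) == 0L)
    return(data.frame(drug_code = character(), n_eligible = integer(),
                      p_both = numeric(), p_single_only = numeric(),
                      p_full_only = numeric(), p_neither = numeric()))
  det <- function(r) r$ci_low > 0 | r$ci_high < 0
  ds <- det(sgl); df_ <- det(ful)
  out <- do.call(rbind, lapply(split(seq_len(nrow(ful)), ful$drug_code),
    function(i) {
      n <- length(i)
      data.frame(drug_code = ful$drug_code[i[1]], n_eligible = n,
                 p_both = mean(ds[i] & df_[i]),
                 p_single_only = mean(ds[i] & !df_[i]),
                 p_full_only = mean(!ds[i] & df_[i]),
                 p_neither = mean(!ds[i] & !df_[i]),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Assemble the long-format performance table
#'
#' Computes every performance measure for every scenario and model present
#' in the stacked records: bias, MSE, RMSE and coverage per model, and
#' relative precision of the full model versus the single-drug model
#' (reported for the full model only). Mirrors the layout of a
#' scenario-by-measure simulation-study summary table.
#'
#' @param records stacked [estimate_records()] carrying a `scenario` column
#'   in addition to the record fields, covering both models for each
#'   scenario.
#' @param errors_based passed to [relative_precision()].
#' @return data frame with columns `scenario`, `measure`, `model`,
#'   `estimate`, `mcse`.
#' @export
performance_table <- function(records, errors_based = FALSE) {
  stopifnot("scenario" %in% names(records))
  measures <- list(bias = measure_bias, mse = measure_mse,
                   rmse = measure_rmse, coverage = measure_coverage)
  rows <- list()
  for (sc in unique(records$scenario)) {
    rsc <- records[records$scenario == sc, , drop = FALSE]
    for (mod in c("single", "full")) {
      rm_ <- rsc[rsc$model == mod, , drop = FALSE]
      if (nrow(rm_) == 0L)
        stop("missing cell: scenario '", sc, "', model '", mod, "'")
      for (ms in names(measures)) {
        v <- measures[[ms]](rm_)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, measure = ms, model = mod,
          estimate = v$estimate, mcse = v$mcse, stringsAsFactors = FALSE)
      }
    }
    rp <- relative_precision(rsc[rsc$model == "single", , drop = FALSE],
                             rsc[rsc$model == "full", , drop = FALSE],
                             errors_based = errors_based)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sc, measure = "rel_precision", model = "full",
      estimate = rp$estimate, mcse = rp$mcse, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-class relative precision
#'
#' [relative_precision()] computed separately for the drugs of each ATC
#' class, the breakdown behind class-level precision-gain comparisons.
#'
#' @param records_single,records_full paired [estimate_records()].
#' @param network the [trial_network()] supplying the drug-class map.
#' @param errors_based passed to [relative_precision()].
#' @return data frame with columns `class_code`, `estimate`, `mcse`.
#' @export
relative_precision_by_class <- function(records_single, records_full,
                                        network, errors_based = FALSE) {
  drugs <- attr(validate_network(network), "drugs")
  cls <- stats::setNames(drugs$class_code, drugs$drug_code)
  out <- do.call(rbind, lapply(sort(unique(drugs$class_code)), function(cc) {
    ds <- records_single[cls[records_single$drug_code] == cc, , drop = FALSE]
    df_ <- records_full[cls[records_full$drug_code] == cc, , drop = FALSE]
    rp <- relative_precision(ds, df_, errors_based = errors_based)
    data.frame(class_code = cc, estimate = rp$estimate, mcse = rp$mcse,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
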