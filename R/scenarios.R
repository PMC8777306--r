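#' Define a data-generating scenario
#'
#' A scenario fixes the data-generating process for simulated trial-level
#' comorbidity-treatment interaction estimates: the overall interaction
#' effect at the top of the hierarchy, the standard deviations of the random
#' variation added at the class, drug and trial levels, and the comorbidity
#' prevalence (which determines each trial's estimate SE through
#' [interaction_se()]).
#'
#' @param name scenario label.
#' @param sd_class,sd_drug,sd_trial nonnegative SDs of the random deviations
#'   added at the drug-class, drug and trial levels (standardized units).
#' @param overall_effect the overall comorbidity-treatment interaction at the
#'   top level of the hierarchy; default -0.1 standardized units, a modest
#'   but plausibly decision-relevant subgroup difference.
#' @param prevalence comorbidity prevalence in (0, 1); default 0.2.
#' @return an object of class `scenario_spec` (a named list).
#' @export
#' @examples
#' scenario_spec("all-low", 0.05, 0.05, 0.05)
scenario_spec <- function(name, sd_class, sd_drug, sd_trial,
                          overall_effect = -0.1, prevalence = 0.2) {
  stopifnot(sd_class >= 0, sd_drug >= 0, sd_trial >= 0,
            prevalence > 0, prevalence < 1, is.finite(overall_effect))
  structure(
    list(name = name, sd_class = sd_class, sd_drug = sd_drug,
         sd_trial = sd_trial, overall_effect = overall_effect,
         prevalence = prevalence),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario> %s: SD class/drug/trial = %.2f/%.2f/%.2f, effect %.2f, prevalence %.2f\n",
    x$name, x$sd_class, x$sd_drug, x$sd_trial, x$overall_effect, x$prevalence))
  invisible(x)
}

#' The nine standard simulation scenarios
#'
#' The standard grid varies the between-class, between-drug and between-trial
#' SDs over low (0.05), medium (0.15) and high (0.25) values: three
#' "all-levels" scenarios with equal SDs at every level, and six scenarios
#' raising one level to medium or high while the other two stay at 0.05.
#' Every scenario uses an overall effect of -0.1 and the given prevalence.
#'
#' @param prevalence comorbidity prevalence applied to all nine scenarios
#'   (default 0.2; the sensitivity analyses rerun the grid at 0.1 and 0.5).
#' @return named list of nine [scenario_spec()] objects: `all-low`,
#'   `all-medium`, `all-high`, `trial-medium`, `trial-high`, `drug-medium`,
#'   `drug-high`, `class-medium`, `class-high`.
#' @export
standard_scenarios <- function(prevalence = 0.2) {
  grid <- list(
    "all-low"      = c(0.05, 0.05, 0.05),
    "all-medium"   = c(0.15, 0.15, 0.15),
    "all-high"     = c(0.25, 0.25, 0.25),
    "trial-medium" = c(0.05, 0.05, 0.15),
    "trial-high"   = c(0.05, 0.05, 0.25),
    "drug-medium"  = c(0.05, 0.15, 0.05),
    "drug-high"    = c(0.05, 0.25, 0.05),
    "class-medium" = c(0.15, 0.05, 0.05),
    "class-high"   = c(0.25, 0.05, 0.05)
  )
  out <- lapply(names(grid), function(nm) {
    sds <- grid[[nm]]
    scenario_spec(nm, sd_class = sds[1], sd_drug = sds[2], sd_trial = sds[3],
                  prevalence = prevalence)
  })
  names(out) <- names(grid)
  out
}

#' Simulate one dataset of trial-level interaction estimates
#'
#' Draws one simulated dataset from the three-level hierarchical
#' data-generating process on a trial network. For each class c a true class
#' effect `gamma_c = overall_effect + N(0, sd_class^2)`; for each drug d in
#' class c a true drug effect `beta_d = gamma_c + N(0, sd_drug^2)`; for each
#' trial z of drug d a true trial effect `mu_z = beta_d + N(0, sd_trial^2)`;
#' and the observed estimate `y_z = mu_z + N(0, s_z^2)` where
#' `s_z = interaction_se(enrollment_z, prevalence)`. Identical seeds give
#' bit-identical datasets.
#'
#' @param network a [trial_network()].
#' @param scenario a [scenario_spec()].
#' @param seed integer seed.
#' @return an object of class `sim_dataset`: a data frame with one row per
#'   trial (`trial_id`, `drug_code`, `class_code`, `enrollment`, `y`, `s`,
#'   `mu_true`, `beta_true`, `gamma_true`) carrying the scenario and seed as
#'   attributes.
#' @export
#' @examples
#' net <- make_network(12, 5, 2, seed = 4)
#' d <- simulate_dataset(net, scenario_spec("demo", 0.05, 0.05, 0.05), seed = 1)
#' head(d)
simulate_dataset <- function(network, scenario, seed) {
  network <- validate_network(network)
  stopifnot(inherits(scenario, "scenario_spec"))
  drugs <- attr(network, "drugs")
  classes <- attr(network, "classes")
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  gamma <- scenario$overall_effect +
    stats::rnorm(length(classes), 0, scenario$sd_class)
  names(gamma) <- classes
  beta <- gamma[drugs$class_code] +
    stats::rnorm(nrow(drugs), 0, scenario$sd_drug)
  names(beta) <- drugs$drug_code
  mu <- beta[network$drug_code] +
    stats::rnorm(nrow(network), 0, scenario$sd_trial)
  s <- interaction_se(network$enrollment, scenario$prevalence)
  y <- mu + stats::rnorm(nrow(network), 0, s)

  out <- data.frame(
    trial_id   = network$trial_id,
    drug_code  = network$drug_code,
    class_code = network$class_code,
    enrollment = network$enrollment,
    y = y, s = s,
    mu_true    = unname(mu),
    beta_true  = unname(beta[network$drug_code]),
    gamma_true = unname(gamma[network$class_code]),
    stringsAsFactors = FALSE
  )
  structure(out,
            scenario = scenario, seed = as.integer(seed),
            beta_by_drug = beta, gamma_by_class = gamma,
            class = c("sim_dataset", "data.frame"))
}

#' Simulate a batch of replicate datasets
#'
#' Replicate i uses the deterministic child seed
#' `(base_seed + 7919 * i) mod (2^31 - 1)`, so batches are reproducible,
#' resumable by replicate index, and independent of evaluation order. The
#' same batch is intended to be fitted with both the full hierarchical model
#' and the single-drug models so that model comparisons are paired.
#'
#' @param network a [trial_network()].
#' @param scenario a [scenario_spec()].
#' @param n_reps number of replicate datasets.
#' @param base_seed integer base seed for the batch.
#' @return list of `n_reps` [simulate_dataset()] results.
#' @export
simulate_batch <- function(network, scenario, n_reps, base_seed) {
  stopifnot(n_reps >= 1)
  network <- validate_network(network)
  lapply(seq_len(n_reps), function(i)
    simulate_dataset(network, scenario, seed = child_seed(base_seed, i)))
}

#' Write / read a simulated dataset as CSV with a YAML sidecar
#'
#' The CSV holds one row per trial
#' (`trial_id,drug_code,class_code,enrollment,y,s,mu_true,beta_true,gamma_true`);
#' the sidecar `<path>.yml` records the scenario parameters and seed so the
#' dataset is fully reproducible.
#'
#' @param dataset a `sim_dataset`.
#' @param path CSV file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns the `sim_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  sc <- attr(dataset, "scenario")
  yaml::write_yaml(
    list(scenario = unclass(sc), seed = attr(dataset, "seed")),
    paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  sc <- do.call(scenario_spec, meta$scenario)
  beta <- df$beta_true[!duplicated(df$drug_code)]
  names(beta) <- df$drug_code[!duplicated(df$drug_code)]
  gamma <- df$gamma_true[!duplicated(df$class_code)]
  names(gamma) <- df$class_code[!duplicated(df$class_code)]
  structure(df, scenario = sc, seed = meta$seed,
            beta_by_drug = beta, gamma_by_class = gamma,
            class = c("sim_dataset", "data.frame"))
}
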