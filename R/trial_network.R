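#' Construct a trial network
#'
#' A trial network is the structural backbone of the simulation study: a set
#' of clinical trials, each testing one drug, with drugs nested in WHO-ATC
#' level-5 classes. Only the structure (which trial belongs to which drug and
#' class, and how many participants each trial enrolled) is used; no outcome
#' data are stored here.
#'
#' @param trial_id character vector of unique trial identifiers.
#' @param drug_code ATC level-7 code of the drug tested in each trial
#'   (e.g. `"A10BH01"`).
#' @param class_code ATC level-5 class code (e.g. `"A10BH"`); must be a
#'   prefix of the corresponding `drug_code`.
#' @param enrollment positive integer number of randomized participants.
#' @param drug_name optional human-readable drug name.
#'
#' @return An object of class `trial_network`: a data frame with columns
#'   `trial_id`, `drug_code`, `drug_name`, `class_code`, `enrollment`, plus
#'   attributes `drugs` (data frame mapping each drug to its class) and
#'   `classes` (character vector of class codes).
#' @seealso [read_network()], [default_network()], [make_network()]
#' @export
#' @examples
#' net <- trial_network(
#'   trial_id   = c("T1", "T2", "T3"),
#'   drug_code  = c("A10BH01", "A10BH01", "A10BH05"),
#'   class_code = c("A10BH", "A10BH", "A10BH"),
#'   enrollment = c(500L, 1200L, 800L)
#' )
#' n_trials(net)
trial_network <- function(trial_id, drug_code, class_code, enrollment,
                          drug_name = NULL) {
  if (is.null(drug_name)) drug_name <- drug_code
  records <- data.frame(
    trial_id   = as.character(trial_id),
    drug_code  = as.character(drug_code),
    drug_name  = as.character(drug_name),
    class_code = as.character(class_code),
    enrollment = as.integer(enrollment),
    stringsAsFactors = FALSE
  )
  validate_network(new_trial_network(records))
}

new_trial_network <- function(records) {
  drugs <- unique(records[, c("drug_code", "class_code")])
  drugs <- drugs[order(drugs$class_code, drugs$drug_code), , drop = FALSE]
  rownames(drugs) <- NULL
  structure(records,
            drugs = drugs,
            classes = sort(unique(records$class_code)),
            class = c("trial_network", "data.frame"))
}

#' Validate a trial network
#'
#' Checks the structural invariants: unique trial ids, positive enrollment,
#' each drug assigned to exactly one class, class code a prefix of the drug
#' code. Validation is idempotent; a valid network is returned unchanged.
#' Trials enrolling fewer than 300 participants trigger a warning only:
#' 300 was a selection criterion for the exemplar network of glucose-lowering
#' drug trials, not a model requirement.
#'
#' @param net a `trial_network`.
#' @return `net`, invisibly unchanged, or an error.
#' @export
validate_network <- function(net) {
  stopifnot(is.data.frame(net))
  needed <- c("trial_id", "drug_code", "drug_name", "class_code", "enrollment")
  missing_cols <- setdiff(needed, names(net))
  if (length(missing_cols) > 0L)
    stop("network is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(net) == 0L) stop("network has no trials")
  dup <- net$trial_id[duplicated(net$trial_id)]
  if (length(dup) > 0L)
    stop("duplicate trial_id: ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(net$enrollment) | net$enrollment < 1L))
    stop("enrollment must be a positive integer for every trial")
  map <- unique(net[, c("drug_code", "class_code")])
  multi <- map$drug_code[duplicated(map$drug_code)]
  if (length(multi) > 0L)
    stop("drug assigned to more than one class: ",
         paste(unique(multi), collapse = ", "))
  bad_prefix <- !startsWith(net$drug_code, net$class_code)
  if (any(bad_prefix))
    stop("class_code is not a prefix of drug_code for trial(s): ",
         paste(net$trial_id[bad_prefix], collapse = ", "))
  if (any(net$enrollment < 300L))
    warning("trial(s) with enrollment < 300: ",
            paste(net$trial_id[net$enrollment < 300L], collapse = ", "),
            " (selection criterion of the exemplar network, not required)")
  new_trial_network(as.data.frame(net)[, needed])
}

#' @export
print.trial_network <- function(x, ...) {
  cat(sprintf("<trial_network> %d trials, %d drugs, %d classes, %s participants\n",
              n_trials(x), n_drugs(x), n_classes(x),
              format(total_enrollment(x), big.mark = ",")))
  invisible(x)
}

#' Network summary counts
#'
#' @param net a `trial_network`.
#' @return integer (or numeric for `total_enrollment`) scalar.
#' @export
n_trials <- function(net) nrow(net)

#' @rdname n_trials
#' @export
n_drugs <- function(net) nrow(attr(net, "drugs"))

#' @rdname n_trials
#' @export
n_classes <- function(net) length(attr(net, "classes"))

#' @rdname n_trials
#' @export
total_enrollment <- function(net) sum(as.numeric(net$enrollment))

#' Read / write a trial network as CSV
#'
#' The CSV dialect is a UTF-8 comma-separated file with a header row and
#' columns `trial_id,drug_code,drug_name,class_code,enrollment`
#' (`drug_name` optional on read). `write_network()` emits the identical
#' dialect, so a write/read round trip reproduces the records exactly.
#'
#' @param path file path.
#' @param columns optional named character vector remapping file column names
#'   to the canonical ones, e.g. `c(trial_id = "nct_id")` if the file calls
#'   the trial identifier `nct_id`.
#' @return `read_network()` returns a validated [trial_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      if (columns[[canon]] %in% names(raw))
        names(raw)[names(raw) == columns[[canon]]] <- canon
    }
  }
  needed <- c("trial_id", "drug_code", "class_code", "enrollment")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L)
    stop("network file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"drug_name" %in% names(raw)) raw$drug_name <- raw$drug_code
  trial_network(raw$trial_id, raw$drug_code, raw$class_code,
                raw$enrollment, raw$drug_name)
}

#' @rdname read_network
#' @param net a `trial_network`.
#' @export
write_network <- function(net, path) {
  validate_network(net)
  utils::write.csv(as.data.frame(net), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged stand-in trial network
#'
#' Returns the packaged synthetic stand-in for the exemplar network of
#' noninsulin glucose-lowering drug trials: 161 trials of 24 drugs in 7
#' WHO-ATC level-5 classes, 210,046 participants in total. The per-drug trial
#' counts and per-trial enrollments are synthetic (the trial-level listing of
#' the real network is not redistributed here) but reproduce the aggregate
#' counts and the qualitative features the hierarchical model's behaviour
#' depends on: a right-skewed trials-per-drug distribution, right-skewed
#' enrollments with a minimum of 300, classes ranging from a single drug to
#' seven drugs, and one drug (taspoglutide) represented by a single small
#' trial. The allocation is frozen in
#' `system.file("extdata", "default_network.csv", package = "ontopool")` and
#' can be replaced by a real network via [read_network()].
#'
#' @return a validated [trial_network()].
#' @export
#' @examples
#' net <- default_network()
#' c(n_trials(net), n_drugs(net), n_classes(net), total_enrollment(net))
default_network <- function() {
  path <- system.file("extdata", "default_network.csv", package = "ontopool")
  read_network(path)
}

#' Standard error of a trial-level interaction estimate
#'
#' Analytic standard error of the comorbidity-treatment interaction estimated
#' by least squares from a balanced two-arm trial with a standardized
#' (unit-variance) continuous outcome: the difference-in-differences contrast
#' between arms and comorbidity subgroups has variance
#' `4 * outcome_sd^2 / (n * p * (1 - p))` under 1:1 allocation, where `p` is
#' the comorbidity prevalence. The SE is strictly decreasing in enrollment
#' and, for fixed enrollment, smallest at `p = 0.5`. The formula is kept in
#' this single function so an alternative convention can be swapped in.
#'
#' @param enrollment positive integer, participants randomized.
#' @param prevalence comorbidity prevalence, strictly between 0 and 1.
#' @param outcome_sd standard deviation of the outcome (default 1, i.e. a
#'   standardized scale).
#' @return positive numeric SE (vectorized over `enrollment`).
#' @export
#' @examples
#' interaction_se(1000, 0.2)  # 0.1581
#' interaction_se(400, 0.5)   # 0.2
interaction_se <- function(enrollment, prevalence, outcome_sd = 1) {
  if (any(!is.finite(prevalence) | prevalence <= 0 | prevalence >= 1))
    stop("prevalence must be strictly between 0 and 1")
  if (any(!is.finite(enrollment) | enrollment < 1))
    stop("enrollment must be >= 1")
  if (any(outcome_sd <= 0)) stop("outcome_sd must be positive")
  2 * outcome_sd / sqrt(enrollment * prevalence * (1 - prevalence))
}

#' Synthesize a trial network
#'
#' Generates a random trial network with the qualitative shape of real drug
#' development programmes: trials-per-drug right-skewed (most drugs have few
#' trials, a few have many) and enrollments drawn from a log-normal
#' distribution truncated below, optionally rescaled so total enrollment hits
#' an exact target. Used to build test networks of arbitrary size; the
#' packaged [default_network()] was produced by this generator.
#'
#' @param n_trials,n_drugs,n_classes network dimensions
#'   (`n_trials >= n_drugs >= n_classes`).
#' @param total_enrollment optional exact total across trials; when supplied,
#'   enrollments are proportionally rescaled (respecting `min_enrollment`)
#'   and the rounding residual is absorbed by the largest trial.
#' @param min_enrollment smallest allowed per-trial enrollment (default 300).
#' @param meanlog,sdlog log-normal enrollment parameters before truncation
#'   (defaults give a median near 900 with a heavy right tail).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a validated [trial_network()].
#' @export
make_network <- function(n_trials, n_drugs, n_classes,
                         total_enrollment = NULL, min_enrollment = 300L,
                         meanlog = 6.8, sdlog = 0.9, seed = 1L) {
  stopifnot(n_trials >= n_drugs, n_drugs >= n_classes, n_classes >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  # right-skewed allocation of drugs to classes and trials to drugs:
  # geometric-ish weights, then guarantee at least one per group
  class_of_drug <- sort(c(seq_len(n_classes),
                          sample.int(n_classes, n_drugs - n_classes,
                                     replace = TRUE,
                                     prob = 0.6^seq_len(n_classes))))
  drug_of_trial <- sort(c(seq_len(n_drugs),
                          sample.int(n_drugs, n_trials - n_drugs,
                                     replace = TRUE,
                                     prob = 0.75^seq_len(n_drugs))))
  enroll <- pmax(round(stats::rlnorm(n_trials, meanlog, sdlog)),
                 min_enrollment)
  if (!is.null(total_enrollment)) {
    stopifnot(total_enrollment >= n_trials * min_enrollment)
    enroll <- pmax(round(enroll * total_enrollment / sum(enroll)),
                   min_enrollment)
    enroll[which.max(enroll)] <- enroll[which.max(enroll)] +
      (total_enrollment - sum(enroll))
  }
  classes <- sprintf("A10B%s", LETTERS[seq_len(n_classes)])
  drugs <- sprintf("%s%02d", classes[class_of_drug],
                   stats::ave(class_of_drug, class_of_drug, FUN = seq_along))
  trial_network(
    trial_id   = sprintf("SIM%04d", seq_len(n_trials)),
    drug_code  = drugs[drug_of_trial],
    class_code = classes[class_of_drug[drug_of_trial]],
    enrollment = enroll
  )
}

# Seed management: save/restore .Random.seed so generator calls do not
# disturb the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# deterministic counter-based child seed for replicate i of a batch
child_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) + 7919 * as.numeric(i)) %% 2147483647)
}
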