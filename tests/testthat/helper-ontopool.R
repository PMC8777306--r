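# shared fixtures: built in code, never stored

child_seed <- ontopool:::child_seed

# 6-trial, 3-drug, 2-class network with mixed enrollments
toy_network <- function() {
  trial_network(
    trial_id   = paste0("T", 1:6),
    drug_code  = c("A10BH01", "A10BH01", "A10BH05", "A10BH05", "A10BK01",
                   "A10BK01"),
    class_code = c(rep("A10BH", 4), rep("A10BK", 2)),
    enrollment = c(400L, 2000L, 350L, 900L, 5000L, 600L)
  )
}

# sampler settings sized for unit tests (2600 retained draws)
quick_settings <- function(seed = NULL) {
  inference_settings(chains = 2L, iter = 1600L, burn = 300L, seed = seed,
                     ess_min = 200)
}

# random small network for property-style loops
random_small_network <- function(seed, max_trials = 10L) {
  set.seed(seed)
  n_classes <- sample(1:3, 1)
  n_drugs <- n_classes + sample(0:3, 1)
  n_trials <- max(n_drugs, sample(n_drugs:max_trials, 1))
  make_network(n_trials, n_drugs, n_classes, seed = seed + 1L,
               min_enrollment = 500L)
}

# independent IPD least-squares oracle for the trial-level interaction SE:
# a balanced trial design (exact 1:1 arms, comorbidity at exactly prevalence
# p in each arm — the design the closed form describes) with unit-variance
# normal outcomes; the interaction coefficient SE from lm(), averaged over
# replicate trials so only the residual-variance estimate fluctuates
ipd_se_oracle <- function(n, p, reps = 60, seed = 1) {
  stopifnot(n %% 2 == 0, (n / 2 * p) %% 1 == 0)
  arm <- rep(0:1, each = n / 2)
  com_arm <- c(rep(1, n / 2 * p), rep(0, n / 2 * (1 - p)))
  set.seed(seed)
  mean(vapply(seq_len(reps), function(i) {
    com <- c(sample(com_arm), sample(com_arm))
    out <- stats::rnorm(n)
    fit <- stats::lm(out ~ arm * com)
    sqrt(stats::vcov(fit)["arm:com", "arm:com"])
  }, numeric(1)))
}
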