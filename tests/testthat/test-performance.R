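# minimal record builder for hand-computed cases
rec <- function(est, truth = 0, ci_low = est - 0.1, ci_high = est + 0.1,
                rep = seq_along(est), drug = "D1", model = "full") {
  data.frame(rep = rep, drug_code = drug, model = model, est = est,
             ci_low = ci_low, ci_high = ci_high, truth = truth,
             stringsAsFactors = FALSE)
}

test_that("bias, mse and rmse match hand arithmetic", {
  perfect <- rec(c(-0.1, -0.1, -0.1), truth = -0.1)
  expect_equal(measure_bias(perfect), list(estimate = 0, mcse = 0))
  expect_equal(measure_mse(perfect), list(estimate = 0, mcse = 0))
  expect_equal(measure_rmse(perfect), list(estimate = 0, mcse = 0))

  # errors +0.1 and -0.1
  r <- rec(c(0.1, -0.1))
  b <- measure_bias(r)
  expect_equal(b$estimate, 0)
  expect_equal(b$mcse, 0.1)

  # errors 0.1 and 0.3
  r2 <- rec(c(0.1, 0.3))
  expect_equal(measure_mse(r2)$estimate, 0.05)

  # delta-method MCSE for RMSE: mse 0.04, mcse_mse 0.004 -> rmse 0.2, 0.01
  errs <- c(sqrt(0.02), sqrt(0.06))  # mse 0.04
  r3 <- rec(errs)
  m <- measure_mse(r3)
  expect_equal(m$estimate, 0.04, tolerance = 1e-12)
  rm_ <- measure_rmse(r3)
  expect_equal(rm_$estimate, 0.2, tolerance = 1e-12)
  expect_equal(rm_$mcse, m$mcse / (2 * 0.2), tolerance = 1e-12)

  expect_error(measure_bias(rec(0.1)[0, ]), "at least")
})

test_that("measure identities hold exactly", {
  set.seed(77)
  r <- rec(rnorm(200, -0.1, 0.2), truth = rnorm(200, -0.1, 0.05))
  err <- r$est - r$truth
  N <- length(err)
  b <- measure_bias(r)$estimate
  m <- measure_mse(r)$estimate
  expect_equal(measure_rmse(r)$estimate^2, m, tolerance = 1e-12)
  expect_equal(m, b^2 + var(err) * (N - 1) / N, tolerance = 1e-12)
  cv <- measure_coverage(r)
  expect_equal(cv$mcse, sqrt(cv$estimate * (1 - cv$estimate) / N),
               tolerance = 1e-15)
})

test_that("coverage matches the binomial formula", {
  r <- rec(c(0, 0, 0, 0), truth = c(0.05, -0.05, 0.09, 0.2))
  cv <- measure_coverage(r)  # 3 of 4 intervals (+-0.1) cover
  expect_equal(cv$estimate, 0.75)
  expect_equal(cv$mcse, sqrt(0.75 * 0.25 / 4))
  expect_equal(cv$mcse, 0.2165, tolerance = 1e-3)

  all_in <- rec(c(0, 0), truth = c(0, 0))
  expect_equal(measure_coverage(all_in), list(estimate = 1, mcse = 0))
})

test_that("relative precision follows the empSE-squared ratio convention", {
  # empSE(single) = 0.2, empSE(full) = 0.1 -> 300%
  sgl <- rec(c(-0.2, 0, 0.2), model = "single")
  ful <- rec(c(-0.1, 0, 0.1), model = "full")
  rp <- relative_precision(sgl, ful)
  expect_equal(rp$estimate, 300)

  # self-comparison is exactly zero with zero jackknife spread
  self <- relative_precision(ful, ful)
  expect_equal(self$estimate, 0)
  expect_equal(self$mcse, 0)

  expect_error(relative_precision(sgl, rec(c(0.1, 0.1, 0.1))), "zero")
  expect_error(relative_precision(rec(c(1, 2), rep = 1:2),
                                  rec(c(1, 2), rep = 3:4)),
               "not paired")
})

test_that("jackknife MCSE approaches the analytic value for Gaussian pairs", {
  set.seed(123)
  N <- 10000
  sd_s <- 0.2; sd_f <- 0.1
  sgl <- rec(rnorm(N, 0, sd_s), model = "single")
  ful <- rec(rnorm(N, 0, sd_f), model = "full")
  rp <- relative_precision(sgl, ful)
  # independent variance ratio: Var[100((S_s/S_f)^2 - 1)]
  #   = 100^2 * r^2 * (2/(N-1) + 2/(N-1)),  r = (sd_s/sd_f)^2
  analytic <- 100 * (sd_s / sd_f)^2 * sqrt(4 / (N - 1))
  expect_lt(abs(rp$mcse / analytic - 1), 0.15)
})

test_that("detection classes partition paired replicates", {
  # full always detects, single never
  sgl <- rec(c(0, 0), truth = -0.2, ci_low = -0.3, ci_high = 0.3,
             model = "single")
  ful <- rec(c(-0.2, -0.2), truth = -0.2, ci_low = -0.3, ci_high = -0.1,
             model = "full")
  det <- detection_classes(sgl, ful)
  expect_equal(det$p_full_only, 1)
  expect_equal(det$p_both + det$p_single_only + det$p_full_only +
                 det$p_neither, 1, tolerance = 1e-12)

  # self-comparison: nothing is model-specific
  self <- detection_classes(ful, ful)
  expect_equal(self$p_single_only, 0)
  expect_equal(self$p_full_only, 0)

  # conditioning excludes small true effects
  mix_s <- rec(c(0, 0), truth = c(-0.2, -0.05), ci_low = -0.5,
               ci_high = 0.5, model = "single")
  mix_f <- rec(c(-0.2, -0.05), truth = c(-0.2, -0.05), ci_low = -0.4,
               ci_high = -0.01, model = "full")
  det2 <- detection_classes(mix_s, mix_f, truth_threshold = -0.10)
  expect_equal(det2$n_eligible, 1L)
  det3 <- detection_classes(mix_s, mix_f, condition = FALSE)
  expect_equal(det3$n_eligible, 2L)

  expect_error(detection_classes(mix_s[1, ], mix_f), "not paired")
})

test_that("performance_table assembles every scenario-model-measure cell", {
  set.seed(9)
  mk <- function(scen, model, sd) {
    r <- rec(rnorm(40, -0.1, sd), truth = rnorm(40, -0.1, 0.05),
             rep = rep(1:10, each = 4),
             drug = rep(c("D1", "D2", "D3", "D4"), 10), model = model)
    r$scenario <- scen
    r
  }
  records <- rbind(mk("s1", "single", 0.2), mk("s1", "full", 0.1),
                   mk("s2", "single", 0.3), mk("s2", "full", 0.15))
  tab <- performance_table(records)
  # per scenario: 4 measures x 2 models + relative precision (full only)
  expect_equal(nrow(tab), 2 * (4 * 2 + 1))
  expect_setequal(unique(tab$measure),
                  c("bias", "mse", "rmse", "coverage", "rel_precision"))
  expect_equal(sum(tab$measure == "rel_precision"), 2L)
  expect_true(all(tab$model[tab$measure == "rel_precision"] == "full"))
  # rmse^2 = mse cell by cell
  for (sc in c("s1", "s2")) for (md in c("single", "full")) {
    mse <- tab$estimate[tab$scenario == sc & tab$model == md &
                          tab$measure == "mse"]
    rmse <- tab$estimate[tab$scenario == sc & tab$model == md &
                           tab$measure == "rmse"]
    expect_equal(rmse^2, mse, tolerance = 1e-12)
  }
  # missing cells are named
  expect_error(performance_table(records[records$model == "full", ]),
               "missing cell.*single")

  # CSV round trip is lossless
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$estimate, tab$estimate, tolerance = 1e-12)
})

test_that("per-class relative precision splits by the ontology", {
  net <- toy_network()
  set.seed(41)
  reps <- rep(1:20, each = 3)
  drugs <- rep(c("A10BH01", "A10BH05", "A10BK01"), 20)
  sgl <- rec(rnorm(60, 0, 0.2), rep = reps, drug = drugs, model = "single")
  ful <- rec(rnorm(60, 0, 0.1), rep = reps, drug = drugs, model = "full")
  rpc <- relative_precision_by_class(sgl, ful, net)
  expect_equal(rpc$class_code, c("A10BH", "A10BK"))
  expect_true(all(is.finite(rpc$estimate)))
})
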