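test_that("conjugate oracle reduces to scalar shrinkage for one trial", {
  # one trial, collapsing the class levels: beta prior is effectively N(0, 4)
  y <- -0.1; s <- 0.158; tau <- 0.05
  or <- fit_conjugate_oracle(y, s, "D1", "C1",
                             fixed_scales = list(tau = tau, sigma = 0,
                                                 zeta = 0))
  w <- (1 / (s^2 + tau^2)) / (1 / (s^2 + tau^2) + 1 / 4)
  expect_equal(unname(or$mean["beta[D1]"]), y * w, tolerance = 1e-6)
  expect_equal(y * w, -0.0993, tolerance = 1e-3)
})

test_that("oracle with a flat location prior gives the inverse-variance mean", {
  set.seed(31)
  y <- rnorm(6, -0.1, 0.1)
  s <- runif(6, 0.05, 0.3)
  tau <- 0.1
  or <- fit_conjugate_oracle(
    y, s, rep("D1", 6), rep("C1", 6),
    fixed_scales = list(tau = tau, sigma = 0, zeta = 0),
    priors = prior_spec(location_prior_sd = 1e6))
  w <- 1 / (s^2 + tau^2)
  expect_equal(unname(or$mean["beta[D1]"]), sum(w * y) / sum(w),
               tolerance = 1e-6)
})

test_that("oracle posteriors respect the model's symmetries", {
  y <- c(-0.3, 0.1)
  fx <- list(tau = 0.05, sigma = 0.1, zeta = 0.1)
  or <- fit_conjugate_oracle(y, c(0.1, 0.1), c("D1", "D2"), c("C1", "C1"), fx)
  # negating the data negates every location posterior (priors are centred)
  neg <- fit_conjugate_oracle(-y, c(0.1, 0.1), c("D1", "D2"), c("C1", "C1"),
                              fx)
  expect_equal(unname(neg$mean), -unname(or$mean), tolerance = 1e-9)
  expect_equal(neg$summary$sd, or$summary$sd, tolerance = 1e-9)
  # swapping the two drugs' data swaps their posteriors
  or2 <- fit_conjugate_oracle(rev(y), c(0.1, 0.1), c("D1", "D2"),
                              c("C1", "C1"), fx)
  expect_equal(unname(or$mean["beta[D1]"]), unname(or2$mean["beta[D2]"]),
               tolerance = 1e-9)
  expect_equal(sort(or$summary$sd), sort(or2$summary$sd), tolerance = 1e-9)
})

test_that("fixed-scale sampler agrees with the conjugate oracle", {
  # smaller version of the decisive engine check (full sweep in acceptance)
  for (seed in c(2, 9)) {
    net <- random_small_network(seed)
    sc <- scenario_spec("t", 0.1, 0.1, 0.1)
    d <- simulate_dataset(net, sc, seed = seed + 100)
    fx <- list(tau = 0.1, sigma = 0.12, zeta = 0.08)
    fit <- fit_full(d, fix_scales = fx,
                    settings = inference_settings(chains = 2, iter = 20500,
                                                  burn = 500,
                                                  seed = seed + 200))
    or <- fit_conjugate_oracle(d$y, d$s, d$drug_code, d$class_code, fx)
    fb <- fit$summary[fit$summary$param == "beta", ]
    ob <- or$summary[or$summary$param == "beta", ]
    expect_equal(fb$unit, ob$unit)
    expect_lt(max(abs(fb$mean - ob$mean)), 0.005)
    expect_lt(max(abs(fb$sd / ob$sd - 1)), 0.02)
  }
})

test_that("with uninformative data the posteriors recover the priors", {
  net <- toy_network()
  d <- data.frame(y = rnorm(6, 0, 1), s = rep(1e6, 6),
                  drug_code = net$drug_code, class_code = net$class_code)
  fit <- fit_full(d, settings = inference_settings(seed = 5))
  a <- fit$summary[fit$summary$param == "alpha", ]
  expect_lt(abs(a$mean), 0.05 * 2)
  expect_lt(abs(a$sd / 2 - 1), 0.05)

  fs <- fit_single(data.frame(y = 0.3, s = 1e6, drug_code = "D1"),
                   settings = inference_settings(seed = 6))
  b <- fs$summary[fs$summary$param == "beta", ]
  expect_lt(abs(b$mean), 0.1)
  expect_lt(abs(b$sd / 2 - 1), 0.05)
})

test_that("single-drug fit is consistent under concordant data", {
  d <- data.frame(y = rep(-0.1, 200), s = rep(0.05, 200),
                  drug_code = "A10BH01")
  fit <- fit_single(d, settings = quick_settings(seed = 7))
  b <- fit$summary[fit$summary$param == "beta", ]
  expect_equal(b$mean, -0.1, tolerance = 0.005 / 0.1)
  # matches the inverse-variance weighted mean closely
  expect_lt(abs(b$mean - mean(d$y)), 0.005)
})

test_that("full-model estimates shrink extreme drugs toward the class mean", {
  net <- default_network()
  sc <- standard_scenarios()[["all-low"]]
  d <- simulate_dataset(net, sc, seed = 14)
  st <- quick_settings(seed = 15)
  ff <- fit_full(d, settings = st)
  singles <- lapply(attr(net, "drugs")$drug_code, function(dg)
    fit_single(d, drug = dg, settings = st))
  sgl_mean <- vapply(singles, function(f)
    f$summary$mean[f$summary$param == "beta"], numeric(1))
  names(sgl_mean) <- attr(net, "drugs")$drug_code

  gam <- ff$summary[ff$summary$param == "gamma", ]
  class_mean <- stats::setNames(gam$mean, gam$unit)
  cls <- stats::setNames(attr(net, "drugs")$class_code,
                         attr(net, "drugs")$drug_code)
  dev <- sgl_mean - class_mean[cls]
  extreme <- names(which.max(abs(dev)))
  fb <- ff$summary[ff$summary$param == "beta" & ff$summary$unit == extreme, ]
  lo <- min(sgl_mean[extreme], class_mean[cls[extreme]])
  hi <- max(sgl_mean[extreme], class_mean[cls[extreme]])
  expect_gte(fb$mean, lo)
  expect_lte(fb$mean, hi)
  # and the full model is at least as precise for that drug
  sgl_sd <- singles[[which(names(sgl_mean) == extreme)]]$summary$sd[1]
  expect_lt(fb$sd, sgl_sd * 1.05)
})

test_that("pooling responds monotonically to concordant evidence", {
  # adding concordant trials moves the drug posterior toward the data and
  # tightens it
  base <- data.frame(
    y = c(0.3, -0.12, -0.09, -0.11), s = c(0.2, 0.05, 0.05, 0.05),
    drug_code = c("A10BA01", "A10BA02", "A10BA02", "A10BA03"),
    class_code = "A10BA")
  st <- inference_settings(chains = 2, iter = 10500, burn = 500, seed = 21)
  f1 <- fit_full(base, settings = st)
  more <- rbind(base, data.frame(y = rep(0.3, 6), s = rep(0.1, 6),
                                 drug_code = "A10BA01",
                                 class_code = "A10BA"))
  f2 <- fit_full(more, settings = st)
  b1 <- f1$summary[f1$summary$param == "beta" & f1$summary$unit == "A10BA01", ]
  b2 <- f2$summary[f2$summary$param == "beta" & f2$summary$unit == "A10BA01", ]
  expect_gt(b2$mean, b1$mean)   # toward the concordant data at 0.3
  expect_lt(b2$sd, b1$sd)
})

test_that("posterior summaries are invariant to relabeling drugs and classes", {
  net <- toy_network()
  sc <- scenario_spec("t", 0.1, 0.1, 0.1)
  d <- simulate_dataset(net, sc, seed = 33)
  st <- inference_settings(chains = 2, iter = 5500, burn = 500, seed = 34)
  f1 <- fit_full(d, settings = st)
  relab <- as.data.frame(d)
  relab$drug_code <- chartr("15", "82", relab$drug_code)  # H01->H08 etc.
  f2 <- fit_full(relab, settings = st)
  b1 <- f1$summary[f1$summary$param == "beta", ]
  b2 <- f2$summary[f2$summary$param == "beta", ]
  m2 <- stats::setNames(b2$mean, b2$unit)
  expect_lt(max(abs(m2[chartr("15", "82", b1$unit)] - b1$mean)), 0.015)
})

test_that("convergence diagnostics separate healthy and stuck chains", {
  set.seed(50)
  iid <- matrix(rnorm(4000), ncol = 2)
  expect_lt(ontopool:::split_rhat(iid), 1.01)
  stuck <- cbind(rep(0, 2000) + rnorm(2000, 0, 1e-3),
                 rep(5, 2000) + rnorm(2000, 0, 1e-3))
  expect_gt(ontopool:::split_rhat(stuck), 2)

  net <- toy_network()
  d <- simulate_dataset(net, scenario_spec("t", 0.1, 0.1, 0.1), seed = 51)
  fit <- fit_full(d, settings = inference_settings(seed = 52))
  expect_true(fit$diagnostics$converged)
  expect_length(fit$diagnostics$flagged, 0L)
  # tightening thresholds beyond reason flags parameters, never errors
  harsh <- check_convergence(fit, rhat_max = 1.0000001, ess_min = 1e9)
  expect_false(harsh$converged)
  expect_gt(length(harsh$flagged), 0L)
})

test_that("fits reject non-positive standard errors", {
  d <- data.frame(y = c(-0.1, 0.2), s = c(0.1, 0),
                  drug_code = c("D1", "D1"), class_code = c("C1", "C1"))
  expect_error(fit_full(d), "s > 0")
  expect_error(fit_single(d), "s > 0")
  expect_error(fit_conjugate_oracle(d$y, d$s, d$drug_code, d$class_code,
                                    list(tau = 0.1, sigma = 0.1, zeta = 0.1)),
               "s > 0")
})
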