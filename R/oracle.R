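#' Exact conjugate posterior with fixed scale parameters
#'
#' With all scale parameters (`zeta`, `sigma_c`, `tau_d`) held fixed, the
#' hierarchical model is jointly Gaussian in its location parameters
#' (`alpha`, `gamma_c`, `beta_d`, `mu_z`), so the posterior is multivariate
#' normal and available exactly from one sparse precision-matrix solve.
#' This closed form is the independent oracle used to validate the Gibbs
#' sampler, and doubles as a fast approximate fitter when plausible scale
#' values are known.
#'
#' @param y,s numeric vectors of trial estimates and their SEs (`s > 0`).
#' @param drug_code,class_code character vectors aligned with `y` giving
#'   each trial's drug and class.
#' @param fixed_scales list with `tau` (scalar or named by drug), `sigma`
#'   (scalar or named by class) and `zeta`, all `>= 0`.
#' @param priors a [prior_spec()]; only `location_prior_sd` is used.
#' @return list with `mean` (named posterior mean vector over
#'   `alpha`, `gamma[.]`, `beta[.]`, `mu[.]`), `cov` (posterior covariance,
#'   same order), and `summary` (data frame `param`, `unit`, `mean`, `sd`).
#' @export
#' @examples
#' # one trial of one drug: scalar normal-normal shrinkage
#' or <- fit_conjugate_oracle(
#'   y = -0.1, s = 0.158, drug_code = "D1", class_code = "C1",
#'   fixed_scales = list(tau = 0.05, sigma = 1e-8, zeta = 1e-8)
#' )
#' or$summary
fit_conjugate_oracle <- function(y, s, drug_code, class_code,
                                 fixed_scales, priors = prior_spec()) {
  n <- length(y)
  stopifnot(length(s) == n, length(drug_code) == n, length(class_code) == n)
  if (any(s <= 0)) stop("every trial must have s > 0")

  drugs <- unique(data.frame(drug_code = as.character(drug_code),
                             class_code = as.character(class_code),
                             stringsAsFactors = FALSE))
  if (anyDuplicated(drugs$drug_code))
    stop("drug assigned to more than one class")
  drugs <- drugs[order(drugs$class_code, drugs$drug_code), , drop = FALSE]
  classes <- sort(unique(drugs$class_code))
  D <- nrow(drugs); C <- length(classes)

  tau <- rep_len(fixed_scales$tau, D)
  if (!is.null(names(fixed_scales$tau)))
    tau <- unname(fixed_scales$tau[drugs$drug_code])
  sigma <- rep_len(fixed_scales$sigma, C)
  if (!is.null(names(fixed_scales$sigma)))
    sigma <- unname(fixed_scales$sigma[classes])
  zeta <- fixed_scales$zeta
  stopifnot(all(tau >= 0), all(sigma >= 0), zeta >= 0)
  # exact zeros collapse a level; bound below so the precision matrix stays
  # well conditioned (an SD of 1e-4 adds variance 1e-8, negligible here)
  tau <- pmax(tau, 1e-4); sigma <- pmax(sigma, 1e-4)
  zeta <- max(zeta, 1e-4)

  d_of_z <- match(as.character(drug_code), drugs$drug_code)
  c_of_d <- match(drugs$class_code, classes)

  # parameter order: alpha, gamma[1..C], beta[1..D], mu[1..n]
  p <- 1L + C + D + n
  ia <- 1L; ig <- 1L + seq_len(C); ib <- 1L + C + seq_len(D)
  im <- 1L + C + D + seq_len(n)
  Q <- matrix(0, p, p)
  b <- numeric(p)

  Q[ia, ia] <- 1 / priors$location_prior_sd^2
  for (cc in seq_len(C)) {          # (gamma_c - alpha)^2 / zeta^2
    w <- 1 / zeta^2
    Q[ig[cc], ig[cc]] <- Q[ig[cc], ig[cc]] + w
    Q[ia, ia] <- Q[ia, ia] + w
    Q[ig[cc], ia] <- Q[ig[cc], ia] - w
    Q[ia, ig[cc]] <- Q[ia, ig[cc]] - w
  }
  for (d in seq_len(D)) {           # (beta_d - gamma_c)^2 / sigma_c^2
    g <- ig[c_of_d[d]]
    w <- 1 / sigma[c_of_d[d]]^2
    Q[ib[d], ib[d]] <- Q[ib[d], ib[d]] + w
    Q[g, g] <- Q[g, g] + w
    Q[ib[d], g] <- Q[ib[d], g] - w
    Q[g, ib[d]] <- Q[g, ib[d]] - w
  }
  for (z in seq_len(n)) {           # (mu_z - beta_d)^2/tau_d^2 + data term
    bd <- ib[d_of_z[z]]
    w <- 1 / tau[d_of_z[z]]^2
    Q[im[z], im[z]] <- Q[im[z], im[z]] + w + 1 / s[z]^2
    Q[bd, bd] <- Q[bd, bd] + w
    Q[im[z], bd] <- Q[im[z], bd] - w
    Q[bd, im[z]] <- Q[bd, im[z]] - w
    b[im[z]] <- y[z] / s[z]^2
  }

  R <- tryCatch(chol(Q), error = function(e)
    stop("singular precision matrix (should be impossible for s > 0 ",
         "and a proper location prior)"))
  mean_vec <- drop(backsolve(R, backsolve(R, b, transpose = TRUE)))
  cov_mat <- chol2inv(R)
  nms <- c("alpha", paste0("gamma[", classes, "]"),
           paste0("beta[", drugs$drug_code, "]"),
           paste0("mu[", seq_len(n), "]"))
  names(mean_vec) <- nms
  dimnames(cov_mat) <- list(nms, nms)
  summary <- data.frame(
    param = c("alpha", rep("gamma", C), rep("beta", D), rep("mu", n)),
    unit = c("", classes, drugs$drug_code, as.character(seq_len(n))),
    mean = mean_vec, sd = sqrt(diag(cov_mat)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(mean = mean_vec, cov = cov_mat, summary = summary,
       drugs = drugs, classes = classes)
}
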