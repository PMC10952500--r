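# Forward simulation of index event bias in a case-only survival study.
#
# Disease incidence follows a logistic model with a genotype G and a latent
# standard-normal confounder U; survival among ascertained cases follows a
# Weibull proportional-hazards model driven by U alone. G has no true effect
# on survival, so the Cox log hazard ratio of G estimated among cases equals
# the index event bias induced by conditioning on disease.

#' Simulation configuration
#'
#' Bundles all parameters of the case-ascertained survival simulation. The
#' defaults describe a rare-disease scenario modelled on idiopathic pulmonary
#' fibrosis and its strongest risk variant: a SNP with minor allele frequency
#' 0.11 and odds ratio 5 on disease, population prevalence 0.05\%, 2 million
#' simulated individuals (about 1000 cases on average), and Weibull survival
#' with scale \eqn{\lambda = e^{-12.5}} and shape \eqn{\rho = 1.7}
#' approximating observed IPF survival times.
#'
#' @param n_individuals population size per replicate.
#' @param maf minor allele frequency in (0, 0.5].
#' @param beta_gx genotype log odds ratio on disease.
#' @param beta_ux confounder log odds ratio on disease (>= 0); varied over a
#'   grid to induce different amounts of collider bias.
#' @param target_prevalence mean disease risk the intercept is solved for.
#' @param weibull_lambda,weibull_rho Weibull baseline scale and shape.
#' @param n_reps number of simulation replicates.
#' @param observed_log_hr observed case-only log hazard ratio whose implied
#'   true value is back-calculated (default `log(0.766)`).
#' @param seed master seed; replicate seeds are derived from it.
#' @param censor_time optional administrative censoring time; `NULL` (the
#'   default) disables censoring.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2e6, maf = 0.11, beta_gx = log(5),
                       beta_ux = 0, target_prevalence = 5e-4,
                       weibull_lambda = exp(-12.5), weibull_rho = 1.7,
                       n_reps = 1000, observed_log_hr = log(0.766),
                       seed = 1L, censor_time = NULL) {
  stopifnot(n_individuals >= 1, maf > 0, maf <= 0.5, beta_ux >= 0,
            target_prevalence > 0, target_prevalence < 0.5,
            weibull_lambda > 0, weibull_rho > 0, n_reps >= 1)
  structure(list(n_individuals = as.integer(n_individuals), maf = maf,
                 beta_gx = beta_gx, beta_ux = beta_ux,
                 target_prevalence = target_prevalence,
                 weibull_lambda = weibull_lambda, weibull_rho = weibull_rho,
                 n_reps = as.integer(n_reps),
                 observed_log_hr = observed_log_hr,
                 seed = as.integer(seed), censor_time = censor_time),
            class = "sim_config")
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Additive allele counts in \{0, 1, 2\} with class probabilities
#' \eqn{((1-f)^2, 2f(1-f), f^2)}, i.e. Binomial(2, f).
#'
#' @param n number of individuals.
#' @param maf minor allele frequency in (0, 0.5].
#' @return integer vector of allele counts.
#' @export
simulate_genotypes <- function(n, maf) {
  stopifnot(n >= 1)
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  rbinom(n, 2L, maf)
}

# Gauss-Hermite nodes/weights, cached per node count. Transformed so that
# E[f(U)] for U ~ N(0,1) is sum(w * f(x)).
gh_cache <- new.env(parent = emptyenv())
gauss_hermite_normal <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(gh_cache[[key]])) {
    gh <- pracma::gaussHermite(nodes)
    gh_cache[[key]] <- list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
  }
  gh_cache[[key]]
}

#' Population mean disease risk under the logistic incidence model
#'
#' Evaluates \eqn{E[p] = \sum_g P(g)\, E_U[\mathrm{expit}(\beta_0 +
#' \beta_{GX} g + \beta_{UX} U)]} exactly over the three genotype classes and
#' by Gauss-Hermite quadrature over the standard-normal confounder. With 201
#' nodes the quadrature remains accurate out to `beta_ux = 20`, where almost
#' all incidence comes from the far upper tail of U.
#'
#' @param beta0 logistic intercept.
#' @param config a [sim_config()].
#' @param nodes number of quadrature nodes (default 201).
#' @return scalar mean risk.
#' @export
expected_prevalence <- function(beta0, config, nodes = 201L) {
  gh <- gauss_hermite_normal(nodes)
  f <- config$maf
  pg <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  total <- 0
  for (g in 0:2) {
    total <- total + pg[g + 1L] *
      sum(gh$w * plogis(beta0 + config$beta_gx * g + config$beta_ux * gh$x))
  }
  total
}

#' Solve the logistic intercept for a target prevalence
#'
#' Finds \eqn{\beta_0} such that the population mean disease risk equals
#' `config$target_prevalence`, by bisection on the monotone map
#' \eqn{\beta_0 \mapsto E[p]} with the expectation evaluated by
#' [expected_prevalence()]. Convergence requires the achieved mean risk to
#' match the target to a relative tolerance of `tol`.
#'
#' @param config a [sim_config()].
#' @param nodes quadrature nodes passed to [expected_prevalence()].
#' @param tol relative tolerance on the achieved prevalence (default 1e-8).
#' @param max_iter maximum bisection iterations.
#' @return scalar \eqn{\beta_0}.
#' @export
#' @examples
#' cfg <- sim_config(beta_gx = 0, beta_ux = 0)
#' solve_beta0(cfg)          # equals qlogis(0.0005)
solve_beta0 <- function(config, nodes = 201L, tol = 1e-8, max_iter = 300L) {
  target <- config$target_prevalence
  lo <- -2000; hi <- 0
  f_lo <- expected_prevalence(lo, config, nodes) - target
  f_hi <- expected_prevalence(hi, config, nodes) - target
  if (f_lo > 0 || f_hi < 0)
    stop("target prevalence not bracketed by beta0 in [", lo, ", ", hi, "]")
  mid <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- expected_prevalence(mid, config, nodes) - target
    if (abs(f_mid) <= tol * target) return(mid)
    if (f_mid < 0) lo <- mid else hi <- mid
  }
  stop("solve_beta0 did not converge after ", max_iter,
       " iterations; last bracket [", lo, ", ", hi, "]")
}

#' Simulate a population and ascertain disease cases
#'
#' Draws genotypes under HWE and a standard-normal confounder U, computes
#' each individual's disease probability
#' \eqn{\mathrm{expit}(\beta_0 + \beta_{GX} G + \beta_{UX} U)}, draws disease
#' indicators, and returns genotype and confounder restricted to cases (the
#' ascertained study sample).
#'
#' @param config a [sim_config()].
#' @param beta0 intercept from [solve_beta0()].
#' @return list with `g` (case genotypes), `u` (case confounder values) and
#'   `n_cases`.
#' @export
simulate_cohort <- function(config, beta0) {
  n <- config$n_individuals
  g <- simulate_genotypes(n, config$maf)
  u <- rnorm(n)
  p <- plogis(beta0 + config$beta_gx * g + config$beta_ux * u)
  case <- rbinom(n, 1L, p) == 1L
  list(g = g[case], u = u[case], n_cases = sum(case))
}

#' Simulate Weibull survival times by the inverse-probability method
#'
#' Generates event times under a proportional-hazards model with Weibull
#' baseline hazard \eqn{\lambda \rho t^{\rho-1}} and linear predictor U:
#' \deqn{t_i = \left(\frac{-\log v_i}{\lambda e^{U_i}}\right)^{1/\rho},
#'       \quad v_i \sim \mathrm{Unif}(0, 1).}
#' Times are uncensored and strictly positive, and are decreasing in U at
#' fixed v (higher hazard, shorter survival).
#'
#' @param u linear-predictor values (the confounder for ascertained cases).
#' @param lambda,rho Weibull scale and shape (> 0).
#' @param v optional uniform draws, supplied for reproducibility tests;
#'   drawn internally when `NULL`.
#' @return vector of survival times.
#' @export
simulate_survival <- function(u, lambda, rho, v = NULL) {
  stopifnot(lambda > 0, rho > 0)
  if (is.null(v)) v <- runif(length(u))
  ((-log(v)) / (lambda * exp(u)))^(1 / rho)
}

#' Cox log hazard ratio of a single covariate
#'
#' Fits a Cox proportional-hazards model with one predictor on fully observed
#' (uncensored) event times, using Breslow tie handling (continuous simulated
#' times make ties improbable).
#'
#' @param times event times.
#' @param covariate the single predictor (e.g. genotype).
#' @param status optional event indicator; defaults to all events.
#' @return named vector `c(loghr, se)`.
#' @export
fit_cox_loghr <- function(times, covariate, status = NULL) {
  if (length(unique(covariate)) < 2L)
    stop("covariate is constant; log hazard ratio undefined")
  if (length(unique(times)) < 2L) stop("need at least 2 distinct event times")
  if (is.null(status)) status <- rep(1L, length(times))
  fit <- survival::coxph(survival::Surv(times, status) ~ covariate,
                         ties = "breslow")
  c(loghr = unname(coef(fit)[1L]), se = sqrt(unname(fit$var[1L, 1L])))
}

# one simulation replicate: ascertain cases, generate their survival, fit Cox
# on genotype. Returns c(bias_hat, n_cases); bias_hat is NA when the replicate
# cannot be analysed (no cases, constant genotype, Cox failure).
run_replicate <- function(config, beta0, rep_seed) {
  set.seed(rep_seed)
  cohort <- simulate_cohort(config, beta0)
  if (cohort$n_cases < 2L) return(c(NA_real_, cohort$n_cases))
  t <- simulate_survival(cohort$u, config$weibull_lambda, config$weibull_rho)
  status <- rep(1L, cohort$n_cases)
  if (!is.null(config$censor_time)) {
    status <- as.integer(t <= config$censor_time)
    t <- pmin(t, config$censor_time)
    if (sum(status) < 2L) return(c(NA_real_, cohort$n_cases))
  }
  bias <- tryCatch(fit_cox_loghr(t, cohort$g, status)[["loghr"]],
                   error = function(e) NA_real_)
  c(bias, cohort$n_cases)
}

#' Run the bias simulation over a grid of confounder effects
#'
#' For each confounder effect `beta_ux` in the grid: solve the logistic
#' intercept for the target prevalence, run `n_reps` independent replicates
#' (each simulating the population, ascertaining cases, generating their
#' Weibull survival and fitting a Cox model of survival on genotype), average
#' the per-replicate log hazard ratios into the mean index event bias, and
#' back-calculate the true log hazard ratio that would produce the observed
#' one: `true_log_hr = observed_log_hr - mean_bias`.
#'
#' Replicate seeds are derived from `config$seed`, so a given (config, grid)
#' is bit-reproducible and each grid cell is independently reproducible.
#'
#' @param config a [sim_config()]; its `beta_ux` entry is overridden by the
#'   grid.
#' @param beta_ux_grid vector of confounder log odds ratios (default
#'   `seq(0, 20, by = 2)`).
#' @return data.frame with one row per grid point: `beta_ux`, `beta0`,
#'   `mean_bias`, `mc_se_bias`, `true_log_hr`, `true_hr`, `mean_n_cases`,
#'   `n_reps_used`, `reliable` (FALSE when more than 10\% of replicates
#'   failed).
#' @export
run_grid <- function(config, beta_ux_grid = seq(0, 20, by = 2)) {
  stopifnot(inherits(config, "sim_config"), length(beta_ux_grid) >= 1)
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max,
                             length(beta_ux_grid) * config$n_reps),
                  nrow = length(beta_ux_grid))
  rows <- lapply(seq_along(beta_ux_grid), function(i) {
    cfg <- config
    cfg$beta_ux <- beta_ux_grid[i]
    beta0 <- solve_beta0(cfg)
    res <- vapply(seq_len(cfg$n_reps),
                  function(r) run_replicate(cfg, beta0, seeds[i, r]),
                  numeric(2))
    bias <- res[1L, ]
    ok <- is.finite(bias)
    if (!any(ok)) stop("all replicates failed at beta_ux = ", cfg$beta_ux)
    n_failed <- sum(!ok)
    if (n_failed > 0L)
      ib_log(n_failed, " of ", cfg$n_reps, " replicates failed at beta_ux = ",
             cfg$beta_ux)
    mean_bias <- mean(bias[ok])
    data.frame(beta_ux = cfg$beta_ux,
               beta0 = beta0,
               mean_bias = mean_bias,
               mc_se_bias = sd(bias[ok]) / sqrt(sum(ok)),
               true_log_hr = cfg$observed_log_hr - mean_bias,
               true_hr = exp(cfg$observed_log_hr - mean_bias),
               mean_n_cases = mean(res[2L, ]),
               n_reps_used = sum(ok),
               reliable = n_failed <= 0.1 * cfg$n_reps)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
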