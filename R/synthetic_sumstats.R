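# Synthetic two-trait summary statistics with a known bias slope, for
# parameter-recovery studies of the slope estimators.

#' Configuration for the synthetic summary-statistics generator
#'
#' Describes the generative model: per-SNP true risk effects
#' \eqn{\beta_{GX,j} \sim N(0, \tau_{gx}^2)}; direct (pleiotropic) survival
#' effects drawn point-normal — nonzero with probability `prop_direct`, then
#' \eqn{N(0, \tau_{gy}^2)} — independent of the risk effects; observed
#' estimates add sampling noise at per-SNP standard errors drawn uniformly
#' from the stated ranges, with the observed survival effect carrying the
#' bias term: \eqn{\hat\beta_{GY',j} = b\,\beta_{GX,j} + \beta_{GY,j} +
#' N(0, se_{gy,j}^2)}.
#'
#' The default panel size of 140,092 SNPs matches the scale of an
#' LD-pruned, high-imputation-quality panel from a real GWAS; tests use
#' smaller panels.
#'
#' @param n_snps number of SNPs (>= 100 recommended for recovery studies).
#' @param b_true true bias slope.
#' @param tau_gx SD of true risk effects (> 0).
#' @param prop_direct fraction of SNPs with direct survival effects in
#'   \[0, 1\].
#' @param tau_gy SD of direct survival effects (>= 0).
#' @param se_gx_range,se_gy_range `c(low, high)` ranges for per-SNP standard
#'   errors (low may be 0 for noiseless risk effects).
#' @param seed RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_snps = 140092L, b_true = -0.025, tau_gx = 0.1,
                         prop_direct = 0, tau_gy = 0.05,
                         se_gx_range = c(0.05, 0.15),
                         se_gy_range = c(0.1, 0.2), seed = 1L) {
  stopifnot(n_snps >= 3, tau_gx > 0, prop_direct >= 0, prop_direct <= 1,
            tau_gy >= 0,
            length(se_gx_range) == 2, se_gx_range[1] >= 0,
            se_gx_range[1] <= se_gx_range[2],
            length(se_gy_range) == 2, se_gy_range[1] > 0,
            se_gy_range[1] <= se_gy_range[2])
  structure(list(n_snps = as.integer(n_snps), b_true = b_true,
                 tau_gx = tau_gx, prop_direct = prop_direct, tau_gy = tau_gy,
                 se_gx_range = se_gx_range, se_gy_range = se_gy_range,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# ordered non-palindromic allele pairs, so harmonization keeps every SNP
NONPALINDROMIC_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                                 "G","A", "G","T", "T","C", "T","G"),
                               ncol = 2, byrow = TRUE)

#' Generate synthetic two-trait GWAS summary statistics
#'
#' Draws a panel of independent SNPs from the model in [synth_config()] and
#' returns both the harmonized pairs ready for the slope estimators and the
#' two summary-statistics tables (risk and survival) for round-trip I/O, plus
#' the generation truth for assertions. The truth is never consumed by any
#' estimator.
#'
#' @param config a [synth_config()].
#' @return list with elements `pairs` (data.frame as from [harmonize()]),
#'   `risk` and `survival` (data.frames as from [read_sumstats()]), and
#'   `truth` (list with `b_true`, `beta_gx_true`, `beta_gy_direct`).
#' @export
#' @examples
#' gen <- generate_sumstats(synth_config(n_snps = 500, seed = 42))
#' fit_slope_wls(gen$pairs)$b
generate_sumstats <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_snps

  beta_gx_true <- rnorm(n, 0, config$tau_gx)
  direct <- rbinom(n, 1L, config$prop_direct) * rnorm(n, 0, config$tau_gy)
  se_gx <- runif(n, config$se_gx_range[1], config$se_gx_range[2])
  se_gy <- runif(n, config$se_gy_range[1], config$se_gy_range[2])
  beta_gx_hat <- beta_gx_true + rnorm(n, 0, 1) * se_gx
  beta_gy_hat <- config$b_true * beta_gx_true + direct + rnorm(n, 0, 1) * se_gy

  alleles <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), n,
                                             replace = TRUE), , drop = FALSE]
  snp_id <- sprintf("rs%07d", seq_len(n))
  # se_gx may be 0 (noiseless risk effects); floor the file SE at a tiny
  # positive value so records satisfy se > 0 while pairs keep the exact 0
  se_gx_file <- pmax(se_gx, .Machine$double.xmin)

  risk <- data.frame(snp_id = snp_id, chrom = "1", pos = seq_len(n),
                     effect_allele = alleles[, 1], other_allele = alleles[, 2],
                     beta = beta_gx_hat, se = se_gx_file,
                     pvalue = pmax(2 * pnorm(-abs(beta_gx_hat / se_gx_file)),
                                   .Machine$double.xmin),
                     info = 1, n_studies = 5L,
                     eaf = runif(n, 0.05, 0.5),
                     stringsAsFactors = FALSE)
  survival <- data.frame(snp_id = snp_id, chrom = "1", pos = seq_len(n),
                         effect_allele = alleles[, 1],
                         other_allele = alleles[, 2],
                         beta = beta_gy_hat, se = se_gy,
                         pvalue = pmax(2 * pnorm(-abs(beta_gy_hat / se_gy)),
                                       .Machine$double.xmin),
                         stringsAsFactors = FALSE)
  pairs <- data.frame(snp_id = snp_id, beta_gx = beta_gx_hat, se_gx = se_gx,
                      beta_gy = beta_gy_hat, se_gy = se_gy, flipped = FALSE,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, risk = risk, survival = survival,
       truth = list(b_true = config$b_true, beta_gx_true = beta_gx_true,
                    beta_gy_direct = direct))
}
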