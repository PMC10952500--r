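# Shared fixtures: tiny summary-statistics tables built in code.

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# three well-formed SNPs, GWAS-catalog-ish header
fixture_risk_lines <- c(
  "snp_id\tchrom\tpos\teffect_allele\tother_allele\tbeta\tse\tpvalue\tinfo\tn_studies",
  "rs1\t1\t100\tA\tG\t0.20\t0.05\t1e-4\t0.999\t5",
  "rs2\t1\t200\tC\tT\t-0.10\t0.04\t0.01\t0.995\t4",
  "rs3\t2\t300\tG\tA\t0.05\t0.06\t0.40\t0.98\t3"
)

fixture_surv_lines <- c(
  "snp_id\tchrom\tpos\teffect_allele\tother_allele\tbeta\tse",
  "rs1\t1\t100\tA\tG\t-0.10\t0.10",
  "rs2\t1\t200\tT\tC\t0.08\t0.12",   # swapped alleles: beta must be negated
  "rs3\t2\t300\tG\tA\t0.02\t0.15"
)

# harmonized pairs with exact values for hand-arithmetic oracles
make_pairs <- function(beta_gx, beta_gy, se_gx = 0.01, se_gy = 0.1) {
  data.frame(snp_id = sprintf("rs%d", seq_along(beta_gx)),
             beta_gx = beta_gx, se_gx = se_gx,
             beta_gy = beta_gy, se_gy = se_gy,
             flipped = FALSE, stringsAsFactors = FALSE)
}

# brute-force weighted normal equations, independent of lm()
brute_force_slope <- function(x, y, w = rep(1, length(x)), intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  unname(beta[nrow(beta), 1])
}
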