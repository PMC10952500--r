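test_that("well-formed files parse to one record per row with standardized columns", {
  path <- write_tsv_fixture(fixture_risk_lines)
  rec <- read_sumstats(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(rec$beta, c(0.20, -0.10, 0.05))
  expect_equal(rec$se, c(0.05, 0.04, 0.06))
  expect_equal(rec$info, c(0.999, 0.995, 0.98))
  expect_equal(attr(rec, "n_dropped"), 0)

  # gzip transparency: same content, same records
  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "w"); writeLines(fixture_risk_lines, con); close(con)
  expect_equal(read_sumstats(gz)$beta, rec$beta)
})

test_that("rows with unparseable numerics are dropped with a count", {
  path <- write_tsv_fixture(c(fixture_risk_lines,
                              "rs4\t2\t400\tA\tC\t0.1\tNA\t0.5\t1\t5",
                              "rs5\t2\t500\tA\tC\tnot_a_number\t0.1\t0.5\t1\t5"))
  expect_message(rec <- read_sumstats(path), "dropped 2")
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "n_dropped"), 2)
})

test_that("missing required column is a fatal error naming the column", {
  lines <- c("snp_id\teffect_allele\tother_allele\tbeta",
             "rs1\tA\tG\t0.2")
  expect_error(read_sumstats(write_tsv_fixture(lines)), "'se'")
  expect_error(read_sumstats(write_tsv_fixture(character(0))), "empty")
})

test_that("column_map overrides header matching", {
  lines <- c("marker\tA1\tA2\teffect_size\tstderr",
             "rs1\tA\tG\t0.2\t0.05",
             "rs2\tC\tT\t-0.1\t0.04",
             "rs9\tG\tA\t0.0\t0.03")
  rec <- read_sumstats(write_tsv_fixture(lines),
                       column_map = c(snp_id = "marker", beta = "effect_size"))
  expect_equal(rec$snp_id, c("rs1", "rs2", "rs9"))
  expect_equal(rec$beta, c(0.2, -0.1, 0))
})

test_that("duplicated snp_id keeps the smallest-se record, ties by file order", {
  lines <- c("snp_id\teffect_allele\tother_allele\tbeta\tse",
             "rs1\tA\tG\t0.10\t0.08",
             "rs1\tA\tG\t0.20\t0.05",
             "rs2\tC\tT\t0.30\t0.04",
             "rs2\tC\tT\t0.40\t0.04")
  expect_message(rec <- read_sumstats(write_tsv_fixture(lines)), "duplicated")
  expect_equal(rec$beta[rec$snp_id == "rs1"], 0.20)  # smaller se wins
  expect_equal(rec$beta[rec$snp_id == "rs2"], 0.30)  # tie: first in file
})

test_that("harmonize aligns effects to the risk file's effect allele", {
  risk <- suppressMessages(read_sumstats(write_tsv_fixture(fixture_risk_lines)))
  surv <- suppressMessages(read_sumstats(write_tsv_fixture(fixture_surv_lines)))
  pairs <- harmonize(risk, surv)
  expect_equal(pairs$snp_id, c("rs1", "rs2", "rs3"))
  # same alleles: sign kept
  expect_equal(pairs$beta_gy[1], -0.10)
  expect_false(pairs$flipped[1])
  # swapped effect/other alleles: survival beta negated
  expect_equal(pairs$beta_gy[2], -0.08)
  expect_true(pairs$flipped[2])
  expect_equal(pairs$beta_gx, risk$beta)
})

test_that("strand-complement alleles reconcile; irreconcilable and palindromic drop", {
  risk <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                     effect_allele = c("A", "A", "A", "A"),
                     other_allele  = c("G", "G", "C", "T"),
                     beta = c(0.2, 0.2, 0.2, 0.2), se = 0.05,
                     stringsAsFactors = FALSE)
  surv <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                     # rs1: complement same (T/C ~ A/G); rs2: complement
                     # swapped (C/T ~ reversed A/G); rs3: irreconcilable;
                     # rs4: palindromic A/T
                     effect_allele = c("T", "C", "A", "A"),
                     other_allele  = c("C", "T", "G", "T"),
                     beta = c(-0.1, -0.1, -0.1, -0.1), se = 0.1,
                     stringsAsFactors = FALSE)
  pairs <- suppressMessages(harmonize(risk, surv))
  expect_equal(pairs$snp_id, c("rs1", "rs2"))
  expect_equal(pairs$beta_gy, c(-0.1, 0.1))
  expect_equal(pairs$flipped, c(FALSE, TRUE))
  expect_equal(attr(pairs, "n_dropped"), 2)
  # palindromic SNPs retained on request
  kept <- suppressMessages(harmonize(risk, surv, drop_palindromic = FALSE))
  expect_true("rs4" %in% kept$snp_id)
  # empty intersection is fatal
  surv2 <- surv; surv2$snp_id <- paste0("x", surv2$snp_id)
  expect_error(harmonize(risk, surv2), "shared")
})

test_that("harmonize is idempotent and equivariant to survival allele coding", {
  risk <- suppressMessages(read_sumstats(write_tsv_fixture(fixture_risk_lines)))
  surv <- suppressMessages(read_sumstats(write_tsv_fixture(fixture_surv_lines)))
  pairs <- harmonize(risk, surv)

  # idempotence: re-harmonizing aligned inputs changes nothing
  surv_aligned <- surv
  surv_aligned$effect_allele <- risk$effect_allele
  surv_aligned$other_allele <- risk$other_allele
  surv_aligned$beta <- pairs$beta_gy
  again <- harmonize(risk, surv_aligned)
  expect_equal(again$beta_gy, pairs$beta_gy)
  expect_equal(again$beta_gx, pairs$beta_gx)
  expect_false(any(again$flipped))

  # allele-coding equivariance: swapping the survival file's alleles and
  # negating its beta leaves the harmonized pair invariant
  surv_flip <- surv
  surv_flip$effect_allele <- surv$other_allele
  surv_flip$other_allele <- surv$effect_allele
  surv_flip$beta <- -surv$beta
  flipped <- harmonize(risk, surv_flip)
  expect_equal(flipped$beta_gy, pairs$beta_gy)
  expect_equal(flipped$beta_gx, pairs$beta_gx)
})

test_that("filter_snps applies info, study-count and keep-list rules", {
  n <- 5
  pairs <- make_pairs(beta_gx = seq(0.1, 0.5, by = 0.1),
                      beta_gy = rep(0, n))
  records <- data.frame(snp_id = pairs$snp_id,
                        info = c(1.0, 0.995, 0.99, 0.98, NA),
                        n_studies = c(5, 4, 3, 5, 5),
                        stringsAsFactors = FALSE)
  # info rule: {1.0, 0.995, 0.99} pass, 0.98 fails, missing passes -> 4
  out <- suppressWarnings(filter_snps(pairs, records, min_info = 0.99))
  expect_equal(nrow(out), 4)
  expect_false("rs4" %in% out$snp_id)
  # study-count rule: {5,4} pass among first three, plus rs4/rs5 -> 4; on the
  # three-SNP subset {5,4,3} exactly 2 pass
  sub <- filter_snps(pairs[1:3, ], records, min_studies = 4)
  expect_equal(nrow(sub), 2)
  # vacuous filter returns input unchanged
  expect_equal(filter_snps(pairs, records), pairs)
  # keep-list stands in for the LD-pruned panel
  out2 <- filter_snps(pairs, records, keep_list = c("rs1", "rs3"))
  expect_equal(out2$snp_id, c("rs1", "rs3"))
})

test_that("filters yield subsets and compose commutatively", {
  set.seed(41)
  n <- 50
  pairs <- make_pairs(rnorm(n), rnorm(n))
  records <- data.frame(snp_id = pairs$snp_id,
                        info = runif(n, 0.9, 1),
                        n_studies = sample(1:6, n, replace = TRUE),
                        stringsAsFactors = FALSE)
  a <- filter_snps(filter_snps(pairs, records, min_info = 0.99),
                   records, min_studies = 4)
  b <- filter_snps(filter_snps(pairs, records, min_studies = 4),
                   records, min_info = 0.99)
  both <- filter_snps(pairs, records, min_info = 0.99, min_studies = 4)
  expect_equal(a, b)
  expect_equal(a, both)
  expect_true(all(a$snp_id %in% pairs$snp_id))
})

test_that("pairs survive a write/read round trip exactly", {
  set.seed(7)
  pairs <- make_pairs(rnorm(20), rnorm(20), se_gx = runif(20, 0.01, 0.2),
                      se_gy = runif(20, 0.05, 0.3))
  path <- tempfile(fileext = ".tsv")
  write_pairs(pairs, path)
  back <- read_pairs(path)
  expect_equal(back, pairs, tolerance = 0)
})
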