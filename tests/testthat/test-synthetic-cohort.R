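test_that("genotype panel respects frequency targets, bounds and phasing", {
  panel <- simulate_genotypes(10000, list(list(n_snps = 1, r2 = 0, freq = 0.5)),
                              seed = 1)
  # binomial bound: 6 sd of a Bernoulli(0.5) mean over 2n draws
  expect_gte(panel$snps$alt_freq, 0.48)
  expect_lte(panel$snps$alt_freq, 0.52)

  panel <- simulate_genotypes(200,
    list(list(n_snps = 5, r2 = 0.6, freq = c(0.2, 0.4)),
         list(n_snps = 3, r2 = 0, freq = 0.3)), seed = 2)
  expect_true(all(panel$dosages >= 0 & panel$dosages <= 2))
  expect_equal(unname(colMeans(panel$dosages) / 2), panel$snps$alt_freq)
  # positions strictly increasing within chromosome
  expect_true(all(diff(panel$snps$pos) > 0))
  # dosage = sum of the sample's two haplotypes
  n <- length(panel$sample_ids)
  h1 <- panel$haplotypes[seq(1, 2 * n, 2), ]
  h2 <- panel$haplotypes[seq(2, 2 * n, 2), ]
  expect_equal(unname(panel$dosages), unname(h1 + h2))
})

test_that("r2 = 1 blocks are perfect copies and generation is deterministic", {
  panel <- simulate_genotypes(100, list(list(n_snps = 6, r2 = 1, freq = 0.3)),
                              seed = 3)
  expect_true(all(panel$dosages == panel$dosages[, 1]))

  a <- simulate_genotypes(50, list(list(n_snps = 4, r2 = 0.5, freq = c(0.1, 0.5))),
                          seed = 9)
  b <- simulate_genotypes(50, list(list(n_snps = 4, r2 = 0.5, freq = c(0.1, 0.5))),
                          seed = 9)
  expect_identical(a, b)
})

test_that("within-block LD hits the target and decays across distance", {
  panel <- simulate_genotypes(5000, list(list(n_snps = 10, r2 = 0.64, freq = 0.4)),
                              seed = 4)
  r2 <- ld_r2(panel, panel$snps$snp_id)
  adj <- r2[cbind(1:9, 2:10)]
  expect_equal(mean(adj), 0.64, tolerance = 0.08)
  expect_lt(mean(r2[cbind(1:5, 6:10)]), mean(adj))
})

test_that("argument errors are raised", {
  expect_error(simulate_genotypes(1, list(list(n_snps = 2, r2 = 0, freq = 0.5)),
                                  seed = 1), "n_samples")
  expect_error(simulate_genotypes(10, list(list(n_snps = 2, r2 = 0, freq = 1.2)),
                                  seed = 1), "frequencies")
  expect_error(
    effect_plan(data.frame(snp_id = "s", metabolite = "m", matrix = "both",
                           beta = 1),
                metabolites = "m", h2_targets = c(m = 1)),
    "heritability targets")
})

test_that("null metabolome is uncorrelated with genotypes", {
  panel <- simulate_genotypes(1000,
    lapply(1:100, function(b) list(n_snps = 10, r2 = 0.3, freq = c(0.1, 0.5))),
    seed = 5)
  covariates <- simulate_covariates(panel$sample_ids, 6)
  plan <- effect_plan(data.frame(snp_id = character(), metabolite = character(),
                                 matrix = character(), beta = numeric()),
                      metabolites = "m1", missing_rate = 0,
                      covariate_betas = c(age = 0))
  sim <- simulate_metabolomes(panel, plan, covariates, seed = 7)
  y <- log2(sim$plasma$values[, "m1"])
  r <- abs(cor(panel$dosages, y))
  expect_lt(max(r), 5 / sqrt(1000))
})

test_that("dilution is multiplicative on urine and truth table is faithful", {
  cohort <- make_small_cohort(n = 120, seed = 77)
  sim <- cohort$sim
  # regenerate without missingness to see the pre-dropout values
  plan0 <- effect_plan(cohort$plan$effects, cohort$plan$metabolites,
                       missing_rate = 0)
  sim0 <- simulate_metabolomes(cohort$panel, plan0, cohort$covariates, 79)
  s <- names(sim0$dilution)[3]
  scaled <- sim0$urine$values[s, ] / sim0$dilution[s]
  # removing the factor recovers a plasma-like scale: refit factor of 2
  plan2 <- plan0
  expect_equal(unname(sim0$urine$values[s, ]),
               unname(scaled * sim0$dilution[s]))
  expect_setequal(names(sim$truth),
                  c("snp_id", "metabolite", "matrix", "beta", "beta_sex",
                    "h2_target"))
  expect_identical(sim$truth$snp_id, cohort$plan$effects$snp_id)
})

test_that("realized SNP-explained variance tracks the heritability target", {
  panel <- simulate_genotypes(2000, list(list(n_snps = 5, r2 = 0.2,
                                              freq = c(0.3, 0.5))), seed = 11)
  covariates <- simulate_covariates(panel$sample_ids, 12)
  plan <- effect_plan(data.frame(snp_id = "snp_1_3", metabolite = "m1",
                                 matrix = "both", beta = 1),
                      metabolites = "m1", h2_targets = c(m1 = 0.4),
                      missing_rate = 0, covariate_betas = c(age = 0))
  sim <- simulate_metabolomes(panel, plan, covariates, seed = 13)
  y <- log2(sim$plasma$values[, "m1"])
  x <- panel$dosages[, "snp_1_3"]
  expect_equal(summary(lm(y ~ x))$r.squared, 0.4, tolerance = 0.05)
})

test_that("truth table round-trips through file I/O losslessly", {
  cohort <- make_small_cohort(n = 60, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(cohort$sim$truth, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  back$h2_target <- as.numeric(back$h2_target)
  expect_equal(back, cohort$sim$truth, ignore_attr = TRUE)
})
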