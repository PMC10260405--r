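test_that("residualization is orthogonal to the design", {
  covariates <- simulate_covariates(sprintf("S%03d", 1:300), 1)
  set.seed(2)
  # planted age effect: 0.3 per decade
  y <- setNames(0.03 * covariates$age + rnorm(300), rownames(covariates))
  r <- residualize(y, covariates, "plasma")
  expect_lt(abs(mean(r)), 1e-10)
  for (cc in c("age", "sex", "pc1", "ln_egfr", "albumin"))
    expect_lt(abs(cov(r, covariates[names(r), cc])), 1e-8)
  expect_lt(abs(coef(lm(r ~ covariates[names(r), "age"]))[2]), 1e-10)

  # perfect fit: trait = 2 x age -> residuals all ~0
  y2 <- setNames(2 * covariates$age, rownames(covariates))
  expect_lt(max(abs(residualize(y2, covariates, "urine"))), 1e-10)

  # collinear design errors with the offending column named
  cov2 <- covariates
  cov2$albumin <- 2 * cov2$age
  expect_error(residualize(y, cov2, "plasma"), "collinear")
})

test_that("per-SNP regression matches lm and handles monomorphic SNPs", {
  fix <- make_single_signal(n = 200, m_snps = 8, beta = 0.4, seed = 3)
  panel <- fix$panel
  # graft a monomorphic column
  panel$dosages[, 1] <- 0
  tab <- run_gwas(fix$y, panel)
  expect_true(tab$undefined[1])
  expect_false(any(tab$undefined[-1]))
  for (j in c(2, 4, 8)) {
    ref <- summary(lm(fix$y ~ panel$dosages[, j]))$coefficients
    expect_equal(tab$beta[j], ref[2, 1], tolerance = 1e-12)
    expect_equal(tab$se[j], ref[2, 2], tolerance = 1e-12)
    expect_equal(tab$p[j], ref[2, 4], tolerance = 1e-9)
  }
  # p consistent with beta/se under the t reference
  ok <- !tab$undefined
  expect_equal(tab$p[ok],
               2 * pt(abs(tab$beta[ok] / tab$se[ok]), tab$n[ok] - 2,
                      lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("perfect proportionality gives the exact slope with vanishing p", {
  panel <- simulate_genotypes(100, list(list(n_snps = 1, r2 = 0, freq = 0.5)),
                              seed = 4)
  y <- setNames(3 * panel$dosages[, 1], panel$sample_ids)
  tab <- run_gwas(y, panel)
  expect_equal(tab$beta, 3)
  expect_lt(tab$p, 1e-200)
})

test_that("effects are allele-coding equivariant", {
  fix <- make_single_signal(n = 300, m_snps = 5, beta = 0.5, seed = 5)
  flipped <- fix$panel
  flipped$dosages <- 2 - flipped$dosages
  a <- run_gwas(fix$y, fix$panel)
  b <- run_gwas(fix$y, flipped)
  expect_equal(b$beta, -a$beta, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("Bonferroni thresholds divide the base alpha exactly", {
  expect_equal(significance_config(1)$threshold, 5e-8)
  cfg <- significance_config(250)
  expect_identical(cfg$threshold, 5e-8 / 250)
  tab <- data.frame(snp_id = c("a", "b"), p = c(1e-10, 3e-10))
  expect_equal(apply_threshold(tab, 2.5e-10)$snp_id, "a")  # strict <
  expect_error(significance_config(0))
})

test_that("inverse-normal transform follows the c = 0.5 offset convention", {
  # n = 3 tie-free: quantiles at (r - 0.5)/3
  out <- inverse_normal_transform(c(10, 30, 20))
  expect_equal(out, qnorm(c(1 / 6, 5 / 6, 3 / 6)))
  # two tied minima among n = 4: average rank 1.5
  out2 <- inverse_normal_transform(c(1, 1, 5, 9))
  expect_equal(out2[1:2], rep(qnorm((1.5 - 0.5) / 4), 2))
  # rank preservation
  set.seed(6)
  x <- rnorm(50)
  expect_equal(cor(x, inverse_normal_transform(x), method = "spearman"), 1)
  expect_equal(mean(inverse_normal_transform(x)), 0, tolerance = 1e-10)
  expect_error(inverse_normal_transform(rep(1, 5)), "distinct")
})

test_that("two-stage residual GWAS approximates the joint fit", {
  fix <- make_single_signal(n = 400, m_snps = 6, beta = 0.4, seed = 8)
  covariates <- simulate_covariates(fix$panel$sample_ids, 9)
  y <- fix$y + 0.02 * covariates[names(fix$y), "age"]
  r <- residualize(y, covariates, "urine")
  two_stage <- run_gwas(r, fix$panel)
  x <- fix$panel$dosages[names(r), fix$causal]
  joint <- summary(lm(y[names(r)] ~ x + age + sex + pc1 + pc2 + pc3,
                      data = covariates[names(r), ]))$coefficients
  i <- match(fix$causal, two_stage$snp_id)
  expect_equal(two_stage$beta[i], joint["x", 1], tolerance = 0.02)
  expect_equal(log10(two_stage$p[i]), log10(joint["x", 4]), tolerance = 0.15)
})

test_that("sex interaction test flags male-only effects and not shared ones", {
  panel <- simulate_genotypes(2000, list(list(n_snps = 3, r2 = 0.2,
                                              freq = c(0.3, 0.5))), seed = 10)
  covariates <- simulate_covariates(panel$sample_ids, 11)
  set.seed(12)
  x <- panel$dosages[, "snp_1_2"]
  sex <- covariates$sex
  y_shared <- setNames(0.4 * x + rnorm(2000), panel$sample_ids)
  y_male <- setNames(0.6 * x * sex + rnorm(2000), panel$sample_ids)

  shared <- test_sex_interaction("snp_1_2", y_shared, covariates, panel,
                                 "urine", n_mqtls = 10)
  expect_gt(shared$p_interaction, 0.05 / 10)

  male <- test_sex_interaction("snp_1_2", y_male, covariates, panel,
                               "urine", n_mqtls = 10)
  expect_lt(male$p_interaction, 0.05 / 10)
  expect_gt(male$beta_male, male$beta_female + 0.2)

  cov_one_sex <- covariates
  cov_one_sex$sex <- 1
  expect_error(test_sex_interaction("snp_1_2", y_male, cov_one_sex, panel,
                                    "urine"), "both sexes")
})
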