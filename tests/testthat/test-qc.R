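make_log2_matrix <- function(n = 60, m = 30, seed = 1, label = "plasma") {
  set.seed(seed)
  vals <- matrix(rnorm(n * m, 10), n, m,
                 dimnames = list(sprintf("S%03d", 1:n), paste0("met", 1:m)))
  metabolite_matrix(vals, label)
}

test_that("duplicated samples are detected and null pairs are not", {
  mm <- make_log2_matrix(50, 200, seed = 2)
  vals <- mm$values
  vals["S050", ] <- vals["S001", ]        # duplicate under a new id
  dup <- detect_duplicates(metabolite_matrix(vals, "plasma"), 0.9)
  expect_equal(nrow(dup), 1L)
  expect_setequal(c(dup$sample_a, dup$sample_b), c("S001", "S050"))
  expect_equal(dup$r, 1)

  # independent samples: no pair exceeds 0.9 over 50 samples x 200 metabolites
  dup0 <- detect_duplicates(mm, 0.9)
  expect_equal(nrow(dup0), 0L)

  # strict inequality: threshold 1 never flags noisy duplicates
  vals["S050", 1] <- vals["S050", 1] + 0.01
  expect_equal(nrow(detect_duplicates(metabolite_matrix(vals, "plasma"), 1)), 0L)
})

test_that("pq normalization recovers relative dilution and is scale-equivariant", {
  set.seed(3)
  # per-metabolite characteristic level plus small sample-level noise, so the
  # median quotient estimates the planted scale factor tightly
  mu <- rnorm(20, 10, 2)
  base <- 2^(outer(rep(0, 40), mu, "+") + rnorm(40 * 20, 0, 0.1))
  dimnames(base) <- list(sprintf("S%02d", 1:40), paste0("met", 1:20))
  scaled <- base
  scaled["S01", ] <- scaled["S01", ] * 2
  pq <- pq_normalize(metabolite_matrix(scaled, "urine"), 1)
  others <- setdiff(rownames(base), "S01")
  expect_equal(pq$factors[["S01"]] / median(pq$factors[others]), 2,
               tolerance = 0.05)
  # after normalization the scaled sample matches the normalized cohort medians
  norm_med <- apply(pq$matrix$values, 2, median)
  expect_equal(pq$matrix$values["S01", ] / norm_med,
               setNames(rep(1, 20), paste0("met", 1:20)), tolerance = 0.25)

  # scale equivariance: c x row => c x factor, normalized row unchanged
  # (up to the at-most-one-order-statistic shift of the median reference
  # spectrum caused by moving the sample's own values)
  c2 <- scaled
  c2["S05", ] <- c2["S05", ] * 7
  pq2 <- pq_normalize(metabolite_matrix(c2, "urine"), 1)
  expect_equal(pq2$factors[["S05"]], pq$factors[["S05"]] * 7, tolerance = 0.01)
  expect_equal(pq2$matrix$values["S05", ], pq$matrix$values["S05", ],
               tolerance = 0.01)

  # all-identical samples: factors all equal, output proportional to input
  same <- matrix(rep(2^seq(8, 12, length.out = 10), each = 5), 5, 10,
                 dimnames = list(paste0("S", 1:5), paste0("met", 1:10)))
  pq3 <- pq_normalize(metabolite_matrix(same, "urine"), 1)
  expect_true(all(abs(pq3$factors - pq3$factors[1]) < 1e-12))
})

test_that("pq factor recovery on generator dilution is near-perfect", {
  panel <- simulate_genotypes(500, list(list(n_snps = 2, r2 = 0, freq = 0.3)),
                              seed = 31)
  covariates <- simulate_covariates(panel$sample_ids, 32)
  plan <- effect_plan(data.frame(snp_id = character(), metabolite = character(),
                                 matrix = character(), beta = numeric()),
                      metabolites = paste0("met", 1:400),
                      missing_rate = c(rep(0, 300), rep(0.1, 100)))
  sim <- simulate_metabolomes(panel, plan, covariates, seed = 33)
  pq <- pq_normalize(sim$urine, 0.01)
  expect_gt(cor(pq$factors, sim$dilution, method = "spearman"), 0.99)
})

test_that("pq errors are informative", {
  vals <- matrix(c(1, NA, 2, NA), 2, 2,
                 dimnames = list(c("a", "b"), c("m1", "m2")))
  expect_error(pq_normalize(vals, 0.01), "no metabolite qualifies")
  vals2 <- rbind(a = c(1, 2), b = c(NA, NA))
  colnames(vals2) <- c("m1", "m2")
  expect_error(pq_normalize(vals2, 1), "zero observed reference")
})

test_that("filters apply in order with attributed removals", {
  mm <- make_log2_matrix(80, 20, seed = 4)
  vals <- mm$values
  vals[, "met1"] <- 5                       # constant -> variance rule
  vals[1:70, "met2"] <- NA                  # observed in 10 < 15 samples
  vals["S080", 1:15] <- NA                  # 75% missing sample
  cfg <- qc_config(min_samples_per_metabolite = 15, sample_missing_max = 0.5,
                   n_pcs = 5)
  out <- filter_metabolites_and_samples(metabolite_matrix(vals, "plasma"), cfg)
  rp <- out$report
  expect_equal(rp$rule[rp$id == "met1"], "low_variance")
  expect_equal(rp$rule[rp$id == "met2"], "min_sample_count")
  expect_equal(rp$rule[rp$id == "S080"], "sample_missingness")
  # each removal attributed to exactly one rule
  expect_false(any(duplicated(rp$id)))
  # idempotent: rerun removes nothing
  out2 <- filter_metabolites_and_samples(out$matrix, cfg)
  expect_equal(nrow(out2$report), 0L)
  expect_equal(out2$matrix$values, out$matrix$values)
})

test_that("a sample displaced along PC1 is removed by the PC rule", {
  set.seed(6)
  n <- 100; m <- 12
  vals <- matrix(rnorm(n * m), n, m,
                 dimnames = list(sprintf("S%03d", 1:n), paste0("met", 1:m)))
  # displace one sample 10 s.d. along the leading eigenvector of the cloud
  v1 <- prcomp(vals, center = TRUE, scale. = TRUE)$rotation[, 1]
  vals["S100", ] <- colMeans(vals) + 10 * sqrt(n) / sqrt(n) * 10 * v1
  out <- filter_metabolites_and_samples(
    metabolite_matrix(vals, "plasma"),
    qc_config(min_samples_per_metabolite = 10, n_pcs = 5, variance_min = 1e-6))
  expect_true("S100" %in% out$report$id[out$report$rule == "pc_outlier"])
})

test_that("qc_pipeline rejects non-positive abundances and runs end to end", {
  cohort <- make_small_cohort(n = 350, seed = 21)
  bad <- cohort$sim$plasma
  bad$values[1, 1] <- -1
  expect_error(qc_pipeline(bad), "non-positive")
  out <- qc_pipeline(cohort$sim$urine,
                     qc_config(min_samples_per_metabolite = 100))
  expect_s3_class(out$matrix, "metabolite_matrix")
  expect_true(is.numeric(out$dilution_factors))
  expect_true(all(out$report$rule %in%
                    c("duplicate", "sample_missingness", "min_sample_count",
                      "low_variance", "outlier_metabolite", "pc_outlier")))
})
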