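make_stats <- function(z, se = 0.03, ids = sprintf("rs%03d", seq_along(z))) {
  data.frame(snp_id = ids, chr = "1", pos = seq_along(z) * 1000,
             ea = "G", oa = "A", eaf = 0.3,
             beta = z * se, se = se, p = 2 * pnorm(-abs(z)), n = 5000,
             stringsAsFactors = FALSE)
}

test_that("self-colocalization of a strong signal gives H4 near 1", {
  set.seed(1)
  z <- rnorm(100)
  z[40] <- 15
  a <- make_stats(z)
  res <- coloc_abf(a, a)
  expect_equal(sum(res$pp), 1, tolerance = 1e-9)
  expect_gt(res$pp[["H4"]], 0.95)
})

test_that("distinct causal variants give H3 and double-null gives H0", {
  set.seed(2)
  za <- rnorm(200); zb <- rnorm(200)
  za[30] <- 14; zb[170] <- 14            # far apart, LD-free by construction
  res <- coloc_abf(make_stats(za), make_stats(zb))
  expect_gt(res$pp[["H3"]], 0.95)

  null <- coloc_abf(make_stats(rnorm(200) * 0.3), make_stats(rnorm(200) * 0.3))
  expect_gt(null$pp[["H0"]], 0.9)
})

test_that("coloc is symmetric with H1/H2 swapped and scale-invariant", {
  set.seed(3)
  za <- rnorm(80); za[10] <- 12
  zb <- rnorm(80) * 0.5
  a <- make_stats(za); b <- make_stats(zb)
  ab <- coloc_abf(a, b)
  ba <- coloc_abf(b, a)
  expect_equal(ab$pp[["H1"]], ba$pp[["H2"]], tolerance = 1e-12)
  expect_equal(ab$pp[["H2"]], ba$pp[["H1"]], tolerance = 1e-12)
  expect_equal(ab$pp[["H4"]], ba$pp[["H4"]], tolerance = 1e-12)

  # uniform scaling of both traits' effects and SEs leaves posteriors alone
  a2 <- a; a2$beta <- a2$beta * 10; a2$se <- a2$se * 10
  b2 <- b; b2$beta <- b2$beta * 10; b2$se <- b2$se * 10
  # prior_sd scales with the effects for exact invariance of the z-based part
  ab2 <- coloc_abf(a2, b2, prior_sd = 1.5)
  ab1 <- coloc_abf(a, b, prior_sd = 0.15)
  expect_equal(ab2$pp, ab1$pp, tolerance = 1e-9)
})

test_that("allele orientation is harmonized and mismatches dropped", {
  set.seed(4)
  z <- rnorm(50); z[25] <- 13
  a <- make_stats(z)
  b <- a
  flip <- c(10, 25)
  b$ea[flip] <- "A"; b$oa[flip] <- "G"; b$beta[flip] <- -b$beta[flip]
  res <- coloc_abf(a, b)
  expect_gt(res$pp[["H4"]], 0.95)         # flipped coding, same signal

  b2 <- a
  b2$ea[1] <- "T"                          # unresolvable mismatch
  expect_message(res2 <- coloc_abf(a, b2), "allele mismatch")
  expect_equal(res2$n_snps, 49L)
  expect_error(coloc_abf(a, make_stats(rnorm(3), ids = c("x", "y", "z"))),
               "no shared SNPs")
})

test_that("mQTL pairing follows the +/-500 kb window-overlap rule", {
  mq <- data.frame(trait = c("a", "b", "c", "d"),
                   matrix = c("plasma", "urine", "plasma", "plasma"),
                   chr = c("1", "1", "1", "2"),
                   index_pos = c(10e6, 10.6e6, 11.5e6, 10e6),
                   stringsAsFactors = FALSE)
  pr <- pair_mqtls(mq)
  # a-b: 600 kb apart -> paired; b-c: 900 kb -> paired; a-c: 1.5 Mb -> not;
  # d on another chromosome -> never
  expect_equal(nrow(pr), 2L)
  expect_equal(pr$row_a, c(1L, 2L))
  expect_equal(pr$row_b, c(2L, 3L))
  r1 <- pr[1, ]
  expect_equal(c(r1$start, r1$end), c(10e6 - 5e5, 10.6e6 + 5e5))  # 1.6 Mb span
})

test_that("pair classification covers the four groups", {
  lab <- function(ta, ma, tb, mb)
    classify_coloc_pair(list(trait_a = ta, matrix_a = ma,
                             trait_b = tb, matrix_b = mb))
  expect_equal(lab("glycine", "plasma", "serine", "plasma"), "intraplasma")
  expect_equal(lab("glycine", "urine", "serine", "urine"), "intraurine")
  expect_equal(lab("glycine", "plasma", "glycine", "urine"),
               "intermatrix_same_metabolite")
  expect_equal(lab("glycine", "plasma", "serine", "urine"),
               "intermatrix_different_metabolite")
})

test_that("external colocalization only runs when the trigger fires", {
  set.seed(5)
  z <- rnorm(60); z[30] <- 12
  mstats <- make_stats(z)
  mq <- data.frame(trait = "m1", matrix = "plasma", chr = "1",
                   index_pos = 30000, stringsAsFactors = FALSE)

  # p = 1e-3 within 100 kb: above 0.05/409 = 1.22e-4 -> not triggered
  ext <- make_stats(rep(0, 60)); ext$p[] <- 1; ext$p[31] <- 1e-3
  expect_null(external_coloc_trigger(mq, mstats, ext, n_index = 409))

  # strong p but MAF below the gate -> not triggered
  ext2 <- ext; ext2$p[31] <- 1e-6; ext2$eaf[31] <- 0.005
  expect_null(external_coloc_trigger(mq, mstats, ext2, n_index = 409))

  # strong p, common variant, 50 kb away -> triggered
  ext3 <- make_stats(z + rnorm(60, 0, 0.2))
  expect_s3_class(external_coloc_trigger(mq, mstats, ext3, n_index = 409),
                  "coloc_result")
})
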