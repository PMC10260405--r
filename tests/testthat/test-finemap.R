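test_that("Wakefield ABF matches an independent dual coding", {
  # z = 0, V = W: analytically sqrt(1/2)
  expect_equal(wakefield_abf(0, 1.33, prior_sd = 1.33), sqrt(0.5))

  # independent log-scale implementation of the same formula
  abf_oracle <- function(beta, se, w_sd) {
    v <- se^2; w <- w_sd^2; z <- beta / se
    exp(0.5 * (log(v) - log(v + w)) + (z^2 / 2) * (w / (v + w)))
  }
  for (pars in list(c(0.3, 0.05), c(-1.2, 0.4), c(0.01, 0.3))) {
    expect_equal(wakefield_abf(pars[1], pars[2]),
                 abf_oracle(pars[1], pars[2], 1.33), tolerance = 1e-10)
    expect_equal(wakefield_abf(pars[1], pars[2], log = TRUE),
                 log(abf_oracle(pars[1], pars[2], 1.33)), tolerance = 1e-10)
  }

  # strictly increasing in |z| at fixed V, W
  z <- seq(0, 6, by = 0.5)
  abf <- wakefield_abf(z * 0.1, rep(0.1, length(z)))
  expect_true(all(diff(abf) > 0))
  expect_error(wakefield_abf(1, 0), "positive")
})

test_that("credible sets use the strict >99% prefix rule", {
  # single SNP: PPA 1, size 1
  cs <- credible_set(c(a = 5))
  expect_equal(cs$ppa, 1)
  expect_equal(attr(cs, "set_size"), 1L)

  # hand prefix sums
  cs2 <- credible_set(c(a = 0.95, b = 0.045, c = 0.005) * 7)  # scale-invariant
  expect_equal(attr(cs2, "set_size"), 2L)
  expect_equal(cs2$in_set, c(TRUE, TRUE, FALSE))

  # cumulative exactly 0.99 at 3 is not > 0.99 -> size 4
  cs3 <- credible_set(c(a = 0.80, b = 0.15, c = 0.04, d = 0.01))
  expect_equal(attr(cs3, "set_size"), 4L)

  # PPAs sum to 1 and are invariant to scaling all ABFs
  x <- c(a = 2, b = 1, c = 0.5)
  expect_equal(sum(credible_set(x)$ppa), 1, tolerance = 1e-9)
  expect_equal(credible_set(x * 100)$ppa, credible_set(x)$ppa)
  # log-scale route agrees
  expect_equal(credible_set(log(x), log = TRUE)$ppa, credible_set(x)$ppa)
  expect_error(credible_set(c(a = 0, b = 0)), "zero")
})

test_that("stepwise selection separates independent signals", {
  # one causal SNP among tight proxies: exactly one signal
  fix <- make_single_signal(n = 1500, m_snps = 12, beta = 0.4, seed = 11,
                            r2 = 0.9)
  sel <- stepwise_select(fix$panel$snps$snp_id, fix$y, fix$panel, 5e-8)
  expect_equal(nrow(sel), 1L)

  # two causal SNPs in different blocks (r2 ~ 0), both powered
  panel <- simulate_genotypes(2000,
    list(list(n_snps = 10, r2 = 0.6, freq = c(0.3, 0.4)),
         list(n_snps = 10, r2 = 0.6, freq = c(0.3, 0.4))), seed = 12)
  set.seed(13)
  x1 <- panel$dosages[, "snp_1_5"]; x2 <- panel$dosages[, "snp_2_5"]
  y <- setNames(0.4 * x1 + 0.4 * x2 + rnorm(2000), panel$sample_ids)
  sel2 <- stepwise_select(panel$snps$snp_id, y, panel, 5e-8)
  expect_equal(nrow(sel2), 2L)
  expect_setequal(sel2$snp_id, c("snp_1_5", "snp_2_5"))
  expect_lt(abs(sel2$beta_cond[1] - 0.4), 3 * sel2$se_cond[1])
  expect_lt(abs(sel2$beta_cond[2] - 0.4), 3 * sel2$se_cond[2])
  # conditional p below threshold, leads mutually quasi-independent
  expect_true(all(sel2$p_cond < 5e-8))
  expect_lt(ld_r2(panel, sel2$snp_id)[1, 2], 0.1)

  # nothing significant -> empty selection
  set.seed(14)
  y0 <- setNames(rnorm(2000), panel$sample_ids)
  expect_equal(nrow(stepwise_select(panel$snps$snp_id, y0, panel, 5e-8)), 0L)
  expect_error(stepwise_select(character(), y0, panel, 5e-8), "empty")
})

test_that("region alignment is single linkage on index-SNP LD", {
  # identical index SNPs -> one region
  mq <- data.frame(trait = c("a", "b"), matrix = "urine",
                   index_snp = c("snp_1_1", "snp_1_1"), chr = "1",
                   start = c(1e6, 2e6), end = c(3e6, 4e6),
                   stringsAsFactors = FALSE)
  panel <- simulate_genotypes(300, list(list(n_snps = 4, r2 = 1, freq = 0.3),
                                        list(n_snps = 2, r2 = 0, freq = 0.3)),
                              seed = 15)
  al <- align_regions(mq, panel)
  expect_equal(nrow(al), 1L)
  expect_equal(c(al$start, al$end), c(1e6, 4e6))

  # independent blocks stay separate; r2 = 1 chain merges transitively
  mq2 <- data.frame(trait = c("a", "b", "c"), matrix = "urine",
                    index_snp = c("snp_1_1", "snp_1_3", "snp_2_1"), chr = "1",
                    start = c(1e6, 1.5e6, 9e6), end = c(2e6, 2.5e6, 10e6),
                    stringsAsFactors = FALSE)
  al2 <- align_regions(mq2, panel)
  expect_equal(nrow(al2), 2L)
  sizes <- sort(vapply(al2$mqtl_rows, length, integer(1)))
  expect_equal(sizes, c(1L, 2L))
  expect_error(align_regions(data.frame(trait = "a", matrix = "urine",
                                        index_snp = "nope", chr = "1",
                                        start = 1, end = 2), panel),
               "absent")
})

test_that("finemap_region returns credible sets per independent signal", {
  fix <- make_single_signal(n = 1500, m_snps = 20, beta = 0.35, seed = 16)
  fm <- finemap_region(fix$panel$snps$snp_id, fix$y, fix$panel, 5e-8)
  expect_equal(nrow(fm$signals), 1L)
  cs <- fm$credible_sets[[1]]
  expect_equal(sum(cs$ppa), 1, tolerance = 1e-9)
  expect_true(fix$causal %in% cs$snp_id[cs$in_set])
})
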