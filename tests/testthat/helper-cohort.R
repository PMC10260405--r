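# Shared small fixtures, built in code.

# A modest paired cohort with one shared and one plasma-only planted mQTL.
make_small_cohort <- function(n = 400, seed = 42) {
  panel <- simulate_genotypes(
    n,
    block_spec = list(list(n_snps = 15, r2 = 0.5, freq = c(0.2, 0.4)),
                      list(n_snps = 15, r2 = 0.5, freq = c(0.2, 0.4)),
                      list(n_snps = 10, r2 = 0, freq = c(0.1, 0.5))),
    seed = seed)
  covariates <- simulate_covariates(panel$sample_ids, seed + 1L)
  mets <- paste0("m", 1:40)
  eff <- data.frame(snp_id = c("snp_1_8", "snp_2_5"),
                    metabolite = c("m1", "m2"),
                    matrix = c("both", "plasma"),
                    beta = c(0.9, 0.9))
  plan <- effect_plan(eff, metabolites = mets, missing_rate = 0.01)
  sim <- simulate_metabolomes(panel, plan, covariates, seed + 2L)
  list(panel = panel, covariates = covariates, plan = plan, sim = sim)
}

# Single-block panel + single causal SNP trait on residual scale.
make_single_signal <- function(n = 500, m_snps = 20, beta = 0.5, seed = 7,
                               r2 = 0.5, causal = ceiling(m_snps / 2)) {
  panel <- simulate_genotypes(
    n, list(list(n_snps = m_snps, r2 = r2, freq = c(0.2, 0.4))), seed = seed)
  set.seed(seed + 1000L)
  x <- panel$dosages[, causal]
  y <- stats::setNames(beta * x + stats::rnorm(n), panel$sample_ids)
  list(panel = panel, y = y, causal = colnames(panel$dosages)[causal])
}
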