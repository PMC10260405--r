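# mqtlkit

Genetic mapping of metabolite levels in **paired plasma and urine**. The
kidney clears waste solutes from plasma while reabsorbing valuable ones, so
the two fluids carry complementary genetic signals: a transporter at the
apical membrane of the tubule leaves its footprint in urine, a basolateral
one in plasma, and filtration propagates plasma effects into urine. This
package implements the full analysis chain needed to study such paired
metabolomes with genome-wide genotypes, for statistical geneticists and
metabolomics researchers:

* metabolite QC with probabilistic quotient normalization of urine
  (correcting per-sample dilution), log2 transform, variance/outlier/PC
  filters;
* additive linear metabolite GWAS on covariate-adjusted residuals with
  Bonferroni thresholds per matrix (e.g. 5×10⁻⁸/1,296 traits ≈
  3.9×10⁻¹¹), rank-based inverse-normal guards for rare variants, and
  SNP×sex interaction tests;
* iterative mQTL calling (±500 kb windows, interval merging, MHC
  collapsing);
* stepwise conditional fine mapping with Wakefield approximate Bayes
  factors,
  `ABF = sqrt(V/(V+W)) · exp(z²W / 2(V+W))`,
  per-SNP posterior probabilities of association and >99% credible sets;
* pairwise Bayesian colocalization (posterior probabilities H0–H4 of the
  single-shared-causal-variant model; positive at PP H4 > 0.8) with a
  four-group classification of cross-matrix sharing and trigger-gated
  colocalization against external traits;
* evidence-code gene prioritization with the documented tie-break cascade;
* matched-permutation and Fisher enrichment tests with
  Benjamini–Hochberg adjustment;
* extended haplotype homozygosity (EHH) decay curves for derived vs
  ancestral core alleles;
* GCTA-style GRM and single-component REML (GREML) SNP heritability.

A synthetic paired-cohort generator with a machine-readable truth table
(LD-blocked phased genotypes, planted shared / plasma-only / urine-only
mQTLs, per-sample urine dilution, missing-at-random dropout) makes every
stage testable end to end. See the vignette
`vignettes/paired-mqtl-workflow.Rmd` for the methods in detail.

## Worked example

Simulate a paired cohort with one shared planted mQTL, run QC, GWAS, locus
calling, fine mapping and cross-matrix colocalization:

```r
library(mqtlkit)

panel <- simulate_genotypes(
  n_samples = 800,
  block_spec = list(list(n_snps = 15, r2 = 0.5, freq = c(0.2, 0.4)),
                    list(n_snps = 15, r2 = 0.5, freq = c(0.2, 0.4))),
  seed = 1)
covariates <- simulate_covariates(panel$sample_ids, seed = 2)
plan <- effect_plan(
  effects = data.frame(snp_id = "snp_1_8", metabolite = "glycerol",
                       matrix = "both", beta = 0.6),
  metabolites = c("glycerol", paste0("met", 1:29)),
  missing_rate = 0)
cohort <- simulate_metabolomes(panel, plan, covariates, seed = 3)

qc <- qc_pipeline(cohort$urine, qc_config(min_samples_per_metabolite = 200))
resid <- residualize(qc$matrix$values[, "glycerol"], covariates, "urine")
assoc <- run_gwas(resid, panel)
sig <- significance_config(n_traits = 30)   # threshold 5e-8 / 30
mqtls <- call_mqtls(assoc, sig, trait = "glycerol", matrix_label = "urine")
mqtls[, c("index_snp", "chr", "index_pos", "p", "beta", "se", "n_members")]
#>   index_snp chr index_pos            p      beta         se n_members
#> 1   snp_1_8   1   1014000 8.035341e-24 0.6155381 0.05917304         3
```

The planted SNP is recovered as the index SNP with its effect (0.62 per
alt allele on the log2 scale, planted 0.6) and a locus of three
genome-wide-significant members. Fine mapping resolves the signal to a
single-SNP credible set:

```r
fm <- finemap_region(unlist(mqtls$members[1]), resid, panel, sig)
head(fm$credible_sets[[1]], 3)
#>    snp_id          ppa cum_ppa in_set     labf
#> 1 snp_1_8 1.000000e+00       1   TRUE 50.88400
#> 2 snp_1_7 6.651031e-11       1  FALSE 27.45034
#> 3 snp_1_9 1.012932e-13       1  FALSE 20.96324
```

`snp_1_8` carries essentially all posterior mass (PPA ≈ 1), so the >99%
credible set has size 1. Because the effect was planted in both matrices,
the plasma and urine signals colocalize:

```r
resid_p <- residualize(log2(cohort$plasma$values[, "glycerol"]),
                       covariates, "plasma")
coloc_abf(run_gwas(resid_p, panel), assoc,
          trait_a = "glycerol", matrix_a = "plasma",
          trait_b = "glycerol", matrix_b = "urine")
#> coloc_result [intermatrix_same_metabolite]: glycerol/plasma vs glycerol/urine over 30 SNPs
#> H0 H1 H2 H3 H4
#>  0  0  0  0  1
```

PP H4 = 1: one shared causal variant drives both matrices, and the pair is
classified `intermatrix_same_metabolite`. `run_pipeline()` chains all
stages (QC → GWAS → loci → fine mapping → colocalization, optionally
heritability) and writes per-stage TSVs plus a checksummed manifest.

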