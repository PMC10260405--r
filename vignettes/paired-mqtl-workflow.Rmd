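---
title: "Mapping metabolite QTLs in paired plasma and urine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping metabolite QTLs in paired plasma and urine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlkit)
```

`mqtlkit` implements a complete workflow for genetic studies of paired body
fluids: quality control and normalization of plasma and urine metabolite
panels, additive linear metabolite GWAS, locus ("mQTL") calling, statistical
fine mapping with approximate Bayes factors, pairwise Bayesian
colocalization across and within matrices, causal-gene prioritization from
evidence codes, matched-permutation enrichment, extended haplotype
homozygosity, and SNP heritability. This vignette explains the statistical
model behind every stage, the tunable parameters and their defaults, what
the synthetic cohort generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open.

## The data model

A cohort consists of three aligned objects:

* a `genotype_panel`: alt-allele dosages in $[0,2]$ for $n$ samples at $M$
  SNPs, per-SNP metadata (chromosome, position, alleles, alt frequency,
  imputation quality), and optionally $2n$ phased haplotypes;
* two `metabolite_matrix` objects (plasma, urine): raw-scale abundances
  with missing values;
* a covariate table: age (years), sex (0/1), three genetic principal
  components, eGFR (ml/min/1.73m²) and serum albumin (g/l).

## Quality control and normalization

QC mirrors the cleaning pipeline of large non-targeted metabolomics
cohorts, in a fixed, logged order:

1. **Duplicates** — sample pairs with pairwise-complete Pearson $r > 0.9$
   under different ids are removed (both members).
2. **Sample missingness** — samples with more than 50% missing values.
3. **Metabolite support** — metabolites observed in fewer than 300 samples
   (too few for a stable GWAS).
4. **Probabilistic quotient (pq) normalization, urine only** — urine
   concentrations are confounded by hydration status. The reference
   spectrum is the per-metabolite median over the metabolites with < 1%
   missing values; each sample is divided by the median of its
   value/reference quotients. Plasma is under tight osmotic control and is
   not normalized.
5. **log2 transform** — all downstream statistics are per-doubling of
   abundance. Non-positive abundances are rejected at load time.
6. **Variance floor** — log2-scale variance < 0.01 (near-constant readouts
   carry quantification noise only). The floor is applied after pq
   normalization and log2, the package's reading of an ambiguous ordering.
7. **Outlying metabolites** — more than 5% of samples beyond 5 s.d.
8. **PC outliers** — samples beyond 5 s.d. on any of the first 15
   principal components of the complete-information metabolites.

pq equivariance (scaling a sample by $c$ scales its factor by $c$ and
leaves its normalized row unchanged) holds up to one order statistic of the
median reference, which the test suite checks at 1% tolerance.

## Metabolite GWAS

Following the two-stage design common to metabolome GWAS, each log2 trait
is first residualized on age, sex and three genetic PCs (plasma
additionally on ln(eGFR) and serum albumin, since kidney function strongly
shapes circulating metabolite levels), then each SNP is tested by simple
linear regression of the residuals on dosage with a $t_{n-2}$ reference.
The two-stage fit equals the joint fit up to $O(1/n)$, which the suite
verifies. Effects are per alt allele and allele-coding equivariant.

Genome-wide significance is Bonferroni over traits per matrix:
$\alpha = 5\times10^{-8}/n_\text{traits}$, e.g. $3.9\times10^{-11}$ for
1,296 plasma traits and $3.6\times10^{-11}$ for 1,401 urine traits. All
threshold comparisons are strict (`<`).

Rank-based inverse-normal transforms use the offset-½ convention
$\Phi^{-1}((r_i - 0.5)/n)$ with average ranks for ties; the offset is the
package's documented choice where conventions differ. SNP-by-sex
interactions are tested only at index SNPs with
`trait ~ dosage * sex + covariates` at $0.05/n_\text{mQTLs}$; sex is
excluded from stage-1 residualization there to avoid double adjustment.

## Locus calling

Significant SNPs are grouped by iterative peak picking: take the smallest-p
unassigned SNP as an index, assign every significant SNP within ±500 kb on
its chromosome to that locus, repeat. Ties on p are broken by position,
then SNP id, making the output invariant to row order. Loci whose index SNP
falls in the extended MHC (chr6:25.5–34 Mb) are collapsed into one region
regardless of spacing. Overlapping per-trait intervals (1-based inclusive,
sharing a base pair) are merged; the merged locus re-selects its index SNP
as the lowest-p member of the union — re-selection, rather than keeping the
first iteration's index, is the package's choice where either reading is
defensible. mQTLs with index MAF < 3% are kept only if the association
survives on inverse-normal-transformed trait values, which guards
rare-allele signals against single outlying measurements. Variance
explained is the squared dosage–trait Pearson correlation, deliberately
computed without covariates.

## Fine mapping

Independent signals come from forward stepwise selection on
individual-level data: candidates in LD $r^2 > 0.1$ with any selected SNP
are excluded; the candidate with the smallest conditional p (from the joint
regression, via Frisch–Waugh–Lovell residualization) is added while below
the genome-wide threshold. An exact joint regression is used rather than a
summary-statistic approximation: at these cohort sizes the exact fit is
simpler and strictly more accurate, and a summary-stat mode is a documented
extension point.

Per signal, each region SNP gets a Wakefield approximate Bayes factor
$$\mathrm{ABF} = \sqrt{\frac{V}{V+W}}\;
\exp\!\left(\frac{z^2}{2}\frac{W}{V+W}\right),$$
with $V$ the squared SE, $W$ the squared prior s.d. (default 1.33, applied
to effects on the residual scale) and $z = \hat\beta/\mathrm{SE}$. With a
single signal the marginal estimates are used; with several, effects are
conditioned on the other selected signals. Posterior probabilities of
association are ABFs normalized over the region (uniform prior), and the
credible set is the minimal PPA-ranked prefix with cumulative PPA strictly
above 99%. ABFs are handled in log space throughout, so extreme $z$ never
overflows. Fine-mapping regions are aligned across metabolites within a
matrix by single-linkage grouping of index SNPs at LD $r^2 > 0.8$.

Calibration: over 500 single-causal simulations ($n = 2{,}000$, one 50-SNP
LD block at adjacent $r^2 = 0.5$, causal effect explaining ~2.5% of
variance) the planted variant falls inside the >99% credible set in well
over 95% of runs. The relation between credible-set size and causal-variant
MAF is reported as a regression slope but its sign is not asserted — it
depends on the allele-frequency design of the cohort.

## Colocalization

For two association tables over shared SNPs (matched by id, alleles
harmonized by flipping swapped codings and dropping mismatches), five
hypotheses are enumerated under a single-causal-variant model: no
association (H0), trait A only (H1), B only (H2), two distinct variants
(H3), one shared variant (H4). Per-SNP evidence is again a Wakefield ABF,
with a default prior s.d. of 0.15 — deliberately distinct from the
fine-mapping prior, which is specified for fine mapping only; both are
config-exposed. Priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ are the
canonical single-variant colocalization defaults. All sums are in log
space; posteriors sum to 1 within $10^{-9}$, and a pair is called positive
at H4 > 0.8.

mQTL pairs are formed whenever ±500 kb windows around the index SNPs
overlap (the region is the union of the windows), and positive pairs are
classified as intraplasma, intraurine, intermatrix–same-metabolite or
intermatrix–different-metabolite. Colocalization against external traits
(phenotypes, eQTLs, pQTLs) is gated by a trigger: at least one external
variant with MAF > 0.01 and $p < 0.05/n_\text{index}$ within ±100 kb of the
index SNP; the phenotype and eQTL/pQTL triggers share this code path with
the denominator as a parameter.

## Gene prioritization

Candidate genes carry evidence codes — `h` (hit or close by), `r`
(regulated), `e`/`p` (cis eQTL/pQTL), `m` (missense), `c` (monogenic
disease gene), `E`/`P` (positive expression/protein colocalization). The
score sums h, r, m, c plus one point for e/E and one for p/P. Ties resolve
in order: E present, P present, a known inborn error of metabolism matching
the metabolite, Ee over E (then Pp over P), then smallest index-SNP
distance to the gene body (gene body rather than TSS is the package's
configurable choice), with a logged lexicographic fallback for exact
distance ties. Every locus yields exactly one winner with the deciding rule
recorded; the proportion of loci decided purely by distance can be read off
the recorded rules. Evidence codes are supplied as an input table (their
retrieval from annotation databases is out of scope); E and P can be
auto-populated from this package's own colocalization output. Manual
reassignment for biological plausibility is supported only as an explicit
override, never silently.

## Enrichment

Over-representation of a source gene list in an annotation set is tested by
matched permutation: each draw samples, within every stratum of the
(independent-SNP-count decile × gene-length decile) matching, as many
universe genes as the source has there, without replacement. The implementation
samples the per-stratum overlap count from the corresponding
hypergeometric distribution — distributionally identical to drawing gene
identities, and O(1) per stratum per draw; the tests verify agreement with
exhaustive enumeration. The empirical p uses add-one smoothing,
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{draws})$, so it is
never zero at finite draws. Defaults use $10^5$ draws (the $10^8$ scale of
very large analyses is reachable by configuration). Fisher's exact test
against a fixed universe and Benjamini–Hochberg adjustment (a validated
wrapper over `stats::p.adjust`) complete the module.

## Extended haplotype homozygosity

EHH at a flanking marker is the probability that two random carrier
haplotypes of the core allele are identical at every marker from the core
through the flank. It is computed by partition refinement — carrier groups
split at each successive marker, $O(nm)$ — which makes the curve monotone
non-increasing by construction; a brute-force pair-enumeration oracle backs
it in the tests. Haplotypes with missing calls are dropped per side.
Distances are physical (bp); derived/ancestral orientation is an input
annotation. `compare_alleles()` integrates both curves by the trapezoid
rule and reports the derived/ancestral ratio, which exceeds 1 under a
recent sweep on the derived background.

## Heritability

The genetic relationship matrix follows the standard frequency-scaled
cross-product over autosomal SNPs with imputation quality > 0.6,
$A_{jk} = M^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$.
Single-component REML for $y = X\beta + g + e$, $g \sim N(0, \sigma_g^2A)$,
is fitted in the eigenbasis of $A$ (one decomposition per cohort, $O(n)$
per iteration afterwards) by average-information updates with an EM
fallback and step halving, so the restricted log-likelihood never decreases
— an invariant asserted in the tests. Variance components are bounded below
at $10^{-6}\,\mathrm{var}(y)$, constraining $h^2$ to $[0,1]$; the SE comes
from the inverse AI matrix by the delta method. GWAS covariate sets are
reused per matrix, the package's choice where the adjustment set for REML
is not separately specified.

## The synthetic cohort generator

The generator exists so that every stage is testable against known ground
truth without any external download; it is first-class, tested code.

* **Genotypes** are phased haplotypes in independent LD blocks. Within a
  block each haplotype is a copying chain: site $j$ copies site $j-1$ with
  probability $\sqrt{r^2_\text{target}}$, else redraws from the block
  allele frequency. Adjacent-pair dosage $r^2$ equals the target (an
  $r^2 = 1$ block degenerates to identical columns exactly) and LD decays
  geometrically with distance. One frequency per block keeps the chain
  exchangeable.
* **Metabolites** are log2-scale: intercept + planted SNP effects (+
  optional SNP×sex terms) + per-metabolite covariate effects + Gaussian
  noise. When a heritability target is set, the noise variance is chosen
  from the realized genetic variance to hit it. Covariate coefficients are
  drawn per metabolite, $N(0, 0.01)$ per year of age and $N(0, 0.25)$ for
  sex — real covariate effects differ between metabolites in sign and
  size, and a uniform per-sample shift would masquerade as dilution.
* **Urine dilution** is a per-sample log-normal factor, median 1, sdlog
  0.8 — spot-urine solute concentrations (urinary creatinine spans roughly
  20–300 mg/dl) vary well over an order of magnitude, and 0.8 gives a
  ~20-fold 95% range.
* **Missingness** is missing-at-random per cell, scalar or per-metabolite.

The generator deliberately does **not** emulate demographic or coalescent
realism (no recombination maps, no allele-frequency spectra from drift), no
genotype imputation error, no batch or run-day effects beyond dilution, no
limit-of-detection (left-censored) missingness, and no correlated
metabolite modules beyond what shared causal SNPs induce. Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under a clean additive model — not robustness to platform
artifacts of real mass-spectrometry data.

## Numerical choices and degenerate inputs

* Strict `<` at every significance threshold; strict `>` at the 99%
  credible level and the H4 > 0.8 call.
* Locus tie-breaks: (p, position, SNP id); intervals clipped at base 1.
* Monomorphic SNPs yield flagged records (`undefined`), never silent drops;
  zero-variance inputs give `NA` variance explained.
* All Bayes-factor arithmetic in log space; log-sum-exp and `log1p`-based
  differences for the H3 configuration sum.
* REML convergence at $|\Delta\ell| < 10^{-8}$, iteration cap 100,
  non-convergence flagged with a warning, never silent.
* All randomness flows from explicit integer seeds; full generation is
  bit-reproducible, which the pipeline manifest (per-file checksums)
  makes verifiable.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
whole suite completes in minutes while keeping every Monte-Carlo bound
meaningful: 500 fine-mapping simulations at $n = 2{,}000$; 200 shared-
variant and 60 distinct-variant colocalization pairs at $n = 1{,}000$; 20
heritability replicates at $n = 1{,}000$, $M = 2{,}000$; $10^5$ permutation
draws; 10,000 null SNPs for the type-I error check; pq recovery at
$n = 500$ with 300 reference metabolites.

## Known limitations

* Single-causal-variant assumption inside colocalization (no multi-signal
  or SuSiE-style decomposition; conditioning on external index SNPs is an
  extension point).
* No mixed-model GWAS: relatedness is assumed absent, as in the synthetic
  cohorts; the GRM machinery exists but is not used for association.
* No X-chromosome handling, genomic control, or cross-chromosome loci.
* The two-stage residual GWAS is an $O(1/n)$ approximation to the joint
  fit, matching common practice rather than maximal efficiency.
* Evidence codes and ancestral-allele orientation are inputs; the package
  does not retrieve annotations.
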