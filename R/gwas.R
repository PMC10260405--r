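#' Residualize a trait on matrix-specific covariates
#'
#' Regresses log2 metabolite levels on age, sex and the first three genetic
#' principal components; plasma traits are additionally adjusted for
#' ln(eGFR) and serum albumin. Residuals are computed on complete cases of
#' trait plus covariates and are orthogonal to the design by construction.
#'
#' @param trait named numeric vector of per-sample log2 abundances (NAs
#'   allowed, dropped).
#' @param covariates data.frame with rownames = sample ids containing at
#'   least `age`, `sex`, `pc1`..`pc3` and, for plasma, `ln_egfr`, `albumin`.
#' @param matrix_label "plasma" or "urine"; selects the covariate set.
#' @param include_sex set FALSE to leave sex out of the adjustment (used
#'   before fitting an explicit SNP-by-sex interaction model).
#' @return named numeric vector of residuals (mean 0) for the complete-case
#'   samples.
#' @export
residualize <- function(trait, covariates,
                        matrix_label = c("plasma", "urine"),
                        include_sex = TRUE) {
  matrix_label <- match.arg(matrix_label)
  cols <- c("age", if (include_sex) "sex", "pc1", "pc2", "pc3")
  if (matrix_label == "plasma") cols <- c(cols, "ln_egfr", "albumin")
  miss <- setdiff(cols, names(covariates))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  if (is.null(names(trait))) stop("trait must be named by sample id")

  ids <- intersect(names(trait), rownames(covariates))
  X <- as.matrix(covariates[ids, cols, drop = FALSE])
  y <- trait[ids]
  keep <- !is.na(y) & stats::complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]

  # drop constant columns (an all-zero covariate carries no information)
  const <- apply(X, 2L, function(v) stats::var(v) == 0)
  X <- X[, !const, drop = FALSE]
  D <- cbind(`(Intercept)` = 1, X)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    bad <- colnames(D)[qd$pivot[(qd$rank + 1L):ncol(D)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  r <- stats::setNames(qr.resid(qd, y), names(y))
  r
}

#' Per-SNP additive linear GWAS on residuals
#'
#' Simple linear regression of the residualized trait on alt-allele dosage
#' with an intercept, one SNP at a time (vectorized); two-sided p-values
#' from the t distribution with n - 2 degrees of freedom. Monomorphic SNPs
#' yield a record with NA effect and `undefined = TRUE`, never a silent
#' drop.
#'
#' @param residuals named numeric vector from [residualize()].
#' @param panel a `genotype_panel` (or list with `dosages` and `snps`).
#' @param snp_ids optional subset of SNPs to test.
#' @return An `assoc_table` data.frame: `snp_id`, `chr`, `pos`, `ea` (effect
#'   = alt allele), `oa`, `eaf`, `beta`, `se`, `p`, `n`, `undefined`.
#' @export
run_gwas <- function(residuals, panel, snp_ids = NULL) {
  ids <- intersect(names(residuals), rownames(panel$dosages))
  if (!length(ids)) stop("no overlapping samples between residuals and panel")
  y <- residuals[ids]
  snps <- panel$snps
  if (!is.null(snp_ids)) snps <- snps[match(snp_ids, snps$snp_id), , drop = FALSE]
  X <- panel$dosages[ids, snps$snp_id, drop = FALSE]

  n <- length(y)
  ybar <- mean(y)
  yc <- y - ybar
  xbar <- colMeans(X)
  Sxx <- colSums(X^2) - n * xbar^2
  Sxy <- as.numeric(crossprod(X, yc))
  Syy <- sum(yc^2)

  beta <- Sxy / Sxx
  rss <- Syy - beta^2 * Sxx
  rss[rss < 0] <- 0
  sigma2 <- rss / (n - 2L)
  se <- sqrt(sigma2 / Sxx)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - 2L, lower.tail = FALSE)

  undef <- Sxx <= 0 | !is.finite(beta)
  beta[undef] <- NA_real_; se[undef] <- NA_real_; p[undef] <- NA_real_

  out <- data.frame(snp_id = snps$snp_id, chr = snps$chr, pos = snps$pos,
                    ea = snps$alt, oa = snps$ref,
                    eaf = xbar / 2,
                    beta = beta, se = se, p = p, n = n,
                    undefined = undef,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Bonferroni significance configuration
#'
#' The genome-wide threshold is the base alpha divided by the number of
#' traits tested in the matrix (e.g. 5e-8 / 1296 plasma traits = 3.9e-11,
#' 5e-8 / 1401 urine traits = 3.6e-11 at two significant digits).
#'
#' @param n_traits number of traits tested in the matrix.
#' @param base_alpha genome-wide base level (default 5e-8).
#' @export
significance_config <- function(n_traits, base_alpha = 5e-8) {
  if (n_traits < 1) stop("n_traits must be >= 1")
  structure(list(base_alpha = base_alpha, n_traits = n_traits,
                 threshold = base_alpha / n_traits),
            class = "significance_config")
}

#' Keep genome-wide significant associations
#'
#' Strict comparison: records with `p < threshold`.
#'
#' @param table an `assoc_table`.
#' @param config a [significance_config()] (or bare numeric threshold).
#' @export
apply_threshold <- function(table, config) {
  thr <- if (inherits(config, "significance_config")) config$threshold else config
  table[!is.na(table$p) & table$p < thr, , drop = FALSE]
}

#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal quantiles via `qnorm((rank - 0.5)/n)`
#' with average ranks for ties; NAs are preserved in place.
#'
#' @param values numeric vector with at least two distinct non-NA values.
#' @export
inverse_normal_transform <- function(values) {
  obs <- !is.na(values)
  x <- values[obs]
  if (length(unique(x)) < 2L) stop("inverse-normal transform needs >= 2 distinct values")
  n <- length(x)
  out <- values
  out[obs] <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  out
}

#' SNP-by-sex interaction test at index SNPs
#'
#' Fits trait ~ dosage + sex + dosage:sex + covariates (the same adjustment
#' set as the main GWAS, with sex entering the interaction model rather than
#' the residualization) for each index SNP, and reports the interaction
#' p-value. mQTLs significant at `0.05 / n_mqtls` additionally get per-sex
#' stratified GWAS effects.
#'
#' @param index_snps character vector of SNP ids.
#' @param trait named numeric vector of log2 abundances.
#' @param covariates covariate data.frame (must include `sex`).
#' @param panel a `genotype_panel`.
#' @param matrix_label "plasma" or "urine".
#' @param n_mqtls total number of mQTLs tested (Bonferroni denominator).
#' @return data.frame: `snp_id`, `p_interaction`, `significant`,
#'   `beta_male`, `se_male`, `beta_female`, `se_female` (stratified columns
#'   NA unless significant). Here sex codes 1 = male stratum, 0 = female.
#' @export
test_sex_interaction <- function(index_snps, trait, covariates, panel,
                                 matrix_label = c("plasma", "urine"),
                                 n_mqtls = length(index_snps)) {
  matrix_label <- match.arg(matrix_label)
  ids <- intersect(names(trait), rownames(panel$dosages))
  ids <- intersect(ids, rownames(covariates))
  sex <- covariates[ids, "sex"]
  if (length(unique(stats::na.omit(sex))) < 2L)
    stop("both sexes must be present for the interaction test")
  thr <- 0.05 / n_mqtls

  cols <- c("age", "pc1", "pc2", "pc3")
  if (matrix_label == "plasma") cols <- c(cols, "ln_egfr", "albumin")
  Z <- as.matrix(covariates[ids, cols, drop = FALSE])

  res <- lapply(index_snps, function(s) {
    x <- panel$dosages[ids, s]
    y <- trait[ids]
    dat <- data.frame(y = y, x = x, sex = sex, Z)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    fit <- stats::lm(y ~ x * sex + ., data = dat[, c("y", "x", "sex", cols)])
    cf <- summary(fit)$coefficients
    p_int <- cf["x:sex", "Pr(>|t|)"]
    out <- data.frame(snp_id = s, p_interaction = p_int,
                      significant = p_int < thr,
                      beta_male = NA_real_, se_male = NA_real_,
                      beta_female = NA_real_, se_female = NA_real_,
                      stringsAsFactors = FALSE)
    if (out$significant) {
      for (lv in c(1, 0)) {
        sub <- dat[dat$sex == lv, , drop = FALSE]
        f2 <- stats::lm(y ~ x + ., data = sub[, c("y", "x", cols)])
        c2 <- summary(f2)$coefficients
        lab <- if (lv == 1) "male" else "female"
        out[[paste0("beta_", lab)]] <- c2["x", "Estimate"]
        out[[paste0("se_", lab)]] <- c2["x", "Std. Error"]
      }
    }
    out
  })
  do.call(rbind, res)
}
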