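#' Simulate an LD-blocked genotype panel
#'
#' Generates phased haplotypes for `n_samples` diploid individuals in
#' independent LD blocks. Within a block every haplotype is built by a
#' copying chain along the sites: the first site is drawn from the block
#' allele frequency, and each subsequent site copies the previous site's
#' allele with probability `sqrt(r2)` (the block's LD target) or is redrawn
#' from the block frequency otherwise. Adjacent sites therefore reach the
#' target dosage r-squared and LD decays geometrically with marker distance;
#' blocks are mutually independent. Dosages are the sums of the two
#' haplotypes, so the haplotype/dosage consistency invariant holds exactly.
#'
#' @param n_samples number of diploid samples (>= 2).
#' @param block_spec list of blocks, each a list/vector with elements
#'   `n_snps` (sites in the block), `r2` (within-block adjacent-pair LD
#'   target in `[0,1]`) and `freq` (length-2 allele-frequency range in (0,1)
#'   from which the block frequency is drawn; a single value fixes it).
#' @param seed integer seed; the full panel is reproducible bit-exact.
#' @param chr chromosome label for all blocks (recycled over blocks).
#' @param start_bp position of the first SNP of the first block.
#' @param snp_spacing_bp distance between adjacent SNPs within a block.
#' @param block_gap_bp gap between the last SNP of a block and the first of
#'   the next.
#' @param imputation_quality per-SNP imputation r-squared to record
#'   (recycled); the generator itself emits exact genotypes.
#'
#' @return A `genotype_panel`: list with `sample_ids`, `snps` (data.frame:
#'   `snp_id`, `chr`, `pos`, `ref`, `alt`, `alt_freq`, `imp_quality`),
#'   `dosages` (n x M matrix in `[0,2]`) and `haplotypes` (2n x M binary,
#'   rows `<sample>_h1`/`<sample>_h2`). `alt_freq` is the realized
#'   frequency, i.e. mean dosage / 2.
#' @export
simulate_genotypes <- function(n_samples, block_spec, seed,
                               chr = "1", start_bp = 1e6L,
                               snp_spacing_bp = 2000L, block_gap_bp = 200000L,
                               imputation_quality = 1) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2)
    stop("n_samples must be a single count >= 2")
  if (!length(block_spec)) stop("block_spec must contain at least one block")
  set.seed(as.integer(seed))
  chr <- rep_len(as.character(chr), length(block_spec))

  n_hap <- 2L * as.integer(n_samples)
  hap_cols <- list(); snp_rows <- list()
  pos <- as.integer(start_bp); snp_idx <- 0L

  for (b in seq_along(block_spec)) {
    bl <- block_spec[[b]]
    m <- as.integer(bl$n_snps %||% bl[[1L]])
    r2 <- as.numeric(bl$r2 %||% bl[[2L]])
    fr <- as.numeric(bl$freq %||% bl[[3L]])
    if (m < 1L) stop("block n_snps must be positive")
    if (r2 < 0 || r2 > 1) stop("block r2 target must be in [0,1]")
    if (any(fr <= 0) || any(fr >= 1)) stop("block frequencies must be in (0,1)")
    p <- if (length(fr) == 1L) fr else stats::runif(1L, fr[1L], fr[2L])
    copy_prob <- sqrt(r2)

    h <- matrix(0L, nrow = n_hap, ncol = m)
    h[, 1L] <- stats::rbinom(n_hap, 1L, p)
    if (m > 1L) for (j in 2:m) {
      keep <- stats::runif(n_hap) < copy_prob
      h[, j] <- ifelse(keep, h[, j - 1L], stats::rbinom(n_hap, 1L, p))
    }
    hap_cols[[b]] <- h
    snp_rows[[b]] <- data.frame(
      snp_id = sprintf("snp_%d_%d", b, seq_len(m)),
      chr = chr[b],
      pos = pos + (seq_len(m) - 1L) * as.integer(snp_spacing_bp),
      ref = "A", alt = "G",
      stringsAsFactors = FALSE)
    pos <- pos + (m - 1L) * as.integer(snp_spacing_bp) + as.integer(block_gap_bp)
    snp_idx <- snp_idx + m
  }

  haplotypes <- do.call(cbind, hap_cols)
  snps <- do.call(rbind, snp_rows)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  rownames(haplotypes) <- paste0(rep(sample_ids, each = 2L), c("_h1", "_h2"))
  colnames(haplotypes) <- snps$snp_id
  dosages <- haplotypes[seq(1L, n_hap, by = 2L), , drop = FALSE] +
    haplotypes[seq(2L, n_hap, by = 2L), , drop = FALSE]
  rownames(dosages) <- sample_ids
  snps$alt_freq <- colMeans(dosages) / 2
  snps$imp_quality <- rep_len(imputation_quality, nrow(snps))

  structure(list(sample_ids = sample_ids, snps = snps,
                 dosages = dosages, haplotypes = haplotypes),
            class = "genotype_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d SNPs (%s)\n",
              length(x$sample_ids), nrow(x$snps),
              if (is.null(x$haplotypes)) "unphased" else "phased"))
  invisible(x)
}

#' Simulate covariates for a synthetic cohort
#'
#' Age, sex (0/1), three genetic principal-component stand-ins, eGFR
#' (ml/min/1.73m2, log-normal around ~45 as in a CKD cohort) and serum
#' albumin (g/l). These are stand-ins, not derived from the genotypes.
#'
#' @param sample_ids character vector of sample ids.
#' @param seed integer seed.
#' @return data.frame with rownames = sample ids and columns `age`, `sex`,
#'   `pc1`..`pc3`, `egfr`, `ln_egfr`, `albumin`.
#' @export
simulate_covariates <- function(sample_ids, seed) {
  set.seed(as.integer(seed))
  n <- length(sample_ids)
  egfr <- exp(stats::rnorm(n, log(45), 0.35))
  out <- data.frame(
    age = round(stats::rnorm(n, 60, 12)),
    sex = stats::rbinom(n, 1L, 0.4),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n),
    egfr = egfr, ln_egfr = log(egfr),
    albumin = stats::rnorm(n, 38, 4),
    row.names = sample_ids)
  out
}

#' Construct an effect plan for the metabolome generator
#'
#' @param effects data.frame with columns `snp_id`, `metabolite`,
#'   `matrix` (one of "plasma", "urine", "both"), `beta` (effect per alt
#'   allele on the log2 scale) and optionally `beta_sex` (additional effect
#'   per alt allele in samples with `sex == 1`; default 0).
#' @param metabolites character vector of all metabolite names (must include
#'   every planted metabolite); metabolites without planted effects are pure
#'   covariate + noise traits.
#' @param h2_targets named numeric vector in `[0,1)`: per-metabolite target
#'   for the fraction of (pre-dilution, log2-scale) variance explained by the
#'   planted SNPs. Metabolites with planted effects but no target get the
#'   noise s.d. `noise_sd`.
#' @param dilution_sdlog s.d. of the log-normal per-sample urine dilution
#'   factor (meanlog 0, so the median factor is 1). The default 0.8
#'   reflects the wide concentration range of spot urine (roughly a
#'   20-fold 95% range, as seen for urinary creatinine).
#' @param missing_rate missing-at-random per-cell dropout rate; scalar or
#'   one value per metabolite (recycled, in `metabolites` order).
#' @param noise_sd residual s.d. on the log2 scale when no heritability
#'   target is given.
#' @param covariate_betas named numeric vector giving, per covariate, the
#'   s.d. of the per-metabolite effect on the log2 scale (each metabolite
#'   draws its own coefficient, centered at zero, as covariate effects on
#'   real metabolomes differ in sign and size between metabolites);
#'   defaults make age and sex non-trivial so residualization matters.
#' @return An `effect_plan` list.
#' @export
effect_plan <- function(effects, metabolites,
                        h2_targets = NULL,
                        dilution_sdlog = 0.8,
                        missing_rate = 0.05,
                        noise_sd = 1,
                        covariate_betas = c(age = 0.01, sex = 0.25)) {
  effects <- as.data.frame(effects)
  if (nrow(effects)) {
    need <- c("snp_id", "metabolite", "matrix", "beta")
    if (!all(need %in% names(effects)))
      stop("effects needs columns: ", paste(need, collapse = ", "))
    if (!all(effects$matrix %in% c("plasma", "urine", "both")))
      stop("effect matrix must be plasma, urine or both")
    if (is.null(effects$beta_sex)) effects$beta_sex <- 0
    if (!all(effects$metabolite %in% metabolites))
      stop("planted metabolites missing from `metabolites`")
  } else {
    effects <- data.frame(snp_id = character(), metabolite = character(),
                          matrix = character(), beta = numeric(),
                          beta_sex = numeric())
  }
  if (!is.null(h2_targets)) {
    if (any(h2_targets < 0 | h2_targets >= 1))
      stop("heritability targets must lie in [0, 1)")
    if (is.null(names(h2_targets)) || !all(names(h2_targets) %in% metabolites))
      stop("h2_targets must be named by metabolite")
  }
  structure(list(effects = effects, metabolites = metabolites,
                 h2_targets = h2_targets,
                 dilution_sdlog = dilution_sdlog,
                 missing_rate = rep_len(missing_rate, length(metabolites)),
                 noise_sd = noise_sd,
                 covariate_betas = covariate_betas),
            class = "effect_plan")
}

#' Simulate paired plasma/urine metabolomes with a truth table
#'
#' Log2-scale abundance is intercept + sum(dosage x effect) + covariate
#' effects + Gaussian noise; when a heritability target is set for a
#' metabolite the noise variance is chosen from the realized genetic-value
#' variance so that var(g)/var(g + e) equals the target. Values are returned
#' on the raw abundance scale (2^log2). Urine values are then multiplied by
#' a per-sample log-normal dilution factor (median 1) and missing-at-random
#' dropout is applied to both matrices.
#'
#' @param panel a `genotype_panel`.
#' @param plan an [effect_plan()].
#' @param covariates data.frame from [simulate_covariates()] (rownames must
#'   cover the panel samples).
#' @param seed integer seed.
#' @return list with `plasma` and `urine` (each a `metabolite_matrix`:
#'   list(values = sample x metabolite raw-abundance matrix, matrix =
#'   label)), `truth` (data.frame of every planted mQTL: snp_id, metabolite,
#'   matrix, beta, beta_sex, h2_target), and `dilution` (named per-sample
#'   urine factor).
#' @export
simulate_metabolomes <- function(panel, plan, covariates, seed) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(plan, "effect_plan"))
  miss_snp <- setdiff(plan$effects$snp_id, panel$snps$snp_id)
  if (length(miss_snp))
    stop("planted SNPs absent from panel: ", paste(miss_snp, collapse = ", "))
  if (!all(panel$sample_ids %in% rownames(covariates)))
    stop("covariates must cover all panel samples")
  set.seed(as.integer(seed))

  ids <- panel$sample_ids
  n <- length(ids)
  cov <- covariates[ids, , drop = FALSE]
  mets <- plan$metabolites

  # per-metabolite covariate coefficients: each metabolite responds to age,
  # sex, ... with its own (possibly opposite-sign) effect
  bad_cov <- setdiff(names(plan$covariate_betas), names(cov))
  if (length(bad_cov))
    stop("covariate_betas names unknown: ", paste(bad_cov, collapse = ", "))
  cov_coef <- sapply(names(plan$covariate_betas), function(nm)
    stats::rnorm(length(mets), 0, plan$covariate_betas[[nm]]))
  cov_coef <- matrix(cov_coef, nrow = length(mets),
                     dimnames = list(mets, names(plan$covariate_betas)))
  cov_vals <- as.matrix(cov[, names(plan$covariate_betas), drop = FALSE])

  make_matrix <- function(label) {
    vals <- matrix(NA_real_, n, length(mets), dimnames = list(ids, mets))
    for (k in seq_along(mets)) {
      m <- mets[k]
      cov_eff <- as.numeric(cov_vals %*% cov_coef[k, ])
      eff <- plan$effects[plan$effects$metabolite == m &
                            plan$effects$matrix %in% c(label, "both"), ,
                          drop = FALSE]
      g <- rep(0, n)
      if (nrow(eff)) {
        for (i in seq_len(nrow(eff))) {
          x <- panel$dosages[, eff$snp_id[i]]
          g <- g + eff$beta[i] * x + eff$beta_sex[i] * x * cov$sex
        }
      }
      h2 <- plan$h2_targets[m]
      sd_e <- if (!is.null(plan$h2_targets) && !is.na(h2) && length(h2) &&
                  stats::var(g) > 0 && h2 > 0) {
        sqrt(stats::var(g) * (1 - h2) / h2)
      } else plan$noise_sd
      vals[, k] <- 10 + g + cov_eff + stats::rnorm(n, 0, sd_e)
    }
    2^vals
  }

  plasma <- make_matrix("plasma")
  urine <- make_matrix("urine")

  dilution <- stats::setNames(
    exp(stats::rnorm(n, 0, plan$dilution_sdlog)), ids)
  urine <- urine * dilution

  drop_mask <- function(vals) {
    for (k in seq_len(ncol(vals))) {
      r <- plan$missing_rate[k]
      if (r > 0) vals[stats::runif(nrow(vals)) < r, k] <- NA_real_
    }
    vals
  }
  plasma <- drop_mask(plasma)
  urine <- drop_mask(urine)

  h2t <- if (is.null(plan$h2_targets)) rep(NA_real_, nrow(plan$effects)) else
    unname(plan$h2_targets[plan$effects$metabolite])
  truth <- cbind(plan$effects,
                 h2_target = if (nrow(plan$effects)) h2t else numeric())

  list(plasma = metabolite_matrix(plasma, "plasma"),
       urine = metabolite_matrix(urine, "urine"),
       truth = truth,
       dilution = dilution)
}

#' Construct a metabolite matrix container
#'
#' @param values sample x metabolite numeric matrix (raw abundances or log2,
#'   depending on pipeline stage); NAs mark missing measurements.
#' @param matrix_label "plasma" or "urine".
#' @export
metabolite_matrix <- function(values, matrix_label = c("plasma", "urine")) {
  matrix_label <- match.arg(matrix_label)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("metabolite matrix needs sample rownames and metabolite colnames")
  structure(list(values = values, matrix = matrix_label),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("metabolite_matrix [%s]: %d samples x %d metabolites (%.1f%% missing)\n",
              x$matrix, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}
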