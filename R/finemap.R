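#' Pairwise LD (r-squared) between SNPs in a panel
#'
#' @param panel a `genotype_panel`.
#' @param snp_ids SNPs to include.
#' @return symmetric matrix of squared Pearson correlations of dosages.
#' @export
ld_r2 <- function(panel, snp_ids) {
  miss <- setdiff(snp_ids, colnames(panel$dosages))
  if (length(miss)) stop("SNPs absent from panel: ", paste(miss, collapse = ", "))
  suppressWarnings(stats::cor(panel$dosages[, snp_ids, drop = FALSE]))^2
}

#' Stepwise conditional selection of independent signals
#'
#' Forward selection on individual-level data: start from the marginal lead
#' SNP; at each step refit a joint regression of the residualized trait on
#' all selected SNPs plus each remaining candidate (candidates in LD
#' r-squared above the collinearity cutoff with any selected SNP are
#' excluded) and add the candidate with the smallest conditional p-value if
#' it is below the threshold. Conditional statistics for every selected SNP
#' come from the final joint regression, i.e. conditioning on the other
#' selected SNPs in the region.
#'
#' @param region_snps character vector of SNP ids in the region.
#' @param residuals named residual vector (trait after covariate
#'   adjustment).
#' @param panel a `genotype_panel`.
#' @param threshold conditional significance threshold (strict `<`), or a
#'   [significance_config()].
#' @param collinearity LD r-squared cutoff for candidate exclusion
#'   (default 0.1).
#' @return data.frame of independent signals: `snp_id`, `beta_cond`,
#'   `se_cond`, `p_cond`, `beta_marg`, `se_marg`, `p_marg`, `step`. Zero
#'   rows when no SNP passes the threshold.
#' @export
stepwise_select <- function(region_snps, residuals, panel, threshold,
                            collinearity = 0.1) {
  if (!length(region_snps)) stop("region is empty")
  thr <- if (inherits(threshold, "significance_config")) threshold$threshold else threshold
  ids <- intersect(names(residuals), rownames(panel$dosages))
  y <- residuals[ids]
  X <- panel$dosages[ids, region_snps, drop = FALSE]
  n <- length(y)

  marg <- run_gwas(y, panel, snp_ids = region_snps)
  r2 <- suppressWarnings(stats::cor(X))^2

  selected <- character()
  repeat {
    cand <- setdiff(region_snps, selected)
    if (length(selected)) {
      ok <- vapply(cand, function(s)
        all(r2[s, selected] <= collinearity, na.rm = TRUE), logical(1L))
      cand <- cand[ok]
    }
    if (!length(cand)) break

    # FWL: regress y and each candidate on the selected set, then the
    # candidate's conditional t-test is a simple regression of residuals
    # with df = n - (#selected + 2)
    if (length(selected)) {
      qs <- qr(cbind(1, X[, selected, drop = FALSE]))
      my <- qr.resid(qs, y)
      mx <- qr.resid(qs, X[, cand, drop = FALSE])
    } else {
      my <- y - mean(y)
      mx <- sweep(X[, cand, drop = FALSE], 2L, colMeans(X[, cand, drop = FALSE]))
    }
    sxx <- colSums(mx^2)
    sxy <- as.numeric(crossprod(mx, my))
    b <- sxy / sxx
    df <- n - length(selected) - 2L
    rss <- sum(my^2) - b^2 * sxx
    rss[rss < 0] <- 0
    se <- sqrt(rss / df / sxx)
    p <- 2 * stats::pt(abs(b / se), df = df, lower.tail = FALSE)
    p[!is.finite(p)] <- 1

    best <- which.min(p)
    if (!length(best) || !(p[best] < thr)) break
    selected <- c(selected, cand[best])
  }

  if (!length(selected))
    return(data.frame(snp_id = character(), beta_cond = numeric(),
                      se_cond = numeric(), p_cond = numeric(),
                      beta_marg = numeric(), se_marg = numeric(),
                      p_marg = numeric(), step = integer()))

  fit <- stats::lm(y ~ X[, selected, drop = FALSE])
  cf <- summary(fit)$coefficients[-1L, , drop = FALSE]
  mi <- match(selected, marg$snp_id)
  data.frame(snp_id = selected,
             beta_cond = cf[, "Estimate"],
             se_cond = cf[, "Std. Error"],
             p_cond = cf[, "Pr(>|t|)"],
             beta_marg = marg$beta[mi],
             se_marg = marg$se[mi],
             p_marg = marg$p[mi],
             step = seq_along(selected),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Wakefield approximate Bayes factor
#'
#' With V the squared standard error, W the squared prior standard
#' deviation and z = effect/SE, the approximate Bayes factor in favor of
#' association is `sqrt(V/(V+W)) * exp(z^2 W / (2 (V+W)))`. Vectorized; use
#' `log = TRUE` for regions with very large z to avoid overflow.
#'
#' @param effect,se effect estimate(s) and standard error(s) (se > 0).
#' @param prior_sd prior standard deviation on the effect (default 1.33).
#' @param log return the natural log of the ABF.
#' @export
wakefield_abf <- function(effect, se, prior_sd = 1.33, log = FALSE) {
  if (any(!is.finite(se) | se <= 0)) stop("se must be positive and finite")
  V <- se^2
  W <- prior_sd^2
  z <- effect / se
  labf <- 0.5 * base::log(V / (V + W)) + z^2 * W / (2 * (V + W))
  if (log) labf else exp(labf)
}

#' Credible set from per-SNP Bayes factors
#'
#' Posterior probabilities of association (PPA) are the ABFs normalized
#' over the region (uniform prior across region SNPs). The credible set is
#' the minimal PPA-descending prefix whose cumulative PPA strictly exceeds
#' `level`.
#'
#' @param abf named numeric vector of ABFs (or log ABFs with
#'   `log = TRUE`); names are SNP ids.
#' @param level credible level (default 0.99).
#' @param log treat `abf` as natural-log Bayes factors (normalized via
#'   log-sum-exp; recommended for strong signals).
#' @return data.frame ordered by decreasing PPA: `snp_id`, `abf` (or
#'   `labf`), `ppa`, `cum_ppa`, `in_set`; attribute `set_size`.
#' @export
credible_set <- function(abf, level = 0.99, log = FALSE) {
  if (!length(abf)) stop("need at least one SNP")
  if (is.null(names(abf))) names(abf) <- paste0("snp", seq_along(abf))
  if (log) {
    if (any(!is.finite(abf))) stop("non-finite log ABFs")
    m <- max(abf)
    ppa <- exp(abf - m) / sum(exp(abf - m))
  } else {
    if (any(!is.finite(abf) | abf < 0)) stop("ABFs must be finite and non-negative")
    if (sum(abf) == 0) stop("all ABFs are zero")
    ppa <- abf / sum(abf)
  }
  ord <- order(-ppa, names(abf))
  ppa <- ppa[ord]
  cum <- cumsum(ppa)
  size <- unname(which(cum > level))[1L]
  if (is.na(size)) size <- length(ppa)  # numerical guard; cum sums to 1
  out <- data.frame(snp_id = names(ppa),
                    ppa = as.numeric(ppa),
                    cum_ppa = as.numeric(cum),
                    in_set = seq_along(ppa) <= size,
                    stringsAsFactors = FALSE)
  out[[if (log) "labf" else "abf"]] <- as.numeric(abf[ord])
  attr(out, "set_size") <- size
  out
}

#' Align fine-mapping regions across metabolites within a matrix
#'
#' Single-linkage grouping of mQTLs whose index SNPs are in LD (r-squared
#' strictly above the threshold); each group is fine-mapped over the union
#' of the member locus intervals.
#'
#' @param mqtls data.frame from [call_mqtls()] (possibly row-bound over
#'   traits of one matrix).
#' @param panel a `genotype_panel` containing every index SNP.
#' @param r2_threshold LD threshold for linking (default 0.8).
#' @return data.frame of merged regions: `region_id`, `chr`, `start`,
#'   `end`, plus list-columns `index_snps` and `mqtl_rows` (row indices of
#'   the member mQTLs).
#' @export
align_regions <- function(mqtls, panel, r2_threshold = 0.8) {
  if (!nrow(mqtls)) return(data.frame(region_id = integer(), chr = character(),
                                      start = numeric(), end = numeric()))
  idx <- mqtls$index_snp
  miss <- setdiff(idx, colnames(panel$dosages))
  if (length(miss)) stop("index SNPs absent from panel: ",
                         paste(miss, collapse = ", "))
  n <- nrow(mqtls)
  r2 <- ld_r2(panel, unique(idx))
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (mqtls$chr[i] == mqtls$chr[j] && r2[idx[i], idx[j]] > r2_threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  groups <- split(seq_len(n), roots)
  out <- do.call(rbind, lapply(seq_along(groups), function(g) {
    rows <- groups[[g]]
    data.frame(region_id = g, chr = mqtls$chr[rows[1L]],
               start = min(mqtls$start[rows]), end = max(mqtls$end[rows]),
               stringsAsFactors = FALSE)
  }))
  out$index_snps <- lapply(groups, function(rows) unique(idx[rows]))
  out$mqtl_rows <- unname(groups)
  rownames(out) <- NULL
  out
}

#' Fine-map an mQTL region
#'
#' Runs [stepwise_select()] and, per independent signal, computes Wakefield
#' ABFs and the >99% credible set. With a single signal the marginal
#' statistics are used; with multiple signals each SNP's ABF is derived
#' from effects conditioned on the other selected signals (each
#' non-selected region SNP is refit jointly with the other signals' lead
#' SNPs).
#'
#' @param region_snps SNP ids in the region.
#' @param residuals named residual vector.
#' @param panel a `genotype_panel`.
#' @param threshold conditional significance threshold.
#' @param prior_sd Wakefield prior s.d. (default 1.33).
#' @param collinearity stepwise LD cutoff.
#' @param level credible level.
#' @return list with `signals` (from [stepwise_select()]) and
#'   `credible_sets` (list of [credible_set()] frames, one per signal,
#'   named by the signal's lead SNP).
#' @export
finemap_region <- function(region_snps, residuals, panel, threshold,
                           prior_sd = 1.33, collinearity = 0.1,
                           level = 0.99) {
  sig <- stepwise_select(region_snps, residuals, panel, threshold,
                         collinearity)
  if (!nrow(sig)) return(list(signals = sig, credible_sets = list()))
  ids <- intersect(names(residuals), rownames(panel$dosages))
  y <- residuals[ids]
  X <- panel$dosages[ids, region_snps, drop = FALSE]
  n <- length(y)

  sets <- lapply(seq_len(nrow(sig)), function(k) {
    others <- sig$snp_id[-k]
    if (!length(others)) {
      marg <- run_gwas(y, panel, snp_ids = region_snps)
      keep <- !marg$undefined
      labf <- wakefield_abf(marg$beta[keep], marg$se[keep], prior_sd, log = TRUE)
      names(labf) <- marg$snp_id[keep]
    } else {
      qs <- qr(cbind(1, X[, others, drop = FALSE]))
      my <- qr.resid(qs, y)
      cand <- setdiff(region_snps, others)
      mx <- qr.resid(qs, X[, cand, drop = FALSE])
      sxx <- colSums(mx^2)
      ok <- sxx > 1e-12
      b <- sxy_over <- as.numeric(crossprod(mx, my)) / sxx
      df <- n - length(others) - 2L
      rss <- sum(my^2) - b^2 * sxx
      rss[rss < 0] <- 0
      se <- sqrt(rss / df / sxx)
      labf <- wakefield_abf(b[ok], se[ok], prior_sd, log = TRUE)
      names(labf) <- cand[ok]
    }
    credible_set(labf, level = level, log = TRUE)
  })
  names(sets) <- sig$snp_id
  list(signals = sig, credible_sets = sets)
}
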