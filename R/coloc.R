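logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, numerically safe
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Pairwise Bayesian colocalization of two association tables
#'
#' Enumerates, over the shared SNPs of a region, the five hypotheses of a
#' single-causal-variant colocalization model: no association (H0),
#' association with trait A only (H1), with B only (H2), two distinct
#' causal variants (H3) and one shared causal variant (H4). Per-SNP
#' evidence is the Wakefield approximate Bayes factor for each trait;
#' configuration sums are combined with the per-SNP priors `p1`, `p2`,
#' `p12` in log space and normalized.
#'
#' SNPs are matched by id; when both tables carry `ea`/`oa` columns,
#' records whose alleles are swapped between tables have the B effect
#' flipped, and records whose alleles do not match at all are dropped with
#' a message.
#'
#' @param stats_a,stats_b `assoc_table` slices covering the region (need
#'   `snp_id`, `beta`, `se`; optionally `ea`, `oa`).
#' @param p1,p2,p12 prior probabilities that a SNP is causal for A only, B
#'   only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd per-trait Wakefield prior s.d. used inside the
#'   colocalization (default 0.15, on residual-scale effects).
#' @param trait_a,matrix_a,trait_b,matrix_b labels carried into the result.
#' @return A `coloc_result`: list with `pp` (named H0..H4, summing to 1),
#'   `n_snps`, `pair` (labels) and `group` (four-group label from
#'   [classify_coloc_pair()], or "mqtl_vs_external" when `matrix_b` is
#'   "external").
#' @export
coloc_abf <- function(stats_a, stats_b, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd = 0.15,
                      trait_a = "traitA", matrix_a = "plasma",
                      trait_b = "traitB", matrix_b = "urine") {
  a <- stats_a[!is.na(stats_a$beta) & !is.na(stats_a$se) & stats_a$se > 0, ]
  b <- stats_b[!is.na(stats_b$beta) & !is.na(stats_b$se) & stats_b$se > 0, ]
  shared <- intersect(a$snp_id, b$snp_id)
  if (!length(shared)) stop("no shared SNPs between the two tables")
  a <- a[match(shared, a$snp_id), ]
  b <- b[match(shared, b$snp_id), ]

  if (all(c("ea", "oa") %in% names(a)) && all(c("ea", "oa") %in% names(b))) {
    same <- a$ea == b$ea & a$oa == b$oa
    flip <- a$ea == b$oa & a$oa == b$ea
    bad <- !same & !flip
    if (any(flip)) b$beta[flip] <- -b$beta[flip]
    if (any(bad)) {
      message(sum(bad), " SNP(s) dropped for allele mismatch")
      keep <- !bad
      a <- a[keep, ]; b <- b[keep, ]
      if (!nrow(a)) stop("no shared SNPs after allele matching")
    }
  }

  la <- wakefield_abf(a$beta, a$se, prior_sd, log = TRUE)
  lb <- wakefield_abf(b$beta, b$se, prior_sd, log = TRUE)

  s1 <- logsumexp(la)                    # sum_i BF_A(i)
  s2 <- logsumexp(lb)                    # sum_j BF_B(j)
  s12 <- logsumexp(la + lb)              # sum_i BF_A(i) BF_B(i)
  s3 <- logdiff(s1 + s2, s12)            # sum_{i != j} BF_A(i) BF_B(j)

  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + s3,
          H4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)

  pair <- list(trait_a = trait_a, matrix_a = matrix_a,
               trait_b = trait_b, matrix_b = matrix_b)
  group <- if (matrix_b == "external" || matrix_a == "external")
    "mqtl_vs_external" else classify_coloc_pair(pair)
  structure(list(pp = pp, n_snps = length(la), pair = pair, group = group),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result [%s]: %s/%s vs %s/%s over %d SNPs\n",
              x$group, x$pair$trait_a, x$pair$matrix_a,
              x$pair$trait_b, x$pair$matrix_b, x$n_snps))
  print(round(x$pp, 4))
  invisible(x)
}

#' Pair mQTLs whose index windows overlap
#'
#' All unordered pairs of mQTLs (across both matrices) whose +/- `half_bp`
#' windows around the index SNPs share at least one base pair on the same
#' chromosome; the colocalization region is the union of the two windows.
#'
#' @param mqtls data.frame of mQTLs (rows from [call_mqtls()], possibly
#'   row-bound across traits/matrices).
#' @param half_bp half-window (default 500 kb).
#' @return data.frame: `row_a`, `row_b` (row indices into `mqtls`), `chr`,
#'   `start`, `end`.
#' @export
pair_mqtls <- function(mqtls, half_bp = 5e5) {
  n <- nrow(mqtls)
  out <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (mqtls$chr[i] != mqtls$chr[j]) next
    if (abs(mqtls$index_pos[i] - mqtls$index_pos[j]) > 2 * half_bp) next
    out[[length(out) + 1L]] <- data.frame(
      row_a = i, row_b = j, chr = mqtls$chr[i],
      start = max(1, min(mqtls$index_pos[i], mqtls$index_pos[j]) - half_bp),
      end = max(mqtls$index_pos[i], mqtls$index_pos[j]) + half_bp)
  }
  if (!length(out))
    return(data.frame(row_a = integer(), row_b = integer(),
                      chr = character(), start = numeric(), end = numeric()))
  do.call(rbind, out)
}

#' Classify a colocalizing mQTL pair
#'
#' Four-group labels: `intraplasma`, `intraurine`,
#' `intermatrix_same_metabolite`, `intermatrix_different_metabolite`.
#'
#' @param pair list with `trait_a`, `matrix_a`, `trait_b`, `matrix_b`.
#' @export
classify_coloc_pair <- function(pair) {
  if (pair$matrix_a == pair$matrix_b)
    return(paste0("intra", pair$matrix_a))
  if (pair$trait_a == pair$trait_b)
    "intermatrix_same_metabolite" else "intermatrix_different_metabolite"
}

#' Trigger-gated colocalization with an external trait
#'
#' Colocalization against an external association table (phenotype, eQTL or
#' pQTL summary statistics) is run over the index +/- `coloc_half_bp`
#' window only when the external trait has at least one variant with
#' MAF > `maf_min` and p below `0.05 / n_index` within
#' +/- `trigger_half_bp` of the index SNP. Variants with missing MAF are
#' ineligible for the trigger.
#'
#' @param mqtl one mQTL row (needs `index_pos`, `chr`, `trait`, `matrix`).
#' @param mqtl_stats `assoc_table` for the mQTL's trait covering the region.
#' @param external_stats external table (`snp_id`, `chr`, `pos`, `beta`,
#'   `se`, `p`; `eaf` or `maf` used for the MAF gate).
#' @param n_index Bonferroni denominator for the trigger threshold (the
#'   number of unique index SNPs in the matrix, e.g. 409 plasma / 410
#'   urine).
#' @param maf_min trigger MAF gate (default 0.01).
#' @param trigger_half_bp,coloc_half_bp windows (defaults 100 kb, 500 kb).
#' @param ... passed to [coloc_abf()].
#' @return a `coloc_result`, or NULL when not triggered.
#' @export
external_coloc_trigger <- function(mqtl, mqtl_stats, external_stats,
                                   n_index = 409, maf_min = 0.01,
                                   trigger_half_bp = 1e5,
                                   coloc_half_bp = 5e5, ...) {
  thr <- 0.05 / n_index
  ext <- external_stats
  maf <- if (!is.null(ext$maf)) ext$maf else pmin(ext$eaf, 1 - ext$eaf)
  if (is.null(maf)) stop("external stats need a maf or eaf column")
  near <- ext$chr == mqtl$chr & abs(ext$pos - mqtl$index_pos) <= trigger_half_bp
  elig <- near & !is.na(maf) & maf > maf_min & !is.na(ext$p)
  if (any(is.na(maf) & near))
    message("external variants with missing MAF ineligible for trigger: ",
            sum(is.na(maf) & near))
  if (!any(elig & ext$p < thr)) return(NULL)

  reg_a <- mqtl_stats[mqtl_stats$chr == mqtl$chr &
                        abs(mqtl_stats$pos - mqtl$index_pos) <= coloc_half_bp, ]
  reg_b <- ext[ext$chr == mqtl$chr &
                 abs(ext$pos - mqtl$index_pos) <= coloc_half_bp, ]
  coloc_abf(reg_a, reg_b,
            trait_a = mqtl$trait, matrix_a = mqtl$matrix,
            trait_b = attr(external_stats, "trait") %||% "external",
            matrix_b = "external", ...)
}
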