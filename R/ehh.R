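#' Extended haplotype homozygosity curve around a core SNP
#'
#' For the haplotypes carrying `core_allele` at the core SNP, EHH at a
#' flanking marker x is the fraction of carrier haplotype pairs that are
#' identical at every marker from the core through x inclusive, out of
#' C(n, 2) pairs. Computed separately to the left and right of the core by
#' partition refinement (carrier groups are split at each successive
#' marker), which makes the curve monotone non-increasing with distance by
#' construction. Haplotypes with a missing call on a side (within the span)
#' are dropped for that side.
#'
#' @param haplotypes 2n x M binary matrix of phased haplotypes (columns =
#'   markers in position order), or a `genotype_panel`.
#' @param positions marker positions in bp (taken from the panel when one
#'   is supplied).
#' @param core core marker: column index or SNP id.
#' @param core_allele allele (0/1) defining the carrier haplotypes.
#' @param max_span_bp maximum distance from the core to include (default
#'   Inf).
#' @return data.frame: `pos`, `marker`, `side` ("core"/"left"/"right"),
#'   `ehh`; attributes `n_carriers_left`/`n_carriers_right`.
#' @export
ehh_curve <- function(haplotypes, core, core_allele = 1, positions = NULL,
                      max_span_bp = Inf) {
  if (inherits(haplotypes, "genotype_panel")) {
    positions <- haplotypes$snps$pos
    haplotypes <- haplotypes$haplotypes
  }
  if (is.null(positions)) stop("marker positions are required")
  if (is.character(core)) core <- match(core, colnames(haplotypes))
  if (is.na(core) || core < 1L || core > ncol(haplotypes))
    stop("core marker not found")
  carriers <- which(!is.na(haplotypes[, core]) &
                      haplotypes[, core] == core_allele)
  if (length(carriers) < 2L)
    stop("need at least 2 carrier haplotypes of the core allele")

  core_pos <- positions[core]
  side_curve <- function(marker_idx) {
    # marker_idx: markers ordered moving away from the core
    H <- haplotypes[carriers, marker_idx, drop = FALSE]
    ok <- rowSums(is.na(H)) == 0L
    if (any(!ok))
      message(sum(!ok), " haplotype(s) dropped for missing calls on one side")
    H <- H[ok, , drop = FALSE]
    n <- nrow(H)
    if (n < 2L) return(list(ehh = rep(NA_real_, length(marker_idx)), n = n))
    denom <- choose(n, 2L)
    grp <- rep(1L, n)
    ehh <- numeric(length(marker_idx))
    for (k in seq_along(marker_idx)) {
      grp <- as.integer(factor(paste(grp, H[, k])))
      sizes <- tabulate(grp)
      ehh[k] <- sum(choose(sizes, 2L)) / denom
    }
    list(ehh = ehh, n = n)
  }

  right_idx <- which(seq_along(positions) > core &
                       positions - core_pos <= max_span_bp)
  left_idx <- rev(which(seq_along(positions) < core &
                          core_pos - positions <= max_span_bp))
  r <- side_curve(right_idx)
  l <- side_curve(left_idx)

  out <- rbind(
    data.frame(pos = positions[left_idx], marker = left_idx,
               side = rep("left", length(left_idx)), ehh = l$ehh),
    data.frame(pos = core_pos, marker = core, side = "core", ehh = 1),
    data.frame(pos = positions[right_idx], marker = right_idx,
               side = rep("right", length(right_idx)), ehh = r$ehh))
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_carriers_left") <- l$n
  attr(out, "n_carriers_right") <- r$n
  attr(out, "core_allele") <- core_allele
  out
}

#' Compare EHH decay between derived and ancestral core alleles
#'
#' Computes the EHH curve for each allele at the core SNP and the ratio of
#' their integrated EHH (trapezoid rule over bp along the full curve).
#' Under a recent positive sweep the derived-allele haplotype retains
#' homozygosity further from the core, giving a ratio above 1.
#'
#' @param haplotypes phased binary matrix or `genotype_panel`.
#' @param core core marker index or SNP id.
#' @param derived_allele allele treated as derived (default 1); the other
#'   allele is ancestral.
#' @param positions marker positions (taken from the panel if supplied).
#' @param max_span_bp span limit.
#' @return list: `derived`, `ancestral` (curves from [ehh_curve()]),
#'   `iehh_derived`, `iehh_ancestral` (bp), `ratio`.
#' @export
compare_alleles <- function(haplotypes, core, derived_allele = 1,
                            positions = NULL, max_span_bp = Inf) {
  if (inherits(haplotypes, "genotype_panel")) {
    positions <- haplotypes$snps$pos
    haplotypes <- haplotypes$haplotypes
  }
  ci <- if (is.character(core)) match(core, colnames(haplotypes)) else core
  al <- stats::na.omit(unique(haplotypes[, ci]))
  if (length(al) < 2L) stop("core SNP is monomorphic")
  anc <- setdiff(al, derived_allele)[1L]
  der <- ehh_curve(haplotypes, core, derived_allele, positions, max_span_bp)
  anc_c <- ehh_curve(haplotypes, core, anc, positions, max_span_bp)
  trap <- function(curve) {
    cv <- curve[!is.na(curve$ehh), ]
    if (nrow(cv) < 2L) return(0)
    sum(diff(cv$pos) * (utils::head(cv$ehh, -1L) + utils::tail(cv$ehh, -1L)) / 2)
  }
  i_d <- trap(der); i_a <- trap(anc_c)
  list(derived = der, ancestral = anc_c,
       iehh_derived = i_d, iehh_ancestral = i_a,
       ratio = if (i_a > 0) i_d / i_a else NA_real_)
}
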