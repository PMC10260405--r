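#' Call metabolite QTLs from an association table
#'
#' Iterative peak picking over genome-wide significant SNPs: pick the
#' unassigned SNP with the lowest p-value (ties by smaller position, then
#' lexicographic SNP id), assign every significant SNP on the same
#' chromosome within half a window of it to that locus, and repeat until no
#' significant SNP remains. Loci whose index SNP falls in the extended MHC
#' region are collapsed into one region regardless of spacing. Finally,
#' overlapping intervals for the trait are merged into a single mQTL whose
#' index SNP is re-selected as the lowest-p member of the union. Intervals
#' are `[pos - window/2, pos + window/2]`, 1-based inclusive, clipped at 1.
#'
#' @param table an `assoc_table` for one trait.
#' @param threshold significance threshold (strict `<`), or a
#'   [significance_config()].
#' @param window_bp locus window (default 1 Mb, i.e. +/- 500 kb).
#' @param mhc list(chr, start, end) for the extended MHC
#'   (default chr6:25.5-34 Mb); NULL disables collapsing.
#' @param trait,matrix_label labels carried into the output.
#' @return data.frame of mQTLs: `trait`, `matrix`, `index_snp`, `chr`,
#'   `index_pos`, `p`, `beta`, `se`, `eaf`, `start`, `end`, `n_members`,
#'   plus a list-column `members` of member SNP ids.
#' @export
call_mqtls <- function(table, threshold, window_bp = 1e6,
                       mhc = list(chr = "6", start = 25.5e6, end = 34e6),
                       trait = "trait", matrix_label = "plasma") {
  thr <- if (inherits(threshold, "significance_config")) threshold$threshold else threshold
  sig <- table[!is.na(table$p) & table$p < thr, , drop = FALSE]
  empty <- data.frame(trait = character(), matrix = character(),
                      index_snp = character(), chr = character(),
                      index_pos = numeric(), p = numeric(), beta = numeric(),
                      se = numeric(), eaf = numeric(), start = numeric(),
                      end = numeric(), n_members = integer())
  empty$members <- list()
  if (!nrow(sig)) return(empty)

  half <- window_bp / 2
  # deterministic tie-break order: p, then position, then id
  sig <- sig[order(sig$p, sig$pos, sig$snp_id), , drop = FALSE]
  assigned <- rep(FALSE, nrow(sig))
  loci <- list()
  while (!all(assigned)) {
    i <- which(!assigned)[1L]
    idx <- sig[i, ]
    mem <- !assigned & sig$chr == idx$chr & abs(sig$pos - idx$pos) <= half
    loci[[length(loci) + 1L]] <- list(
      index = idx, members = sig[mem, , drop = FALSE],
      start = max(1, idx$pos - half), end = idx$pos + half)
    assigned[mem] <- TRUE
  }

  if (!is.null(mhc)) {
    in_mhc <- vapply(loci, function(l)
      l$index$chr == mhc$chr && l$index$pos >= mhc$start &&
        l$index$pos <= mhc$end, logical(1L))
    if (sum(in_mhc) > 1L) {
      grp <- loci[in_mhc]
      members <- do.call(rbind, lapply(grp, `[[`, "members"))
      members <- members[order(members$p, members$pos, members$snp_id), ]
      merged <- list(index = members[1L, ],
                     members = members,
                     start = min(vapply(grp, `[[`, numeric(1L), "start")),
                     end = max(vapply(grp, `[[`, numeric(1L), "end")))
      loci <- c(loci[!in_mhc], list(merged))
    }
  }

  # merge overlapping intervals per chromosome (shared base pair counts)
  merged <- list()
  for (ch in unique(vapply(loci, function(l) l$index$chr, character(1L)))) {
    ll <- loci[vapply(loci, function(l) l$index$chr == ch, logical(1L))]
    ll <- ll[order(vapply(ll, `[[`, numeric(1L), "start"))]
    cur <- ll[[1L]]
    flush <- function(x) merged[[length(merged) + 1L]] <<- x
    if (length(ll) > 1L) for (k in 2:length(ll)) {
      nxt <- ll[[k]]
      if (nxt$start <= cur$end) {
        members <- rbind(cur$members, nxt$members)
        members <- members[order(members$p, members$pos, members$snp_id), ]
        cur <- list(index = members[1L, ], members = members,
                    start = min(cur$start, nxt$start),
                    end = max(cur$end, nxt$end))
      } else {
        flush(cur); cur <- nxt
      }
    }
    flush(cur)
  }

  out <- do.call(rbind, lapply(merged, function(l) {
    data.frame(trait = trait, matrix = matrix_label,
               index_snp = l$index$snp_id, chr = l$index$chr,
               index_pos = l$index$pos, p = l$index$p,
               beta = l$index$beta, se = l$index$se, eaf = l$index$eaf,
               start = l$start, end = l$end,
               n_members = nrow(l$members),
               stringsAsFactors = FALSE)
  }))
  out$members <- lapply(merged, function(l) l$members$snp_id)
  out <- out[order(out$chr, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rare-variant robustness check for an mQTL
#'
#' mQTLs whose index SNP has MAF below the cutoff are only kept if the
#' association remains significant after an inverse-normal transform of the
#' metabolite values (guarding rare-allele signals against being driven by
#' outlying trait values). Common-variant mQTLs are kept unconditionally.
#'
#' @param mqtl one row of the [call_mqtls()] output.
#' @param trait named log2 abundance vector (pre-residualization).
#' @param covariates covariate data.frame.
#' @param panel a `genotype_panel`.
#' @param threshold significance threshold for the re-test.
#' @param matrix_label "plasma" or "urine".
#' @param maf_cutoff MAF gate (default 0.03).
#' @return list(keep = logical, maf, p_int = re-test p or NA if not run).
#' @export
rare_variant_check <- function(mqtl, trait, covariates, panel, threshold,
                               matrix_label = c("plasma", "urine"),
                               maf_cutoff = 0.03) {
  matrix_label <- match.arg(matrix_label)
  thr <- if (inherits(threshold, "significance_config")) threshold$threshold else threshold
  eaf <- mqtl$eaf
  maf <- min(eaf, 1 - eaf)
  if (is.na(maf)) stop("index SNP MAF not computable")
  if (maf >= maf_cutoff)
    return(list(keep = TRUE, maf = maf, p_int = NA_real_))
  y_int <- inverse_normal_transform(trait)
  r <- residualize(y_int, covariates, matrix_label)
  tab <- run_gwas(r, panel, snp_ids = mqtl$index_snp)
  list(keep = !is.na(tab$p) && tab$p < thr, maf = maf, p_int = tab$p)
}

#' Variance in a trait explained by an index SNP
#'
#' Squared Pearson correlation between dosage and log2 trait values over
#' complete pairs, computed independently of any covariates.
#'
#' @param dosage numeric dosage vector.
#' @param trait numeric log2 trait vector (same order/length).
#' @return fraction in `[0,1]`, or NA if either input has zero variance.
#' @export
variance_explained <- function(dosage, trait) {
  keep <- !is.na(dosage) & !is.na(trait)
  x <- dosage[keep]; y <- trait[keep]
  if (length(x) < 3L || stats::var(x) == 0 || stats::var(y) == 0)
    return(NA_real_)
  stats::cor(x, y)^2
}
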