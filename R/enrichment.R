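#' Build matching strata from gene annotation
#'
#' Assigns each universe gene to the stratum (decile of independent-SNP
#' count) x (decile of gene length). Deciles are computed over the universe
#' with `ties.method = "min"` ranks so every gene lands in exactly one of
#' 1..10 per dimension.
#'
#' @param annotation data.frame: `gene`, `n_independent_snps`,
#'   `gene_length`.
#' @return named character vector: stratum id ("d<snp>_l<len>") per gene.
#' @export
matching_strata <- function(annotation) {
  dec <- function(x) {
    r <- rank(x, ties.method = "min")
    pmin(10L, 1L + as.integer(10 * (r - 1L) / length(x)))
  }
  stats::setNames(sprintf("d%d_l%d",
                          dec(annotation$n_independent_snps),
                          dec(annotation$gene_length)),
                  annotation$gene)
}

#' Matched-permutation over-representation test
#'
#' Draws random gene lists matched to the source list within strata
#' (same number of genes drawn, without replacement, from every stratum the
#' source occupies) and compares the overlap with the annotation set to the
#' observed overlap. Per draw, the within-stratum overlap count is sampled
#' from the corresponding hypergeometric distribution, which is
#' distributionally identical to drawing gene identities. The empirical
#' p-value uses add-one smoothing: `(1 + #{draws >= observed}) / (1 + n)`.
#'
#' @param source character vector of source genes (subset of the universe).
#' @param set character vector, the annotation gene set.
#' @param universe character vector of all genes.
#' @param strata named stratum id per universe gene (see
#'   [matching_strata()]); NULL treats the universe as one stratum.
#' @param n_draws number of random draws (default 1e5).
#' @param seed integer seed.
#' @return list: `observed`, `expected` (mean null overlap), `fold`,
#'   `p_empirical`, `n_draws`.
#' @export
matched_permutation_test <- function(source, set, universe, strata = NULL,
                                     n_draws = 1e5, seed = 1) {
  if (!all(source %in% universe)) stop("source must be a subset of the universe")
  if (is.null(strata))
    strata <- stats::setNames(rep("all", length(universe)), universe)
  if (!all(universe %in% names(strata))) stop("strata must cover the universe")
  set.seed(as.integer(seed))
  set <- intersect(set, universe)
  observed <- length(intersect(source, set))

  src_str <- table(strata[source])
  null <- numeric(n_draws)
  for (st in names(src_str)) {
    uni_st <- universe[strata[universe] == st]
    k <- as.integer(src_str[[st]])
    m <- length(intersect(uni_st, set))     # set genes in the stratum
    nn <- length(uni_st) - m
    if (k > length(uni_st))
      stop("unsatisfiable stratum (source larger than universe): ", st)
    null <- null + stats::rhyper(n_draws, m, nn, k)
  }
  expected <- mean(null)
  list(observed = observed,
       expected = expected,
       fold = if (expected > 0) observed / expected else NA_real_,
       p_empirical = (1 + sum(null >= observed)) / (1 + n_draws),
       n_draws = n_draws)
}

#' Fisher's exact over-representation test against a fixed universe
#'
#' One-sided (upper tail) exact test of the 2x2 table source-membership x
#' set-membership over a universe of `universe_size` genes, with the sample
#' odds ratio.
#'
#' @param n_source,n_set,overlap counts: source size, annotation-set size,
#'   observed overlap.
#' @param universe_size total genes in the universe.
#' @return list: `p` (one-sided), `odds_ratio` (sample OR; Inf/NaN possible
#'   on zero cells), `table`, `degenerate` (TRUE with p = 1 when a margin
#'   is zero).
#' @export
fisher_overrep <- function(n_source, n_set, overlap, universe_size) {
  a <- overlap
  b <- n_source - overlap
  c_ <- n_set - overlap
  d <- universe_size - n_source - n_set + overlap
  if (min(a, b, c_, d) < 0) stop("inconsistent counts for the 2x2 table")
  tab <- matrix(c(a, b, c_, d), 2L, 2L,
                dimnames = list(in_source = c("yes", "no"),
                                in_set = c("yes", "no")))
  if (n_source == 0L || n_set == 0L || n_source == universe_size ||
      n_set == universe_size)
    return(list(p = 1, odds_ratio = NA_real_, table = tab, degenerate = TRUE))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(p = p, odds_ratio = (a * d) / (b * c_), table = tab,
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0,1]` (NAs preserved).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Greedy LD-pruned independent-SNP counts per gene
#'
#' Helper producing the `n_independent_snps` annotation for
#' [matching_strata()] from a synthetic panel: per gene interval, greedily
#' keeps SNPs so that no kept pair has r-squared above the cutoff and
#' counts the kept set.
#'
#' @param panel a `genotype_panel`.
#' @param genes data.frame: `gene`, `chr`, `start`, `end`.
#' @param r2_max pruning threshold (default 0.2).
#' @return data.frame: `gene`, `n_independent_snps`, `gene_length`.
#' @export
independent_snp_counts <- function(panel, genes, r2_max = 0.2) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    in_gene <- panel$snps$chr == g$chr & panel$snps$pos >= g$start &
      panel$snps$pos <= g$end
    ids <- panel$snps$snp_id[in_gene]
    n_ind <- 0L
    if (length(ids)) {
      keep <- character()
      r2 <- if (length(ids) > 1L) ld_r2(panel, ids) else NULL
      for (s in ids) {
        if (!length(keep) || all(r2[s, keep] <= r2_max, na.rm = TRUE))
          keep <- c(keep, s)
      }
      n_ind <- length(keep)
    }
    data.frame(gene = g$gene, n_independent_snps = n_ind,
               gene_length = g$end - g$start + 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
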