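#' Distance from an index SNP to a gene
#'
#' Zero when the SNP lies within the gene body, otherwise the gap to the
#' nearer end. Genes on a different chromosome get NA (ineligible for the
#' distance tie-break).
#'
#' @param snp_pos index SNP position (bp).
#' @param gene_start,gene_end gene interval (1-based inclusive).
#' @param snp_chr,gene_chr optional chromosome labels; if both given and
#'   unequal the distance is NA.
#' @export
distance_to_gene <- function(snp_pos, gene_start, gene_end,
                             snp_chr = NULL, gene_chr = NULL) {
  if (!is.null(snp_chr) && !is.null(gene_chr) && snp_chr != gene_chr)
    return(NA_real_)
  if (snp_pos >= gene_start && snp_pos <= gene_end) return(0)
  min(abs(snp_pos - gene_start), abs(snp_pos - gene_end))
}

score_one_gene <- function(codes) {
  # h, r, m, c count once each; e/E together count once; p/P together once
  sum(c("h", "r", "m", "c") %in% codes) +
    any(c("e", "E") %in% codes) + any(c("p", "P") %in% codes)
}

#' Score candidate genes at a locus and pick the most likely causal gene
#'
#' Evidence codes per gene: `h` (gene hit or close by), `r` (regulated
#' gene), `e` (cis eQTL), `p` (cis pQTL), `m` (missense variant), `c`
#' (monogenic disease gene), `E` (positive colocalization with gene
#' expression), `P` (positive colocalization with protein levels). The
#' score sums h, r, m and c plus one point for e/E (together) and one for
#' p/P (together). The highest score wins; ties are resolved in order by
#' (1) presence of E, (2) presence of P, (3) a known inborn error of
#' metabolism matching the metabolite, (4) Ee over E alone, then Pp over P
#' alone, (5) smallest distance of the index SNP to the gene, with a
#' lexicographic gene-id fallback for exact distance ties.
#'
#' @param evidence data.frame with one row per candidate gene: `gene`,
#'   `codes` (comma/semicolon-separated string or list of code sets),
#'   optional `inborn_error_match` (logical) and `distance` (bp; or
#'   `start`/`end` plus `index_pos` to compute it).
#' @param index_pos index SNP position, used if `distance` is absent.
#' @return list with `ranking` (data.frame: gene, score, codes,
#'   distance, winner flag) and `deciding_rule` (character; "score" when
#'   the top score is unique, else the tie-break rule that decided, or
#'   "none" for a single candidate).
#' @export
score_genes <- function(evidence, index_pos = NULL) {
  if (!nrow(evidence)) stop("empty candidate gene list")
  ev <- as.data.frame(evidence)
  codes <- if (is.list(ev$codes) && !is.character(ev$codes)) ev$codes else
    lapply(strsplit(as.character(ev$codes), "[,;[:space:]]+"),
           function(x) unique(x[nzchar(x)]))
  if (is.null(ev$inborn_error_match)) ev$inborn_error_match <- FALSE
  if (is.null(ev$distance)) {
    if (!is.null(ev$start) && !is.null(ev$end) && !is.null(index_pos)) {
      ev$distance <- mapply(distance_to_gene, index_pos, ev$start, ev$end)
    } else ev$distance <- NA_real_
  }
  score <- vapply(codes, score_one_gene, numeric(1L))

  rk <- data.frame(gene = ev$gene, score = score,
                   codes = vapply(codes, paste, "", collapse = ","),
                   distance = ev$distance,
                   inborn_error_match = ev$inborn_error_match,
                   stringsAsFactors = FALSE)
  cand <- which(score == max(score))
  rule <- if (nrow(ev) == 1L) "none" else if (length(cand) == 1L) "score" else NA

  has <- function(code) vapply(codes, function(cc) code %in% cc, logical(1L))
  tie_steps <- list(
    expression_coloc = has("E"),
    protein_coloc = has("P"),
    inborn_error = as.logical(ev$inborn_error_match),
    Ee_over_E = has("E") & has("e"),
    Pp_over_P = has("P") & has("p"))
  if (is.na(rule)) for (nm in names(tie_steps)) {
    flag <- tie_steps[[nm]]
    if (any(flag[cand]) && !all(flag[cand])) {
      cand <- cand[flag[cand]]
      if (length(cand) == 1L) { rule <- nm; break }
    }
  }
  if (is.na(rule) && length(cand) > 1L) {
    d <- ev$distance[cand]
    if (all(is.na(d))) {
      cand <- cand[order(ev$gene[cand])][1L]
      rule <- "lexicographic"
    } else {
      d[is.na(d)] <- Inf
      best <- cand[d == min(d)]
      if (length(best) == 1L) { cand <- best; rule <- "distance" }
      else {
        cand <- best[order(ev$gene[best])][1L]
        rule <- "lexicographic"
        message("equidistant candidate genes; lexicographic fallback applied")
      }
    }
  }
  winner <- cand[1L]
  rk$winner <- seq_len(nrow(rk)) == winner
  rk <- rk[order(-rk$score, !rk$winner, rk$gene), , drop = FALSE]
  rownames(rk) <- NULL
  list(ranking = rk, winner = ev$gene[winner], deciding_rule = rule)
}
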