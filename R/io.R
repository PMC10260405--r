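#' Write / read GWAS summary statistics TSV
#'
#' One file per trait x matrix; tab-separated with header columns
#' `snp_id chr pos ea oa eaf beta se p n` (extra columns preserved).
#'
#' @param table an `assoc_table` (or compatible data.frame).
#' @param path output file.
#' @export
write_summary_stats <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(chr = "character"))
  need <- c("snp_id", "chr", "pos", "beta", "se", "p")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("summary-stat file ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Write / read a metabolite matrix TSV (samples in rows)
#'
#' @param matrix a `metabolite_matrix`.
#' @param path output file.
#' @export
write_metabolite_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  df <- data.frame(sample_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolite_tsv
#' @param matrix_label matrix label for the reconstructed object.
#' @export
read_metabolite_tsv <- function(path, matrix_label = c("plasma", "urine")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("metabolite TSV ", path, " must start with a sample_id column")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$sample_id
  metabolite_matrix(vals, match.arg(matrix_label))
}

#' Write a genotype panel as dosage TSV
#'
#' First columns `snp_id chr pos ref alt alt_freq imp_quality`, then one
#' dosage column per sample. A `# seed:` header line records the seed when
#' one is supplied.
#'
#' @param panel a `genotype_panel`.
#' @param path output file.
#' @param seed optional seed recorded in the header.
#' @export
write_dosage_tsv <- function(panel, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  df <- cbind(panel$snps, as.data.frame(t(panel$dosages)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = c(chr = "character"),
                          check.names = FALSE)
  meta_cols <- c("snp_id", "chr", "pos", "ref", "alt", "alt_freq",
                 "imp_quality")
  miss <- setdiff(meta_cols, names(df))
  if (length(miss)) stop("dosage TSV lacks columns: ",
                         paste(miss, collapse = ", "))
  dos <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  colnames(dos) <- df$snp_id
  structure(list(sample_ids = rownames(dos), snps = df[, meta_cols],
                 dosages = dos, haplotypes = NULL),
            class = "genotype_panel")
}

#' Write a genotype panel as VCF with GT and DS fields
#'
#' Positions are 1-based as per VCF. Imputation quality is stored as the
#' INFO key `R2`; the seed is recorded in a `##source` header line.
#'
#' @param panel a `genotype_panel` (haplotypes required for GT phase).
#' @param path output file (plain text .vcf).
#' @param seed optional seed recorded in the header.
#' @export
write_genotype_vcf <- function(panel, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=mqtlkit",
                      if (!is.null(seed)) paste0(" seed=", seed)),
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alt allele frequency\">",
               "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt dosage\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$sample_ids), collapse = "\t"),
             con)
  n <- length(panel$sample_ids)
  h1 <- panel$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- panel$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE]
  for (i in seq_len(nrow(panel$snps))) {
    s <- panel$snps[i, ]
    gt <- paste0(h1[, i], "|", h2[, i], ":",
                 format(panel$dosages[, s$snp_id], trim = TRUE))
    writeLines(paste(c(s$chr, s$pos, s$snp_id, s$ref, s$alt, ".", "PASS",
                       sprintf("AF=%.6g;R2=%.4g", s$alt_freq, s$imp_quality),
                       "GT:DS", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages (DS field, falling back to GT) from a VCF
#'
#' Requires the `vcfR` package.
#'
#' @param path VCF file.
#' @return a `genotype_panel` (haplotypes populated when GT is phased).
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosages requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::extract.info(v, "R2", as.numeric = TRUE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(ds)
  dos <- t(ds)
  colnames(dos) <- fix$ID
  haps <- NULL
  if (!is.null(gt) && all(grepl("\\|", gt[!is.na(gt)]))) {
    a1 <- t(apply(gt, 1:2, function(g) as.integer(substr(g, 1L, 1L))))
    a2 <- t(apply(gt, 1:2, function(g) as.integer(substr(g, 3L, 3L))))
    haps <- matrix(0L, 2L * length(samples), nrow(fix))
    haps[seq(1L, nrow(haps), 2L), ] <- a1
    haps[seq(2L, nrow(haps), 2L), ] <- a2
    rownames(haps) <- paste0(rep(samples, each = 2L), c("_h1", "_h2"))
    colnames(haps) <- fix$ID
  }
  snps <- data.frame(snp_id = fix$ID, chr = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     alt_freq = colMeans(dos) / 2,
                     imp_quality = if (all(is.na(info))) 1 else info,
                     stringsAsFactors = FALSE)
  structure(list(sample_ids = samples, snps = snps, dosages = dos,
                 haplotypes = haps),
            class = "genotype_panel")
}

#' Export / import mQTL loci as BED
#'
#' Internally intervals are 1-based inclusive; the BED export converts to
#' 0-based half-open (`start - 1`, `end`) and the import reverses it.
#'
#' @param mqtls data.frame from [call_mqtls()].
#' @param path BED file.
#' @export
write_bed_loci <- function(mqtls, path) {
  bed <- data.frame(chrom = mqtls$chr,
                    start = format(mqtls$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(mqtls$end, scientific = FALSE, trim = TRUE),
                    name = paste(mqtls$trait, mqtls$matrix, mqtls$index_snp,
                                 sep = "|"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_loci
#' @export
read_bed_loci <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  data.frame(trait = vapply(parts, `[`, "", 1L),
             matrix = vapply(parts, `[`, "", 2L),
             index_snp = vapply(parts, `[`, "", 3L),
             chr = as.character(bed$chrom),
             start = bed$start + 1,
             end = bed$end,
             stringsAsFactors = FALSE)
}
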