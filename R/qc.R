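#' QC configuration
#'
#' Defaults follow the cleaning rules used for the paired-cohort analysis:
#' duplicate samples at Pearson r > 0.9, samples with > 50% missing data,
#' metabolites quantified in fewer than 300 samples, a probabilistic-quotient
#' reference set of metabolites with < 1% missing values, a log2-scale
#' variance floor of 0.01, an outlier rule flagging metabolites with > 5% of
#' samples beyond 5 s.d., and sample exclusion beyond 5 s.d. on any of the
#' first 15 principal components of the complete-information metabolites.
#'
#' @param duplicate_r_threshold Pearson correlation above which two samples
#'   with different ids are treated as duplicates.
#' @param sample_missing_max maximum tolerated per-sample missing fraction.
#' @param min_samples_per_metabolite minimum observed samples per metabolite.
#' @param reference_missing_max missingness ceiling for the pq reference set.
#' @param variance_min minimum log2-scale variance per metabolite.
#' @param outlier_sd,outlier_sample_fraction metabolite outlier rule: drop
#'   the metabolite when more than `outlier_sample_fraction` of samples lie
#'   more than `outlier_sd` s.d. from its mean.
#' @param n_pcs,pc_outlier_sd sample PC rule: drop samples more than
#'   `pc_outlier_sd` s.d. from the mean on any of the first `n_pcs` PCs.
#' @export
qc_config <- function(duplicate_r_threshold = 0.9,
                      sample_missing_max = 0.5,
                      min_samples_per_metabolite = 300,
                      reference_missing_max = 0.01,
                      variance_min = 0.01,
                      outlier_sd = 5,
                      outlier_sample_fraction = 0.05,
                      n_pcs = 15,
                      pc_outlier_sd = 5) {
  cfg <- list(duplicate_r_threshold = duplicate_r_threshold,
              sample_missing_max = sample_missing_max,
              min_samples_per_metabolite = min_samples_per_metabolite,
              reference_missing_max = reference_missing_max,
              variance_min = variance_min,
              outlier_sd = outlier_sd,
              outlier_sample_fraction = outlier_sample_fraction,
              n_pcs = n_pcs,
              pc_outlier_sd = pc_outlier_sd)
  fr <- c("sample_missing_max", "reference_missing_max",
          "outlier_sample_fraction")
  if (any(unlist(cfg[fr]) < 0 | unlist(cfg[fr]) > 1))
    stop("fractions must lie in [0,1]")
  if (any(unlist(cfg[setdiff(names(cfg), fr)]) <= 0))
    stop("thresholds must be positive")
  structure(cfg, class = "qc_config")
}

mm_values <- function(x) if (inherits(x, "metabolite_matrix")) x$values else as.matrix(x)

#' Detect duplicate samples
#'
#' Flags sample pairs whose metabolite profiles have pairwise-complete
#' Pearson correlation strictly greater than the threshold despite differing
#' ids. Samples with no observed values are excluded from comparison.
#'
#' @param matrix a `metabolite_matrix` or sample x metabolite matrix.
#' @param r_threshold correlation threshold (default 0.9).
#' @return data.frame with columns `sample_a`, `sample_b`, `r`.
#' @export
detect_duplicates <- function(matrix, r_threshold = 0.9) {
  vals <- mm_values(matrix)
  if (nrow(vals) < 2L) stop("need at least two samples")
  ok <- rowSums(!is.na(vals)) > 0L
  if (any(!ok))
    message("excluding all-missing samples from duplicate scan: ",
            paste(rownames(vals)[!ok], collapse = ", "))
  vals <- vals[ok, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(vals), use = "pairwise.complete.obs"))
  cc[lower.tri(cc, diag = TRUE)] <- NA
  hit <- which(!is.na(cc) & cc > r_threshold, arr.ind = TRUE)
  data.frame(sample_a = rownames(cc)[hit[, 1L]],
             sample_b = colnames(cc)[hit[, 2L]],
             r = cc[hit],
             stringsAsFactors = FALSE)
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution (urine) by dividing each sample by the
#' median ratio of its values to a reference spectrum. The reference set is
#' the metabolites with missing fraction strictly below
#' `reference_missing_max`; the reference spectrum is their per-metabolite
#' median across samples; the per-sample factor is the median of
#' observed-value / reference-value over the reference set.
#'
#' @param matrix a `metabolite_matrix` (raw abundance scale) or matrix.
#' @param reference_missing_max missingness ceiling for the reference set.
#' @return list with `matrix` (same class as input, values divided by the
#'   factors) and `factors` (named per-sample dilution factor).
#' @export
pq_normalize <- function(matrix, reference_missing_max = 0.01) {
  vals <- mm_values(matrix)
  miss <- colMeans(is.na(vals))
  ref_set <- which(miss < reference_missing_max)
  if (!length(ref_set))
    stop("no metabolite qualifies for the pq reference set (missingness < ",
         reference_missing_max, ")")
  ref <- apply(vals[, ref_set, drop = FALSE], 2L, stats::median, na.rm = TRUE)
  quot <- sweep(vals[, ref_set, drop = FALSE], 2L, ref, "/")
  n_obs <- rowSums(!is.na(quot))
  if (any(n_obs == 0L))
    stop("sample(s) with zero observed reference metabolites: ",
         paste(rownames(vals)[n_obs == 0L], collapse = ", "))
  factors <- apply(quot, 1L, stats::median, na.rm = TRUE)
  out <- vals / factors
  if (inherits(matrix, "metabolite_matrix"))
    out <- metabolite_matrix(out, matrix$matrix)
  list(matrix = out, factors = factors)
}

#' Filter metabolites and samples after log2 transform
#'
#' Applies, in this fixed order: (1) samples with missing fraction above
#' `sample_missing_max`; (2) metabolites observed in fewer than
#' `min_samples_per_metabolite` samples; (3) metabolites with log2-scale
#' variance below `variance_min`; (4) metabolites where more than
#' `outlier_sample_fraction` of observed samples lie beyond `outlier_sd`
#' s.d. of the metabolite mean; (5) samples beyond `pc_outlier_sd` s.d. from
#' the mean on any of the first `n_pcs` principal components computed on
#' metabolites with complete information. Expects log2-transformed (and, for
#' urine, pq-normalized) values.
#'
#' @param matrix `metabolite_matrix` or matrix of log2 values.
#' @param config a [qc_config()].
#' @return list with `matrix` (filtered) and `report` (data.frame: `unit`
#'   ("sample"/"metabolite"), `id`, `rule`).
#' @export
filter_metabolites_and_samples <- function(matrix, config = qc_config()) {
  vals <- mm_values(matrix)
  rep_rows <- list()
  note <- function(unit, ids, rule) {
    if (length(ids))
      rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
        unit = unit, id = ids, rule = rule, stringsAsFactors = FALSE)
  }

  smiss <- rowMeans(is.na(vals))
  drop_s <- rownames(vals)[smiss > config$sample_missing_max]
  note("sample", drop_s, "sample_missingness")
  vals <- vals[setdiff(rownames(vals), drop_s), , drop = FALSE]

  nobs <- colSums(!is.na(vals))
  drop_m <- colnames(vals)[nobs < config$min_samples_per_metabolite]
  note("metabolite", drop_m, "min_sample_count")
  vals <- vals[, setdiff(colnames(vals), drop_m), drop = FALSE]

  v <- apply(vals, 2L, stats::var, na.rm = TRUE)
  drop_m <- colnames(vals)[!is.na(v) & v < config$variance_min |
                             is.na(v)]
  note("metabolite", drop_m, "low_variance")
  vals <- vals[, setdiff(colnames(vals), drop_m), drop = FALSE]

  mu <- colMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  z <- abs(sweep(sweep(vals, 2L, mu, "-"), 2L, sdv, "/"))
  out_frac <- colMeans(z > config$outlier_sd, na.rm = TRUE)
  drop_m <- colnames(vals)[out_frac > config$outlier_sample_fraction]
  note("metabolite", drop_m, "outlier_metabolite")
  vals <- vals[, setdiff(colnames(vals), drop_m), drop = FALSE]

  complete <- colSums(is.na(vals)) == 0L
  if (!any(complete)) {
    warning("no metabolite with complete information; PC outlier rule skipped")
  } else {
    pc <- stats::prcomp(vals[, complete, drop = FALSE],
                        center = TRUE, scale. = TRUE)
    k <- min(config$n_pcs, ncol(pc$x))
    sc <- scale(pc$x[, seq_len(k), drop = FALSE])
    bad <- rowSums(abs(sc) > config$pc_outlier_sd, na.rm = TRUE) > 0L
    drop_s <- rownames(vals)[bad]
    note("sample", drop_s, "pc_outlier")
    vals <- vals[setdiff(rownames(vals), drop_s), , drop = FALSE]
  }

  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(unit = character(), id = character(), rule = character())
  out <- vals
  if (inherits(matrix, "metabolite_matrix"))
    out <- metabolite_matrix(out, matrix$matrix)
  list(matrix = out, report = report)
}

#' Full metabolite QC pipeline for one matrix
#'
#' Duplicate removal, sample-missingness and metabolite-count filters on raw
#' abundances, probabilistic quotient normalization (urine only), log2
#' transform, then the variance/outlier/PC filters of
#' [filter_metabolites_and_samples()]. Zero or negative abundances are
#' rejected (log2 undefined).
#'
#' @param matrix a `metabolite_matrix` on the raw abundance scale.
#' @param config a [qc_config()].
#' @return list with `matrix` (log2 scale, filtered), `report`, and
#'   `dilution_factors` (urine; NULL for plasma).
#' @export
qc_pipeline <- function(matrix, config = qc_config()) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  vals <- matrix$values
  if (any(vals <= 0, na.rm = TRUE))
    stop("non-positive abundances: log2 undefined; check input scale")
  rep_rows <- list()

  dup <- detect_duplicates(vals, config$duplicate_r_threshold)
  drop_s <- unique(c(dup$sample_a, dup$sample_b))
  if (length(drop_s))
    rep_rows[[1L]] <- data.frame(unit = "sample", id = drop_s,
                                 rule = "duplicate", stringsAsFactors = FALSE)
  vals <- vals[setdiff(rownames(vals), drop_s), , drop = FALSE]

  smiss <- rowMeans(is.na(vals))
  drop_s <- rownames(vals)[smiss > config$sample_missing_max]
  if (length(drop_s))
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      unit = "sample", id = drop_s, rule = "sample_missingness",
      stringsAsFactors = FALSE)
  vals <- vals[setdiff(rownames(vals), drop_s), , drop = FALSE]

  nobs <- colSums(!is.na(vals))
  drop_m <- colnames(vals)[nobs < config$min_samples_per_metabolite]
  if (length(drop_m))
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      unit = "metabolite", id = drop_m, rule = "min_sample_count",
      stringsAsFactors = FALSE)
  vals <- vals[, setdiff(colnames(vals), drop_m), drop = FALSE]

  factors <- NULL
  if (matrix$matrix == "urine") {
    pq <- pq_normalize(vals, config$reference_missing_max)
    vals <- pq$matrix
    factors <- pq$factors
  }

  flt <- filter_metabolites_and_samples(
    metabolite_matrix(log2(vals), matrix$matrix), config)
  report <- do.call(rbind, c(rep_rows, list(flt$report)))
  list(matrix = flt$matrix, report = report, dilution_factors = factors)
}
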