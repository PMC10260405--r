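#' Pipeline configuration
#'
#' Collects every tunable of the paired-matrix workflow with the analysis
#' defaults; unknown keys are rejected. A YAML file with the same keys can
#' be loaded via `pipeline_config_from_yaml()`.
#'
#' @param seed master seed; all stage randomness derives from it.
#' @param base_alpha genome-wide base significance level.
#' @param window_bp locus window for [call_mqtls()].
#' @param maf_cutoff rare-variant gate for [rare_variant_check()].
#' @param finemap_prior_sd Wakefield prior s.d. for fine mapping.
#' @param coloc_prior_sd per-trait prior s.d. inside colocalization.
#' @param coloc_p1,coloc_p2,coloc_p12 colocalization priors.
#' @param collinearity stepwise LD cutoff.
#' @param credible_level credible-set level.
#' @param h4_call PP H4 threshold for a positive colocalization.
#' @param stages character vector of stages to run, a subset of
#'   `c("qc", "gwas", "loci", "finemap", "coloc", "prioritize", "enrich",
#'   "h2", "ehh")`. The annotation-driven stages (`prioritize`, `enrich`,
#'   `ehh`) only run when their inputs are passed to [run_pipeline()].
#' @param qc a [qc_config()].
#' @param ... rejected; unknown keys are an error.
#' @export
pipeline_config <- function(seed = 1L,
                            base_alpha = 5e-8,
                            window_bp = 1e6,
                            maf_cutoff = 0.03,
                            finemap_prior_sd = 1.33,
                            coloc_prior_sd = 0.15,
                            coloc_p1 = 1e-4, coloc_p2 = 1e-4,
                            coloc_p12 = 1e-5,
                            collinearity = 0.1,
                            credible_level = 0.99,
                            h4_call = 0.8,
                            stages = c("qc", "gwas", "loci", "finemap",
                                       "coloc", "prioritize", "enrich"),
                            qc = qc_config(),
                            ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ",
         paste(names(extra), collapse = ", "))
  known <- c("qc", "gwas", "loci", "finemap", "coloc", "prioritize",
             "enrich", "h2", "ehh")
  if (!all(stages %in% known))
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(seed = as.integer(seed), base_alpha = base_alpha,
                 window_bp = window_bp, maf_cutoff = maf_cutoff,
                 finemap_prior_sd = finemap_prior_sd,
                 coloc_prior_sd = coloc_prior_sd,
                 coloc_p1 = coloc_p1, coloc_p2 = coloc_p2,
                 coloc_p12 = coloc_p12,
                 collinearity = collinearity,
                 credible_level = credible_level,
                 h4_call = h4_call, stages = stages, qc = qc),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file of overrides.
#' @export
pipeline_config_from_yaml <- function(path) {
  ov <- yaml::read_yaml(path)
  if (!is.null(ov$qc)) ov$qc <- do.call(qc_config, ov$qc)
  do.call(pipeline_config, ov)
}

#' Run the paired-matrix mQTL pipeline on a synthetic or loaded cohort
#'
#' Executes QC, per-metabolite GWAS with Bonferroni thresholds, locus
#' calling with the rare-variant inverse-normal re-check, fine mapping, and
#' pairwise colocalization with four-group classification, writing
#' per-stage TSV outputs and a JSON manifest into `out_dir`. Heritability
#' (`"h2"` stage) is optional.
#'
#' @param panel a `genotype_panel`.
#' @param plasma,urine `metabolite_matrix` objects on the raw abundance
#'   scale.
#' @param covariates covariate data.frame.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; existing files overwritten).
#' @param gene_evidence optional data.frame for the prioritize stage:
#'   one row per (index SNP, candidate gene) with columns `index_snp`,
#'   `gene`, `codes`, optionally `start`, `end`, `inborn_error_match`
#'   (see [score_genes()]).
#' @param gene_sets optional named list of gene-id vectors for the enrich
#'   stage (source list = prioritized winners).
#' @param gene_annotation optional data.frame for the enrich stage:
#'   `gene`, `n_independent_snps`, `gene_length` over the gene universe.
#' @param ehh_cores optional SNP ids at which to compute derived/ancestral
#'   EHH curves from the panel haplotypes.
#' @return invisible list with the in-memory stage outputs (`qc`, `gwas`,
#'   `mqtls`, `finemap`, `coloc`, and — when their inputs are given —
#'   `prioritized`, `enrichment`, `h2`, `ehh`) and `manifest`.
#' @export
run_pipeline <- function(panel, plasma, urine, covariates,
                         config = pipeline_config(), out_dir,
                         gene_evidence = NULL, gene_sets = NULL,
                         gene_annotation = NULL, ehh_cores = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   config = config[setdiff(names(config), "qc")])
  res <- list()
  stage <- function(name, expr) {
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- "complete"
    out
  }

  cleaned <- list()
  if ("qc" %in% config$stages) {
    cleaned <- stage("qc", {
      out <- list(plasma = qc_pipeline(plasma, config$qc),
                  urine = qc_pipeline(urine, config$qc))
      for (mx in names(out)) {
        write_metabolite_tsv(out[[mx]]$matrix,
                             file.path(out_dir, paste0(mx, "_qc.tsv")))
        utils::write.table(out[[mx]]$report,
                           file.path(out_dir, paste0(mx, "_qc_report.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      out
    })
    res$qc <- cleaned
  } else {
    cleaned <- list(plasma = list(matrix = metabolite_matrix(
                      log2(plasma$values), "plasma")),
                    urine = list(matrix = metabolite_matrix(
                      log2(urine$values), "urine")))
  }

  if (!"gwas" %in% config$stages) {
    write_manifest(manifest, out_dir)
    return(invisible(c(res, list(manifest = manifest))))
  }

  gwas <- stage("gwas", {
    out <- list()
    for (mx in c("plasma", "urine")) {
      vals <- cleaned[[mx]]$matrix$values
      cfg <- significance_config(ncol(vals), config$base_alpha)
      tabs <- lapply(colnames(vals), function(m) {
        r <- residualize(vals[, m], covariates, mx)
        run_gwas(r, panel)
      })
      names(tabs) <- colnames(vals)
      out[[mx]] <- list(tables = tabs, sig = cfg)
    }
    out
  })
  res$gwas <- gwas

  if ("loci" %in% config$stages) {
    res$mqtls <- stage("loci", {
      rows <- list()
      for (mx in c("plasma", "urine")) {
        vals <- cleaned[[mx]]$matrix$values
        for (m in names(gwas[[mx]]$tables)) {
          mq <- call_mqtls(gwas[[mx]]$tables[[m]], gwas[[mx]]$sig,
                           window_bp = config$window_bp,
                           trait = m, matrix_label = mx)
          if (!nrow(mq)) next
          keep <- vapply(seq_len(nrow(mq)), function(i) {
            rare_variant_check(mq[i, ], vals[, m], covariates, panel,
                               gwas[[mx]]$sig, mx,
                               maf_cutoff = config$maf_cutoff)$keep
          }, logical(1L))
          mq <- mq[keep, , drop = FALSE]
          if (nrow(mq)) {
            shared <- intersect(rownames(panel$dosages), rownames(vals))
            mq$variance_explained <- vapply(seq_len(nrow(mq)), function(i)
              variance_explained(panel$dosages[shared, mq$index_snp[i]],
                                 vals[shared, m]),
              numeric(1L))
            rows[[length(rows) + 1L]] <- mq
          }
        }
      }
      mqtls <- if (length(rows)) do.call(rbind, rows) else
        call_mqtls(gwas$plasma$tables[[1L]], 0)
      if (nrow(mqtls))
        write_bed_loci(mqtls, file.path(out_dir, "mqtl_loci.bed"))
      utils::write.table(mqtls[, setdiff(names(mqtls), "members")],
                         file.path(out_dir, "mqtls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      mqtls
    })
  }

  if ("finemap" %in% config$stages && !is.null(res$mqtls) && nrow(res$mqtls)) {
    res$finemap <- stage("finemap", {
      out <- lapply(seq_len(nrow(res$mqtls)), function(i) {
        mq <- res$mqtls[i, ]
        mx <- mq$matrix
        vals <- cleaned[[mx]]$matrix$values
        region <- panel$snps$snp_id[panel$snps$chr == mq$chr &
                                      panel$snps$pos >= mq$start &
                                      panel$snps$pos <= mq$end]
        r <- residualize(vals[, mq$trait], covariates, mx)
        finemap_region(region, r, panel, gwas[[mx]]$sig,
                       prior_sd = config$finemap_prior_sd,
                       collinearity = config$collinearity,
                       level = config$credible_level)
      })
      names(out) <- paste(res$mqtls$trait, res$mqtls$matrix,
                          res$mqtls$index_snp, sep = "|")
      cs <- do.call(rbind, lapply(names(out), function(k) {
        sets <- out[[k]]$credible_sets
        if (!length(sets)) return(NULL)
        do.call(rbind, lapply(names(sets), function(s)
          cbind(mqtl = k, signal = s, sets[[s]])))
      }))
      if (!is.null(cs))
        utils::write.table(cs, file.path(out_dir, "credible_sets.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      out
    })
  }

  if ("coloc" %in% config$stages && !is.null(res$mqtls) &&
      nrow(res$mqtls) >= 2L) {
    res$coloc <- stage("coloc", {
      pairs <- pair_mqtls(res$mqtls)
      out <- lapply(seq_len(nrow(pairs)), function(k) {
        a <- res$mqtls[pairs$row_a[k], ]
        b <- res$mqtls[pairs$row_b[k], ]
        in_reg <- function(tab) tab[tab$chr == pairs$chr[k] &
                                      tab$pos >= pairs$start[k] &
                                      tab$pos <= pairs$end[k], ]
        coloc_abf(in_reg(gwas[[a$matrix]]$tables[[a$trait]]),
                  in_reg(gwas[[b$matrix]]$tables[[b$trait]]),
                  p1 = config$coloc_p1, p2 = config$coloc_p2,
                  p12 = config$coloc_p12,
                  prior_sd = config$coloc_prior_sd,
                  trait_a = a$trait, matrix_a = a$matrix,
                  trait_b = b$trait, matrix_b = b$matrix)
      })
      tab <- do.call(rbind, lapply(out, function(cr)
        data.frame(trait_a = cr$pair$trait_a, matrix_a = cr$pair$matrix_a,
                   trait_b = cr$pair$trait_b, matrix_b = cr$pair$matrix_b,
                   t(cr$pp), n_snps = cr$n_snps, group = cr$group,
                   positive = cr$pp[["H4"]] > config$h4_call)))
      if (!is.null(tab))
        utils::write.table(tab, file.path(out_dir, "coloc.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      list(results = out, table = tab)
    })
  }

  if ("prioritize" %in% config$stages && !is.null(gene_evidence) &&
      !is.null(res$mqtls) && nrow(res$mqtls)) {
    res$prioritized <- stage("prioritize", {
      rows <- lapply(seq_len(nrow(res$mqtls)), function(i) {
        mq <- res$mqtls[i, ]
        ev <- gene_evidence[gene_evidence$index_snp == mq$index_snp, ,
                            drop = FALSE]
        if (!nrow(ev)) return(NULL)
        sg <- score_genes(ev, index_pos = mq$index_pos)
        data.frame(trait = mq$trait, matrix = mq$matrix,
                   index_snp = mq$index_snp, gene = sg$winner,
                   deciding_rule = sg$deciding_rule,
                   score = sg$ranking$score[sg$ranking$winner],
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      if (!is.null(tab))
        utils::write.table(tab, file.path(out_dir, "prioritized_genes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
  }

  if ("enrich" %in% config$stages && !is.null(gene_sets) &&
      !is.null(gene_annotation) && !is.null(res$prioritized)) {
    res$enrichment <- stage("enrich", {
      strata <- matching_strata(gene_annotation)
      src <- unique(res$prioritized$gene)
      src <- intersect(src, gene_annotation$gene)
      rows <- lapply(names(gene_sets), function(nm) {
        mp <- matched_permutation_test(src, gene_sets[[nm]],
                                       gene_annotation$gene, strata,
                                       n_draws = 1e5, seed = config$seed)
        data.frame(set = nm, observed = mp$observed, expected = mp$expected,
                   fold = mp$fold, p = mp$p_empirical,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      tab$p_adj <- bh_adjust(tab$p)
      utils::write.table(tab, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
  }

  if ("ehh" %in% config$stages && !is.null(ehh_cores) &&
      !is.null(panel$haplotypes)) {
    res$ehh <- stage("ehh", {
      out <- lapply(ehh_cores, function(s) compare_alleles(panel, s))
      names(out) <- ehh_cores
      tab <- do.call(rbind, lapply(ehh_cores, function(s)
        cbind(core = s, allele = rep(c("derived", "ancestral"),
                                     c(nrow(out[[s]]$derived),
                                       nrow(out[[s]]$ancestral))),
              rbind(out[[s]]$derived, out[[s]]$ancestral))))
      utils::write.table(tab, file.path(out_dir, "ehh_curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out
    })
  }

  if ("h2" %in% config$stages) {
    res$h2 <- stage("h2", {
      grm <- compute_grm(panel)
      attr(grm, "eigen") <- eigen(grm$A, symmetric = TRUE)
      out <- list()
      for (mx in c("plasma", "urine")) {
        vals <- cleaned[[mx]]$matrix$values
        cols <- c("age", "sex", "pc1", "pc2", "pc3",
                  if (mx == "plasma") c("ln_egfr", "albumin"))
        out[[mx]] <- lapply(colnames(vals), function(m)
          reml_h2(vals[, m], grm, covariates, covariate_cols = cols))
        names(out[[mx]]) <- colnames(vals)
      }
      tab <- do.call(rbind, lapply(names(out), function(mx)
        data.frame(matrix = mx, metabolite = names(out[[mx]]),
                   h2 = vapply(out[[mx]], `[[`, 0, "h2"),
                   se = vapply(out[[mx]], `[[`, 0, "se"))))
      utils::write.table(tab, file.path(out_dir, "heritability.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out
    })
  }

  write_manifest(manifest, out_dir)
  res$manifest <- manifest
  invisible(res)
}

write_manifest <- function(manifest, out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest$outputs <- lapply(stats::setNames(files, files), function(f)
    unname(tools::md5sum(file.path(out_dir, f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
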