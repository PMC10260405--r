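#' Genetic relationship matrix
#'
#' GCTA-style GRM over autosomal SNPs passing the imputation-quality
#' filter: `A_jk = (1/M) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 -
#' p_i))` with `p_i` the in-sample alt frequency. Monomorphic SNPs are
#' excluded.
#'
#' @param panel a `genotype_panel`.
#' @param quality_min imputation-quality floor (strict `>`, default 0.6).
#' @param autosomes chromosome labels counted as autosomal (default: not
#'   X/Y/MT).
#' @return a `grm`: list with `A` (n x n), `M` (SNPs used), `sample_ids`,
#'   `filter` (record of applied SNP filters).
#' @export
compute_grm <- function(panel, quality_min = 0.6, autosomes = NULL) {
  if (length(panel$sample_ids) < 2L) stop("need at least 2 samples")
  snps <- panel$snps
  auto <- if (is.null(autosomes)) !snps$chr %in% c("X", "Y", "MT", "chrX", "chrY", "chrM")
  else snps$chr %in% autosomes
  keep <- auto & snps$imp_quality > quality_min
  X <- panel$dosages[, keep, drop = FALSE]
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  M <- ncol(X)
  if (M == 0L) stop("no SNPs pass the GRM filters")
  Z <- sweep(sweep(X, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(Z) / M
  dimnames(A) <- list(panel$sample_ids, panel$sample_ids)
  structure(list(A = A, M = M, sample_ids = panel$sample_ids,
                 filter = list(quality_min = quality_min,
                               n_input = nrow(snps),
                               n_autosomal_pass_quality = sum(keep),
                               n_used = M)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, M = %d SNPs (mean diag %.3f)\n",
              nrow(x$A), x$M, mean(diag(x$A))))
  invisible(x)
}

#' SNP heritability by single-component REML (GREML)
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sg2 A)` and `e ~ N(0, se2 I)` by
#' average-information REML in the eigenbasis of the GRM (one
#' eigendecomposition per GRM, then O(n) per iteration). AI steps are
#' safeguarded: when an AI update would decrease the restricted
#' log-likelihood or leave the parameter space, an EM step (then step
#' halving) is used instead, so the log-likelihood is non-decreasing across
#' iterations. Variance components are bounded below at a small positive
#' floor, which constrains h2 = sg2/(sg2+se2) to [0,1]. The SE of h2 comes
#' from the inverse AI matrix by the delta method.
#'
#' @param trait named numeric vector (complete cases used).
#' @param grm a [compute_grm()] result (eigendecomposition cached in place
#'   via attribute when reused).
#' @param covariates data.frame of fixed-effect covariates (rownames =
#'   sample ids); NULL for intercept only.
#' @param covariate_cols columns of `covariates` to use (default: all
#'   numeric columns).
#' @param max_iter,tol iteration cap and log-likelihood convergence
#'   tolerance.
#' @return list: `h2`, `se`, `sigma_g2`, `sigma_e2`, `loglik`, `converged`,
#'   `n_iter`, `loglik_trace`.
#' @export
reml_h2 <- function(trait, grm, covariates = NULL, covariate_cols = NULL,
                    max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(grm, "grm"))
  ids <- names(trait)[!is.na(trait)]
  ids <- intersect(ids, grm$sample_ids)
  if (!is.null(covariates)) {
    if (is.null(covariate_cols))
      covariate_cols <- names(covariates)[vapply(covariates, is.numeric, logical(1L))]
    ids <- intersect(ids, rownames(covariates)[stats::complete.cases(
      covariates[, covariate_cols, drop = FALSE])])
  }
  y <- as.numeric(trait[ids])
  n <- length(y)
  if (n < 10L) stop("too few complete cases for REML")
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates))
    X <- cbind(X, as.matrix(covariates[ids, covariate_cols, drop = FALSE]))

  sub <- !all(grm$sample_ids %in% ids) || length(ids) != nrow(grm$A)
  A <- grm$A[ids, ids]
  eg <- if (!sub && !is.null(attr(grm, "eigen"))) attr(grm, "eigen") else
    eigen(A, symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  ys <- as.numeric(crossprod(U, y))
  Xs <- crossprod(U, X)
  q <- ncol(Xs)

  # restricted log-likelihood and the quantities needed for AI/EM updates,
  # all diagonal in the rotated basis
  pieces <- function(sg, se) {
    v <- sg * d + se
    XtViX <- crossprod(Xs, Xs / v)
    C <- solve(XtViX)
    XtViy <- crossprod(Xs, ys / v)
    Py <- ys / v - (Xs / v) %*% (C %*% XtViy)
    ll <- -0.5 * (sum(log(v)) + determinant(XtViX, logarithm = TRUE)$modulus[1L] +
                    sum(ys * Py))
    list(v = v, C = C, Py = as.numeric(Py), ll = as.numeric(ll))
  }
  Pvec <- function(u, v, C) {
    as.numeric(u / v - (Xs / v) %*% (C %*% crossprod(Xs, u / v)))
  }

  vary <- stats::var(y)
  floor_v <- 1e-6 * vary
  sg <- se <- vary / 2
  pc <- pieces(sg, se)
  trace <- pc$ll
  converged <- FALSE
  AI <- NULL

  for (it in seq_len(max_iter)) {
    v <- pc$v; C <- pc$C; Py <- pc$Py
    # traces of P G_k: G_g = diag(d), G_e = I
    trP <- function(g) sum(g / v) -
      sum(diag(C %*% crossprod(Xs, Xs * (g / v^2))))
    yPGPy <- c(sum(Py^2 * d), sum(Py^2))
    score <- -0.5 * c(trP(d) - yPGPy[1L], trP(rep(1, n)) - yPGPy[2L])

    w_g <- Pvec(d * Py, v, C)
    w_e <- Pvec(Py, v, C)
    AI <- 0.5 * matrix(c(sum(d * Py * w_g), sum(d * Py * w_e),
                         sum(Py * w_g), sum(Py * w_e)), 2L, 2L)

    step_ok <- function(par) {
      if (any(!is.finite(par)) || any(par < floor_v)) return(NULL)
      p2 <- pieces(par[1L], par[2L])
      if (!is.finite(p2$ll) || p2$ll < pc$ll - 1e-10) return(NULL)
      p2
    }
    prop <- tryCatch(c(sg, se) + solve(AI, score), error = function(e) c(NA, NA))
    prop[!is.finite(prop)] <- NA
    prop <- pmax(prop, floor_v)
    new <- step_ok(prop)
    if (is.null(new)) {                              # EM fallback
      em <- c(sg + sg^2 / n * (yPGPy[1L] - trP(d)),
              se + se^2 / n * (yPGPy[2L] - trP(rep(1, n))))
      em <- pmax(em, floor_v)
      new <- step_ok(em)
      if (is.null(new)) {                            # step halving toward EM
        for (h in 1:20) {
          half <- c(sg, se) + (em - c(sg, se)) / 2^h
          new <- step_ok(pmax(half, floor_v))
          if (!is.null(new)) { em <- pmax(half, floor_v); break }
        }
        prop <- em
      } else prop <- em
    }
    if (is.null(new)) break                          # cannot improve further
    delta <- new$ll - pc$ll
    sg <- prop[1L]; se <- prop[2L]
    pc <- new
    trace <- c(trace, pc$ll)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }

  h2 <- sg / (sg + se)
  se_h2 <- NA_real_
  cov_par <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(cov_par)) {
    grad <- c(se, -sg) / (sg + se)^2
    vh <- drop(t(grad) %*% cov_par %*% grad)
    if (is.finite(vh) && vh >= 0) se_h2 <- sqrt(vh)
  }
  if (!converged)
    warning("REML did not converge within ", max_iter, " iterations")
  list(h2 = min(max(h2, 0), 1), se = se_h2,
       sigma_g2 = sg, sigma_e2 = se,
       loglik = pc$ll, converged = converged,
       n_iter = length(trace) - 1L, loglik_trace = trace)
}
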