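## User-level NB GLM fitting, nested-model likelihood-ratio tests and
## Benjamini-Hochberg adjustment.

#' Fit per-gene negative binomial GLMs
#'
#' Log-link NB GLMs are fitted gene-by-gene by iteratively reweighted
#' least squares with step-halving, holding each gene's dispersion fixed.
#' Offsets are `log(lib_size * norm_factor)`. Coefficients are on the
#' natural-log scale; divide by `log(2)` for log2 fold changes.
#'
#' @param x a [count_data] object.
#' @param design model matrix or formula (treatment coding, reference
#'   levels female / carbohydrate-rich).
#' @param norm factors from [tmm_normalize()]; computed if `NULL`.
#' @param dispersions a `dispersion_estimates` object, a numeric vector
#'   (one per gene, recycled), or a single value.
#' @param maxit,tol IRLS iteration cap and relative deviance tolerance.
#' @return An `nb_glm_fit` object: coefficients, per-gene log-likelihood,
#'   deviance, Cox-Reid adjustment, convergence and boundary flags, plus
#'   the design, offsets and dispersions used.
#' @export
fit_nb_glm <- function(x, design, norm = NULL, dispersions = 0.1,
                       maxit = 50L, tol = 1e-8) {
  stopifnot(inherits(x, "count_data"))
  X <- build_design(design, x$samples)
  if (is.null(norm)) norm <- tmm_normalize(x)
  offset <- log(norm$lib_size * norm$norm_factor)
  phi <- dispersion_vector(dispersions, x)
  fit <- fit_nb_glm_cpp(x$counts, X, offset, phi, maxit, tol)
  rownames(fit$coefficients) <- rownames(x$counts)
  colnames(fit$coefficients) <- colnames(X)
  structure(list(genes = rownames(x$counts),
                 coefficients = fit$coefficients,
                 fitted = fit$fitted,
                 loglik = as.numeric(fit$loglik),
                 deviance = as.numeric(fit$deviance),
                 cr_adj = as.numeric(fit$cr_adj),
                 converged = as.logical(fit$converged),
                 boundary = as.logical(fit$boundary),
                 design = X, offset = offset, dispersion = phi),
            class = "nb_glm_fit")
}

dispersion_vector <- function(dispersions, x) {
  g <- nrow(x$counts)
  if (inherits(dispersions, "dispersion_estimates")) {
    phi <- dispersions$genewise$tagwise[match(rownames(x$counts),
                                              dispersions$genewise$gene)]
    if (anyNA(phi)) abort_usage("dispersions missing for some genes.")
    phi
  } else if (length(dispersions) == 1L) {
    rep(as.numeric(dispersions), g)
  } else if (length(dispersions) == g) {
    as.numeric(dispersions)
  } else {
    abort_usage("`dispersions` must be scalar, per-gene, or a dispersion_estimates object.")
  }
}

#' @export
print.nb_glm_fit <- function(x, ...) {
  cat(sprintf("<nb_glm_fit> %d genes, %d coefficients, %d non-converged\n",
              length(x$genes), ncol(x$coefficients), sum(!x$converged)))
  invisible(x)
}

#' Likelihood-ratio test between nested per-gene fits
#'
#' `LR = 2 (ll_full - ll_reduced)`, clipped at zero, referred to a
#' chi-squared distribution with degrees of freedom equal to the rank
#' difference of the two designs. Dispersions must be identical in both
#' fits (they are profiled out once, then held fixed, so the models are
#' nested in the mean structure only).
#'
#' @param fit_full,fit_reduced `nb_glm_fit` objects on the same genes; the
#'   reduced design must be nested in the full design.
#' @return Tibble with columns `gene`, `LR`, `df`, `p`.
#' @export
lrt_term <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "nb_glm_fit"), inherits(fit_reduced, "nb_glm_fit"))
  if (!identical(fit_full$genes, fit_reduced$genes)) {
    abort_usage("fits cover different genes.")
  }
  if (max(abs(fit_full$dispersion - fit_reduced$dispersion)) > 1e-12) {
    abort_usage("dispersions differ between fits; hold them fixed across both.")
  }
  Xf <- fit_full$design; Xr <- fit_reduced$design
  rank_f <- qr(Xf)$rank; rank_r <- qr(Xr)$rank
  # nestedness: every reduced column must lie in the full column space
  proj <- Xf %*% qr.coef(qr(Xf), Xr)
  proj[is.na(proj)] <- 0
  if (max(abs(proj - Xr)) > 1e-8 || rank_r > rank_f) {
    abort_usage("reduced design is not nested in the full design.")
  }
  df <- rank_f - rank_r
  LR <- pmax(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- if (df == 0) rep(1, length(LR)) else pchisq(LR, df = df, lower.tail = FALSE)
  if (df == 0) LR <- rep(0, length(LR))   # identical model spaces
  tibble(gene = fit_full$genes, LR = LR, df = df, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone in rank with ties preserved.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    abort_data("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}
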