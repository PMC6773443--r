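## High-level differential expression for the sex x diet design, and
## per-sex diet-only fold changes.

#' Sex-by-diet differential expression
#'
#' Runs the full engine on shared genes: TMM normalization, Cox-Reid
#' dispersion estimation on the complete design, NB GLM fits, and one
#' likelihood-ratio test per model term (each df = 1, dispersions held
#' fixed, all invariant to factor coding):
#'
#' * `S`  — sex main effect: `~ sex + diet` vs `~ diet`;
#' * `D`  — diet main effect: `~ sex + diet` vs `~ sex`;
#' * `DxS` — interaction: `~ sex * diet` vs `~ sex + diet`.
#'
#' Reported log2 fold changes use treatment coding with reference female /
#' carbohydrate-rich: `logFC_D` is the carbohydrate-to-protein shift
#' (additive model), `logFC_S` the male-vs-female shift, and `logFC_DxS`
#' the male-minus-female difference in diet response. q-values are BH
#' within each term across all genes tested.
#'
#' @param x a [count_data] of shared genes (already filtered).
#' @param norm factors from [tmm_normalize()]; computed if `NULL`.
#' @param dispersions a `dispersion_estimates` object; estimated on the
#'   full dataset if `NULL`.
#' @param prior_df shrinkage prior df when dispersions are estimated here.
#' @return A `de_result` object whose `results` element is a tibble with
#'   columns `gene`, `logCPM`, then `logFC`/`LR`/`p`/`q` per term, plus a
#'   `converged` flag.
#' @export
de_fit <- function(x, norm = NULL, dispersions = NULL, prior_df = 10) {
  stopifnot(inherits(x, "count_data"))
  if (length(unique(x$samples$sex)) < 2 || length(unique(x$samples$diet)) < 2) {
    abort_usage("de_fit needs both sexes and both diets.")
  }
  if (is.null(norm)) norm <- tmm_normalize(x)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(x, ~ sex * diet, norm, prior_df = prior_df)
  }
  fit_full <- fit_nb_glm(x, ~ sex * diet, norm, dispersions)
  fit_sd <- fit_nb_glm(x, ~ sex + diet, norm, dispersions)
  fit_s <- fit_nb_glm(x, ~ sex, norm, dispersions)
  fit_d <- fit_nb_glm(x, ~ diet, norm, dispersions)

  t_S <- lrt_term(fit_sd, fit_d)
  t_D <- lrt_term(fit_sd, fit_s)
  t_I <- lrt_term(fit_full, fit_sd)

  log2e <- 1 / log(2)
  results <- tibble(
    gene = fit_full$genes,
    logCPM = ave_log_cpm(x, norm),
    logFC_S = fit_sd$coefficients[, "sexM"] * log2e,
    LR_S = t_S$LR, p_S = t_S$p, q_S = bh_adjust(t_S$p),
    logFC_D = fit_sd$coefficients[, "dietP"] * log2e,
    LR_D = t_D$LR, p_D = t_D$p, q_D = bh_adjust(t_D$p),
    logFC_DxS = fit_full$coefficients[, "sexM:dietP"] * log2e,
    LR_DxS = t_I$LR, p_DxS = t_I$p, q_DxS = bh_adjust(t_I$p),
    converged = fit_full$converged & fit_sd$converged &
      fit_s$converged & fit_d$converged)
  nd_log(sprintf("de_fit: %d genes, common dispersion %.4g, %d non-converged.",
                 nrow(results),
                 if (inherits(dispersions, "dispersion_estimates")) dispersions$common else NA,
                 sum(!results$converged)))
  structure(list(results = results, dispersions = dispersions,
                 norm = norm, fits = list(full = fit_full, additive = fit_sd)),
            class = "de_result")
}

ave_log_cpm <- function(x, norm = NULL) {
  log2(rowMeans(cpm(x, norm)) + 0.5)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %d genes\n", nrow(x$results)))
  print(head(x$results))
  invisible(x)
}

#' Per-sex diet-only fold changes
#'
#' Refits a diet-only NB GLM separately to each sex's libraries, with
#' normalization factors and dispersions recomputed within the subset, and
#' tests the diet term by LRT (`~ diet` vs `~ 1`). Fold changes are
#' oriented carbohydrate-to-protein (positive = higher on the protein-rich
#' diet). BH adjustment is within sex; the four-way significance flag
#' combines the two sexes at `alpha`.
#'
#' @param x a [count_data] with both diets present within each sex.
#' @param alpha working FDR threshold for the flags (default 0.05).
#' @param prior_df shrinkage prior df for the within-sex dispersions.
#' @param recompute_within_sex recompute normalization/dispersions within
#'   each sex subset (default) or reuse estimates from the full data.
#' @param dispersions full-data `dispersion_estimates`, used only when
#'   `recompute_within_sex = FALSE`.
#' @return Tibble with columns `gene`, `logfc_female`, `logfc_male`,
#'   `p_female`, `p_male`, `q_female`, `q_male`, `signif` (one of
#'   `both`, `female_only`, `male_only`, `neither`).
#' @export
per_sex_fold_changes <- function(x, alpha = 0.05, prior_df = 10,
                                 recompute_within_sex = TRUE,
                                 dispersions = NULL) {
  stopifnot(inherits(x, "count_data"))
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  one_sex <- function(sex) {
    sub <- subset_samples(x, x$samples$sex == sex)
    if (length(unique(sub$samples$diet)) < 2) {
      abort_usage(sprintf("sex %s has a single diet level.", sex))
    }
    norm <- tmm_normalize(sub)
    disp <- if (recompute_within_sex || is.null(dispersions)) {
      estimate_dispersions(sub, ~ diet, norm, prior_df = prior_df)
    } else dispersions
    fit1 <- fit_nb_glm(sub, ~ diet, norm, disp)
    fit0 <- fit_nb_glm(sub, ~ 1, norm, disp)
    t <- lrt_term(fit1, fit0)
    tibble(gene = fit1$genes,
           logfc = fit1$coefficients[, "dietP"] / log(2),
           p = t$p, q = bh_adjust(t$p),
           boundary = fit1$boundary)
  }
  f <- one_sex("F"); m <- one_sex("M")
  out <- tibble(gene = f$gene,
                logfc_female = ifelse(f$boundary, NA_real_, f$logfc),
                logfc_male = ifelse(m$boundary, NA_real_, m$logfc),
                p_female = f$p, p_male = m$p,
                q_female = f$q, q_male = m$q)
  out$signif <- dplyr::case_when(
    out$q_female < alpha & out$q_male < alpha ~ "both",
    out$q_female < alpha ~ "female_only",
    out$q_male < alpha ~ "male_only",
    TRUE ~ "neither")
  class(out) <- c("fold_change_pair", class(out))
  out
}
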