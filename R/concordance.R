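## Cross-sex fold-change concordance: per-set correlations, the
## non-metabolic baseline set, and the bootstrapped correlation contrast.

#' Cross-sex fold-change correlation within a gene set
#'
#' Pearson correlation (Spearman via `method`) between male and female
#' carbohydrate-to-protein log2 fold changes, restricted to the genes of a
#' set; the two-sided p-value uses the t approximation.
#'
#' @param fc a `fold_change_pair` tibble from [per_sex_fold_changes()].
#' @param gene_set character vector of gene ids (`NULL` = all genes in
#'   `fc`).
#' @param set_name label carried into the result.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble: `set`, `n`, `r`, `p`.
#' @export
cross_sex_correlation <- function(fc, gene_set = NULL, set_name = "set",
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  fc <- as_tibble(fc)
  if (!all(c("gene", "logfc_female", "logfc_male") %in% names(fc))) {
    abort_usage("`fc` must carry gene, logfc_female and logfc_male columns.")
  }
  if (!is.null(gene_set)) fc <- fc[fc$gene %in% gene_set, ]
  fc <- fc[complete.cases(fc[c("logfc_female", "logfc_male")]), ]
  if (nrow(fc) < 3L) abort_data("fewer than 3 usable genes; correlation undefined.")
  ct <- suppressWarnings(
    cor.test(fc$logfc_male, fc$logfc_female, method = method))
  tibble(set = set_name, n = nrow(fc),
         r = unname(ct$estimate), p = ct$p.value)
}

#' Descendants of a term in a parent -> child hierarchy
#'
#' @param hierarchy tibble of `parent`, `child` edges.
#' @param term term name.
#' @param include_self include `term` itself (default TRUE).
#' @return Character vector of term names.
#' @export
term_descendants <- function(hierarchy, term, include_self = TRUE) {
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    kids <- hierarchy$child[hierarchy$parent %in% frontier]
    kids <- setdiff(kids, seen)
    seen <- c(seen, kids)
    frontier <- kids
  }
  if (include_self) unique(c(term, seen)) else unique(seen)
}

#' Build the non-excluded baseline gene set
#'
#' Takes the genes annotated to a parent term and removes every gene
#' annotated to an excluded term or any of its descendants in the
#' hierarchy — the construction used to form a "biological process minus
#' metabolic process" expression baseline.
#'
#' @param collection a `gene_set_collection` (named list of gene vectors).
#' @param hierarchy tibble of `parent`, `child` term edges.
#' @param parent_term,exclude_term term names; `exclude_term` must be a
#'   descendant of `parent_term`.
#' @return Character vector of baseline gene ids.
#' @export
build_baseline_set <- function(collection, hierarchy,
                               parent_term = "biological_process",
                               exclude_term = "metabolic_process") {
  if (!parent_term %in% names(collection)) {
    abort_usage(sprintf("term '%s' missing from the collection.", parent_term))
  }
  if (!exclude_term %in% names(collection)) {
    abort_usage(sprintf("term '%s' missing from the collection.", exclude_term))
  }
  if (!exclude_term %in% term_descendants(hierarchy, parent_term, include_self = FALSE)) {
    abort_usage(sprintf("'%s' is not a descendant of '%s' in the hierarchy.",
                        exclude_term, parent_term))
  }
  branch <- term_descendants(hierarchy, exclude_term, include_self = TRUE)
  excluded <- unique(unlist(collection[intersect(branch, names(collection))]))
  setdiff(collection[[parent_term]], excluded)
}

#' Bootstrapped contrast of two cross-sex correlations
#'
#' Resamples genes with replacement independently within a target set and
#' a baseline set, recomputing both correlations per replicate, and
#' reports 95% percentile intervals for each correlation and for their
#' difference, plus a two-sided empirical p-value for the difference
#' (floored at 1/B). Degenerate resamples with zero variance on either
#' axis are redrawn and counted.
#'
#' @param fc a `fold_change_pair` tibble.
#' @param target_set,baseline_set character vectors of gene ids (>= 3
#'   usable genes each).
#' @param B bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param target_name,baseline_name labels.
#' @param method correlation flavour passed to [cross_sex_correlation()].
#' @return A `bootstrap_contrast` object: observed correlations, replicate
#'   draws, percentile CIs, difference CI and empirical p.
#' @export
bootstrap_correlation_contrast <- function(fc, target_set, baseline_set,
                                           B = 1000, seed = 1L,
                                           target_name = "target",
                                           baseline_name = "baseline",
                                           method = "pearson") {
  if (B < 100) abort_param("B must be at least 100.")
  fc <- as_tibble(fc)
  fc <- fc[complete.cases(fc[c("logfc_female", "logfc_male")]), ]
  pick <- function(set) fc[fc$gene %in% set, c("logfc_female", "logfc_male")]
  tgt <- pick(target_set); base <- pick(baseline_set)
  if (nrow(tgt) < 3L || nrow(base) < 3L) {
    abort_data("both sets need >= 3 genes with fold changes.")
  }
  corr <- function(d) cor(d$logfc_male, d$logfc_female,
                          method = method)
  r_obs_t <- corr(tgt); r_obs_b <- corr(base)

  n_degenerate <- 0L
  draw_one <- function(d) {
    repeat {
      idx <- sample.int(nrow(d), replace = TRUE)
      s <- d[idx, ]
      if (var(s$logfc_male) > 0 && var(s$logfc_female) > 0) return(corr(s))
      n_degenerate <<- n_degenerate + 1L
    }
  }
  draws <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) c(draw_one(tgt), draw_one(base)),
             numeric(2)))
  })
  if (n_degenerate > 0) {
    nd_log(sprintf("bootstrap_correlation_contrast: %d degenerate resample(s) redrawn.",
                   n_degenerate))
  }
  r_t <- draws[, 1]; r_b <- draws[, 2]
  diff <- r_t - r_b
  p <- max(2 * min(mean(diff <= 0), mean(diff >= 0)), 1 / B)
  p <- min(p, 1)
  ci <- function(v) unname(quantile(v, c(0.025, 0.975)))
  structure(list(target = target_name, baseline = baseline_name,
                 B = B, seed = seed, method = method,
                 r_target = r_obs_t, r_baseline = r_obs_b,
                 draws = tibble(replicate = seq_len(B),
                                r_target = r_t, r_baseline = r_b),
                 ci_target = ci(r_t), ci_baseline = ci(r_b),
                 ci_diff = ci(diff), p = p,
                 n_degenerate = n_degenerate),
            class = "bootstrap_contrast")
}

#' @export
print.bootstrap_contrast <- function(x, ...) {
  cat(sprintf("<bootstrap_contrast> %s vs %s (B = %d)\n", x$target, x$baseline, x$B))
  cat(sprintf("  r_%s = %.3f [%.3f, %.3f]\n", x$target, x$r_target,
              x$ci_target[1], x$ci_target[2]))
  cat(sprintf("  r_%s = %.3f [%.3f, %.3f]\n", x$baseline, x$r_baseline,
              x$ci_baseline[1], x$ci_baseline[2]))
  cat(sprintf("  difference CI [%.3f, %.3f], empirical p = %.4g\n",
              x$ci_diff[1], x$ci_diff[2], x$p))
  invisible(x)
}
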