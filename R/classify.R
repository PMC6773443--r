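## Partition genes by detection pattern, classify shared genes into the
## eight significance cells and three headline diet-response categories,
## and summarize sex-limited differential expression.

#' Partition genes by detection across the sexes
#'
#' A gene is "detected" in a library when its raw count is at least one
#' (CPM-based detection available via `min_cpm`). Shared genes are
#' detected in at least one library of each sex; male-limited genes in at
#' least one male library and no female library; female-limited genes
#' symmetric. Genes detected nowhere are dropped with a logged count.
#'
#' @param x a [count_data] with raw (pre-normalization) counts.
#' @param min_cpm optional CPM threshold defining detection instead of the
#'   raw-count rule.
#' @return A `detection_partition` object: list of character vectors
#'   `shared`, `male_limited`, `female_limited` plus a `counts` tibble.
#' @export
partition_by_detection <- function(x, min_cpm = NULL) {
  stopifnot(inherits(x, "count_data"))
  if (!all(c("F", "M") %in% x$samples$sex)) abort_usage("both sexes required.")
  mat <- if (is.null(min_cpm)) x$counts >= 1 else cpm(x) > min_cpm
  det_f <- rowSums(mat[, x$samples$sex == "F", drop = FALSE]) > 0
  det_m <- rowSums(mat[, x$samples$sex == "M", drop = FALSE]) > 0
  genes <- rownames(x$counts)
  shared <- genes[det_f & det_m]
  male_limited <- genes[det_m & !det_f]
  female_limited <- genes[det_f & !det_m]
  n_none <- sum(!det_f & !det_m)
  nd_log(sprintf(
    "partition_by_detection: %d shared, %d male-limited, %d female-limited, %d undetected (dropped).",
    length(shared), length(male_limited), length(female_limited), n_none))
  structure(list(shared = shared, male_limited = male_limited,
                 female_limited = female_limited,
                 counts = tibble(class = c("shared", "male_limited",
                                           "female_limited", "undetected"),
                                 n = c(length(shared), length(male_limited),
                                       length(female_limited), n_none))),
            class = "detection_partition")
}

#' @export
print.detection_partition <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Classify shared genes by significance pattern
#'
#' Assigns each gene to one of the eight cells defined by the significance
#' (q < `alpha`) of the sex, diet and interaction terms, and to a headline
#' category: `D` (diet significant, interaction not — sexually concordant
#' response), `DxS` (interaction significant, diet not — opposing
#' response), `DplusDxS` (both — sex-biased response), `none` otherwise.
#' Genes whose GLM failed to converge are assigned cell `untestable` and
#' excluded from the cell summary, with a logged count.
#'
#' @param de a `de_result` from [de_fit()] (or its `results` tibble).
#' @param alpha working FDR threshold (default 0.05).
#' @return A `gene_classification` object: `genes` tibble (`gene`, `q_S`,
#'   `q_D`, `q_DxS`, `sig_S`, `sig_D`, `sig_DxS`, `cell`, `category`) and
#'   `cells`, an 8-row summary in the S/D/DxS layout.
#' @export
classify_patterns <- function(de, alpha = 0.05) {
  res <- if (inherits(de, "de_result")) de$results else as_tibble(de)
  need <- c("gene", "q_S", "q_D", "q_DxS")
  if (!all(need %in% names(res))) {
    abort_usage("classification needs q-values for all three terms (q_S, q_D, q_DxS).")
  }
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  converged <- res$converged %||% rep(TRUE, nrow(res))

  g <- tibble(gene = res$gene,
              q_S = res$q_S, q_D = res$q_D, q_DxS = res$q_DxS,
              sig_S = res$q_S < alpha,
              sig_D = res$q_D < alpha,
              sig_DxS = res$q_DxS < alpha,
              testable = converged)
  g$cell <- ifelse(g$testable,
                   paste0(ifelse(g$sig_S, "S", "-"),
                          ifelse(g$sig_D, "D", "-"),
                          ifelse(g$sig_DxS, "I", "-")),
                   "untestable")
  g$category <- dplyr::case_when(
    !g$testable ~ "untestable",
    g$sig_D & g$sig_DxS ~ "DplusDxS",
    g$sig_D ~ "D",
    g$sig_DxS ~ "DxS",
    TRUE ~ "none")
  if (any(!g$testable)) {
    nd_log(sprintf("classify_patterns: %d untestable gene(s) excluded from totals.",
                   sum(!g$testable)))
  }

  layout <- tidyr::expand_grid(sig_S = c(FALSE, TRUE),
                               sig_D = c(FALSE, TRUE),
                               sig_DxS = c(FALSE, TRUE))
  cells <- g |>
    filter(.data$testable) |>
    count(.data$sig_S, .data$sig_D, .data$sig_DxS, name = "n_genes") |>
    right_join2(layout) |>
    mutate(n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes)) |>
    arrange(.data$sig_S, .data$sig_D, .data$sig_DxS) |>
    mutate(S = ifelse(.data$sig_S, "Y", "-"),
           D = ifelse(.data$sig_D, "Y", "-"),
           DxS = ifelse(.data$sig_DxS, "Y", "-"),
           category = dplyr::case_when(
             .data$sig_D & .data$sig_DxS ~ "DplusDxS",
             .data$sig_D ~ "D",
             .data$sig_DxS ~ "DxS",
             TRUE ~ "none")) |>
    select("S", "D", "DxS", "n_genes", "category")

  structure(list(genes = g, cells = cells, alpha = alpha),
            class = "gene_classification")
}

# right join without dplyr's key messages
right_join2 <- function(x, y) dplyr::right_join(x, y, by = intersect(names(x), names(y)))

#' @export
print.gene_classification <- function(x, ...) {
  cat(sprintf("<gene_classification> %d genes at FDR < %g\n",
              nrow(x$genes), x$alpha))
  print(x$cells)
  invisible(x)
}

#' Diet-only differential expression within sex-limited genes
#'
#' For each sex, fits a diet-only NB GLM to that sex's libraries on its
#' sex-limited genes, tests the diet term by LRT, and adjusts by BH within
#' the tested set only. Library sizes and TMM factors come from the sex's
#' complete count matrix (a small gene set cannot normalize itself: if all
#' its members shift together the shift is real signal, not depth);
#' dispersions are estimated on the sex-limited genes with those offsets.
#' `UP` counts significant genes with positive
#' carbohydrate-to-protein log2 fold change, `DOWN` significant negative,
#' `Ns` the rest, so `UP + Ns + DOWN` equals the number of genes tested.
#'
#' @param x a [count_data] with raw counts for all genes.
#' @param partition a `detection_partition` from [partition_by_detection()].
#' @param alpha FDR threshold (default 0.05; the source study also reports
#'   a 0.1 table).
#' @param prior_df shrinkage prior df for within-subset dispersions.
#' @return A `sex_limited_de` object: `genes` tibble (`gene`, `sex`,
#'   `logfc`, `p`, `q`, `call`) and `summary` tibble (`sex`, `UP`, `Ns`,
#'   `DOWN`, `total`).
#' @export
sex_limited_de <- function(x, partition, alpha = 0.05, prior_df = 10) {
  stopifnot(inherits(x, "count_data"), inherits(partition, "detection_partition"))
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  one_sex <- function(sex, genes) {
    if (length(genes) == 0L) {
      return(tibble(gene = character(), sex = character(), logfc = numeric(),
                    p = numeric(), q = numeric(), call = character()))
    }
    sub_all <- subset_samples(x, x$samples$sex == sex)
    if (length(unique(sub_all$samples$diet)) < 2) {
      abort_usage(sprintf("sex %s lacks libraries for both diets.", sex))
    }
    norm <- tmm_normalize(sub_all)          # whole-transcriptome offsets
    sub <- subset_genes(sub_all, genes)
    disp <- estimate_dispersions(sub, ~ diet, norm, prior_df = prior_df)
    fit1 <- fit_nb_glm(sub, ~ diet, norm, disp)
    fit0 <- fit_nb_glm(sub, ~ 1, norm, disp)
    t <- lrt_term(fit1, fit0)
    q <- bh_adjust(t$p)
    logfc <- fit1$coefficients[, "dietP"] / log(2)
    tibble(gene = genes, sex = sex, logfc = logfc, p = t$p, q = q,
           call = dplyr::case_when(q < alpha & logfc > 0 ~ "UP",
                                   q < alpha & logfc < 0 ~ "DOWN",
                                   TRUE ~ "Ns"))
  }
  genes <- bind_rows(one_sex("F", partition$female_limited),
                     one_sex("M", partition$male_limited))
  summary <- genes |>
    group_by(.data$sex) |>
    summarise(UP = sum(.data$call == "UP"), Ns = sum(.data$call == "Ns"),
              DOWN = sum(.data$call == "DOWN"), total = n(), .groups = "drop")
  structure(list(genes = genes, summary = summary, alpha = alpha),
            class = "sex_limited_de")
}

#' @export
print.sex_limited_de <- function(x, ...) {
  cat(sprintf("<sex_limited_de> FDR < %g\n", x$alpha))
  print(x$summary)
  invisible(x)
}

#' Summarize a classification in the headline-category layout
#'
#' Reports the gene count of each diet-response category and its
#' proportion of the diet-responsive total (D + DxS + DplusDxS).
#'
#' @param classification a `gene_classification` from [classify_patterns()].
#' @param partition optional `detection_partition`; when given, detection
#'   counts are attached to the report.
#' @return A list with `categories` (tibble: `category`, `n_genes`,
#'   `prop_of_responsive` in percent) and optionally `detection`.
#' @export
summarize_classification <- function(classification, partition = NULL) {
  stopifnot(inherits(classification, "gene_classification"))
  cats <- c("D", "DxS", "DplusDxS")
  counts <- vapply(cats, function(cc) sum(classification$genes$category == cc),
                   integer(1))
  total <- sum(counts)
  categories <- tibble(category = cats, n_genes = unname(counts),
                       prop_of_responsive = if (total > 0)
                         100 * unname(counts) / total else rep(0, 3))
  out <- list(categories = categories, responsive_total = total)
  if (!is.null(partition)) out$detection <- partition$counts
  out
}
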