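## Gene-list overlap testing with an explicit universe, classification
## correspondence (Pearson chi-squared), and generic hypergeometric
## gene-set enrichment.

#' Overlap of two gene lists in an explicit universe
#'
#' One-sided over-enrichment p-value `P(X >= k)` for
#' `X ~ Hypergeometric(N, n_a, n_b)` (equivalent to a one-sided Fisher
#' exact test on the 2x2 table), plus the expected overlap
#' `n_a * n_b / N`, the percent excess `100 * (k / expected - 1)`, and the
#' sample odds ratio (Haldane 0.5 correction only when a zero cell occurs,
#' logged). Sets must be subsets of the universe — they are never silently
#' intersected.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe character vector containing both sets.
#' @param alternative `"greater"` (default, over-enrichment) or
#'   `"two.sided"`.
#' @param name_a,name_b labels carried into the result.
#' @return One-row tibble: `set_a`, `set_b`, `N`, `n_a`, `n_b`, `overlap`,
#'   `expected`, `pct_excess`, `odds_ratio`, `p`.
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           alternative = c("greater", "two.sided"),
                           name_a = "A", name_b = "B") {
  alternative <- match.arg(alternative)
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort_usage("both sets must be contained in the universe (no silent intersection).")
  }
  N <- length(universe); n_a <- length(set_a); n_b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  expected <- n_a * n_b / N
  p <- switch(alternative,
    greater = phyper(k - 1, n_a, N - n_a, n_b, lower.tail = FALSE),
    two.sided = {
      dk <- dhyper(0:min(n_a, n_b), n_a, N - n_a, n_b)
      sum(dk[dk <= dhyper(k, n_a, N - n_a, n_b) * (1 + 1e-7)])
    })
  a <- k; b <- n_a - k; c_ <- n_b - k; d <- N - n_a - n_b + k
  if (min(a, b, c_, d) == 0) {
    nd_log("fisher_overlap: zero cell, Haldane 0.5 correction applied to the odds ratio.")
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  tibble(set_a = name_a, set_b = name_b, N = N, n_a = n_a, n_b = n_b,
         overlap = k, expected = expected,
         pct_excess = if (expected > 0) 100 * (k / expected - 1) else NA_real_,
         odds_ratio = (a * d) / (b * c_), p = min(p, 1))
}

#' Intersect two expressed-gene lists into a comparison universe
#'
#' Cross-study comparisons should test overlap only among genes expressed
#' in both datasets; this helper builds that universe.
#'
#' @param expressed_a,expressed_b character vectors of expressed genes.
#' @return Character vector, the intersection.
#' @export
shared_universe <- function(expressed_a, expressed_b) {
  intersect(unique(expressed_a), unique(expressed_b))
}

#' Correspondence of two categorical gene classifications
#'
#' Pearson chi-squared test (no continuity correction) on the R x C
#' contingency table of two labelings over the identical gene universe,
#' with per-cell observed/expected ratios. A warning is logged when any
#' expected cell is below 5.
#'
#' @param labels_a,labels_b named character vectors (names = gene ids) or
#'   factors/characters of equal length on the same genes.
#' @return A `correspondence_result`: list with `table`, `statistic`,
#'   `df`, `p`, and `cells` (tibble of observed, expected, ratio).
#' @export
classification_correspondence <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      abort_usage("labelings are defined on different gene universes.")
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    abort_usage("labelings are defined on different gene universes.")
  }
  tab <- table(a = as.character(labels_a), b = as.character(labels_b))
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort_usage("each labeling needs at least two classes.")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    nd_log("classification_correspondence: expected cell(s) < 5; chi-squared approximation is rough.")
  }
  cells <- as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(cells) <- c("class_a", "class_b", "observed")
  rowm <- rowSums(tab); colm <- colSums(tab); N <- sum(tab)
  cells$expected <- rowm[cells$class_a] * colm[cells$class_b] / N
  cells$ratio <- cells$observed / cells$expected
  structure(list(table = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value, cells = cells),
            class = "correspondence_result")
}

#' @export
print.correspondence_result <- function(x, ...) {
  cat(sprintf("<correspondence_result> X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  print(x$table)
  invisible(x)
}

#' Hypergeometric enrichment of a query set against a collection
#'
#' Runs [fisher_overlap()] of the query against every member of a gene-set
#' collection, adjusts p-values by BH across the collection, and sorts by
#' q then p.
#'
#' @param query_set character vector of gene ids, a subset of `universe`.
#' @param collection a `gene_set_collection` (named list of gene vectors);
#'   members are restricted to the universe before testing.
#' @param universe explicit gene universe.
#' @return Tibble of per-set overlap rows with a `q` column, sorted by
#'   ascending q.
#' @export
enrich_gene_sets <- function(query_set, collection, universe) {
  if (length(collection) == 0L) {
    return(tibble(set_a = character(), set_b = character(), N = integer(),
                  n_a = integer(), n_b = integer(), overlap = integer(),
                  expected = numeric(), pct_excess = numeric(),
                  odds_ratio = numeric(), p = numeric(), q = numeric()))
  }
  rows <- purrr::imap(unclass(collection)[names(collection)], function(members, nm) {
    fisher_overlap(query_set, intersect(members, universe), universe,
                   name_a = "query", name_b = nm)
  })
  out <- bind_rows(rows)
  out$q <- bh_adjust(out$p)
  arrange(out, .data$q, .data$p)
}
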