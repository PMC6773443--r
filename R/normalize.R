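## TMM normalization, CPM and expression filtering.

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes between-library scaling factors from first principles. The
#' reference library is the one whose 75th-percentile count fraction is
#' closest to the mean across libraries. For each library, M (log2 ratio)
#' and A (average log2 abundance) values are computed on genes nonzero in
#' both the library and the reference; genes in the most extreme 30% of M
#' (two-sided) or 5% of A are trimmed; the factor is 2 to the
#' precision-weighted mean of the retained M values (inverse delta-method
#' variances as weights), and factors are rescaled to geometric mean 1.
#'
#' @param x a [count_data] object or a count matrix.
#' @return Tibble with columns `sample`, `lib_size`, `norm_factor`.
#' @export
tmm_normalize <- function(x) {
  counts <- if (inherits(x, "count_data")) x$counts else as.matrix(x)
  if (ncol(counts) < 2L) abort_data("TMM needs at least two samples.")
  lib <- colSums(counts)
  if (any(lib == 0)) abort_data("sample with zero total count.")
  if (all(counts == 0)) abort_data("all counts are zero.")

  frac75 <- apply(counts, 2, function(col) quantile(col, 0.75)) / lib
  ref <- which.min(abs(frac75 - mean(frac75)))

  f <- vapply(seq_len(ncol(counts)), function(i) {
    tmm_pair_factor(counts[, i], counts[, ref], lib[i], lib[ref])
  }, numeric(1))
  f <- f / geometric_mean(f)
  tibble(sample = colnames(counts) %||% paste0("s", seq_along(lib)),
         lib_size = unname(lib), norm_factor = unname(f))
}

# one library against the reference; the trim-and-weight recipe
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            m_trim = 0.3, a_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / n_obs) / (r / n_ref))
  A <- 0.5 * log2((o / n_obs) * (r / n_ref))
  v <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)

  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * m_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * a_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  kept <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(kept)) return(1)
  2^(sum(M[kept] / v[kept]) / sum(1 / v[kept]))
}

#' Counts per million
#'
#' @param x a [count_data] or count matrix.
#' @param norm optional tibble from [tmm_normalize()]; when supplied,
#'   effective library sizes `lib_size * norm_factor` are used.
#' @param log return `log2(cpm + prior)`?
#' @param prior_count prior added before taking logs.
#' @return Matrix of CPM values with the input dimnames.
#' @export
cpm <- function(x, norm = NULL, log = FALSE, prior_count = 0.5) {
  counts <- if (inherits(x, "count_data")) x$counts else as.matrix(x)
  lib <- colSums(counts)
  if (!is.null(norm)) {
    f <- norm$norm_factor[match(colnames(counts), norm$sample)]
    lib <- lib * f
  }
  out <- t(t(counts) / lib) * 1e6
  if (log) log2(out + prior_count) else out
}

#' Remove lowly expressed genes
#'
#' Keeps genes with CPM strictly above `cpm_threshold` in at least
#' `min_samples` libraries (raw library sizes; filtering precedes
#' normalization). The number removed is logged.
#'
#' @param x a [count_data] object.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param min_samples minimum libraries above the cutoff (default 3, the
#'   smallest cell size in the target design).
#' @return The retained [count_data] subset.
#' @export
filter_low_expression <- function(x, cpm_threshold = 1, min_samples = 3) {
  stopifnot(inherits(x, "count_data"))
  if (cpm_threshold < 0 || min_samples < 0) abort_param("thresholds must be >= 0.")
  keep <- rowSums(cpm(x) > cpm_threshold) >= min_samples
  nd_log(sprintf("filter_low_expression: removed %d of %d genes (CPM > %g in >= %d samples).",
                 sum(!keep), length(keep), cpm_threshold, min_samples))
  subset_genes(x, rownames(x$counts)[keep])
}

#' Subset a count dataset to named genes
#'
#' @param x a [count_data] object.
#' @param genes character vector of gene identifiers to keep (order kept).
#' @return A [count_data] with the same samples.
#' @export
subset_genes <- function(x, genes) {
  structure(list(counts = x$counts[genes, , drop = FALSE], samples = x$samples),
            class = "count_data")
}

subset_samples <- function(x, idx) {
  structure(list(counts = x$counts[, idx, drop = FALSE],
                 samples = x$samples[idx, , drop = FALSE]),
            class = "count_data")
}
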