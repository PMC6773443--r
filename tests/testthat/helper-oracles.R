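## Independent oracles, coded from the written recipes and kept separate
## from the package implementations they check.

options(nutridimorph.verbose = FALSE)

# literal, loop-based TMM: reference by 75th-percentile fraction, M/A on
# doubly-nonzero genes, 30%/5% two-sided trims by rank, inverse-variance
# weighted mean of retained M, geometric-mean-1 rescale
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  p75 <- numeric(ncol(counts))
  for (i in seq_len(ncol(counts))) p75[i] <- quantile(counts[, i], 0.75) / lib[i]
  ref <- which.min(abs(p75 - mean(p75)))
  f <- numeric(ncol(counts))
  for (i in seq_len(ncol(counts))) {
    M <- c(); A <- c(); v <- c()
    for (g in seq_len(nrow(counts))) {
      yo <- counts[g, i]; yr <- counts[g, ref]
      if (yo > 0 && yr > 0) {
        M <- c(M, log2((yo / lib[i]) / (yr / lib[ref])))
        A <- c(A, 0.5 * log2((yo / lib[i]) * (yr / lib[ref])))
        v <- c(v, (lib[i] - yo) / (lib[i] * yo) + (lib[ref] - yr) / (lib[ref] * yr))
      }
    }
    if (length(M) == 0 || max(abs(M)) < 1e-6) { f[i] <- 1; next }
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f[i] <- if (any(keep)) 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep])) else 1
  }
  f / exp(mean(log(f)))
}

# sort-and-cumulative-minimum BH
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# hypergeometric upper tail P(X >= k) by the choose() formula
oracle_hyper_p <- function(N, na, nb, k) {
  js <- k:min(na, nb)
  if (k > min(na, nb)) return(0)
  sum(choose(na, js) * choose(N - na, nb - js)) / choose(N, nb)
}

# exhaustive enumeration over all C(N, nb) draws of set B
oracle_hyper_enum <- function(N, na, k) {
  function(nb) {
    draws <- utils::combn(N, nb)
    mean(apply(draws, 2, function(b) sum(b <= na) >= k))
  }
}

ks_uniform <- function(p) {
  n <- length(p)
  sp <- sort(p)
  max(pmax(abs(sp - (seq_len(n) - 1) / n), abs(sp - seq_len(n) / n)))
}

# tiny count_data fixture with explicit values
tiny_counts <- function(counts, sexes, diets) {
  n <- ncol(counts)
  samp <- data.frame(sample = colnames(counts), sex = sexes, diet = diets,
                     replicate = ave(seq_len(n), sexes, diets, FUN = seq_along))
  count_data(counts, samp)
}

# bivariate-normal fold changes with target correlation, as a fold_change_pair
synth_fc <- function(genes, r, seed = 1, sd = 1) {
  set.seed(seed)
  n <- length(genes)
  x <- rnorm(n); y <- r * x + sqrt(1 - r^2) * rnorm(n)
  tibble::tibble(gene = genes, logfc_female = sd * x, logfc_male = sd * y,
                 p_female = NA_real_, p_male = NA_real_,
                 q_female = NA_real_, q_male = NA_real_, signif = "neither")
}
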