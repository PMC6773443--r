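test_that("fisher_overlap reproduces small exact cases", {
  fx <- make_overlap_fixture(4, 2, 2, 2, seed = 1)
  res <- fisher_overlap(fx$set_a, fx$set_b, fx$universe)
  expect_equal(res$p, 1 / 6)              # all C(4,2) draws equally likely
  expect_equal(res$expected, 1)
  fx0 <- make_overlap_fixture(20, 6, 5, 0, seed = 2)
  expect_equal(fisher_overlap(fx0$set_a, fx0$set_b, fx0$universe)$p, 1)
  expect_error(fisher_overlap(c("x", "zzz"), c("x"), c("x", "y")),
               class = "nutridimorph_usage_error")
})

test_that("fisher_overlap matches exhaustive enumeration and the choose() oracle", {
  # full subset enumeration for small universes
  for (case in list(c(6, 3, 2), c(8, 4, 4), c(10, 5, 3), c(12, 6, 4))) {
    N <- case[1]; na <- case[2]; nb <- case[3]
    universe <- sprintf("u%02d", 1:N)
    set_a <- universe[1:na]
    for (k in 0:min(na, nb)) {
      set_b <- c(set_a[seq_len(k)], setdiff(universe, set_a)[seq_len(nb - k)])
      p <- fisher_overlap(set_a, set_b, universe)$p
      expect_equal(p, oracle_hyper_enum(N, na, k)(nb), tolerance = 1e-12,
                   label = sprintf("N=%d na=%d nb=%d k=%d", N, na, nb, k))
    }
  }
  # choose()-formula oracle up to N = 30
  set.seed(9)
  for (i in 1:40) {
    N <- sample(10:30, 1); na <- sample(1:(N - 1), 1); nb <- sample(1:(N - 1), 1)
    k <- sample(max(0, na + nb - N):min(na, nb), 1)
    fx <- make_overlap_fixture(N, na, nb, k, seed = i)
    p <- fisher_overlap(fx$set_a, fx$set_b, fx$universe)$p
    expect_equal(p, oracle_hyper_p(N, na, nb, k), tolerance = 1e-12)
  }
})

test_that("overlap statistics are symmetric in set order", {
  fx <- make_overlap_fixture(50, 20, 12, 7, seed = 3)
  ab <- fisher_overlap(fx$set_a, fx$set_b, fx$universe)
  ba <- fisher_overlap(fx$set_b, fx$set_a, fx$universe)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$expected, ba$expected)
  expect_equal(ab$pct_excess, ba$pct_excess)
})

test_that("excess over expectation matches the reported-scale arithmetic", {
  # 489 observed vs ~351 expected in an N = 8310 universe -> ~39% excess
  fx <- make_overlap_fixture(8310, 806, 3618, 489, seed = 4)
  res <- fisher_overlap(fx$set_a, fx$set_b, fx$universe)
  expect_equal(res$expected, 806 * 3618 / 8310)
  expect_equal(res$pct_excess, 100 * (489 / res$expected - 1))
  expect_equal(round(res$pct_excess), 39)
  expect_lt(res$p, 0.001)
})

test_that("overlap p-values are calibrated under random sets", {
  set.seed(11)
  universe <- sprintf("u%04d", 1:400)
  ps <- vapply(1:1000, function(i) {
    a <- sample(universe, 40); b <- sample(universe, 60)
    fisher_overlap(a, b, universe)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.07)   # discrete p => at or below nominal
})

test_that("classification correspondence matches hand Pearson arithmetic", {
  labels_a <- setNames(rep(c("x", "y"), each = 10), sprintf("g%02d", 1:20))
  labels_b <- setNames(rep(c("u", "v"), each = 10), sprintf("g%02d", 1:20))
  res <- classification_correspondence(labels_a, labels_b)
  expect_equal(res$statistic, 20)      # [[10,0],[0,10]] closed form
  expect_equal(res$df, 1L)
  expect_equal(sum(res$table), 20)
  # proportional rows => exact independence, chi-squared 0
  lb <- setNames(rep(c("u", "v"), 10), sprintf("g%02d", 1:20))
  res0 <- classification_correspondence(labels_a, lb)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  # mismatched universes are refused
  expect_error(classification_correspondence(labels_a,
                                             setNames(lb, sprintf("h%02d", 1:20))),
               class = "nutridimorph_usage_error")
  # per-cell expected come from the margins
  expect_equal(sum(res$cells$expected), 20)
})

test_that("correspondence chi-squared agrees with a 4x4 hand computation", {
  set.seed(12)
  classes <- c("none", "D", "DxS", "DplusDxS")
  a <- sample(classes, 500, replace = TRUE, prob = c(0.7, 0.15, 0.05, 0.1))
  b <- ifelse(runif(500) < 0.4, a, sample(classes, 500, replace = TRUE))
  names(a) <- names(b) <- sprintf("g%03d", 1:500)
  res <- classification_correspondence(a, b)
  tab <- table(a, b)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 9L)
})

test_that("enrichment ranks the query's own set first with BH q >= p", {
  fx <- make_overlap_fixture(5000, 100, 100, 80, seed = 5)
  universe <- fx$universe
  set.seed(13)
  coll <- nutridimorph:::gene_set_collection(list(
    planted = fx$set_a,
    random1 = sample(universe, 120),
    random2 = sample(universe, 80),
    self = fx$set_b))
  res <- enrich_gene_sets(fx$set_b, coll, universe)
  expect_equal(res$set_b[1], "self")
  expect_lt(res$q[res$set_b == "planted"], 0.05)
  expect_true(all(res$q >= res$p - 1e-12))
  empty <- enrich_gene_sets(fx$set_b, nutridimorph:::gene_set_collection(list()),
                            universe)
  expect_equal(nrow(empty), 0L)
})
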