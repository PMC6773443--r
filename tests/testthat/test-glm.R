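unit_norm <- function(cd) {
  tibble::tibble(sample = cd$samples$sample,
                 lib_size = 1, norm_factor = 1)
}

test_that("saturated group design gives exact group-mean fold changes", {
  # groups (10, 20) vs (40, 80): NB MLE of each group mean is the
  # arithmetic mean for any dispersion, so log2FC = log2(60/15) = 2
  counts <- matrix(c(10L, 20L, 40L, 80L), 1, 4,
                   dimnames = list("g", paste0("s", 1:4)))
  cd <- tiny_counts(counts, rep("F", 4), c("C", "C", "P", "P"))
  for (phi in c(0, 0.05, 0.4)) {
    fit <- fit_nb_glm(cd, ~ diet, unit_norm(cd), dispersions = phi)
    expect_equal(unname(fit$coefficients[1, "dietP"]) / log(2), 2,
                 tolerance = 1e-8)
  }
})

test_that("coefficients match a fixed-theta NB GLM and the Poisson limit", {
  set.seed(2)
  G <- 25
  counts <- matrix(rnbinom(G * 12, mu = 60, size = 10), G, 12,
                   dimnames = list(sprintf("g%02d", 1:G), paste0("s", 1:12)))
  cd <- tiny_counts(counts, rep(c("F", "M"), each = 6),
                    rep(rep(c("C", "P"), each = 3), 2))
  norm <- tibble::tibble(sample = cd$samples$sample,
                         lib_size = colSums(counts), norm_factor = 1)
  fit <- fit_nb_glm(cd, ~ sex * diet, norm, dispersions = 0.1)
  fit0 <- fit_nb_glm(cd, ~ sex * diet, norm, dispersions = 0)
  df <- data.frame(sex = cd$samples$sex, diet = cd$samples$diet,
                   off = log(colSums(counts)))
  for (g in seq_len(G)) {
    df$y <- counts[g, ]
    gm <- glm(y ~ sex * diet + offset(off), data = df,
              family = MASS::negative.binomial(theta = 10))
    expect_equal(unname(fit$coefficients[g, ]), unname(coef(gm)),
                 tolerance = 1e-6)
    pm <- glm(y ~ sex * diet + offset(off), data = df, family = poisson())
    expect_equal(unname(fit0$coefficients[g, ]), unname(coef(pm)),
                 tolerance = 1e-6)
  }
})

test_that("intercept-only fit with equal offsets returns the mean count", {
  counts <- matrix(c(3L, 9L, 12L, 24L), 1, 4,
                   dimnames = list("g", paste0("s", 1:4)))
  cd <- tiny_counts(counts, rep("F", 4), rep("C", 4))
  fit <- fit_nb_glm(cd, ~ 1, unit_norm(cd), dispersions = 0.2)
  expect_equal(unname(exp(fit$coefficients[1, 1])), mean(counts), tolerance = 1e-8)
})

test_that("LRT is zero for identical designs and rejects non-nested ones", {
  set.seed(3)
  counts <- matrix(rnbinom(10 * 12, mu = 50, size = 8), 10, 12,
                   dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:12)))
  cd <- tiny_counts(counts, rep(c("F", "M"), each = 6),
                    rep(rep(c("C", "P"), each = 3), 2))
  norm <- tmm_normalize(cd)
  f1 <- fit_nb_glm(cd, ~ sex + diet, norm, dispersions = 0.1)
  f1b <- fit_nb_glm(cd, ~ sex + diet, norm, dispersions = 0.1)
  t <- lrt_term(f1, f1b)
  expect_true(all(t$LR == 0))
  expect_true(all(t$p == 1))
  fs <- fit_nb_glm(cd, ~ sex, norm, dispersions = 0.1)
  fd <- fit_nb_glm(cd, ~ diet, norm, dispersions = 0.1)
  expect_error(lrt_term(fs, fd), class = "nutridimorph_usage_error")
  # mismatched dispersions are refused
  fphi <- fit_nb_glm(cd, ~ sex, norm, dispersions = 0.2)
  expect_error(lrt_term(f1, fphi), class = "nutridimorph_usage_error")
})

test_that("LR statistics are invariant to design reparameterization", {
  set.seed(4)
  counts <- matrix(rnbinom(50 * 12, mu = 80, size = 10), 50, 12,
                   dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:12)))
  cd <- tiny_counts(counts, rep(c("F", "M"), each = 6),
                    rep(rep(c("C", "P"), each = 3), 2))
  norm <- tmm_normalize(cd)
  s <- ifelse(cd$samples$sex == "M", 1, -1)
  d <- ifelse(cd$samples$diet == "P", 1, -1)
  # treatment coding
  Xt_full <- model.matrix(~ sex * diet, data.frame(cd$samples))
  Xt_sd <- model.matrix(~ sex + diet, data.frame(cd$samples))
  Xt_s <- model.matrix(~ sex, data.frame(cd$samples))
  # sum-to-zero coding of the same model spaces
  Xs_full <- cbind(1, s, d, s * d)
  Xs_sd <- cbind(1, s, d)
  Xs_s <- cbind(1, s)
  lr <- function(Xf, Xr) {
    lrt_term(fit_nb_glm(cd, Xf, norm, dispersions = 0.1),
             fit_nb_glm(cd, Xr, norm, dispersions = 0.1))$LR
  }
  expect_equal(lr(Xt_full, Xt_sd), lr(Xs_full, Xs_sd), tolerance = 1e-6)
  expect_equal(lr(Xt_sd, Xt_s), lr(Xs_sd, Xs_s), tolerance = 1e-6)
})

test_that("planted diet effects yield tiny p-values at moderate dispersion", {
  p <- sim_count_params(n_genes = 300, n_D = 300, n_DxS = 0, n_DplusDxS = 0,
                        n_sexlim_male = 0, n_sexlim_female = 0,
                        effect_logfc = 2, dispersion = list(mean = 0.05, cv = 0),
                        lib_size_mean = 2e6, seed = 21)
  de <- de_fit(simulate_counts(p)$data)
  expect_lt(median(de$results$p_D), 1e-3)
})

test_that("BH adjustment follows the step-up rule and its oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "nutridimorph_data_error")
  expect_error(bh_adjust(c(0.1, NA)), class = "nutridimorph_data_error")
})
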