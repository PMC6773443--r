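test_that("standardization gives exact within-sex moments and keeps raw values", {
  lp <- landscape_params(n_per_sex = 60, seed = 1)
  tb <- standardize_fitness(simulate_landscape(lp))
  for (s in c("F", "M")) {
    z <- tb$fitness_z[tb$sex == s]
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
  expect_true("fitness_raw" %in% names(tb))
  const <- tibble::tibble(sex = rep(c("F", "M"), each = 5),
                          protein_intake = runif(10), carbohydrate_intake = runif(10),
                          fitness = rep(c(1, 2), c(5, 5)))
  expect_error(standardize_fitness(const), class = "nutridimorph_data_error")
})

test_that("noiseless gradients are recovered exactly up to the z scale", {
  lp <- landscape_params(n_per_sex = 80, beta_f = c(0.5, -0.2),
                         gamma_f = matrix(0, 2, 2), noise_sd = 0, seed = 2)
  raw <- simulate_landscape(lp)
  tb <- standardize_fitness(raw)
  s_f <- sd(raw$fitness[raw$sex == "F"])   # the z-transform scale factor
  fit <- fit_gradients(tb, "F")
  expect_equal(fit$beta$estimate * s_f, c(0.5, -0.2), tolerance = 1e-8)
  expect_equal(fit$gamma * s_f, matrix(0, 2, 2), ignore_attr = TRUE,
               tolerance = 1e-8)

  # curvature: generative gamma_PP = -0.4 must come back doubled from the
  # fitted squared-term coefficient (the 0.5 z'Gz convention)
  lp2 <- landscape_params(n_per_sex = 80, beta_f = c(0.5, -0.2),
                          gamma_f = matrix(c(-0.4, 0, 0, 0), 2, 2),
                          noise_sd = 0, seed = 3)
  raw2 <- simulate_landscape(lp2)
  tb2 <- standardize_fitness(raw2)
  s2 <- sd(raw2$fitness[raw2$sex == "F"])
  fit2 <- fit_gradients(tb2, "F")
  expect_equal(fit2$gamma["P", "P"] * s2, -0.4, tolerance = 1e-8)
  expect_equal(unname(fit2$full_coef[["I(P^2)"]] * s2), -0.2, tolerance = 1e-8)
})

test_that("degenerate intake designs are refused", {
  lp <- landscape_params(n_per_sex = 40, rails = 1, seed = 4)  # one rail only
  tb <- standardize_fitness(simulate_landscape(lp))
  expect_error(fit_gradients(tb, "F"), class = "nutridimorph_data_error")
})

test_that("surface prediction matches fitted values and the analytic optimum", {
  lp <- landscape_params(seed = 5)
  tb <- standardize_fitness(simulate_landscape(lp))
  fit <- fit_gradients(tb, "F")
  # at observed design points the prediction equals the model's fitted value
  d <- fit$model$model
  pred <- predict_surface(fit, tibble::tibble(protein_intake = d$P,
                                              carbohydrate_intake = d$C))
  expect_equal(pred$fitness_z, unname(fitted(fit$model)), tolerance = 1e-10)
  # fine-grid argmax vs -gamma^{-1} beta
  opt <- surface_optimum(fit)
  grid <- tidyr::expand_grid(
    protein_intake = seq(opt[1] - 0.3, opt[1] + 0.3, length.out = 121),
    carbohydrate_intake = seq(opt[2] - 0.3, opt[2] + 0.3, length.out = 121))
  gp <- predict_surface(fit, grid)
  best <- gp[which.max(gp$fitness_z), ]
  expect_equal(best$protein_intake, unname(opt[1]), tolerance = 0.01)
  expect_equal(best$carbohydrate_intake, unname(opt[2]), tolerance = 0.01)
  # a planar fit is constant in the carbohydrate direction
  lp0 <- landscape_params(n_per_sex = 60, beta_f = c(1, 0),
                          gamma_f = matrix(0, 2, 2), noise_sd = 0, seed = 6)
  tb0 <- standardize_fitness(simulate_landscape(lp0))
  fit0 <- fit_gradients(tb0, "F")
  g0 <- predict_surface(fit0, tidyr::expand_grid(protein_intake = 0.5,
                                                 carbohydrate_intake = c(0.1, 0.9)))
  expect_equal(g0$fitness_z[1], g0$fitness_z[2], tolerance = 1e-6)
})

test_that("gradients rescale correctly under affine changes of intake units", {
  lp <- landscape_params(seed = 7)
  raw <- simulate_landscape(lp)
  tb <- standardize_fitness(raw)
  fit <- fit_gradients(tb, "M")
  scaled <- raw
  scaled$protein_intake <- raw$protein_intake * 3
  scaled$carbohydrate_intake <- raw$carbohydrate_intake * 0.5
  fit_s <- fit_gradients(standardize_fitness(scaled), "M")
  expect_equal(fit_s$beta$estimate, fit$beta$estimate / c(3, 0.5),
               tolerance = 1e-8)
  expect_equal(fit_s$gamma["P", "P"], fit$gamma["P", "P"] / 9, tolerance = 1e-8)
  expect_equal(fit_s$gamma["P", "C"], fit$gamma["P", "C"] / 1.5, tolerance = 1e-8)
})

test_that("the PB statistic is non-negative, seeded and sex-label invariant", {
  lp <- landscape_params(n_per_sex = 120, seed = 8)
  tb <- standardize_fitness(simulate_landscape(lp))
  pb <- parametric_bootstrap_sex_difference(tb, B = 199, seed = 9)
  expect_gte(pb$statistic, 0)
  expect_true(all(pb$null_draws >= 0))
  pb2 <- parametric_bootstrap_sex_difference(tb, B = 199, seed = 9)
  expect_identical(pb$null_draws, pb2$null_draws)
  # relabeling the sexes changes nothing
  swapped <- tb
  swapped$sex <- ifelse(tb$sex == "F", "M", "F")
  pb3 <- parametric_bootstrap_sex_difference(swapped, B = 199, seed = 9)
  expect_equal(pb3$statistic, pb$statistic, tolerance = 1e-10)
  expect_equal(pb3$p, pb$p)
  expect_error(parametric_bootstrap_sex_difference(tb, B = 50),
               class = "nutridimorph_param_error")
})

test_that("strongly divergent optima are detected", {
  lp <- landscape_params(seed = 10)   # defaults: 2:1 vs 1:4 optima
  tb <- standardize_fitness(simulate_landscape(lp))
  pb <- parametric_bootstrap_sex_difference(tb, B = 199, seed = 11)
  expect_lte(pb$p, 0.01)
  # and the fitted per-sex optima sit near their rails
  opt_f <- surface_optimum(fit_gradients(tb, "F"))
  opt_m <- surface_optimum(fit_gradients(tb, "M"))
  expect_equal(unname(opt_f["protein"] / opt_f["carbohydrate"]), 2,
               tolerance = 0.25)
  expect_equal(unname(opt_m["protein"] / opt_m["carbohydrate"]), 0.25,
               tolerance = 0.25)
})
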