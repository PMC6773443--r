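test_that("count simulation is seed-deterministic and respects the design", {
  p <- sim_count_params(n_genes = 200, n_D = 20, n_DxS = 5, n_DplusDxS = 10,
                        n_sexlim_male = 8, n_sexlim_female = 4,
                        lib_size_mean = 1e6, seed = 42)
  a <- simulate_counts(p)
  b <- simulate_counts(p)
  expect_identical(a$data$counts, b$data$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(dim(a$data$counts), c(200L, 12L))
  expect_true(all(a$data$counts == round(a$data$counts)))
  expect_equal(nrow(dplyr::distinct(a$data$samples, sex, diet)), 4L)
  # different seed changes the data
  p2 <- sim_count_params(n_genes = 200, n_D = 20, n_DxS = 5, n_DplusDxS = 10,
                         n_sexlim_male = 8, n_sexlim_female = 4,
                         lib_size_mean = 1e6, seed = 43)
  expect_false(identical(simulate_counts(p2)$data$counts, a$data$counts))
})

test_that("zero effect size gives all-zero true fold changes", {
  p <- sim_count_params(n_genes = 100, n_D = 10, n_DxS = 5, n_DplusDxS = 5,
                        n_sexlim_male = 0, n_sexlim_female = 0,
                        effect_logfc = 0, lib_size_mean = 1e5, seed = 1)
  sim <- simulate_counts(p)
  expect_true(all(sim$truth$true_logfc_female == 0))
  expect_true(all(sim$truth$true_logfc_male == 0))
})

test_that("planted sizes exceeding n_genes are rejected", {
  expect_error(sim_count_params(n_genes = 100, n_D = 90, n_DxS = 20),
               class = "nutridimorph_param_error")
})

test_that("sex-limited genes are all zero in the silent sex", {
  p <- sim_count_params(n_genes = 300, n_D = 0, n_DxS = 0, n_DplusDxS = 0,
                        n_sexlim_male = 30, n_sexlim_female = 20,
                        lib_size_mean = 1e6, seed = 5)
  sim <- simulate_counts(p)
  ml <- sim$truth$gene[sim$truth$category == "male_limited"]
  fl <- sim$truth$gene[sim$truth$category == "female_limited"]
  female_cols <- sim$data$samples$sex == "F"
  expect_true(all(sim$data$counts[ml, female_cols] == 0))
  expect_true(all(sim$data$counts[fl, !female_cols] == 0))
  expect_true(all(rowSums(sim$data$counts[ml, !female_cols]) > 0))
})

test_that("simulated counts follow the NB mean-variance law", {
  # 10k draws of each gene at fixed library size; var should match mu + phi mu^2
  mk <- function(disp_mean) {
    sim_count_params(n_genes = 20, n_reps = 2500, n_D = 0, n_DxS = 0,
                     n_DplusDxS = 0, n_sexlim_male = 0, n_sexlim_female = 0,
                     lib_size_mean = 2e6, lib_size_cv = 0, sex_logfc = 0,
                     sex_effect_frac = 0,
                     dispersion = list(mean = disp_mean, cv = 0),
                     baseline_logcpm_range = c(5, 8), seed = 9)
  }
  y <- simulate_counts(mk(0.1))$data$counts
  # same seed with zero dispersion draws the same per-gene means mu, so its
  # 10k-draw Poisson average pins mu to ~0.1% relative error
  mu <- rowMeans(simulate_counts(mk(0))$data$counts)
  mu_hat <- rowMeans(y)
  v_hat <- apply(y, 1, var)
  v_law <- mu + 0.1 * mu^2
  expect_true(all(abs(mu_hat / mu - 1) < 0.02))
  expect_true(all(abs(v_hat / v_law - 1) < 0.10))
})

test_that("landscape simulation is seeded and sized as designed", {
  lp <- landscape_params(seed = 3)
  a <- simulate_landscape(lp)
  expect_identical(a, simulate_landscape(lp))
  expect_equal(nrow(a), 960L)  # 60 flies x 8 rails x 2 sexes
  expect_equal(sort(unique(a$sex)), c("F", "M"))
  lp120 <- landscape_params(n_per_sex = 120, seed = 3)
  expect_equal(nrow(simulate_landscape(lp120)), 240L)
  expect_error(landscape_params(rails = numeric()),
               class = "nutridimorph_param_error")
  expect_error(landscape_params(gamma_f = matrix(c(1, 2, 3, 4), 2)),
               class = "nutridimorph_param_error")
})

test_that("noiseless linear landscape is exactly the quadratic form", {
  lp <- landscape_params(n_per_sex = 40, beta_f = c(1, 0), beta_m = c(1, 0),
                         gamma_f = matrix(0, 2, 2), gamma_m = matrix(0, 2, 2),
                         noise_sd = 0, seed = 8)
  tb <- simulate_landscape(lp)
  expect_equal(tb$fitness, tb$protein_intake, tolerance = 1e-12)
})

test_that("annotation hierarchy is closed and seeded", {
  ann <- simulate_annotation(1000, seed = 4)
  expect_identical(ann, simulate_annotation(1000, seed = 4))
  root <- ann$collection$biological_process
  for (child in setdiff(names(ann$collection), "biological_process")) {
    expect_true(all(ann$collection[[child]] %in% root), label = child)
  }
  # grandchildren sit inside the metabolic branch
  expect_true(all(ann$collection$glycolysis %in% ann$collection$metabolic_process))
  expect_true(all(ann$collection$tca_cycle %in% ann$collection$metabolic_process))
})

test_that("overlap fixtures have exactly the requested intersection", {
  fx <- make_overlap_fixture(20, 10, 10, 10, seed = 1)
  expect_length(intersect(fx$set_a, fx$set_b), 10L)
  expect_setequal(fx$set_a, fx$set_b)
  fx0 <- make_overlap_fixture(20, 10, 10, 0, seed = 1)
  expect_length(intersect(fx0$set_a, fx0$set_b), 0L)
  expect_identical(make_overlap_fixture(50, 20, 15, 5, seed = 2),
                   make_overlap_fixture(50, 20, 15, 5, seed = 2))
  expect_error(make_overlap_fixture(20, 15, 10, 12),
               class = "nutridimorph_param_error")
  expect_error(make_overlap_fixture(10, 8, 8, 2),
               class = "nutridimorph_param_error")
})
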