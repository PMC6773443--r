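## Seeded synthetic-data generators with known ground truth: NB count
## matrices for the 2 sexes x 2 diets x n replicates design, annotation
## hierarchies for baseline construction, overlap fixtures, and quadratic
## fitness landscapes over protein:carbohydrate rails.

with_seed <- function(seed, code) {
  seed <- check_seed(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters for the count simulator
#'
#' Defaults mirror the study design this package targets: pooled whole-fly
#' libraries in a 2 sexes x 2 diets x 3 replicates layout, with planted
#' gene categories echoing the reported magnitudes (600 concordant "D",
#' 50 opposing "DxS", 120 sex-biased "D+DxS" among 9000 genes), plus
#' sex-limited genes whose silent sex has expected count exactly zero.
#'
#' @param n_genes total genes simulated.
#' @param n_reps replicate libraries per sex-by-diet cell (>= 2).
#' @param lib_size_mean expected library depth in reads.
#' @param lib_size_cv coefficient of variation of depth across libraries.
#' @param baseline_logcpm_range interval (log2 scale) for gene abundance draws.
#' @param dispersion list with `mean` and `cv` of the gene-wise NB
#'   dispersion distribution (gamma-distributed; `cv = 0` gives a common
#'   dispersion).
#' @param n_D,n_DxS,n_DplusDxS planted diet-response category sizes.
#' @param n_sexlim_male,n_sexlim_female planted sex-limited gene counts.
#' @param effect_logfc magnitude (log2) of planted diet fold changes.
#' @param sex_logfc magnitude (log2) of planted sex effects.
#' @param sex_effect_frac fraction of genes given a sex effect (the study
#'   found sex effects in the vast majority of shared genes).
#' @param sexbias_female_frac fraction of sex-biased (D+DxS) genes whose
#'   response is female-dominated.
#' @param sexlim_de_frac fraction of sex-limited genes with a planted diet
#'   response (female-limited respond upward carb->protein, male-limited
#'   downward, as observed).
#' @param seed integer seed.
#' @return A `sim_count_params` list.
#' @export
sim_count_params <- function(n_genes = 9000, n_reps = 3,
                             lib_size_mean = 18e6, lib_size_cv = 0.15,
                             baseline_logcpm_range = c(0, 9),
                             dispersion = list(mean = 0.1, cv = 0),
                             n_D = 600, n_DxS = 50, n_DplusDxS = 120,
                             n_sexlim_male = 400, n_sexlim_female = 80,
                             effect_logfc = 1.5, sex_logfc = 2,
                             sex_effect_frac = 0.9,
                             sexbias_female_frac = 0.8,
                             sexlim_de_frac = 0.3,
                             seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
            lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
            baseline_logcpm_range = baseline_logcpm_range,
            dispersion = dispersion,
            n_D = as.integer(n_D), n_DxS = as.integer(n_DxS),
            n_DplusDxS = as.integer(n_DplusDxS),
            n_sexlim_male = as.integer(n_sexlim_male),
            n_sexlim_female = as.integer(n_sexlim_female),
            effect_logfc = effect_logfc, sex_logfc = sex_logfc,
            sex_effect_frac = sex_effect_frac,
            sexbias_female_frac = sexbias_female_frac,
            sexlim_de_frac = sexlim_de_frac,
            seed = check_seed(seed))
  check_scalar_number(p$n_reps, "n_reps", lower = 2)
  check_scalar_number(p$lib_size_mean, "lib_size_mean", lower = 1)
  check_scalar_number(p$effect_logfc, "effect_logfc")
  check_scalar_number(p$sex_logfc, "sex_logfc")
  planted <- p$n_D + p$n_DxS + p$n_DplusDxS + p$n_sexlim_male + p$n_sexlim_female
  if (planted > p$n_genes) {
    abort_param("planted category sizes exceed n_genes.")
  }
  structure(p, class = "sim_count_params")
}

#' Simulate an NB count dataset with planted diet-response categories
#'
#' Counts are drawn from a gamma-Poisson (negative binomial) model with
#' log-normal library sizes. Per-sex diet log2 fold changes are planted by
#' category: concordant (`D`, same shift both sexes), opposing (`DxS`,
#' equal and opposite), sex-biased (`DplusDxS`, shift in one sex only),
#' and sex-limited genes whose silent sex has mean exactly zero. The
#' remaining genes are null for diet. Identical seeds give identical
#' output.
#'
#' @param params a [sim_count_params()] list.
#' @return A list with `data` (a [count_data]) and `truth` (tibble: `gene`,
#'   `category`, `true_logfc_female`, `true_logfc_male`, `sex_effect`).
#' @export
simulate_counts <- function(params = sim_count_params()) {
  stopifnot(inherits(params, "sim_count_params"))
  p <- params
  with_seed(p$seed, {
    genes <- sprintf("gene%05d", seq_len(p$n_genes))
    idx <- seq_len(p$n_genes)
    take <- function(n) {
      if (n == 0L) return(integer(0))
      out <- idx[seq_len(n)]; idx <<- idx[-seq_len(n)]; out
    }
    i_D <- take(p$n_D); i_DxS <- take(p$n_DxS); i_DpD <- take(p$n_DplusDxS)
    i_ml <- take(p$n_sexlim_male); i_fl <- take(p$n_sexlim_female)

    category <- rep("null", p$n_genes)
    category[i_D] <- "D"; category[i_DxS] <- "DxS"; category[i_DpD] <- "DplusDxS"
    category[i_ml] <- "male_limited"; category[i_fl] <- "female_limited"

    sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
    lfc_f <- lfc_m <- numeric(p$n_genes)
    e <- p$effect_logfc
    s <- sgn(p$n_D); lfc_f[i_D] <- s * e; lfc_m[i_D] <- s * e
    s <- sgn(p$n_DxS); lfc_f[i_DxS] <- s * e; lfc_m[i_DxS] <- -s * e
    fem_dom <- runif(p$n_DplusDxS) < p$sexbias_female_frac
    s <- sgn(p$n_DplusDxS)
    lfc_f[i_DpD] <- ifelse(fem_dom, s * e, 0)
    lfc_m[i_DpD] <- ifelse(fem_dom, 0, s * e)
    # sex-limited diet responses follow the observed directions
    fl_de <- i_fl[runif(length(i_fl)) < p$sexlim_de_frac]
    ml_de <- i_ml[runif(length(i_ml)) < p$sexlim_de_frac]
    lfc_f[fl_de] <- e
    lfc_m[ml_de] <- -e

    sex_eff <- numeric(p$n_genes)
    has_sex <- runif(p$n_genes) < p$sex_effect_frac
    sex_eff[has_sex] <- sgn(sum(has_sex)) * p$sex_logfc

    base <- runif(p$n_genes, p$baseline_logcpm_range[1], p$baseline_logcpm_range[2])

    n <- 4L * p$n_reps
    samples <- tidyr::expand_grid(sex = c("F", "M"), diet = c("C", "P"),
                                  replicate = seq_len(p$n_reps))
    samples <- mutate(samples,
                      sample = sprintf("%s_%s_r%d", .data$sex, .data$diet, .data$replicate),
                      .before = 1)

    sdlog <- sqrt(log(1 + p$lib_size_cv^2))
    lib <- round(rlnorm(n, log(p$lib_size_mean) - sdlog^2 / 2, sdlog))

    disp_mean <- p$dispersion$mean %||% 0.1
    disp_cv <- p$dispersion$cv %||% 0
    phi <- if (disp_cv > 0 && disp_mean > 0) {
      rgamma(p$n_genes, shape = 1 / disp_cv^2, scale = disp_mean * disp_cv^2)
    } else rep(disp_mean, p$n_genes)

    counts <- matrix(0, p$n_genes, n, dimnames = list(genes, samples$sample))
    for (j in seq_len(n)) {
      male <- samples$sex[j] == "M"
      prot <- samples$diet[j] == "P"
      l2 <- base + if (male) sex_eff else 0
      l2 <- l2 + if (prot) (if (male) lfc_m else lfc_f) else 0
      w <- 2^l2
      if (male) w[i_fl] <- 0 else w[i_ml] <- 0
      mu <- lib[j] * w / sum(w)
      lambda <- if (any(phi > 0)) {
        g <- ifelse(phi > 0, rgamma(p$n_genes, shape = 1 / pmax(phi, 1e-12),
                                    scale = pmax(phi, 1e-12)), 1)
        mu * ifelse(phi > 0, g, 1)
      } else mu
      counts[, j] <- rpois(p$n_genes, lambda)
    }

    truth <- tibble(gene = genes, category = category,
                    true_logfc_female = lfc_f, true_logfc_male = lfc_m,
                    sex_effect = sex_eff, dispersion = phi)
    list(data = count_data(counts, samples), truth = truth)
  })
}

#' Parameters for the fitness-landscape simulator
#'
#' Observations are scattered along protein:carbohydrate "rails" (fixed
#' P:C ratios, defaults the study's eight), with log-normal variation in
#' total intake, and fitness generated from a per-sex quadratic surface
#' `w = alpha + beta'z + 0.5 z' gamma z + Normal(0, noise_sd)`. Default
#' gradients place the female optimum on the 2:1 rail and the male optimum
#' on the 1:4 rail, the configuration reported for this species.
#'
#' @param n_per_sex observations per sex, spread as evenly as possible
#'   across the rails (default 480, i.e. 60 flies per sex per rail, 960
#'   rows in all).
#' @param rails protein:carbohydrate ratios.
#' @param intake_scale mean total intake per observation (mass units).
#' @param intake_cv coefficient of variation of total intake.
#' @param alpha_f,alpha_m per-sex surface intercepts.
#' @param beta_f,beta_m per-sex linear gradients (protein, carbohydrate).
#' @param gamma_f,gamma_m per-sex symmetric 2x2 quadratic-gradient matrices.
#' @param noise_sd residual standard deviation (>= 0).
#' @param seed integer seed.
#' @export
landscape_params <- function(n_per_sex = 480,
                             rails = c(4, 2, 1, 1/2, 1/4, 1/8, 1/16, 1/32),
                             intake_scale = 1, intake_cv = 0.35,
                             alpha_f = 0, alpha_m = 0,
                             beta_f = c(4/3, 2/3), beta_m = c(0.4, 1.6),
                             gamma_f = diag(c(-2, -2)),
                             gamma_m = diag(c(-2, -2)),
                             noise_sd = 0.5, seed = 1L) {
  if (length(rails) == 0L) abort_param("`rails` must be a non-empty set of P:C ratios.")
  if (any(!is.finite(rails)) || any(rails <= 0)) {
    abort_param("`rails` must be strictly positive P:C ratios.")
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(intake_scale, "intake_scale", lower = 0)
  sym <- function(g, nm) {
    g <- as.matrix(g)
    if (!all(dim(g) == c(2, 2)) || max(abs(g - t(g))) > 1e-12) {
      abort_param(sprintf("`%s` must be a symmetric 2x2 matrix.", nm))
    }
    g
  }
  structure(list(n_per_sex = as.integer(n_per_sex), rails = rails,
                 intake_scale = intake_scale, intake_cv = intake_cv,
                 alpha_f = alpha_f, alpha_m = alpha_m,
                 beta_f = beta_f, beta_m = beta_m,
                 gamma_f = sym(gamma_f, "gamma_f"), gamma_m = sym(gamma_m, "gamma_m"),
                 noise_sd = noise_sd, seed = check_seed(seed)),
            class = "landscape_params")
}

#' Simulate a fitness table over nutritional rails
#'
#' @param params a [landscape_params()] list.
#' @return Tibble with columns `sex`, `rail` (P:C ratio),
#'   `protein_intake`, `carbohydrate_intake`, `fitness`.
#' @export
simulate_landscape <- function(params = landscape_params()) {
  stopifnot(inherits(params, "landscape_params"))
  p <- params
  with_seed(p$seed, {
    k <- length(p$rails)
    per_rail <- rep(p$n_per_sex %/% k, k)
    extra <- p$n_per_sex %% k
    if (extra > 0) per_rail[seq_len(extra)] <- per_rail[seq_len(extra)] + 1L
    sdlog <- sqrt(log(1 + p$intake_cv^2))
    one_sex <- function(sex, alpha, beta, gamma) {
      rail <- rep(p$rails, per_rail)
      total <- rlnorm(length(rail), log(p$intake_scale) - sdlog^2 / 2, sdlog)
      prot <- total * rail / (1 + rail)
      carb <- total / (1 + rail)
      z <- cbind(prot, carb)
      w <- alpha + z %*% beta + 0.5 * rowSums((z %*% gamma) * z)
      tibble(sex = sex, rail = rail, protein_intake = prot,
             carbohydrate_intake = carb,
             fitness = as.numeric(w) + rnorm(length(rail), 0, p$noise_sd))
    }
    bind_rows(one_sex("F", p$alpha_f, p$beta_f, p$gamma_f),
              one_sex("M", p$alpha_m, p$beta_m, p$gamma_m))
  })
}

#' Simulate a term collection and hierarchy with known structure
#'
#' Builds a root term covering most genes, a "metabolic-like" child with
#' two grandchildren (glycolysis- and TCA-like), and unrelated sibling
#' terms, such that every gene annotated to a child is also annotated to
#' the root. This is the fixture shape needed to exercise non-metabolic
#' baseline construction.
#'
#' @param n_genes number of genes in the annotated universe.
#' @param seed integer seed.
#' @param genes optional character vector of gene ids (defaults to
#'   `gene00001...`).
#' @return A list with `collection` (a `gene_set_collection`) and
#'   `hierarchy` (tibble of parent -> child edges).
#' @export
simulate_annotation <- function(n_genes, seed = 1L, genes = NULL) {
  if (n_genes <= 0) abort_param("`n_genes` must be positive.")
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(n_genes))
  with_seed(seed, {
    root <- sort(sample(genes, max(1, round(0.85 * n_genes))))
    metab <- sort(sample(root, max(1, round(0.25 * length(root)))))
    gly <- sort(sample(metab, max(1, min(length(metab), round(0.1 * length(metab))))))
    tca <- sort(sample(metab, max(1, min(length(metab), round(0.08 * length(metab))))))
    neuro <- sort(sample(root, max(1, round(0.15 * length(root)))))
    repro <- sort(sample(root, max(1, round(0.1 * length(root)))))
    collection <- gene_set_collection(
      list(biological_process = root,
           metabolic_process = metab,
           glycolysis = gly,
           tca_cycle = tca,
           neuron_development = neuro,
           reproduction = repro),
      setNames(c("root biological process", "metabolism branch",
                 "glycolysis-like grandchild", "TCA-like grandchild",
                 "unrelated sibling", "unrelated sibling"),
               c("biological_process", "metabolic_process", "glycolysis",
                 "tca_cycle", "neuron_development", "reproduction")))
    hierarchy <- tibble(
      parent = c("biological_process", "biological_process", "biological_process",
                 "metabolic_process", "metabolic_process"),
      child = c("metabolic_process", "neuron_development", "reproduction",
                "glycolysis", "tca_cycle"))
    list(collection = collection, hierarchy = hierarchy)
  })
}

#' Construct two gene sets with an exact overlap inside a universe
#'
#' @param universe_size,size_a,size_b,overlap set sizes; must be feasible
#'   (`overlap <= min(size_a, size_b)` and the union must fit in the
#'   universe).
#' @param seed integer seed.
#' @return List with `set_a`, `set_b`, `universe` (character vectors).
#' @export
make_overlap_fixture <- function(universe_size, size_a, size_b, overlap, seed = 1L) {
  if (overlap > min(size_a, size_b) || size_a > universe_size ||
      size_b > universe_size || (size_a + size_b - overlap) > universe_size) {
    abort_param("infeasible overlap-fixture sizes.")
  }
  with_seed(seed, {
    universe <- sprintf("u%05d", seq_len(universe_size))
    pool <- sample(universe)
    shared <- pool[seq_len(overlap)]
    a_only <- pool[overlap + seq_len(size_a - overlap)]
    b_only <- pool[size_a + seq_len(size_b - overlap)]
    list(set_a = sort(c(shared, a_only)), set_b = sort(c(shared, b_only)),
         universe = universe)
  })
}

#' Write a simulated count dataset and its ground truth to disk
#'
#' Emits counts TSV, metadata TSV, truth TSV and a run manifest recording
#' the seed and parameters.
#'
#' @param sim result of [simulate_counts()].
#' @param out_dir output directory.
#' @param params the `sim_count_params` used (recorded in the manifest).
#' @export
write_simulation <- function(sim, out_dir, params = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$data, file.path(out_dir, "counts.tsv"),
               file.path(out_dir, "samples.tsv"))
  write_results(list(truth = sim$truth), out_dir,
                params = unclass(params) %||% list())
  invisible(out_dir)
}
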