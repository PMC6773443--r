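## End-to-end orchestration: a validated config drives
## simulate -> de -> classify -> concordance -> overlap -> landscape,
## writing one TSV per result plus a manifest. All randomness flows from
## config seeds; identical configs give identical outputs.

#' Default pipeline configuration
#'
#' @param seed master seed; step seeds derive from it.
#' @param out_dir output directory (`NULL` = return results only).
#' @param alpha working FDR threshold.
#' @return Nested named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, out_dir = NULL, alpha = 0.05) {
  list(seed = seed, out_dir = out_dir, alpha = alpha,
       filter = list(cpm_threshold = 1, min_samples = 3),
       prior_df = 10,
       counts_path = NULL, metadata_path = NULL,
       simulate = list(counts = list(), landscape = list()),
       concordance = list(B = 1000,
                          parent_term = "biological_process",
                          exclude_term = "metabolic_process",
                          target_term = "metabolic_process"),
       landscape = list(B = 999))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  validate_config(modifyList(default_config(), user))
}

#' @rdname read_config
#' @param config nested list to validate.
#' @export
validate_config <- function(config) {
  check_scalar_number(config$alpha, "alpha", lower = 0, upper = 1)
  if (config$alpha <= 0 || config$alpha >= 1) abort_param("`alpha` must lie in (0, 1).")
  config$seed <- check_seed(config$seed)
  for (p in c("counts_path", "metadata_path")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      abort_param(sprintf("`%s` does not exist: %s", p, config[[p]]))
    }
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes the requested steps on either a simulated dataset (default) or
#' counts read from `config$counts_path` / `config$metadata_path`. When
#' `config$out_dir` is set, every result table is written as TSV with a
#' manifest recording the config and seeds.
#'
#' @param config list from [default_config()], [read_config()], or
#'   compatible.
#' @param steps subset of `c("simulate", "de", "classify", "concordance",
#'   "overlap", "landscape")`; `"all"` expands to every step.
#' @return Named list of step results, invisibly when writing to disk.
#' @export
run_pipeline <- function(config = default_config(), steps = "all") {
  all_steps <- c("simulate", "de", "classify", "concordance", "overlap", "landscape")
  if (identical(steps, "all")) steps <- all_steps
  steps <- match.arg(steps, all_steps, several.ok = TRUE)
  config <- validate_config(config)
  seed <- config$seed
  res <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                   parent = e)
    })
  }

  # --- data in ------------------------------------------------------------
  if (!is.null(config$counts_path)) {
    data <- run_stage("read", read_counts(config$counts_path, config$metadata_path))
    truth <- NULL
  } else {
    sim <- run_stage("simulate", {
      par <- do.call(sim_count_params,
                     modifyList(config$simulate$counts %||% list(),
                                list(seed = seed)))
      simulate_counts(par)
    })
    data <- sim$data; truth <- sim$truth
    res$simulate <- sim
  }
  ann <- run_stage("simulate", simulate_annotation(nrow(data$counts), seed = seed + 1L,
                                                   genes = rownames(data$counts)))
  res$annotation <- ann

  # --- differential expression -------------------------------------------
  if (any(c("de", "classify", "concordance", "overlap") %in% steps)) {
    res$partition <- run_stage("de", partition_by_detection(data))
    shared <- subset_genes(data, res$partition$shared)
    shared <- run_stage("de", filter_low_expression(
      shared, config$filter$cpm_threshold, config$filter$min_samples))
    res$de <- run_stage("de", de_fit(shared, prior_df = config$prior_df))
    res$fold_changes <- run_stage("de", per_sex_fold_changes(
      shared, alpha = config$alpha, prior_df = config$prior_df))
    res$shared <- shared
  }

  if (any(c("classify", "concordance", "overlap") %in% steps)) {
    res$classification <- run_stage("classify", classify_patterns(res$de, config$alpha))
    res$sex_limited <- run_stage("classify", sex_limited_de(
      data, res$partition, alpha = config$alpha, prior_df = config$prior_df))
    res$summary <- run_stage("classify", summarize_classification(
      res$classification, res$partition))
  }

  if ("concordance" %in% steps) {
    cc <- config$concordance
    res$correlations <- run_stage("concordance", {
      cats <- c("D", "DxS", "DplusDxS")
      bind_rows(lapply(cats, function(cat) {
        genes <- res$classification$genes$gene[res$classification$genes$category == cat]
        if (length(genes) >= 3) {
          cross_sex_correlation(res$fold_changes, genes, set_name = cat)
        } else tibble(set = cat, n = length(genes), r = NA_real_, p = NA_real_)
      }))
    })
    res$baseline <- run_stage("concordance", build_baseline_set(
      ann$collection, ann$hierarchy, cc$parent_term, cc$exclude_term))
    res$contrast <- run_stage("concordance", bootstrap_correlation_contrast(
      res$fold_changes,
      target_set = ann$collection[[cc$target_term]],
      baseline_set = res$baseline,
      B = cc$B, seed = seed + 2L,
      target_name = cc$target_term, baseline_name = "non_metabolic_baseline"))
  }

  if ("overlap" %in% steps) {
    res$enrichment <- run_stage("overlap", {
      universe <- rownames(res$shared$counts)
      d_genes <- res$classification$genes$gene[
        res$classification$genes$category %in% c("D", "DplusDxS")]
      coll <- lapply(unclass(ann$collection), intersect, universe)
      coll <- coll[vapply(coll, length, integer(1)) > 0]
      enrich_gene_sets(d_genes, gene_set_collection(coll), universe)
    })
  }

  if ("landscape" %in% steps) {
    lp <- run_stage("landscape", do.call(
      landscape_params,
      modifyList(config$simulate$landscape %||% list(), list(seed = seed + 3L))))
    fitness <- run_stage("landscape", standardize_fitness(simulate_landscape(lp)))
    res$landscape <- run_stage("landscape", list(
      table = fitness,
      fit_f = fit_gradients(fitness, "F"),
      fit_m = fit_gradients(fitness, "M"),
      pb = parametric_bootstrap_sex_difference(
        fitness, B = config$landscape$B, seed = seed + 4L)))
  }

  if (!is.null(config$out_dir)) {
    tables <- list()
    if (!is.null(res$de)) tables$de_results <- res$de$results
    if (!is.null(res$fold_changes)) tables$fold_changes <- as_tibble(res$fold_changes)
    if (!is.null(res$classification)) {
      tables$classification <- res$classification$genes
      tables$classification_cells <- res$classification$cells
    }
    if (!is.null(res$sex_limited)) tables$sex_limited <- res$sex_limited$summary
    if (!is.null(res$correlations)) tables$correlations <- res$correlations
    if (!is.null(res$contrast)) tables$bootstrap_draws <- res$contrast$draws
    if (!is.null(res$enrichment)) tables$enrichment <- res$enrichment
    if (!is.null(res$landscape)) {
      tables$gradients <- bind_rows(tidy(res$landscape$fit_f),
                                    tidy(res$landscape$fit_m))
      tables$pb_null <- tibble(draw = res$landscape$pb$null_draws)
    }
    res$manifest <- write_results(tables, config$out_dir,
                                  params = list(seed = seed, alpha = config$alpha,
                                                steps = steps))
    return(invisible(res))
  }
  res
}
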