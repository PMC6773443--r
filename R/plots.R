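## ggplot2 visualisations for each result type.

#' Cross-sex fold-change scatter
#'
#' Male vs female carbohydrate-to-protein log2 fold changes, coloured by
#' the per-sex significance flag; optionally faceted by a gene
#' classification's headline categories.
#'
#' @param object a `fold_change_pair` tibble.
#' @param classification optional `gene_classification`; when given, only
#'   diet-responsive genes are shown, faceted by category.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fold_change_pair <- function(object, classification = NULL, ...) {
  fc <- as_tibble(object)
  if (!is.null(classification)) {
    fc <- dplyr::inner_join(fc,
                            classification$genes[c("gene", "category")], by = "gene")
    fc <- fc[fc$category %in% c("D", "DxS", "DplusDxS"), ]
  }
  p <- ggplot2::ggplot(fc, ggplot2::aes(.data$logfc_male, .data$logfc_female,
                                        colour = .data$signif)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(both = "#e6b800", female_only = "#c0392b",
                                            male_only = "#2980b9", neither = "grey65")) +
    ggplot2::labs(x = "male log2 fold change (carb → protein)",
                  y = "female log2 fold change (carb → protein)",
                  colour = "significant in") +
    ggplot2::theme_minimal()
  if (!is.null(classification)) p <- p + ggplot2::facet_wrap(~category)
  p
}

#' Volcano plot of sex-limited diet responses
#'
#' @param object a `sex_limited_de` result.
#' @param ... unused.
#' @export
autoplot.sex_limited_de <- function(object, ...) {
  g <- object$genes
  ggplot2::ggplot(g, ggplot2::aes(.data$logfc, -log10(pmax(.data$p, 1e-300)),
                                  colour = .data$call != "Ns")) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#e6b800", `FALSE` = "grey60"),
                                 labels = c(`TRUE` = "DE", `FALSE` = "ns"),
                                 name = NULL) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "log2 fold change (carb → protein)",
                  y = expression(-log[10]~p)) +
    ggplot2::theme_minimal()
}

#' Bootstrap correlation distributions for target vs baseline
#'
#' @param object a `bootstrap_contrast`.
#' @param ... unused.
#' @export
autoplot.bootstrap_contrast <- function(object, ...) {
  draws <- tidyr::pivot_longer(object$draws, -"replicate",
                               names_to = "set", values_to = "r")
  draws$set <- ifelse(draws$set == "r_target", object$target, object$baseline)
  ggplot2::ggplot(draws, ggplot2::aes(.data$r, fill = .data$set)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::scale_fill_manual(values = setNames(c("#c0392b", "grey50"),
                                                 c(object$target, object$baseline))) +
    ggplot2::labs(x = "bootstrapped cross-sex correlation", y = "replicates",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Fitted nutritional landscape
#'
#' Filled-contour map of predicted standardized fitness over the intake
#' plane, with the observed intake coordinates overlaid.
#'
#' @param object a `surface_fit`.
#' @param n grid resolution per axis.
#' @param ... unused.
#' @export
autoplot.surface_fit <- function(object, n = 61, ...) {
  grid <- predict_surface(object, n = n)
  d <- object$model$model
  ggplot2::ggplot(grid, ggplot2::aes(.data$protein_intake,
                                     .data$carbohydrate_intake)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fitness_z)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$fitness_z),
                          colour = "white", linewidth = 0.2) +
    ggplot2::geom_point(data = tibble(protein_intake = d$P,
                                      carbohydrate_intake = d$C),
                        size = 0.4, alpha = 0.4, colour = "grey20") +
    ggplot2::scale_fill_viridis_c(name = "z fitness") +
    ggplot2::labs(x = "protein intake", y = "carbohydrate intake",
                  title = sprintf("sex %s", object$sex)) +
    ggplot2::theme_minimal()
}

#' Classification cell counts in the S/D/DxS layout
#'
#' @param object a `gene_classification`.
#' @param ... unused.
#' @export
autoplot.gene_classification <- function(object, ...) {
  cells <- mutate(object$cells,
                  label = paste(.data$S, .data$D, .data$DxS, sep = "/"))
  ggplot2::ggplot(cells, ggplot2::aes(.data$label, .data$n_genes,
                                      fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "significance cell (S/D/DxS)", y = "genes (log scale)",
                  fill = "category") +
    ggplot2::theme_minimal()
}
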