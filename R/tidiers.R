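## broom-style tidiers for the package's fitted objects.

#' Tidy a differential-expression result
#'
#' @param x a `de_result`.
#' @param ... unused.
#' @return Long tibble: one row per gene x term with `logFC`, `LR`, `p`,
#'   `q`.
#' @export
tidy.de_result <- function(x, ...) {
  res <- x$results
  purrr::map_dfr(c("S", "D", "DxS"), function(tm) {
    tibble(gene = res$gene, term = tm,
           logFC = res[[paste0("logFC_", tm)]],
           LR = res[[paste0("LR_", tm)]],
           p = res[[paste0("p_", tm)]],
           q = res[[paste0("q_", tm)]])
  })
}

#' @rdname tidy.de_result
#' @export
glance.de_result <- function(x, ...) {
  disp <- x$dispersions
  tibble(n_genes = nrow(x$results),
         common_dispersion = if (inherits(disp, "dispersion_estimates"))
           disp$common else NA_real_,
         n_nonconverged = sum(!x$results$converged))
}

#' Tidy a fitted fitness surface
#'
#' @param x a `surface_fit`.
#' @param ... unused.
#' @return Tibble of gradient estimates: linear gradients (`beta_*`, with
#'   SEs and 95% CIs from the linear-only model) and quadratic gradients
#'   (`gamma_*`, `w = a + b'z + 0.5 z'Gz` convention).
#' @export
tidy.surface_fit <- function(x, ...) {
  qci <- x$quad_ci
  bind_rows(
    mutate(x$beta, term = paste0("beta_", .data$term), .keep = "unused",
           .before = 1),
    tibble(term = c("gamma_PP", "gamma_CC", "gamma_PC"),
           estimate = c(x$gamma["P", "P"], x$gamma["C", "C"], x$gamma["P", "C"]),
           se = NA_real_,
           conf_low = c(2 * qci["I(P^2)", 1], 2 * qci["I(C^2)", 1],
                        qci["I(P * C)", 1]),
           conf_high = c(2 * qci["I(P^2)", 2], 2 * qci["I(C^2)", 2],
                         qci["I(P * C)", 2]))) |>
    mutate(sex = x$sex, .before = 1)
}

#' @rdname tidy.surface_fit
#' @export
glance.surface_fit <- function(x, ...) {
  tibble(sex = x$sex, n = x$n, sigma = x$sigma, loglik = x$loglik)
}

#' Tidy a parametric-bootstrap result
#'
#' @param x a `pb_result`.
#' @param ... unused.
#' @export
tidy.pb_result <- function(x, ...) {
  tibble(statistic = x$statistic, B = x$B, p = x$p)
}

#' @rdname tidy.pb_result
#' @export
glance.pb_result <- function(x, ...) tidy(x)

#' Tidy a bootstrap correlation contrast
#'
#' @param x a `bootstrap_contrast`.
#' @param ... unused.
#' @return Two rows (target, baseline) with observed r and percentile CI,
#'   plus difference columns.
#' @export
tidy.bootstrap_contrast <- function(x, ...) {
  tibble(set = c(x$target, x$baseline),
         r = c(x$r_target, x$r_baseline),
         conf_low = c(x$ci_target[1], x$ci_baseline[1]),
         conf_high = c(x$ci_target[2], x$ci_baseline[2]),
         diff_low = x$ci_diff[1], diff_high = x$ci_diff[2], p = x$p)
}

#' @rdname tidy.bootstrap_contrast
#' @export
glance.bootstrap_contrast <- function(x, ...) {
  tibble(B = x$B, p = x$p, n_degenerate = x$n_degenerate)
}
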