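## internal validation / logging helpers

nd_log <- function(..., .verbose = getOption("nutridimorph.verbose", TRUE)) {
  if (isTRUE(.verbose)) rlang::inform(paste0(...))
  invisible(NULL)
}

abort_param <- function(msg) rlang::abort(msg, class = "nutridimorph_param_error")
abort_data <- function(msg) rlang::abort(msg, class = "nutridimorph_data_error")
abort_format <- function(msg) rlang::abort(msg, class = "nutridimorph_format_error")
abort_usage <- function(msg) rlang::abort(msg, class = "nutridimorph_usage_error")

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort_param(sprintf("`%s` must be a single finite number in [%s, %s].",
                        name, format(lower), format(upper)))
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    abort_param("`seed` must be a single integer.")
  }
  as.integer(seed %% .Machine$integer.max)
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- rlang::`%||%`
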