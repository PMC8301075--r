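#' @importFrom rlang abort warn inform hash .data
#' @importFrom stats pchisq pnorm pt qnorm phyper rnorm rbinom rnbinom runif
#'   median p.adjust ks.test setNames
#' @importFrom utils head
NULL

abort_config <- function(field, msg) {
  abort(sprintf("invalid configuration: `%s` %s", field, msg),
        class = "dosagemeta_config_error")
}

abort_data <- function(msg) {
  abort(msg, class = "dosagemeta_data_error")
}

# p-values are clamped before any quantile transform so downstream normal
# quantiles stay finite
clamp_p <- function(p, lower = 1e-300) {
  pmin(pmax(p, lower), 1)
}

is_integerish_matrix <- function(x, tol = 1e-8) {
  all(is.finite(x)) && all(x >= 0) && max(abs(x - round(x))) < tol
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
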