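#' Volcano-style plot of a meta-analysis result
#'
#' Combined Z against -log10 meta q-value, coloured by inclusion and
#' direction.
#'
#' @param object A `meta_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_result <- function(object, ...) {
  df <- object$genes |>
    dplyr::mutate(neglog_q = -log10(pmax(.data$q_meta, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_meta, y = .data$neglog_q,
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(up = "#D55E00", down = "#0072B2",
                                            none = "grey60")) +
    ggplot2::labs(x = "combined Z", y = expression(-log[10] ~ q),
                  colour = NULL,
                  title = "Signed Z-score meta-analysis") +
    ggplot2::theme_minimal()
}

#' Dot plot of top enriched gene sets
#'
#' @param object An `ora_result`.
#' @param n Number of top sets to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ora_result <- function(object, n = 15, ...) {
  df <- utils::head(tibble::as_tibble(object), n) |>
    dplyr::mutate(set = stats::reorder(.data$set, .data$ratio),
                  neglog_p = -log10(pmax(.data$p_adjusted, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$set,
                                   size = .data$observed,
                                   colour = .data$neglog_p)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed / expected", y = NULL,
                  colour = expression(-log[10] ~ p[adj]), size = "observed",
                  title = "Over-representation analysis") +
    ggplot2::theme_minimal()
}

#' OCR trace plot with injection phases
#'
#' @param trace OCR trace data frame (`time`, `ocr`, `phase`, optional
#'   `well`).
#' @return A ggplot.
#' @export
plot_ocr_trace <- function(trace) {
  trace <- tibble::as_tibble(trace)
  aes <- if ("well" %in% names(trace)) {
    ggplot2::aes(x = .data$time, y = .data$ocr, colour = .data$phase,
                 group = .data$well)
  } else {
    ggplot2::aes(x = .data$time, y = .data$ocr, colour = .data$phase,
                 group = 1)
  }
  ggplot2::ggplot(trace, aes) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "time (min)", y = "OCR (pmol O2/min)", colour = "phase",
                  title = "Mito Stress oxygen-consumption trace") +
    ggplot2::theme_minimal()
}
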