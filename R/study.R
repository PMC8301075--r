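#' Construct a case/control expression study
#'
#' Container for one two-group expression study: a feature-by-sample numeric
#' matrix plus per-sample group labels and a platform dialect. Array studies
#' carry log2 intensities (finite reals); RNA-seq studies carry non-negative
#' integer counts.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param group Character vector, one of `"case"`/`"control"` per sample
#'   (column of `values`).
#' @param study_id Study identifier.
#' @param platform `"array"` (log-intensity) or `"rnaseq"` (integer counts).
#' @return An `expression_study` object.
#' @export
expression_study <- function(values, group, study_id, platform = c("array", "rnaseq")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    abort_data("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_data("`values` must have feature rownames and sample colnames")
  if (length(group) != ncol(values))
    abort_data("`group` length must equal the number of samples")
  if (!all(group %in% c("case", "control")))
    abort_data("`group` labels must be 'case' or 'control'")
  n_case <- sum(group == "case")
  n_control <- sum(group == "control")
  if (platform == "rnaseq" && !is_integerish_matrix(values))
    abort_data(sprintf("study '%s': rnaseq values must be non-negative integers", study_id))
  if (platform == "array" && !all(is.finite(values)))
    abort_data(sprintf("study '%s': array values must be finite", study_id))
  structure(
    list(study_id = as.character(study_id), platform = platform,
         values = values, group = as.character(group),
         n_case = n_case, n_control = n_control),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study '%s'> %s platform: %d features x %d samples (%d case / %d control)\n",
              x$study_id, x$platform, nrow(x$values), ncol(x$values),
              x$n_case, x$n_control))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Tidy an expression study into long format
#'
#' @param x An `expression_study`.
#' @param ... Unused.
#' @return A tibble with columns `study_id`, `feature`, `sample`, `group`,
#'   `value`.
#' @export
tidy.expression_study <- function(x, ...) {
  tibble::tibble(
    study_id = x$study_id,
    feature = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    group = rep(x$group, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}
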