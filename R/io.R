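#' Read an expression matrix TSV
#'
#' First column = feature id, remaining columns = samples.
#'
#' @param path TSV path.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("matrix file '%s' does not exist", path))
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a sample sheet TSV
#'
#' Columns: `sample_id`, `group` in case/control.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("sample sheet '%s' does not exist", path))
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    abort_data(sprintf("sample sheet '%s' needs columns sample_id, group", path))
  df
}

#' Read a probe map TSV
#'
#' Columns: `probe_id`, `symbol` (empty = unmapped).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("probe map '%s' does not exist", path))
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("probe_id", "symbol") %in% names(df)))
    abort_data(sprintf("probe map '%s' needs columns probe_id, symbol", path))
  df$symbol[is.na(df$symbol)] <- ""
  df
}

#' Load one study from matrix + sample sheet files
#'
#' @param matrix_path,samples_path TSV paths.
#' @param study_id Study identifier.
#' @param platform `"array"` or `"rnaseq"`.
#' @return An [expression_study()].
#' @export
load_study <- function(matrix_path, samples_path, study_id, platform) {
  m <- read_expression_matrix(matrix_path)
  sheet <- read_sample_sheet(samples_path)
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing))
    abort_data(sprintf("study '%s': sample sheet lacks sample(s): %s",
                       study_id, paste(missing, collapse = ", ")))
  group <- setNames(sheet$group, sheet$sample_id)[colnames(m)]
  expression_study(m, unname(group), study_id, platform)
}
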