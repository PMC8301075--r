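#' Map a study's platform-native features to gene symbols
#'
#' Relabels probe- or transcript-keyed rows to official gene symbols via a
#' probe map and collapses multi-probe genes to one row per symbol. Probes
#' absent from the map or mapping to the empty symbol are dropped (their count
#' is reported via a message). Symbols are opaque, case-sensitive strings; no
#' alias resolution is attempted.
#'
#' Collapse rules: `"max_mean"` (default) keeps the probe with the highest
#' mean expression, common array practice; `"first"` keeps the first probe in
#' row order; `"median"` takes the element-wise median across probes. The
#' first two never invent values; `"median"` can produce non-integer rows for
#' count studies, which the count DE engine will reject.
#'
#' @param study An [expression_study()] keyed by platform-native feature ids.
#' @param map Probe map: data frame with columns `probe_id`, `symbol`
#'   (empty string = unmapped).
#' @param collapse_rule One of `"max_mean"`, `"median"`, `"first"`.
#' @param quiet Suppress the dropped/collapsed log message.
#' @return An [expression_study()] keyed by unique gene symbols, with
#'   attributes `n_dropped` (unmapped probes) and `n_collapsed` (probes
#'   removed by collapsing).
#' @export
harmonize_study <- function(study, map,
                            collapse_rule = c("max_mean", "median", "first"),
                            quiet = FALSE) {
  collapse_rule <- match.arg(collapse_rule)
  map <- tibble::as_tibble(map)
  if (anyDuplicated(map$probe_id))
    abort_data("probe map has duplicated probe ids")
  features <- rownames(study$values)
  symbol <- setNames(map$symbol, map$probe_id)[features]
  mapped <- !is.na(symbol) & symbol != ""
  n_dropped <- sum(!mapped)
  if (!any(mapped))
    abort(sprintf("harmonization error: study '%s' shares no mapped feature with the probe map",
                  study$study_id),
          class = "dosagemeta_harmonize_error")

  values <- study$values[mapped, , drop = FALSE]
  symbol <- unname(symbol[mapped])
  n_probes <- nrow(values)

  if (collapse_rule == "max_mean") {
    ord <- order(-rowMeans(values))
    keep <- ord[!duplicated(symbol[ord])]
    keep <- sort(keep)  # preserve original row order among kept probes
    out <- values[keep, , drop = FALSE]
    rownames(out) <- symbol[keep]
  } else if (collapse_rule == "first") {
    keep <- which(!duplicated(symbol))
    out <- values[keep, , drop = FALSE]
    rownames(out) <- symbol[keep]
  } else {
    dup_syms <- unique(symbol[duplicated(symbol)])
    keep <- which(!symbol %in% dup_syms)
    singles <- values[keep, , drop = FALSE]
    rownames(singles) <- symbol[keep]
    med_rows <- t(vapply(dup_syms, function(s) {
      apply(values[symbol == s, , drop = FALSE], 2, median)
    }, numeric(ncol(values))))
    out <- rbind(singles, med_rows)
    out <- out[order(match(rownames(out), symbol)), , drop = FALSE]
  }
  n_collapsed <- n_probes - nrow(out)
  if (!quiet)
    inform(sprintf("harmonize '%s': %d probes -> %d symbols (%d unmapped dropped, %d collapsed)",
                   study$study_id, length(features), nrow(out), n_dropped, n_collapsed))
  res <- expression_study(out, study$group, study$study_id, study$platform)
  attr(res, "n_dropped") <- n_dropped
  attr(res, "n_collapsed") <- n_collapsed
  res
}

#' Gene universe across harmonized studies
#'
#' Union of gene symbols over a set of harmonized studies, with the number of
#' studies measuring each gene (the quantity behind the "assayed in at least
#' two datasets" inclusion criterion).
#'
#' @param studies List of symbol-keyed [expression_study()] objects.
#' @return A tibble with columns `gene` and `n_studies`, sorted by gene.
#' @export
gene_universe <- function(studies) {
  genes <- unlist(lapply(studies, function(s) rownames(s$values)), use.names = FALSE)
  tab <- table(genes)
  tibble::tibble(gene = names(tab), n_studies = as.integer(tab))
}
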