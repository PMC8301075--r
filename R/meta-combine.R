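#' Signed Z-score of a two-sided p-value
#'
#' Converts a two-sided p-value and a fold-change direction into a signed
#' standard-normal score, \eqn{Z = \mathrm{sign}(\mathrm{log2FC}) \cdot
#' \Phi^{-1}(1 - p/2)}. A zero fold change has sign 0 and hence Z = 0.
#' p-values are clamped to \[1e-300, 1\] first so the quantile is finite.
#'
#' @param p Two-sided p-values in (0, 1].
#' @param log2FC Finite log2 fold changes giving the direction.
#' @return Signed Z-scores, vectorized.
#' @export
signed_z <- function(p, log2FC) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    abort_data("p-values must lie in (0, 1]")
  if (any(!is.finite(log2FC)))
    abort_data("log2FC must be finite")
  sign(log2FC) * qnorm(clamp_p(p) / 2, lower.tail = FALSE)
}

#' Sample-size-weighted Stouffer combination
#'
#' Combines per-study signed Z-scores into one meta-analytic Z with weights
#' \eqn{w_i}, \deqn{Z = \sum_i w_i Z_i / \sqrt{\sum_i w_i^2},} and a two-sided
#' p-value \eqn{2(1 - \Phi(|Z|))}. The default weight is \eqn{\sqrt{n_i}}
#' (total sample size); `scheme = "effective"` uses the square root of the
#' effective sample size \eqn{4 / (1/n_\mathrm{case} + 1/n_\mathrm{control})},
#' which requires `n_case`/`n_control`. The result is invariant to study
#' order and to rescaling all sample sizes by a common factor.
#'
#' @param z Per-study signed Z-scores.
#' @param n Per-study total sample sizes (>= 1).
#' @param scheme Weighting scheme, `"sqrt_n"` or `"effective"`.
#' @param n_case,n_control Per-study group sizes (only for
#'   `scheme = "effective"`).
#' @return A list with `z_meta` and `p_meta`.
#' @export
combine_stouffer <- function(z, n, scheme = c("sqrt_n", "effective"),
                             n_case = NULL, n_control = NULL) {
  scheme <- match.arg(scheme)
  if (length(z) == 0) abort_data("combine_stouffer() needs at least one study")
  if (length(z) != length(n)) abort_data("`z` and `n` must have equal length")
  if (any(n < 1)) abort_data("sample sizes must be >= 1")
  if (scheme == "sqrt_n") {
    w <- sqrt(n)
  } else {
    if (is.null(n_case) || is.null(n_control))
      abort_data("`effective` weighting needs n_case and n_control")
    w <- sqrt(4 / (1 / n_case + 1 / n_control))
  }
  z_meta <- sum(w * z) / sqrt(sum(w^2))
  list(z_meta = z_meta, p_meta = 2 * pnorm(-abs(z_meta)))
}

#' Cochran's Q heterogeneity test on signed Z-scores
#'
#' Between-study inconsistency test treating each signed Z as a unit-variance
#' estimate (equal inverse-variance weights): \eqn{Q = \sum_i (Z_i - \bar
#' Z)^2} referred to \eqn{\chi^2_{k-1}}. A single study returns Q = 0 and
#' HetP = 1 by convention, flagged.
#'
#' @param z Per-study signed Z-scores (length k).
#' @return A list with `q_het`, `het_p`, and `flag` (`"ok"` or
#'   `"single_study"`).
#' @export
heterogeneity_test <- function(z) {
  k <- length(z)
  if (k == 0) abort_data("heterogeneity_test() needs at least one study")
  if (k == 1) return(list(q_het = 0, het_p = 1, flag = "single_study"))
  q <- sum((z - mean(z))^2)
  list(q_het = q, het_p = pchisq(q, df = k - 1, lower.tail = FALSE), flag = "ok")
}

#' Gene-wise meta-analysis across harmonized studies
#'
#' Assembles per-study differential-expression tables into per-gene records,
#' combines them with the signed sample-size-weighted Z-score method, tests
#' between-study heterogeneity, computes BH q-values over all genes entering
#' the meta-analysis, and applies the three-criterion inclusion filter: a
#' gene is significantly dysregulated if (1) q <= `q_threshold` (default
#' 0.01), (2) it is assayed in at least `min_studies` datasets (default 2),
#' and (3) it is non-significant in the heterogeneity test
#' (HetP > `het_p_threshold`, default 0.05). Direction is up when the
#' combined Z is positive. Ties are resolved exactly as the thresholds read:
#' `<=` for q, `>` for HetP.
#'
#' @param de_tables A `de_result` tibble (or list of them, bound together)
#'   with columns `study_id`, `gene`, `log2FC`, `p`, `n_total`.
#' @param q_threshold,min_studies,het_p_threshold The filter thresholds.
#' @param weight_scheme Passed to [combine_stouffer()].
#' @param fdr_scope `"all"` computes BH over every gene with at least one
#'   study (default; the `min_studies` filter is applied afterwards);
#'   `"min_studies"` restricts the FDR universe to genes already meeting the
#'   study-count criterion.
#' @return A `meta_result` object: list with `genes` (per-gene tibble:
#'   `gene`, `k`, `z_meta`, `p_meta`, `q_meta`, `q_het`, `het_p`,
#'   `mean_log2FC`, `direction`, `included`, `reason_excluded`), `per_study`
#'   (long tibble of per-study Z contributions), and `summary` (counts:
#'   genes entered, included, up, down, per-criterion exclusion tallies).
#' @export
run_meta <- function(de_tables,
                     q_threshold = 0.01, min_studies = 2,
                     het_p_threshold = 0.05,
                     weight_scheme = c("sqrt_n", "effective"),
                     fdr_scope = c("all", "min_studies")) {
  weight_scheme <- match.arg(weight_scheme)
  fdr_scope <- match.arg(fdr_scope)
  if (is.list(de_tables) && !is.data.frame(de_tables))
    de_tables <- dplyr::bind_rows(de_tables)
  de_tables <- tibble::as_tibble(de_tables)
  needed <- c("study_id", "gene", "log2FC", "p", "n_total")
  if (!all(needed %in% names(de_tables)))
    abort_data(paste("DE tables need columns:", paste(needed, collapse = ", ")))
  if (anyDuplicated(de_tables[c("study_id", "gene")]))
    abort_data("duplicate (study, gene) pairs: harmonize each study before the meta-analysis")

  if (weight_scheme == "effective" &&
      !all(c("n_case", "n_control") %in% names(de_tables)))
    abort_data("`effective` weighting needs n_case and n_control columns")
  per_study <- de_tables |>
    dplyr::mutate(
      z = signed_z(.data$p, .data$log2FC),
      weight = if (weight_scheme == "sqrt_n") sqrt(.data$n_total) else
        sqrt(4 / (1 / .data$n_case + 1 / .data$n_control))
    ) |>
    dplyr::select("study_id", "gene", "z", "weight", "n_total", "log2FC", "p")

  genes <- per_study |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      k = dplyr::n(),
      z_meta = sum(.data$weight * .data$z) / sqrt(sum(.data$weight^2)),
      q_het = if (dplyr::n() > 1) sum((.data$z - mean(.data$z))^2) else 0,
      mean_log2FC = mean(.data$log2FC),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_meta = clamp_p(2 * pnorm(-abs(.data$z_meta))),
      het_p = ifelse(.data$k > 1,
                     pchisq(.data$q_het, df = pmax(.data$k - 1, 1), lower.tail = FALSE),
                     1)
    )

  fdr_idx <- if (fdr_scope == "all") rep(TRUE, nrow(genes)) else genes$k >= min_studies
  genes$q_meta <- NA_real_
  genes$q_meta[fdr_idx] <- fdr_bh(genes$p_meta[fdr_idx])

  fail_q <- is.na(genes$q_meta) | genes$q_meta > q_threshold
  fail_k <- genes$k < min_studies
  fail_het <- !(genes$het_p > het_p_threshold)
  included <- !fail_q & !fail_k & !fail_het
  reason <- rep(NA_character_, nrow(genes))
  reason[!included] <- paste0(
    ifelse(fail_q[!included], "q_above_threshold;", ""),
    ifelse(fail_k[!included], "fewer_than_min_studies;", ""),
    ifelse(fail_het[!included], "heterogeneous;", "")
  )
  genes$included <- included
  genes$direction <- dplyr::case_when(
    included & genes$z_meta > 0 ~ "up",
    included & genes$z_meta < 0 ~ "down",
    .default = "none"
  )
  genes$reason_excluded <- sub(";$", "", reason)
  genes <- dplyr::select(
    genes, "gene", "k", "z_meta", "p_meta", "q_meta", "q_het", "het_p",
    "mean_log2FC", "direction", "included", "reason_excluded")

  summary <- list(
    n_entered = nrow(genes),
    n_included = sum(included),
    n_up = sum(genes$direction == "up"),
    n_down = sum(genes$direction == "down"),
    n_excluded_q = sum(fail_q),
    n_excluded_min_studies = sum(fail_k),
    n_excluded_heterogeneity = sum(fail_het),
    thresholds = list(q = q_threshold, min_studies = min_studies,
                      het_p = het_p_threshold, weight_scheme = weight_scheme,
                      fdr_scope = fdr_scope)
  )
  structure(list(genes = genes, per_study = per_study, summary = summary),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<meta_result> %d genes entered; %d included (%d up, %d down)\n",
              s$n_entered, s$n_included, s$n_up, s$n_down))
  cat(sprintf("  excluded: %d by q > %.3g, %d measured in < %d studies, %d heterogeneous (HetP <= %.3g)\n",
              s$n_excluded_q, s$thresholds$q, s$n_excluded_min_studies,
              s$thresholds$min_studies, s$n_excluded_heterogeneity, s$thresholds$het_p))
  invisible(x)
}

#' Per-gene meta-analysis table
#'
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return The per-gene tibble (one row per gene entering the meta-analysis).
#' @export
tidy.meta_result <- function(x, ...) x$genes

#' One-row meta-analysis summary
#'
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return A one-row tibble with the headline counts.
#' @export
glance.meta_result <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_entered = s$n_entered, n_included = s$n_included,
    n_up = s$n_up, n_down = s$n_down,
    n_excluded_q = s$n_excluded_q,
    n_excluded_min_studies = s$n_excluded_min_studies,
    n_excluded_heterogeneity = s$n_excluded_heterogeneity
  )
}
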