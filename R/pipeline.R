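#' Pipeline configuration
#'
#' Collects input paths and thresholds for the end-to-end analysis. The
#' defaults are the published analysis conventions: per-study DEGs at
#' q <= 0.05; meta-analytic inclusion at q <= 0.01, at least 2 datasets,
#' and HetP > 0.05.
#'
#' @param studies Tibble with one row per study: `study_id`, `platform`
#'   (array/rnaseq), `matrix` (path), `samples` (path), `probes` (path).
#' @param gmt Path to the gene-set GMT file.
#' @param out_dir Output directory for tables and the run report.
#' @param per_study_q Per-study DEG q-value threshold.
#' @param meta_q Meta-analysis inclusion q-value threshold.
#' @param het_p Heterogeneity HetP threshold (exclude when HetP <= het_p).
#' @param min_studies Minimum number of datasets measuring a gene.
#' @param collapse_rule Probe collapse rule for [harmonize_study()].
#' @param weight_scheme Stouffer weighting scheme for [run_meta()].
#' @param universe_policy ORA universe policy for
#'   [directional_enrichment()].
#' @param seed Integer seed recorded with the run.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(studies, gmt, out_dir,
                            per_study_q = 0.05, meta_q = 0.01,
                            het_p = 0.05, min_studies = 2,
                            collapse_rule = "max_mean",
                            weight_scheme = "sqrt_n",
                            universe_policy = "annotated",
                            seed = 1L) {
  studies <- tibble::as_tibble(studies)
  needed <- c("study_id", "platform", "matrix", "samples", "probes")
  missing_cols <- setdiff(needed, names(studies))
  if (length(missing_cols))
    abort_config("studies", paste("lacks column(s):", paste(missing_cols, collapse = ", ")))
  for (fld in c("per_study_q", "meta_q", "het_p")) {
    v <- get(fld)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      abort_config(fld, "must lie in (0, 1)")
  }
  if (min_studies < 1) abort_config("min_studies", "must be >= 1")
  structure(
    list(studies = studies, gmt = gmt, out_dir = out_dir,
         per_study_q = per_study_q, meta_q = meta_q, het_p = het_p,
         min_studies = min_studies, collapse_rule = collapse_rule,
         weight_scheme = weight_scheme, universe_policy = universe_policy,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Point a pipeline config at a written fixture set
#'
#' Convenience wrapper: writes the fixtures of a [simulation_config()] with
#' [write_fixture_set()] and returns a matching [pipeline_config()].
#'
#' @param sim_config A [simulation_config()].
#' @param fixture_dir Directory for the fixture files.
#' @param out_dir Pipeline output directory.
#' @param ... Passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
fixture_pipeline_config <- function(sim_config, fixture_dir, out_dir, ...) {
  write_fixture_set(sim_config, fixture_dir)
  studies <- sim_config$studies |>
    dplyr::transmute(
      study_id = .data$study_id, platform = .data$platform,
      matrix = file.path(fixture_dir, paste0(.data$study_id, "_matrix.tsv")),
      samples = file.path(fixture_dir, paste0(.data$study_id, "_samples.tsv")),
      probes = file.path(fixture_dir, paste0(.data$study_id, "_probes.tsv"))
    )
  pipeline_config(studies, gmt = file.path(fixture_dir, "gene_sets.gmt"),
                  out_dir = out_dir, seed = sim_config$seed, ...)
}

#' Validate pipeline inputs
#'
#' Checks that every referenced file exists and parses, that matrices and
#' sample sheets agree, that group labels are case/control with at least two
#' samples each, that RNA-seq matrices contain non-negative integers, and
#' that the GMT parses. Never modifies files; returns structured failures
#' rather than raising (unreadable files are reported as failures too).
#'
#' @param config A [pipeline_config()].
#' @return A tibble of failures (`stage`, `item`, `message`); zero rows when
#'   everything is well-formed.
#' @export
validate_inputs <- function(config) {
  failures <- list()
  fail <- function(stage, item, message) {
    failures[[length(failures) + 1]] <<- tibble::tibble(
      stage = stage, item = item, message = message)
  }

  for (i in seq_len(nrow(config$studies))) {
    d <- config$studies[i, ]
    for (fld in c("matrix", "samples", "probes")) {
      if (!file.exists(d[[fld]])) {
        fail("files", d$study_id, sprintf("%s file '%s' does not exist", fld, d[[fld]]))
      }
    }
    if (!file.exists(d$matrix) || !file.exists(d$samples)) next
    m <- tryCatch(read_expression_matrix(d$matrix), error = function(e) e)
    sheet <- tryCatch(read_sample_sheet(d$samples), error = function(e) e)
    if (inherits(m, "error")) { fail("matrix", d$study_id, conditionMessage(m)); next }
    if (inherits(sheet, "error")) { fail("samples", d$study_id, conditionMessage(sheet)); next }
    missing <- setdiff(colnames(m), sheet$sample_id)
    for (s in missing)
      fail("samples", d$study_id, sprintf("sample sheet missing sample '%s'", s))
    bad_grp <- setdiff(unique(sheet$group), c("case", "control"))
    for (gp in bad_grp)
      fail("samples", d$study_id, sprintf("unknown group label '%s'", gp))
    if (!length(missing) && !length(bad_grp)) {
      grp <- setNames(sheet$group, sheet$sample_id)[colnames(m)]
      if (sum(grp == "case") < 2 || sum(grp == "control") < 2)
        fail("design", d$study_id, "each group needs >= 2 samples")
    }
    if (d$platform == "rnaseq" && !inherits(m, "error")) {
      bad <- which(!(m >= 0 & abs(m - round(m)) < 1e-8), arr.ind = TRUE)
      if (nrow(bad))
        fail("matrix", d$study_id,
             sprintf("non-integer count %g at gene '%s', sample '%s'",
                     m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                     colnames(m)[bad[1, 2]]))
    }
  }
  if (!file.exists(config$gmt)) {
    fail("gmt", config$gmt, "GMT file does not exist")
  } else {
    g <- tryCatch(read_gmt(config$gmt), error = function(e) e)
    if (inherits(g, "error")) fail("gmt", config$gmt, conditionMessage(g))
  }
  if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(stage = character(), item = character(), message = character())
}

#' Run the full meta-analysis pipeline
#'
#' Orchestrates harmonize -> per-study DE -> signed-Z meta-analysis ->
#' direction-split enrichment on the studies named by a
#' [pipeline_config()], writing per-study DE tables, the meta table, the
#' enrichment tables, a JSON run report, and a file manifest under
#' `config$out_dir`. The run is deterministic given the config (the DE and
#' meta stages involve no randomness; the seed is recorded for provenance).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log messages.
#' @return A `pipeline_run` object: list with `de` (named list of
#'   `de_result`), `per_study_degs` (tibble), `meta` (`meta_result`),
#'   `enrichment` (`directional_ora`), `universe` (gene/study-count tibble),
#'   `report` (list), and `files` (manifest tibble).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    abort_config("config", "must be a pipeline_config()")
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "dosagemeta_pipeline_error")
    })
  }

  files <- list()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    readr::write_tsv(df, path)
    files[[length(files) + 1]] <<- tibble::tibble(file = name, rows = nrow(df))
  }

  # harmonize + per-study DE
  de <- list(); timings <- list(); n_harmonized <- list()
  for (i in seq_len(nrow(config$studies))) {
    d <- config$studies[i, ]
    st <- stage(paste0("load:", d$study_id),
                load_study(d$matrix, d$samples, d$study_id, d$platform))
    pm <- stage(paste0("probe_map:", d$study_id), read_probe_map(d$probes))
    hs <- stage(paste0("harmonize:", d$study_id),
                harmonize_study(st, pm, collapse_rule = config$collapse_rule,
                                quiet = quiet))
    n_harmonized[[d$study_id]] <- nrow(hs$values)
    res <- stage(paste0("de:", d$study_id),
                 if (d$platform == "array") moderated_t_de(hs) else nb_count_de(hs))
    res$q <- fdr_bh(res$p)
    de[[d$study_id]] <- res
    emit(res, paste0("de_", d$study_id, ".tsv"))
    say("de '%s': %d genes, %d DEGs at q <= %.3g", d$study_id, nrow(res),
        sum(res$q <= config$per_study_q), config$per_study_q)
  }

  per_study_degs <- purrr::map_dfr(de, function(res) {
    tibble::tibble(study_id = res$study_id[1], n_genes = nrow(res),
                   n_deg = sum(res$q <= config$per_study_q))
  })

  universe <- stage("universe", {
    harmonized_genes <- lapply(de, function(res) res$gene)
    tab <- table(unlist(harmonized_genes, use.names = FALSE))
    tibble::tibble(gene = names(tab), n_studies = as.integer(tab))
  })

  meta <- stage("meta", run_meta(
    de, q_threshold = config$meta_q, min_studies = config$min_studies,
    het_p_threshold = config$het_p, weight_scheme = config$weight_scheme))
  emit(meta$genes, "meta_table.tsv")
  say("meta: %d genes entered, %d included (%d up / %d down)",
      meta$summary$n_entered, meta$summary$n_included,
      meta$summary$n_up, meta$summary$n_down)

  collection <- stage("gmt", read_gmt(config$gmt))
  enr <- stage("enrichment", directional_enrichment(
    meta, collection, universe_policy = config$universe_policy))
  emit(tibble::as_tibble(enr$up), "enrichment_up.tsv")
  emit(tibble::as_tibble(enr$down), "enrichment_down.tsv")
  emit(tibble::as_tibble(enr$all), "enrichment_all.tsv")

  report <- list(
    config_hash = hash(config),
    seed = config$seed,
    thresholds = list(per_study_q = config$per_study_q, meta_q = config$meta_q,
                      het_p = config$het_p, min_studies = config$min_studies),
    genes_harmonized = n_harmonized,
    per_study_degs = per_study_degs,
    genes_entered = meta$summary$n_entered,
    genes_included = meta$summary$n_included,
    n_up = meta$summary$n_up,
    n_down = meta$summary$n_down,
    exclusions = list(q = meta$summary$n_excluded_q,
                      min_studies = meta$summary$n_excluded_min_studies,
                      heterogeneity = meta$summary$n_excluded_heterogeneity),
    top_enriched_up = utils::head(enr$up$set, 5),
    top_enriched_down = utils::head(enr$down$set, 5),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files[[length(files) + 1]] <- tibble::tibble(file = "report.json", rows = NA_integer_)
  files <- dplyr::bind_rows(files)
  readr::write_tsv(files, file.path(config$out_dir, "manifest.tsv"))

  structure(list(de = de, per_study_degs = per_study_degs, meta = meta,
                 enrichment = enr, universe = universe, report = report,
                 files = files, config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<pipeline_run> %d studies -> %d genes entered, %d included (%d up / %d down)\n",
              nrow(x$config$studies), r$genes_entered, r$genes_included,
              r$n_up, r$n_down))
  print(x$per_study_degs)
  cat("top enriched (up):", paste(r$top_enriched_up, collapse = ", "), "\n")
  invisible(x)
}

#' One-row pipeline summary
#'
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @return A one-row tibble with the headline run counts.
#' @export
glance.pipeline_run <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_studies = nrow(x$config$studies),
    genes_entered = r$genes_entered, genes_included = r$genes_included,
    n_up = r$n_up, n_down = r$n_down,
    top_up_set = r$top_enriched_up[1] %||% NA_character_
  )
}
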