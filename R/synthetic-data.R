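#' Default four-study design
#'
#' Study-level design table emulating a published four-study compendium of
#' trisomy-21 versus euploid iPSC expression data: two microarray studies
#' (6 vs 3 and 12 vs 15 samples) and two RNA-seq studies (3 vs 4 and 3 vs 3),
#' with partially overlapping gene panels of roughly 16k-21k genes drawn from
#' a ~28k-gene universe.
#'
#' Per-study noise levels are not published for that compendium; the defaults
#' here were fixed a priori by a power calculation so that a 1.5-fold dosage
#' effect yields a comparable expected signed Z (about 4-5) in every study:
#' array residual SD 0.18 for the 6/3 study and 0.30 for the 12/15 study
#' (different platforms), and NB dispersion 0.012 for the count studies
#' (biological CV ~ 0.11, typical of isogenic cell-line clones).
#'
#' @return A tibble with one row per study: `study_id`, `platform`, `n_case`,
#'   `n_control`, `panel_size`, `noise_sd` (arrays; NA for counts),
#'   `dispersion` (counts; NA for arrays).
#' @export
default_study_design <- function() {
  tibble::tibble(
    study_id   = c("S1_array", "S2_rnaseq", "S3_array", "S4_rnaseq"),
    platform   = c("array", "rnaseq", "array", "rnaseq"),
    n_case     = c(6L, 3L, 12L, 3L),
    n_control  = c(3L, 4L, 15L, 3L),
    panel_size = c(20534L, 16214L, 21037L, 17251L),
    noise_sd   = c(0.18, NA, 0.30, NA),
    dispersion = c(NA, 0.012, NA, 0.012)
  )
}

#' Simulation configuration for multi-platform case/control studies
#'
#' Defines the ground-truth model: a shared latent log2 abundance per gene, a
#' cis block of genes on the simulated trisomic chromosome with a common
#' linear fold change in cases (gene dosage), a sparser set of trans genes
#' with heterogeneous log2 effects, and platform-specific observation noise
#' (Gaussian on log2 intensities for arrays, negative binomial for counts).
#'
#' @param studies Study design tibble; see [default_study_design()] for the
#'   required columns and the default four-study shape.
#' @param universe_size Number of distinct gene symbols in the universe.
#' @param cis_fraction Proportion of the universe on the trisomic chromosome.
#' @param cis_fold Linear fold change of cis genes in cases (default 1.5,
#'   the three-copy dosage expectation).
#' @param trans_fraction Proportion of non-cis genes truly dysregulated.
#' @param trans_effect_sd SD of trans log2 effects.
#' @param baseline_log2_mean,baseline_log2_sd Mean/SD of the latent per-gene
#'   log2 abundance shared by both platforms.
#' @param duplicate_probe_rate Proportion of panel genes given a second probe.
#' @param unmapped_probe_rate Proportion of the final probe list mapping to no
#'   gene symbol (control probes).
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return A `simulation_config` object (validated list).
#' @export
simulation_config <- function(studies = default_study_design(),
                              universe_size = 28000L,
                              cis_fraction = 0.02,
                              cis_fold = 1.5,
                              trans_fraction = 0.08,
                              trans_effect_sd = 0.5,
                              baseline_log2_mean = 9,
                              baseline_log2_sd = 1,
                              duplicate_probe_rate = 0.1,
                              unmapped_probe_rate = 0.02,
                              seed = 1L) {
  studies <- tibble::as_tibble(studies)
  needed <- c("study_id", "platform", "n_case", "n_control", "panel_size")
  missing_cols <- setdiff(needed, names(studies))
  if (length(missing_cols))
    abort_config("studies", paste("lacks column(s):", paste(missing_cols, collapse = ", ")))
  if (!"noise_sd" %in% names(studies)) studies$noise_sd <- ifelse(studies$platform == "array", 0.25, NA)
  if (!"dispersion" %in% names(studies)) studies$dispersion <- ifelse(studies$platform == "rnaseq", 0.012, NA)
  if (!all(studies$platform %in% c("array", "rnaseq")))
    abort_config("studies$platform", "must be 'array' or 'rnaseq'")
  if (any(studies$n_case < 2) || any(studies$n_control < 2))
    abort_config("studies$n_case/n_control", "must be >= 2 in every study")
  if (any(studies$panel_size > universe_size))
    abort_config("studies$panel_size", "cannot exceed universe_size")
  for (fld in c("cis_fraction", "trans_fraction", "duplicate_probe_rate", "unmapped_probe_rate")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      abort_config(fld, "must be a proportion in [0, 1]")
  }
  if (!is.numeric(cis_fold) || cis_fold <= 0) abort_config("cis_fold", "must be > 0")
  if (trans_effect_sd < 0) abort_config("trans_effect_sd", "must be >= 0")
  if (baseline_log2_sd < 0) abort_config("baseline_log2_sd", "must be >= 0")
  if (universe_size < 1) abort_config("universe_size", "must be >= 1")
  bad_noise <- studies$platform == "array" & (is.na(studies$noise_sd) | studies$noise_sd <= 0)
  if (any(bad_noise)) abort_config("studies$noise_sd", "must be > 0 for array studies")
  bad_disp <- studies$platform == "rnaseq" & (is.na(studies$dispersion) | studies$dispersion < 0)
  if (any(bad_disp)) abort_config("studies$dispersion", "must be >= 0 for rnaseq studies")
  structure(
    list(studies = studies, universe_size = as.integer(universe_size),
         cis_fraction = cis_fraction, cis_fold = cis_fold,
         trans_fraction = trans_fraction, trans_effect_sd = trans_effect_sd,
         baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
         duplicate_probe_rate = duplicate_probe_rate,
         unmapped_probe_rate = unmapped_probe_rate, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d studies, universe %d genes, cis %.3f x%.2g, trans %.3f (sd %.2f), seed %d\n",
              nrow(x$studies), x$universe_size, x$cis_fraction, x$cis_fold,
              x$trans_fraction, x$trans_effect_sd, x$seed))
  print(x$studies)
  invisible(x)
}

# Ground truth: gene status (null/cis/trans), true log2 effect, chromosome.
simulate_truth <- function(config) {
  genes <- sprintf("G%05d", seq_len(config$universe_size))
  n_cis <- round(config$cis_fraction * config$universe_size)
  cis <- sample(genes, n_cis)
  rest <- setdiff(genes, cis)
  n_trans <- round(config$trans_fraction * length(rest))
  trans <- sample(rest, n_trans)
  status <- setNames(rep("null", length(genes)), genes)
  status[cis] <- "cis"
  status[trans] <- "trans"
  effect <- setNames(rep(0, length(genes)), genes)
  effect[cis] <- log2(config$cis_fold)
  effect[trans] <- rnorm(n_trans, 0, config$trans_effect_sd)
  chrom <- setNames(sample(paste0("chr", c(1:20, "X")), length(genes), replace = TRUE), genes)
  chrom[cis] <- "chr21"
  tibble::tibble(gene = genes, status = unname(status[genes]),
                 true_log2fc = unname(effect[genes]),
                 chromosome = unname(chrom[genes]))
}

#' Simulate a set of multi-platform case/control studies with known truth
#'
#' Generates the configured studies from a shared latent truth: array studies
#' return log2 intensities `baseline + group effect + N(0, noise_sd)`; RNA-seq
#' studies return counts `NB(mean = 2^baseline * fold^group * libsize,
#' dispersion)`. The cis effect is applied on the linear scale (x `cis_fold`)
#' before noise, modelling gene dosage. Each study's panel is a random subset
#' of the universe; features are relabelled to platform-native probe ids via
#' [simulate_probe_map()]. Identical configuration (including seed) gives
#' byte-identical output.
#'
#' @param config A [simulation_config()].
#' @return A list with `studies` (list of [expression_study()] keyed by probe
#'   id), `probe_maps` (list of probe-to-symbol tibbles), and `truth`
#'   (tibble: `gene`, `status` in null/cis/trans, `true_log2fc`,
#'   `chromosome`).
#' @export
simulate_studies <- function(config) {
  if (!inherits(config, "simulation_config"))
    abort_config("config", "must be created by simulation_config()")
  set.seed(config$seed)
  truth <- simulate_truth(config)
  baseline <- setNames(rnorm(config$universe_size, config$baseline_log2_mean,
                             config$baseline_log2_sd), truth$gene)
  effect <- setNames(truth$true_log2fc, truth$gene)

  studies <- vector("list", nrow(config$studies))
  probe_maps <- vector("list", nrow(config$studies))
  for (i in seq_len(nrow(config$studies))) {
    d <- config$studies[i, ]
    panel <- sort(sample(truth$gene, d$panel_size))
    n <- d$n_case + d$n_control
    group <- c(rep("case", d$n_case), rep("control", d$n_control))
    samples <- sprintf("%s_%s%02d", d$study_id,
                       ifelse(group == "case", "case", "ctrl"),
                       c(seq_len(d$n_case), seq_len(d$n_control)))
    is_case <- as.numeric(group == "case")
    if (d$platform == "array") {
      mu <- outer(baseline[panel], rep(1, n)) + outer(effect[panel], is_case)
      values <- mu + matrix(rnorm(length(mu), 0, d$noise_sd), nrow(mu))
    } else {
      libsize <- exp(rnorm(n, 0, 0.15))
      mu <- (2^baseline[panel]) %o% libsize * 2^outer(effect[panel], is_case)
      values <- matrix(rnbinom(length(mu), mu = mu,
                               size = 1 / max(d$dispersion, 1e-8)), nrow(mu))
    }
    dimnames(values) <- list(panel, samples)
    sym_study <- expression_study(values, group, d$study_id, d$platform)
    pm <- simulate_probe_map(sym_study,
                             duplicate_probe_rate = config$duplicate_probe_rate,
                             unmapped_probe_rate = config$unmapped_probe_rate,
                             noise_sd = if (d$platform == "array") d$noise_sd else NA,
                             dispersion = if (d$platform == "rnaseq") d$dispersion else NA)
    studies[[i]] <- pm$study
    probe_maps[[i]] <- pm$map
  }
  names(studies) <- config$studies$study_id
  names(probe_maps) <- config$studies$study_id
  list(studies = studies, probe_maps = probe_maps, truth = truth)
}

#' Relabel a symbol-keyed study with platform-native probe ids
#'
#' Gives every panel gene at least one probe, a configurable fraction a second
#' (replicate) probe whose row is an independently re-measured copy, and adds
#' a fraction of control probes that map to no symbol. Returns the probe-keyed
#' study together with the probe-to-symbol map (empty symbol = unmapped).
#'
#' @param study A symbol-keyed [expression_study()].
#' @param duplicate_probe_rate Proportion of genes given a second probe.
#' @param unmapped_probe_rate Proportion of the final probe list with no
#'   symbol.
#' @param noise_sd,dispersion Platform noise used to re-measure replicate and
#'   control probe rows (defaults match typical use from
#'   [simulate_studies()]).
#' @param seed Optional seed; by default the current RNG stream is used so
#'   [simulate_studies()] stays a pure function of its config.
#' @return A list with `study` (probe-keyed) and `map` (tibble `probe_id`,
#'   `symbol`).
#' @export
simulate_probe_map <- function(study, duplicate_probe_rate = 0.1,
                               unmapped_probe_rate = 0.02,
                               noise_sd = 0.25, dispersion = 0.012,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- rownames(study$values)
  n_genes <- length(genes)
  n <- ncol(study$values)

  remeasure <- function(base_rows) {
    # an independent re-measurement of the same underlying abundance
    if (study$platform == "array") {
      base_rows + matrix(rnorm(length(base_rows), 0, noise_sd), nrow(base_rows))
    } else {
      matrix(rnbinom(length(base_rows), mu = pmax(base_rows, 0.5),
                     size = 1 / max(dispersion, 1e-8)), nrow(base_rows))
    }
  }

  dup_genes <- if (duplicate_probe_rate > 0) {
    genes[runif(n_genes) < duplicate_probe_rate]
  } else character(0)
  n_mapped <- n_genes + length(dup_genes)
  n_unmapped <- if (unmapped_probe_rate > 0) {
    round(n_mapped * unmapped_probe_rate / (1 - unmapped_probe_rate))
  } else 0L

  symbols <- c(genes, dup_genes, rep("", n_unmapped))
  probe_ids <- sprintf("%s_p%06d", study$study_id, seq_along(symbols))

  rows <- study$values
  if (length(dup_genes))
    rows <- rbind(rows, remeasure(study$values[dup_genes, , drop = FALSE]))
  if (n_unmapped > 0) {
    ctrl_base <- matrix(stats::median(study$values), n_unmapped, n)
    rows <- rbind(rows, remeasure(ctrl_base))
  }
  dimnames(rows) <- list(probe_ids, colnames(study$values))

  list(
    study = expression_study(rows, study$group, study$study_id, study$platform),
    map = tibble::tibble(probe_id = probe_ids, symbol = symbols)
  )
}

#' Write a self-contained demo fixture set to disk
#'
#' Emits, for each simulated study, a TSV expression matrix (first column
#' `feature`), a sample sheet (`sample_id`, `group`), and a probe map
#' (`probe_id`, `symbol`), plus one GMT gene-set collection containing a
#' positional set per chromosome (including the all-cis `POS_chr21` set) and a
#' handful of random "pathway" sets, and the ground-truth table. Re-running
#' with the same configuration produces identical files.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return The file manifest: a tibble with `file`, `type`, `rows`, `cols`.
#' @export
write_fixture_set <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort_data(sprintf("cannot create fixture directory '%s'", dir))
  sim <- simulate_studies(config)

  manifest <- list()
  add <- function(file, type, rows, cols) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      file = file, type = type, rows = rows, cols = cols)
  }

  for (id in names(sim$studies)) {
    st <- sim$studies[[id]]
    mat_file <- file.path(dir, paste0(id, "_matrix.tsv"))
    df <- tibble::as_tibble(st$values, rownames = "feature")
    readr::write_tsv(df, mat_file)
    add(basename(mat_file), "matrix", nrow(df), ncol(df))

    sheet_file <- file.path(dir, paste0(id, "_samples.tsv"))
    sheet <- tibble::tibble(sample_id = colnames(st$values), group = st$group)
    readr::write_tsv(sheet, sheet_file)
    add(basename(sheet_file), "samples", nrow(sheet), ncol(sheet))

    map_file <- file.path(dir, paste0(id, "_probes.tsv"))
    readr::write_tsv(sim$probe_maps[[id]], map_file)
    add(basename(map_file), "probe_map", nrow(sim$probe_maps[[id]]), 2L)
  }

  sets <- positional_gene_sets(sim$truth)
  extra <- random_gene_sets(sim$truth$gene, n_sets = 15)
  collection <- dplyr::bind_rows(sets, extra)
  gmt_file <- file.path(dir, "gene_sets.gmt")
  write_gmt(collection, gmt_file)
  add(basename(gmt_file), "gmt", nrow(collection), NA_integer_)

  truth_file <- file.path(dir, "truth.tsv")
  readr::write_tsv(sim$truth, truth_file)
  add(basename(truth_file), "truth", nrow(sim$truth), ncol(sim$truth))

  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}

# One positional set per chromosome; POS_chr21 is all-cis by construction.
positional_gene_sets <- function(truth) {
  truth |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(members = list(.data$gene), .groups = "drop") |>
    dplyr::transmute(set = paste0("POS_", .data$chromosome),
                     description = paste("genes on", .data$chromosome),
                     members = .data$members)
}

random_gene_sets <- function(genes, n_sets = 15, size_range = c(50, 400)) {
  hi <- min(size_range[2], max(2, floor(length(genes) / 2)))
  lo <- min(size_range[1], hi)
  tibble::tibble(
    set = sprintf("SET_random_%02d", seq_len(n_sets)),
    description = "random functional set",
    members = purrr::map(seq_len(n_sets), function(i) {
      sample(genes, sample(seq(lo, hi), 1))
    })
  )
}
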