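#' Fura-2 calcium calibration parameters
#'
#' Parameters of the ratiometric Grynkiewicz calibration: the Fura-2
#' dissociation constant Kd (224 nM by default), the ratio bounds Rmin/Rmax
#' measured at zero and saturating calcium, and the scaling factor beta
#' (Sf2/Sb2, the free-to-bound fluorescence ratio at the second wavelength).
#' When beta is not supplied it defaults to 1 with a warning, since assays do
#' not always report it.
#'
#' @param Rmin,Rmax Ratio bounds, `Rmax > Rmin > 0`.
#' @param Kd Dissociation constant in nM (> 0).
#' @param beta Sf2/Sb2 scaling factor (> 0); defaults to 1 with a warning.
#' @return A `calcium_calibration` object.
#' @export
calcium_calibration <- function(Rmin, Rmax, Kd = 224, beta = NULL) {
  if (is.null(beta)) {
    warn("beta (Sf2/Sb2) not supplied; defaulting to 1")
    beta <- 1
  }
  if (!is.numeric(Rmin) || !is.numeric(Rmax) || !(Rmax > Rmin) || Rmin <= 0)
    abort_config("Rmin/Rmax", "must satisfy Rmax > Rmin > 0")
  if (Kd <= 0) abort_config("Kd", "must be > 0")
  if (beta <= 0) abort_config("beta", "must be > 0")
  structure(list(Kd = Kd, Rmin = Rmin, Rmax = Rmax, beta = beta),
            class = "calcium_calibration")
}

#' Grynkiewicz ratiometric calcium concentration
#'
#' Converts Fura-2 340/380 fluorescence ratios to cytosolic free calcium via
#' the Grynkiewicz equation,
#' \deqn{[\mathrm{Ca}^{2+}] = K_d \, \beta \, (R - R_{min}) / (R_{max} - R),}
#' strictly increasing in R on \[Rmin, Rmax).
#'
#' @param R Fluorescence ratio(s), `Rmin <= R < Rmax`.
#' @param calib A [calcium_calibration()].
#' @return Calcium concentration(s) in nM.
#' @export
grynkiewicz_ca <- function(R, calib) {
  if (!inherits(calib, "calcium_calibration"))
    abort_config("calib", "must be a calcium_calibration()")
  if (any(R < calib$Rmin))
    abort_data("calibration error: ratio below Rmin")
  if (any(R >= calib$Rmax))
    abort_data("saturation: ratio at or above Rmax has no finite concentration")
  calib$Kd * calib$beta * (R - calib$Rmin) / (calib$Rmax - R)
}

#' Invert the Grynkiewicz equation
#'
#' @param ca Calcium concentration(s) in nM (>= 0).
#' @param calib A [calcium_calibration()].
#' @return The fluorescence ratio(s) R producing `ca`.
#' @export
grynkiewicz_ratio <- function(ca, calib) {
  if (any(ca < 0)) abort_data("concentrations must be >= 0")
  kb <- calib$Kd * calib$beta
  (ca * calib$Rmax + kb * calib$Rmin) / (ca + kb)
}

#' FCCP peak over basal calcium, as a percent difference
#'
#' The mitochondrial calcium-efflux index: the percentage difference of the
#' post-FCCP peak cytosolic calcium with respect to the basal level,
#' `100 * (peak - basal) / basal`. Negative excursions are allowed.
#'
#' @param basal_ca Basal calcium (> 0), nM.
#' @param peak_ca Post-FCCP peak calcium, nM.
#' @return Percent difference(s).
#' @export
fccp_peak_percent <- function(basal_ca, peak_ca) {
  if (any(basal_ca <= 0)) abort_data("basal calcium must be > 0")
  100 * (peak_ca - basal_ca) / basal_ca
}

#' Mito Stress respiratory indices from an OCR trace
#'
#' Standard extracellular-flux (Seahorse Mito Stress Test) index definitions
#' applied to one well's oxygen-consumption trace across the four injection
#' phases (baseline, oligomycin, FCCP, antimycin-A/rotenone):
#' non-mitochondrial = mean of the post-antimycin/rotenone segment; basal =
#' baseline reading - non-mitochondrial; ATP-linked = baseline reading -
#' minimum post-oligomycin; maximal = maximum post-FCCP -
#' non-mitochondrial; spare = maximal - basal. The baseline reading is the
#' last pre-oligomycin measurement by default (`baseline_stat = "last"`) or
#' the baseline segment mean.
#'
#' @param trace Data frame with columns `time`, `ocr`, and `phase` in
#'   `baseline`, `oligomycin`, `fccp`, `antimycin_rotenone`; optionally a
#'   `well` column, in which case indices are computed per well.
#' @param baseline_stat `"last"` (default) or `"mean"`.
#' @return A tibble with one row per well: `well` (if present), `non_mito`,
#'   `basal`, `atp_linked`, `maximal`, `spare` (all pmol O2/min).
#' @export
ocr_indices <- function(trace, baseline_stat = c("last", "mean")) {
  baseline_stat <- match.arg(baseline_stat)
  trace <- tibble::as_tibble(trace)
  phases <- c("baseline", "oligomycin", "fccp", "antimycin_rotenone")
  if (!all(c("time", "ocr", "phase") %in% names(trace)))
    abort_data("OCR trace needs columns time, ocr, phase")
  if (!all(trace$phase %in% phases))
    abort_data("trace phases must be baseline/oligomycin/fccp/antimycin_rotenone")

  one_well <- function(df) {
    df <- dplyr::arrange(df, .data$time)
    missing <- setdiff(phases, unique(df$phase))
    if (length(missing))
      abort_data(paste("trace-structure error: missing segment(s):",
                       paste(missing, collapse = ", ")))
    seg <- function(ph) df$ocr[df$phase == ph]
    non_mito <- mean(seg("antimycin_rotenone"))
    base_read <- if (baseline_stat == "last") {
      utils::tail(seg("baseline"), 1)
    } else mean(seg("baseline"))
    basal <- base_read - non_mito
    atp_linked <- base_read - min(seg("oligomycin"))
    maximal <- max(seg("fccp")) - non_mito
    tibble::tibble(non_mito = non_mito, basal = basal,
                   atp_linked = atp_linked, maximal = maximal,
                   spare = maximal - basal)
  }

  if ("well" %in% names(trace)) {
    trace |>
      dplyr::group_by(.data$well) |>
      dplyr::group_modify(~ one_well(.x)) |>
      dplyr::ungroup()
  } else {
    one_well(trace)
  }
}

#' Read an OCR trace TSV
#'
#' Expected columns: `time`, `well`, `ocr`, `phase`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_ocr_trace <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("OCR trace '%s' does not exist", path))
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a Fura-2 ratio table with a calibration header
#'
#' Tabular records (`cell_id`, `R`) preceded by a comment header block of
#' `# key: value` lines supplying `Rmin`, `Rmax`, and optionally `Kd` and
#' `beta`.
#'
#' @param path TSV path.
#' @return A list with `calibration` (a [calcium_calibration()]) and `data`
#'   (tibble with `cell_id`, `R`, and the computed `ca_nM`).
#' @export
read_calcium_table <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("calcium table '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*(\\w+)\\s*[:=]\\s*([-0-9.eE]+)", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- as.numeric(m[3])
  }
  for (fld in c("Rmin", "Rmax"))
    if (is.null(kv[[fld]])) abort_data(sprintf("calcium header lacks '%s'", fld))
  calib <- calcium_calibration(Rmin = kv$Rmin, Rmax = kv$Rmax,
                               Kd = kv$Kd %||% 224, beta = kv$beta)
  df <- readr::read_tsv(I(lines[!grepl("^#", lines)]), show_col_types = FALSE)
  df$ca_nM <- grynkiewicz_ca(df$R, calib)
  list(calibration = calib, data = df)
}

#' Percent-of-control normalization
#'
#' Expresses measurements as a percentage of the control-group mean, which
#' maps to exactly 100 (the convention used to report trisomic assay values
#' relative to euploid controls).
#'
#' @param values Measurements to normalize.
#' @param control_values Control-group measurements; their mean must be > 0.
#' @return `100 * values / mean(control_values)`.
#' @export
percent_of_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) abort_data("control mean must be > 0")
  100 * values / m
}
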