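# Scaled-down study designs used throughout the suite; the default full-size
# design is exercised once in the end-to-end acceptance checks.

small_design <- function(panels = c(600L, 500L, 650L, 550L)) {
  d <- default_study_design()
  d$panel_size <- panels
  d
}

small_config <- function(universe_size = 800L, seed = 101L,
                         studies = small_design(), ...) {
  simulation_config(studies = studies, universe_size = universe_size,
                    seed = seed, ...)
}

null_config <- function(universe_size = 2000L, seed = 1L,
                        panels = c(1500L, 1300L, 1600L, 1400L)) {
  simulation_config(studies = small_design(panels), universe_size = universe_size,
                    cis_fraction = 0, trans_fraction = 0, seed = seed)
}

toy_array_study <- function(n_genes = 50, n1 = 4, n2 = 4, seed = 1, sd = 0.3,
                            study_id = "toy") {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * (n1 + n2), mean = 8, sd = sd), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n1 + n2))))
  expression_study(x, c(rep("case", n1), rep("control", n2)), study_id, "array")
}

# one well, three measurements per segment, constant within segment
toy_ocr_trace <- function(baseline = 100, oligo = 40, fccp = 130, aarot = 10) {
  tibble::tibble(
    time = seq_len(12) * 6.5,
    ocr = rep(c(baseline, oligo, fccp, aarot), each = 3),
    phase = rep(c("baseline", "oligomycin", "fccp", "antimycin_rotenone"), each = 3)
  )
}

# run harmonize + platform DE + meta on a simulated dataset
meta_from_sim <- function(sim, ...) {
  de <- lapply(names(sim$studies), function(id) {
    hs <- harmonize_study(sim$studies[[id]], sim$probe_maps[[id]], quiet = TRUE)
    if (hs$platform == "array") moderated_t_de(hs) else nb_count_de(hs)
  })
  run_meta(de, ...)
}
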