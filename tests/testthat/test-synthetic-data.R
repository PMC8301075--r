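test_that("configuration validation names the offending field", {
  expect_error(simulation_config(cis_fraction = 1.2), "cis_fraction")
  expect_error(simulation_config(cis_fold = -1), "cis_fold")
  expect_error(simulation_config(universe_size = 100,
                                 studies = small_design(c(200L, 200L, 200L, 200L))),
               "panel_size")
  d <- small_design(); d$n_case[1] <- 1L
  expect_error(simulation_config(studies = d), "n_case")
})

test_that("identical configuration gives byte-identical output", {
  a <- simulate_studies(small_config(seed = 7))
  b <- simulate_studies(small_config(seed = 7))
  expect_identical(a$truth, b$truth)
  for (id in names(a$studies)) {
    expect_identical(a$studies[[id]]$values, b$studies[[id]]$values)
    expect_identical(a$probe_maps[[id]], b$probe_maps[[id]])
  }
  c <- simulate_studies(small_config(seed = 8))
  expect_false(identical(a$studies[[1]]$values, c$studies[[1]]$values))
})

test_that("zero-effect configuration is all-null truth", {
  sim <- simulate_studies(null_config(universe_size = 500,
                                      panels = c(400L, 350L, 420L, 380L)))
  expect_true(all(sim$truth$status == "null"))
  expect_true(all(sim$truth$true_log2fc == 0))
})

test_that("platform dialects honour their value contracts", {
  sim <- simulate_studies(small_config(seed = 5))
  for (id in names(sim$studies)) {
    st <- sim$studies[[id]]
    if (st$platform == "array") {
      expect_true(all(is.finite(st$values)))
    } else {
      expect_true(all(st$values >= 0))
      expect_true(all(st$values == round(st$values)))
    }
    expect_equal(st$n_case + st$n_control, ncol(st$values))
  }
})

test_that("observed cis contrast matches the 1.5-fold dosage effect", {
  # default full-size design; generator-level case/control contrast averaged
  # over all cis genes in each study should sit near log2(1.5) = 0.585
  sim <- simulate_studies(simulation_config(seed = 31))
  cis <- sim$truth$gene[sim$truth$status == "cis"]
  expect_gt(length(cis), 500)
  contrasts <- purrr::map_dbl(names(sim$studies), function(id) {
    hs <- harmonize_study(sim$studies[[id]], sim$probe_maps[[id]], quiet = TRUE)
    x <- hs$values[intersect(rownames(hs$values), cis), , drop = FALSE]
    case <- hs$group == "case"
    if (hs$platform == "array") {
      mean(rowMeans(x[, case, drop = FALSE]) - rowMeans(x[, !case, drop = FALSE]))
    } else {
      sf <- colSums(hs$values) / exp(mean(log(colSums(hs$values))))
      xn <- sweep(x, 2, sf, "/")
      mean(log2(rowMeans(xn[, case, drop = FALSE]) + 0.5) -
             log2(rowMeans(xn[, !case, drop = FALSE]) + 0.5))
    }
  })
  expect_true(all(abs(contrasts - log2(1.5)) < 0.05))
})

test_that("probe maps meet their duplication and mapping contracts", {
  sim <- simulate_studies(small_config(seed = 3, duplicate_probe_rate = 0,
                                       unmapped_probe_rate = 0))
  pm <- sim$probe_maps[[1]]
  expect_equal(anyDuplicated(pm$symbol), 0)  # bijective
  expect_equal(nrow(pm), nrow(sim$studies[[1]]$values))

  st <- toy_array_study(n_genes = 100, seed = 9)
  set.seed(42)
  res <- simulate_probe_map(st, duplicate_probe_rate = 0.5, unmapped_probe_rate = 0)
  n_multi <- sum(table(res$map$symbol[res$map$symbol != ""]) >= 2)
  # Binomial(100, 0.5): +/- 4 sd
  expect_true(n_multi >= 30 && n_multi <= 70)

  res2 <- simulate_probe_map(st, duplicate_probe_rate = 0, unmapped_probe_rate = 0.1,
                             seed = 77)
  frac <- mean(res2$map$symbol == "")
  expect_true(abs(frac - 0.1) < 0.04)
  # every panel gene still has at least one probe
  expect_true(all(rownames(st$values) %in% res2$map$symbol))
  # probe-keyed study rows align with the map
  expect_identical(rownames(res2$study$values), res2$map$probe_id)
})

test_that("fixture sets are complete, correctly sized, and reproducible", {
  cfg <- small_config(seed = 12, universe_size = 400L,
                      studies = small_design(c(300L, 250L, 320L, 280L)))
  dir1 <- withr::local_tempdir()
  man <- write_fixture_set(cfg, dir1)
  expect_equal(sum(man$type == "matrix"), 4)
  expect_equal(sum(man$type == "samples"), 4)
  expect_equal(sum(man$type == "probe_map"), 4)
  expect_equal(sum(man$type == "gmt"), 1)
  # matrix row counts equal the probe list length (panel + duplicates + controls)
  for (i in seq_len(4)) {
    id <- cfg$studies$study_id[i]
    mat_rows <- man$rows[man$file == paste0(id, "_matrix.tsv")]
    map_rows <- man$rows[man$file == paste0(id, "_probes.tsv")]
    expect_equal(mat_rows, map_rows)
    expect_gte(mat_rows, cfg$studies$panel_size[i])
  }
  # GMT contains the all-cis positional set
  gmt <- read_gmt(file.path(dir1, "gene_sets.gmt"))
  truth <- readr::read_tsv(file.path(dir1, "truth.tsv"), show_col_types = FALSE)
  cis <- truth$gene[truth$status == "cis"]
  expect_setequal(gmt$members[[match("POS_chr21", gmt$set)]], cis)

  dir2 <- withr::local_tempdir()
  write_fixture_set(cfg, dir2)
  for (f in man$file) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     info = f)
  }
})
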