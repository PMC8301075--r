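test_that("signed Z matches the standard-normal quantile with the fold-change sign", {
  expect_equal(signed_z(1, 2.3), 0)
  expect_equal(signed_z(1, -0.4), 0)
  expect_equal(signed_z(0.05, 0.8), 1.959964, tolerance = 1e-6)
  expect_equal(signed_z(0.05, -0.8), -1.959964, tolerance = 1e-6)
  expect_equal(signed_z(0.5, 0), 0)
  expect_error(signed_z(0, 1), "\\(0, 1\\]")
  expect_error(signed_z(1.2, 1), "\\(0, 1\\]")
  expect_error(signed_z(0.1, Inf), "finite")
})

test_that("Stouffer combination follows the weighted-sum definition", {
  # single study: identity
  one <- combine_stouffer(1.7, 9)
  expect_equal(one$z_meta, 1.7)
  expect_equal(one$p_meta, 2 * pnorm(-1.7))
  # symmetric opposites cancel
  sym <- combine_stouffer(c(1.96, -1.96), c(5, 5))
  expect_equal(sym$z_meta, 0)
  expect_equal(sym$p_meta, 1)
  # hand computation: (3*2 + 4*1)/5 = 2
  hand <- combine_stouffer(c(2, 1), c(9, 16))
  expect_equal(hand$z_meta, 2)
  expect_equal(hand$p_meta, 0.0455, tolerance = 1e-3)
  expect_error(combine_stouffer(numeric(0), numeric(0)), "at least one")
})

test_that("Stouffer combination is order-invariant, scale-invariant, and oracle-exact", {
  set.seed(41)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    z <- rnorm(k, sd = 2)
    n <- sample(4:40, k, replace = TRUE)
    res <- combine_stouffer(z, n)
    perm <- sample(k)
    expect_equal(combine_stouffer(z[perm], n[perm])$z_meta, res$z_meta, tolerance = 1e-12)
    expect_equal(combine_stouffer(z, 7 * n)$z_meta, res$z_meta, tolerance = 1e-12)
    # independent oracle: round-trip each Z through its two-sided p and sign
    p_i <- 2 * pnorm(-abs(z))
    z_back <- sign(z) * qnorm(p_i / 2, lower.tail = FALSE)
    w <- sqrt(n)
    expect_lt(abs(res$z_meta - sum(w * z_back) / sqrt(sum(w^2))), 1e-10)
  }
})

test_that("effective-sample-size weighting is available", {
  res <- combine_stouffer(c(2, 1), c(10, 10), scheme = "effective",
                          n_case = c(5, 2), n_control = c(5, 8))
  w <- sqrt(4 / (1 / c(5, 2) + 1 / c(5, 8)))
  expect_equal(res$z_meta, sum(w * c(2, 1)) / sqrt(sum(w^2)))
})

test_that("Cochran's Q on signed Z behaves as defined", {
  same <- heterogeneity_test(c(1.3, 1.3, 1.3))
  expect_identical(same$q_het, 0)
  expect_identical(same$het_p, 1)
  opp <- heterogeneity_test(c(2, -2))
  expect_equal(opp$q_het, 8)
  expect_equal(opp$het_p, pchisq(8, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(opp$het_p, 0.00468, tolerance = 1e-3)
  one <- heterogeneity_test(0.5)
  expect_equal(one$q_het, 0)
  expect_equal(one$het_p, 1)
  expect_equal(one$flag, "single_study")
  # continuity: Q -> 0 and HetP -> 1 as a perturbation vanishes
  qs <- sapply(c(0.1, 0.01, 0.001), function(eps) {
    heterogeneity_test(c(1, 1, 1, 1 + eps))$q_het
  })
  expect_true(all(diff(qs) < 0))
  expect_lt(qs[3], 1e-5)
})

test_that("the three-criterion inclusion filter is applied verbatim", {
  mk_tbl <- function(gene, studies, z_target) {
    # build per-study DE rows that produce the requested combined behaviour
    purrr::map_dfr(seq_len(studies), function(i) {
      tibble::tibble(study_id = paste0("s", i), gene = gene,
                     log2FC = sign(z_target) * 1,
                     p = 2 * pnorm(-abs(z_target)), n_total = 10)
    })
  }
  # strong concordant gene in 3 studies + background nulls to steady the FDR
  set.seed(53)
  bg <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(study_id = paste0("s", i), gene = paste0("null", 1:200),
                   log2FC = rnorm(200, 0, 0.1), p = runif(200), n_total = 10)
  })
  tbl <- dplyr::bind_rows(mk_tbl("HIT", 3, 5), bg)
  res <- run_meta(tbl)
  hit <- res$genes[res$genes$gene == "HIT", ]
  expect_true(hit$included)
  expect_equal(hit$direction, "up")
  expect_lte(hit$q_meta, 0.01)
  expect_gt(hit$het_p, 0.05)

  # the same evidence in a single study fails the >= 2 datasets criterion
  tbl1 <- dplyr::bind_rows(mk_tbl("SOLO", 1, 6), bg)
  res1 <- run_meta(tbl1)
  solo <- res1$genes[res1$genes$gene == "SOLO", ]
  expect_false(solo$included)
  expect_match(solo$reason_excluded, "fewer_than_min_studies")

  # discordant directions fail the heterogeneity criterion
  het_tbl <- dplyr::bind_rows(
    tibble::tibble(study_id = c("s1", "s2", "s3"), gene = "DISC",
                   log2FC = c(2, 2, -2), p = c(1e-8, 1e-8, 1e-8), n_total = 10),
    bg)
  resh <- run_meta(het_tbl)
  disc <- resh$genes[resh$genes$gene == "DISC", ]
  expect_false(disc$included)
  expect_match(disc$reason_excluded, "heterogeneous")

  # duplicated (study, gene) pairs signal an upstream harmonization bug
  expect_error(run_meta(dplyr::bind_rows(bg, bg[1, ])), "duplicate")
})

test_that("up and down counts partition the included genes", {
  sim <- simulate_studies(small_config(seed = 67))
  res <- meta_from_sim(sim)
  expect_equal(res$summary$n_up + res$summary$n_down, res$summary$n_included)
  expect_true(all(res$genes$z_meta[res$genes$direction == "up"] > 0))
  expect_true(all(res$genes$z_meta[res$genes$direction == "down"] < 0))
  g <- glance(res)
  expect_equal(g$n_included, res$summary$n_included)
  expect_equal(nrow(tidy(res)), res$summary$n_entered)
})

test_that("null genes produce a standard-normal combined Z", {
  set.seed(71)
  g <- 2000
  tbl <- purrr::map_dfr(1:4, function(i) {
    z <- rnorm(g)
    tibble::tibble(study_id = paste0("s", i), gene = paste0("g", 1:g),
                   log2FC = z, p = 2 * pnorm(-abs(z)),
                   n_total = c(9, 7, 27, 6)[i])
  })
  res <- run_meta(tbl)
  expect_gt(ks.test(res$genes$z_meta, "pnorm")$p.value, 0.01)
  expect_equal(res$summary$n_included, 0)
})
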