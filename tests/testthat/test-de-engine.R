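test_that("moderated t with zero prior df equals the ordinary pooled t", {
  st <- toy_array_study(n_genes = 100, n1 = 5, n2 = 5, seed = 2)
  res <- moderated_t_de(st, prior_df = 0)
  for (i in seq_len(100)) {
    tv <- t.test(st$values[i, 1:5], st$values[i, 6:10], var.equal = TRUE)
    expect_lt(abs(res$statistic[i] - unname(tv$statistic)), 1e-10)
    expect_lt(abs(res$p[i] - tv$p.value), 1e-10)
  }
})

test_that("moderated t in the infinite-prior limit uses the common variance", {
  st <- toy_array_study(n_genes = 200, n1 = 4, n2 = 6, seed = 3)
  res <- moderated_t_de(st, prior_df = Inf)
  s0 <- attr(res, "prior")$s0_sq
  expected <- res$log2FC / sqrt(s0 * (1 / 4 + 1 / 6))
  expect_equal(res$statistic, expected, tolerance = 1e-12)
})

test_that("the moment-matched prior agrees with the established empirical-Bayes fit", {
  set.seed(17)
  g <- 2000
  x <- matrix(rnorm(g * 8, sd = rep(exp(rnorm(g, 0, 0.4)), 8)), g,
              dimnames = list(paste0("g", 1:g), paste0("s", 1:8)))
  grp <- rep(c("case", "control"), each = 4)
  res <- moderated_t_de(expression_study(x, grp, "cc", "array"))
  design <- cbind(1, grp == "case")
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(res, "prior")$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(res, "prior")$s0_sq, fit$s2.prior, tolerance = 1e-8)
  expect_lt(max(abs(res$statistic - fit$t[, 2])), 1e-10)
  expect_lt(max(abs(res$p - fit$p.value[, 2])), 1e-10)
})

test_that("null array data gives calibrated, uniform p-values", {
  set.seed(19)
  g <- 2000
  x <- matrix(rnorm(g * 10), g, dimnames = list(paste0("g", 1:g), paste0("s", 1:10)))
  st <- expression_study(x, rep(c("case", "control"), each = 5), "null", "array")
  res <- moderated_t_de(st)
  expect_gt(mean(res$p <= 0.05), 0.035)
  expect_lt(mean(res$p <= 0.05), 0.065)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
  # per-study DEG call at q <= 0.05 on null data: at most 1 gene
  expect_lte(sum(fdr_bh(res$p) <= 0.05), 1)
})

test_that("null count data gives calibrated p-values, including the Poisson limit", {
  set.seed(23)
  g <- 2000
  mu <- 2^rnorm(g, 9, 1)
  cnt <- matrix(rnbinom(g * 7, mu = rep(mu, 7), size = 1 / 0.012), g,
                dimnames = list(paste0("g", 1:g), paste0("s", 1:7)))
  st <- expression_study(cnt, c(rep("case", 3), rep("control", 4)), "null", "rnaseq")
  res <- nb_count_de(st)
  expect_gt(mean(res$p <= 0.05), 0.03)
  expect_lt(mean(res$p <= 0.05), 0.07)
  # dispersion 0: reduces to a Poisson likelihood-ratio test
  cntp <- matrix(rpois(g * 7, rep(mu, 7)), g, dimnames = dimnames(cnt))
  stp <- expression_study(cntp, st$group, "pois", "rnaseq")
  resp <- nb_count_de(stp, dispersion = 0)
  expect_gt(mean(resp$p <= 0.05), 0.03)
  expect_lt(mean(resp$p <= 0.05), 0.07)
})

test_that("count engine recovers a 1.5-fold dosage effect at n = 12 vs 15", {
  d <- tibble::tibble(study_id = "big_counts", platform = "rnaseq",
                      n_case = 12L, n_control = 15L, panel_size = 3000L,
                      noise_sd = NA, dispersion = 0.012)
  cfg <- simulation_config(studies = d, universe_size = 3000L, seed = 29,
                           duplicate_probe_rate = 0, unmapped_probe_rate = 0)
  sim <- simulate_studies(cfg)
  hs <- harmonize_study(sim$studies[[1]], sim$probe_maps[[1]], quiet = TRUE)
  res <- nb_count_de(hs)
  cis <- sim$truth$gene[sim$truth$status == "cis"]
  expect_lt(abs(median(res$log2FC[res$gene %in% cis]) - log2(1.5)), 0.1)
  # and the test detects most of them at per-study q <= 0.05
  q <- fdr_bh(res$p)
  expect_gt(mean(q[res$gene %in% cis] <= 0.05), 0.8)
})

test_that("count fold changes and significance track an established NB engine", {
  set.seed(31)
  g <- 500
  mu <- 2^rnorm(g, 9, 1)
  fold <- ifelse(seq_len(g) <= 100, 2, 1)
  grp <- c(rep("case", 3), rep("control", 4))
  mu_mat <- outer(mu * fold, as.numeric(grp == "case")) + outer(mu, as.numeric(grp != "case"))
  cnt <- matrix(rnbinom(length(mu_mat), mu = mu_mat, size = 1 / 0.05), g,
                dimnames = list(paste0("g", 1:g), paste0("s", 1:7)))
  st <- expression_study(cnt, grp, "x", "rnaseq")
  res <- nb_count_de(st)
  y <- edgeR::DGEList(counts = cnt, group = factor(grp, levels = c("control", "case")))
  y <- edgeR::calcNormFactors(y, method = "none")
  design <- stats::model.matrix(~ factor(grp, levels = c("control", "case")))
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  qlf <- edgeR::glmQLFTest(fit)
  expect_gt(cor(res$log2FC, qlf$table$logFC), 0.98)
  expect_gt(cor(-log10(res$p), -log10(qlf$table$PValue), method = "spearman"), 0.9)
})

test_that("degenerate genes are flagged, not fatal", {
  x <- rbind(flat = rep(5, 8), ok = rnorm(8))
  colnames(x) <- paste0("s", 1:8)
  st <- expression_study(x, rep(c("case", "control"), each = 4), "d", "array")
  res <- moderated_t_de(st)
  expect_equal(res$p[res$gene == "flat"], 1)
  expect_equal(res$flag[res$gene == "flat"], "degenerate")

  cnt <- rbind(zero = rep(0L, 6), ok = c(5L, 8L, 6L, 7L, 9L, 4L))
  colnames(cnt) <- paste0("s", 1:6)
  stc <- expression_study(cnt, rep(c("case", "control"), each = 3), "dz", "rnaseq")
  resc <- nb_count_de(stc)
  expect_equal(resc$log2FC[resc$gene == "zero"], 0)
  expect_equal(resc$p[resc$gene == "zero"], 1)
  expect_equal(resc$flag[resc$gene == "zero"], "degenerate")
})

test_that("results are invariant to sample order and direction-consistent", {
  st <- toy_array_study(n_genes = 80, seed = 7)
  perm <- sample(ncol(st$values))
  stp <- expression_study(st$values[, perm], st$group[perm], st$study_id, "array")
  a <- moderated_t_de(st); b <- moderated_t_de(stp)
  expect_equal(a$log2FC, b$log2FC, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  case <- st$group == "case"
  diff <- rowMeans(st$values[, case]) - rowMeans(st$values[, !case])
  nondeg <- a$flag == "ok" & diff != 0
  expect_true(all(sign(a$log2FC[nondeg]) == sign(diff[nondeg])))
})

test_that("BH adjustment matches its definition and validates input", {
  expect_equal(fdr_bh(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)
  expect_error(fdr_bh(c(0.1, NaN)), "NA/NaN")
  expect_error(fdr_bh(c(0.1, 0)), "\\(0, 1\\]")
  # independent step-up oracle on random vectors
  step_up <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:200, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p), step_up(p), tolerance = 1e-12)
  }
})
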