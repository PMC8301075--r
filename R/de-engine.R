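#' Empirical-Bayes moderated t-test for log-intensity studies
#'
#' Two-group differential expression for array (log2 intensity) studies. Per
#' gene, the case-minus-control mean difference is tested with a moderated
#' t-statistic: the pooled residual variance \eqn{s_g^2} (df \eqn{d_g = n-2})
#' is shrunk toward a prior variance \eqn{s_0^2} with prior df \eqn{d_0},
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and \eqn{t = \mathrm{log2FC} / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}} is
#' referred to a t distribution on \eqn{d_0 + d_g} df. The prior
#' \eqn{(d_0, s_0^2)} is estimated by moment matching on \eqn{\log s_g^2}
#' (mean and variance of log variances against their scaled-F expectation);
#' \eqn{d_0} is capped at 1e6, which behaves as the normal-reference
#' (complete-shrinkage) limit.
#'
#' @param study An [expression_study()] with log-intensity values and at
#'   least two samples per group.
#' @param prior_df Optional prior df override: `0` gives the ordinary pooled
#'   two-sample t; `Inf` shrinks every variance fully to \eqn{s_0^2}. By
#'   default the prior is estimated from the data.
#' @return A `de_result` tibble: `study_id`, `gene`, `log2FC`, `statistic`,
#'   `df`, `p`, `n_total`, `flag` (`"ok"` or `"degenerate"` for genes with no
#'   variance in either group, reported with p = 1). The estimated prior is
#'   attached as attribute `prior` (list `d0`, `s0_sq`).
#' @export
moderated_t_de <- function(study, prior_df = NULL) {
  g <- study$group
  n1 <- sum(g == "case"); n2 <- sum(g == "control")
  if (n1 < 2 || n2 < 2)
    abort_data(sprintf("study '%s': each group needs >= 2 samples", study$study_id))
  x <- study$values
  case <- x[, g == "case", drop = FALSE]
  ctrl <- x[, g == "control", drop = FALSE]
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  lfc <- m1 - m2
  ss <- rowSums((case - m1)^2) + rowSums((ctrl - m2)^2)
  d_g <- n1 + n2 - 2
  s2 <- ss / d_g
  degenerate <- s2 <= 0

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2[!degenerate], d_g)
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s0_sq = NA_real_)
  } else if (is.infinite(prior_df)) {
    s0 <- if (any(!degenerate)) exp(mean(log(s2[!degenerate]))) else 1
    prior <- list(d0 = Inf, s0_sq = s0)
  } else {
    s0 <- if (any(!degenerate)) exp(mean(log(s2[!degenerate]))) else 1
    prior <- list(d0 = min(prior_df, 1e6), s0_sq = s0)
  }
  d0 <- prior$d0
  s2_tilde <- if (d0 == 0) s2 else if (is.infinite(d0)) {
    rep(prior$s0_sq, length(s2))
  } else (d0 * prior$s0_sq + d_g * s2) / (d0 + d_g)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  stat <- ifelse(degenerate, 0, lfc / se)
  df_total <- d0 + d_g
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(stat)) else
    2 * pt(-abs(stat), df = df_total)
  p[degenerate] <- 1
  res <- tibble::tibble(
    study_id = study$study_id, gene = rownames(x),
    log2FC = unname(lfc), statistic = unname(stat), df = df_total,
    p = clamp_p(unname(p)), n_total = n1 + n2,
    flag = unname(ifelse(degenerate, "degenerate", "ok"))
  )
  class(res) <- c("de_result", class(res))
  attr(res, "prior") <- prior
  res
}

# Moment matching of (d0, s0^2) on log sample variances: if
# s^2 ~ s0^2 * F(d_g, d0) then
#   E[log s^2] = log s0^2 + digamma(d_g/2) - log(d_g/2)
#                         - digamma(d0/2) + log(d0/2)
#   Var[log s^2] = trigamma(d_g/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, d_g) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(d0 = 1e6, s0_sq = mean(s2)))
  z <- log(s2)
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  target <- stats::var(e) - trigamma(d_g / 2)
  if (is.na(target) || target <= 0) {
    d0 <- 1e6
  } else {
    d0 <- min(2 * trigamma_inverse(target), 1e6)
  }
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(x) = y by Newton iteration on the monotone decreasing
# trigamma; accurate to ~1e-8 over the ranges arising from log-variance
# moments.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Negative-binomial likelihood-ratio test for count studies
#'
#' Two-group differential expression for RNA-seq (integer count) studies.
#' Library sizes are normalized as column-sum ratios to the geometric-mean
#' library. Per gene, a negative-binomial model with log link and library-size
#' offsets is fitted under the null (common mean) and the alternative
#' (group-specific means) by Newton iteration, and the group effect is tested
#' by a likelihood-ratio statistic on \eqn{\chi^2_1}. The NB dispersion is a
#' per-gene moment estimate shrunk toward the all-gene median dispersion;
#' zero dispersion reduces the model to Poisson. log2 fold changes come from
#' normalized group means with a 0.5 pseudo-count.
#'
#' @param study An [expression_study()] with integer counts and at least two
#'   samples per group.
#' @param dispersion_shrink Weight on the median dispersion in the shrunk
#'   per-gene estimate (default 0.8; 1 = common dispersion for all genes).
#' @param dispersion Optional fixed dispersion (scalar or per-gene),
#'   bypassing estimation; `0` gives a Poisson LRT.
#' @return A `de_result` tibble with the same columns as [moderated_t_de()];
#'   `df` is the LRT df (1). All-zero genes are flagged `"degenerate"` with
#'   log2FC 0 and p 1. The shrunk dispersions are attached as attribute
#'   `dispersion`.
#' @export
nb_count_de <- function(study, dispersion_shrink = 0.8, dispersion = NULL) {
  g <- study$group
  n1 <- sum(g == "case"); n2 <- sum(g == "control")
  if (n1 < 2 || n2 < 2)
    abort_data(sprintf("study '%s': each group needs >= 2 samples", study$study_id))
  x <- study$values
  if (!is_integerish_matrix(x))
    abort_data(sprintf("study '%s': counts must be non-negative integers", study$study_id))
  libs <- colSums(x)
  if (any(libs <= 0)) abort_data("every sample must have positive total counts")
  sf <- libs / geometric_mean(libs)

  xn <- sweep(x, 2, sf, "/")
  case <- xn[, g == "case", drop = FALSE]
  ctrl <- xn[, g == "control", drop = FALSE]
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  lfc <- log2(m1 + 0.5) - log2(m2 + 0.5)
  all_zero <- rowSums(x) == 0

  if (is.null(dispersion)) {
    # moment estimator on normalized counts: Var = mu + phi mu^2, pooled
    # within groups (df n - 2), then shrunk toward the all-gene median
    ss <- rowSums((case - m1)^2) + rowSums((ctrl - m2)^2)
    v <- ss / (n1 + n2 - 2)
    m <- (n1 * m1 + n2 * m2) / (n1 + n2)
    phi_raw <- ifelse(m > 0, pmax((v - m) / m^2, 0), 0)
    phi_med <- median(phi_raw[m > 0])
    phi <- dispersion_shrink * phi_med + (1 - dispersion_shrink) * phi_raw
  } else {
    phi <- rep_len(pmax(dispersion, 0), nrow(x))
  }

  ll_null <- nb_profile_loglik(x, sf, phi)
  ll_case <- nb_profile_loglik(x[, g == "case", drop = FALSE], sf[g == "case"], phi)
  ll_ctrl <- nb_profile_loglik(x[, g == "control", drop = FALSE], sf[g == "control"], phi)
  lrt <- pmax(2 * (ll_case + ll_ctrl - ll_null), 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)

  lfc[all_zero] <- 0
  p[all_zero] <- 1
  res <- tibble::tibble(
    study_id = study$study_id, gene = rownames(x),
    log2FC = unname(lfc), statistic = unname(lrt), df = 1,
    p = clamp_p(unname(p)), n_total = n1 + n2,
    flag = unname(ifelse(all_zero, "degenerate", "ok"))
  )
  class(res) <- c("de_result", class(res))
  attr(res, "dispersion") <- phi
  res
}

# Maximized NB log-likelihood of a one-mean model with offsets, per gene.
# Newton iteration on the scalar log-mean, vectorized over genes.
nb_profile_loglik <- function(x, sf, phi) {
  size <- 1 / pmax(phi, 1e-8)
  beta <- log((rowSums(x) + 0.1) / sum(sf))
  for (it in 1:50) {
    mu <- exp(beta) %o% sf
    w <- 1 + phi * mu
    score <- rowSums((x - mu) / w)
    info <- rowSums(mu * (1 + phi * x) / w^2)
    step <- score / pmax(info, 1e-12)
    step <- pmax(pmin(step, 3), -3)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(beta) %o% sf
  rowSums(stats::dnbinom(x, size = size, mu = pmax(mu, 1e-12), log = TRUE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input).
#'
#' @param p Vector of p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
fdr_bh <- function(p) {
  if (any(is.na(p))) abort_data("p-values contain NA/NaN")
  if (any(p <= 0 | p > 1)) abort_data("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' @export
glance.de_result <- function(x, ...) {
  prior <- attr(x, "prior")
  tibble::tibble(
    study_id = x$study_id[1],
    n_genes = nrow(x),
    n_degenerate = sum(x$flag == "degenerate"),
    prior_df = if (!is.null(prior)) prior$d0 else NA_real_,
    prior_var = if (!is.null(prior)) prior$s0_sq else NA_real_,
    median_dispersion = if (!is.null(attr(x, "dispersion"))) median(attr(x, "dispersion")) else NA_real_
  )
}
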