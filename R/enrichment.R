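#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Duplicate members within a line are
#' deduplicated; empty trailing fields are ignored.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set`, `description`, and a list-column
#'   `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("GMT file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(tibble::tibble(set = character(), description = character(),
                          members = list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3)
  if (length(bad))
    abort_data(sprintf("malformed GMT line %d in '%s': fewer than 3 tab-separated fields",
                       bad[1], path))
  tibble::tibble(
    set = vapply(parts, `[[`, "", 1),
    description = vapply(parts, `[[`, "", 2),
    members = lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  )
}

#' Write a gene-set collection to GMT
#'
#' @param collection Tibble with `set`, `description`, `members` (list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set, description, members, ...) {
    paste(c(set, description, members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the dysregulated-gene list overlaps the
#' set more than expected by chance against a background universe. Per set:
#' `size` = members in the universe, `expected` = size x (DEGs / universe),
#' `observed` = members in the DEG list, `ratio` = observed / expected, and
#' an upper-tail hypergeometric p-value
#' \eqn{P(X \ge \mathrm{observed})} with
#' \eqn{X \sim \mathrm{Hypergeom}(N = |\mathrm{universe}|, K =
#' \mathrm{size}, n = |\mathrm{DEG}|)}. Adjusted p-values are BH across the
#' collection; rows are sorted by p ascending.
#'
#' @param deg_genes Character vector of dysregulated genes (subset of
#'   `universe`).
#' @param universe Character vector: the background gene universe.
#' @param collection Gene-set tibble from [read_gmt()] (columns `set`,
#'   `description`, `members`).
#' @param outside How to treat DEG genes absent from the universe:
#'   `"error"` (default) or `"drop"` with a warning.
#' @return An `ora_result` tibble: `set`, `description`, `size`, `expected`,
#'   `observed`, `ratio`, `p`, `p_adjusted`. Universe and list sizes are
#'   attached as attributes `n_universe` and `n_deg`.
#' @export
ora <- function(deg_genes, universe, collection, outside = c("error", "drop")) {
  outside <- match.arg(outside)
  universe <- unique(universe)
  deg_genes <- unique(deg_genes)
  if (!length(universe)) abort_data("the universe must be non-empty")
  stray <- setdiff(deg_genes, universe)
  if (length(stray)) {
    if (outside == "error")
      abort_data(sprintf("%d DEG gene(s) outside the universe (e.g. '%s')",
                         length(stray), stray[1]))
    warn(sprintf("dropping %d DEG gene(s) outside the universe", length(stray)))
    deg_genes <- intersect(deg_genes, universe)
  }
  n_univ <- length(universe)
  n_deg <- length(deg_genes)

  rows <- purrr::pmap(collection, function(set, description, members, ...) {
    in_univ <- intersect(members, universe)
    size <- length(in_univ)
    observed <- length(intersect(in_univ, deg_genes))
    expected <- size * n_deg / n_univ
    tibble::tibble(
      set = set, description = description, size = size,
      expected = expected, observed = observed,
      ratio = if (expected > 0) observed / expected else 0,
      p = if (observed == 0) 1 else
        clamp_p(phyper(observed - 1, size, n_univ - size, n_deg, lower.tail = FALSE))
    )
  })
  res <- dplyr::bind_rows(rows)
  res$p_adjusted <- if (nrow(res)) fdr_bh(res$p) else numeric(0)
  res <- dplyr::arrange(res, .data$p)
  class(res) <- c("ora_result", class(res))
  attr(res, "n_universe") <- n_univ
  attr(res, "n_deg") <- n_deg
  res
}

#' Direction-split over-representation analysis
#'
#' Runs [ora()] separately on the up-regulated, down-regulated, and combined
#' included genes of a meta-analysis, reporting per-set split counts
#' (`n_up_members`, `n_down_members`) alongside; for the combined analysis
#' these two sum to `observed` for every set.
#'
#' @param meta A `meta_result` from [run_meta()].
#' @param collection Gene-set tibble (see [read_gmt()]).
#' @param universe Background universe; by default chosen per
#'   `universe_policy`.
#' @param universe_policy `"annotated"` (default) intersects the genes that
#'   entered the meta-analysis with the genes annotated anywhere in the
#'   collection; `"entered"` uses every gene that entered the meta-analysis.
#' @return A `directional_ora` list with `up`, `down`, `all` (`ora_result`
#'   tibbles) and `genes` (the gene lists used).
#' @export
directional_enrichment <- function(meta, collection, universe = NULL,
                                   universe_policy = c("annotated", "entered")) {
  universe_policy <- match.arg(universe_policy)
  entered <- meta$genes$gene
  if (is.null(universe)) {
    universe <- switch(universe_policy,
      annotated = intersect(entered, unique(unlist(collection$members))),
      entered = entered)
  }
  up <- intersect(meta$genes$gene[meta$genes$direction == "up"], universe)
  down <- intersect(meta$genes$gene[meta$genes$direction == "down"], universe)
  both <- c(up, down)

  add_split <- function(res) {
    res$n_up_members <- vapply(res$set, function(s) {
      length(intersect(intersect(collection$members[[match(s, collection$set)]], universe), up))
    }, 1L, USE.NAMES = FALSE)
    res$n_down_members <- vapply(res$set, function(s) {
      length(intersect(intersect(collection$members[[match(s, collection$set)]], universe), down))
    }, 1L, USE.NAMES = FALSE)
    res
  }

  out <- list(
    up = add_split(ora(up, universe, collection)),
    down = add_split(ora(down, universe, collection)),
    all = add_split(ora(both, universe, collection)),
    genes = list(up = up, down = down, universe = universe)
  )
  class(out) <- "directional_ora"
  out
}

#' @export
print.ora_result <- function(x, n = 10, ...) {
  cat(sprintf("<ora_result> %d sets; universe %d genes, list %d genes\n",
              nrow(x), attr(x, "n_universe"), attr(x, "n_deg")))
  print(tibble::as_tibble(x), n = n)
  invisible(x)
}

#' One-row ORA summary
#'
#' @param x An `ora_result`.
#' @param ... Unused.
#' @return A one-row tibble: universe size, list size, sets tested, sets with
#'   adjusted p below 0.05.
#' @export
glance.ora_result <- function(x, ...) {
  tibble::tibble(
    n_universe = attr(x, "n_universe"), n_deg = attr(x, "n_deg"),
    n_sets = nrow(x), n_significant = sum(x$p_adjusted <= 0.05)
  )
}

#' Format an ORA table for display
#'
#' Full-precision columns rounded only for presentation: `expected` and
#' `ratio` to 2 decimals, p-values in scientific notation.
#'
#' @param x An `ora_result`.
#' @param digits Decimal places for `expected`/`ratio`.
#' @return A tibble of character/rounded display columns.
#' @export
format_ora_table <- function(x, digits = 2) {
  tibble::tibble(
    set = x$set, description = x$description, size = x$size,
    expected = round(x$expected, digits), observed = x$observed,
    ratio = round(x$ratio, digits),
    p = signif(x$p, 5), p_adjusted = signif(x$p_adjusted, 5)
  )
}
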