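#' Pool CpG tables across biological replicates
#'
#' Sums methylated and total counts per CpG (chrom, position) across
#' replicates; CpGs present in only some replicates are carried through.
#'
#' @param tables list of CpG tibbles (`chrom`, `pos0`, `meth`, `total`)
#' @return pooled CpG tibble
#' @export
pool_replicates <- function(tables) {
  if (!length(tables)) stop("empty replicate list", call. = FALSE)
  dplyr::bind_rows(tables) |>
    dplyr::group_by(.data$chrom, .data$pos0) |>
    dplyr::summarise(meth = sum(.data$meth), total = sum(.data$total),
                     .groups = "drop")
}

#' Coverage-weighted region methylation fractions
#'
#' Assigns each CpG to every region containing it under the half-open
#' convention (`start <= pos0 < end`; overlapping regions are allowed and
#' a CpG may count toward several) and returns the coverage-weighted
#' fraction `sum(meth) / sum(total)` per region. Regions without covered
#' CpGs get `NA`.
#'
#' @param cpg pooled CpG tibble (`chrom`, `pos0`, `meth`, `total`)
#' @param regions region tibble (`chrom`, `start`, `end`, `name`, `class`)
#' @param min_coverage minimum per-CpG total for a site to contribute
#'   (default 1)
#' @return tibble with `name`, `class`, `n_cpg`, `meth`, `total`,
#'   `fraction`
#' @export
region_fraction <- function(cpg, regions, min_coverage = 1) {
  regions <- validate_regions(regions)
  cpg <- cpg[cpg$total >= min_coverage, , drop = FALSE]
  out <- regions[, c("name", "class")]
  out$n_cpg <- 0L; out$meth <- 0; out$total <- 0
  for (chr in unique(regions$chrom)) {
    r_idx <- which(regions$chrom == chr)
    c_idx <- which(cpg$chrom == chr)
    if (!length(c_idx)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = cpg$pos0[c_idx] + 1L, width = 1L),
      IRanges::IRanges(start = regions$start[r_idx] + 1L,
                       end = regions$end[r_idx]))
    if (!length(hits)) next
    q <- c_idx[S4Vectors::queryHits(hits)]
    s <- r_idx[S4Vectors::subjectHits(hits)]
    agg_m <- tapply(cpg$meth[q], s, sum)
    agg_t <- tapply(cpg$total[q], s, sum)
    agg_n <- tapply(cpg$meth[q], s, length)
    idx <- as.integer(names(agg_m))
    out$meth[idx] <- out$meth[idx] + as.numeric(agg_m)
    out$total[idx] <- out$total[idx] + as.numeric(agg_t)
    out$n_cpg[idx] <- out$n_cpg[idx] + as.integer(agg_n)
  }
  out$fraction <- ifelse(out$total > 0, out$meth / out$total, NA_real_)
  out
}

#' Differential region methylation between latent and proliferative cells
#'
#' Joins two region-fraction tables on region name/class and calls each
#' region `hypo` when the proliferative fraction exceeds the latent one by
#' more than `min_diff` (strict), `hyper` for the reverse, `unchanged`
#' otherwise and `NA` when either fraction is undefined. The `sealed`
#' flag marks regions with proliferative methylation strictly above
#' `sealed_threshold`.
#'
#' @param rf_latent,rf_proliferative [region_fraction()] tables sharing
#'   region ids
#' @param min_diff methylation-difference threshold (default 0.10)
#' @param sealed_threshold proliferative-methylation threshold for the
#'   sealed flag (default 0.70)
#' @return a `region_meth` tibble: `name`, `class`, `meth_lat`,
#'   `total_lat`, `meth_pro`, `total_pro`, `frac_lat`, `frac_pro`, `diff`
#'   (`frac_lat - frac_pro`), `call`, `sealed`
#' @export
differential_regions <- function(rf_latent, rf_proliferative,
                                 min_diff = 0.10, sealed_threshold = 0.70) {
  tab <- dplyr::inner_join(
    dplyr::rename(rf_latent, meth_lat = "meth", total_lat = "total",
                  frac_lat = "fraction", n_cpg_lat = "n_cpg"),
    dplyr::rename(rf_proliferative, meth_pro = "meth", total_pro = "total",
                  frac_pro = "fraction", n_cpg_pro = "n_cpg"),
    by = c("name", "class"))
  tab$diff <- tab$frac_lat - tab$frac_pro
  tab$call <- dplyr::case_when(
    is.na(tab$diff) ~ NA_character_,
    tab$frac_pro - tab$frac_lat > min_diff ~ "hypo",
    tab$frac_lat - tab$frac_pro > min_diff ~ "hyper",
    .default = "unchanged")
  tab$sealed <- sealed_flag(tab$frac_pro, threshold = sealed_threshold)
  out <- tab[, c("name", "class", "meth_lat", "total_lat", "meth_pro",
                 "total_pro", "frac_lat", "frac_pro", "diff", "call",
                 "sealed")]
  class(out) <- c("region_meth", class(out))
  out
}

#' Sealed-region flag
#'
#' A region is epigenetically sealed when its methylation fraction in
#' proliferative cells strictly exceeds the threshold (default 70%).
#'
#' @param frac_pro proliferative methylation fraction(s)
#' @param threshold strict threshold (default 0.70)
#' @return logical vector (`NA` propagates)
#' @export
sealed_flag <- function(frac_pro, threshold = 0.70) {
  frac_pro > threshold
}

#' Gene-set over-representation of hypomethylated genes
#'
#' One-sided hypergeometric test of the overlap between a query gene set
#' (e.g. genes with >10% hypomethylation) and each term set, within a
#' fixed gene universe, with BH adjustment across terms.
#'
#' @param query character vector of query genes (subset of `universe`)
#' @param term_sets named list of term gene sets (intersected with the
#'   universe)
#' @param universe character vector of all eligible genes
#' @return tibble with `term`, `n_term`, `n_query`, `overlap`, `p`, `padj`
#' @export
overlap_enrichment <- function(query, term_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  query <- intersect(unique(query), universe)
  rows <- purrr::imap(term_sets, function(genes, term) {
    term_genes <- intersect(unique(genes), universe)
    k <- length(intersect(query, term_genes))
    # P(X >= k) for X ~ Hypergeom(|term|, |universe|-|term|, |query|)
    p <- if (!length(query) || !length(term_genes)) 1 else
      stats::phyper(k - 1, length(term_genes),
                    length(universe) - length(term_genes), length(query),
                    lower.tail = FALSE)
    tibble::tibble(term = term, n_term = length(term_genes),
                   n_query = length(query), overlap = k, p = p)
  })
  out <- purrr::list_rbind(rows)
  out$padj <- bh_adjust(out$p)
  out
}

#' Plot latent vs proliferative region methylation
#'
#' Scatter of per-region methylation fractions with the identity line and
#' dotted lines at +/- `min_diff`, colored by call.
#'
#' @param object a `region_meth` tibble from [differential_regions()]
#' @param min_diff difference threshold drawn as dotted guides
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.region_meth <- function(object, min_diff = 0.10, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frac_pro,
                                       y = .data$frac_lat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_abline(slope = 1, intercept = c(-min_diff, min_diff),
                         colour = "red", linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$call), alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "methylation fraction, proliferative TCs",
                  y = "methylation fraction, latent TCs", colour = "call") +
    ggplot2::theme_minimal()
}
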