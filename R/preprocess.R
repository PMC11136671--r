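#' Quality-control filtering of cells
#'
#' Applies the study's QC rules, with strict inequalities exactly as
#' stated. For the EC dataset, a cell is *excluded* when its mitochondrial
#' transcript fraction is > `max_mito` **or** it has < `min_genes` detected
#' genes (detected = raw count > 0). For the TC dataset, a cell is
#' *retained* only when its mitochondrial fraction is < `max_mito` **and**
#' it has > `min_genes` detected genes; a cell sitting exactly on a
#' threshold is therefore kept under the EC rule but removed under the TC
#' rule.
#'
#' @param x a raw [cell_matrix()] with at least one mitochondrial gene
#' @param cell_class `"ec"` or `"tc"`
#' @param max_mito mitochondrial-fraction threshold (default 0.05)
#' @param min_genes detected-gene threshold; defaults to 1000 for ECs and
#'   2500 for TCs
#' @return list with `matrix` (filtered `cell_matrix`) and `report`
#'   (tibble: `cell_id`, `n_detected`, `mito_fraction`, `kept`, `reason`)
#' @export
qc_filter <- function(x, cell_class = c("ec", "tc"), max_mito = 0.05,
                      min_genes = NULL) {
  cell_class <- match.arg(cell_class)
  stopifnot(inherits(x, "cell_matrix"))
  if (!any(x$gene_meta$is_mito)) {
    stop("no mitochondrial genes flagged; mitochondrial fraction undefined",
         call. = FALSE)
  }
  if (is.null(min_genes)) min_genes <- if (cell_class == "ec") 1000L else 2500L
  st <- cell_stats(x)
  if (cell_class == "ec") {
    fail_mito <- st$mito_fraction > max_mito
    fail_genes <- st$n_detected < min_genes
  } else {
    fail_mito <- !(st$mito_fraction < max_mito)
    fail_genes <- !(st$n_detected > min_genes)
  }
  fail_mito[is.na(fail_mito)] <- TRUE
  kept <- !(fail_mito | fail_genes)
  reason <- dplyr::case_when(
    fail_mito & fail_genes ~ "mito_fraction;n_detected",
    fail_mito ~ "mito_fraction",
    fail_genes ~ "n_detected",
    .default = NA_character_)
  report <- tibble::tibble(cell_id = st$cell_id, n_detected = st$n_detected,
                           mito_fraction = st$mito_fraction, kept = kept,
                           reason = reason)
  list(matrix = subset_cells(x, cells = which(kept)), report = report)
}

#' Housekeeping-panel normalization
#'
#' Normalizes each cell to the mean raw expression of a housekeeping gene
#' panel, scales by `scale_factor` (default 10,000) and log10-transforms
#' with a pseudocount of 1:
#' `value(g, c) = log10(1 + scale_factor * x(g, c) / mean_panel(c))`.
#' The panel mean is taken over all panel genes present in the matrix,
#' including zeros; panel genes missing from the matrix are dropped with a
#' warning. The transform is invariant to per-cell depth scaling.
#'
#' @param x a raw [cell_matrix()]
#' @param panel character vector of housekeeping gene ids
#'   (default [housekeeping_panel()])
#' @param scale_factor scale applied to the panel-mean ratio
#' @return a `normalized_matrix` (a [cell_matrix()] subclass); the
#'   normalization record is stored in `attr(, "normalization")`
#' @export
hk_normalize <- function(x, panel = housekeeping_panel(), scale_factor = 1e4) {
  stopifnot(inherits(x, "cell_matrix"))
  present <- intersect(panel, rownames(x$counts))
  if (!length(present)) stop("no housekeeping panel gene present", call. = FALSE)
  if (length(present) < length(panel)) {
    warning("housekeeping panel genes missing from matrix: ",
            paste(setdiff(panel, present), collapse = ", "), call. = FALSE)
  }
  panel_mean <- colMeans(x$counts[present, , drop = FALSE])
  zero <- panel_mean == 0
  if (any(zero)) {
    stop("housekeeping panel mean is 0 for cell(s): ",
         paste(utils::head(colnames(x$counts)[zero], 5), collapse = ", "),
         call. = FALSE)
  }
  norm <- log10(1 + scale_factor * sweep(x$counts, 2, panel_mean, "/"))
  out <- cell_matrix(norm, cell_meta = x$cell_meta,
                     mito_prefix = attr(x, "mito_prefix"), normalized = TRUE)
  attr(out, "normalization") <- list(panel = present,
                                     scale_factor = scale_factor,
                                     log_base = 10, pseudocount = 1)
  out
}

#' Control-binned gene-module score
#'
#' Scores each cell for a gene program as the mean normalized expression of
#' the program's genes minus the mean over a pooled control list. Genes are
#' binned into `n_bins` of near-equal size by their mean expression across
#' cells; for every program gene, `n_ctrl` control genes are drawn
#' uniformly without replacement from that gene's bin (with a fixed seed),
#' and the controls are pooled *with repeats* across program genes.
#'
#' @param x a `normalized_matrix` from [hk_normalize()]
#' @param gene_set character vector of program genes; members absent from
#'   the matrix are ignored (an error if none remain)
#' @param n_bins number of expression bins (default 24; reduced with a
#'   warning when the matrix has fewer genes than bins)
#' @param n_ctrl controls drawn per program gene (default 100; capped at
#'   the bin size)
#' @param seed RNG seed for the control draw
#' @return tibble with `cell_id` and `score`
#' @export
module_score <- function(x, gene_set, n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(inherits(x, "cell_matrix"))
  m <- x$counts
  genes <- intersect(gene_set, rownames(m))
  if (!length(genes)) {
    stop("no gene of the set is present in the matrix", call. = FALSE)
  }
  if (nrow(m) < n_bins) {
    warning("fewer genes (", nrow(m), ") than bins (", n_bins,
            "); reducing bin count", call. = FALSE)
    n_bins <- nrow(m)
  }
  gene_means <- rowMeans(m)
  bin <- .bin_by_mean(gene_means, n_bins)
  set.seed(seed)
  ctrl <- unlist(lapply(genes, function(g) {
    pool <- names(bin)[bin == bin[[g]]]
    sample(pool, size = min(n_ctrl, length(pool)), replace = FALSE)
  }))
  score <- colMeans(m[genes, , drop = FALSE]) -
    colMeans(m[ctrl, , drop = FALSE])
  tibble::tibble(cell_id = colnames(m), score = unname(score))
}

# Equal-count bins on the rank of gene means (ties broken by order).
.bin_by_mean <- function(means, n_bins) {
  r <- rank(means, ties.method = "first")
  bin <- ceiling(r / (length(means) / n_bins))
  stats::setNames(pmin(bin, n_bins), names(means))
}

#' Score several gene programs at once
#'
#' @param x a `normalized_matrix`
#' @param gene_sets named list of program gene vectors
#' @inheritParams module_score
#' @return tibble with `cell_id` and one score column per program
#' @export
score_modules <- function(x, gene_sets, n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  out <- tibble::tibble(cell_id = colnames(x$counts))
  for (nm in names(gene_sets)) {
    out[[nm]] <- module_score(x, gene_sets[[nm]], n_bins = n_bins,
                              n_ctrl = n_ctrl, seed = seed)$score
  }
  out
}

#' Remove contaminating cells by marker detection
#'
#' A cell is removed when it has detected expression (value > 0) of at
#' least `min_positive_genes` members of any single contaminant marker set
#' (for example immune or stromal/mural markers).
#'
#' @param x a [cell_matrix()] (raw or normalized; detection is value > 0)
#' @param sets named list of contaminant marker sets
#'   (default [contaminant_sets()])
#' @param min_positive_genes detection threshold per set (default 2)
#' @return the filtered `cell_matrix`, with the removal table in
#'   `attr(, "contaminant_report")`
#' @export
remove_contaminants <- function(x, sets = contaminant_sets(),
                                min_positive_genes = 2) {
  stopifnot(inherits(x, "cell_matrix"))
  if (!length(sets)) return(x)
  if (any(!lengths(sets))) stop("contaminant sets must be non-empty", call. = FALSE)
  hits <- vapply(sets, function(s) {
    g <- intersect(s, rownames(x$counts))
    if (!length(g)) return(rep(FALSE, ncol(x$counts)))
    colSums(x$counts[g, , drop = FALSE] > 0) >= min_positive_genes
  }, logical(ncol(x$counts)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = 1)
  flagged <- rowSums(hits) > 0
  out <- subset_cells(x, cells = which(!flagged))
  attr(out, "contaminant_report") <- tibble::tibble(
    cell_id = colnames(x$counts), removed = flagged)
  out
}
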