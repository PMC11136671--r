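#' Derive condition-specific marker panels from all-vs-all comparisons
#'
#' Given differential-expression results for every unordered pair among a
#' roster of sample types, a gene becomes a marker of type X when it is
#' significantly upregulated for X (p < `alpha` and log2 fold change >
#' `lfc_min`) in at least `min_support` of X's comparisons against the
#' other types, and is never significantly upregulated for any other type
#' in any comparison (specificity). Panels are disjoint across types by
#' construction.
#'
#' @param pairwise tibble of per-pair DGE results with columns `type_a`,
#'   `type_b`, `gene`, `log2fc` (a-over-b orientation) and `p`
#' @param types the full sample-type roster; defaults to the types present
#' @param alpha,lfc_min upregulation thresholds (defaults 0.01 and 0.5)
#' @param min_support minimum supporting comparisons (default 3)
#' @return a `marker_panel` tibble: `condition`, `gene`, `n_support`
#' @export
derive_condition_markers <- function(pairwise, types = NULL, alpha = 0.01,
                                     lfc_min = 0.5, min_support = 3) {
  need <- c("type_a", "type_b", "gene", "log2fc", "p")
  stopifnot(all(need %in% names(pairwise)))
  if (is.null(types)) types <- sort(unique(c(pairwise$type_a, pairwise$type_b)))
  have <- unique(paste(pmin(pairwise$type_a, pairwise$type_b),
                       pmax(pairwise$type_a, pairwise$type_b)))
  want <- utils::combn(sort(types), 2, paste, collapse = " ")
  missing <- setdiff(want, have)
  if (length(missing)) {
    stop("missing pairwise table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  # one "up" record per (type, gene, opponent) where the type is the
  # significantly higher side of the comparison
  up <- dplyr::bind_rows(
    pairwise |>
      dplyr::filter(.data$p < alpha, .data$log2fc > lfc_min) |>
      dplyr::transmute(type = .data$type_a, opponent = .data$type_b,
                       gene = .data$gene),
    pairwise |>
      dplyr::filter(.data$p < alpha, .data$log2fc < -lfc_min) |>
      dplyr::transmute(type = .data$type_b, opponent = .data$type_a,
                       gene = .data$gene)) |>
    dplyr::distinct()
  support <- up |> dplyr::count(.data$type, .data$gene, name = "n_support")
  n_types_up <- up |>
    dplyr::distinct(.data$gene, .data$type) |>
    dplyr::count(.data$gene, name = "n_types_up")
  panel <- support |>
    dplyr::left_join(n_types_up, by = "gene") |>
    dplyr::filter(.data$n_support >= min_support, .data$n_types_up == 1) |>
    dplyr::transmute(condition = .data$type, gene = .data$gene,
                     n_support = .data$n_support) |>
    dplyr::arrange(.data$condition, .data$gene)
  class(panel) <- c("marker_panel", class(panel))
  panel
}

#' Derive stable aCap/gCap marker panels across the timeline
#'
#' A gene enters a subtype's panel when it is significantly upregulated in
#' that subtype versus the other (Wilcoxon rank-sum on normalized
#' expression, p < `alpha`, log2 fold change > `lfc_min`) at *every* time
#' point, and is detected in at least `min_pct` of the subtype's cells at
#' every time point — i.e. robust, temporally stable markers suitable for
#' bulk deconvolution.
#'
#' @param x a `normalized_matrix` whose `cell_meta$time_point` is set
#' @param labels tibble with `cell_id` and `label` (values `"aCap"`,
#'   `"gCap"`; other labels are ignored)
#' @param alpha,lfc_min,min_pct thresholds (defaults 0.01, 0.5, 0.25)
#' @return list with character vectors `aCap` and `gCap`
#' @export
derive_stable_subtype_panels <- function(x, labels, alpha = 0.01,
                                         lfc_min = 0.5, min_pct = 0.25) {
  stopifnot(inherits(x, "cell_matrix"))
  meta <- dplyr::inner_join(x$cell_meta, labels, by = "cell_id")
  tps <- sort(unique(meta$time_point))
  if (!length(tps)) stop("no labeled cells with a time point", call. = FALSE)
  per_tp <- lapply(tps, function(tp) {
    a_cells <- meta$cell_id[meta$time_point == tp & meta$label == "aCap"]
    g_cells <- meta$cell_id[meta$time_point == tp & meta$label == "gCap"]
    if (!length(a_cells) || !length(g_cells)) {
      stop("time point ", tp, " lacks one of the subtypes", call. = FALSE)
    }
    wilcoxon_dge(x$counts[, a_cells, drop = FALSE],
                 x$counts[, g_cells, drop = FALSE],
                 alpha = alpha, lfc_min = lfc_min)
  })
  up_a <- lapply(per_tp, function(d) {
    d$gene[d$p < alpha & d$log2fc > lfc_min & d$pct_a >= min_pct]
  })
  up_g <- lapply(per_tp, function(d) {
    d$gene[d$p < alpha & d$log2fc < -lfc_min & d$pct_b >= min_pct]
  })
  list(aCap = sort(Reduce(intersect, up_a)),
       gCap = sort(Reduce(intersect, up_g)))
}
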