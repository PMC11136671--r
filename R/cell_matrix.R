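#' Genes-by-cells count container
#'
#' A `cell_matrix` bundles a genes x cells matrix with per-gene and per-cell
#' metadata. Raw objects carry non-negative integer counts; normalized
#' objects (see [hk_normalize()]) carry non-negative reals plus a
#' normalization record. Gene identifiers are treated as opaque strings; a
#' per-gene mitochondrial flag is derived from a configurable prefix because
#' annotation-level mitochondrial gene lists are organism- and
#' assembly-specific.
#'
#' @param counts numeric matrix, genes in rows (unique rownames required),
#'   cells in columns. Raw mode requires non-negative integers.
#' @param cell_meta data frame with one row per cell. A `cell_id` column is
#'   matched against `colnames(counts)`; missing columns among `replicate`,
#'   `time_point`, `gate`, `truth_label` are filled with `NA`.
#' @param mito_prefix case-insensitive gene-id prefix marking mitochondrial
#'   genes (default `"mt-"`).
#' @param normalized logical; `FALSE` (default) enforces integer counts.
#'
#' @return An object of class `cell_matrix`: a list with elements `counts`
#'   (matrix), `gene_meta` (tibble: `gene_id`, `is_mito`), `cell_meta`
#'   (tibble: `cell_id`, `replicate`, `time_point`, `gate`, `truth_label`).
#' @export
cell_matrix <- function(counts, cell_meta = NULL, mito_prefix = "mt-",
                        normalized = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("`counts` must have gene identifiers as rownames", call. = FALSE)
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("gene identifiers must be unique", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("cell identifiers must be unique", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  if (!normalized && ncol(counts) > 0 && any(counts != round(counts))) {
    stop("raw counts must be integers; use `normalized = TRUE` for reals",
         call. = FALSE)
  }

  is_mito <- startsWith(tolower(rownames(counts)), tolower(mito_prefix))
  gene_meta <- tibble::tibble(gene_id = rownames(counts), is_mito = is_mito)

  cell_meta <- .complete_cell_meta(cell_meta, colnames(counts))

  structure(
    list(counts = counts, gene_meta = gene_meta, cell_meta = cell_meta),
    mito_prefix = mito_prefix,
    class = if (normalized) c("normalized_matrix", "cell_matrix") else "cell_matrix"
  )
}

.complete_cell_meta <- function(cell_meta, cell_ids) {
  std_cols <- c("replicate", "time_point", "gate", "truth_label")
  if (is.null(cell_meta)) {
    cell_meta <- tibble::tibble(cell_id = cell_ids)
  } else {
    cell_meta <- tibble::as_tibble(cell_meta)
    if (!"cell_id" %in% names(cell_meta)) {
      stop("`cell_meta` needs a `cell_id` column", call. = FALSE)
    }
    if (nrow(cell_meta) != length(cell_ids)) {
      stop("`cell_meta` must have one row per matrix column (",
           length(cell_ids), " cells, got ", nrow(cell_meta), " rows)",
           call. = FALSE)
    }
    if (!setequal(cell_meta$cell_id, cell_ids)) {
      stop("`cell_meta$cell_id` does not match matrix column names",
           call. = FALSE)
    }
    cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  }
  for (col in std_cols) {
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- NA_character_
  }
  dplyr::relocate(cell_meta, "cell_id", dplyr::all_of(std_cols))
}

#' @export
print.cell_matrix <- function(x, ...) {
  kind <- if (inherits(x, "normalized_matrix")) "normalized" else "raw counts"
  cat(sprintf("<cell_matrix> %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts), kind))
  cat(sprintf("  mitochondrial genes: %d\n", sum(x$gene_meta$is_mito)))
  gates <- unique(stats::na.omit(x$cell_meta$gate))
  if (length(gates)) cat("  gates: ", paste(gates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subset a cell matrix by genes and/or cells
#'
#' @param x a [cell_matrix()]
#' @param genes,cells character identifiers or logical/integer index vectors;
#'   `NULL` keeps everything.
#' @return a `cell_matrix` of the same kind with metadata subset in step.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else cells
  out <- x
  out$counts <- x$counts[gi, ci, drop = FALSE]
  out$gene_meta <- x$gene_meta[match(rownames(out$counts), x$gene_meta$gene_id), ]
  out$cell_meta <- x$cell_meta[match(colnames(out$counts), x$cell_meta$cell_id), ]
  out
}

#' Per-cell summary statistics
#'
#' Detected genes (raw value > 0), total counts and mitochondrial fraction
#' per cell, as used by the QC rules.
#'
#' @param x a [cell_matrix()]
#' @return tibble with columns `cell_id`, `n_detected`, `total_counts`,
#'   `mito_fraction`.
#' @export
cell_stats <- function(x) {
  stopifnot(inherits(x, "cell_matrix"))
  totals <- colSums(x$counts)
  mito <- x$gene_meta$is_mito
  mito_counts <- if (any(mito)) colSums(x$counts[mito, , drop = FALSE]) else
    rep(NA_real_, ncol(x$counts))
  tibble::tibble(
    cell_id = colnames(x$counts) %||% character(0),
    n_detected = unname(colSums(x$counts > 0)),
    total_counts = unname(totals),
    mito_fraction = unname(ifelse(totals > 0, mito_counts / totals, NA_real_))
  )
}
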