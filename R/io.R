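#' Read a genes-by-cells count matrix
#'
#' Supports the MatrixMarket triplet layout (a directory holding
#' `matrix.mtx`, `features.tsv`, `barcodes.tsv`) and a dense TSV (genes in
#' rows, first column gene id, remaining columns cells). Omitted entries in
#' the sparse triplet are zeros.
#'
#' @param path directory (mtx triplet) or file (dense TSV)
#' @param format `"auto"` picks by whether `path` is a directory.
#' @param cell_meta optional per-cell metadata, see [cell_matrix()]
#' @param mito_prefix mitochondrial gene-id prefix (default `"mt-"`)
#' @param normalized set `TRUE` to accept non-integer values
#' @return a [cell_matrix()]
#' @export
read_cell_matrix <- function(path, format = c("auto", "mtx", "dense"),
                             cell_meta = NULL, mito_prefix = "mt-",
                             normalized = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "mtx" else "dense"
  if (format == "mtx") {
    mfile <- file.path(path, "matrix.mtx")
    ffile <- file.path(path, "features.tsv")
    bfile <- file.path(path, "barcodes.tsv")
    for (f in c(mfile, ffile, bfile)) {
      if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(mfile))
    features <- readr::read_tsv(ffile, col_names = FALSE, show_col_types = FALSE)
    barcodes <- readr::read_tsv(bfile, col_names = FALSE, show_col_types = FALSE)
    if (nrow(features) != nrow(m)) {
      stop(sprintf("feature list length (%d) does not match matrix rows (%d)",
                   nrow(features), nrow(m)), call. = FALSE)
    }
    if (nrow(barcodes) != ncol(m)) {
      stop(sprintf("barcode list length (%d) does not match matrix columns (%d)",
                   nrow(barcodes), ncol(m)), call. = FALSE)
    }
    rownames(m) <- features[[1]]
    colnames(m) <- barcodes[[1]]
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
  }
  cell_matrix(m, cell_meta = cell_meta, mito_prefix = mito_prefix,
              normalized = normalized)
}

#' Write a cell matrix
#'
#' @param x a [cell_matrix()]
#' @param path directory (`"mtx"`) or file (`"dense"`) to write
#' @param format output layout
#' @return `path`, invisibly
#' @export
write_cell_matrix <- function(x, path, format = c("mtx", "dense")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "cell_matrix"))
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble::tibble(x = rownames(x$counts)),
                     file.path(path, "features.tsv"), col_names = FALSE)
    readr::write_tsv(tibble::tibble(x = colnames(x$counts)),
                     file.path(path, "barcodes.tsv"), col_names = FALSE)
  } else {
    tab <- tibble::as_tibble(x$counts, rownames = "gene_id")
    readr::write_tsv(tab, path)
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a line are dropped with a warning; order is kept.
#'
#' @param path GMT file
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(list(), character()))
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >=1 gene",
                   i, length(fields)), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("set '%s': dropped %d duplicate gene(s)",
                      fields[[1]], sum(duplicated(genes))), call. = FALSE)
      genes <- unique(genes)
    }
    stats::setNames(list(genes), fields[[1]])
  })
  out <- unlist(sets, recursive = FALSE)
  if (anyDuplicated(names(out))) {
    stop("duplicate set names in GMT file", call. = FALSE)
  }
  out
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors
#' @param path output file
#' @param description description field written for every set
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Bismark coverage file
#'
#' Columns: chrom, start, end, methylation percentage, methylated count,
#' unmethylated count, with 1-based inclusive positions. Positions are
#' converted to the package's internal 0-based convention (`pos0`); a
#' methylation percentage inconsistent with the counts beyond rounding
#' raises a warning.
#'
#' @param path coverage file (TSV, no header)
#' @return tibble with columns `chrom`, `pos0`, `meth`, `total`
#' @export
read_bismark_cov <- function(path) {
  tab <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "pct", "meth", "unmeth"),
    col_types = "ciidii")
  if (any(tab$meth < 0 | tab$unmeth < 0)) {
    stop("negative methylation counts in ", path, call. = FALSE)
  }
  total <- tab$meth + tab$unmeth
  implied <- ifelse(total > 0, 100 * tab$meth / total, 0)
  bad <- total > 0 & abs(implied - tab$pct) > 0.51
  if (any(bad)) {
    warning(sum(bad), " row(s) with methylation % inconsistent with counts",
            call. = FALSE)
  }
  tibble::tibble(chrom = tab$chrom, pos0 = tab$start - 1L,
                 meth = tab$meth, total = total)
}

#' Write a CpG table as a Bismark coverage file
#'
#' Inverse of [read_bismark_cov()]: internal 0-based positions are written
#' back as 1-based inclusive single-base intervals.
#'
#' @param cpg tibble with `chrom`, `pos0`, `meth`, `total`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bismark_cov <- function(cpg, path) {
  unmeth <- cpg$total - cpg$meth
  pct <- ifelse(cpg$total > 0, 100 * cpg$meth / cpg$total, 0)
  readr::write_tsv(
    tibble::tibble(chrom = cpg$chrom, start = cpg$pos0 + 1L,
                   end = cpg$pos0 + 1L, pct = pct, meth = cpg$meth,
                   unmeth = unmeth),
    path, col_names = FALSE)
  invisible(path)
}

#' Read genomic regions from a BED-like file
#'
#' Coordinates are taken as already 0-based half-open (BED convention).
#' Expected columns: chrom, start, end, name and optionally a region class
#' (`promoter`, `gene_body` or `regulatory_element`).
#'
#' @param path BED file (TSV, no header)
#' @param class region class assigned when the file has no fifth column
#' @return tibble with `chrom`, `start`, `end`, `name`, `class`
#' @export
read_regions_bed <- function(path, class = "gene_body") {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 4) stop("BED region file needs chrom,start,end,name", call. = FALSE)
  out <- tibble::tibble(
    chrom = as.character(tab[[1]]), start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]]), name = as.character(tab[[4]]),
    class = if (ncol(tab) >= 5) as.character(tab[[5]]) else class)
  validate_regions(out)
}

#' Validate a region table
#'
#' Checks the half-open convention (`start < end`) and name uniqueness
#' within each region class.
#'
#' @param regions tibble with `chrom`, `start`, `end`, `name`, `class`
#' @return the validated tibble
#' @export
validate_regions <- function(regions) {
  stopifnot(all(c("chrom", "start", "end", "name", "class") %in% names(regions)))
  if (any(regions$start >= regions$end)) {
    stop("regions must satisfy start < end (0-based half-open)", call. = FALSE)
  }
  dup <- regions |>
    dplyr::count(.data$class, .data$name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate region names within a class: ",
         paste(dup$name, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(regions)
}

#' Read a ligand-receptor partner table
#'
#' Flat two-partner table in the style of CellPhoneDB exports, with columns
#' `partner_a`, `partner_b`, `role_a`, `role_b`; roles must be `ligand` or
#' `receptor`. Duplicated rows are stored once.
#'
#' @param path TSV with a header
#' @return tibble with the four columns above
#' @export
read_interaction_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  validate_interactions(tab)
}

#' Validate a ligand-receptor partner table
#' @param tab data frame with `partner_a`, `partner_b`, `role_a`, `role_b`
#' @return deduplicated tibble
#' @export
validate_interactions <- function(tab) {
  need <- c("partner_a", "partner_b", "role_a", "role_b")
  if (!all(need %in% names(tab))) {
    stop("interaction table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  roles <- c(tab$role_a, tab$role_b)
  bad <- setdiff(unique(roles), c("ligand", "receptor"))
  if (length(bad)) {
    stop("unknown role token(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(tibble::as_tibble(tab))
}

#' Look up interaction partners of a gene
#'
#' Symmetric lookup: the gene may appear on either side of the table.
#'
#' @param db validated interaction table
#' @param gene gene identifier
#' @return tibble with `partner` and `partner_role` for each match
#' @export
interaction_partners <- function(db, gene) {
  a <- db |> dplyr::filter(.data$partner_a == gene) |>
    dplyr::transmute(partner = .data$partner_b, partner_role = .data$role_b)
  b <- db |> dplyr::filter(.data$partner_b == gene) |>
    dplyr::transmute(partner = .data$partner_a, partner_role = .data$role_a)
  dplyr::distinct(dplyr::bind_rows(a, b))
}

#' Pipeline configuration with study defaults
#'
#' All tunable thresholds of the pipeline in one place, each at the study's
#' stated value where one exists; the remainder are package defaults
#' documented in the methods vignette. The object serializes to and from
#' YAML so a run is reproducible from a single plain-text file.
#'
#' @param ... name-value overrides of the defaults
#' @return named list of parameters, class `niche_config`
#' @export
niche_config <- function(...) {
  cfg <- list(
    seed = 0L,
    mito_prefix = "mt-",
    max_mito_fraction = 0.05,
    min_genes_ec = 1000L,
    min_genes_tc = 2500L,
    hk_scale_factor = 1e4,
    score_n_bins = 24L,
    score_n_ctrl = 100L,
    contaminant_min_positive = 2L,
    ec_large_vessel_min = 1,
    ec_cycling_min = 0.5,
    ec_acap_min = 0,
    ec_gcap_max_for_acap = 0,
    ec_acap_max_for_gcap = 0,
    ec_gcap_min = -0.5,
    latent_score_max = -1,
    proliferative_score_min = 0,
    dge_alpha = 0.01,
    dge_lfc_min = 0.5,
    nb_alpha = 0.05,
    marker_min_support = 3L,
    marker_min_pct = 0.25,
    partner_min_pct = 0.10,
    meth_min_diff = 0.10,
    meth_sealed_threshold = 0.70,
    meth_min_coverage = 1L,
    array_offset = 100
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("niche_config", "list"))
}

#' @rdname niche_config
#' @param cfg a `niche_config`
#' @param path YAML file
#' @export
write_niche_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname niche_config
#' @export
read_niche_config <- function(path) {
  do.call(niche_config, yaml::read_yaml(path))
}

#' Default housekeeping normalization panel
#'
#' The stably expressed reference genes used for per-cell normalization.
#' @return character vector of gene symbols
#' @export
housekeeping_panel <- function() {
  c("Actb", "Gapdh", "Tubb5", "Ppia", "Ywhaz", "B2m", "Pgk1", "Tbo",
    "Arbp", "Gusb", "Hprt1")
}

#' Default contaminant marker sets
#'
#' Immune and stromal/mural marker genes used to flag non-endothelial,
#' non-tumor contaminating cells.
#' @return named list with elements `immune` and `stromal`
#' @export
contaminant_sets <- function() {
  list(
    immune = c("Ptprc", "Itgam", "Itgax", "Adgre1", "Cd3e", "Cd19", "Cd56"),
    stromal = c("Pdgfrb", "Des", "Myh11", "Col1a2", "Pdgfra", "Cspg4",
                "Pdpn", "Acta2")
  )
}
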