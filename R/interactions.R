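#' Dual pseudobulk comparisons for the trajectory screen
#'
#' Runs the two tumor-cell comparisons of the ligand-receptor screen on
#' gate-level pseudobulks with the NB-Wald engine: extravascular vs
#' intravascular, and latent vs proliferative. Cell-cycle set genes can be
#' excluded from the latent comparison's gene universe (the package's
#' substitute for cell-cycle regression).
#'
#' @param pb a [make_pseudobulk()] object keyed by replicate and gate
#' @param gate_col metadata column with the gate labels
#' @param exclude_latent_genes genes removed from the latent-vs-
#'   proliferative universe (typically the S and G2M sets)
#' @param alpha BH-adjusted significance level passed to [nb_wald_dge()]
#' @param lfc_min absolute log2 fold-change threshold for the flags
#' @return list with `dge_tables` (named list `extra_vs_intra`,
#'   `latent_vs_prolif`)
#' @export
dual_dge <- function(pb, gate_col = "gate", exclude_latent_genes = NULL,
                     alpha = 0.05, lfc_min = 0.5) {
  gates <- unique(pb$sample_meta[[gate_col]])
  need <- c("intravascular", "extravascular", "latent", "proliferative")
  missing <- setdiff(need, gates)
  if (length(missing)) {
    stop("gate(s) absent from pseudobulk: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- nb_wald_dge(pb, contrast = c("extravascular", "intravascular"),
                       group_col = gate_col, alpha = alpha, lfc_min = lfc_min)
  pb_lat <- pb
  if (length(exclude_latent_genes)) {
    keep <- !rownames(pb$counts) %in% exclude_latent_genes
    pb_lat$counts <- pb$counts[keep, , drop = FALSE]
  }
  latent <- nb_wald_dge(pb_lat, contrast = c("latent", "proliferative"),
                        group_col = gate_col, alpha = alpha, lfc_min = lfc_min)
  list(extra_vs_intra = extra, latent_vs_prolif = latent)
}

#' Map differentially expressed genes onto a partner database
#'
#' Keeps the genes that are significant in at least one of the two
#' comparisons and that appear as a partner in the interaction table, and
#' annotates each with its role and partner list. Genes absent from one
#' comparison's universe are dropped with a warning, so both fold changes
#' are always defined.
#'
#' @param dge_tables list from [dual_dge()]
#' @param db validated interaction table ([read_interaction_table()])
#' @return candidate tibble: `gene`, `role`, `partners` (list-column),
#'   `lfc_extra_vs_intra`, `lfc_latent_vs_prolif`, `sig_extra`,
#'   `sig_latent`
#' @export
map_interactions <- function(dge_tables, db) {
  extra <- dge_tables$extra_vs_intra
  latent <- dge_tables$latent_vs_prolif
  shared <- intersect(extra$gene, latent$gene)
  degs <- union(extra$gene[extra$significant], latent$gene[latent$significant])
  dropped <- setdiff(degs, shared)
  if (length(dropped)) {
    warning(length(dropped),
            " DEG(s) absent from one comparison's universe were dropped",
            call. = FALSE)
  }
  degs <- intersect(degs, shared)
  in_db <- degs[degs %in% c(db$partner_a, db$partner_b)]
  if (!length(in_db)) {
    return(tibble::tibble(gene = character(), role = character(),
                          partners = list(), lfc_extra_vs_intra = numeric(),
                          lfc_latent_vs_prolif = numeric(),
                          sig_extra = logical(), sig_latent = logical()))
  }
  ann <- purrr::map(in_db, function(g) {
    role_self <- unique(c(db$role_a[db$partner_a == g],
                          db$role_b[db$partner_b == g]))
    tibble::tibble(gene = g, role = paste(role_self, collapse = ";"),
                   partners = list(interaction_partners(db, g)$partner))
  }) |> purrr::list_rbind()
  ei <- extra[match(ann$gene, extra$gene), ]
  la <- latent[match(ann$gene, latent$gene), ]
  ann$lfc_extra_vs_intra <- ei$log2fc
  ann$lfc_latent_vs_prolif <- la$log2fc
  ann$sig_extra <- ei$significant
  ann$sig_latent <- la$significant
  dplyr::arrange(ann, .data$gene)
}

#' Filter candidates for partner expression in endothelial cells
#'
#' A candidate is retained when at least one of its partners is detected
#' (raw count > 0) in at least `min_pct` of the endothelial cells at the
#' time point matched to the comparison in which the candidate is
#' significant: day 1.5 for the intravascular-vs-extravascular comparison
#' and day 3.5 for the latent-vs-proliferative one.
#'
#' @param cands candidate tibble from [map_interactions()]
#' @param ec_matrix endothelial [cell_matrix()] with `time_point` metadata
#' @param min_pct detection fraction threshold (default 0.10)
#' @param time_extra,time_latent time points matched to the two comparisons
#' @return the filtered tibble with logical columns `partner_d1.5`,
#'   `partner_d3.5` and `partner_expressed_ec` added
#' @export
filter_partner_expression <- function(cands, ec_matrix, min_pct = 0.10,
                                      time_extra = "d1.5",
                                      time_latent = "d3.5") {
  stopifnot(inherits(ec_matrix, "cell_matrix"))
  for (tp in c(time_extra, time_latent)) {
    if (!tp %in% ec_matrix$cell_meta$time_point) {
      stop("time point ", tp, " absent from the EC dataset", call. = FALSE)
    }
  }
  if (!nrow(cands)) {
    return(dplyr::mutate(cands, partner_d1.5 = logical(),
                         partner_d3.5 = logical(),
                         partner_expressed_ec = logical()))
  }
  det_frac <- function(genes, tp) {
    cells <- ec_matrix$cell_meta$cell_id[ec_matrix$cell_meta$time_point == tp]
    sub <- ec_matrix$counts[intersect(genes, rownames(ec_matrix$counts)),
                            cells, drop = FALSE]
    if (!nrow(sub)) return(numeric(0))
    rowMeans(sub > 0)
  }
  expressed_at <- function(partners, tp) {
    f <- det_frac(partners, tp)
    if (min_pct == 0) any(f > 0) else any(f >= min_pct)
  }
  cands$partner_d1.5 <- purrr::map_lgl(cands$partners, expressed_at, time_extra)
  cands$partner_d3.5 <- purrr::map_lgl(cands$partners, expressed_at, time_latent)
  keep <- (cands$sig_extra & cands$partner_d1.5) |
    (cands$sig_latent & cands$partner_d3.5)
  cands$partner_expressed_ec <- cands$partner_d1.5 | cands$partner_d3.5
  cands[keep, , drop = FALSE]
}

#' Categorize screen candidates and call trajectory-defining genes
#'
#' Category reflects the two significance flags (`both`, `latent_only`,
#' `intra_extra_only`, `none`); the quadrant is determined solely by the
#' signs of the two fold changes (`extravasation_latency` when both are
#' positive, `intravascular_proliferative` when both are negative, `mixed`
#' otherwise). A candidate is trajectory-defining when it is significant
#' in both comparisons with a concordant, non-mixed quadrant.
#'
#' @param cands candidate tibble with fold changes and significance flags
#' @return a `screen_candidates` tibble with `category`, `quadrant` and
#'   `trajectory_defining` added
#' @export
classify_candidates <- function(cands) {
  out <- dplyr::mutate(
    cands,
    category = dplyr::case_when(
      .data$sig_extra & .data$sig_latent ~ "both",
      .data$sig_latent ~ "latent_only",
      .data$sig_extra ~ "intra_extra_only",
      .default = "none"),
    quadrant = dplyr::case_when(
      .data$lfc_extra_vs_intra > 0 & .data$lfc_latent_vs_prolif > 0 ~
        "extravasation_latency",
      .data$lfc_extra_vs_intra < 0 & .data$lfc_latent_vs_prolif < 0 ~
        "intravascular_proliferative",
      .default = "mixed"),
    trajectory_defining = .data$category == "both" & .data$quadrant != "mixed")
  class(out) <- c("screen_candidates", class(out))
  out
}

#' Run the ligand-receptor trajectory screen end to end
#'
#' Pseudobulks the tumor cells by replicate and gate, runs the dual
#' NB-Wald comparisons, maps significant genes onto the partner database,
#' filters for endothelial partner expression at the matched time points
#' and classifies the survivors. Supervised re-analysis of a fixed gene
#' list (bypassing the DEG filter but keeping significance annotation) is
#' available through `restrict_genes`.
#'
#' @param tc_matrix raw tumor-cell [cell_matrix()] with `replicate` and
#'   `gate` metadata
#' @param ec_matrix endothelial [cell_matrix()] with `time_point` metadata
#' @param db interaction table
#' @param exclude_latent_genes see [dual_dge()]
#' @param alpha,lfc_min significance thresholds of the dual comparisons
#' @param min_pct partner detection threshold in ECs (default 0.10)
#' @param restrict_genes optional gene list screened regardless of
#'   significance (partner filtering then requires expression at either
#'   time point)
#' @return a `screen_candidates` tibble; the two DGE tables are attached
#'   as `attr(, "dge_tables")`
#' @export
interaction_screen <- function(tc_matrix, ec_matrix, db,
                               exclude_latent_genes = NULL, alpha = 0.05,
                               lfc_min = 0.5, min_pct = 0.10,
                               restrict_genes = NULL) {
  pb <- make_pseudobulk(tc_matrix, keys = c("replicate", "gate"))
  tabs <- dual_dge(pb, exclude_latent_genes = exclude_latent_genes,
                   alpha = alpha, lfc_min = lfc_min)
  cands <- map_interactions(tabs, db)
  if (!is.null(restrict_genes)) {
    forced <- .forced_candidates(restrict_genes, tabs, db)
    cands <- dplyr::bind_rows(cands, forced) |>
      dplyr::distinct(.data$gene, .keep_all = TRUE)
    cands <- filter_partner_expression(
      dplyr::mutate(cands, sig_extra = TRUE, sig_latent = TRUE),
      ec_matrix, min_pct = min_pct) |>
      dplyr::mutate(sig_extra = .data$gene %in%
                      tabs$extra_vs_intra$gene[tabs$extra_vs_intra$significant],
                    sig_latent = .data$gene %in%
                      tabs$latent_vs_prolif$gene[tabs$latent_vs_prolif$significant])
  } else {
    cands <- filter_partner_expression(cands, ec_matrix, min_pct = min_pct)
  }
  out <- classify_candidates(cands)
  out$pct_expressed_tc <- .tc_detection(out$gene, tc_matrix)
  attr(out, "dge_tables") <- tabs
  out
}

.forced_candidates <- function(genes, tabs, db) {
  genes <- intersect(genes, c(db$partner_a, db$partner_b))
  genes <- intersect(genes, intersect(tabs$extra_vs_intra$gene,
                                      tabs$latent_vs_prolif$gene))
  if (!length(genes)) {
    return(tibble::tibble(gene = character(), role = character(),
                          partners = list(), lfc_extra_vs_intra = numeric(),
                          lfc_latent_vs_prolif = numeric(),
                          sig_extra = logical(), sig_latent = logical()))
  }
  ei <- tabs$extra_vs_intra[match(genes, tabs$extra_vs_intra$gene), ]
  la <- tabs$latent_vs_prolif[match(genes, tabs$latent_vs_prolif$gene), ]
  tibble::tibble(
    gene = genes,
    role = purrr::map_chr(genes, function(g) {
      paste(unique(c(db$role_a[db$partner_a == g],
                     db$role_b[db$partner_b == g])), collapse = ";")
    }),
    partners = purrr::map(genes, ~interaction_partners(db, .x)$partner),
    lfc_extra_vs_intra = ei$log2fc,
    lfc_latent_vs_prolif = la$log2fc,
    sig_extra = ei$significant,
    sig_latent = la$significant)
}

.tc_detection <- function(genes, tc_matrix) {
  sub <- tc_matrix$counts[intersect(genes, rownames(tc_matrix$counts)), ,
                          drop = FALSE]
  frac <- rowMeans(sub > 0)
  unname(frac[match(genes, names(frac))])
}

#' Plot the trajectory screen
#'
#' Fold change of the latent-vs-proliferative comparison against the
#' extravascular-vs-intravascular one; color marks the significance
#' category, size the fraction of tumor cells expressing the gene, and
#' the shaded quadrants mark the two trajectories.
#'
#' @param object a `screen_candidates` tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.screen_candidates <- function(object, ...) {
  lim_x <- max(abs(object$lfc_extra_vs_intra), 1) * 1.1
  lim_y <- max(abs(object$lfc_latent_vs_prolif), 1) * 1.1
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$lfc_extra_vs_intra,
                               y = .data$lfc_latent_vs_prolif)) +
    ggplot2::annotate("rect", xmin = 0, xmax = lim_x, ymin = 0, ymax = lim_y,
                      fill = "steelblue", alpha = 0.08) +
    ggplot2::annotate("rect", xmin = -lim_x, xmax = 0, ymin = -lim_y, ymax = 0,
                      fill = "firebrick", alpha = 0.08) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category,
                                     size = .data$pct_expressed_tc)) +
    ggplot2::labs(x = "log2 FC extravascular vs intravascular",
                  y = "log2 FC latent vs proliferative",
                  size = "Pct. expressed (TC)", colour = "Significant in") +
    ggplot2::theme_minimal()
}
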