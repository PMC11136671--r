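#' Build pseudobulk profiles from single cells
#'
#' Sums raw counts over every combination of the requested metadata keys
#' (e.g. replicate x FACS gate), yielding replicate-level bulk profiles for
#' count-based testing. Total counts are conserved.
#'
#' @param x a raw [cell_matrix()]
#' @param keys metadata column names in `x$cell_meta`
#' @return a `pseudobulk` object: list with `counts` (genes x samples
#'   matrix) and `sample_meta` (tibble with one row per key combination,
#'   plus `sample` and `n_cells`)
#' @export
make_pseudobulk <- function(x, keys = c("replicate", "gate")) {
  stopifnot(inherits(x, "cell_matrix"))
  missing <- setdiff(keys, names(x$cell_meta))
  if (length(missing)) {
    stop("metadata key(s) absent: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  combo <- do.call(paste, c(x$cell_meta[keys], sep = "."))
  groups <- split(seq_along(combo), combo)
  counts <- vapply(groups, function(idx) {
    rowSums(x$counts[, idx, drop = FALSE])
  }, numeric(nrow(x$counts)))
  meta <- x$cell_meta[match(names(groups), combo), keys, drop = FALSE]
  meta$sample <- names(groups)
  meta$n_cells <- lengths(groups)
  structure(list(counts = counts,
                 sample_meta = dplyr::relocate(tibble::as_tibble(meta),
                                               "sample")),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %d genes x %d samples\n", nrow(x$counts),
              ncol(x$counts)))
  print(x$sample_meta, n = 6)
  invisible(x)
}

#' Wilcoxon rank-sum differential expression
#'
#' Two-sided rank-sum test per gene between two groups of expression
#' columns, with the exact null distribution when the combined sample size
#' is at most 10 and the gene is tie-free, and the normal approximation
#' with tie-corrected variance otherwise. Fold change is
#' `log2((mean_a + eps) / (mean_b + eps))` on the supplied (normalized)
#' scale. A gene is flagged significant when its log2 fold change exceeds
#' `lfc_min` in absolute value and its p value (raw by default, or
#' BH-adjusted with `sig_on = "padj"`) is below `alpha`.
#'
#' @param a,b numeric matrices (genes x cells) with identical rownames
#' @param alpha significance level (default 0.01)
#' @param lfc_min absolute log2 fold-change threshold (default 0.5)
#' @param sig_on `"p"` (default) or `"padj"`: which value the significance
#'   flag thresholds
#' @param eps fold-change pseudocount on the expression scale
#' @return a `dge_table` tibble: `gene`, `log2fc`, `p`, `padj`, `pct_a`,
#'   `pct_b`, `significant`
#' @export
wilcoxon_dge <- function(a, b, alpha = 0.01, lfc_min = 0.5,
                         sig_on = c("p", "padj"), eps = 1e-9) {
  sig_on <- match.arg(sig_on)
  stopifnot(is.matrix(a), is.matrix(b), identical(rownames(a), rownames(b)))
  if (ncol(a) < 2 || ncol(b) < 2) {
    stop("each group needs at least 2 columns", call. = FALSE)
  }
  p <- vapply(seq_len(nrow(a)), function(i) {
    wilcoxon_p(a[i, ], b[i, ])
  }, numeric(1))
  mean_a <- unname(rowMeans(a)); mean_b <- unname(rowMeans(b))
  out <- tibble::tibble(
    gene = rownames(a),
    log2fc = ifelse(mean_a == mean_b, 0,
                    log2((mean_a + eps) / (mean_b + eps))),
    p = p,
    padj = bh_adjust(p),
    pct_a = unname(rowMeans(a > 0)),
    pct_b = unname(rowMeans(b > 0)))
  out$significant <- abs(out$log2fc) > lfc_min &
    (if (sig_on == "p") out$p else out$padj) < alpha
  class(out) <- c("dge_table", class(out))
  out
}

#' Two-sided rank-sum p value for one gene
#'
#' Exact enumeration when `length(x) + length(y) <= 10` and the pooled
#' values are tie-free; otherwise the continuity-corrected normal
#' approximation with tie-corrected variance (the two branches agree
#' within 0.02 on tie-free data at n = 8 vs 8). Constant genes return
#' p = 1.
#'
#' @param x,y numeric vectors
#' @return p value in (0, 1]
#' @export
wilcoxon_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1) return(1)
  exact <- (length(x) + length(y)) <= 10 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p values, monotone and capped at 1; invariant
#' to input order up to permutation.
#'
#' @param p numeric vector of p values in \[0, 1\]
#' @return adjusted p values, elementwise >= `p`
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Simplified negative-binomial Wald differential expression
#'
#' A pseudobulk DGE engine in the DESeq2 mold, deliberately simplified:
#' median-of-ratios size factors, gene-wise method-of-moments dispersion on
#' normalized counts (floored at 1e-8, no shrinkage), a per-gene NB
#' log-linear model with a group coefficient fitted by IRLS, a Wald test on
#' the coefficient and BH adjustment. All-zero genes are reported untested.
#'
#' @param pb a [make_pseudobulk()] object, or a plain genes x samples
#'   count matrix with `sample_meta` supplied via `meta`
#' @param contrast length-2 character vector `c(group_a, group_b)`; the
#'   fold change is a-over-b
#' @param group_col column of the sample metadata holding the group labels
#' @param alpha BH-adjusted significance level (default 0.05)
#' @param lfc_min absolute log2 fold-change threshold used for the
#'   significance flag (default 0)
#' @param meta sample metadata when `pb` is a plain matrix
#' @return a `dge_table` tibble: `gene`, `log2fc`, `se_log2fc`, `p`,
#'   `padj`, `tested`, `significant`
#' @export
nb_wald_dge <- function(pb, contrast, group_col = "gate", alpha = 0.05,
                        lfc_min = 0, meta = NULL) {
  if (inherits(pb, "pseudobulk")) {
    counts <- pb$counts
    meta <- pb$sample_meta
  } else {
    counts <- pb
    if (is.null(meta)) stop("`meta` required for a plain matrix", call. = FALSE)
  }
  stopifnot(length(contrast) == 2, group_col %in% names(meta))
  grp <- meta[[group_col]]
  sel <- grp %in% contrast
  if (sum(grp == contrast[1]) < 2 || sum(grp == contrast[2]) < 2) {
    stop("each contrast group needs >= 2 samples", call. = FALSE)
  }
  counts <- counts[, sel, drop = FALSE]
  grp <- factor(grp[sel], levels = rev(contrast))  # coefficient = a vs b
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")

  # gene-wise MoM dispersion: within-group residual variance vs mean
  disp <- .mom_dispersion(norm, grp)

  design <- stats::model.matrix(~grp)
  off <- log(sf)
  n_gene <- nrow(counts)
  beta <- se <- rep(NA_real_, n_gene)
  tested <- rowSums(counts) > 0
  for (i in which(tested)) {
    fam <- MASS::negative.binomial(theta = 1 / disp[i], link = "log")
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(design, counts[i, ], family = fam,
                                      offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    cf <- fit$coefficients[2]
    cov <- tryCatch(chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(cov)) next
    beta[i] <- cf
    se[i] <- sqrt(cov[2, 2])
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  padj <- rep(NA_real_, n_gene)
  ok <- !is.na(p)
  padj[ok] <- bh_adjust(p[ok])
  out <- tibble::tibble(
    gene = rownames(counts),
    log2fc = beta / log(2),
    se_log2fc = se / log(2),
    p = p, padj = padj,
    tested = tested & ok,
    significant = !is.na(padj) & padj < alpha & abs(beta / log(2)) > lfc_min)
  class(out) <- c("dge_table", class(out))
  out
}

#' Median-of-ratios size factors
#'
#' The size factor of a sample is the median, over genes positive in every
#' sample, of the ratio of its count to the gene's geometric mean.
#'
#' @param counts genes x samples count matrix
#' @return numeric vector of size factors, one per sample
#' @export
size_factors <- function(counts) {
  logs <- log(counts)
  usable <- rowSums(is.finite(logs)) == ncol(counts)
  if (!any(usable)) {
    stop("no gene is positive in every sample; size factors undefined",
         call. = FALSE)
  }
  geo <- rowMeans(logs[usable, , drop = FALSE])
  apply(logs[usable, , drop = FALSE], 2, function(lc) exp(stats::median(lc - geo)))
}

.mom_dispersion <- function(norm, grp, floor = 1e-8) {
  k <- nlevels(grp)
  n <- ncol(norm)
  group_means <- vapply(levels(grp), function(g) {
    rowMeans(norm[, grp == g, drop = FALSE])
  }, numeric(nrow(norm)))
  centered <- norm - group_means[, as.integer(grp)]
  resid_var <- rowSums(centered^2) / (n - k)
  mu <- rowMeans(norm)
  pmax((resid_var - mu) / mu^2, floor)
}

#' Relative fold changes from qPCR Ct values
#'
#' Delta Ct is target minus reference per sample; delta-delta Ct subtracts
#' the mean delta Ct of the control samples; the relative fold change is
#' `2^-ddCt`. The geometric mean of the control-group fold changes is 1 by
#' construction.
#'
#' @param data tibble with columns `sample`, `ct_target`, `ct_reference`
#' @param control character vector of control sample ids (non-empty,
#'   all present in `data$sample`)
#' @return tibble with `sample`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`
#' @export
ddct_fold_change <- function(data, control) {
  stopifnot(all(c("sample", "ct_target", "ct_reference") %in% names(data)))
  if (!length(control)) stop("control sample set is empty", call. = FALSE)
  if (!all(control %in% data$sample)) {
    stop("control id(s) absent from `data$sample`", call. = FALSE)
  }
  if (any(!is.finite(data$ct_target)) || any(!is.finite(data$ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  dct <- data$ct_target - data$ct_reference
  ddct <- dct - mean(dct[data$sample %in% control])
  tibble::tibble(sample = data$sample, delta_ct = dct,
                 delta_delta_ct = ddct, fold_change = 2^(-ddct))
}
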