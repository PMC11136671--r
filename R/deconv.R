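#' Quasibinomial aCap/gCap log-odds deconvolution of bulk samples
#'
#' For every bulk sample the summed aCap-marker counts are treated as
#' successes and the summed gCap-marker counts as failures, giving a
#' per-sample log-odds `theta = ln(sum aCap / sum gCap)` that is invariant
#' to sequencing depth. Per group, an intercept-only quasibinomial logit
#' fit pools the samples: the estimate is the logit of the pooled
#' proportion and its standard error is inflated by the square root of the
#' group's Pearson dispersion; the 95% CI is estimate +/- 1.96 SE. An
#' empirical across-sample CI (mean theta +/- 1.96 sd/sqrt(n)) is reported
#' alongside; the quasibinomial one is primary. Samples with zero counts
#' on either panel are excluded with a warning, and a group of size 1 gets
#' dispersion 1 with a warning.
#'
#' @param counts genes x samples count matrix
#' @param sample_meta tibble with `sample` (matching `colnames(counts)`)
#'   and `group`
#' @param panels list with character vectors `aCap` and `gCap` of marker
#'   gene ids
#' @return a `deconv_fit`: list with `samples` (tibble: `sample`, `group`,
#'   `acap_counts`, `gcap_counts`, `theta`) and `groups` (tibble: `group`,
#'   `n`, `estimate`, `phi`, `se`, `ci_lo`, `ci_hi`, `se_emp`,
#'   `ci_lo_emp`, `ci_hi_emp`)
#' @export
deconvolve <- function(counts, sample_meta, panels) {
  stopifnot(all(c("sample", "group") %in% names(sample_meta)),
            all(c("aCap", "gCap") %in% names(panels)))
  counts <- counts[, sample_meta$sample, drop = FALSE]
  a_genes <- intersect(panels$aCap, rownames(counts))
  g_genes <- intersect(panels$gCap, rownames(counts))
  if (!length(a_genes) || !length(g_genes)) {
    stop("marker panel gene(s) absent from the count table", call. = FALSE)
  }
  samples <- tibble::tibble(
    sample = sample_meta$sample,
    group = sample_meta$group,
    acap_counts = unname(colSums(counts[a_genes, , drop = FALSE])),
    gcap_counts = unname(colSums(counts[g_genes, , drop = FALSE])))
  bad <- samples$acap_counts == 0 | samples$gcap_counts == 0
  if (any(bad)) {
    warning("excluding sample(s) with zero counts on a panel: ",
            paste(samples$sample[bad], collapse = ", "), call. = FALSE)
    samples <- samples[!bad, , drop = FALSE]
  }
  samples$theta <- log(samples$acap_counts / samples$gcap_counts)

  groups <- samples |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~.quasibinomial_group(.x)) |>
    dplyr::ungroup()
  structure(list(samples = samples, groups = groups), class = "deconv_fit")
}

.quasibinomial_group <- function(d) {
  succ <- d$acap_counts
  tot <- d$acap_counts + d$gcap_counts
  if (nrow(d) == 1) {
    warning("group of size 1: Pearson dispersion undefined, set to 1",
            call. = FALSE)
    p_hat <- succ / tot
    est <- stats::qlogis(p_hat)
    se <- sqrt(1 / (tot * p_hat * (1 - p_hat)))
    phi <- 1
  } else {
    fit <- stats::glm(cbind(succ, tot - succ) ~ 1,
                      family = stats::quasibinomial())
    sm <- summary(fit)
    est <- unname(stats::coef(fit)[1])
    se <- unname(sm$coefficients[1, 2])
    phi <- sm$dispersion
  }
  emp_se <- if (nrow(d) > 1) stats::sd(d$theta) / sqrt(nrow(d)) else NA_real_
  tibble::tibble(
    n = nrow(d), estimate = est, phi = phi, se = se,
    ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
    se_emp = emp_se,
    ci_lo_emp = mean(d$theta) - 1.96 * emp_se,
    ci_hi_emp = mean(d$theta) + 1.96 * emp_se)
}

#' Normalize a deconvolution fit to a control group
#'
#' Subtracts the control group's log-odds estimate from every group (a
#' ratio of odds ratios), reports the result on the log2 scale with a CI
#' whose SE combines both groups' SEs in quadrature, and exponentiates the
#' ratio for plotting. The control group's own normalized log2 ratio is 0
#' with a zero-width CI by construction.
#'
#' @param fit a [deconvolve()] result
#' @param control control group id present in `fit$groups$group`
#' @return the `deconv_fit` with columns `log2_ratio`, `log2_ratio_se`,
#'   `log2_ratio_lo`, `log2_ratio_hi`, `ratio` added to `$groups` and the
#'   control recorded in `attr(, "control")`
#' @export
normalize_to_control <- function(fit, control) {
  stopifnot(inherits(fit, "deconv_fit"))
  g <- fit$groups
  if (!control %in% g$group) {
    stop("control group '", control, "' absent from fit", call. = FALSE)
  }
  ctrl <- g[g$group == control, ]
  is_ctrl <- g$group == control
  se2 <- sqrt(g$se^2 + ctrl$se^2) / log(2)
  g$log2_ratio <- (g$estimate - ctrl$estimate) / log(2)
  g$log2_ratio_se <- ifelse(is_ctrl, 0, se2)
  g$log2_ratio_lo <- g$log2_ratio - 1.96 * g$log2_ratio_se
  g$log2_ratio_hi <- g$log2_ratio + 1.96 * g$log2_ratio_se
  g$ratio <- 2^g$log2_ratio
  fit$groups <- g
  attr(fit, "control") <- control
  fit
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf("<deconv_fit> %d samples, %d groups\n", nrow(x$samples),
              nrow(x$groups)))
  ctrl <- attr(x, "control")
  if (!is.null(ctrl)) cat("  normalized to control:", ctrl, "\n")
  print(x$groups)
  invisible(x)
}

#' Tidy a deconvolution fit
#'
#' @param x a `deconv_fit`
#' @param ... unused
#' @return the per-group estimates tibble, one row per group
#' @export
tidy.deconv_fit <- function(x, ...) x$groups

#' One-row summary of a deconvolution fit
#'
#' @param x a `deconv_fit`
#' @param ... unused
#' @return tibble with sample/group counts, the control (if normalized)
#'   and the dispersion range
#' @export
glance.deconv_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_groups = nrow(x$groups),
    control = attr(x, "control") %||% NA_character_,
    phi_min = min(x$groups$phi),
    phi_max = max(x$groups$phi))
}

#' Plot control-normalized deconvolution ratios
#'
#' Points are exponentiated aCap/gCap odds ratios relative to the control
#' group; error bars are the exponentiated 95% CI.
#'
#' @param object a control-normalized `deconv_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.deconv_fit <- function(object, ...) {
  g <- object$groups
  if (is.null(g$ratio)) {
    stop("call normalize_to_control() before plotting", call. = FALSE)
  }
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = 2^.data$log2_ratio_lo,
                                          ymax = 2^.data$log2_ratio_hi)) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "aCap/gCap odds ratio vs control",
                  title = "Capillary composition shift") +
    ggplot2::theme_minimal()
}
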