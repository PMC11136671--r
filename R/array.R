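#' Beta-values from bead intensities
#'
#' Aggregates bead-level channel intensities to per-probe (per-group)
#' means and computes the methylation beta-value per color channel with
#' the +offset regularizer: `beta = B / (B + A + offset)`. The offset
#' keeps the denominator positive, so betas lie in \[0, 1).
#'
#' @param beads tibble with `probe`, `grn_a`, `grn_b`, `red_a`, `red_b`
#'   and optionally `group`
#' @param offset intensity regularizer (default 100)
#' @return tibble with `probe` (and `group` if present), `beta_grn`,
#'   `beta_red`
#' @export
beta_values <- function(beads, offset = 100) {
  stopifnot(all(c("probe", "grn_a", "grn_b", "red_a", "red_b") %in%
                  names(beads)))
  if (any(beads[c("grn_a", "grn_b", "red_a", "red_b")] < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  keys <- intersect(c("probe", "group"), names(beads))
  beads |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(dplyr::across(c("grn_a", "grn_b", "red_a", "red_b"),
                                   mean), .groups = "drop") |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(keys)),
      beta_grn = .data$grn_b / (.data$grn_b + .data$grn_a + offset),
      beta_red = .data$red_b / (.data$red_b + .data$red_a + offset))
}

#' M-values from a pair of beta-values
#'
#' `M = log2((beta_b + 1) / (beta_a + 1))`; for betas in \[0, 1\] the
#' result is bounded in \[-1, 1\].
#'
#' @param beta_a,beta_b beta-values in \[0, 1\]
#' @return numeric vector of M-values
#' @export
m_values <- function(beta_a, beta_b) {
  if (any(beta_a < 0 | beta_a > 1 | beta_b < 0 | beta_b > 1, na.rm = TRUE)) {
    stop("beta-values must lie in [0, 1]", call. = FALSE)
  }
  log2((beta_b + 1) / (beta_a + 1))
}

#' Within-channel quantile normalization of bead intensities
#'
#' Quantile-normalizes each channel (grn.A, grn.B, red.A, red.B)
#' separately across sample groups, equalizing the per-group intensity
#' distributions before beta computation. Toggleable; raw intensities are
#' used when skipped.
#'
#' @param beads tibble with `probe`, `group` and the four channel columns
#' @return the tibble with channel intensities replaced by their
#'   quantile-normalized values
#' @export
quantile_normalize_beads <- function(beads) {
  stopifnot("group" %in% names(beads))
  groups <- split(seq_len(nrow(beads)), beads$group)
  n <- min(lengths(groups))
  for (ch in c("grn_a", "grn_b", "red_a", "red_b")) {
    mat <- vapply(groups, function(idx) {
      stats::quantile(beads[[ch]][idx], probs = seq(0, 1, length.out = n),
                      names = FALSE)
    }, numeric(n))
    normed <- limma::normalizeQuantiles(mat)
    for (j in seq_along(groups)) {
      idx <- groups[[j]]
      # map each intensity to its normalized quantile value
      r <- rank(beads[[ch]][idx], ties.method = "average")
      q <- (r - 1) / (length(idx) - 1)
      beads[[ch]][idx] <- stats::approx(seq(0, 1, length.out = n),
                                        normed[, j], xout = q,
                                        rule = 2)$y
    }
  }
  beads
}

#' Bead-level differential methylation test between two groups
#'
#' Per probe, computes bead-level beta series for each color channel,
#' runs a two-sided two-sample t-test across beads between the groups for
#' each channel, and takes the probe p value as the minimum of the two
#' (both component p values are reported). The delta is the difference of
#' group mean betas per channel; BH adjustment is applied across probes.
#' Probes with fewer than `min_beads` beads in either group are flagged
#' untested.
#'
#' @param beads tibble with `probe`, `group` and the four channel columns
#' @param group1,group2 group labels to compare (delta = group1 - group2)
#' @param offset beta-value regularizer (default 100)
#' @param min_beads minimum beads per probe per group (default 3)
#' @return tibble with `probe`, `delta_grn`, `delta_red`, `p_grn`,
#'   `p_red`, `p`, `padj`, `tested`
#' @export
bead_group_test <- function(beads, group1, group2, offset = 100,
                            min_beads = 3) {
  b <- beads |>
    dplyr::filter(.data$group %in% c(group1, group2)) |>
    dplyr::mutate(
      beta_grn = .data$grn_b / (.data$grn_b + .data$grn_a + offset),
      beta_red = .data$red_b / (.data$red_b + .data$red_a + offset))
  rows <- b |>
    dplyr::group_by(.data$probe) |>
    dplyr::group_modify(function(d, key) {
      g1 <- d[d$group == group1, ]
      g2 <- d[d$group == group2, ]
      if (nrow(g1) < min_beads || nrow(g2) < min_beads) {
        return(tibble::tibble(delta_grn = NA_real_, delta_red = NA_real_,
                              p_grn = NA_real_, p_red = NA_real_,
                              p = NA_real_, tested = FALSE))
      }
      tp <- function(x, y) {
        if (stats::sd(x) == 0 && stats::sd(y) == 0) {
          return(if (mean(x) == mean(y)) 1 else 0)
        }
        stats::t.test(x, y)$p.value
      }
      p_grn <- tp(g1$beta_grn, g2$beta_grn)
      p_red <- tp(g1$beta_red, g2$beta_red)
      tibble::tibble(
        delta_grn = mean(g1$beta_grn) - mean(g2$beta_grn),
        delta_red = mean(g1$beta_red) - mean(g2$beta_red),
        p_grn = p_grn, p_red = p_red, p = min(p_grn, p_red), tested = TRUE)
    }) |>
    dplyr::ungroup()
  rows$padj <- NA_real_
  rows$padj[rows$tested] <- bh_adjust(rows$p[rows$tested])
  rows
}
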