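#' Threshold set for endothelial subtype classification
#'
#' The study's module-score thresholds for calling lung EC subtypes; all
#' inequalities are strict, so a score sitting exactly on a threshold fails
#' that rule.
#'
#' @param large_vessel_min large-vessel score threshold (default 1)
#' @param cycling_min cycling score threshold (default 0.5)
#' @param acap_min,gcap_max_for_acap aerocyte rule: aCap score > 0 and
#'   gCap score < 0
#' @param acap_max_for_gcap,gcap_min general-capillary rule: aCap score < 0
#'   and gCap score > -0.5
#' @return named list of thresholds
#' @export
ec_class_thresholds <- function(large_vessel_min = 1, cycling_min = 0.5,
                                acap_min = 0, gcap_max_for_acap = 0,
                                acap_max_for_gcap = 0, gcap_min = -0.5) {
  out <- list(large_vessel_min = large_vessel_min, cycling_min = cycling_min,
              acap_min = acap_min, gcap_max_for_acap = gcap_max_for_acap,
              acap_max_for_gcap = acap_max_for_gcap, gcap_min = gcap_min)
  stopifnot(all(vapply(out, is.finite, logical(1))))
  out
}

#' Classify endothelial cells from module scores
#'
#' Applies the threshold rules in fixed precedence: large-vessel, then
#' cycling, then aerocyte (aCap), then general capillary (gCap); the first
#' matching rule assigns the label and cells matching none are labeled
#' `"Unclassified"` (and retained). Every cell receives exactly one label.
#'
#' @param scores tibble with columns `cell_id`, `large_vessel`, `cycling`,
#'   `aCap`, `gCap` (e.g. from [score_modules()])
#' @param thresholds an [ec_class_thresholds()] list
#' @return tibble with `cell_id` and `label` in
#'   {LargeVessel, Cycling, aCap, gCap, Unclassified}
#' @export
classify_ec <- function(scores, thresholds = ec_class_thresholds()) {
  need <- c("cell_id", "large_vessel", "cycling", "aCap", "gCap")
  missing <- setdiff(need, names(scores))
  if (length(missing)) {
    stop("missing program score(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  th <- thresholds
  label <- dplyr::case_when(
    scores$large_vessel > th$large_vessel_min ~ "LargeVessel",
    scores$cycling > th$cycling_min ~ "Cycling",
    scores$aCap > th$acap_min & scores$gCap < th$gcap_max_for_acap ~ "aCap",
    scores$aCap < th$acap_max_for_gcap & scores$gCap > th$gcap_min ~ "gCap",
    .default = "Unclassified")
  tibble::tibble(cell_id = scores$cell_id, label = label)
}

#' Cell-cycle scores
#'
#' Scores each cell for S-phase and G2/M programs via [module_score()] and
#' returns the per-cell score sum used to gate latent vs proliferative
#' tumor cells.
#'
#' @param x a `normalized_matrix`
#' @param s_set,g2m_set S-phase and G2/M gene sets
#' @inheritParams module_score
#' @return tibble with `cell_id`, `s_score`, `g2m_score`, `score_sum`
#' @export
cc_scores <- function(x, s_set, g2m_set, n_bins = 24, n_ctrl = 100, seed = 0) {
  s <- module_score(x, s_set, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  g <- module_score(x, g2m_set, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  tibble::tibble(cell_id = s$cell_id, s_score = s$score, g2m_score = g$score,
                 score_sum = s$score + g$score)
}

#' Select bona fide latent and proliferative tumor cells
#'
#' Latent-gate cells with cell-cycle score sum < `latent_score_max`
#' (default -1) are bona fide latent; proliferative-gate cells with score
#' sum > `proliferative_score_min` (default 0) are selected proliferative;
#' every other cell is excluded. The two selections are disjoint by
#' construction.
#'
#' @param cc tibble from [cc_scores()]
#' @param gates tibble with `cell_id` and `gate` (values include
#'   `"latent"` and `"proliferative"`)
#' @param latent_score_max,proliferative_score_min strict thresholds
#' @return tibble with `cell_id`, `gate`, `score_sum` and `partition` in
#'   {bona_fide_latent, proliferative_selected, excluded}
#' @export
bona_fide_partition <- function(cc, gates, latent_score_max = -1,
                                proliferative_score_min = 0) {
  tab <- dplyr::inner_join(cc, gates[, c("cell_id", "gate")], by = "cell_id")
  tab$partition <- dplyr::case_when(
    tab$gate == "latent" & tab$score_sum < latent_score_max ~
      "bona_fide_latent",
    tab$gate == "proliferative" & tab$score_sum > proliferative_score_min ~
      "proliferative_selected",
    .default = "excluded")
  if (!any(tab$partition == "bona_fide_latent") ||
      !any(tab$partition == "proliferative_selected")) {
    warning("an output partition is empty; downstream DGE is not possible",
            call. = FALSE)
  }
  tab[, c("cell_id", "gate", "score_sum", "partition")]
}
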