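# hand-built pairwise DGE tables for the marker rule
pairwise_fixture <- function() {
  types <- paste0("T", 1:6)
  pairs <- utils::combn(types, 2)
  base <- purrr::map(seq_len(ncol(pairs)), function(k) {
    tibble::tibble(type_a = pairs[1, k], type_b = pairs[2, k],
                   gene = c("gA", "gB", "gC", "gD"),
                   log2fc = 0, p = 1)
  }) |> purrr::list_rbind()
  up <- function(tab, gene, type, opponents) {
    for (op in opponents) {
      i <- tab$gene == gene &
        ((tab$type_a == type & tab$type_b == op))
      tab$log2fc[i] <- 2; tab$p[i] <- 1e-5
      j <- tab$gene == gene & (tab$type_a == op & tab$type_b == type)
      tab$log2fc[j] <- -2; tab$p[j] <- 1e-5
    }
    tab
  }
  base |>
    up("gA", "T1", paste0("T", 2:6)) |>   # 5/5, specific -> marker of T1
    up("gB", "T2", c("T1", "T3", "T4")) |> # 3/5, specific -> marker of T2
    up("gC", "T3", c("T1", "T2", "T4")) |> # 3/5 for T3 ...
    up("gC", "T5", "T6") |>                # ... but also up for T5 once
    up("gD", "T4", c("T1", "T2"))          # only 2/5
}

test_that("marker rule needs >= 3 supports and exclusive upregulation", {
  mp <- derive_condition_markers(pairwise_fixture())
  expect_identical(mp$gene, c("gA", "gB"))
  expect_identical(mp$condition, c("T1", "T2"))
  expect_identical(mp$n_support, c(5L, 3L))
  # panels disjoint by construction
  expect_equal(anyDuplicated(mp$gene), 0)
  # missing pair table is an error naming the pair
  broken <- dplyr::filter(pairwise_fixture(),
                          !(type_a == "T1" & type_b == "T2"))
  expect_error(derive_condition_markers(broken, types = paste0("T", 1:6)),
               "T1 T2")
})

test_that("marker derivation is exact on the synthetic 6-type design", {
  md <- sim_marker_design(seed = 41)
  types <- unique(md$sample_meta$group)
  pairs <- utils::combn(types, 2)
  pw <- purrr::map(seq_len(ncol(pairs)), function(k) {
    d <- nb_wald_dge(md$counts, contrast = pairs[, k], group_col = "group",
                     meta = md$sample_meta)
    dplyr::mutate(d, type_a = pairs[1, k], type_b = pairs[2, k])
  }) |> purrr::list_rbind()
  mp <- derive_condition_markers(pw, types = types)
  want <- md$truth[md$truth$status == "marker", ]
  expect_setequal(mp$gene, want$gene)
  expect_identical(mp$condition[match(want$gene, mp$gene)], want$marker_of)
})

test_that("stable subtype panels require support at every time point", {
  fix <- ec_pipeline_fixture()
  nm <- fix$normalized
  labels <- classify_ec(score_modules(
    nm, fix$sim$gene_sets[c("large_vessel", "cycling", "aCap", "gCap")],
    seed = 0))
  panels <- derive_stable_subtype_panels(nm, labels)
  # constitutive planted markers are recovered, and nothing from the
  # other subtype's block leaks in
  expect_gt(length(intersect(panels$aCap, fix$sim$gene_sets$aCap)),
            0.8 * length(fix$sim$gene_sets$aCap))
  expect_length(intersect(panels$aCap, fix$sim$gene_sets$gCap), 0)
  expect_length(intersect(panels$gCap, fix$sim$gene_sets$aCap), 0)
  expect_error(derive_stable_subtype_panels(
    nm, labels[labels$label != "aCap", ]), "lacks")
})

test_that("per-sample log-odds follow the summed-marker arithmetic", {
  counts <- matrix(c(300, 100,
                     150, 150), nrow = 2, byrow = FALSE,
                   dimnames = list(c("a1", "g1"), c("s1", "s2")))
  meta <- tibble::tibble(sample = c("s1", "s2"), group = "g")
  fit <- deconvolve(counts, meta, panels = list(aCap = "a1", gCap = "g1"))
  expect_equal(fit$samples$theta, c(log(3), 0))
  # uniform depth scaling leaves everything unchanged
  fit2 <- deconvolve(counts * 7, meta, panels = list(aCap = "a1", gCap = "g1"))
  expect_equal(fit$samples$theta, fit2$samples$theta)
  expect_equal(fit$groups$estimate, fit2$groups$estimate)
})

test_that("group estimate is the pooled logit with dispersion-inflated SE", {
  set.seed(42)
  bs <- sim_bulk_mixture(bulk_sim_config(seed = 42))
  fit <- deconvolve(bs$counts, bs$sample_meta, bs$panels)
  g <- fit$groups[fit$groups$group == "PBS", ]
  s <- fit$samples[fit$samples$group == "PBS", ]
  pooled <- sum(s$acap_counts) / sum(s$acap_counts + s$gcap_counts)
  expect_equal(g$estimate, qlogis(pooled), tolerance = 1e-9)
  # binomial SE inflated by sqrt(phi)
  se0 <- sqrt(1 / (sum(s$acap_counts + s$gcap_counts) * pooled * (1 - pooled)))
  expect_equal(g$se, se0 * sqrt(g$phi), tolerance = 1e-6)
  expect_true(g$ci_lo <= g$estimate && g$estimate <= g$ci_hi)
})

test_that("degenerate deconvolution inputs are flagged", {
  counts <- matrix(c(10, 0, 5, 5), 2,
                   dimnames = list(c("a1", "g1"), c("s1", "s2")))
  meta <- tibble::tibble(sample = c("s1", "s2"), group = c("g", "g"))
  expect_warning(
    expect_warning(fit <- deconvolve(counts, meta,
                                     list(aCap = "a1", gCap = "g1")),
                   "zero counts"),
    "size 1")  # only one sample survives the exclusion
  expect_equal(nrow(fit$samples), 1)
  expect_warning(deconvolve(matrix(c(5, 5), 2,
                                   dimnames = list(c("a1", "g1"), "s1")),
                            tibble::tibble(sample = "s1", group = "g"),
                            list(aCap = "a1", gCap = "g1")),
                 "size 1")
})

test_that("control normalization pins the control at ratio 1", {
  bs <- sim_bulk_mixture(bulk_sim_config(seed = 43))
  fit <- normalize_to_control(
    deconvolve(bs$counts, bs$sample_meta, bs$panels), "PBS")
  g <- fit$groups
  expect_equal(g$log2_ratio[g$group == "PBS"], 0)
  expect_equal(g$ratio[g$group == "PBS"], 1)
  expect_equal(g$log2_ratio_se[g$group == "PBS"], 0)
  # planted odds 1.5 vs 0.75 -> log2 ratio ~ 1
  expect_lt(abs(g$log2_ratio[g$group == "treated"] - 1), 0.2)
  expect_error(normalize_to_control(fit, "nope"), "absent")
})

test_that("deconv fits expose tidy, glance and autoplot", {
  bs <- sim_bulk_mixture(bulk_sim_config(seed = 44))
  fit <- normalize_to_control(
    deconvolve(bs$counts, bs$sample_meta, bs$panels), "PBS")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$n_samples, 12)
  expect_equal(gl$control, "PBS")
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
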