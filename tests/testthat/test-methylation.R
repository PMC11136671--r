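test_that("replicate pooling sums counts per CpG", {
  r1 <- tibble::tibble(chrom = "chr1", pos0 = c(10L, 20L),
                       meth = c(3L, 1L), total = c(10L, 5L))
  r2 <- tibble::tibble(chrom = "chr1", pos0 = 10L, meth = 2L, total = 10L)
  pooled <- pool_replicates(list(r1, r2))
  expect_equal(pooled$meth[pooled$pos0 == 10], 5)
  expect_equal(pooled$total[pooled$pos0 == 10], 20)
  # CpG present in one replicate only is carried through
  expect_equal(pooled$meth[pooled$pos0 == 20], 1)
  expect_error(pool_replicates(list()), "empty")
})

test_that("region fractions are coverage-weighted and half-open", {
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                            name = "r1", class = "gene_body")
  cpg <- tibble::tibble(chrom = "chr1", pos0 = c(10L, 50L, 100L),
                        meth = c(5L, 15L, 99L), total = c(10L, 20L, 99L))
  rf <- region_fraction(cpg, regions)
  # CpG at pos0 = end excluded; (5 + 15) / (10 + 20)
  expect_equal(rf$fraction, 20 / 30)
  expect_equal(rf$n_cpg, 2L)

  none <- region_fraction(cpg[0, ], regions)
  expect_true(is.na(none$fraction))
})

test_that("region fractions match a brute-force per-CpG oracle", {
  set.seed(51)
  regions <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 1000, TRUE),
    start = sample.int(100000, 1000))
  regions$end <- regions$start + sample.int(500, 1000, replace = TRUE)
  regions$name <- sprintf("r%04d", seq_len(1000))
  regions$class <- "regulatory_element"
  cpg <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 5000, TRUE),
    pos0 = sample.int(101000, 5000),
    total = rpois(5000, 15))
  cpg$meth <- rbinom(5000, cpg$total, 0.4)

  rf <- region_fraction(cpg, regions)

  oracle_m <- oracle_t <- numeric(1000)
  for (i in seq_len(1000)) {
    hit <- cpg$chrom == regions$chrom[i] & cpg$pos0 >= regions$start[i] &
      cpg$pos0 < regions$end[i] & cpg$total >= 1
    oracle_m[i] <- sum(cpg$meth[hit]); oracle_t[i] <- sum(cpg$total[hit])
  }
  expect_identical(rf$meth, oracle_m)
  expect_identical(rf$total, oracle_t)
  expect_identical(rf$fraction,
                   ifelse(oracle_t > 0, oracle_m / oracle_t, NA_real_))
})

test_that("pooling then fractioning equals fractioning weighted sums", {
  ms <- sim_bisulfite(meth_sim_config(
    prob_table = tibble::tibble(name = c("a", "b"), truth = "x",
                                prob_latent = c(0.2, 0.7),
                                prob_proliferative = c(0.2, 0.7)),
    cpgs_per_region = 50, replicates = 3, seed = 52))
  pooled <- pool_replicates(ms$tables$latent)
  rf_pool <- region_fraction(pooled, ms$regions)
  per_rep <- lapply(ms$tables$latent, region_fraction, regions = ms$regions)
  m <- Reduce(`+`, lapply(per_rep, `[[`, "meth"))
  t <- Reduce(`+`, lapply(per_rep, `[[`, "total"))
  expect_identical(rf_pool$meth, m)     # exact integer identity
  expect_identical(rf_pool$total, t)
  expect_equal(rf_pool$fraction, m / t)
})

test_that("differential calls use the strict 10% threshold and flip by symmetry", {
  mk <- function(frac) tibble::tibble(
    name = paste0("r", seq_along(frac)), class = "gene_body",
    n_cpg = 10L, meth = round(frac * 100), total = 100,
    fraction = frac)
  lat <- mk(c(0.55, 0.45, 0.30, NA))
  pro <- mk(c(0.70, 0.50, 0.10, 0.50))
  dr <- differential_regions(lat, pro)
  expect_identical(dr$call, c("hypo", "unchanged", "hyper", NA))
  expect_equal(dr$diff, c(-0.15, -0.05, 0.20, NA))
  # swap conditions: hypo <-> hyper
  dr_swap <- differential_regions(pro, lat)
  expect_identical(dr_swap$call, c("hyper", "unchanged", "hypo", NA))
  # exactly 10% difference is unchanged (strict)
  dr10 <- differential_regions(mk(0.50), mk(0.60))
  expect_identical(dr10$call, "unchanged")
})

test_that("sealed flag is strict at 70% and propagates NA", {
  expect_identical(sealed_flag(c(0.71, 0.70, NA)), c(TRUE, FALSE, NA))
  lat <- tibble::tibble(name = "r", class = "gene_body", n_cpg = 1L,
                        meth = 50, total = 100, fraction = 0.5)
  pro <- dplyr::mutate(lat, meth = 71, fraction = 0.71)
  expect_true(differential_regions(lat, pro)$sealed)
})

test_that("planted region differences are recovered at study coverage", {
  ms <- sim_bisulfite(meth_sim_config(seed = 53))
  rf_l <- region_fraction(pool_replicates(ms$tables$latent), ms$regions)
  rf_p <- region_fraction(pool_replicates(ms$tables$proliferative),
                          ms$regions)
  dr <- differential_regions(rf_l, rf_p)
  truth <- ms$truth$truth[match(dr$name, ms$truth$name)]
  expect_gte(mean(dr$call[truth == "hypo"] == "hypo"), 0.95)
  expect_lt(mean(dr$call[truth != "hypo"] != "unchanged"), 0.05)
  expect_true(all(dr$sealed == (dr$frac_pro > 0.70)))
})

test_that("hypergeometric overlap enrichment matches tail arithmetic", {
  universe <- paste0("g", 1:20)
  res <- overlap_enrichment(paste0("g", 1:5),
                            list(term = paste0("g", 1:5)), universe)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # saturated query: p forced to 1
  sat <- overlap_enrichment(universe, list(term = universe), universe)
  expect_equal(sat$p, 1)
  # empty query: all p = 1
  none <- overlap_enrichment(character(0), list(term = paste0("g", 1:5)),
                             universe)
  expect_equal(none$p, 1)
  expect_error(overlap_enrichment("g1", list(t = "g1"), character(0)),
               "empty")
})

test_that("beta and M formulas are exact against direct arithmetic", {
  beads <- tibble::tibble(probe = "p", grn_a = 0, grn_b = 100,
                          red_a = 300, red_b = 100)
  bv <- beta_values(beads)
  expect_identical(bv$beta_grn, 100 / (100 + 0 + 100))   # = 0.5
  expect_identical(bv$beta_red, 100 / (100 + 300 + 100))
  zero <- beta_values(tibble::tibble(probe = "p", grn_a = 0, grn_b = 0,
                                     red_a = 0, red_b = 0))
  expect_identical(zero$beta_grn, 0)
  expect_error(beta_values(dplyr::mutate(beads, grn_a = -1)), "non-negative")

  expect_identical(m_values(0.4, 0.4), 0)
  expect_identical(m_values(0, 1), 1)                    # log2(2/1)
  b <- seq(0, 1, 0.05)
  grid <- expand.grid(a = b, bb = b)
  expect_true(all(abs(m_values(grid$a, grid$bb)) <= 1))
  expect_error(m_values(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("bead-level test takes the minimum of the two channel p values", {
  pt <- tibble::tibble(name = c("null", "shift"), truth = "x",
                       prob_latent = c(0.5, 0.6), prob_proliferative =
                         c(0.5, 0.3))
  as <- sim_array(meth_sim_config(prob_table = pt, n_beads = 50,
                                  noise_sd = 0.05, seed = 54))
  bt <- bead_group_test(as$beads, "latent", "proliferative")
  expect_true(all(bt$p <= bt$p_grn & bt$p <= bt$p_red))
  expect_lt(bt$padj[bt$probe == "shift"], 0.05)
  expect_equal(bt$delta_grn[bt$probe == "shift"], 0.3, tolerance = 0.05)

  # identical bead sets in both groups -> delta 0, p = 1
  same <- dplyr::bind_rows(
    dplyr::mutate(as$beads[as$beads$group == "latent", ], group = "g1"),
    dplyr::mutate(as$beads[as$beads$group == "latent", ], group = "g2"))
  bt2 <- bead_group_test(same, "g1", "g2")
  expect_equal(bt2$delta_grn, c(0, 0))
  expect_equal(bt2$p, c(1, 1))

  # insufficient beads -> untested
  few <- as$beads[as$beads$bead <= 2, ]
  bt3 <- bead_group_test(few, "latent", "proliferative")
  expect_false(any(bt3$tested))
})

test_that("quantile normalization equalizes channel distributions", {
  set.seed(55)
  beads <- tibble::tibble(
    probe = rep(paste0("p", 1:40), 2),
    group = rep(c("g1", "g2"), each = 40),
    grn_a = c(rlnorm(40, 5), rlnorm(40, 6)),
    grn_b = c(rlnorm(40, 5), rlnorm(40, 6)),
    red_a = c(rlnorm(40, 5), rlnorm(40, 6)),
    red_b = c(rlnorm(40, 5), rlnorm(40, 6)))
  qn <- quantile_normalize_beads(beads)
  m1 <- mean(qn$grn_a[qn$group == "g1"]); m2 <- mean(qn$grn_a[qn$group == "g2"])
  expect_lt(abs(m1 - m2) / m2, 0.05)
  expect_gt(abs(mean(beads$grn_a[beads$group == "g1"]) -
                  mean(beads$grn_a[beads$group == "g2"])) /
              mean(beads$grn_a[beads$group == "g2"]), 0.4)
})
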