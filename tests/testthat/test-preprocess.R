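test_that("QC rules apply the printed strict inequalities", {
  # one cell with exactly `n_det` detected genes and exact mito fraction:
  # mito count 300, nuclear total 300 * (1 - f) / f (integer for the
  # fractions used), spread over n_det - 1 nuclear genes
  build <- function(mito, n_det) {
    n_genes <- max(3000, n_det + 10)
    genes <- c("mt-1", paste0("G", seq_len(n_genes - 1)))
    v <- numeric(n_genes)
    v[1] <- 300
    nuc_total <- 300 * (1 - mito) / mito
    stopifnot(nuc_total == round(nuc_total), nuc_total >= n_det - 1)
    v[2] <- nuc_total - (n_det - 2)
    v[2 + seq_len(n_det - 2)] <- 1
    matrix(v, ncol = 1, dimnames = list(genes, "c1"))
  }
  # EC rule: mito 6%, 2000 detected genes -> removed
  m <- cell_matrix(build(0.06, 2000))
  expect_equal(nrow(qc_filter(m, "ec")$matrix$cell_meta), 0)
  # EC rule: exactly 5% mito and exactly 1000 genes -> retained
  m2 <- cell_matrix(build(0.05, 1000))
  st <- cell_stats(m2)
  expect_equal(st$mito_fraction, 0.05)
  expect_equal(st$n_detected, 1000)
  expect_equal(nrow(qc_filter(m2, "ec")$matrix$cell_meta), 1)
  # TC rule is strict the other way: the same cell fails both conditions
  expect_equal(nrow(qc_filter(m2, "tc")$matrix$cell_meta), 0)
  # TC rule keeps a cell strictly inside both bounds
  m3 <- cell_matrix(build(0.04, 2600))
  expect_equal(nrow(qc_filter(m3, "tc")$matrix$cell_meta), 1)
})

test_that("QC is idempotent, reports reasons, and needs mito flags", {
  fix <- ec_pipeline_fixture()
  sim <- fix$sim
  ec <- subset_cells(sim$matrix,
                     cells = which(sim$matrix$cell_meta$gate == "none"))
  once <- qc_filter(ec, "ec")
  twice <- qc_filter(once$matrix, "ec")
  expect_identical(once$matrix$counts, twice$matrix$counts)
  expect_true(all(!is.na(once$report$reason[!once$report$kept])))
  expect_equal(sum(once$report$kept), ncol(once$matrix$counts))

  no_mito <- tiny_matrix(1:4, genes = c("A", "B"), cells = c("c1", "c2"))
  expect_error(qc_filter(no_mito, "ec"), "mitochondrial")

  empty <- subset_cells(ec, cells = integer(0))
  res <- qc_filter(empty, "ec")
  expect_equal(ncol(res$matrix$counts), 0)
  expect_equal(nrow(res$report), 0)
})

test_that("housekeeping normalization computes the documented transform", {
  genes <- c(housekeeping_panel()[1:2], "G1", "mt-1")
  m <- tiny_matrix(c(10, 10, 10, 0,
                     20, 20, 20, 0), genes = genes,
                   cells = c("c1", "c2"))
  nm <- hk_normalize(m, panel = housekeeping_panel()[1:2])
  # panel mean 10 -> value log10(1 + 1e4 * 10/10) = log10(10001)
  expect_equal(nm$counts["G1", "c1"], log10(10001))
  expect_equal(nm$counts["mt-1", "c1"], 0)  # zeros map to 0
  # depth invariance: c2 = 2 x c1 -> identical normalized columns
  expect_equal(nm$counts[, "c1"], nm$counts[, "c2"])

  zero <- tiny_matrix(c(0, 0, 1, 0), genes = genes, cells = "c1")
  expect_error(hk_normalize(zero, panel = housekeeping_panel()[1:2]),
               "panel mean is 0.*c1")
  expect_warning(hk_normalize(m, panel = c(housekeeping_panel()[1:2], "Nope")),
                 "missing")
})

test_that("module score matches an explicit-loop oracle to 1e-10", {
  set.seed(101)
  n_gene <- 50; n_cell <- 30
  m <- matrix(abs(rnorm(n_gene * n_cell)), n_gene,
              dimnames = list(paste0("g", 1:n_gene), paste0("c", 1:n_cell)))
  nm <- cell_matrix(m, normalized = TRUE)
  gene_set <- paste0("g", c(3, 17, 41))
  n_bins <- 5; n_ctrl <- 4; seed <- 9

  got <- module_score(nm, gene_set, n_bins = n_bins, n_ctrl = n_ctrl,
                      seed = seed)

  # naive oracle: re-derive bins, controls and scores with explicit loops
  means <- apply(m, 1, mean)
  r <- rank(means, ties.method = "first")
  bin <- ceiling(r / (n_gene / n_bins)); bin <- pmin(bin, n_bins)
  set.seed(seed)
  ctrl <- character(0)
  for (g in gene_set) {
    pool <- rownames(m)[bin == bin[[which(rownames(m) == g)]]]
    ctrl <- c(ctrl, sample(pool, min(n_ctrl, length(pool))))
  }
  expected <- numeric(n_cell)
  for (j in seq_len(n_cell)) {
    s_sum <- 0; for (g in gene_set) s_sum <- s_sum + m[g, j]
    c_sum <- 0; for (g in ctrl) c_sum <- c_sum + m[g, j]
    expected[j] <- s_sum / length(gene_set) - c_sum / length(ctrl)
  }
  expect_equal(got$score, expected, tolerance = 1e-10)
})

test_that("module score is zero on a null construction and shifts additively", {
  # 40 genes in 4 groups of identical expression profiles: controls drawn
  # from a set gene's bin are copies of it, so the score is exactly 0
  base <- matrix(rep(c(1, 2, 3, 4), each = 10) +
                   rep(seq(0, 0.009, length.out = 10), 4), ncol = 1)
  m <- base %*% t(rep(1, 20)) + matrix(rep(seq(0, 1.9, 0.1), each = 40), 40)
  dimnames(m) <- list(paste0("g", 1:40), paste0("c", 1:20))
  # make genes within a bin exactly identical
  for (b in 1:4) m[(b - 1) * 10 + 1:10, ] <-
      m[rep((b - 1) * 10 + 1, 10), ]
  nm <- cell_matrix(m, normalized = TRUE)
  sc <- module_score(nm, c("g5", "g15"), n_bins = 4, n_ctrl = 5, seed = 1)
  expect_equal(sc$score, rep(0, 20), tolerance = 1e-12)

  # additive shift: set genes = controls + c in every cell
  m2 <- m
  m2[c(5, 15), ] <- m2[c(5, 15), ] + 0.37
  # keep the set genes inside their original bins by re-ranking check:
  nm2 <- cell_matrix(m2, normalized = TRUE)
  means2 <- rowMeans(m2)
  sc2 <- module_score(nm2, c("g5", "g15"), n_bins = 4, n_ctrl = 5, seed = 1)
  # controls may now include the shifted genes themselves; allow sampling slack
  expect_lt(max(abs(sc2$score - 0.37)), 0.37 * 0.5)
})

test_that("module score is reproducible and separates a planted program", {
  fix <- ec_pipeline_fixture()
  nm <- fix$normalized
  sets <- fix$sim$gene_sets
  s1 <- module_score(nm, sets$aCap, seed = 3)
  s2 <- module_score(nm, sets$aCap, seed = 3)
  expect_identical(s1, s2)

  lab <- nm$cell_meta$truth_label
  pos <- s1$score[lab == "aCap"]
  neg <- s1$score[lab == "gCap"]
  auc <- mean(outer(pos, neg, ">"))
  expect_gt(auc, 0.95)
})

test_that("module score guards degenerate inputs", {
  m <- tiny_matrix(matrix(runif(40), 10, 4,
                          dimnames = list(paste0("g", 1:10),
                                          paste0("c", 1:4))),
                   genes = paste0("g", 1:10), cells = paste0("c", 1:4),
                   normalized = TRUE)
  expect_warning(module_score(m, "g1", n_bins = 24), "fewer genes")
  expect_error(module_score(m, c("x", "y")), "no gene of the set")
})

test_that("contaminant removal counts detected markers per set", {
  genes <- c("Ptprc", "Itgam", "Cd3e", "Pdgfrb", "G1", "mt-1")
  m <- tiny_matrix(c(1, 1, 1, 0, 5, 1,   # 3 immune markers -> removed
                     0, 0, 0, 1, 5, 1,   # 1 stromal marker -> retained
                     0, 0, 0, 0, 5, 1),  # clean -> retained
                   genes = genes, cells = c("c1", "c2", "c3"))
  out <- remove_contaminants(m, min_positive_genes = 2)
  expect_identical(colnames(out$counts), c("c2", "c3"))
  expect_identical(remove_contaminants(m, sets = list())$counts, m$counts)
  expect_error(remove_contaminants(m, sets = list(immune = character(0))),
               "non-empty")
})
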