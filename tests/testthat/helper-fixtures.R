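# Small fixtures built in code; nothing is read from disk except what a
# test writes to tempdir() itself.

tiny_matrix <- function(values, genes = NULL, cells = NULL, meta = NULL,
                        normalized = FALSE) {
  m <- matrix(values, nrow = if (is.null(genes)) nrow(values) else length(genes))
  if (!is.null(genes)) rownames(m) <- genes
  if (!is.null(cells)) colnames(m) <- cells
  cell_matrix(m, cell_meta = meta, normalized = normalized)
}

# raw matrix with a mito gene and a full housekeeping panel so qc/normalize
# work out of the box
demo_matrix <- function(n_extra = 5, n_cells = 4, seed = 42) {
  set.seed(seed)
  genes <- c(housekeeping_panel(), "mt-1", paste0("G", seq_len(n_extra)))
  m <- matrix(rpois(length(genes) * n_cells, 5), nrow = length(genes),
              dimnames = list(genes, paste0("c", seq_len(n_cells))))
  cell_matrix(m)
}

# EC arm of the default simulator, preprocessed; memoised because several
# tests share it
ec_pipeline_fixture <- local({
  cache <- NULL
  function(seed = 1) {
    if (!is.null(cache)) return(cache)
    sim <- sim_sc_counts(sc_sim_config(seed = seed))
    ec_pops <- c("gCap", "aCap", "cycling_ec", "large_vessel", "contaminant")
    ec <- subset_cells(sim$matrix,
                       cells = which(sim$matrix$cell_meta$truth_label %in% ec_pops))
    filt <- remove_contaminants(qc_filter(ec, "ec")$matrix)
    nm <- hk_normalize(filt)
    cache <<- list(sim = sim, filtered = filt, normalized = nm)
    cache
  }
})
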