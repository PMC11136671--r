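#' Configuration for the single-cell count simulator
#'
#' Defines a gene universe and cell populations with the statistical
#' structure the downstream analysis assumes: negative-binomial counts with
#' population-specific marker blocks, a stable housekeeping panel,
#' mitochondrial counts targeting a per-cell fraction, planted cell-cycle
#' and Wnt/EMT program activity in the tumor-cell gates, planted
#' trajectory-defining ligands with endothelial receptor partners, decoy
#' pairs whose partners are silent in endothelial cells, and an immune
#' contaminant population.
#'
#' Populations: the four lung EC subtypes (`gCap`, `aCap`, `cycling_ec`,
#' `large_vessel`, sampled at days 0/1.5/3.5), the four tumor-cell FACS
#' gates (`intravascular`/`extravascular` at day 1.5,
#' `latent`/`proliferative` at day 3.5) and `contaminant`.
#'
#' @param n_cells named integer vector of cells per population; populations
#'   may be set to 0, but not all of them.
#' @param n_genes total gene universe size (marker blocks plus background)
#' @param n_replicates biological replicates cells are cycled through
#' @param marker_size genes per EC subtype marker block
#' @param marker_multiplier fold boost of a subtype's marker block in its
#'   own population
#' @param cycling_multiplier fold boost of the S+G2M union in cycling ECs
#' @param program_multiplier fold boost of Wnt/EMT/ligand blocks in
#'   extravascular and latent tumor cells
#' @param latent_cycle_multiplier multiplier of S/G2M genes in latent tumor
#'   cells (dormant cells downregulate cycle genes)
#' @param proliferative_cycle_multiplier multiplier of S/G2M genes in
#'   proliferative tumor cells
#' @param n_s,n_g2m sizes of the S-phase and G2/M gene sets
#' @param n_ligands,n_decoys planted trajectory ligand pairs and decoy pairs
#' @param disp_ec,disp_tc NB dispersion (variance = mu + mu^2 * alpha) for
#'   genes in EC-derived and TC-derived cells
#' @param hk_mean,hk_disp mean and dispersion of housekeeping panel genes
#' @param mito_shape shape parameters of the Beta distribution of per-cell
#'   mitochondrial fractions
#' @param marker_base,program_base,cycle_base,background_meanlog baseline
#'   NB means of marker blocks, program blocks and cycle genes, and the
#'   log-normal meanlog of background genes
#' @param seed RNG seed
#' @return a `sc_sim_config` list
#' @export
sc_sim_config <- function(n_cells = c(gCap = 400, aCap = 250, cycling_ec = 120,
                                      large_vessel = 120, intravascular = 160,
                                      extravascular = 160, latent = 160,
                                      proliferative = 160, contaminant = 40),
                          n_genes = 4000, n_replicates = 4,
                          marker_size = 40, marker_multiplier = 24,
                          cycling_multiplier = 12, program_multiplier = 4,
                          latent_cycle_multiplier = 0.25,
                          proliferative_cycle_multiplier = 4,
                          n_s = 43, n_g2m = 54,
                          n_ligands = 6, n_decoys = 6,
                          disp_ec = 0.1, disp_tc = 0.3,
                          hk_mean = 50, hk_disp = 0.05,
                          mito_shape = c(2, 60),
                          marker_base = 2, program_base = 2, cycle_base = 4,
                          background_meanlog = log(2),
                          seed = 0) {
  pops <- c("gCap", "aCap", "cycling_ec", "large_vessel", "intravascular",
            "extravascular", "latent", "proliferative", "contaminant")
  full <- stats::setNames(rep(0L, length(pops)), pops)
  full[names(n_cells)] <- as.integer(n_cells)
  if (any(full < 0)) stop("cell counts must be >= 0", call. = FALSE)
  if (sum(full) == 0) stop("at least one population must have cells", call. = FALSE)
  mult <- c(marker_multiplier, cycling_multiplier, program_multiplier,
            latent_cycle_multiplier, proliferative_cycle_multiplier)
  if (any(mult <= 0)) stop("multipliers must be > 0", call. = FALSE)
  structure(
    list(n_cells = full, n_genes = n_genes, n_replicates = n_replicates,
         marker_size = marker_size, marker_multiplier = marker_multiplier,
         cycling_multiplier = cycling_multiplier,
         program_multiplier = program_multiplier,
         latent_cycle_multiplier = latent_cycle_multiplier,
         proliferative_cycle_multiplier = proliferative_cycle_multiplier,
         n_s = n_s, n_g2m = n_g2m, n_ligands = n_ligands, n_decoys = n_decoys,
         disp_ec = disp_ec, disp_tc = disp_tc, hk_mean = hk_mean,
         hk_disp = hk_disp, mito_shape = mito_shape,
         marker_base = marker_base, program_base = program_base,
         cycle_base = cycle_base, background_meanlog = background_meanlog,
         seed = seed),
    class = c("sc_sim_config", "list"))
}

.ec_pops <- c("gCap", "aCap", "cycling_ec", "large_vessel")
.tc_pops <- c("intravascular", "extravascular", "latent", "proliferative")

# Build the gene universe and the genes x populations expected-mean matrix.
.sc_gene_model <- function(cfg) {
  pops <- names(cfg$n_cells)
  blocks <- list(
    hk = housekeeping_panel(),
    mito = sprintf("mt-%02d", seq_len(10)),
    gCap_mk = sprintf("gCap_mk%02d", seq_len(cfg$marker_size)),
    aCap_mk = sprintf("aCap_mk%02d", seq_len(cfg$marker_size)),
    lv_mk = sprintf("LV_mk%02d", seq_len(cfg$marker_size)),
    s_phase = sprintf("Sph%03d", seq_len(cfg$n_s)),
    g2m = sprintf("G2M%03d", seq_len(cfg$n_g2m)),
    wnt = sprintf("WntT%02d", seq_len(20)),
    emt = sprintf("EmtT%02d", seq_len(20)),
    ligand = sprintf("Lig%02d", seq_len(cfg$n_ligands)),
    receptor = sprintf("Rec%02d", seq_len(cfg$n_ligands)),
    decoy_tc = sprintf("DecoyTC%02d", seq_len(cfg$n_decoys)),
    decoy_ec = sprintf("DecoyEC%02d", seq_len(cfg$n_decoys)),
    immune = contaminant_sets()$immune
  )
  n_named <- length(unlist(blocks))
  n_bg <- cfg$n_genes - n_named
  if (n_bg < 0) stop("n_genes too small for the configured blocks", call. = FALSE)
  blocks$background <- sprintf("Gene%04d", seq_len(n_bg))
  genes <- unlist(blocks, use.names = FALSE)
  block_of <- rep(names(blocks), lengths(blocks))

  bg_mean <- stats::rlnorm(n_bg, meanlog = cfg$background_meanlog, sdlog = 1)
  base <- numeric(length(genes))
  base[block_of == "hk"] <- cfg$hk_mean
  base[block_of == "mito"] <- 0          # filled per cell from the target fraction
  base[block_of %in% c("gCap_mk", "aCap_mk", "lv_mk")] <- cfg$marker_base
  base[block_of %in% c("s_phase", "g2m")] <- cfg$cycle_base
  base[block_of %in% c("wnt", "emt", "ligand", "decoy_tc")] <- cfg$program_base
  base[block_of == "receptor"] <- 5
  base[block_of == "decoy_ec"] <- 0      # overridden to 1 in TC populations
  base[block_of == "immune"] <- 0        # expressed in contaminants only
  base[block_of == "background"] <- bg_mean

  mu <- matrix(base, nrow = length(genes), ncol = length(pops),
               dimnames = list(genes, pops))
  boost <- function(block, pop, k) {
    mu[block_of == block, pop] <<- mu[block_of == block, pop] * k
  }
  boost("gCap_mk", "gCap", cfg$marker_multiplier)
  boost("aCap_mk", "aCap", cfg$marker_multiplier)
  boost("lv_mk", "large_vessel", cfg$marker_multiplier)
  for (b in c("s_phase", "g2m")) {
    boost(b, "cycling_ec", cfg$cycling_multiplier)
    boost(b, "proliferative", cfg$proliferative_cycle_multiplier)
    boost(b, "latent", cfg$latent_cycle_multiplier)
  }
  for (b in c("wnt", "emt", "ligand", "decoy_tc")) {
    boost(b, "extravascular", cfg$program_multiplier)
    boost(b, "latent", cfg$program_multiplier)
  }
  mu[block_of == "decoy_ec", .tc_pops] <- 1
  mu[block_of == "immune", "contaminant"] <- 10

  disp <- matrix(cfg$disp_tc, nrow = length(genes), ncol = length(pops),
                 dimnames = list(genes, pops))
  disp[, .ec_pops] <- cfg$disp_ec
  disp[block_of == "hk", ] <- cfg$hk_disp
  disp[block_of == "mito", ] <- 0.1

  gene_sets <- list(
    large_vessel = blocks$lv_mk,
    cycling = c(blocks$s_phase, blocks$g2m),
    aCap = blocks$aCap_mk,
    gCap = blocks$gCap_mk,
    S = blocks$s_phase,
    G2M = blocks$g2m,
    Wnt = blocks$wnt,
    EMT = blocks$emt
  )
  list(genes = genes, block_of = block_of, mu = mu, disp = disp,
       gene_sets = gene_sets, blocks = blocks)
}

#' Simulate a single-cell count matrix with ground truth
#'
#' Draws per-gene, per-cell negative-binomial counts from the
#' population-specific mean model of [sc_sim_config()], adds mitochondrial
#' counts targeting a Beta-distributed per-cell fraction, and attaches
#' replicate, time point, FACS gate and true population labels.
#'
#' @param cfg an [sc_sim_config()]
#' @return list with elements `matrix` (a raw [cell_matrix()] whose
#'   `cell_meta$truth_label` holds the planted population), `truth` (per-cell
#'   tibble), `gene_sets` (the planted marker/program sets), `gene_truth`
#'   (per-gene tibble with block membership), `expected_means` (genes x
#'   populations matrix of configured NB means) and `config`.
#' @export
sim_sc_counts <- function(cfg = sc_sim_config()) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  set.seed(cfg$seed)
  gm <- .sc_gene_model(cfg)
  pops <- names(cfg$n_cells)
  keep <- pops[cfg$n_cells > 0]

  cols <- list(); meta <- list()
  for (p in keep) {
    n <- cfg$n_cells[[p]]
    mu_p <- gm$mu[, p]
    size_p <- 1 / gm$disp[, p]
    m <- matrix(stats::rnbinom(length(mu_p) * n, mu = rep(mu_p, n),
                               size = rep(size_p, n)),
                nrow = length(mu_p))
    # mitochondrial counts: hit a per-cell Beta target fraction
    f <- stats::rbeta(n, cfg$mito_shape[1], cfg$mito_shape[2])
    mito_idx <- which(gm$block_of == "mito")
    nonmito_tot <- colSums(m)
    mito_tot <- stats::rpois(n, nonmito_tot * f / (1 - f))
    for (j in seq_len(n)) {
      if (mito_tot[j] > 0) {
        m[mito_idx, j] <- stats::rmultinom(1, mito_tot[j],
                                           rep(1, length(mito_idx)))[, 1]
      }
    }
    cols[[p]] <- m
    tp <- switch(p,
                 intravascular = , extravascular = "d1.5",
                 latent = , proliferative = "d3.5",
                 contaminant = "d1.5",
                 c("d0", "d1.5", "d3.5")[(seq_len(n) %% 3) + 1])
    gate <- if (p %in% .tc_pops) p else "none"
    meta[[p]] <- tibble::tibble(
      population = p,
      replicate = paste0("R", (seq_len(n) %% cfg$n_replicates) + 1),
      time_point = tp, gate = gate)
  }
  counts <- do.call(cbind, cols)
  meta <- dplyr::bind_rows(meta)
  meta$cell_id <- sprintf("c%05d", seq_len(nrow(meta)))
  colnames(counts) <- meta$cell_id
  rownames(counts) <- gm$genes

  cm <- cell_matrix(counts,
                    cell_meta = tibble::tibble(
                      cell_id = meta$cell_id, replicate = meta$replicate,
                      time_point = meta$time_point, gate = meta$gate,
                      truth_label = meta$population))
  list(matrix = cm,
       truth = dplyr::relocate(meta, "cell_id"),
       gene_sets = gm$gene_sets,
       gene_truth = tibble::tibble(gene_id = gm$genes, block = gm$block_of),
       expected_means = gm$mu[, keep, drop = FALSE],
       config = cfg)
}

#' Configuration for the bulk aCap/gCap mixture simulator
#'
#' @param groups tibble with columns `group`, `f` (aCap mixing fraction,
#'   strictly inside (0,1)) and `n_samples`
#' @param depth total marker-panel reads per sample
#' @param rho beta-binomial overdispersion (0 = pure binomial)
#' @param panel_size genes per marker panel
#' @param seed RNG seed
#' @return a `bulk_sim_config` list
#' @export
bulk_sim_config <- function(groups = tibble::tibble(
                              group = c("PBS", "treated"),
                              f = c(0.429, 0.6),
                              n_samples = c(6, 6)),
                            depth = 5e4, rho = 0, panel_size = 30, seed = 0) {
  if (any(groups$f <= 0 | groups$f >= 1)) {
    stop("mixing fractions must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  structure(list(groups = tibble::as_tibble(groups), depth = depth, rho = rho,
                 panel_size = panel_size, seed = seed),
            class = c("bulk_sim_config", "list"))
}

#' Simulate overdispersed bulk aCap/gCap marker mixtures
#'
#' For each sample, the aCap-marker read total is drawn beta-binomially
#' around the group's mixing fraction `f` (logit truth = `qlogis(f)`), the
#' gCap total is the remainder of `depth`, and each panel total is spread
#' multinomially across that panel's genes so the result is an ordinary
#' genes x samples count table.
#'
#' @param cfg a [bulk_sim_config()]
#' @return list with `counts` (matrix), `sample_meta` (tibble: `sample`,
#'   `group`), `truth` (tibble: `group`, `f`, `logodds`), `panels` (list
#'   with `aCap` and `gCap` gene vectors) and `config`.
#' @export
sim_bulk_mixture <- function(cfg = bulk_sim_config()) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  set.seed(cfg$seed)
  panels <- list(aCap = sprintf("aCap_mk%02d", seq_len(cfg$panel_size)),
                 gCap = sprintf("gCap_mk%02d", seq_len(cfg$panel_size)))
  rows <- tidyr::uncount(cfg$groups, weights = .data$n_samples)
  n <- nrow(rows)
  p <- if (cfg$rho == 0) rows$f else {
    nu <- 1 / cfg$rho - 1
    stats::rbeta(n, rows$f * nu, (1 - rows$f) * nu)
  }
  a_tot <- stats::rbinom(n, cfg$depth, p)
  g_tot <- cfg$depth - a_tot
  spread <- function(tot, genes) {
    vapply(tot, function(x) stats::rmultinom(1, x, rep(1, length(genes)))[, 1],
           numeric(length(genes)))
  }
  counts <- rbind(spread(a_tot, panels$aCap), spread(g_tot, panels$gCap))
  rownames(counts) <- c(panels$aCap, panels$gCap)
  colnames(counts) <- sprintf("s%02d", seq_len(n))
  list(counts = counts,
       sample_meta = tibble::tibble(sample = colnames(counts),
                                    group = rows$group),
       truth = dplyr::mutate(cfg$groups, logodds = stats::qlogis(.data$f)),
       panels = panels,
       config = cfg)
}

#' Configuration for the bisulfite and methylation-array simulators
#'
#' The default region design plants gene-body regions that are
#' hypomethylated in latent tumor cells relative to sealed proliferative
#' cells, plus unchanged low- and high-methylation controls; coverage
#' defaults to the study's genome-wide mean of 15x.
#'
#' @param regions region tibble (`chrom`, `start`, `end`, `name`, `class`);
#'   built automatically from `prob_table` when `NULL`
#' @param prob_table per-region methylation probabilities: tibble with
#'   `name`, `prob_latent`, `prob_proliferative` and a `truth` label
#' @param cpgs_per_region CpGs placed evenly in each region
#' @param coverage mean per-CpG read coverage (Poisson)
#' @param replicates biological replicates per condition
#' @param n_beads,total_intensity,noise_sd,array_offset bead-array settings:
#'   beads per probe, target A+B+offset intensity, multiplicative
#'   per-bead noise SD, and the beta-value regularizer
#' @param seed RNG seed
#' @return a `meth_sim_config` list
#' @export
meth_sim_config <- function(regions = NULL, prob_table = NULL,
                            cpgs_per_region = 200, coverage = 15,
                            replicates = 4, n_beads = 50,
                            total_intensity = 1100, noise_sd = 0.05,
                            array_offset = 100, seed = 0) {
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  if (is.null(prob_table)) {
    prob_table <- tibble::tibble(
      name = sprintf("gb%03d", seq_len(150)),
      truth = rep(c("hypo", "null_mid", "null_sealed"), c(50, 50, 50)),
      prob_latent = rep(c(0.55, 0.50, 0.80), c(50, 50, 50)),
      prob_proliferative = rep(c(0.75, 0.50, 0.80), c(50, 50, 50)))
  }
  if (any(prob_table$prob_latent < 0 | prob_table$prob_latent > 1 |
          prob_table$prob_proliferative < 0 | prob_table$prob_proliferative > 1)) {
    stop("methylation probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(regions)) {
    width <- cpgs_per_region * 10L
    n <- nrow(prob_table)
    regions <- tibble::tibble(
      chrom = "chr1",
      start = (seq_len(n) - 1L) * (width + 1000L),
      end = (seq_len(n) - 1L) * (width + 1000L) + width,
      name = prob_table$name, class = "gene_body")
  }
  validate_regions(regions)
  structure(list(regions = regions, prob_table = prob_table,
                 cpgs_per_region = cpgs_per_region, coverage = coverage,
                 replicates = replicates, n_beads = n_beads,
                 total_intensity = total_intensity, noise_sd = noise_sd,
                 array_offset = array_offset, seed = seed),
            class = c("meth_sim_config", "list"))
}

#' Simulate bisulfite CpG count tables
#'
#' Per CpG: coverage ~ Poisson(mean coverage), methylated count ~
#' Binomial(coverage, region probability). CpGs are placed evenly inside
#' each region.
#'
#' @param cfg a [meth_sim_config()]
#' @return list with `tables` (nested list: condition -> replicate -> CpG
#'   tibble with `chrom`, `pos0`, `meth`, `total`), `truth`, `regions`,
#'   `config`.
#' @export
sim_bisulfite <- function(cfg = meth_sim_config()) {
  stopifnot(inherits(cfg, "meth_sim_config"))
  set.seed(cfg$seed)
  if (cfg$cpgs_per_region == 0) {
    warning("regions configured with 0 CpGs are emitted empty", call. = FALSE)
  }
  reg <- dplyr::left_join(cfg$regions, cfg$prob_table, by = "name")
  pos <- purrr::pmap(reg, function(chrom, start, end, ...) {
    if (cfg$cpgs_per_region == 0) return(integer(0))
    as.integer(floor(seq(start, end - 1, length.out = cfg$cpgs_per_region)))
  })
  skeleton <- tibble::tibble(
    chrom = rep(reg$chrom, lengths(pos)),
    pos0 = unlist(pos),
    p_latent = rep(reg$prob_latent, lengths(pos)),
    p_proliferative = rep(reg$prob_proliferative, lengths(pos)))
  tables <- list()
  for (cond in c("latent", "proliferative")) {
    pcol <- paste0("p_", cond)
    tables[[cond]] <- lapply(seq_len(cfg$replicates), function(r) {
      total <- stats::rpois(nrow(skeleton), cfg$coverage)
      meth <- stats::rbinom(nrow(skeleton), total, skeleton[[pcol]])
      tibble::tibble(chrom = skeleton$chrom, pos0 = skeleton$pos0,
                     meth = meth, total = total)
    })
    names(tables[[cond]]) <- paste0("rep", seq_len(cfg$replicates))
  }
  list(tables = tables, truth = cfg$prob_table, regions = cfg$regions,
       config = cfg)
}

#' Simulate bead-level methylation-array intensities
#'
#' For a probe with target beta `b` and total intensity `T`, the
#' methylated-allele intensity is `B = b * T` and the unmethylated one
#' `A = T - offset - B`, so that `B / (B + A + offset) = b` exactly;
#' per-bead multiplicative Gaussian noise is then applied to both channels.
#' Both color channels are generated at the same target.
#'
#' @param cfg a [meth_sim_config()]; targets are taken from
#'   `cfg$prob_table` (`prob_latent` for group `latent`,
#'   `prob_proliferative` for group `proliferative`, interpreted as betas)
#' @return list with `beads` (tibble: `probe`, `group`, `bead`, `grn_a`,
#'   `grn_b`, `red_a`, `red_b`), `truth`, `config`.
#' @export
sim_array <- function(cfg = meth_sim_config()) {
  stopifnot(inherits(cfg, "meth_sim_config"))
  set.seed(cfg$seed + 1L)
  off <- cfg$array_offset
  tot <- cfg$total_intensity
  targets <- tidyr::pivot_longer(
    cfg$prob_table, cols = c("prob_latent", "prob_proliferative"),
    names_to = "group", values_to = "beta",
    names_prefix = "prob_")
  if (any(targets$beta >= 1)) {
    stop("target beta >= 1 is unreachable under the +", off, " offset",
         call. = FALSE)
  }
  if (any(targets$beta > (tot - off) / tot)) {
    stop("target beta exceeds (total - offset)/total; raise total_intensity",
         call. = FALSE)
  }
  b_int <- targets$beta * tot
  a_int <- tot - off - b_int
  n <- nrow(targets)
  noise <- function() matrix(pmax(0, 1 + stats::rnorm(n * cfg$n_beads, 0,
                                                      cfg$noise_sd)),
                             nrow = n)
  beads <- tibble::tibble(
    probe = rep(targets$name, each = cfg$n_beads),
    group = rep(targets$group, each = cfg$n_beads),
    bead = rep(seq_len(cfg$n_beads), times = n),
    grn_a = as.vector(t(a_int * noise())),
    grn_b = as.vector(t(b_int * noise())),
    red_a = as.vector(t(a_int * noise())),
    red_b = as.vector(t(b_int * noise())))
  list(beads = beads,
       truth = dplyr::rename(targets, beta_target = "beta"),
       config = cfg)
}

#' Build a ligand-receptor table with planted and decoy pairs
#'
#' Planted pairs couple the simulator's trajectory-defining tumor-cell
#' ligands to endothelial receptors that are expressed in the EC
#' populations; decoy pairs couple differentially expressed tumor-cell
#' genes to partners whose expression is forced to zero in every EC
#' population, so a correct screen must discard them at the
#' partner-expression step. Duplicate pairs are stored once.
#'
#' @param sc_sim output of [sim_sc_counts()]
#' @param planted ligand gene ids to plant (default: the simulator's
#'   ligand block); must exist in the simulated gene universe
#' @return list with `db` (interaction tibble) and `truth` (tibble:
#'   `gene`, `partner`, `status` in planted/decoy).
#' @export
sim_interaction_truth <- function(sc_sim, planted = NULL) {
  blocks <- split(sc_sim$gene_truth$gene_id, sc_sim$gene_truth$block)
  if (is.null(planted)) planted <- blocks$ligand
  missing <- setdiff(planted, sc_sim$gene_truth$gene_id)
  if (length(missing)) {
    stop("planted gene(s) absent from the simulated universe: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  planted <- unique(planted)
  receptors <- rep_len(blocks$receptor, length(planted))
  db <- tibble::tibble(
    partner_a = c(planted, blocks$decoy_tc),
    partner_b = c(receptors, blocks$decoy_ec),
    role_a = "ligand", role_b = "receptor")
  truth <- tibble::tibble(
    gene = c(planted, blocks$decoy_tc),
    partner = c(receptors, blocks$decoy_ec),
    status = rep(c("planted", "decoy"), c(length(planted),
                                          length(blocks$decoy_tc))))
  list(db = validate_interactions(db), truth = truth)
}

#' Simulate a multi-type bulk design for marker derivation
#'
#' Emulates the replicate-level bulk RNA-seq design behind the all-vs-all
#' marker rule: `n_types` sample types with `n_replicates` each, a set of
#' planted type-specific markers per type (boosted `fold`-fold in exactly
#' one type), planted *shared* genes boosted in exactly two types (they
#' gather enough supports but fail specificity) and planted *weak* genes
#' boosted in four of six types (at most two supporting comparisons), on
#' a background of null genes. Dispersion defaults to a bulk-like 0.01.
#'
#' @param n_types number of sample types (default 6)
#' @param n_replicates replicates per type (default 6)
#' @param n_markers planted specific markers per type (default 5)
#' @param n_shared,n_weak planted shared and weak genes (defaults 12 each)
#' @param n_null background null genes (default 150)
#' @param mu baseline NB mean (default 100)
#' @param dispersion NB dispersion alpha (default 0.01)
#' @param fold boost applied to planted genes (default 4)
#' @param seed RNG seed
#' @return list with `counts` (genes x samples), `sample_meta` (tibble:
#'   `sample`, `group`), `truth` (tibble: `gene`, `status`, `marker_of`).
#' @export
sim_marker_design <- function(n_types = 6, n_replicates = 6, n_markers = 5,
                              n_shared = 12, n_weak = 12, n_null = 150,
                              mu = 100, dispersion = 0.01, fold = 4,
                              seed = 0) {
  stopifnot(n_types >= 3)
  set.seed(seed)
  types <- paste0("T", seq_len(n_types))
  n_genes <- n_types * n_markers + n_shared + n_weak + n_null
  mu_mat <- matrix(mu, n_genes, n_types,
                   dimnames = list(sprintf("g%04d", seq_len(n_genes)), types))
  truth <- tibble::tibble(gene = rownames(mu_mat),
                          status = "null", marker_of = NA_character_)
  row <- 0
  for (i in seq_len(n_types)) {
    idx <- row + seq_len(n_markers); row <- row + n_markers
    mu_mat[idx, i] <- mu * fold
    truth$status[idx] <- "marker"; truth$marker_of[idx] <- types[i]
  }
  for (j in seq_len(n_shared)) {
    row <- row + 1
    pair <- ((j - 1 + 0:1) %% n_types) + 1
    mu_mat[row, pair] <- mu * fold
    truth$status[row] <- "shared"
  }
  for (j in seq_len(n_weak)) {
    row <- row + 1
    high <- (((j - 1) + 0:3) %% n_types) + 1   # high in 4 types
    mu_mat[row, high] <- mu * fold
    truth$status[row] <- "weak"
  }
  counts <- do.call(cbind, lapply(seq_len(n_types), function(i) {
    matrix(stats::rnbinom(n_genes * n_replicates,
                          mu = rep(mu_mat[, i], n_replicates),
                          size = 1 / dispersion), nrow = n_genes)
  }))
  rownames(counts) <- rownames(mu_mat)
  colnames(counts) <- paste0(rep(types, each = n_replicates), "_r",
                             seq_len(n_replicates))
  list(counts = counts,
       sample_meta = tibble::tibble(sample = colnames(counts),
                                    group = rep(types, each = n_replicates)),
       truth = truth)
}

#' Simulate a two-group negative-binomial count table
#'
#' Small direct generator used for differential-expression calibration and
#' power checks: `n_genes` NB genes across two groups, with an optional set
#' of planted log2 fold changes applied to group A.
#'
#' @param n_genes number of genes
#' @param n_per_group length-2 vector of samples in groups A and B
#' @param mu baseline NB mean (scalar or per-gene vector)
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2)
#' @param lfc_genes indices of genes given a fold change in group A
#' @param lfc log2 fold change applied to `lfc_genes`
#' @param seed RNG seed
#' @return list with `counts` (genes x samples matrix), `group` (factor),
#'   `truth_lfc` (per-gene planted log2 fold change).
#' @export
sim_group_counts <- function(n_genes, n_per_group = c(4, 4), mu = 100,
                             dispersion = 0.1, lfc_genes = integer(0),
                             lfc = 0, seed = 0) {
  set.seed(seed)
  mu <- rep_len(mu, n_genes)
  truth <- numeric(n_genes)
  truth[lfc_genes] <- lfc
  mu_a <- mu * 2^truth
  n <- sum(n_per_group)
  draw <- function(m, k) {
    matrix(stats::rnbinom(n_genes * k, mu = rep(m, k),
                          size = rep(1 / dispersion, n_genes * k)),
           nrow = n_genes)
  }
  counts <- cbind(draw(mu_a, n_per_group[1]), draw(mu, n_per_group[2]))
  rownames(counts) <- sprintf("g%05d", seq_len(n_genes))
  colnames(counts) <- sprintf("s%02d", seq_len(n))
  list(counts = counts,
       group = factor(rep(c("A", "B"), n_per_group), levels = c("A", "B")),
       truth_lfc = truth)
}
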