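---
title: "Methods: models, thresholds and design choices in nichefates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in nichefates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nichefates` implements the computational pipeline for mapping
metastasizing tumor-cell (mTC) fates in the lung vascular niche: after
arrest in the lung capillaries, tumor cells either proliferate
intravascularly or extravasate into latency, a bifurcation driven by
endothelial Wnt signals and gated by the tumor cells' methylation state.
This vignette documents the models behind each stage, every tunable
parameter with its default and rationale, what the synthetic-data
generators emulate (and what they do not), and the numerical and design
choices made where the procedure left room for interpretation.

```{r setup}
library(nichefates)
```

## Normalization and quality control

Cells are normalized to the mean raw expression of a housekeeping panel
(`housekeeping_panel()`: *Actb*, *Gapdh*, *Tubb5*, *Ppia*, *Ywhaz*,
*B2m*, *Pgk1*, *Tbo*, *Arbp*, *Gusb*, *Hprt1*), scaled by 10,000 and
log10-transformed:

$$v_{gc} = \log_{10}\!\left(1 + 10^4\,\frac{x_{gc}}{\overline{x}^{\,\mathrm{hk}}_c}\right).$$

Two numerical choices are worth stating. First, the pseudocount of 1
inside the logarithm: the transform must map zero counts to zero, and a
pseudocount of 1 on the scaled ratio is the smallest choice that does so
while keeping values non-negative. Second, the panel mean is taken over
*all* panel genes present in the matrix, zeros included — dropping
undetected panel genes would make the denominator depend on per-cell
detection and break the transform's invariance to sequencing depth
(multiplying a cell's counts by any $k > 0$ leaves its normalized column
unchanged, a property the test suite asserts). A cell whose panel mean is
zero cannot be normalized and is reported by name as an error rather than
silently dropped.

QC thresholds are applied with strict inequalities exactly as printed in
the underlying protocol: endothelial cells (ECs) are *excluded* at
mitochondrial fraction > 5% **or** < 1,000 detected genes, while tumor
cells (TCs) are *retained* at < 5% **and** > 2,500 genes. The two rules
are deliberately not symmetric: a cell sitting exactly on a boundary
survives the EC rule but fails the TC rule. "Detected" means raw count
> 0; no more elaborate detection rule is used. Mitochondrial genes are
flagged by a configurable, case-insensitive identifier prefix (default
`"mt-"`) since gene identifiers are treated as opaque strings.

## Gene-module scoring

`module_score()` scores a cell for a gene program as the mean normalized
expression of the program genes minus the mean of a pooled control list.
Genes are ranked by mean expression across cells and cut into `n_bins`
near-equal bins (default 24, the referenced scoring method's default);
for each program gene, `n_ctrl` (default 100) control genes are drawn
uniformly *without replacement from that gene's bin*, and the draws are
pooled *with repeats across program genes* — so a bin shared by several
program genes contributes more weight to the control mean, mirroring the
per-gene matching logic. The draw is governed by an explicit seed and is
bit-reproducible. When the matrix has fewer genes than bins the bin count
is reduced with a warning; controls may include the program gene itself
(no exclusion is applied, matching the referenced implementation).

The implementation is checked against a brute-force oracle — explicit
loops re-deriving bins, controls and per-cell means — to 1e-10, and
against a null construction (program genes identical to their bin's
genes) where scores are exactly zero.

## Endothelial subtypes and cell-cycle gating

EC subtype calls threshold four module scores with strict inequalities:
large-vessel score > 1; cycling score > 0.5; aerocytes at aCap > 0 and
gCap < 0; general capillaries at aCap < 0 and gCap > −0.5. The rules are
applied in that fixed order — the order in which they are stated — because
a cell can satisfy several (e.g. a large-vessel cell with a high cycling
score); first-match precedence makes the classifier a total function.
Cells matching no rule are labeled `Unclassified` and retained rather
than dropped, since downstream marker panels only consume labeled
subtypes. A score exactly at a threshold fails it.

Cell-cycle state uses 43 S-phase and 54 G2/M genes scored separately; the
per-cell *score sum* gates the tumor-cell partition: latent-gate cells
with sum < −1 are *bona fide latent*, proliferative-gate cells with
sum > 0 are selected; everything else is excluded, making the two sets
disjoint by construction. For the latent-vs-proliferative differential
comparison, cell-cycle regression is approximated by removing the S and
G2M set genes from the tested gene universe; this is a documented
substitute for an unspecified regression model, not a claim of
equivalence — it controls the direct contribution of cycle genes to the
DEG list but not indirect correlates of cycling.

## Contaminant removal

Contaminating cells are flagged by detected expression (raw count > 0) of
markers from a contaminant set (`contaminant_sets()`: immune — *Ptprc*,
*Itgam*, *Itgax*, *Adgre1*, *Cd3e*, *Cd19*, *Cd56*; stromal/mural —
*Pdgfrb*, *Des*, *Myh11*, *Col1a2*, *Pdgfra*, *Cspg4*, *Pdpn*, *Acta2*).
The quantitative cutoff is a package decision: a cell is removed when it
detects **at least 2** markers of any single set (`min_positive_genes`,
configurable). One detected marker is tolerated because single-marker
detection at single-cell depth is compatible with ambient RNA; two
independent markers of the same lineage are not.

## Differential expression

Two engines are provided behind one table format (`gene`, `log2fc`, `p`,
`padj`, detection fractions, `significant`).

**Wilcoxon rank-sum** (single-cell comparisons): two-sided, with exact
enumeration when the combined sample size is ≤ 10 and the gene is
tie-free, otherwise a normal approximation with tie-corrected variance
and continuity correction. The continuity correction is used because the
two branches then agree within 0.02 on tie-free data at n = 8 vs 8,
which the suite asserts; without it the mid-range disagreement reaches
~0.05. Constant genes get p = 1 and log2fc = 0. Significance defaults to
raw p < 0.01 and |log2FC| > 0.5 — raw rather than adjusted p, following
the stated single-cell DEG rule; a `sig_on = "padj"` switch is provided.
Fold changes are `log2((mean_a + eps)/(mean_b + eps))` with
`eps = 1e-9` on the normalized scale; the pseudocount only matters for
all-zero groups.

**Negative-binomial Wald** (pseudobulk, replicate-level): a deliberately
simplified engine in the DESeq2 mold — median-of-ratios size factors
(over genes positive in every sample); gene-wise method-of-moments
dispersion on normalized counts, $\alpha_g = \max((s^2_g - \bar\mu_g) /
\bar\mu_g^2,\ 10^{-8})$ with within-group residual variance; a per-gene
NB log-linear model with a group coefficient fitted by IRLS with the
size factors as offsets; Wald p from coefficient over standard error;
BH adjustment. There is **no** dispersion shrinkage, no fold-change
shrinkage and no outlier replacement: this is an approximation whose
acceptance is defined on simulations (null call rate, power, fold-change
bias), not on matching any reference tool bit for bit. The practical
consequence of skipping shrinkage is anticonservative raw p values at
few replicates; the calibration tests therefore check the BH-adjusted
call rate, and the marker-derivation design (below) is chosen so that
the fold-change threshold, not raw-p calibration, carries the
specificity burden. All-zero genes are excluded from testing and
reported as untested.

`bh_adjust()` wraps the standard step-up procedure; `ddct_fold_change()`
implements ΔCt → ΔΔCt (centered on the control-sample mean) → $2^{-\Delta\Delta Ct}$,
so the geometric mean of control fold changes is exactly 1.

## Marker panels and quasibinomial deconvolution

The all-vs-all marker rule: with six sample types and all 15 pairwise
DGE tables, a gene is a marker of type X iff it is significantly
upregulated for X (p < 0.01, log2FC > 0.5) in at least 3 of X's 5
comparisons **and** is not significantly upregulated for any other type
in any comparison. The type roster is an argument, not hard-coded, and a
missing pair table is an error naming the pair. Panels are disjoint
across types by construction.

Temporally stable aCap/gCap panels additionally require significance
with the same sign at *every* time point and detection in ≥ 25% of the
subtype's cells at every time point (`min_pct = 0.25`) — the detection
requirement operationalizes "robust" expression and is configurable.

Deconvolution treats each bulk sample's summed aCap-marker counts as
binomial successes against the summed gCap-marker counts:
$\theta_s = \ln(\Sigma_a/\Sigma_g)$, invariant to sequencing depth. Per
group, an intercept-only quasibinomial logit fit pools the samples: the
estimate is the logit of the pooled proportion and the binomial standard
error is inflated by $\sqrt{\varphi}$ with $\varphi$ the group's Pearson
dispersion; the 95% CI is $\pm 1.96\,\mathrm{SE}$. The grouping (one fit
per experimental group) and the Pearson-dispersion estimator are package
choices following standard quasi-likelihood practice; an empirical
across-sample CI is reported alongside, with the quasibinomial one
primary. Samples with zero counts on either panel are excluded with a
warning; a group of size one gets $\varphi = 1$ with a warning.
Normalization to the control subtracts the control's log-odds (a ratio
of odds ratios), converts to log2 and exponentiates for plotting; the
control's own normalized ratio is exactly 0 with a zero-width interval
by construction, and other groups combine the two standard errors in
quadrature.

## The ligand–receptor trajectory screen

Tumor-cell pseudobulks (replicate × FACS gate) are compared
extravascular-vs-intravascular and latent-vs-proliferative with the NB
engine. Genes significant in at least one comparison are intersected
with a partner database (symmetric lookup; heteromeric entries should be
pre-expanded to pairwise subunits). A candidate is then retained only if
at least one partner is detected in ≥ 10% of endothelial cells at the
comparison-matched time point (day 1.5 for the intravascular comparison,
day 3.5 for the latent one); 10% is a package quantification of
"expressed in the EC dataset" and is configurable, and "at least one
partner" (rather than all) is the deliberate reading, with per-time-point
flags exposed per candidate. Categories (`both`, `latent_only`,
`intra_extra_only`, `none`) partition candidates by the two significance
flags; the quadrant depends only on the fold-change signs; and
*trajectory-defining* means significant in both with concordant sign.
Supervised re-analysis of a fixed gene list (e.g. Wnt receptors) uses
`restrict_genes`, bypassing the DEG filter while keeping significance
annotation.

## Methylation

Bisulfite replicates are pooled by summing methylated and total counts
per CpG; region fractions are coverage-weighted,
$\Sigma\,\mathrm{meth}/\Sigma\,\mathrm{total}$ over the member CpGs,
rather than means of per-CpG fractions — the weighted form is the
variance-optimal estimator and commutes with replicate pooling, an
identity the suite checks exactly on integer fixtures. Coordinates are
0-based half-open internally; BED input is taken as already half-open
and Bismark coverage (1-based inclusive) is shifted on read, with the
round trip asserted as an involution. A CpG at a region's end coordinate
is outside it. A minimum per-CpG coverage filter (default total ≥ 1,
configurable) is applied before aggregation. Overlapping regions are
allowed and a CpG may count toward several.

Differential calls use the strict 10% threshold: `hypo` when the
proliferative fraction exceeds the latent one by more than 0.10, `hyper`
for the reverse, `unchanged` otherwise, with NA propagation. The
*sealed* flag is strictly > 0.70 proliferative methylation. Gene-set
over-representation of hypomethylated genes is a one-sided
hypergeometric tail within a caller-supplied universe, BH-adjusted
across terms.

Methylation-array beta values are computed per color channel on
bead-aggregated intensities, $\beta = B/(B + A + 100)$; the +100 offset
regularizes low intensities and bounds $\beta$ in $[0, 1)$. M-values are
$\log_2((\beta_B + 1)/(\beta_A + 1))$, bounded in $[-1, 1]$. The
bead-level test interprets the "two p values, minimum of both" rule as
one two-sample t-test per color channel's bead-level beta series with
the probe p the minimum of the two — the underlying description (probe
variants A and B as independent variables) is ambiguous, so both
component p values are also emitted. Within-channel quantile
normalization across sample groups is available and toggleable
(`quantile_normalize_beads()`); raw intensities are the default.

## The synthetic-data generators

The generators exist so every stage is testable against planted truth;
their defaults *are* the study conditions the tests assume.

`sim_sc_counts()` draws negative-binomial counts (variance
$\mu + \alpha\mu^2$; $\alpha$ = 0.1 for EC populations and 0.3 for TC
populations, typical single-cell overdispersion) for nine populations:
the four EC subtypes across days 0/1.5/3.5, the four TC FACS gates
(intravascular/extravascular at day 1.5, latent/proliferative at day
3.5), and an immune contaminant population. Planted structure: 40-gene
subtype marker blocks at baseline mean 2 boosted ×24 in their own
subtype; the S+G2M union boosted ×12 in cycling ECs; S/G2M at baseline
mean 4, ×4 in proliferative and ×0.25 in latent TCs (dormant cells
downregulate cycle genes — this is what places the latent gate's score
sums below −1 and the proliferative gate's above 0); Wnt/EMT/ligand
blocks ×4 in extravascular and latent TCs; the housekeeping panel at
mean 50 with dispersion 0.05; mitochondrial fractions per cell from
Beta(2, 60) (mean ≈ 3%, a realistic tail above the 5% QC cut). The
marker-block magnitudes were settled once, by checking that module-score
distributions sit clear of the strict classification boundaries
("well-separated scores"); weaker settings leave single cells within
score noise of a boundary, and the thresholds themselves are never
moved. Decoy ligand–receptor pairs couple genuinely differential TC
genes to partners with zero expression in every EC population, so a
correct screen must remove them at the partner-expression step, not
before.

`sim_bulk_mixture()` plants a group-level aCap mixing fraction `f` and
draws each sample's aCap-marker total beta-binomially
(overdispersion ρ) at depth 50,000, then spreads panel totals
multinomially across panel genes — the deconvolution statistic consumes
only panel sums, so per-gene realism is not needed. Defaults encode a
control at f = 0.429 (odds 0.75) and a treated group at f = 0.6 (odds
1.5), i.e. a planted control-normalized log2 odds ratio of 1.

`sim_bisulfite()` places 200 CpGs per region, Poisson coverage at the
study's genome-wide mean of 15×, binomial methylated counts at the
region probability, 4 replicates per condition; the default design
plants 50 hypomethylated gene-body regions (0.55 vs 0.75), 50
mid-methylation nulls and 50 sealed nulls (0.80). `sim_array()` inverts
the beta formula exactly — $B = \beta T$, $A = T - 100 - B$ at total
intensity $T = 1100$ — and applies 5% multiplicative bead noise, 50
beads per probe.

`sim_marker_design()` emulates the replicate-level bulk design behind
the marker rule: 6 types × 6 replicates, bulk-like dispersion 0.01,
baseline mean 100, planted ×4 type-specific markers plus *shared* genes
(high in exactly two types: enough supports, fails specificity) and
*weak* genes (high in four types: at most two supports). At these
settings the null log2 fold-change standard deviation is ≈ 0.12, so a
spurious up-call — which requires log2FC > 0.5 *and* p < 0.01 — has
probability ~1e-5 per test and exact recovery of the planted panel is
the expected outcome. With single-cell dispersions and fewer replicates
exact recovery is not attainable under these thresholds: fold-change
noise alone produces about one spurious exclusion per run, which is why
the design mirrors bulk data.

What the generators do **not** emulate: doublets, ambient RNA,
batch effects, gene–gene correlation beyond block structure, per-CpG
coverage dependence, dye bias, or realistic marker co-expression
gradients. Tests passing on these simulations therefore demonstrate the
*statistical machinery* — calibration, recovery, invariances, threshold
logic — not robustness to every artifact of real data.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed; scoring is
bit-reproducible under a fixed seed. The calibration and recovery checks
use: 10,000 tie-free null genes at n = 5 vs 5 for rank-sum type-I error
(the exact test's attainable level just below 0.01 is 2/252 ≈ 0.0079, a
discreteness worth remembering when reading the observed rate); 5,000
null and 2,000 power genes for the NB engine; 500 simulations for
deconvolution bias, 200 for CI coverage, 25 per planted fraction for
monotonicity; the default single-cell configuration (~1,570 cells ×
4,000 genes) for classification and the screen; and 150 regions × 200
CpGs for methylation. These sizes keep each property estimate's Monte
Carlo error well inside the margin being asserted, and a full run of
`scripts/acceptance.R` completes in well under a minute on one CPU.

## Known limitations

* The NB-Wald engine's raw p values are anticonservative at small
  replicate numbers (no dispersion shrinkage); use the BH-adjusted
  column, or the Wilcoxon engine, when raw-p calibration matters.
* Cell-cycle "regression" is gene-set exclusion, as discussed above.
* The quasibinomial CI uses a normal 1.96 quantile; at very small group
  sizes a t-quantile would be wider, and the empirical CI is reported
  for comparison.
* `classify_ec()` precedence resolves multi-rule cells in stated order;
  cells near several boundaries are sensitive to that choice.
* Heteromeric interaction complexes must be supplied pre-expanded to
  pairwise partners.
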