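---
title: "Methods: core and stress-specific gene discovery with corestress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core and stress-specific gene discovery with corestress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corestress)
```

# The problem

Plants facing drought, heat, cold, salt, flooding or nitrogen starvation
mount responses that partly overlap: oxidative-stress mitigation, osmolyte
accumulation, hormone signalling and large transcriptional reprogramming.
A *core* stress-responsive gene is one that responds under every stressor; a
*stress-specific* gene responds under exactly one. Identifying both from a
heterogeneous compendium of public RNA-seq experiments is a meta-analysis
problem: experiments (BioProjects) differ in platform, tissue, genotype and
growth conditions, so per-experiment contrasts and explicit batch handling
are essential.

`corestress` implements that meta-analysis as a reusable, fully tested
pipeline over a genes x samples TPM matrix plus sample metadata (BioProject,
treatment, tissue, genotype). Two complementary routes define core genes:

1. **Set operations on TN-ratios.** Within each experiment, the ratio
   (mean stressed TPM + 1) / (mean control TPM + 1) calls a gene up
   (ratio > 2) or down (ratio < 0.5). Per stressor, directional sets are the
   union over that stressor's experiments; core sets are the intersection
   across all stressors; specific sets are genes differentially expressed
   under exactly one stressor.
2. **Hold-one-stressor-out random forests.** A binary stressed/control
   classifier is trained on all samples except those from one stressor's
   BioProjects (which form the test set), repeated for every stressor. If a
   core transcriptome exists, a model never shown, say, salt stress can
   still classify salt-stressed samples. Genes ranked in the top slice of
   impurity importance in *all* models form the random-forest core set.

Downstream, the package characterizes these sets with weighted
co-expression modules and kME hub genes, one-sided Fisher/FDR enrichment
(TFs overall, TF families, arbitrary annotation terms, modules), and a
GENIE3-style regulatory network whose mean edge weights per gene class are
compared by a repeated Dunnett test.

# The synthetic compendium

Because the real compendium (~1,900 SRA samples) is neither shippable nor
needed for testing the *method*, `generate_compendium()` builds compendia
with known ground truth. On the log2 scale, gene g in sample s is

$$
y_{gs} = b_g + \tau_{gs} + u_{gs} + \gamma_{b(s)} + \delta_{b(s)}\,
\sigma \varepsilon_{gs},
$$

* $b_g \sim N(5, 2)$: baseline log2 abundance, giving the familiar
  heavy-tailed TPM range without modelling counts (the pipeline consumes
  TPM, not counts, so log-normal noise replaces a negative binomial).
* $\tau_{gs}$: planted treatment effects. Core-up genes gain
  $\log_2(\mathrm{fc})$ in every stressed sample, core-down genes lose it;
  specific genes only in stressed samples of their own stressor (by
  default in all of that stressor's BioProjects, configurable down to one).
* $u_{gs}$: latent structure — each TF carries a per-sample activity
  ($\mathrm{sd}=1$ log2 unit) copied into its targets with weight
  `tf_regulation_strength`; co-expression blocks share a latent factor.
  These create the correlation structure the GRN and module stages must
  recover, and they are switched off (sd 0) alongside noise when testing
  the fully degenerate configuration.
* $\gamma_b \sim N(0, \texttt{batch\_shift\_sd})$ and
  $\delta_b = e^{N(0,\, \texttt{batch\_scale\_sd})}$: per-BioProject
  location shift and noise scaling. Applying the scale to the *deviation*
  rather than the mean makes the planted distortion exactly the
  location/scale model that parametric empirical-Bayes batch adjustment
  assumes, so batch-correction tests are sharp.
* $\sigma = \sqrt{\ln(1 + \mathrm{CV}^2)}/\ln 2$ converts the biological
  coefficient of variation into log2 noise sd.

Default conditions — 2,000 genes, six stressors x three BioProjects x
(6 + 6) samples, 4-fold core and specific effects, noise CV 0.2, batch
shift sd 1, batch scale sd 0.2 — are the reference conditions every
simulation-based check runs under. The stressor count and the three
independent experiments per stressor mirror the curation rule of the
motivating meta-analysis design; the noise and batch magnitudes are not
measurable from any published quantity, so they were fixed once at values a
bulk RNA-seq practitioner would call realistic (between-batch shifts
comparable to treatment effects, within-group CV of 20%) and are not
revisited.

What the generator deliberately does *not* emulate: read-level artefacts,
isoform structure, count-based mean-variance coupling, tissue- and
developmental-stage gradients (a two-tissue additive separation is the only
tissue option), genotype effects, and correlated DE among non-planted
genes. Passing recovery tests therefore demonstrates the pipeline is
correct under its own model class; it does not certify performance on real
compendia, where effect sizes are smaller and batch structure is messier.

# Preprocessing

TPM are log2(x + 1) transformed; genes with zero variance across samples
are removed; per-BioProject batch effects are adjusted with parametric
empirical-Bayes ComBat (location and scale, no covariates — only the batch
label is modelled, keeping the model identifiable without treatment
labels). A single-batch input is returned unchanged. PCA is centred but not
scaled (the inputs are already on a common log scale); component signs are
fixed by making the largest-magnitude loading positive. Gene-wise z-scores
divide by the *population* standard deviation (denominator n, the
StandardScaler convention), which makes z-scoring idempotent; the
per-treatment dendrogram averages the z-scored profiles per treatment and
clusters them with Euclidean distance and average linkage (both
configurable — the choice is a convention, not a result).

Note one empirical subtlety established during testing: after EB
adjustment, gene-wise between-batch *variance* ratios centre tightly on 1
but retain a sampling-noise residual (95% of genes within roughly
[0.7, 1.4] at 50 samples/batch), because the scale parameters are shrunk
toward a pooled prior rather than matched per gene. Location differences,
in contrast, shrink by well over an order of magnitude.

# TN-ratio calls and set operations

TN-ratios are computed on raw TPM: the ratio is within-experiment, so
additive batch effects cancel, and the +1 pseudocount keeps it finite and
positive at zero expression. Thresholds are strict inequalities (a ratio of
exactly 2 is *not* called up). Experiments with several stress treatments
are split into one (BioProject, stressor) contrast each; multiple
timepoints or severities within one experiment are pooled into a single
stressed group. A gene called up in one experiment and down in another of
the same stressor legitimately enters both directional sets — the union
semantics are documented rather than silently resolved. The per-stressor
union requires membership in at least one experiment by default
(`min_experiments` exposes the stricter option).

# Random-forest core genes

For each held-out stressor, all samples of that stressor's BioProjects
(stressed *and* their controls) form the test set; everything else trains.
Class imbalance in the training set is corrected by SMOTE (synthetic
minority points interpolated between k = 5 nearest minority neighbours),
applied inside each cross-validation fold and again on the full training
set before the final fit — never to test data. Hyperparameters
(bootstrapping, tree depth, feature fraction, leaf and split sizes, tree
count) are chosen by a seeded randomized search with stratified 3-fold
cross-validation on AUC; an exhaustive grid across six models is not
worth its cost when the search space plateaus.

Two numerical choices matter:

* **Importance stability.** Held-out AUC saturates long before impurity
  importance *ranks* do. The final model is therefore regrown with at least
  `importance_num_trees` (default 1,000) trees before importances are
  extracted; at the tuned 100-300 trees the six top-k sets are noisy enough
  that their intersection loses most planted core genes, while at 1,000
  trees recovery is essentially perfect under the reference conditions.
* **Rank ties.** The top-k cut sorts by decreasing importance with ties
  broken by gene id, so the core intersection is deterministic.

The feature-selection curve refits the model on the top-X genes for a
ladder of subset sizes (default 50 ... 15,000) and reports the smallest X
whose AUC is within 0.01 of the best over sizes — the tolerance
operationalizes "optimum performance with the smallest subset", which is
otherwise underdetermined. At synthetic scale, top_k is set to three times
the planted signal count, since an absolute 6,000 only makes sense against
a ~40k-gene genome.

# Co-expression modules and hubs

The network is unsigned: adjacency $|\mathrm{cor}|^\beta$ with soft power
$\beta = 9$ by default (a signed variant is available; module membership
uses the signed kME convention regardless). Genes are clustered by
average-linkage on topological-overlap dissimilarity and the tree is cut
statically at 99% of its height; branches of at least `min_module_size`
(default 20) genes become modules M1, M2, ... by decreasing size, and
everything else — including all genes in degenerate, all-noise inputs — is
labelled M0. No eigengene-merging step is applied. Module eigengenes are
the first principal component of the module's gene-standardized expression,
oriented to correlate positively with the module mean profile; kME is the
Pearson correlation of each gene with each eigengene. Hub genes are those
whose own-module |kME| strictly exceeds the 95th percentile (type-7, linear
interpolation — percentile definitions differ across software, so the
convention is fixed and tested) taken over all assigned genes. Module x
gene-set overlaps use the same one-sided Fisher machinery as every other
enrichment, FDR-corrected across modules.

# Enrichment statistics

All overlap tests are one-sided (greater) Fisher exact tests; the p-value
is the upper hypergeometric tail and the reported odds ratio is the sample
odds ratio (ad)/(bc). The "classic" per-term algorithm is used for
annotation terms: each term tested independently against a caller-supplied,
pre-propagated gene-to-term map — no ontology-graph decorrelation. The
universe defaults to all genes present after zero-variance filtering.
Benjamini-Hochberg correction is applied within one logical battery (all
families for one gene set; all terms for one set; all modules for one set);
the pooled all-TF test is corrected separately from the family tests.
q < 0.05 is "enriched" and 0.05 <= q < 0.1 "near-enriched", the secondary
reporting band. Up- and downregulated sets are always tested separately.
Because the test is discrete, its attained level sits just below the
nominal 5%; calibration tests compare simulated rejection rates against the
exactly computed attained level rather than the nominal one.

# Regulatory network and repeated Dunnett comparisons

For every target gene, a random-forest regression of its (batch-corrected,
log2) expression on all TF profiles yields impurity importances as edge
weights, normalized per target to sum to 1. By default every regulator is a
split candidate (`mtry = "all"`): with modest TF panels, restricting each
split to $\sqrt{p}$ regulators lets competitors accrue chance importance
and blurs single-regulator dominance; `"sqrt"` remains available for large
catalogs where decorrelation and speed matter more.

The question "do focal TFs regulate class X more strongly than background
genes?" is answered on per-target mean incoming weights from the focal TFs,
compared across classes (core, one class per stressor-specific set, and
"other" as control) with Dunnett's many-to-one test: pooled equal-variance
estimate, two-sided family-wise p-values from the multivariate-t
distribution of the contrasts. That distribution always has one-factor
correlation $\rho_{ij} = \lambda_i\lambda_j$, so it is evaluated by a
deterministic Gauss-Legendre double quadrature (64 nodes over the shared
normal factor, 32 over the pooled-variance chi scale; absolute error below
1e-4, cross-checked against quasi-Monte-Carlo integration), with the
closed-form t distribution in the single-contrast case.

Dunnett's test on fixed data is deterministic, so "repeat it 5,000 times"
requires a resampling scheme; the package bootstrap-resamples targets
within each class (with replacement, original class sizes) per repetition —
refitting the network thousands of times would be the alternative reading
and is computationally out of reach. A comparison is significant when the
97.5th percentile of its bootstrap p-value distribution falls below 0.05;
the stricter of the two readings of "the 97.5% confidence interval is less
than 0.05". The result always carries the sign of the mean difference,
since a class can be *significantly less* regulated than background. Under
a null with exchangeable classes this rule fires in well under 5% of
replicates; under a 3-pooled-sd shift it fires essentially always.

# Pipeline, seeds and problem sizes

`run_pipeline()` executes preprocess, set-ops DE, random forest,
co-expression, enrichment and GRN in dependency order from one
configuration (R list or YAML), writing TSV/JSON artifacts plus a
provenance record (parameters, derived seed, input MD5 checksums) per
stage. One global seed fans out to per-stage seeds through a label hash
(`derive_seed()`), so any stage can be reproduced in isolation; every stage
rerun with the same configuration writes byte-identical outputs.

Tests and the acceptance script run at deliberately compact sizes chosen to
exercise every code path with comfortable margins: the reference compendium
(2,000 genes, 216 samples) for recovery checks; 60-gene two-block models
for module recovery; a 20-TF / 200-target network for edge recovery; 500
bootstrap repetitions and 200 targets per class for Dunnett calibration;
exhaustive enumeration of all 2x2 tables with n <= 60 for Fisher
exactness. These sizes are the package's own test design; scaling any of
them up only tightens the same statistics.

# Known limitations

* TN-ratio calls are threshold rules without replicate-aware inference; no
  per-gene p-values are produced, by design.
* The module detector is a static-height tree cut, not the full dynamic
  hybrid algorithm; on data with nested or weakly separated modules it will
  be more conservative (more M0) than WGCNA's default.
* The GRN stage infers association-based directionality only; edge weights
  are not causal effects, and the Dunnett comparison inherits whatever
  biases the importance estimates carry.
* The repeated-Dunnett bootstrap quantifies sampling variability of the
  class comparison given one inferred network, not variability of the
  network inference itself (`reseed-grn`-style refitting is out of scope).
* Recovery guarantees are with respect to the generator's model class; real
  compendia violate it in the ways listed above.
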