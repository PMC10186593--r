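---
title: "Models and methods behind stemtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stemtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stemtraj quantifies how aging — and late-life treatment with the
geroprotectors metformin and rapamycin — reshapes intestinal stem cells
(ISCs) and the maturation of their progeny in single-cell RNA-seq data.
This vignette explains the models the package implements, the choices made
where the design was genuinely open, and what the bundled synthetic cohorts
do and do not demonstrate.

## The analysis, end to end

The pipeline consumes a genes x cells count matrix with per-cell mouse and
condition labels (four arms: young `Y`, old `O`, old + metformin `O_met`,
old + rapamycin `O_rap`) and produces six headline results:

1. **Differential-expression counts** per cluster and contrast.
2. **Signature ratio compartments**: for a stem signature gene set, the
   per-gene ratio of mean expression (treated or aged vs. young) is binned
   into six fixed compartments — (0,0.5], (0.5,0.8], (0.8,1], (1,1.2],
   (1.2,1.5], (>1.5) — and summarized as percentages. The "fraction below
   one" (compartments 1–3) measures overall signature repression.
3. **Kolmogorov–Smirnov comparisons** of the ratio distributions between
   contrasts (does a drug shift the distribution back toward one?).
4. **Compartment transition tests**: cell-type x condition contingency
   tables in early/mid/late pseudotime compartments, tested by Pearson
   chi-squared with a Monte-Carlo p value.
5. **Emergence delays**: the pseudotime at which each cell type first
   appears (a low quantile of its main-path cells), per condition, minus
   the young reference.
6. **Co-expression delay index**: the fraction of cells positive for both
   an early (Uhrf1-like) and a late (Ccnb1-like) progenitor marker over
   the sum of single-positive cells — a transcript analog of a dual-stain
   quantification; delayed maturation leaves more cells in the hand-over
   state and raises the index.

## Preprocessing

QC keeps cells with 200–5000 detected genes (bounds exclusive on the
removal side: exactly 200 or 5000 is kept) and a mitochondrial fraction of
at most 20%, identified by the `mt-` name prefix. Normalization is
counts-per-10k with `log1p`. The embedding is a PCA (truncated SVD via
irlba when available, with a deterministic fallback and a sign convention
that makes each component's largest-magnitude loading positive) of the
centered top-variable genes (standardized dispersion within 20 mean bins;
2000 genes and 30 components by default). Clustering builds an exact
k-nearest-neighbor graph (k = 15), weights edges by the Jaccard overlap of
neighborhoods (shared nearest neighbors, pruned below 1/15), and runs
Louvain modularity optimization under a fixed seed.

Cross-sample anchor integration is deliberately not re-implemented: the
synthetic cohorts are batch-free, so samples are co-embedded by a joint
PCA. One consequence matters for the delay analysis. In a joint embedding,
a cluster can contain cells from different arms whose *identity* differs —
aged cells at a given trajectory position lag behind young cells in their
developmental program. If such a mixed cluster is annotated by a majority
vote, the minority arm's delayed identity is voted away and the delay
becomes invisible (or even reversed through misassignment). The pipeline
therefore annotates **cluster x condition strata**: each cluster's cells
from each arm are typed separately against the marker sets (highest mean
marker expression wins; ties break lexicographically and are logged). This
plays the role that anchor integration plays in the original toolkit —
aligning arms before typing — without inventing an integration model. The
pipeline's default Louvain resolution is 1.5 (finer than the module
default of 0.8) so that every arm contributes typed cells for every
abundant type.

## Expression ratios on the linear scale

`mean_expression_by_condition()` de-logs normalized values back to the
linear counts-per-10k scale before averaging, because a ratio of means of
log-transformed values does not estimate the underlying expression ratio.
Means are taken per mouse and then averaged over each arm's mice — the
mouse is the experimental unit; a pooled-cell mode is available. Genes
with zero mean in the reference arm are excluded and reported, matching
the convention that a signature is restricted to genes expressed in young
animals. A ratio of exactly 1 falls in compartment 3, so the bin labels
partition the line without overlap.

With roughly 650 stem-cluster cells per arm and signature genes at a mean
of about two counts per cell, the per-gene ratio standard error is around
5%. Genes whose true ratio sits near a bin edge can therefore be
misclassified, which slightly smears the recovered compartment vector
(about one percentage point at the steep 0.5 edge). The acceptance checks
use the multinomial 95% half-width at n = 467 floored at three points,
acknowledging this estimation noise on top of the multinomial draw.

## Module scores

A pathway's per-cell score is the mean normalized expression of its genes
minus that of expression-matched random controls: genes are ranked by
dataset-average expression into 24 bins and each set gene draws 100
controls (with replacement) from its bin. Control pools exclude the set's
own genes — this makes the additive contract exact (set genes equal to
their bin-mates plus a constant score exactly that constant) — and fall
back to the whole bin if a set saturates it. The control draw is seeded;
per-pathway seeds are derived from the stage seed and the pathway name.

Bivariate coordination of two pathways is tested on mouse-level mean
scores by a Pillai-trace MANOVA (mice independent), with per-condition
95% Gaussian ellipses (covariance eigen-axes scaled by
`sqrt(qchisq(0.95, 2))`).

## Differential expression

The per-gene model is a negative-binomial regression with a log link,
fixed condition effects, `log(total counts)` as offset, and a Gaussian
random intercept per mouse, fitted by Laplace approximation
(`lme4::glmer.nb`) with a profiled NB dispersion — one dispersion per
gene. Wald tests of the condition coefficients are BH-adjusted (Bonferroni
available; which adjustment the original toolkit used is ambiguous, so
both are provided). A mouse-level pseudobulk NB regression (counts and
offsets summed per mouse, `MASS::glm.nb`) is the fast default for
genome-wide scans; the per-cell GLMM is the reference estimator and the
two agree exactly when the mouse variance is zero. A gene counts as
differentially expressed at fold change >= 1.5 ("at least", treating the
stricter of the two stated conventions as authoritative) and adjusted
p < 0.01; non-converged fits are excluded from counts and reported.

At three mice per group the between-mouse variance carries only four
degrees of freedom, so the 95% Wald interval evaluated with the normal
quantile undercovers (about 84% in our simulations). Coverage assessments
therefore use the t quantile on mouse-level df — the standard small-sample
correction — under which nominal coverage is restored.

## Preranked GSEA

Genes are ranked by log fold-change (descending, ties broken by gene id).
The enrichment score is the classic weighted running sum: hits add
`|metric|^weight` normalized over the set's hits (weight 1 by default),
misses subtract `1/(N - n_set)`, and the score is the signed extremum
(verified against `fgsea::calcGseaStat`). The null distribution re-draws
the set's positions uniformly (gene-label permutation preserving set
size); `NES = ES / mean(|null ES| of the same sign)`; the nominal p is
two-sided on |ES| with a +1 pseudo-count, BH-adjusted across sets. When
`choose(N, n)` does not exceed the permutation budget the null is
enumerated exactly, making small-set p values deterministic.

## Trajectory, dichotomization and delay

The principal graph is deterministic by construction: one medoid per
annotated type, a Euclidean minimum spanning tree over medoids, cells
projected onto the nearest point of their type's incident edges, and
pseudotime as the geodesic distance from the Stem root to the projection,
min-max normalized. The main path runs from the root to the terminus (the
enterocyte cluster by default); cells on path edges are `main`, cells on
subtrees attached strictly before the terminus are `side`, and cells on
the subtree hanging off the terminus are `excluded` (beyond the selected
portion). Externally computed trajectories can be substituted by
constructing the same vertex/edge/projection tables.

Emergence of a type in an arm is the 5% quantile of its main cells'
pseudotimes — a robust operationalization of "the position at which the
type is first detected" — and the delay is the difference to young.
Pseudotime compartments (early/mid/late) are main-cell tertiles; the
dashed boundaries in the source analyses are visual, so tertiles are the
stated reconstruction. The transition test feeds each compartment's
type x condition table, and the pooled table, to the Monte-Carlo
chi-squared test. The "Others" category of the transition analysis is any
type outside the stem/progenitor panel.

## The synthetic cohort generator

The generator is first-class, tested code that encodes the study
conditions: 4 arms x 3 mice x 1000 cells x 2000 genes by default. Each
cell draws a latent maturation coordinate `s ~ U(0,1)`. Cell types (Stem,
R, R-Div, Div1, Div2, EC) occupy equal intervals of an *identity*
coordinate `d = max(0, s - delta_c)`, where `delta_c` is the arm's
maturation delay (defaults: O 0.15, O_met 0.03, O_rap 0.06 — aged mice
delayed, metformin almost fully restored, rapamycin partially). The gene
panel composes:

- a **backbone** program of condition-independent bumps along `s` that
  carries most of the continuum's geometric arc length, so estimated
  pseudotime tracks overall maturation;
- **stage markers** following `d`, so marker-based typing tracks the
  (delayed) identity — the structure the delay analysis assumes;
- a **stem signature** (467 genes) and an Lgr5-like marker with *flat*
  trajectory profiles whose true arm/young ratios are drawn per gene from
  compartment mixtures (young ratios are 1; the aged and drug vectors
  follow the repression-and-partial-reversal pattern, renormalized to sum
  to one). Flat profiles matter: with an identity-dependent profile, the
  measured stem-cluster ratio would be confounded by the arm-dependent
  composition of the cluster and the true ratio would not be identifiable.
  Drug arms can instead be parameterized as a convex pullback toward young
  (`reversal_epsilon`), a single reversal knob;
- four **pathway programs** (Wnt declining, cell cycle peaking
  mid-trajectory, ribosome declining, OXPHOS peaking) with per-arm
  activity multipliers;
- **side branches** hanging off the intermediate progenitor stages: side
  cells occupy a narrow `s` window around their attachment locus and
  express their own marker program *instead of* stage markers. (Spreading
  side cells uniformly along `s` creates a shadow curve that the medoid
  tree routes through, destroying the main-path topology — so branches
  are localized, which is also the topology the dichotomization targets.)
- **Uhrf1/Ccnb1-like plateaus**: the early program follows identity `d`
  (persisting to later positions in delayed arms) while the late program
  follows position `s`, so the co-expression window widens with the delay;
- mitochondrial (`mt-`) genes at a fixed 5% share, and background genes
  that absorb each cell's residual expression budget so the expected
  library size is condition-invariant (programmed repression does not
  masquerade as a library-size shift).

Counts are NB with mean `libsize x mouse_effect x mu_g` (relative
expression summing to one per cell), log-normal library sizes (mean about
3000), a log-normal per-mouse intercept (SD 0.15, mean-corrected), and NB
size 10 — a residual within-cell-type coefficient of variation near 30%,
a realistic level for UMI counts in a purified, homogeneous population.
All randomness flows from one integer seed; identical configurations are
bit-identical.

What the generator does **not** emulate: batch effects, ambient RNA,
doublets, UMI-level read noise, spatial structure, or gene-gene
correlation beyond the shared programs. Passing the recovery checks
therefore shows that the estimators are correct and well-calibrated under
the stated statistical structure — not that real tissue meets that
structure.

## Problem sizes and calibration designs

Simulation-backed checks use sizes chosen for desk-scale reproducibility:
the ratio-compartment and Lgr5 recovery run the full pipeline on the
default cohort (12,000 cells, 2000 genes, about 90 seconds); the
transition-test calibration runs 200 null and 50 delayed cohorts on
generator ground truth (true types and maturation, tertile compartments)
with a reduced gene panel, which isolates the test's size and power from
trajectory-estimation noise — the estimated-trajectory path is exercised
separately at a realistic scale, where the recovered mean post-stem delay
for `delta_O = 0.1` falls in a simulation-calibrated band (roughly 0.03 to
0.3, always exceeding the metformin arm). GLMM checks use 6 mice x 50-100
cells. The full default pipeline completes in under two minutes on one
CPU.

## Known limitations

- Cluster-granularity effects can leave a rare type untyped in some arm
  (reported as NA with a warning) — notably EC in strongly delayed arms,
  where the latest identities barely emerge.
- The Wald z interval undercovers at three mice per group (use the
  t-quantile correction above); pseudobulk inference is anti-conservative
  relative to the GLMM when mouse effects are large.
- The compartment vector inherits roughly a point of edge-misclassification
  smear from count noise; tolerances account for it.
- One printed source table distributes compartment-2 percentages across
  the two drug arms in the opposite order to the accompanying prose; the
  package follows the table.
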