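# stemtraj

Single-cell analysis of intestinal stem-cell aging along the maturation
trajectory, as a tested, reusable R pipeline.

Aging represses the transcriptional program of Lgr5-high intestinal stem
cells and retards the maturation of their progeny along the crypt–villus
axis; late-life metformin or rapamycin partially reverses both effects.
stemtraj implements the quantitative core of that analysis for scRNA-seq
cohorts with a young / old / old+metformin / old+rapamycin design
(conditions `Y`, `O`, `O_met`, `O_rap`; mice as the experimental unit):

- **Signature ratio compartments** — for each signature gene, the ratio of
  mean stem-cluster expression r = mean(condition)/mean(Y) is binned into
  six fixed compartments, (0,0.5], (0.5,0.8], (0.8,1], (1,1.2], (1.2,1.5],
  (>1.5); the compartment percentages and the fraction with r ≤ 1 summarize
  repression, and two-sample Kolmogorov–Smirnov tests compare contrasts.
- **Control-bin module scores** — per-cell pathway activity as
  mean(set) − mean(expression-matched random controls), with mouse-level
  averaging and bivariate (Pillai MANOVA) coordination tests.
- **NB mixed-model differential expression** — per-gene negative-binomial
  regression with log(total counts) offset and a per-mouse random
  intercept (`glmer.nb`), a pseudobulk NB fallback for genome-wide scans,
  BH adjustment, and DEG counting at fold change ≥ 1.5, adjusted p < 0.01.
- **Preranked GSEA** — classic weighted running-sum enrichment score, a
  gene-label permutation null with exact enumeration for small sets,
  NES = ES / mean(|null ES| of matching sign), BH across sets.
- **Trajectory analysis** — a deterministic medoid/minimum-spanning-tree
  principal graph with geodesic pseudotime; dichotomization of cells into
  main-path vs side-branch; chi-squared (Monte-Carlo p) tests of cell-type
  transitions in early/mid/late pseudotime compartments; per-type
  emergence delays vs young; and a co-expression delay index for an
  early/late marker pair (co-positive cells over the sum of positives).
- **A ground-truthed synthetic cohort generator** emulating the four-arm
  design: a branching stem→enterocyte continuum, condition-specific
  maturation delays, a 467-gene stem signature with configurable
  compartment mixtures, pathway activity shifts, NB counts with per-mouse
  random effects.

## Worked example

```r
library(stemtraj)

report <- run_pipeline(run_config(seed = 3))
print(report)
```

```
stemtraj pipeline report (seed 3, config ec4d9fa3)
cells in: 12000 | removed by QC: 0

DEG counts:
             cluster contrast n_deg n_tested n_excluded
Stem.O_met:Y    Stem  O_met:Y   210     1913          0
Stem.O_rap:Y    Stem  O_rap:Y   169     1913          0
Stem.O:Y        Stem      O:Y   305     1913          0

Signature ratio compartments (%):
        (0,0.5] (0.5,0.8]  (0.8,1]  (1,1.2] (1.2,1.5]     >1.5  below_1
O     13.062099  35.11777 22.48394 14.34690  9.421842 5.567452 70.66381
O_met  7.494647  30.62099 34.90364 15.84582  7.922912 3.211991 73.01927
O_rap  5.567452  39.18630 30.83512 15.63169  7.066381 1.713062 75.58887

Transition tests:
      statistic            p
i      559.1209 0.0004997501
ii    1041.6898 0.0004997501
iii   1785.9312 0.0004997501
joint 1950.7460 0.0004997501
```

Reading the output: the aged arm has 13.1% of signature genes repressed
below half their young level and 70.7% repressed overall, while the
metformin arm's strongest-repression compartment shrinks to 7.5% —
recovering the generator's built-in repression-and-reversal pattern. The
transition tests reject equality of cell-type composition across arms in
every pseudotime compartment, reflecting the simulated maturation delay.
The full report also carries the KS comparisons, emergence-delay table,
branch-point module-score profiles, GSEA table and the co-expression
index (`report$headline`, `report$gsea`).

Each stage is also exposed directly — `generate_cohort()`, `qc_filter()`,
`normalize_counts()`, `embed_cells()`, `cluster_cells()`,
`annotate_types()`, `run_de()`, `module_score()`,
`mean_expression_by_condition()`, `expression_ratio()`,
`compartment_summary()`, `rank_genes()`, `gsea_permutation()`,
`learn_trajectory()`, `select_and_dichotomize()`, `emergence_delay()`,
`coexpression_index()`, the stats battery (`ks_two_sample()`,
`anova_tukey()`, `manova_two_response()`, `chisq_mc()`) — and fixtures
round-trip through Matrix Market + TSV + GMT via `write_cohort()` /
`read_cohort()` / `validate_inputs()`.

See `vignettes/stemtraj-methods.Rmd` for the models, parameter choices
and limitations.

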