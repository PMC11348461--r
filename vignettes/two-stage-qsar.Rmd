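---
title: "Two-stage QSAR modeling: heuristic forward selection and gene expression programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage QSAR modeling: heuristic forward selection and gene expression programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsargep)
```

## The modeling problem

The package implements a two-stage quantitative structure–activity
relationship (QSAR) workflow for a set of 39 synthetic RANKL/RANK
inhibitors assayed by TRAP (tartrate-resistant acid phosphatase)
inhibition. The measured quantity is an inhibition percentage in
(0, 100]; the modeled response is its base-10 logarithm,

$$y = \log_{10}(\text{inhibition \%}).$$

The activity table never states this transform explicitly, but every
checkable printed target cell equals `round(log10(inhibition), 3)`
(e.g. 68.4 % → 1.835, 33.6 % → 1.526, 90.3 % → 1.956), so the package
adopts it as the response definition (`log_activity()`).

Stage one (the "heuristic method", HM) screens a large table of
molecular descriptors and builds a multiple linear regression by greedy
forward selection. Stage two evolves a nonlinear symbolic model over a
small set of selected descriptors by gene expression programming (GEP).
Both stages are generic: descriptors are consumed as a numeric
compounds × descriptors matrix (`descriptor_table()`), however they were
computed. Quantum-chemical descriptor generation itself is out of scope.

## The bundled activity table and its audit trail

`load_table1_fixture()` ships the 39-compound table: three scaffold
blocks (16 + 11 + 12 compounds), experimental inhibition with standard
deviations, the linear-model predictions, the evolved-model values, and
the 9 starred test compounds (ids 1, 5, 8, 10, 12, 16, 18, 25, 29; the
remaining 30 are the training set).

The printed table carries typographic noise, which the package handles
by an explicit audit trail (`table1_audit()`) rather than silent
correction or silent failure:

* **Compound 6** prints inhibition 41.7, but its target (1.673), its
  linear difference (1.648 − 1.673 = −0.025) and its evolved-model cells
  are all exactly consistent with 47.1 = antilog(1.673): a digit
  transposition. The fixture stores 47.1 and keeps the printed 41.7 in
  `printed_inhibition_pct`.
* **Compound 28**'s difference cell prints +0.116 where the arithmetic
  gives −0.115: the sign was dropped (the magnitude agrees to one
  printed ulp).
* **Rows 20–26** of the second scaffold block print evolved-model target
  cells shifted up one row relative to the inhibition column; the model
  and residual cells are internally consistent with the shifted targets.
  The fixture stores the self-consistent `target_log` and keeps the
  shifted column verbatim as `gep_target_printed`.
* The **residual column** mixes scales (0.xxx cells alongside
  10^−2/10^−3 renderings such as 5.461); residuals are therefore always
  recomputed from the model and target columns and the printed cells are
  never trusted.

With those cells audited, the evolved model's *training* statistics
recompute from the table to r² = 0.773 and MSE = 0.0083 — matching the
reported 0.78 / 0.0085 at the printed precisions. The reported
*test-set* figures (0.71 / 0.0121) and the linear headline
(r² = 0.5516, s² = 0.0195) are **not** recoverable from the printed
columns under any convention we tried (39-row or 30-row sample, either
target column); `headline_statistics()` reports the recomputations
(test ≈ 0.784 / 0.0147; linear r² ≈ 0.495–0.50, s² ≈ 0.0201) side by
side and the audit trail flags the discrepancy. Because the source does
not state which sample (all 39 or the 30 training compounds) produced
the linear headline, both conventions are always reported.

## Stage one: screening and forward selection

`screen_descriptors()` applies three pruning rules before any model is
built:

1. **Degenerate columns** — all-zero or constant descriptors carry no
   information and are removed.
2. **Inter-correlated pairs** — for every pair with |Pearson r| >
   `r_max`, the member with the smaller |correlation to activity| is
   dropped. Pairs are processed in decreasing |r| with name-order tie
   breaks, so results are deterministic across platforms, and the
   survivors provably contain no pair above the threshold.
3. **Low relevance** — descriptors with |r to activity| < `r_min` are
   dropped.

The source names these rules but no cutoffs; the defaults `r_max = 0.95`
and `r_min = 0.05` are conventional QSAR screening values and both are
arguments. One interaction is worth knowing: rule 3 acts on *marginal*
correlations, so a genuinely causal descriptor with a small coefficient
can be screened out in small samples (at n = 40 a descriptor whose
theoretical |r| is ≈ 0.27 dips below 0.05 in a few percent of draws).
That is the rule working as specified, not a defect; the selection
recovery properties below are therefore stated for the selector itself,
and the end-to-end screen-then-select property for supports whose
correlations sit comfortably above the floor.

`forward_select()` grows the model greedily, at each step adding the
descriptor that maximises the refitted r² (equivalently minimises the
residual sum of squares) — the source describes sequential augmentation
but not the step criterion, and r²-maximisation matches its narrative of
monotonically rising r². Ties break by descriptor name; singular
additions are skipped. Every intermediate model is kept
(`trace_table()`) so r², cross-validated r² and s² can be plotted
against descriptor count.

Model statistics follow the standard definitions: r² = 1 − SSres/SStot,
s² = SSres/(n − k − 1), F = (r²/k)/((1 − r²)/(n − k − 1)), and the
leave-one-out cross-validated r²cv = 1 − PRESS/SStot. `loo_r2cv()` uses
the exact hat-matrix identity e₍ᵢ₎ = eᵢ/(1 − hᵢᵢ), so it costs one fit;
the test suite checks it against literal n-refit leave-one-out. A
constant response is treated as a degenerate input (r² defined as 0 with
a warning) rather than an error, so screening pipelines do not abort.
The intercept is always included and descriptors are never centred or
scaled, keeping coefficients comparable to raw descriptor output.

`breaking_point()` picks the model size: the smallest k at which the r²
gain drops below `tol` (default 0.02 — the source says only that the
fluctuations became negligible near k = 2), further capped by the
sample-size condition n ≥ 3(k + 1), which at n = 30 caps k at 9. The
source variously reports two and five selected descriptors; the package
exposes k as a parameter and takes no side.

## Stage two: the GEP engine

The symbolic-regression stage evolves fixed-length linear chromosomes
decoded into `{+, −, *, /}` expression trees over descriptor terminals
(Karva notation). Each gene has a head of length *h* (functions or
terminals) and a tail of *h* + 1 terminals, so any gene decodes into a
complete tree; decoding is breadth-first (level order), with unused
trailing symbols ignored. A chromosome carries `n_genes` genes whose
sub-trees are joined by the linking function (`+` by default).

Design choices the source leaves open, and how they were fixed:

* **Fitness.** The fitness function is unspecified; the package uses
  `f = 1000/(1 + RMSE)` — bounded, monotone in RMSE, with 0 reserved for
  invalid individuals. All acceptance-level quality checks are stated in
  MSE/r² terms, so they are independent of this choice.
* **Safe division.** Any division whose divisor magnitude is below
  1e−12, and any non-finite intermediate, invalidates the individual
  (fitness 0) instead of returning a sentinel value. Selection can
  therefore never reward numerical artifacts; prediction reports such
  rows as `NA` with a warning rather than dropping them.
* **Operator roster.** Mutation (per-symbol, alphabet-respecting, so
  validity is preserved by construction), one- and two-point
  recombination over the concatenated chromosome, and head-segment
  inversion — the three operator families the source names.
  Transposition operators are a documented extension point, not
  implemented, as the source does not mention them.
* **Selection.** Fitness-proportionate (roulette) sampling with
  replacement plus elitism (best individual copied unchanged), which
  guarantees the best fitness is non-decreasing across generations.
* **No numeric constants.** The terminal set contains descriptors only,
  matching the stated function/terminal inventory; models needing tuned
  constants are outside this engine's search space (a real limitation
  for fitting measured activities).
* **Defaults.** Head 7, 3 genes, population 100, 500 generations,
  mutation 0.044 per symbol, inversion 0.1, recombination 0.3 + 0.3,
  elitism 1 — conventional GEP settings; the original study's control
  parameters are unpublished. Every value is a `gep_config()` argument,
  and a run is fully determined by (config, seed).

## The synthetic-data generator

Because the original 551-descriptor matrix is commercial, unpublished
output, nothing about the fitted models themselves can be reproduced
from structures. The package therefore validates the *method* on
synthetic tables with known ground truth (`synthetic_spec()`,
`generate_synthetic()`): i.i.d. standard-normal base descriptors
(optionally log-normal — real descriptor panels are heterogeneous in
scale, but selection order under the r² criterion is scale-covariant),
a block of degenerate columns, engineered collinear pairs
x′ = r·x + √(1 − r²)·ε, and a planted response — linear over a known
support or a `{+, −, *, /}` expression — plus Gaussian noise. The
default emulation size mirrors the study (39 × 551); tests use smaller
tables for speed.

What the generator does *not* emulate: physical constraints and heavy
inter-correlation structure of real quantum-chemical descriptor
catalogues, measurement error in the activity assay beyond additive
Gaussian noise, and any relationship between scaffold chemistry and
descriptor values. Passing recovery tests therefore demonstrates the
algorithms are implemented correctly, not that two descriptors suffice
for real TRAP data.

## Validation protocol and problem sizes

The test suite pins the implementation to independent oracles and to
recovery experiments at fixed seeds:

* OLS coefficients/r²/s² against an explicit normal-equations solve, and
  `loo_r2cv()` against literal n-refit leave-one-out, to 1e−10 on random
  problems up to n = 50, k = 5.
* Karva decoding and tree evaluation against a second, independently
  written decoder (level-boundary arithmetic + recursive linking) and a
  recursive single-row evaluator, on 500 random genes.
* Operator validity audits: 1000 seeded applications each of mutation,
  recombination and inversion.
* Forward selection recovers planted supports of size 1–3 (n = 40,
  25 descriptors, coefficients 1…k): always when noiseless, and in at
  least 90 % of 50 seeded replicates at noise sd 0.05.
* The evolved stage recovers the planted expression y = d1 + d2·d3
  (n = 60, five terminals, population 100, 200 generations) to training
  RMSE < 1e−6 in at least 60 % of 20 seeds; the measured rate at these
  settings is 19/20.

These sizes keep the full suite around two minutes on one core while
leaving each property comfortably away from its threshold.

## Worked example

```{r example, eval = FALSE}
library(qsargep)

# planted nonlinear truth
spec <- synthetic_spec(60, 5, response_kind = "expression",
                       true_support = c("d1", "d2", "d3"),
                       true_expression = "d1 + d2 * d3", seed = 42)
g <- generate_synthetic(spec)

res <- evolve(gep_config(terminal_set = paste0("d", 1:5),
                         n_generations = 200, seed = 1), g$table)
render_expression(res$best_tree)
#> "(d2*(d5-d5)) + (d2*d3) + d1"
res$train_rmse
#> 0
```

The evolved chromosome spends one gene on an algebraic zero
(`d2*(d5-d5)`) and the other two on the planted structure — typical of
how multigenic GEP absorbs superfluous genes.

## Known limitations

* No numeric constants in the terminal set; no transposition operators;
  no multi-population islands.
* The linear stage is forward-only (no stepwise removal, no best-subset
  search) and inference is homoscedastic-OLS only.
* The headline test-set and linear statistics of the source table are
  reproduced as audited recomputations, not as the printed values — the
  printed columns do not support them.
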