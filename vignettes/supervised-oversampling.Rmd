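---
title: "Supervised over-sampling for imbalanced binding-residue prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised over-sampling for imbalanced binding-residue prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sosampler)
```

## The model

Protein-nucleotide binding-residue prediction is a binary classification
problem with severe class imbalance: roughly one residue in twenty to thirty
contacts the ligand. `sosampler` addresses the imbalance on the data side, by
synthesising minority-class samples before training, and on the evaluation
side, by reporting threshold-optimised, imbalance-robust metrics.

### Supervised over-sampling

All interpolating samplers here share one primitive: a synthetic sample is
`x_new = x_a + λ (x_b − x_a)` with `λ ~ Uniform[0,1]`, so every synthetic
point lies on a segment between two real minority points (the *convexity
invariant*, enforced by tests). They differ in how parents are chosen and
which candidates are kept:

| sampler | parents | filter | per-point counts |
|---|---|---|---|
| ROS | one row, copied | none | uniform random |
| SMOTE | row + one of its k-NN (minority) | none | equal (round-robin) |
| ADASYN | row + one of its k-NN (minority) | none | ∝ majority density Γ̂ᵢ |
| SOS | two random distinct minority rows | confidence interval | emergent |

SOS first fits a model `CM` on the *original* data, then accepts a candidate
iff its minority-class confidence `CM(x_new)` lies in `[c_low, c_high]`,
repeating until `⌈(α−1)|P|⌉` candidates are accepted. Both bounds matter: a
candidate below `c_low` likely fell into majority territory (pairs of minority
points far apart can straddle the boundary), while a candidate above `c_high`
is so deep in minority territory that it behaves like a duplicated minority
point — the over-fitting failure mode of plain replication.

### Feature representation

Each residue is the concatenation of two sliding-window views (window
`w = 17`, the established choice for this problem family):
logistic-normalised PSSM scores (`17 × 20 = 340`) and predicted
coil/helix/strand probabilities (`17 × 3 = 51`), i.e. 391 dimensions.
Normalisation is `1/(1+e^{−x})` in an overflow-safe two-branch form.

### Evaluation

Scores are evaluated with Sen, Spe, Acc, MCC and AUC. Because the first four
are threshold-dependent, the package scans all candidate thresholds
(midpoints between adjacent distinct scores, plus sentinels on both sides)
and reports either the MCC-maximising threshold (*MaxMCC*) or the
`|Sen − Spe|`-minimising one (*Balanced*). The prediction rule is
`score ≥ t ⇒ positive` — inclusive on the boundary, which matters when scores
tie with the threshold. AUC uses the rank/Mann–Whitney formulation with ties
counted one half.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `alpha` | minority size after SOS ÷ before | `|N|/|P|` | synthesise to full balance, the conventional target |
| `c_low, c_high` | SOS acceptance interval | 0.5, 0.95 | 0.5 = minority side of the decision boundary; < 1 to exclude "tied" near-duplicates |
| `max_attempts` | SOS attempt cap | `200 · n_target` | an unreachable interval must error, not hang |
| `k` (SMOTE/ADASYN) | neighbourhood size | 5 | the literature's convention |
| `beta` (ADASYN) | balance level | 1 | full balance |
| `w` | window length (odd) | 17 | established for ligand-binding prediction |
| `C, gamma` | cost and kernel width | grid-searched | libsvm-style grids, 10-fold CV, mean-MCC objective |

The `alpha` and `[c_low, c_high]` defaults are **this package's choices**;
they are deliberately conventional, but no published value is attached to
them. They are ordinary config fields and should be tuned per problem.

## Numerical and design choices

- **SOS pair sampling** uses two *distinct* indices; identical indices would
  reduce synthesis to replication (ROS) and defeat the purpose.
- **RNG contract**: every sampler call uses one seeded generator and draws in
  a documented order (pair/base index first, then neighbour where relevant,
  then λ). The SOS acceptance loop is therefore replayable from its seed —
  the test suite regenerates the proposal stream independently and checks the
  accepted set exactly. Sampler calls never disturb the caller's RNG state.
- **k-NN ties** break toward the lower row index (stable), so results do not
  depend on storage order accidents.
- **ADASYN**: the density estimate Γ̂ᵢ counts majority neighbours in the
  *whole* training set, while synthesis interpolates within the minority set.
  If every Γ̂ᵢ is zero (no majority sample near any minority point) the 0/0
  normalisation is resolved to uniform weights — the SMOTE allocation.
  Integer counts come from the largest-remainder rule (ties to lower index),
  so they sum to `G` exactly and remain monotone in Γ̂ᵢ up to one unit.
- **Terminal windows** are padded with all-zero rows. In normalised-PSSM
  space 0 is outside the attainable range `(0,1)`, so the learner can
  distinguish padding from signal; 0.5-padding would instead mimic a
  zero-information score. Predictions near termini depend on this choice.
- **0/0 metric convention**: Sen, Spe and MCC are defined as 0 when their
  denominator vanishes, keeping the threshold scan total at the sentinels.
- **Threshold tie-breaks**: MaxMCC prefers greater Spe then the smaller
  threshold; Balanced prefers greater MCC then the smaller threshold. These
  rules are part of the contract and are tested against an exhaustive scan.
- **Fold granularity**: protein-level folds whenever group ids are available.
  Residue windows of one protein overlap heavily; residue-level folds would
  leak near-duplicates across the train/test boundary and inflate every
  metric. Sample-level stratified folds remain available for plain tables.
- **Over-sampling inside CV** happens strictly on the training portion of
  each fold. Synthesising before splitting would place interpolants of
  test-fold points into training folds — a subtle, common leak.

## The classifier engine

The probabilistic classifier behind both SOS filtering and prediction is
Gaussian-kernel, ridge-penalised **kernel logistic regression** fitted with
glmnet: the kernel matrix `K(x_i, x_j) = exp(−γ‖x_i−x_j‖²)` enters a
binomial ridge fit with `λ = 1/(nC)`, so `C` keeps its usual
inverse-regularisation reading and confidences are calibrated probabilities
by construction (no Platt post-processing step). No max-margin QP solver is
shipped in this environment, and re-implementing one is explicitly out of
scope; the engine honours the same contract — deterministic fits, `(C, γ)`
grid search by stratified 10-fold cross-validation maximising mean fold MCC,
ties to the smaller `C` then smaller `γ`, confidences in `[0,1]` monotone in
the decision value. Models serialise to a portable JSON file (they carry
their training matrix, as any kernel method must). A `mock` classifier kind
wraps an arbitrary confidence function and is the required test double for
the sampling loop.

## What the synthetic generators emulate — and what they don't

`gen_imbalanced()` draws both classes from unit-variance Gaussians whose
means are `separation` SDs apart, at exact user-given class counts (ratios of
19–28 mirror the published benchmark regimes). This is the simplest world
exhibiting severe imbalance with partial overlap; `separation` exposes
difficulty directly (0 → AUC ≈ 0.5; 3 → AUC > 0.9, both under test).

`gen_toy_profile()` builds integer PSSMs (`round(N(0, 2²))`, matching the
ASCII dialect), adds a mean shift to rows within ±1 of each binding residue
(the stated signal is "near binding residues"; the ±1 radius is this
package's reading), and draws secondary structure from a symmetric Dirichlet
carrying no signal. `write_fixtures()` emits FASTA/PSSM/.ss2/annotation files
that round-trip through the parsers exactly (PSSM) or to the printed 3
decimals (.ss2).

A green test on this world establishes that the machinery is correct —
sizes, filters, leakage guards, metric arithmetic — not that any particular
biological performance level is reached. Real profiles have evolutionary
column correlations, homology between proteins, composition-dependent score
distributions and secondary-structure signal, none of which are simulated.
Published benchmark performance additionally depends on full-database
PSI-BLAST/PSIPRED runs, which are deliberately outside this package: their
*output files* are parsed, never produced.

## Scaling of the shipped experiments

The end-to-end acceptance experiment (40 proteins, 5-fold protein-level CV,
with-SOS vs without-SOS, 5 seeds) uses 20-residue proteins and a single
`(C, γ)` pair so the whole suite stays inside a small CPU budget; the MCC
delta across seeds is printed for inspection rather than asserted, since on
an easy planted signal both pipelines sit near ceiling and the delta
fluctuates around zero.

## Known limitations

- Kernel methods are quadratic in training-set size; beyond ~10⁴ training
  rows the engine needs subsampling or an approximate kernel map.
- SOS cost depends on the acceptance rate; a narrow interval on a hard
  dataset can consume the full attempt budget and error (by design).
- The Balanced policy minimises `|Sen − Spe|` over a finite candidate grid;
  with few distinct scores the gap at the optimum can be large.
- Multi-record FASTA inputs use the first record only (with a warning).
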