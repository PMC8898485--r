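---
title: "Sparse canonical correlation analysis for drug repositioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse canonical correlation analysis for drug repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccaRepo)
```

## The problem

A drug rarely acts through a single molecular target. Beyond binding
proteins, small molecules modulate the expression of non-coding RNAs
(miRNAs and lncRNAs), and those regulatory effects are as much a part
of a drug's mechanism of action as its protein pharmacology. sccaRepo
treats all three categories — proteins, miRNAs, lncRNAs — as *targets*,
and asks which *sets* of targets co-vary with which *sets* of disease
indications across a collection of drugs. Such correlated target/disease
sets serve two purposes: they are interpretable mechanism-of-action
hypotheses, and their linear combination scores new drug–disease
associations for repositioning.

The input is two binary incidence matrices over a shared, ordered set
of $m$ drugs:

* $X \in \{0,1\}^{m \times p}$ — drug–target interactions,
* $Y \in \{0,1\}^{m \times q}$ — drug–disease associations.

`buildMatrixPair()` constructs the pair from two long-format tables,
keeping exactly the drugs that have at least one target (of the
selected classes) *and* at least one indication, and dropping columns
no retained drug uses. Both row and column order are lexicographic in
the C locale, so every downstream result is independent of input file
order. The loaders deliberately do no biological filtering: selecting
small-molecule drugs, approved targets, human-only ncRNA interactions
or approved indications is upstream curation, and the package consumes
the already-filtered tables.

## The model

Canonical correlation analysis seeks weight vectors
$\alpha \in \mathbb{R}^p$, $\beta \in \mathbb{R}^q$ maximizing the
correlation between the projected samples $u_i = \alpha^T t_i$ and
$v_i = \beta^T d_i$ over drugs $i = 1,\dots,m$:

$$\rho = \frac{\sum_i (\alpha^T t_i)(\beta^T d_i)}
{\sqrt{\sum_i (\alpha^T t_i)^2}\sqrt{\sum_i (\beta^T d_i)^2}}.$$

This correlation is **uncentered** — it is the cosine between
$X\alpha$ and $Y\beta$, the natural choice for sparse binary incidence
data where the zero state is meaningful. A `centered` flag on
`canonicalCorrelation()` provides the Pearson variant, but the default
(and everything built on it) is the uncentered form. When either
projection is identically zero the correlation is defined as 0, so a
degenerate projection contributes nothing downstream.

With unit $L_2$ bounds the maximization of $\alpha^T X^T Y \beta$ is
*ordinary* CCA (OCCA), whose solution is the leading singular pair of
the cross-product matrix $Z = X^T Y$ (for binary data, $Z_{ij}$ counts
the drugs carrying both target $i$ and disease $j$). OCCA weight
vectors are dense and hard to read biologically. Sparse CCA (SCCA)
adds $L_1$ budgets

$$\|\alpha\|_1 \le c_1\sqrt{p}, \qquad \|\beta\|_1 \le c_2\sqrt{q},
\qquad c_1, c_2 \in (0, 1],$$

which zero out most weights and make each component a compact
correlated set.

### Rank-one penalized matrix decomposition

`fitRank1()` solves the rank-one problem by alternating the two exact
coordinate maximizations

$$\alpha \leftarrow \arg\max_{\|a\|_2 \le 1, \|a\|_1 \le c_1\sqrt p} a^T (Z\beta),
\qquad
\beta \leftarrow \arg\max_{\|b\|_2 \le 1, \|b\|_1 \le c_2\sqrt q} b^T (Z^T\alpha).$$

Each step has a closed form: soft-threshold the vector and normalize,
with the threshold $\delta \ge 0$ the smallest value bringing the
$L_1$ norm of the normalized vector under the budget
(`l1BoundedUnit()`, bisection to $10^{-8}$). Because each half-step is
an exact constrained argmax, the objective $\alpha^T Z \beta$ is
nondecreasing over iterations (up to the bisection resolution).
`fitSCCA()` extracts $k$ components by deflating
$Z^{(i+1)} = Z^{(i)} - d_i \alpha_i \beta_i^T$ with
$d_i = \alpha_i^T Z^{(i)} \beta_i$ between extractions, exactly as a
truncated SVD would if the sparsity constraints were slack.

### Prediction

For a drug with binary target vector $x_{new}$ (targets unknown to the
model are ignored, with a count reported), the indication scores are

$$y_{new} = \sum_{i=1}^{k} \beta_i\, \rho_i\, \alpha_i^T x_{new},$$

i.e. $B\,\mathrm{diag}(\rho)\,A^T x_{new}$. Components are weighted by
their canonical correlation $\rho_i$ **against the original training
matrices**, not against the deflated residual each was extracted from:
the prediction rule weights a component by how well it explains the
data, and the residual-based correlation would overstate later, weaker
components. Negative $\rho_i$ are kept with their sign — a component
anti-correlated with the data should subtract, not add.
`rankIndications()` orders diseases by descending score with a
lexicographic tie-break, excluding the drug's known indications by
default (the repositioning question is about *new* uses; a flag
restores the full ranking).

### Correlated sets

The published description of a component's correlated set matches "all
strictly positive weights" (a worked example counts 34 targets and 23
diseases with positive weight), and that is the definition
`extractCorrelatedSet()` implements, with an optional top-$N$
truncation. Ties in weight share a rank (competition ranking), so
exactly tied features are reported as equals rather than arbitrarily
ordered.

## Numerical choices

* **Initialization.** The inner loop starts from the leading right
  singular vector of the current residual (deterministic; a seeded
  random init is available via `fitConfig(init = "random")`).
* **Convergence.** Successive change in $\beta$ below `tol` ($10^{-6}$
  by default), capped at `maxIter = 200`; non-convergence is recorded
  per component in the model's diagnostics, and flagged with a
  warning, rather than assumed away.
* **Feasibility.** The $L_1$ budget must satisfy $c\sqrt{p} \ge 1$,
  otherwise the constraint set misses the unit sphere entirely; the
  fit errors with the computed bound. This matters on small matrices,
  where $c = 0.1$ can be infeasible.
* **Exactly tied maxima.** On highly structured data (e.g. the
  noise-free synthetic blocks) the vector being projected can have
  exactly tied top entries. If the tied set has more than
  $(c\sqrt p)^2$ elements, no soft-threshold solution attains the
  budget — the thresholded vector tends to equal weights on the tied
  set. The maximizer is then flat in how weight is distributed over
  the tied set, and `l1BoundedUnit()` resolves the tie
  deterministically with a two-level weight profile that keeps *every*
  tied coordinate in the support while meeting both norm constraints
  exactly. This choice keeps reported supports faithful to the tie
  instead of silently picking a subset.
* **Sign convention.** Each component is flipped so the
  largest-magnitude entry of $\alpha$ is positive; $(\alpha, \beta)$
  flip jointly so $d$ is unchanged. Together with the deterministic
  init this makes refits bit-identical; with exactly equal singular
  values the selected solution is platform-stable but not
  mathematically canonical.
* **Early termination.** If deflation exhausts $Z$ before $k$
  components, the model simply carries fewer components (with a
  warning); all consumers read $k$ from the model.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $c_1, c_2$ | sparsity budgets, fraction of the loosest useful $L_1$ bound (unitless, $(0,1]$) | 0.1 | the operating point favored on the curated benchmark; on small synthetic data use 0.3–0.5 for feasibility |
| $k$ | number of components | 400 | benchmark operating point; on synthetic data set $k$ near the number of planted components |
| `tol` | inner convergence tolerance on $\beta$ | $10^{-6}$ | below typical weight magnitudes, above the $10^{-8}$ bisection resolution |
| `nFolds`, `nRepeats` | CV geometry | 10 × 10 | the standard repeated 10-fold protocol over drugs |

## Evaluation design

`crossValidate()` splits *drugs* into folds (seeded shuffle, then
consecutive blocks, sizes within one of each other), fits on the
training rows only — training-only column registries, so held-out rows
cannot leak — and scores every test drug against all diseases.
Diseases absent from a training fold score 0. All (test drug, disease)
cells of a fold are **pooled into a single ROC** whose AUC is recorded
(micro pooling). Per-drug macro averaging exists behind
`pooling = "macro"`, but micro is the default because per-drug AUC is
undefined for test drugs with zero or all-positive indication rows.
Unobserved cells count as negatives — the usual positive-unlabeled
convention for association data. Aggregation reports the mean and
standard deviation over the per-repeat means.

AUC itself is the Mann–Whitney statistic computed from midranks (ties
count half), and `rankSumTest()` compares two AUC samples with the
two-sided Wilcoxon rank-sum test — exact when the combined sample size
is at most 25 and untied, the tie-corrected normal approximation
otherwise.

One subtlety is worth stating explicitly: with micro pooling, a model
can beat AUC 0.5 on *row-permuted* labels, because pooled ROC rewards
predicting globally popular diseases and row permutation preserves
disease popularity. The chance-level null in the tests therefore
re-places all association cells uniformly (labels fully independent of
the targets), which removes the popularity signal; that null sits at
AUC ≈ 0.5 as it should.

`parameterSweep()` runs the grid with the same fold seeds in every
cell (paired design), marking infeasible cells rather than failing.

### The Jaccard baseline

The comparison baseline is a neighborhood collaborative filter:
drug–drug Jaccard similarity on target profiles, and
$\mathrm{score}(d, s) = \sum_{d'} \mathrm{sim}(d, d')\, Y_{d's} \big/
\sum_{d'} \mathrm{sim}(d, d')$ over training drugs. The original
description gives no propagation formula; the similarity-mass
normalization (weighted mean) is used so scores are comparable across
drugs regardless of neighborhood mass, with `normalize = FALSE`
switching to the raw weighted sum. All training drugs are used (no
top-$k$ neighbor truncation). Self-similarity is zeroed at prediction
time so a training drug never votes for itself.

## The synthetic generator

`generatePlanted()` emulates what curated drug–target and
drug–indication data look like statistically: binary, very sparse
(a few links per drug), with latent structure tying target subsets to
disease subsets through groups of drugs. Each planted component has a
target support, a disease support and a member-drug set (disjoint
across components by default, so recovery scoring is unambiguous);
member drugs carry each support feature with probability `hitProb`,
every cell additionally fires at `backgroundRate`, rows that end up
empty in either view are resampled (bounded retries), and empty
columns are dropped. The default conditions —
$m = 300$, $p = 120$, $q = 100$, five components of 8 targets /
6 diseases / 30 drugs, `hitProb = 0.8`, `backgroundRate = 0.01` — are
small enough for seconds-scale tests yet structured enough for
recovery; the tests also exercise a full-size configuration
(1190 × 1668 / 1111) tuned to the ~4.5 targets and ~4.9 indications
per drug seen in curated data. In the noise-free limit
(`hitProb = 1`, `backgroundRate = 0`) every drug must belong to a
component — otherwise its rows are empty — so that configuration uses
$m = 150 = 5 \times 30$.

What the generator does **not** emulate: real identifier vocabularies
and disease ontologies, hub drugs and hub diseases with heavy-tailed
degree distributions, correlated ascertainment (well-studied drugs
have more recorded targets *and* more recorded indications), and
overlapping mechanisms unless explicitly enabled. Passing recovery and
CV tests on generated data therefore demonstrates correctness of the
machinery, not expected performance on real pharmacology data.

## Problem sizes in the tests and the acceptance script

The test suite runs entirely on generated data: unit oracles on
matrices up to 5 × 4 (exhaustive support enumeration), property checks
on pairs around 40–150 drugs, and cross-validation at 10 × 10 folds ×
repeats on the 300-drug default. `scripts/acceptance.R` reruns the
default conditions end to end — summary ratios, SCCA/OCCA/Jaccard
cross-validated AUCs, the independent-label null, and noise-free
recovery — from a single `--seed`. Reproducing the published
benchmark numbers requires the original curated tables, which are
third-party data not shipped here; the corresponding test states
exactly where to place them and fails (rather than skips) in their
absence.

## Known limitations

* Results depend on the completeness of the input curation; absent
  interactions are treated as true negatives both in fitting and in
  evaluation.
* The deflation scheme does not enforce orthogonality between
  components; with strong overlapping structure, successive
  components can partially re-extract earlier ones.
* With exactly equal block strengths the component *order* is decided
  by numerically tied singular vectors; it is deterministic on a given
  platform but should not be interpreted.
* $k$, $c_1$, $c_2$ are not selected automatically; use
  `parameterSweep()` with paired seeds.
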