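# sccaRepo

Sparse canonical correlation analysis (SCCA) on paired binary drug
matrices for drug repositioning with integrated molecular targets.

## What it does, and for whom

Drugs are polypharmacological: they bind proteins and also modulate
the expression of non-coding RNAs (miRNAs, lncRNAs). This package is
for computational pharmacologists who have two curated tables — drug
→ target interactions (with the target's class) and drug → disease
indications — and want to (1) extract interpretable *correlated sets*
of targets and diseases that co-occur across drugs, as
mechanism-of-action hypotheses, and (2) score new drug–disease
associations for repositioning by combining those sets.

## The model

Let $X \in \{0,1\}^{m\times p}$ and $Y \in \{0,1\}^{m\times q}$ be the
drug×target and drug×disease incidence matrices of the same $m$ drugs.
SCCA finds sparse weight vectors maximizing the (uncentered)
correlation of the projections:

$$\max_{\alpha,\beta}\; \alpha^T X^T Y \beta
\quad\text{s.t.}\quad \|\alpha\|_2^2 \le 1,\; \|\beta\|_2^2 \le 1,\;
\|\alpha\|_1 \le c_1\sqrt{p},\; \|\beta\|_1 \le c_2\sqrt{q}.$$

The problem is solved by rank-one penalized matrix decomposition (PMD)
of $Z = X^T Y$ — alternating exact soft-threshold-and-normalize
updates — and $k$ components are extracted by iterative deflation
$Z^{(i+1)} = Z^{(i)} - d_i\,\alpha_i\beta_i^T$. With the $L_1$ bounds
slack this reduces exactly to the truncated SVD of $Z$ ("ordinary"
CCA, mode `"OCCA"`). A new drug with target vector $x_{new}$ is scored
over all diseases by

$$y_{new} = \sum_{i=1}^{k} \beta_i\,\rho_i\,\alpha_i^T x_{new},$$

where $\rho_i$ is component $i$'s canonical correlation on the
training data. Evaluation is repeated 10-fold cross-validation over
drugs with pooled per-fold ROC/AUC, plus a Jaccard-similarity
collaborative-filtering baseline and Wilcoxon rank-sum comparisons.
See `vignette("scca-drug-repositioning")` for the full account.

## Worked example

The planted-component generator stands in for curated data (the
package never downloads anything):

```r
library(sccaRepo)

gen <- generatePlanted(plantedSpec(seed = 42))
mp  <- gen$pair
summarizeMatrixPair(mp)
#> Dataset summary
#>   drugs:        300
#>   targets:      119 (protein=83, miRNA=25, lncRNA=11)
#>   diseases:     100
#>   interactions: 1425 (protein=972, miRNA=327, lncRNA=126)
#>   associations: 1084
#>   mean targets/drug:  4.8
#>   mean diseases/drug: 3.6

model <- fitSCCA(mp, k = 5, c1 = 0.3, c2 = 0.3)
model
#> ComponentModel: SCCA, k = 5 (119 targets, 100 diseases)
#>   c1 = 0.3, c2 = 0.3
#>   d   = 147.9, 137.9, 134.8, 130.4, 128.5
#>   rho = 0.9563, 0.9524, 0.9458, 0.9422, 0.9301
```

Each component is a correlated set: its positive-weight targets and
diseases, competition-ranked. Component 1 ties a block of targets
(t065, t101, t018, ...) to a block of diseases (dz098, dz087,
dz049, ...):

```r
cs <- extractCorrelatedSet(model, 1)
head(cs$targets, 4)
#>     id    weight rank
#> 1 t065 0.4065211    1
#> 2 t101 0.3947314    2
#> 3 t018 0.3869250    3
#> 4 t049 0.3807242    4
```

Scoring a drug ranks candidate new indications (its known indications
are excluded by default); here the top suggestions are exactly the
diseases of the component the drug's targets load on:

```r
x <- targetMatrix(mp)["drug017", ]
known <- colnames(diseaseMatrix(mp))[diseaseMatrix(mp)["drug017", ] == 1]
rankIndications(scoreDrug(model, x, drugId = "drug017", known = known),
                topN = 3)
#>   drug_id disease_id       score rank
#> 1 drug017      dz098 0.001436629    1
#> 2 drug017      dz087 0.001393757    2
#> 3 drug017      dz049 0.001304160    3
```

Cross-validated link prediction on these conditions:

```r
crossValidate(mp, "SCCA", k = 5, c1 = 0.3, c2 = 0.3,
              nFolds = 10, nRepeats = 10, seed = 1)
#> CVReport: SCCA, 10 repeats x 10 folds
#>   AUC = 0.8116 +/- 0.0026
```

A command-line interface wraps the same functions
(`system.file("scripts", "scca", package = "sccaRepo")`) with
subcommands `simulate`, `fit`, `predict`, `cv`, `sweep`; every run
writes a JSON manifest of its parameters, seeds and input digests.

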