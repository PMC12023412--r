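---
title: "Mass-balance correction of protein stability predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balance correction of protein stability predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcorrect)
```

## The problem

The stability change of a protein upon a single-point mutation is the
difference in unfolding free energy between mutant and wild type,

$$\Delta\Delta G \;=\; \Delta G^{fold}_{m} - \Delta G^{fold}_{w}
 \;=\; \bigl(G^{fold}_m - G^{fold}_w\bigr) - \bigl(G^{unf}_m - G^{unf}_w\bigr)
 \quad \text{(kcal/mol)}.$$

Many fast predictors — knowledge-based potentials, inverse-folding language
models, zero-shot networks — score only the folded structure, implicitly
setting the unfolded-state term $G^{unf}_m - G^{unf}_w$ to zero. That term
is not zero: the mutation swaps one amino acid for another, and the two
residues differ in solvation free energy, side-chain entropy and
main-chain preferences even in the unfolded chain. Dropping it also
violates mass conservation for the implied reaction (the swapped residues
appear on both sides of the folding equilibrium with different
identities).

The *mass-balance correction* (MBC) approximates the neglected term as a
sum of independent per-residue contributions, so that for a mutation of
residue $w$ into residue $m$ only the two swapped amino acids matter. This
package fits and applies that correction to the output of any base
predictor, given nothing but a mutation table with the predictor's scores.

## The models

A mutation is encoded as a 20-element *occurrence vector* $O$ over the
canonical amino acids in alphabetical one-letter order: $-1$ at the
wild-type residue, $+1$ at the mutant, $0$ elsewhere. Three linear forms
are supported, with $\Delta S = S_m - S_w$ the base method's score
difference in its own units:

* **data-driven** (`mode = "dd"`, 21 coefficients):
  $\widehat{\Delta\Delta G} = a_0\,\Delta S + \sum_{i=1}^{20} a_i O_i$
* **burial-scale** (`mode = "rose"`, 2 coefficients):
  $\widehat{\Delta\Delta G} = a_0\,\Delta S + a_1 (R_m - R_w)$, with $R$
  the Rose mean-area-buried scale
* **composition-only** (`mode = "only"`, 20 coefficients):
  $\widehat{\Delta\Delta G} = \sum_i a_i O_i$, no base method at all.

Every form is an odd function of the mutation direction: swapping $w$ and
$m$ negates $O$, $\Delta S$ (after swapping the per-state scores) and the
scale delta, hence negates the prediction. Antisymmetry is therefore
*structural* — it holds to machine precision for any coefficients, fitted
or hand-set, and the package's tests assert it for random models at
1e-10 kcal/mol. For the same reason no intercept is ever fitted: a
constant term is even, not odd, and would be the one way to break the
property.

Because every row of $O$ sums to zero, the residue coefficients are
identifiable only up to a shared additive constant (*gauge freedom*).
Comparisons between coefficient vectors — across base methods, or against
hydrophobicity scales via `coefficient_correlations()` — should therefore
use Pearson correlation, which is invariant to that constant.

## Fitting

Coefficients are obtained by ridge regression through the closed-form
normal equations $(X^\top X + \lambda I)\beta = X^\top y$ with no
intercept and no feature standardization (`ridge_solve()`): occurrence
features are already on a $\pm 1$ scale and coefficients stay
interpretable in kcal/mol. The default penalty is $\lambda = 1$ for the
`dd` and `only` modes and $\lambda = 0$ (plain least squares) for the
two-parameter `rose` mode, all configurable; $\lambda = 0$ with the
21-column design is refused as singular, because the 20 occurrence
columns always sum to the zero vector (the gauge direction), and any
$\lambda > 0$ resolves it by picking the minimum-norm gauge.

`mbc_fit()` by default augments the training set with the antisymmetric
complement of every mutation (reversed residues, negated $\Delta\Delta G$,
swapped per-state scores, negated score delta). The penalty is defined
per *original* mutation: when augmentation doubles the rows, the solver
penalty doubles with them, which makes the augmented and unaugmented
no-intercept fits exactly identical. Augmentation is thus a no-op for
this model family — it could only matter through an intercept — but it is
kept as the default protocol, and as an explicit operation
(`augment_antisymmetric()`) for building balanced evaluation sets.

The complement's score delta is the negated direct delta; the base method
is not re-run on a mutant structure. This matches the retrofit setting,
where only direct predictions exist, and is an approximation whenever the
base method is not itself antisymmetric.

Two further conventions are deliberate. The $\Delta\Delta G$ sign
convention of the input data is stored as a free-text label and never
interpreted: the linear fit is convention-agnostic, and silently flipping
signs is the classic source of stability-benchmark bugs. And parsing is
strict by default — a malformed row aborts the run with its row number —
because training on silently dropped rows changes coefficients; lenient
mode skips and reports instead.

## Evaluation metrics

`pearson()` and `rmse()` implement the two standard assessment scores for
the regression task. Degenerate inputs (zero variance, too few pairs,
missing values) raise typed errors instead of returning `NaN`.
`antisymmetry_metrics()` follows the usual direct/inverse benchmark
convention: the correlation between direct predictions and negated
inverse predictions, and the mean of $(p_{dir} + p_{inv})/2$ as a bias in
kcal/mol. These conventions are documented rather than anchored to any
external table, since published antisymmetry tables differ in their exact
definitions.

## The synthetic generator

`generate_dataset()` emulates a merged thermodynamic training table of
single-point mutations under the correction's own generative assumption.
Per record: an ordered residue pair is drawn uniformly from the 380
possibilities (uniform sampling guarantees every coefficient is
identifiable at moderate n, unlike the skewed compositions of real
benchmarks); a folded-state effect $f \sim N(0, \sigma_{fold}^2)$ is
drawn; the true $\Delta\Delta G$ is $f + u_{mut} - u_{wt}$ for a planted
per-residue vector $u$; the observation adds $N(0, \sigma_{obs}^2)$; and
the base score is $(f + N(0, \sigma_{score}^2)) / a_0^{true}$, so the
score carries the folded signal in its own units and none of the
unfolded-state term.

Defaults: $n = 3322$ records, $a_0^{true} = 0.8$,
$\sigma_{fold} = 1.5$ kcal/mol, $\sigma_{score} = 0.8$ method units,
$\sigma_{obs} = 0.5$ kcal/mol, and $u$ = the Rose scale rescaled linearly
onto $[-2, 2]$ kcal/mol — a realistic magnitude for solvation-like
contributions, and an affine image of a real burial scale so that the
two-parameter `rose` model is exactly well-specified under the defaults.
The folded-effect and noise magnitudes give the observed
$\Delta\Delta G$ a standard deviation around 1.9 kcal/mol, comparable to
curated thermodynamic benchmarks. Generation is reproducible from a
single integer seed, drives one private RNG stream (the caller's
`.Random.seed` is untouched), and the per-record latent truth is returned
alongside the table.

What the generator does *not* emulate: benchmark composition skew,
per-structure and per-position effects, non-Gaussian experimental error,
and any particular base predictor's error structure. Passing the
recovery tests therefore shows that the estimator does what it should
when its assumptions hold, not that any real predictor will improve by a
particular amount.

## What recovery does — and does not — include

`recovery_experiment()` runs, per seed, a fit on one generated table and
an evaluation on a second, independent table (test seed = seed +
500000), comparing the corrected prediction against the raw score and
the fitted residue coefficients against the planted vector. Under the
default conditions the coefficient recovery correlation exceeds 0.99 and
the corrected predictor beats the raw score in every seed by a wide
margin (about +0.30 PCC).

The fitted score weight is a different story, and the package reports it
honestly rather than glossing over it: because the generated score is a
*noisy* measurement of the folded effect, regressing on it is an
errors-in-variables problem, and the population value of the fitted
weight is the attenuated
$a_0^{true}\,\sigma_{fold}^2 / (\sigma_{fold}^2 + \sigma_{score}^2)$
— about 0.623 under the defaults, a 22% shrinkage that no amount of data
removes. A fit at $n = 200{,}000$ lands within 3 decimal places of that
value. The consistency test for $a_0$ therefore sets
$\sigma_{score} = 0$, which is the condition under which the estimator is
actually consistent for $a_0^{true}$; with score noise present the
correct target is the attenuated value, and the test suite asserts
convergence to *that*. None of this affects prediction quality — the
attenuated weight is exactly the coefficient that minimizes prediction
error on new data from the same distribution.

## Problem sizes and numerical choices

The test suite and the acceptance script use 20 replicate seeds at the
default $n = 3322$ for the recovery, improvement and scale-consistency
experiments, 1000 random model/record pairs for the antisymmetry sweep,
and twenty $50 \times 21$ instances for checking the closed-form ridge
against an independent numerical minimizer of the same objective (BFGS
with analytic gradient); agreement is required to 1e-6 max-abs. These
sizes give stable aggregate statistics while keeping a full run in the
order of seconds.

Scale values are not computed from structures; the Kyte–Doolittle
hydropathy index and the Rose mean-area-buried values are transcribed
constants with a provenance comment in the source. The Rose values are
used raw: any linear rescaling is absorbed by the fitted $a_1$. Note the
hydropathy index has tied values (D, E, N, Q all at $-3.5$), so a zero
scale delta does not imply an identity mutation for that scale; the
burial scale's 20 values are distinct.

## Limitations

* The correction is additive and per-residue: no position, structure or
  environment dependence, no interaction terms. This is the model's
  point, not an oversight, but it bounds how much of a real unfolded-state
  term it can capture.
* Reproducing published benchmark numbers requires the external benchmark
  tables and third-party predictor outputs; the package consumes them in
  its CSV dialect (`fit` / `predict` / `eval` compose the published
  cross-benchmark protocol) but does not bundle them.
* The antisymmetric complement reuses the negated direct score rather
  than a re-computed inverse prediction, as discussed above.
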