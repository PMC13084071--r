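---
title: "Methods: GA-MLR QSAR modeling, validation and binding-energy bookkeeping"
author: "phytoQSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-MLR QSAR modeling, validation and binding-energy bookkeeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoQSAR)
```

phytoQSAR implements the statistical core of a ligand-based dual-target
inhibitor-modeling campaign: descriptor-based QSAR construction and
validation, conceptual-DFT reactivity profiling, MM-GBSA
thermodynamic-cycle bookkeeping, and dose-response IC50 estimation.
This vignette records the model assumptions, the parameters that
matter, the numerical choices, and the places where the design was
genuinely open and a decision had to be made.

## The QSAR model and its assumptions

The functional form is ordinary multiple linear regression with
intercept on a small subset of molecular descriptors,

$$\mathrm{pIC}_{50} = \beta_0 + \sum_{j=1}^{L} \beta_j x_j + \varepsilon,$$

with pIC50 the negative decadic logarithm of the molar IC50. The
assumptions are those of OLS: linearity in the selected descriptors,
homoscedastic independent errors, and a training design of full rank
(rank deficiency is an error naming the collinear columns, not a silent
pseudo-inverse). Coefficient uncertainties are reported as standard
errors from the unscaled residual variance and the inverse
normal-equations matrix; published equations of this type print "±"
values without naming the uncertainty, and standard errors are the
convention we adopt.

### Preprocessing

Descriptor matrices from batch descriptor calculators arrive with
unusable columns. `preprocessDescriptors()` removes, in order: columns
with any missing value; columns with variance at or below
`varianceFloor` (default `1e-8`, i.e. numerically constant); and, for
each remaining pair with |Pearson r| above `intercorrelationCap`
(default 0.95), the member with the larger mean absolute correlation to
all other columns. Pairs are resolved most-correlated-first; equal mean
correlations drop the later column, so the procedure is deterministic.
Neither threshold is universal across studies; both are exposed, and
the removal log names every dropped column with its reason so the
choice is auditable. Note a consequence exercised in the test suite:
when an informative descriptor and its near-duplicate both survive to
this stage, the rule may keep the duplicate — selection then recovers a
proxy of the signal, not its original column.

### Kennard-Stone partitioning

The training set is chosen by the classic Kennard-Stone max-min design:
seed with the two most distant compounds in descriptor space, then
repeatedly add the compound whose minimum Euclidean distance to the
selected set is largest. This is deterministic and guarantees the
training set spans the convex hull of the data — which is also its
known bias: the test set is interior, and error estimates on it tend to
be optimistic relative to random splits. Distances are computed on
autoscaled descriptors by default (descriptors carry heterogeneous
units; `autoscale = FALSE` restores raw distances). Ties are broken by
the lowest row index, which makes the split invariant to row
permutation up to that documented rule.

### Genetic-algorithm descriptor selection

Chromosomes are descriptor subsets of fixed size `equationLength`.
The default configuration (`gaConfig()`) — 1000 generations, equation
length 8, crossover probability 1, per-gene mutation probability 0.5,
population 100, 3 elitist survivors — follows the selection settings of
the reference workflow this package mirrors. The GA tool used there
does not document its internals, so three mechanics were fixed here as
design choices:

- **crossover** is single-point over the sorted gene lists of two
  parents drawn from the survivors, with duplicate genes repaired by
  resampling from unused descriptors;
- **mutation** replaces each gene independently with probability
  `mutationProb` by a descriptor not currently in the chromosome; at
  the default 0.5 this is a deliberately aggressive exploration
  operator, and elitism is what preserves progress;
- **fitness** defaults to leave-one-out Q² (selectable: adjusted r²,
  negated MAE), matching the emphasis on internal validation
  parameters when ranking candidate equations.

Fitness values are cached per subset, the best-fitness trace is
monotone non-decreasing (elitism), and the run is a pure function of
the seed. The search stops early when the criterion's theoretical
maximum is reached (Q² or r² of 1, MAE of 0), since no later generation
can improve on it.

## The validation battery

Internal metrics: r², adjusted r², SEE with an $n-p$ denominator ($p$
counts the intercept), PRESS through the leverage shortcut
$e_i/(1-h_i)$ — algebraically exact for OLS, verified in the tests
against explicit $n$-refit leave-one-out at $n \le 30$ — and
$Q^2_{LOO} = 1 - \mathrm{PRESS}/\mathrm{TSS}$.

External metrics: squared Pearson correlation, the
regression-through-origin quantities
($k = \Sigma y\hat y / \Sigma \hat y^2$,
$r_0^2 = 1 - \Sigma(\hat y - k\hat y)^2/\Sigma(\hat y - \bar{\hat y})^2$,
and the axis-inverted primed forms), RMSEP, and
$Q^2_{f1} = 1 - \Sigma(\hat y - y)^2 / \Sigma(y - \bar y_{train})^2$,
$Q^2_{f2}$ with the test-set mean. The $Q^2_{f1}/Q^2_{f2}$ definitions
are the standard ones; the tables this package mirrors label the
quantities but do not print formulas. Two properties of the
through-origin coefficients are deliberately preserved: they can be
negative for poor fits (no clamping), and they can exceed r², in which
case the rm² radicand $\sqrt{r^2 - r_0^2}$ is clamped at zero — making
rm² = r² — and flagged. The rm² form used is the radical form
$r^2(1-\sqrt{r^2-r_0^2})$ of the rm² literature; a rendered linear
variant circulates in some texts but cannot reproduce published rm²
patterns. For the "after scaling" rm² block, both vectors are min-max
scaled to [0, 1] on their **combined** range before computation; the
convention (observed, predicted, or combined range) is not stated by
the sources that print such blocks, and combined-range is our explicit
assumption.

MAE-based judgement: the $\lceil 5\% \rceil$ largest absolute test
errors are dropped; with $r$ the training activity range, the verdict
is GOOD when $\mathrm{MAE}_{95} \le 0.1r$ and
$\mathrm{MAE}_{95} + 3\,\mathrm{SD}_{95} \le 0.2r$, BAD when
$\mathrm{MAE}_{95} > 0.15r$ or
$\mathrm{MAE}_{95} + 3\,\mathrm{SD}_{95} > 0.25r$, else MODERATE. These
thresholds are stated explicitly here because published tables often
print only the verdict.

The Golbraikh-Tropsha checker evaluates the five acceptability
conditions ($Q^2 > 0.5$; $r^2 > 0.6$; ratio-and-slope on either the
plain or primed branch; $|r_0^2 - r_0'^2| < 0.3$; closeness of a
through-origin coefficient to r²) and returns values alongside
verdicts, with the derived ratios attached for reporting.

### Applicability domain

Leverages $h_i = x_i^\top (X^\top X)^{-1} x_i$ are computed on the
training design (model descriptors plus intercept, on the model's
scaling); their sum equals $p$ by the hat-matrix trace identity, which
the tests assert. The structural domain is bounded by the warning
leverage $h^* = 3p/n$; the response domain by standardized residuals
within ±3. The standardization denominator is a design choice the
sources leave undefined: training residuals are divided by the training
SEE, query residuals by the query-set RMSEP — each set's own error
scale — so that a systematically mispredicted external set is not
hidden by an optimistic training SEE.

## Conceptual-DFT descriptors

All eight global reactivity descriptors follow the Koopmans-type
finite-difference approximations from HOMO/LUMO energies in eV. One
convention required a decision: softness is widely printed both as
$\xi = 1/\eta$ and $\xi = 1/2\eta$, and published tables sometimes pair
a $1/2\eta$ formula with $1/\eta$ values (η = 2.07 eV alongside
ξ = 0.48 eV⁻¹ is the give-away: $1/2.07 = 0.48$). The default is
therefore `inverse_eta`, matching printed values; the literal
`inverse_2eta` convention is selectable. Degenerate inputs are
computed, never silently dropped: HOMO ≥ LUMO warns (non-positive
hardness), η = 0 yields flagged non-finite ξ and ω.

## MM-GBSA bookkeeping

The thermodynamic cycle ΔG_bind = ΔG_complex − (ΔG_receptor +
ΔG_ligand) reaches this package in component form, and
`validateThermoCycle()` checks the three component identities with a
configurable tolerance: 0.02 kcal/mol by default, suited to tables
printed to two decimals; use ~1e-9 for machine-precision inputs.
Published tables of this kind mix 1-dp and 2-dp entries, and
accumulated rounding across a subtotal can approach 0.06 kcal/mol, so
the packaged fixture loader flags rows as inconsistent only beyond 0.1
kcal/mol — genuine misprints rather than rounding. Flagged rows load
verbatim with a warning; nothing is corrected. Reported "±" spreads are
carried through but not propagated into residuals (no error-propagation
rule exists for these printed spreads). Entropy terms (−TΔS) are out of
scope by construction: the upstream protocol omits them, and the values
are relative stability indicators, not absolute free energies.
Per-residue rankings sort ascending in energy (most favorable first)
with ties broken by residue number parsed from the identifier.

## Dose-response fitting

Percentage inhibition is blank-relative,
$(A_{blank} - A_{test})/A_{blank} \times 100$, hence invariant to
rescaling all absorbances by a common factor. IC50 fitting is
least-squares on the log-logistic curve against log10 concentration,
parameterized in log10(IC50) (the scale on which the estimate is
near-Gaussian; the IC50-scale standard error is delta-method). The
default model fixes bottom = 0 and top = 100, matching normalized
inhibition curves; the four-parameter variant frees both asymptotes.
Initialization is a multistart over the tested-concentration quantiles
(25/50/75%) crossed with Hill slopes {0.5, 1, 2}, and the best
converged start wins; if no start converges the error reports the best
multistart residual. Two diagnostics are flagged rather than silently
accepted: a negative fitted Hill slope, and an IC50 outside the tested
concentration range. Whether to rescale a curve to span [0, 100]
before fitting is exposed as an option (`rescale`), default off, since
normalization practice varies between labs.

## What the synthetic generators emulate — and what they do not

`genQsarDataset()` emulates the *statistical* structure the modeling
chain assumes: standard-normal descriptor columns, a sparse linear
signal on `kInformative` randomly placed columns, optional
rho-correlated redundant copies, Gaussian activity noise. Defaults
(398 compounds × 564 descriptors, 8 informative, noise 0.2 pIC50,
intercept 6) are the dimensions of the reference campaign. Real PaDEL
descriptor families are *not* emulated: they are heterogeneous in
scale, heavy-tailed, discrete, and block-correlated, and activity noise
in real assays is neither Gaussian nor homoscedastic. Passing tests on
planted data therefore demonstrates that the pipeline machinery is
correct and can recover a recoverable signal — not that a real campaign
will yield a predictive model. Likewise `genDoseResponse()` assumes
exact log-logistic behavior with independent Gaussian replicates, and
`genEnergyTable()` draws components around realistic centers (vdW −30,
electrostatics −50, GB +60, surface −4 kcal/mol) with exact sums — it
emulates table structure, not force-field physics.

Benchmark sizes used in the test suite, chosen as representative desk
scale: the noiseless pipeline benchmark runs the full 398 × 564 /
330-train geometry with the default GA settings; the noisy recovery
benchmark uses 330 × 564 with noise 0.2 and 200 generations over 10
seeds, requiring at least 6 of 8 planted descriptors per seed (the
threshold fixed from pilot runs of exactly that configuration);
PRESS-vs-brute-force equivalence uses n ≤ 30 at tolerance 1e-8.

## Known limitations

- Published equations of the kind this package ships
  (`publishedModel()`) embed an undisclosed descriptor scaling on the
  original software's side: applying their coefficients to raw
  descriptor values does **not** reproduce the published predictions,
  and the scaling is not recoverable from printed material. The
  published prediction table is therefore packaged as a fixture and the
  unit-conversion chain is validated against it; the predictions
  themselves are not recomputation targets. `applyModel()` still runs
  on any input and flags extrapolation beyond the training activity
  range.
- The GA explores subsets stochastically; with aggressive default
  mutation it is robust but not guaranteed to find the global optimum
  in finite generations, and weak descriptors (small coefficients
  relative to noise) are the first to be missed.
- Kennard-Stone test sets are interior by construction; external
  metrics computed on them are optimistic relative to prospective
  validation.
- `correlationMatrix()` is plain Pearson on complete pairs; with the
  5-7 complexes typical of MM-GBSA panels, correlations are descriptive
  statistics, not inferences.
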