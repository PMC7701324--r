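---
title: "Position-specific gapped k-mer prediction of RNA 5hmC sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-specific gapped k-mer prediction of RNA 5hmC sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgkm)
```

## The problem and the representation

RNA 5-hydroxymethylcytosine (5hmC) is a cytosine modification; mapping
experiments reduce each candidate site to a fixed-length window — 41
nucleotides with the candidate C at position 21 — labelled modified or not.
`psgkm` classifies such windows from sequence alone.

The representation is deliberately *positional*: instead of counting how
often a k-mer occurs anywhere in the window (a compositional summary), each
descriptor asks whether a specific pattern occupies a specific window
position. A pattern is a template of fixed nucleotides and gap positions
(`-`), where a gap matches any nucleotide. Ten families generate the space:

| family | templates | example | patterns | length M |
|---|---|---|---|---|
| PsM, PsD, PsT | ungapped k-mers, k = 1,2,3 | `GG` | 4 / 16 / 64 | 1–3 |
| PsM(G)D, G = 1,2,3 | monomer, G gaps, dimer | `A--CG` | 64 per G | 4–6 |
| PsD(G)M, G = 1,2,3 | dimer, G gaps, monomer | `CG-A` | 64 per G | 4–6 |
| PsM(1)M(1)M | three monomers, single gaps | `A-C-G` | 64 | 5 |
| GC | GC-content percentage | — | 1 | — |

Each pattern of length M slides over `L − M + 1` starts; the indicator
`f_ij` is 1 iff pattern j's fixed nucleotides all equal the residues of the
window starting at i. At L = 41 this gives 164 + 640 + 2,496 binary
descriptors for the ungapped families, 7,104 for each gapped two-block
mode, 2,368 for the three-monomer mode, and GC-content: 19,877 in total.
The per-family counts follow the closed form `(L − M + 1) · |family|`,
which the test suite sweeps over L = 6…60. Within one family and one
window position, exactly one fixed-nucleotide combination matches, so every
encoded 41-nt row carries exactly 379 ones — a one-hot invariant the suite
asserts directly and which makes the matrix extremely sparse (379 + 1 of
19,877 entries per row; stored as a `Matrix::dgCMatrix`).

Canonical ordering matters only for column identity, not statistics: types
FT1–FT11 in order, patterns lexicographic under A < C < G < U (gap
configurations ascending first), starts ascending, GC last. Names follow
`FT5:A--CG@7-11` with 1-based inclusive coordinates. The alphabet is
{A,C,G,U}; thymine on input is silently canonicalized to uracil so pattern
identity is unambiguous. The central-C check is a warning by default and an
error under the strict flag, because user data may not guarantee it.

## Mode-wise selection

With ~20k descriptors and ~1k training windows, direct selection lets one
family of mutually correlated descriptors dominate. The protocol therefore
trains an independent impurity ranker per *generation mode* — A = ungapped
k-mers (3,300 descriptors), B = monomer-gap-dimer (7,104), C =
dimer-gap-monomer (7,104), D = three-monomer (2,368) — and keeps the top
k = 100 of each; GC-content is preselected and never counted toward k,
giving 4k + 1 = 401 descriptors.

The ranker is a random forest (via `ranger`): Gini impurity splits,
bootstrap resampling, mean decrease in impurity as importance. The forest
hyperparameters are not part of the protocol's contract, so conventional
defaults are fixed: 100 trees, unlimited depth, `mtry = floor(sqrt(p))`
candidate splitters per node, one thread, an explicit seed recorded in the
`psgkm_selection` object. Ties at rank k are broken by canonical descriptor
index ascending — the stable choice — and selected sets are reported sorted
by canonical index. Selection sees *training rows only*; in
cross-validation it is re-trained inside every fold, and a dedicated test
verifies that perturbing held-out labels cannot move the selection.

`stable_intersection()` implements the interpretability read-out: the
descriptors present in every in-fold selection of a repeated CV (GC
excluded, since its membership is forced). On synthetic data with a planted
motif, the planted descriptor survives every fold.

## The classifier

The classifier is logistic regression with an L2 penalty at unit strength
on the coefficients (never the intercept), i.e. minimising
`0.5·||w||² + Σ_i log(1 + exp(−t_i(x_i'w + b)))` with `t = ±1`. The fit
uses the quasi-Newton L-BFGS-B optimiser with the analytic gradient, a
1000-iteration cap, projected-gradient tolerance 1e-4, and 20 correction
pairs — the GC column is kept on its natural 0–100 percentage scale (there
is a `/100` normalization flag on the encoder, off by default), which
worsens conditioning slightly, and the larger L-BFGS memory absorbs that
without touching the cap or tolerance. The fit is deterministic (zero
initialisation, no stochastic steps); non-convergence is an error carrying
the iteration cap, never a silent warning. The decision threshold is fixed
at 0.5 and not tuned.

Metrics are the confusion-derived set: accuracy, precision, sensitivity and
specificity as percentages; F1 as the harmonic mean of *fractional*
precision and recall (applying the harmonic-mean formula to percentages
would leave [0,1]); MCC. Specificity is `TN/(TN+FP)·100` — the standard
definition. Zero denominators yield 0 with the affected metric recorded in
an `undefined` field rather than NaN, so pooled reports never propagate
missing values. ROC curves sweep the unique scores with trapezoid auROC —
provably equal to the Mann–Whitney U statistic over (P·N), which the suite
checks to 1e-9 — and auPR uses step-wise (average-precision)
interpolation, which avoids the optimistic linear interpolation between PR
points.

Cross-validation is stratified k-fold (default 5) repeated (default 10)
with fresh fold assignments per repeat; per-repeat metrics pool each
repeat's held-out predictions, and the report carries per-fold rows,
per-repeat rows, and mean/sd across repeats. Fold assignment, forest seeds
and everything downstream derive from one user seed, and a fixed seed makes
the whole CV bit-reproducible. `folds = n` is honoured as leave-one-out
(stratification is then vacuous).

## The synthetic generator

`synthetic_spec()`/`generate_dataset()` emulate the benchmark's *shape*:
balanced positive/negative 41-nt windows (662 + 662 in
`benchmark_like()`), i.i.d. background residues (uniform by default), a
forced central C, and planted position-specific gapped motifs. A plant
overwrites only the *fixed* positions of its template, with class-
conditional probabilities `p_pos`/`p_neg`, leaving gap positions as
background draws — so the planted signal is exactly the object the
descriptors detect, and the background collision probability of a
3-fixed-nucleotide plant is (1/4)³ per window. Conflicting plants, plants
that would overwrite the central C, and out-of-window plants are spec
errors. Central-C forcing happens after planting.

`benchmark_like()` carries three moderate plants, one per proposed gapped
mode (`A-CG`@7 at 0.50/0.20, `GG--U`@26 at 0.45/0.15, `C-G-A`@15 at
0.40/0.15) — effect sizes chosen once so that the full pipeline has
recoverable but not trivial signal, roughly matching the headline
accuracy regime of real benchmarks (high 70s–80s).

What the generator does *not* emulate: dinucleotide and codon bias,
transcriptome composition, position-dependent background, correlated
motifs, label noise from peak calling. Tests passing on this generator
therefore demonstrate that the machinery is correct and that the pipeline
recovers position-specific signal at realistic effect sizes — not that any
particular accuracy will transfer to real transcriptome data.

## Problem sizes and numerical choices in the test suite

The suite's calibration checks use sizes at which the relevant sampling
bounds are tight: chance-level calibration runs 2×5-fold CV on n = 1,000
signal-free windows (binomial sd ≈ 1.6 points around 50%); planted-motif
recovery selects on 20 independent n = 400 datasets with match rates
0.9/0.1; and the planted-motif accuracy check averages 5-fold CV over five
independent n = 1,000 datasets, because a single generated dataset carries
a dataset-level accuracy sd near 2.5 points and the claim under test is
about the mean. The selection-size contract runs on a full 1,324 × 19,877
encoding. All seeds are fixed in the tests; `ranger` with one thread and an
explicit seed is deterministic, so every reported number is reproducible
bit for bit.

## Known limitations

- Importance ranking inherits random-forest biases: correlated descriptors
  share importance, and impurity ranking favours the modes' many-valued
  interactions only insofar as trees can express them.
- In-fold selection makes the 401 chosen descriptors fold-dependent; the
  stable intersection is the cross-fold summary, and its size depends on
  signal strength.
- The L2 strength is fixed at 1 by design (no tuning); on very small
  datasets the fit can be visibly under-regularised.
- The 10% holdout helper reproduces split *sizes* (1,192/132 on the
  1,324-window benchmark shape), but any published independent set drawn
  with an unknown seed cannot be reconstructed record for record.
- Prediction-time encoding computes only the model's selected descriptors;
  this fast path is tested to be bit-identical to full encoding followed by
  column selection.
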