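---
title: "Predicting RNA flexibility from localized element-specific persistent homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA flexibility from localized element-specific persistent homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoflex)
```

## The problem

Crystallographic B-factors measure the mean-square displacement of each
atom and are the standard experimental proxy for local flexibility.
Predicting them from structure alone asks: how much of an atom's mobility
is explained by the shape of its surroundings? `topoflex` answers this for
RNA with a purely topological description of each nucleotide's
neighbourhood: the flexibility of a nucleotide (represented by its C1′
atom) is regressed on statistics of persistent-homology barcodes computed
from the atoms around it.

The pipeline has five stages, each exposed as exported functions and
jointly through a command-line interface:

1. **Structure I/O** — parse PDB files into per-chain atom tables
   (`readStructure`), keep the heavy atoms C, N, O, P
   (`selectHeavyAtoms`), and locate the C1′ sample atoms
   (`findSampleAtoms`).
2. **Targets** — per chain, remove B-factor outliers with the
   median/MAD modified z-score rule (`removeOutliersMedian`), then
   z-normalize to mean 0 and *population* variance 1
   (`normalizeBfactors`), so that chains refined on different scales
   become comparable.
3. **Topological features** — for each C1′ atom and each element
   separately, collect the atoms of that element within a Euclidean
   cutoff *E*, compute the Vietoris–Rips persistence barcode of that
   point cloud over the filtration interval [0, *F*] with *F = E ·
   (F/E)*, and bin each dimension's barcode into counts of bars alive at
   the grid points *kF/N* (`featurizeSample`, `binBarcode`). The blocks
   are concatenated element-major (C, N, O, P), dimension-minor.
4. **Learning** — six regression families (ridge, lasso, random forest,
   gradient-boosted trees, RBF support-vector regression, and a small
   multilayer perceptron) behind one interface (`modelSpec`,
   `trainModel`, `predict`), evaluated with *chain-grouped* splits and
   cross-validation so that no chain ever contributes to both sides
   (`splitChains`, `cvScore`, `evaluateModel`).
5. **Synthetic data** — a seeded generator of RNA-like structures with a
   known ground-truth flexibility law (`generatorConfig`,
   `generateStructures`), used for all tests and examples.

## The persistence engine

The Vietoris–Rips complex at scale *t* contains every simplex whose
vertices are pairwise within *t*. Persistence is computed over Z/2 by
column reduction of the boundary matrix, dimension by dimension, in
compiled code (`ripsPersistence`); a deliberately naive pure-R
implementation of the same contract (`bruteForcePersistence`, capped at
12 points) serves as an oracle in the test suite — the two must agree
bar-for-bar to 1e-9 on random clouds.

Conventions, fixed across both implementations:

* dimension-0 bars all have birth 0; there is exactly one per point, and
  one infinite bar per connected component at scale *F*;
* for dimensions ≥ 1, zero-persistence bars (birth = death) are dropped;
* features that survive to the truncation *F* are reported with death
  `+Inf`, and an infinite bar counts as alive at every grid point during
  binning (both bin endpoints are inclusive).

The local clouds always include the central C1′ atom itself, whatever the
element being featurized, so even an otherwise empty neighbourhood yields
a well-defined (single-point) barcode: one infinite dimension-0 bar,
nothing above.

## Parameters and defaults

| parameter | default | why |
|---|---|---|
| cutoff *E* | 15 Å | the scale at which local packing density varies informatively; small neighbourhoods (≲ 5 Å) see only the covalent template |
| *F/E* | 0.5 | bars born past *F* are dominated by the cloud boundary, which is an artefact of the cutoff sphere rather than of the structure |
| bin size *f* | 0.5 Å | resolves the 1.5–6 Å range where nucleotide-scale geometry lives; the constructor enforces that the effective width *F/N* stays within 25 % of the request |
| elements | C, N, O, P | the heavy-atom composition of RNA; each element carries distinct geometry (P traces the backbone, N the bases) |
| dimensions | 0, 1 | components and loops; dimension 2 is supported but rarely populated at these scales |
| outlier threshold | 3.5 | the conventional modified z-score cut; with MAD = 0 the rule removes nothing |
| train fraction | 0.75 | chain-grouped 75/25 split, at least one chain on each side |
| CV folds | 5 | chain-grouped; the CV score is the PCC of the *pooled* out-of-fold predictions |

Model hyperparameter defaults come in two named presets
(`preset = "esph-cnop"` for the four-element feature set, the default,
and `"esph-single"` for single-element features); see `?modelSpec` for
the full table. Ridge is solved in closed form from the penalized normal
equations (objective RSS + α‖β‖², intercept unpenalized; α = 0 reduces
exactly to OLS); lasso delegates to glmnet with λ = α/(2n) so both
penalized families share the same α convention.

## The synthetic generator

Because real curated RNA sets cannot ship with the package, testing and
examples rest on a generator whose ground truth is known by
construction. Each chain is a helical tube — rise 2.81 Å per nucleotide,
radius 9 Å, twist 32° per nucleotide, i.e. A-form-like proportions —
wound around a *confined random-walk axis*: at every step the axis
direction is perturbed by Gaussian noise (`bendSd`) and pulled back
toward the origin (`confinement`), so the tube folds into a compact blob
with genuinely varying local packing. Each nucleotide carries a fixed
21-atom heavy-atom template (9 C, 4 N, 7 O, 1 P — ribonucleotide
stoichiometry) at fixed offsets with 0.3 Å jitter; the C1′ sits exactly
on the tube.

Ground-truth B-factors follow a weighted-contact-number-style law:

> raw B = 110 − 0.1 · (heavy atoms within 15 Å) + N(0, σ), floored at 0.01

so flexibility decreases with packing density and termini are the most
mobile, with σ = 2 by default. Everything — chain lengths, geometry,
noise — derives deterministically from one root seed (per-chain seeds
are `seed + 101·i` and `seed + 101·i + 50`), and `generateStructures`
writes a YAML manifest recording every parameter.

**Design history, for honesty's sake.** The first generator used a
straight helical axis; that geometry is degenerate (every interior
nucleotide has nearly identical packing), the targets were essentially
noise around a constant, and held-out correlation hovered near 0.1. The
folded-axis design was introduced *before* the acceptance thresholds
were frozen, together with the contact radius of 15 Å: a contact count
over a very small radius (e.g. 8 Å) is dominated by which individual
template atoms fall just inside the shell around one specific atom, and
that is information a permutation-invariant Rips barcode of the
neighbourhood cannot isolate even in principle, so no feature set of
this family could recover it. With the 15 Å law the target is a
neighbourhood-scale density property, which is exactly what the features
measure. All generator constants have been frozen since.

**What the generator does not emulate:** base pairing and stacking,
sequence effects, crystal contacts, anisotropic displacement,
experimental refinement artefacts. Conclusions about *relative* merits
of feature scales transfer qualitatively; absolute PCC values on real
RNA will differ.

## Evaluation protocol

Chains are the grouping unit everywhere. The hold-out split and the CV
folds operate on chain identifiers, and `evaluateModel` reports both the
pooled PCC over all test samples and per-chain PCCs — the pooled number
is sensitive to between-chain offsets that per-chain correlations
ignore, and the two are deliberately both available. The CLI's
`evaluate` subcommand refuses (exit code 3) to score a dataset whose
chain identifiers intersect the training chains recorded in the model
bundle.

`gridSearch` featurizes the training structures once per feature
configuration and scores every model-hyperparameter combination by
chain-grouped CV, returning the argmax together with the full score
table; combinations that fail to train are recorded with a missing score
rather than aborting the search.

## Numerical choices

* Homology is over Z/2; reduction is per-dimension column reduction with
  pivot claiming, with a union-find shortcut for dimension 0.
* Simplices are ordered by (filtration value, lexicographic vertices),
  which fixes a deterministic pairing when distances tie.
* PCC is computed from centred sums, matching `stats::cor` to machine
  precision; a zero-variance side is an error, not an NA.
* All stochastic trainers (random forest, boosting, the MLP) are seeded
  and single-threaded, so every number in the package is reproducible
  bit-for-bit; helper functions save and restore the caller's RNG state.
* The MLP is implemented in plain R (sigmoid hidden layers, leaky-ReLU
  output, inverted dropout, Adam): problem sizes here are small enough
  that a deep-learning framework would buy nothing but an installation
  burden.

## Problem sizes

The shipped defaults (8 chains of 30–60 nucleotides; ~350 samples of 120
features) are the package's own choice of a desk-scale study: large
enough that held-out correlations are stable to a few hundredths, small
enough that the full pipeline runs in well under a minute on one CPU.
The sensitivity analyses in the test suite use 6 chains of 15–25
nucleotides for the same reason.

## Limitations

* The persistence engine targets local neighbourhoods (tens to a few
  hundred points, dimensions ≤ 2); it is not a general-purpose TDA
  library and has no landmark/witness approximations.
* Features are integer bar counts on a grid; persistence images,
  landscapes and kernels are out of scope.
* The generator's flexibility law is a single-radius contact count;
  real B-factors mix crystal packing, TLS refinement and dynamics that
  no such law captures.
* Single-conformer PDB handling only: the first-listed altloc is kept,
  models beyond the first are ignored.

## A minimal session

```{r pipeline, eval = FALSE}
set <- generateStructures(generatorConfig(seed = 1), dir = "structures")
cfg <- FeatureConfig(cutoff = 15, feRatio = 0.5, binSize = 0.5)
ds  <- buildDataset(set$structures, cfg)
sp  <- splitChains(unique(chainLabels(ds)), seed = 1)
tr  <- chainLabels(ds) %in% sp$train
m   <- trainModel(modelSpec("rf", seed = 1),
                  featureMatrix(ds)[tr, ], targets(ds)[tr])
evaluateModel(m, ds[, !tr])
```

The README shows this session with its actual output; the same pipeline
is scriptable end-to-end through `cliMain()` / the installed `topoflex`
script with YAML configuration files.
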