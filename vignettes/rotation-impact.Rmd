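---
title: "Factor rotation in Q-methodology: models, choices, and validation"
author: "qrotate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor rotation in Q-methodology: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrotate)
```

## The analysis

Q-methodology identifies shared viewpoints by factor-analyzing *people*
rather than variables: each participant force-ranks S statements into a
fixed quasi-normal grid (a Q-sort), the P Q-sorts are correlated with each
other across statements, and the P x P correlation matrix is factored.
Each retained factor represents a group of participants who sorted the
statements similarly; it is interpreted through its *factor array* (an
idealized Q-sort) and its *distinguishing statements*.

`qrotate` implements this pipeline end to end, with particular care around
the step practitioners most often treat as a black box: **factor
rotation**. The same extraction can look very different after Varimax,
Equamax, or Quartimax rotation — different sorts load, different statements
distinguish — and the package provides the machinery to quantify exactly
how much changes.

### Extraction

Two extraction methods operate on the by-person correlation matrix `r`:

* **PCA** (`extractPCA`): the top-k eigenpairs; loading column j is
  eigenvector j scaled by the square root of eigenvalue j.
* **Iterated PAF** (`extractPAF`): communalities start at the squared
  multiple correlations `h2_i = 1 - 1/(r^-1)_ii`; each iteration places the
  current communalities on the diagonal, eigendecomposes, and rebuilds the
  communalities as row sums of squared top-k loadings; iteration stops when
  the largest communality change falls below `tol` (default 1e-6, capped at
  200 iterations). The centroid extraction used historically in
  Q-methodology is mathematically an approximation of PAF, so PAF stands in
  for it here.

When P > S — as in the 40-sorts-by-19-statements design — the by-person
correlation matrix is rank-deficient and squared multiple correlations are
undefined. `extractPAF` detects this (reciprocal condition number below
1e-10) and falls back to unit initial communalities, the classical
alternative; `init = "ones"` selects that start directly. Communalities
that exceed 1 during iteration (Heywood cases) are clipped to 1 with a
warning.

The number of factors `k` is a required analysis input. No automatic
retention rule (Kaiser criterion, parallel analysis) is applied: in
Q-methodology the choice is substantive, and a three-factor solution is the
common working default for comparisons of this kind.

### Rotation: one criterion, three names

Quartimax, Varimax and Equamax are all members of the **orthomax family**.
For a P x k loading matrix L the objective is

    Q(L) = sum_j [ sum_i L_ij^4  -  (gamma / P) * (sum_i L_ij^2)^2 ]

with gamma = 0 (Quartimax: simplify rows, allow a general factor),
gamma = 1 (Varimax: simplify columns, suppress a general factor), and
gamma = k/2 (Equamax: a compromise). `rotateOrthomax` maximizes Q by
repeated sweeps of pairwise planar (Jacobi) rotations: for each factor pair
the optimal angle has a closed form via `atan2` of fourth-order column
statistics, and pairs are visited in fixed lexicographic order so results
are bit-reproducible. A sweep that improves Q by less than `tol` (default
1e-8) terminates the loop; hitting `maxSweeps` (default 100) flags the
result as non-converged rather than erroring. Convergence is measured on
the criterion change, not the angle, which is robust across gamma
variants.

Kaiser row normalization — dividing each row by the square root of its
communality before rotation and rescaling after — is ON by default, as in
mainstream statistical packages; zero-communality rows pass through
unnormalized. It is exposed as a flag because implementations differ.

After convergence, columns are re-signed so each column's
largest-magnitude loading is positive and re-ordered by descending
explained variance; both operations are folded into the accumulated
transform, so `rotated == loadings %*% transform` holds exactly and the
transform stays orthogonal. Orthogonal rotation preserves the factor
subspace: row communalities and `L %*% t(L)` are invariant, which the test
suite asserts to 1e-8.

### Flagging, scores, arrays, distinguishing statements

A loading is significant when `|a| >= tau` with
`tau = z_(1-alpha/2) / sqrt(S)` (`significanceThreshold`; about 0.45 for
S = 19, 0.30 for S = 42). `flagQSorts` reports two nested notions:

* **loaded** (non-exclusive): every sort with a significant loading on the
  factor. Because one sort can be significant on several factors, these
  counts can sum past P.
* **flagged** (exclusive): significant *and* holding the majority of the
  sort's communality (`a^2 > h2/2`), which at most one factor can. Sorts
  significant somewhere but flagged nowhere are *confounded*; significant
  nowhere, *null*. Flagged sets, confounded and null partition the
  participants.

Factor z-scores (`factorZScores`) are Brown-style weighted composites of
the flagged sorts, with weight `w = f / (1 - f^2)` (loadings clipped at
|f| = 0.999; clipping past 1 warns). Flagged sorts with negative loadings
hold the opposing view and enter with their statement values reflected
about the grid midpoint. The composite is standardized across statements
(mean 0, SD 1). The **factor array** maps the z column back onto the grid:
descending z fills columns from the positive anchor downward against the
capacities, ties broken by ascending statement id — deterministic and
auditable.

When a factor's exclusive flagged set is empty — routine for the later
factors of an *unrotated* solution, where the first factor absorbs most
communality — the factorial runner falls back to the factor's loaded set,
and failing that to its single largest-|loading| sort, so that unrotated
conditions can be scored and compared at all. Direct calls to
`factorZScores` keep the strict erroring behavior unless `fallback = TRUE`.

Statement s **distinguishes** factor f when `|z_sf - z_sg| >= d` for every
other factor g. Both columns are unit variance, so `d` is an effect size
in SD units; the default 0.80 is a conventional large effect. The boundary
uses `>=`, and lowering `d` can only add statements.

### The rotation-impact comparison

`runRotationImpact` runs the full factorial — extraction in {PCA, PAF} x
rotation in {none, Varimax, Equamax, Quartimax} — and, for each rotated
condition, correlates its factor z-scores with the unrotated ones across
statements, matches factors one-to-one by **greedy maximum |r|** (ties
broken by smaller reference then smaller rotated index; signs recorded for
alignment), and draws up a changed-statement ledger per matched pair:
statements newly distinguishing, dropped, and common, with
`nChanged = nNew + nDropped`. Rotation-vs-rotation correlation matrices
are retained as well. Matching operates on factor z-scores, not loadings,
because scores are what interpretation rests on. Greedy matching is the
default and the reported behavior (it mirrors per-factor maxima); an
exhaustive optimal assignment over permutations (`method = "optimal"`) is
available for tie situations at the small k this package targets.

## The synthetic generator

`generateSynthetic` emulates the data-generating story behind a Q study:
`kTrue` latent viewpoint prototypes (standardized pseudo-random z-profiles,
redrawn until pairwise |r| <= `maxCorr`, default 0.3), each participant a
noisy copy of their group's prototype (`prototype + Normal(0, noiseSd)` per
statement), rank-transformed into the forced grid exactly as a participant
would sort. All randomness flows through one explicit seed.

What it emulates: forced quasi-normal sorting, distinct viewpoints, graded
within-group agreement. What it does not: bipolar viewpoints, response
styles, participant-specific noise levels, missing data, or the error
structure of any real dataset. Passing tests on synthetic data therefore
demonstrate the *machinery* (recovery of planted structure, conservation
laws, matching behavior), not calibration to any particular study's
numbers.

Default study conditions used throughout the tests and the acceptance
script: S = 42 statements on a -5..+5 grid with capacities
(1, 2, 3, 5, 6, 8, 6, 5, 3, 2, 1) — quasi-normal, 11 columns, deepest
column 8 — and 33 participants in three groups of 11 with noise SD 0.5
(prototypes are unit variance, so noise is half a signal SD); and a
19-statement companion design on -3..+3 with capacities
(1, 2, 4, 5, 4, 2, 1) and 40 sorts. Exact column capacities are an
analyst's choice in practice; these shapes were fixed once as realistic
quasi-normal grids for their statement counts. At noise 0.5 the
PCA + Varimax pipeline flags essentially all participants onto the factor
matched to their true group over 20 replicates; the test suite requires at
least 90%.

## A worked run

```{r example}
g <- gridSpec(-5:5, c(1, 2, 3, 5, 6, 8, 6, 5, 3, 2, 1))
d <- generateSynthetic(S = 42, kTrue = 3, groupSizes = c(11, 11, 11),
                       noiseSd = 0.5, grid = g, seed = 11)
report <- runRotationImpact(d@qsorts, k = 3)
report
```

The summary mirrors the comparison one would tabulate by hand: per
condition and factor, the non-exclusive loaded count, the exclusive
flagged count, the number of distinguishing statements at d = 0.80, the
matched unrotated factor with its correlation, and the changed-statement
counts. `exportReport(report, dir)` writes the counts, long-format
correlation matrices, ledgers, z-scores and arrays as CSV plus a JSON
overview.

## Numerical choices and limitations

* Ties: eigenvalue ties keep the eigendecomposition's order; array
  assignment and rank transformation break z ties by ascending statement
  id; greedy matching breaks |r| ties by smaller reference index. All are
  arbitrary but deterministic.
* The sign convention (largest-|loading| element positive per column) is
  likewise arbitrary; matching uses absolute correlations, so every
  reported comparison is sign-invariant.
* Degenerate inputs: k = 1 analyses skip distinguishing statements,
  matching and ledgers (undefined with one factor); free-distribution data
  disable capacity checks but keep range checks; zero-variance sorts are
  rejected by name.
* Problem sizes: the package targets the tens-of-sorts, tens-of-statements
  regime typical of Q studies. The test suite and acceptance script run
  the full factorial on 40 x 19 and 33 x 42 designs plus 20 replicate
  recovery runs in a few seconds.
* Out of scope: oblique rotations (oblimin, Promax), manual/theoretical
  rotation, centroid extraction proper, consensus statements,
  standard-error-based distinguishing tests, and factor-retention
  heuristics.
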