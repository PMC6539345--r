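---
title: "QSRR modelling of McReynolds constants for poly(siloxane) stationary phases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSRR modelling of McReynolds constants for poly(siloxane) stationary phases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siloxqsrr)
```

## The problem and the model

Gas–liquid chromatographic retention is governed by solute–stationary-phase
interactions. The McReynolds constants X, Y, Z, U and S quantify a phase's
polarity as the retention-index difference of five probe solutes (benzene,
butanol, 2-pentanone, nitropropane, pyridine) relative to squalane, in
retention-index units. This package treats each constant as the response of
a quantitative structure–retention relationship over a set of 29
poly(siloxane) phases spanning three structural families
(methyl/phenyl-, trifluoropropylmethyl- and cyanoalkyl-substituted):

$$R = b_0 + \sum_{i=1}^{k} b_i\, d_i + \varepsilon, \qquad k \le 6,$$

where the $d_i$ are theoretical molecular descriptors of a simplified
polymer model and the coefficients are estimated by ordinary least squares
on 24 calibration phases, with five phases (OV-7, OV-25, SILAR 7CP, XE-60,
FS-328 — one from each structural neighbourhood) held out for external
prediction. The assumptions are those of small-sample OLS: a linear,
sparse response surface, i.i.d. Gaussian errors, and descriptor subsets
small enough ($\le 6$ for $n = 24$) to leave meaningful residual degrees of
freedom.

## The oligomer model and graph descriptors

A polymer cannot be fed to descriptor software directly, so each phase is
represented by an oligomer of 20 siloxane units terminated by
trimethylsiloxy groups:

* **Allocation** (`allocate_units()`): mole percentages are converted to an
  integer number of units by nearest-integer rounding of $pct \cdot 20/100$
  with a largest-remainder correction (ties broken by unit name). This
  reproduces the recorded geometric-model compositions of FS-169 (25 %),
  FS-328 (30 %) and NSKT-33 (65 %). For OV-61 the rule gives 65 % dimethyl
  where 70 % is recorded; `allocation_report()` surfaces the discrepancy
  rather than hiding it, and the recorded value is kept in the data.
* **Interleaving** (`interleave_units()`): comonomers are positioned
  uniformly along the backbone by an error-diffusion (Bresenham-style)
  schedule — at each position the unit with the largest accumulated quota
  deficit is placed. The result is deterministic and invariant to the
  ordering of the input counts.
* **Graph construction** (`build_oligomer()`): hydrogen-suppressed graphs
  with valence checking (Si 4, C 4, N 3, O 2, F 1; aromatic bonds count
  1.5). The comonomer catalogue (`siloxane_units()`) is configuration, not
  hard-coded: the composition symbols of the source tables were resolved to
  dimethyl, methylphenyl, diphenyl, trifluoropropylmethyl,
  cyanoethylmethyl, cyanopropylmethyl, cyanopropylphenyl and dicyanopropyl
  units by cross-checking which phases may contain cyanoethyl groups
  (exactly NPS-100, NSKI-25, NSKT-33, XE-60) and the relative polarity of
  the homopolymer phases; a di(cyanoethyl) unit is included in the
  catalogue for users who prefer the alternative reading of the mixed
  cyanoethyl phases.

Two descriptors are computed directly on the graph:

* **B04[N-Si]** (`atom_pair_presence()`): 1 iff some N and Si atom lie at
  shortest-path distance exactly 4. In a cyanoethyl substituent
  (Si–CH₂–CH₂–C≡N) the nitrogen is four bonds from its silicon; in a
  cyanopropyl group it is five, and no shorter route exists through the
  backbone, so the descriptor flags exactly the cyanoethyl phases.
* **RBN** (`count_rotatable_bonds()`): single, acyclic bonds between two
  non-terminal heavy atoms, excluding bonds at sp (triple-bonded) atoms.
  The exact convention of commercial descriptor software is proprietary,
  so this package states its own: nitrile carbons are sp, hence bonds into
  them are rigid, which yields the substituent increment order
  methyl (0) < phenyl (1) < cyanoethyl (2) < trifluoropropyl (3) =
  cyanopropyl (3); backbone Si–O bonds count as rotatable, a constant
  offset across equal-length chains that cancels in regression. QSRR uses
  RBN *differences*, which this convention preserves; absolute parity with
  other software may differ by an additive constant.

`write_smiles()` serialises any graph deterministically; tests round-trip
every phase through the Open Babel parser and compare atom/bond counts.

## Descriptor pre-filtering

`prefilter_descriptors()` reproduces the two-step reduction used before
variable selection: near-constant columns are removed (relative standard
deviation below $10^{-4}$ or more than 90 % identical values — the source
protocol gives no number, so both thresholds are explicit configuration),
then groups of highly correlated descriptors ($|r| > 0.85$) are pruned
greedily in order of decreasing variance, keeping the most variable member
of each group. Absolute correlation is used so anticorrelated duplicates
are also caught. A connected-components grouping is available as an option
(`filter_config(grouping = "components")`) since "groups of correlated
descriptors" admits both readings; greedy pruning is the default because
it alone guarantees that all retained pairwise $|r| \le 0.85$.

## GA-MLR descriptor selection

`ga_evolve()` encodes a candidate model as a binary chromosome over the
descriptor pool. The fitness of a chromosome is $Q^2_{loo} = 1 -
\mathrm{PRESS}/\mathrm{TSS}$, computed with the leverage shortcut
$e_{(i)} = e_i/(1 - h_{ii})$, which is algebraically identical to $n$
refits for OLS (and is tested against explicit refitting to $10^{-9}$).
The defaults follow the established protocol: population 100, per-gene
mutation probability 0.001, elitism 1 %, uniform crossover, termination
after five generations without improvement of the best fitness, and at
most six active descriptors. Where the protocol is silent, the package
makes these choices explicit:

* **Parent selection**: fitness-rank roulette. $Q^2$ can be negative, so
  raw fitness-proportional sampling is undefined; ranks are robust.
* **Constraint handling**: offspring with more than six active genes are
  repaired by deactivating uniformly random excess genes, keeping the
  search inside the feasible region rather than penalising it.
* **Initial population**: each gene is on with probability $3/p$, so
  initial models average about three descriptors.
* **Degenerate chromosomes**: empty or rank-deficient supports get fitness
  $-\infty$.
* **Parsimony tie-break**: among chromosomes of equal best fitness
  (within $10^{-12}$) the smallest support is kept. Without this, any
  superset of a perfectly fitting support would tie and noiseless
  identifiability would be lost.
* **Caching**: fitness values are memoised by gene vector, since LOO
  refits dominate the cost.

`multi_start_pool()` implements the two-stage protocol: many GA runs from
different seeded starting populations, the union of all selected
descriptors ("selected at least once" taken literally), and a final GA on
the pooled set whose best model is fitted and returned. Stage-1 seeds are
`seed + 0, 1, ...`, so the whole procedure is reproducible.

## Validation statistics

* `sdec()` / `sdep()`: root-mean-square calibration/prediction error with
  denominator $n$ — the common QSAR convention, consistent with the
  reference statistics; an $n - p - 1$ denominator is available for
  sensitivity checks. Coefficient standard errors always use the unbiased
  $n - p - 1$ residual variance.
* `q2_external()` returns all three standard external-$Q^2$ variants (F1,
  about the calibration mean; F2, about the external mean; F3,
  calibration-variance normalised), because the reference protocol does
  not say which was used; reports default to F1.
* `monte_carlo()` draws 30 random partitions with each phase assigned to
  the test set independently with probability 0.2, redrawing degenerate
  partitions (fewer than 2 test phases, or too few training rows for the
  support) with a bounded number of attempts. The descriptor support is
  **fixed** across repetitions — the established models are re-fitted, not
  re-selected. Both the mean ± SD of per-repetition SDEP and the
  pooled-predictions SDEP are reported, since both readings of "SDEP over
  repeated splits" are in circulation.

## PCA classification

`qsrr_pca()` diagonalises the correlation matrix of the autoscaled
variables (each model's descriptors plus, by default, its response):
eigenvalues sum to the variable count, loadings are orthonormal, scores
are the autoscaled data projected on the loadings. Since a PC's sign is
arbitrary, each component is oriented so its largest-magnitude loading is
positive. `biplot_data()` truncates (never recomputes) to the first two
components for plotting; `autoplot()` draws the biplot.

## The synthetic-data generator

`generate_qsrr()` emulates the statistical shape of the real problem so
that selection, validation and classification are testable end to end:
29 samples by default, 177 candidate descriptors in correlation blocks of
5 with within-block correlation 0.6 (descriptor pools remain clustered
even after the $|r| > 0.85$ filter; correlated decoys are what make
subset selection hard), a sparse response over at most six candidates with
coefficients on the McReynolds scale (default intercept 300 and slopes
150/90/−60/40, giving responses spanning tens to hundreds of
retention-index units), and Gaussian noise calibrated by
`noise_sd_for_r2()` so the true-support model has $R^2 \approx 0.997$,
the fit-quality regime of the real models. What it does **not** emulate:
the heavy-tailed and discrete distributions of real descriptor families,
block structure tied to descriptor semantics, and any polymer physics —
so passing recovery tests demonstrate algorithmic correctness under the
assumed model, not field performance.

`recovery_experiment()` runs the full multi-start protocol on independent
replicates and reports the exact-support recovery rate with a binomial
confidence interval plus coefficient bias/RMSE. At zero noise, recovery is
exact (this is asserted in the tests); under the calibrated noise the GA
tends to select supersets of the true support, and the rate is reported,
never hard-coded.

## The bundled descriptor table is a stand-in

Only RBN and B04[N-Si] can be computed from the molecular graph; the
remaining twelve descriptors of the reference models (3D-MoRSE, GETAWAY,
autocorrelation, edge-adjacency, Burden and property descriptors) require
optimised 3D geometries and spectral machinery that are out of scope here.
The packaged table `descriptors_synthetic.csv` therefore carries the two
computed columns plus twelve *simulated* columns with family-plausible
locations and scales (`simulate_descriptor_table()`, fixed seed). All
pipeline code runs unchanged on it, and the Z/U models — whose two leading
descriptors are the computed ones — fit respectably, but quantitative
agreement with the reference coefficients, the 0.9964–0.9986 calibration
$R^2$ band, the external SDEP values, the $r = 0.79$ correlation between
B04[N-Si] and SpMAD_AEA(bo), and the 67–81 % PC1+PC2 variance band
require the measured descriptor values; the acceptance tests state those
expectations and fail against the stand-in by design. Users with a
measured table in the same layout can drop it in via
`load_descriptors(path)`.

## Numerical conventions and problem sizes

Rank-deficient designs abort with the offending columns named; designs
with condition number above $10^{10}$ warn. Leverages above
$1 - 10^{-10}$ make LOO undefined and yield an error from `q2_loo()`
(inside `fit_qsrr()` the statistic becomes `NA` instead, since Monte Carlo
resampling legitimately produces training sets where a lone carrier of a
binary descriptor has leverage 1). All stochastic components (GA,
Monte Carlo, the generator) take explicit integer seeds and are
bit-reproducible. The test suite exercises the GA-versus-exhaustive check
on a 20 × 30 instance with supports up to size 3 (4,525 subsets) and the
distributional checks of the generator at $n = 2000$ — sizes chosen to
make the oracles exact while keeping the suite quick.

## Known limitations

* The twelve non-graph descriptors are not computed; see above.
* RBN parity with other software is only guaranteed up to an additive
  constant per backbone convention.
* The six-symbol composition notation of the cyanoalkyl family is not
  fully specified in the source tables; the unit catalogue is the
  package's best-evidence resolution and is user-configurable.
* No applicability-domain analysis, y-scrambling or bootstrap; no PLS or
  regularised alternatives to OLS.
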