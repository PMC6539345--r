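# siloxqsrr

Quantitative structure–retention relationship (QSRR) modelling of the first
five McReynolds constants of 29 poly(siloxane) gas-chromatographic
stationary phases.

Poly(siloxane) columns dominate gas–liquid chromatography: an Si–O backbone
whose methyl substituents are partially replaced by phenyl, 3,3,3-trifluoropropyl
or cyanoalkyl groups, tuning polarity and selectivity over a wide range.
Column polarity is traditionally summarised by the McReynolds constants
X, Y, Z, U, S — the retention-index differences of benzene, butanol,
2-pentanone, nitropropane and pyridine between the test phase and squalane.
This package characterises the phases the other way around: each McReynolds
constant is modelled as a sparse multilinear function of **theoretical
molecular descriptors** computed on a 20-unit oligomer model of the polymer,

```
R = b0 + b1 d1 + ... + bk dk ,   k <= 6 ,
```

with the descriptor subset chosen by a genetic algorithm whose fitness is
the leave-one-out cross-validated determination coefficient Q²_loo
(1 − PRESS/TSS). Models are validated on a fixed five-phase external set
(Q², SDEP) and by Monte Carlo repeated random splitting, and the selected
descriptors feed a correlation-matrix PCA that classifies the columns in
the PC1–PC2 plane.

The package is written tidyverse-style: loaders return tibbles, fitted
objects have `tidy()`/`glance()` methods, result objects have `autoplot()`
methods, and everything chains with the pipe.

## What is inside

* **Phase data** — the 29 phase compositions and McReynolds constants, the
  reference model definitions, and the fixed 24 + 5 calibration/external
  split (`load_phases()`, `load_reference_models()`, `split_external()`).
* **Oligomer builder** — nearest-integer allocation of a composition onto a
  20-unit chain, uniform comonomer interleaving, hydrogen-suppressed
  molecular graphs with trimethylsiloxy termini, SMILES export, and the
  graph descriptors RBN (rotatable bonds) and B04[N-Si] (N–Si pair at
  topological distance 4) (`build_oligomer()`, `graph_descriptors()`,
  `write_smiles()`).
* **Descriptor pre-filtering** — variance rule plus greedy |r| > 0.85
  redundancy pruning (`prefilter_descriptors()`).
* **QSRR core** — OLS fits with standard errors, standardised slopes,
  SDEC/SDEP, Q²_loo via the leverage shortcut, external Q² in its three
  standard variants, Monte Carlo validation (`fit_qsrr()`, `q2_loo()`,
  `validate_external()`, `monte_carlo()`).
* **GA selection** — elitist genetic algorithm with uniform crossover,
  rank-roulette selection and multi-start descriptor pooling
  (`ga_evolve()`, `multi_start_pool()`).
* **PCA classification** — correlation-matrix PCA of each model's variable
  set with biplot export (`response_pca()`, `biplot_data()`, `autoplot()`).
* **Synthetic data** — seeded generator of block-correlated descriptor
  matrices with sparse linear responses on the McReynolds scale, plus a
  support-recovery experiment harness (`generate_qsrr()`,
  `recovery_experiment()`).

**Important caveat.** The packaged descriptor table
(`descriptors_synthetic.csv`) is a *synthetic stand-in*: only `RBN` and
`B04[N-Si]` are computed from the oligomer graphs; the twelve
geometry/spectrum-based descriptor columns are simulated
(`simulate_descriptor_table()`) because computing them is outside this
package's scope. Analyses that depend on those twelve columns therefore do
not reproduce the reference models' statistics; supply a measured
descriptor table via `load_descriptors(path)` to do so.

## Worked example

```r
library(siloxqsrr)

phases <- load_phases()
graph_descriptors(phases) |>
  dplyr::filter(code %in% c("OV-1", "OV-17", "OV-210", "SILAR 10CP", "NPS-100"))
#> # A tibble: 5 × 3
#>   code         RBN `B04[N-Si]`
#>   <chr>      <int>       <int>
#> 1 OV-1          42           0
#> 2 OV-17         62           0
#> 3 OV-210       102           0
#> 4 SILAR 10CP   162           0
#> 5 NPS-100       82           1
```

RBN rises from poly(dimethylsiloxane) (OV-1, 42: the 42 backbone Si–O
bonds) through phenyl (OV-17), trifluoropropyl (OV-210) and cyanopropyl
(SILAR 10CP) substitution — the substituent increments follow
methyl < phenyl < cyanoethyl < trifluoropropyl = cyanopropyl — and
B04[N-Si] flags exactly the cyanoethyl-bearing phases (NPS-100 here): in a
cyanoethyl group the nitrile nitrogen sits four bonds from the silicon.

Refitting the reference Z-model descriptor set on the 24 calibration
phases of the bundled (partly synthetic) table:

```r
data <- qsrr_data(phases, load_descriptors())
models <- refit_reference_models(data)
glance(models$Z)
#> # A tibble: 1 × 6
#>   response r.squared  sdec q2.loo  nobs n.descriptors
#> 1 Z            0.984  21.1  0.963    24             6
```

The two structure-derived descriptors carry the fit (RBN slope 5.2 ± 0.2,
standardised slope ~1; B04[N-Si] slope 134 ± 16), while the simulated
columns are statistically silent — which is exactly what a stand-in should
do.

## Learning more

The methods vignette (`vignettes/qsrr-mcreynolds.Rmd`) documents the model,
the GA protocol and its parameters, the validation statistics, the
synthetic-data design and the package's numerical conventions.
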