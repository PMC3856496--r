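# TriTV

Tricluster detection in gene × condition × time expression tensors by
total-variation regularized tensor factorization.

## What problem this solves

Time-series expression experiments repeated under several conditions
(abiotic stresses, treatments, patients) assemble into a third-order tensor
`A` of genes × conditions × time-points, with possibly negative entries.
Practitioners want *modules* (triclusters): a gene set, a condition set and
a — ideally consecutive — set of time-points that respond coherently, e.g.
"these 300 genes co-regulate under cold and osmotic stress between 6 h and
24 h". TriTV is for bioinformaticians who have such a tensor (or want to
benchmark a triclustering method) and need module discovery whose time sets
are encouraged to be contiguous.

## The model

TriTV minimizes, over factor matrices `U` (genes × K), `V` (conditions × K)
and `W` (time × K),

```
|| A − Σₖ uₖ ∘ vₖ ∘ wₖ ||²_F  +  α Σₖ || B wₖ ||₁
    s.t.  W ≥ 0,  1ᵀ wₖ = 1,
```

a rank-K CP/PARAFAC decomposition plus the total variation of each time
profile (`B` is the first-difference matrix). The TV term drives time
profiles toward piecewise-constant shapes, i.e. modules supported on
consecutive time intervals. `U` and `V` are updated in closed form
(alternating least squares); the nonsmooth `W` subproblem is solved by ADMM
with soft-thresholding, the sum-to-one constraint enforced inside each
update. Modules are then read off the factor columns by per-column sign
correction and thresholding with parameters `τ1, τ2, τ3`. Discovered
modules are scored against planted ground truth with matched-mean Fscore
and NMI. The methods vignette (`vignettes/tritv-methods.Rmd`) derives and
justifies every piece.

## Worked example

```r
library(TriTV)

## a 60 x 60 x 20 tensor with 3 planted 15-gene x 15-condition modules,
## each on a 6-time-point interval, 1% of cells overwritten with noise
sim <- generatePlantedTensor(n1 = 60, n2 = 60, n3 = 20, K = 3,
                             genesPerModule = 15, conditionsPerModule = 15,
                             intervalLength = 6, noiseDensity = 0.01,
                             seed = 5)

fit <- tvFactorizeRestarts(sim$tensor, K = 3, nRestarts = 3, seed = 5,
                           alpha = 10)
fit
#> TVFit: K = 3, alpha = 10, rho = 1 (constrained W-update)
#>   16 outer iteration(s), converged (outer tol 0.001)
#>   objective: 2348.14 -> 498.775
#>   best of 3 restarts (objectives 498.821, 498.798, 498.775)

mods <- extractModules(fit)          # tau = (1, 1, 0.75) from the fit
mods[[1]]
#> TriModule 1: 15 gene(s), 15 condition(s), 6 time-point(s)
#>   time: t15, t16, t17, t18, t19, t20 (contiguous)

evaluateModules(mods, sim$truth, fit = fit)[c("fscore", "nmi")]
#> $fscore
#> [1] 1
#>
#> $nmi
#> [1] 1
```

The objective trace is strictly informative: a decreasing sequence ending
near its floor means the alternating solver converged; `fscore = 1, nmi = 1`
say every planted module was recovered exactly (the matching table in the
full `evaluateModules()` output shows which found column pairs with which
planted module). On real data, pick `K` near the expected module count,
keep `alpha = 10`, and loosen `tau` (e.g. `c(0.5, 0.5, 0.75)` for noisy
patient data).

A command-line interface wraps the same functions:

```sh
inst/scripts/tritv simulate  --k 3 --seed 7 --out-dir sim/
inst/scripts/tritv factorize --input sim/tensor.tsv --k 3 --alpha 10 \
    --restarts 5 --seed 7 --out-dir fit/
inst/scripts/tritv evaluate  --modules fit/modules.json --truth sim/truth.json \
    --out report.json
inst/scripts/tritv benchmark --preset 3module-low --restarts 5 --out-dir bench/
```

Tensors travel as long-format TSV (`entity1  entity2  time  value`; dense,
with `--fill-missing interpolate` for gappy time grids), modules and
reports as JSON; every run writes a `manifest.json` (config, seed,
versions, objective trace) sufficient to reproduce it exactly.

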