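---
title: "Tricluster detection with total-variation regularized tensor factorization"
author: "TriTV authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tricluster detection with total-variation regularized tensor factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TriTV)
```

## The problem and the model

Time-series expression experiments run under several conditions (abiotic
stresses, treatments, patients) naturally assemble into a third-order tensor
$\mathcal{A} \in \mathbb{R}^{n_1 \times n_2 \times n_3}$ of genes $\times$
conditions $\times$ time-points; entries may be negative (log-ratio data).
A *module* (tricluster) is a gene set, condition set and time-point set that
behave coherently, and because the data are time series a useful module
should live on a *consecutive* stretch of time-points.

TriTV fits a rank-$K$ CP/PARAFAC-style decomposition whose time factor is
penalized by total variation:

$$
\min_{U, V, W}\;
\Big\|\mathcal{A} - \sum_{k=1}^{K} u_k \circ v_k \circ w_k\Big\|_F^2
+ \alpha \sum_{k=1}^{K} \|B\, w_k\|_1
\qquad \text{s.t. } W \ge 0,\; \mathbf{1}^T w_k = 1,
$$

where $u_k, v_k, w_k$ are the columns of $U$ ($n_1 \times K$, genes), $V$
($n_2 \times K$, conditions) and $W$ ($n_3 \times K$, time), $\circ$ is the
outer product, and $B$ is the $(n_3-1) \times n_3$ first-difference matrix,
so $\|B w_k\|_1$ is the total variation of the $k$-th time profile. The L1
penalty on first differences drives profiles toward piecewise-constant
shapes, i.e. modules supported on consecutive time intervals. $U$ and $V$
carry no sign constraint; the time profiles are nonnegative with unit column
sums, which fixes the scale indeterminacy of the trilinear model along the
time mode.

## The solver

The objective is minimized by block coordinate descent over the three
factors (`tvFactorize()`):

* **Gene and condition factors** have closed-form unconstrained
  least-squares updates through the mode-1 and mode-2 unfoldings,
  $U = A^{(1)} F^T (F F^T)^{-1}$ with $F = (W \odot V)^T$ and the analogous
  expression for $V$ with $F = (W \odot U)^T$, where $\odot$ is the
  column-wise Kronecker (Khatri-Rao) product. The systems are solved by
  dense factorization, never by forming an inverse; a near-collinear factor
  pair (condition number above $10^{12}$) gets a $10^{-10}$ ridge and a
  warning, and an outright singular system falls back to the pseudoinverse.
  The condition update deliberately mixes the *stale* time factor with the
  *fresh* gene factor (Gauss-Seidel ordering).
* **The time factor** couples a quadratic term with the nonsmooth TV
  penalty, so it is solved by ADMM (`solveTimeFactorADMM()`): the penalty is
  split onto an auxiliary variable $P \approx B W$ with scaled dual $Q$, and
  the three updates iterate a quadratic solve for $\mathrm{vec}(W)$, an
  entrywise soft-threshold for $P$ at level $\alpha/\rho$, and dual ascent
  for $Q$. The $n_3 K \times n_3 K$ system matrix
  $F F^T \otimes 2 I + \rho\, I \otimes B^T B$ is assembled explicitly
  ($n_3 K \le 500$ in every case this package targets) and its factorization
  is cached across inner iterations.

**Handling the simplex constraint.** The quadratic $W$-update does not by
itself respect $\mathbf{1}^T w_k = 1$. We enforce the sum constraint
*exactly inside every update* through a KKT system (default,
`wUpdate = "constrained"`): the inner loop then converges to the
sum-constrained minimizer of the time subproblem, and on small instances its
solution matches (or beats) a dense grid search over the probability simplex.
Nonnegativity is enforced on exit by clipping and renormalizing -- in
practice the constrained solution is already nonnegative on expression-like
data, so the clip is inert. The alternative `wUpdate = "projected"` iterates
the plain unconstrained updates and projects once at the end; it is kept
because it is the exact fixed-point iteration of the three printed ADMM
formulas, but its end-projection can land visibly off the constrained
optimum (we measured objective gaps up to 0.24 on small integer instances,
versus $\le 10^{-8}$ for the constrained variant), so it is not the default.

**Stopping.** The inner ADMM loop stops when both the iterate change
$\|W_s - W_{s-1}\|_F$ and the primal residual $\|B W_s - P_s\|_F$ fall below
`innerTol` ($10^{-6}$ by default) or after `innerMaxIter` (200) iterations --
iterate stability alone can be reached while the split variable still
disagrees with $BW$, hence the two-part rule. The outer loop stops when
$\|\Delta U\|^2 + \|\Delta V\|^2 + \|\Delta W\|^2 \le$ `outerTol` (0.001 by
default, on the raw sum of squares, not normalized by matrix size) or after
`outerMaxIter` (100) iterations; `isConverged()` reports which.

**Initialization and determinism.** $U$ and $V$ start from i.i.d. normal
entries scaled by $\|\mathcal{A}\|_F / (K \sqrt{n_1 n_2})$ so the first
residual is on the order of $\|\mathcal{A}\|_F$ regardless of tensor size;
$W$ starts uniform-random and column-normalized; the ADMM state $P, Q$ is
re-randomized (small uniform values, scale $1/n_3$) at every outer iteration.
Every random draw comes from the single seeded RNG, so a fixed `seed` makes
the whole fit bitwise reproducible, and `tvFactorizeRestarts()` runs seeds
`seed + 0:(nRestarts-1)` and keeps the lowest final objective -- alternating
least squares is only locally convergent, and a handful of restarts is the
standard guard.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | -- | number of modules (decomposition rank); choose the expected module count |
| `alpha` | 10 | weight of the TV penalty, in squared data units per unit variation; performance is flat over roughly 1--20 on benchmark data, larger values flatten profiles until, at extreme values ($10^4$), every profile is constant |
| `rho` | 1 | ADMM penalty; any positive value converges, 1 works well at these scales |
| `tau` | (1, 1, 0.75) | extraction thresholds in $[0,1]$ for gene, condition and time modes; lower values admit more members. (1, 1, 0.75) suits sharply separated benchmark modules; real data typically wants looser gene/condition cuts (e.g. 0.5--0.85) |
| `outerTol` | 0.001 | outer stopping threshold on the summed squared factor change |
| `innerTol` / `innerMaxIter` | $10^{-6}$ / 200 | ADMM stopping rule |

## Module extraction

`extractModules()` turns the converged factors into label sets, one module
per column. Because $u_k \circ v_k = (-u_k) \circ (-v_k)$, each gene and
condition column is first *sign-corrected*: if its negative mass exceeds its
positive mass it is negated. An entity then joins module $k$ when its loading
reaches

$$ 0.5\,\tau \left( \max(u_k^+) + \min(u_k^+) \right), $$

where $u_k^+$ is the *positive part* of the column (negative entries counted
as zero). On an all-positive column this is the $\tau$-scaled midpoint of the
loading range; as soon as any entry is at or below zero the lower anchor is 0
and the cut sits at $0.5\,\tau \max$. We deliberately anchor at the positive
part rather than at the smallest strictly-positive entry: the latter is
discontinuous at zero, and on noiseless data -- where off-module loadings are
exact zeros or tiny negatives -- it jumps to the member midpoint and drops
half of every true module's members. The time rule uses the full column
range, $w_{t,k} \ge 0.5\,\tau_3(\max(w_k) + \min(w_k))$, with no sign
correction ($W$ is nonnegative after a completed fit). Ties are inclusive.

A column with no positive entries has an undefined rule; the mode
contributes an empty set, the module is flagged `degenerate`, and nothing is
invented. Degenerate or empty modules are *kept* so module indices stay
aligned with factor columns. Time-set contiguity is reported but not
enforced -- the TV penalty encourages it, and whether a discovered module is
contiguous is itself informative.

`buildMembershipMatrix()` flattens a module list into the binary
entities-by-modules indicator of one axis; with a patient axis this is the
membership matrix one feeds to an off-the-shelf clustering (e.g. `kmeans`)
to group patients by shared module participation. With 14 patients and
$K = 40$ this is a $14 \times 40$ binary matrix.

## The synthetic benchmark generator

`generatePlantedTensor()` emulates the planted-module protocol used to
validate the method: a zero background; $K$ modules, each a random gene set
$\times$ condition set $\times$ consecutive time interval filled with i.i.d.
$\mathrm{Uniform}(0.6, 1)$ signal; then a fraction `noiseDensity` (0.005,
0.01, 0.02 in the published protocol) of *all* tensor cells overwritten with
draws from the same distribution. The full benchmark geometry is
$400 \times 400 \times 50$ with $40 \times 40 \times 10$ modules. Choices
the protocol leaves open, fixed here once:

* module sizes, the signal distribution and the noise model ("density"
  read as a sparse corruption fraction; overwrite by default, additive
  Gaussian behind `noiseType = "additive"`) are as above, chosen so planted
  modules are clearly separable at low noise;
* gene and condition sets are pairwise disjoint across modules by default
  (`disjoint = FALSE` allows overlap);
* time intervals are placed pairwise non-overlapping, uniformly at random
  among such arrangements, whenever $K \cdot$ `intervalLength` $\le n_3$;
  when they cannot all fit (e.g. $K = 8$ or $10$ intervals of length 10 on
  50 time-points) they are placed independently and overlap. This crowding
  is what makes the many-module presets genuinely harder: overlapping
  intervals create correlated time profiles and ambiguous time-point
  ownership, and the benchmark scores drop for $K = 8, 10$ exactly as the
  published comparison shows.

What the generator does *not* emulate: real expression distributions
(heavy tails, gene-specific variance), correlated noise, partially
overlapping gene memberships, or missing data. Passing the benchmark
therefore demonstrates correct recovery of separable planted structure
under sparse corruption -- not performance on any particular organism's
data.

## Evaluation metrics

The published protocol scores discovered against planted modules with
Fscore and NMI but defines neither variant for triclusters; the conventions
here are:

* **Fscore** (`moduleFscore()`): each module is a set over three disjoint
  namespaces (genes, conditions, time-points); every found/truth pair gets
  an F1 (harmonic mean of set precision and recall); the maximum-weight
  one-to-one assignment (Hungarian matching, via igraph's bipartite
  matching) is taken; the score is the mean matched F1 over truth modules,
  unmatched truth modules contributing 0.
* **NMI** (`moduleNMI()`): each module list becomes a labeling of the
  element universe (all genes, conditions and time-points): an element gets
  the index of its module, elements in no module share a background label,
  and an element claimed by several found modules goes to the module with
  the larger absolute factor loading when a fit is supplied (lowest index
  otherwise). The score is $I(X;Y) / \sqrt{H(X) H(Y)}$. If both labelings
  are constant the value is 1 when they are identical and 0 otherwise; if
  exactly one is constant, 0. The square-root normalization is one of
  several in use; with it, reproduction of published score tables is
  meaningful only within a tolerance band.

Both metrics are invariant to module ordering and bounded in $[0, 1]$.

## Numerical choices and degenerate inputs

* Unfolding column order: the lower-numbered retained mode varies fastest;
  this is the unique ordering under which
  $A^{(1)} = U (W \odot V)^T$ (and the mode-2/3 analogues) hold, which the
  closed-form updates require. `foldTensor()` inverts it exactly.
* The objective recorded per outer iteration is computed through cached
  cross-products ($\|A\|^2 - 2\langle W, A^{(3)}F^T\rangle + \langle W^TW,
  FF^T\rangle$ plus the TV term), avoiding a full reconstruction at every
  step; `tvObjective()` recomputes it from scratch when called directly.
* A time-factor column that collapses to all zeros after clipping is reset
  to the uniform profile with a warning.
* Tensors are dense in memory throughout: the largest targeted case
  ($400 \times 400 \times 50$, $8 \times 10^6$ cells) is small by modern
  standards, and sparse storage would buy nothing.
* TV is undefined on a single time-point; `differenceMatrix(1)` and fits on
  $n_3 < 2$ are refused.

## Problem sizes used by the shipped checks

The test suite exercises fits from $2 \times 2 \times 3$ up to
$200 \times 200 \times 50$; the benchmark reproduction (test suite and
`scripts/acceptance.R`) runs the published protocol at half linear scale in
genes and conditions -- $200 \times 200 \times 50$ tensors with $20 \times
20 \times 10$ modules, the published noise densities, $K$ equal to the
planted count, $\alpha = 10$, $\tau = (1, 1, 0.75)$ and best-of-5 restarts.
Noise density and the signal distribution are scale-free, so the
signal-to-noise regime of the full-size benchmark is preserved; the
`benchmark` CLI subcommand runs the full $400 \times 400 \times 50$ geometry
with `--scale full`.

## Known limitations

* Alternating least squares converges only to local minima; restarts
  mitigate but do not remove this. Interpret single-run results with care.
* The factorization is trilinear (CP); Tucker-style mixing across modes is
  out of scope, as are orders above three.
* $K$ must be supplied; the method has no built-in rank selection.
* The extraction thresholds act per column and assume a bimodal loading
  profile (members well above background); diffuse modules extract poorly
  at $\tau$ near 1.
* On real data with overlapping true modules, NMI's unique-labeling
  convention caps the attainable score below 1 even for a perfect fit.
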