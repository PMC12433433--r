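---
title: "Distinguishing extreme and midpoint response styles with the scoring-matrix nominal response model"
author: "respstyles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing extreme and midpoint response styles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respstyles)
```

## The measurement problem

Likert questionnaires assume respondents use the K ordered categories in
the same content-driven way. In practice some respondents prefer the
endpoints (extreme response style, ERS) and others the midpoint (midpoint
response style, MRS), independently of item content. Two competing
conceptualizations exist: ERS and MRS as *opposite poles of one bipolar
trait*, or as *two separate traits*. The choice affects model complexity,
trait estimates and how a correction is applied, so an applied analyst
needs a way to decide between them — and to decide whether any response
style is present at all — from the data.

`respstyles` frames that decision as model selection among three variants
of one model: the multidimensional nominal response model (MNRM) with
fixed scoring functions. The probability that person $p$ answers category
$k \in \{0, \dots, K-1\}$ of item $i$ is

$$
P(Y_i = k \mid \theta) \;=\;
\frac{\exp\!\big([a_i \odot s_k]^\top \theta + c_{ik}\big)}
     {\sum_{m=0}^{K-1}\exp\!\big([a_i \odot s_m]^\top \theta + c_{im}\big)},
$$

where $\theta$ stacks the latent dimensions, $a_i$ holds one slope per
dimension, $c_{ik}$ are category intercepts (the first fixed to 0 for
identification), $\odot$ is the elementwise product, and $s_k$ is the
$k$-th column of a fixed *scoring matrix* with one row per dimension. The
scoring matrix is where the competing conceptualizations live (K = 5):

| model | rows of the scoring matrix |
|---|---|
| `null` | substantive: (0, 1, 2, 3, 4) |
| `ers_mrs` | substantive + bipolar style: (2, 1, 0, 1, 2) |
| `ers_plus_mrs` | substantive + ERS: (1, 0, 0, 0, 1) + MRS: (0, 0, 1, 0, 0) |

With the linear substantive row alone the model is exactly the
generalized partial credit model; the package tests verify this against an
independently coded GPCM. A useful identity (also under test): a bipolar
item with style slope $a$ is indistinguishable from a separate-dimensions
item with ERS and MRS slopes both $a$ evaluated at perfectly
anti-correlated style traits, because $(2,1,0,1,2) - 1 =
(1,0,0,0,1) - (0,0,1,0,0)$ and category-constant terms cancel in the
softmax. The separate-dimensions model therefore *contains* the bipolar
model on the correlation boundary, and both contain the null model.

```{r scoring}
build_scoring_matrix("ers_plus_mrs", K = 5, n_substantive = 1)
```

## What the generator emulates

`generate_dataset()` reproduces the data-generating regimes of the
simulation design the package is built around:

* substantive traits: independent standard normal, 1 or 2 dimensions;
  with 2 dimensions, items split evenly (between-item
  multidimensionality);
* item slopes: i.i.d. log-normal with log-mean 0 and log-SD 0.3 (median
  discrimination 1; printed as a variance with a lost exponent in some
  sources, the log-SD reading is configurable via `slope_log_sd`);
* intercepts: fixed at $(-2,-1,0,-1,-2)$ for every item, giving
  mirror-symmetric category curves peaked on the midpoint at
  $\theta = 0$;
* style traits: one bipolar trait with SD $\sigma_{RS} \in \{0.6, 1,
  1.5\}$ (weak / medium / strong), or an (ERS, MRS) pair with common SD
  $\sigma_{RS}$, correlation $r_{RS} \in \{-.5, 0, .5\}$, independent of
  the substantive traits;
* style slopes: the same log-normal; with `slope_corr = 1` each item's
  MRS slope is its ERS slope copied, with `slope_corr = 0` drawn
  independently.

The factor grids (`condition_grid()`) comprise 12 null, 36 bipolar and
216 separate-dimensions cells. Every (cell, replication) seed is a stable
hash of (base seed, cell index, replication index), so any record can be
reproduced in isolation and a longer run extends a shorter one without
changing its early records. Simulated datasets are redrawn under a derived
sub-seed (and the redraw counted) until every item category is endorsed at
least once, since an unendorsed category makes that intercept
inestimable.

What the generator deliberately does *not* emulate: person-varying item
parameters, non-normal traits, style effects that vary by item position
(e.g. fatigue-driven MRS), correlations between substantive and style
traits, or additional styles such as acquiescence. Passing tests therefore
show that the selection machinery works when the fitted family contains
the generating process — they do not certify behavior under
misspecification.

## Estimation

`fit_mnrm()` maximizes the marginal likelihood (latent means fixed at 0,
variances at 1, all pairwise latent correlations free) with a Bock–Aitkin
EM algorithm:

* **E-step.** Person posteriors over a product Gauss–Hermite grid,
  rotated by the Cholesky factor of the current correlation matrix;
  missing responses simply contribute no factor (ignorable missingness,
  needed for the resampling mode).
* **M-step (items).** Each item's slopes and free intercepts maximize the
  expected complete-data multinomial-logit likelihood by Newton steps
  with step-halving, under box constraints (slopes in $[10^{-3}, 20]$,
  $|c| \le 15$). Items sharing a loading pattern share one design matrix.
* **M-step (correlations).** Posterior second moments rescaled to unit
  diagonal. This update is not an exact conditional maximizer, so it is
  proposed only every third cycle, damped by 0.7, and accepted subject to
  the safeguard below.
* **Safeguard and acceleration.** The algorithm keeps a fallback state
  whose marginal log-likelihood provably did not decrease; any cycle that
  observes a drop (possible only after a correlation update or an
  extrapolation) rolls back to it. Between safeguard points, a
  Ramsay-style geometric extrapolation fires every other cycle. The
  recorded log-likelihood trace is consequently non-decreasing — an
  invariant under test.
* **Convergence.** Log-likelihood change below `tol_loglik` (default
  `1e-6`; the study driver uses `1e-4`, the default of the mirt engine
  this class of analyses is usually run with) or maximum parameter change
  below `tol_param`. Non-converged fits are returned flagged and are
  still scored by the selection layer, with an optional quasi-Newton
  direct-maximization fallback (`direct_fallback`).

### Quadrature choices

Grid sizes are the main cost lever. Standalone fits default to 61 points
(T=1), 21 (T=2), 9 (T=3), 7 (T=4): the unidimensional grid is kept fine
because with N = 2000 and 20 items person posteriors are sharp enough
that a 21-point grid leaves a visible systematic drift (up to ~0.26
logits) in the extreme-category intercepts, which disappears on denser
grids.

`fit_battery()` — the function behind every model comparison — overrides
these defaults, because AIC/BIC differences of a few dozen log-likelihood
units decide selections and quadrature error must not masquerade as model
fit. Two rules shape its grids:

* *matched substantive resolution*: every model integrates the
  substantive dimensions on the same fine grid (15 points per dimension
  for D = 1, 9 for D = 2). These posteriors are the peaked ones (slopes
  reach 4 scoring units), so matching their resolution across models
  cancels the dominant error term and keeps nested likelihoods ordered;
  on dense-grid reference evaluations the residual distortion of
  between-model log-likelihood *differences* on null-generated data is
  ~1–3 units, well below the smallest criterion penalty in the design
  (about 21);
* *finer resolution for smaller models*: the bipolar model's single
  style dimension is resolved on the same fine grid, while the
  separate-dimensions model's two style dimensions get 7 points each
  to keep its node count tractable. Under strong styles
  the bipolar posterior is as sharp as the substantive one, and
  under-resolving it inflates the apparent advantage of the
  separate-dimensions model by tens of log-likelihood units. The
  standard estimation engine for this model class applies the same
  pattern across model dimensionalities (e.g. 31² nodes for
  two-dimensional but 15³ for three-dimensional fits), so comparisons
  inherit an analogous, parsimony-leaning error asymmetry there too.

The battery also applies deterministic *nested restarts*: if a larger
model ends below a model it contains, it is refitted from that model's
solution embedded in the larger space (style slopes at the lower bound,
or ERS = MRS slopes with correlation near −1), and the better fit is
kept.

## Selection rules

`information_criteria()` computes $\mathrm{AIC} = -2\ell + 2p$ and
$\mathrm{BIC} = -2\ell + p\ln N$ with $p = J(1 + R + K - 1) + T(T-1)/2$
free parameters ($R$ style dimensions, $T$ total). Exact ties (measure
zero in practice) go to the more parsimonious model. The combined rule
(`combined_select()`) uses BIC as a gate — null against the better
(lower-BIC) of the two style models, the reading we adopt of a
two-stage proposal whose comparison set is not fully specified — and, if
the gate opens, lets AIC pick between the two style conceptualizations.
Non-finite criteria exclude a model with a warning rather than aborting a
replication.

```{r example, eval = FALSE}
cond <- gen_condition("ers_mrs", N = 500, J = 10, D = 1, sigma_RS = 1,
                      seed = 7)
ds <- generate_dataset(cond)
battery <- fit_battery(ds, K = 5, D = 1,
                       options = fit_options(tol_loglik = 1e-4))
criterion_table(battery)
```

## Study driver and problem sizes

`run_study()` executes cells × replications with derived seeds (the
parallel option cannot change results: seeds attach to records, not
workers), and renders tidy records, per-criterion accuracy tables,
factor marginals, and the conventional "corr 1 / corr 0" paired display
for the separate-dimensions regime. The full design (264 cells × 250
replications, models up to four latent dimensions) is a long-running
mode — hours on one CPU, embarrassingly parallel across records.

The package's own test suite and acceptance script run reduced
reproductions chosen to finish on a single CPU in minutes while keeping
binomial noise interpretable: the D = 1 null crossings at 40–50
replications (BIC should select null essentially always; AIC stays above
its reference bound in the hardest crossing), and the strong-style
bipolar crossings ($\sigma_{RS} \ge 1$, N ≥ 500, J = 20) at 40
replications (BIC accuracy at or near 100%). Tolerances are three
binomial standard errors around the reference percentages.

`resample_study()` implements the companion design for applied data: draw
people and items without replacement from a large dataset, repair
category coverage by writing each never-endorsed category into the
item's first missing cell (logging items that have no missing cells),
fit the battery, and report how often each criterion picks the
model assumed true for the parent dataset.

## Numerical notes and limitations

* Correlation matrices are kept positive definite by an eigenvalue floor
  (`1e-3`) followed by rescaling; style-trait correlations can therefore
  approach but not reach ±1. The bipolar-boundary embedding uses −0.999.
* All internal category codes are 0..K−1; files use 1..K. The generation
  intercepts $(-2,-1,0,-1,-2)$ are reported in recovered form
  $(0,1,2,1,0)$ via softmax location invariance.
* Even K has no single midpoint, so MRS-containing scoring matrices
  reject it; the general odd-K rows are the end-category indicator
  (ERS), the midpoint indicator (MRS) and $|k - (K-1)/2|$ (bipolar).
* Intercept estimates of extreme categories are noisy at realistic N;
  recovery checks are phrased on averages, not per-item maxima.
* Standard errors, Bayesian estimation, IRTree and mixture
  representations, and within-item multidimensional substantive loadings
  are out of scope.
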