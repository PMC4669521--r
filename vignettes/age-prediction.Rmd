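---
title: "Methods: methylation-age scanning, calibration, and SVR panel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-age scanning, calibration, and SVR panel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methage` implements a two-cohort strategy for building a blood
methylation clock: a small genetically controlled discovery cohort is
scanned genome-wide for CpG sites whose beta value tracks chronological
age; the candidate panel is then re-measured in a larger, wider-age
validation cohort on a targeted platform, quality-controlled and
calibrated; finally, competing regression families are compared and the
smallest well-performing CpG panel is chosen by exhaustive leave-one-out
search. This vignette records the models, the tunable parameters, the
synthetic-data design, and the numerical choices, in that order.

## 1. The association scan

### Model and assumptions

For site $j$ with beta values $\beta_{js}$ and ages $a_s$ the scan fits
ordinary least squares $\beta_{js} = b_{0j} + b_j a_s + e_{js}$ and
summarises the fit by the Pearson correlation $R_j$. Significance uses
the exact identity between the OLS slope test and the correlation test,

$$t_j = R_j\sqrt{\frac{n-2}{1-R_j^2}},$$

two-sided on $n-2$ degrees of freedom. The working assumptions are the
usual ones for site-wise array scans: a linear age trend on the beta
scale over the cohort's (narrow) age range, roughly Gaussian residuals,
and independent samples. Monozygotic-twin cohorts mildly violate
independence (pairs share age and genotype); since each pair contributes
one age, the effective age resolution is the number of pairs, which the
synthetic generator reproduces so that test expectations are computed
under the same conditions.

Two selection rules are exposed, both with *strict* inequalities exactly
as stated: a loose rule `p < 0.01 & R² > 0.5` combining nominal
significance with effect size (suited to a 16-sample scan where p-values
alone are weak), and a strict rule `q < 0.01` with Benjamini–Hochberg
adjusted q-values for FDR control. BH is the field default for 450K-scale
scans; the implementation delegates to `stats::p.adjust(method = "BH")`
and is pinned by a hand-computed step-up example in the tests.

### Pre-processing parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `detection_p_max` | 0.01 | – | array calls above this detection p are unreliable; strictly greater-than is masked |
| `knn_k` | 10 | sites | imputation from the 10 nearest site rows, the customary choice for methylation arrays |
| `p_max`, `r2_min` | 0.01, 0.5 | – | loose rule |
| `fdr_max` | 0.01 | – | strict rule |

KNN imputation replaces a missing cell (site $i$, sample $s$) by the mean
of sample $s$'s observed values at the $k$ sites nearest to $i$.
Distances are Euclidean over mutually observed samples, rescaled by
$\sqrt{n_\text{samples}/n_\text{mutual}}$ so that sparsely shared pairs
are not artificially close; candidate neighbours missing in $s$ are
skipped rather than imputed recursively; ties are broken by site order in
the table, which makes the procedure deterministic. This is a documented
approximation to the classic microarray KNN imputation, not a
re-implementation of any specific package.

Zero-variance sites return `R = 0, p = 1, slope = 0` with a `degenerate`
flag instead of `NaN`, so record tables stay total and filterable; a
perfect linear site underflows to `p = 0`. Island enrichment of a
selected set is a two-sided Fisher exact test on
{selected, rest} × {island, non-island}; the annotation is a
user-supplied two-column table (no array manifests are downloaded).

## 2. Targeted-platform calibration and QC

Mass-spectrometric methylation calls are linearly distorted relative to
the true methylated fraction, especially at low–medium methylation. A
dilution series of standards of known methylation (0, 10, …, 100 %)
measured on the platform fits the correction
$\text{corrected} = a\cdot\text{measured} + b$ by OLS of known on
measured. Corrected values are clipped to $[0,1]$ — the correction line
can map extreme measurements slightly outside the unit interval and beta
values are fractions by definition; clip counts are reported. Note the
deliberate asymmetry: the *measured* scale is an instrument scale and is
not clipped.

Because the regression uses the *measured* values as the regressor, a
noisy standard series attenuates the fitted slope by the classical
errors-in-variables factor $S_{xx}/(S_{xx} + (n-1)\sigma^2)$; with 11
levels and measured-scale noise of 0.02 this is a ≈ 1.7 % downward bias.
The acceptance machinery measures the mean fitted slope over 100
simulated series under exactly these conditions, so the reported value
sits slightly below the generating slope — that is a property of the
calibration procedure itself, not an implementation artefact.

The QC order is fixed and logged: per-value confidence filter (keep
strictly above 1.9 on the 0–5 score), then missingness filter (drop sites
with > 70 % missing, then samples with > 70 % missing *on the
site-reduced table* — site-level artefacts such as failed amplicons
should not drive sample exclusion), then calibration, then site
re-selection by `|R| > 0.5` on pairwise-complete data (no imputation at
this stage; the scan is the only imputing step). Re-running a filter on
its own output is a no-op, which the tests assert.

## 3. The four regression families

All four share one contract: a wide table (one row per sample, an age
column, one numeric column per CpG site), `predict()` by column name, and
MAD = mean |predicted − observed| in years as the headline metric.

* **Linear** — least squares via QR. Rank-deficient designs are an
  error naming the collinear columns; there is no silent pseudo-inverse.
* **Quadratic** — least squares on $[1, x_j, x_j^2]$, *pure squares
  only*: with $p = 11$ sites and $n = 49$ samples this is 23 parameters,
  whereas a full second-order model (79) would be unidentifiable.
* **BP neural network** — one hidden layer (default 3 sigmoid units),
  linear output, full-batch gradient descent (rate 0.05) on standardised
  inputs and response for exactly 1000 epochs unless the loss plateaus
  (change < 1e−12); weights initialised uniformly in ±0.5 from the seed,
  so training is bit-reproducible. The loss curve is retained. This is a
  deliberately plain network: proprietary training heuristics from
  commercial tools are not emulated.
* **ε-SVR, RBF kernel** — the package's own solver; see below. Defaults
  `cost = 2, gamma = 0.1, epsilon = 0.1` are the conventional
  fixed-hyperparameter choice for this application; no grid search is
  provided by design.

### The SVR solver

Features and response are standardised internally (without this, a fixed
$\gamma = 0.1$ is meaningless across the beta scale [0, 1] and the age
scale [20, 80]; the widely used LIBSVM interface scales by default, and
`epsilon` applies on the standardised response). The dual

$$\min_\beta\ \tfrac12\beta^\top K\beta - y^\top\beta +
\varepsilon\sum_i|\beta_i| \quad\text{s.t.}\quad \sum_i\beta_i = 0,\;
|\beta_i|\le C$$

is rewritten over $(\alpha,\alpha^*)\in[0,C]^{2n}$ and solved by
sequential minimal optimisation with maximal-violating-pair selection:
each step solves the two-variable subproblem in closed form and updates
the gradient in $O(n)$. Numerical choices:

* stopping at KKT gap $m - M \le$ `tol` = 1e−6; exceeding `max_iter`
  = 1e5 without reaching the gap is an **error**, not a warning;
* curvature guard $\eta \ge$ 1e−12 for (near-)duplicate points;
* the bias is the midpoint $(m+M)/2$ of the optimal-multiplier interval;
  when no point leaves the ε-tube this degenerates gracefully to the
  midpoint of $[\max(y)-\varepsilon,\ \min(y)+\varepsilon]$, chosen for
  determinism since every value in the interval is optimal;
* a zero-variance response short-circuits to a constant predictor with
  no solver call.

The returned object keeps the dual coefficients, support indices, total
slack $\sum\xi_i$, the dual objective, and the KKT gap, so feasibility
($\sum\beta_i = 0$, $|\beta_i|\le C$, zero weight strictly inside the
tube) is assertable. The test suite checks the solver two independent
ways: against a dense convex-QP solver (accelerated projected gradient
with exact projection onto the box–hyperplane intersection, coded in the
test helpers) to 1e−6 on the objective, and against an unrelated LIBSVM
implementation to 1e−3 on predictions.

## 4. Leave-one-out subset search

`loo_cv()` refits on each $n-1$ subset and predicts the held-out sample;
the BPNN is reseeded per fold (`seed + fold`) so folds are independent
but reproducible. `exhaustive_subset_search()` evaluates the LOO MAD of
*every* subset at each requested size — the search is exhaustive by
design (no greedy or penalised shortcut), guarded at $p\le 20$ sites
(override flag available) because the cost is
$\sum_k\binom{p}{k}\times n$ fits. Ties in the per-size minimum are
broken by the lexicographically smallest site-id tuple.

`choose_final_subset()` formalises the accuracy-versus-panel-size
balance: the smallest size whose minimal LOO MAD lies within `tolerance`
(default 0.05 years) of the global minimum. The default reproduces the
canonical decision pattern in which minima of 4.72 y at six sites and
4.71 y at seven sites resolve to the six-site panel. The companion
over-fitting report (`compare_fit_loo()`) contrasts in-sample MAD with
LOO MAD for the same panel — the central methodological point: an
RBF-SVR refit on ~11 sites can show a training MAD several years below
its LOO MAD, so in-sample accuracy must never drive panel choice.

## 5. What the synthetic data emulates — and what it does not

The generator reproduces the statistical structure the analysis relies
on, with defaults chosen once as study conditions:

* **Discovery cohort**: 16 samples as 8 same-age twin pairs, ages
  uniform on [21, 32]. **Validation cohort**: 49–50 unrelated adults on
  [20, 80]; a blind cohort of 10.
* **Sites**: associated sites follow
  $\beta = \mathrm{clip}(b_0 + s\,a + e,\,0,\,1)$, $e\sim N(0,\sigma)$,
  background sites are flat. Noise is Gaussian on the beta scale then
  clipped — the simplest model consistent with bounded fractions. Slope
  magnitudes (defaults 0.005–0.02 beta/year; 0.017–0.03 in the
  high-signal scan-recovery setting, giving population $R^2 > 0.7$
  against $\sigma = 0.03$) and baselines are uniform; the baseline can be
  anchored at any age (`baseline_age`) so that mid-age levels stay inside
  the unit interval.
* **Validation trajectories** are anchored at age 50 with gentler slopes
  (0.003–0.006 beta/year) and a quadratic term
  $q\,(a-50)^2$, $|q|\in[1.5,4.5]\times10^{-4}$, noise 0.04: visibly
  curved (the quadratic deflection at the age extremes is comparable to
  the linear span) but far from pathological. This regime was fixed at
  design time as the package's definition of a nonlinear age signal; under
  it the RBF-SVR beats the linear model in LOO MAD in roughly three
  quarters of seeded replicates, while in-sample it always looks better
  than it generalises.
* **Platform**: measured values are the inverse of the correction line
  `corrected = 2.285·measured − 1.2176` plus measured-scale noise;
  standards at 0–100 % in 10 % steps; confidence scores
  $N(3.25, 0.82)$ clipped to [0, 5], giving ≈ 95 % acceptance at the
  1.9 cutoff; value-level Bernoulli missingness, plus planted detection
  failures (one sample missing ~83 % of sites, one site missing ~80 % of
  samples) that the > 70 % rule must catch.
* **Seeding**: one integer seed, deterministically split into named
  sub-streams (cohort, sites, betas, mask, standards, …), so each stage
  is independently reproducible and a pipeline rerun is byte-identical.

Not emulated: bisulfite-conversion chemistry, probe hybridisation or
read counts; batch effects and cell-composition heterogeneity; sex
chromosomes; population structure; between-twin epigenetic drift. A
passing suite therefore shows the *procedures* are correct under the
stated statistical structure — it does not certify accuracy figures on
real cohorts, where the missing effects (especially cell composition and
batch) typically inflate prediction error.

## 6. Problem sizes and runtime choices

The shipped tests and the acceptance script run desk-scale problems
chosen as representative rather than exhaustive: a 10,000-site scan with
500 planted sites for recovery; 20 replicate 2,000-site null scans for
FDR control; 100 replicate standard series for calibration; 20 replicate
49-sample cohorts for the model-ordering and over-fitting properties; and
subset searches over 6-site panels (63 subsets) where an independent
enumeration is feasible. The end-to-end pipeline default scans 2,000
sites and searches panel sizes 1–2; all stages scale to array size
(485k × 16) since the scan is closed-form vectorised, with memory the
only practical constraint.

## 7. Known limitations

* The per-site model is strictly linear in age; strongly saturating CpGs
  are better served by the quadratic/SVR stages than by the scan itself.
* KNN imputation is quadratic in the number of *incomplete* sites in the
  worst case; for near-complete array data this is immaterial.
* The BPNN is a minimal reference network; it is not intended to match
  any particular commercial implementation cycle-for-cycle.
* Counts reported in different summaries of the same discovery analysis
  can disagree in the source literature of this design (e.g. 2,957
  vs 2,965 = 1,476 + 1,489 loose sites); where such figures matter this
  package treats the itemised positive/negative breakdown as canonical
  and surfaces both totals in documentation rather than reconciling
  silently.
* Exact reproduction of published cohort-specific MADs requires the
  original cohort tables; the package reproduces the *procedures* and
  their qualitative signatures on synthetic cohorts, and accepts any
  user-supplied dense beta TSV for real-data runs.
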