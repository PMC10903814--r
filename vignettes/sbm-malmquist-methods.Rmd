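---
title: "Efficiency and productivity measurement in sbmdea: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficiency and productivity measurement in sbmdea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmdea)
```

## The measurement problem

`sbmdea` benchmarks decision-making units (DMUs) — in the motivating
application, the health systems of 15 cities and counties — that convert
several inputs (institutions, beds, health technicians) into several outputs
(outpatient visits, admissions, bed-utilization rate) over a balanced panel
of years. Two questions are answered:

* **Static**: how efficient is each unit in each year, relative to the best
  practice observed that year?
* **Dynamic**: how did total factor productivity change between adjacent
  years, and how much of the change is catching up to the frontier versus
  the frontier itself moving?

Both are answered nonparametrically with data envelopment analysis (DEA):
the technology is the convex (conical, under constant returns) hull of the
observed input/output bundles, and each unit is compared against it by
linear programming. No production function is estimated.

## The slacks-based measure

Radial DEA models (CCR/BCC) measure only proportional contraction and miss
the slack left in individual inputs and outputs. The non-oriented
slacks-based measure avoids this. For unit $k$ with inputs $x_k \in
\mathbb{R}^m_{>0}$ and outputs $y_k \in \mathbb{R}^q_{>0}$, against peers
$(X, Y)$:

$$
\rho_k \;=\; \min_{\lambda, s^-, s^+}
\frac{1 - \frac{1}{m}\sum_i s^-_i / x_{ik}}
     {1 + \frac{1}{q}\sum_r s^+_r / y_{rk}}
\quad \text{s.t.}\quad
X\lambda + s^- = x_k,\;
Y\lambda - s^+ = y_k,\;
\lambda, s^-, s^+ \ge 0 .
$$

$s^-$ is the input excess and $s^+$ the output shortfall of the projection
$ (X\lambda, Y\lambda)$; $\rho \in (0, 1]$ with $\rho = 1$ exactly when no
slack remains. Variable returns to scale (VRS) add $\sum_j \lambda_j = 1$.
Because every slack enters relative to the unit's own level, the score is
invariant to rescaling any indicator by a positive constant — which is also
why the bed-utilization output can enter on its natural percent scale
without harmonizing units.

### Super-efficiency

Plain SBM cannot rank the efficient units: they all score 1. Tone's
super-efficiency SBM re-scores an efficient unit against the frontier formed
*without* it, measuring the smallest average input expansion
$\bar{x} \ge x_k$ relative to the smallest average output contraction
$\bar{y} \le y_k$ that would put the unit back on the reduced frontier:

$$
\delta_k \;=\; \min
\frac{\frac{1}{m}\sum_i \bar{x}_i / x_{ik}}
     {\frac{1}{q}\sum_r \bar{y}_r / y_{rk}}
\quad \text{s.t.}\quad
\bar{x} \ge X_{-k}\lambda,\;
\bar{y} \le Y_{-k}\lambda,\;
\bar{x} \ge x_k,\; 0 < \bar{y} \le y_k .
$$

$\delta \ge 1$ always, and $\delta > 1$ exactly for units strictly beyond
the reduced frontier. `solve_super_sbm()` implements the *unified* score
used in comprehensive-efficiency tables: inefficient units keep their plain
SBM score (the expansion program would flatten them all to 1, since an
enveloped unit needs no expansion), efficient units get $\delta$. A single
ranking with values on both sides of 1 results, and "DEA-effective" means a
score of at least 1 (`classify_effectiveness()`, tolerance $10^{-9}$ at the
boundary).

### Solving the programs

Both objectives are ratios of affine functions, so each is converted to a
single linear program by the Charnes–Cooper transformation ($t =$ the
reciprocal of the denominator, all variables scaled by $t$) and solved
exactly — no iterative fractional scheme, hence deterministic scores. The
LPs are small but frequently degenerate (ties among peers are common), so
the package carries a dense two-phase primal simplex using Bland's rule for
both pivot choices, which cannot cycle. Solver comparisons in the test suite
are made at $10^{-6}$; LP pivoting tolerances are $10^{-9}$.

The test suite checks the solver against an independent oracle that never
touches the transformation: on tiny instances ($n \le 4$, $m, q \le 2$) the
fractional objective is minimized by brute-force vertex enumeration of the
feasible polyhedron (a linear-fractional objective attains its minimum at a
vertex). The two routes agree to $10^{-6}$ on every instance tried.

## Returns to scale

The static "comprehensive efficiency" score is computed under CRS by
default. CRS is the convention in this methodology tradition and is
required for the scale-efficiency decomposition below to be defined; VRS is
available everywhere via `rts = "vrs"` and is used internally for the pure
technical efficiency component. Non-oriented super-efficiency programs on
strictly positive data remained feasible in all configurations we generate;
should a solver ever fail, the result carries its status and downstream
aggregation excludes and counts it rather than inventing a number.

## The Malmquist index and its decomposition

Let $D^a(z_b)$ be the distance (SBM score) of period-$b$ data on the
period-$a$ frontier. With the geometric-mean (Färe et al.) convention over
the interval $(t, t{+}1)$:

$$
\mathrm{EFFCH} = \frac{D^{t+1}(z_{t+1})}{D^{t}(z_{t})},\qquad
\mathrm{TECH} = \sqrt{\frac{D^{t}(z_{t+1})}{D^{t+1}(z_{t+1})}\cdot
                      \frac{D^{t}(z_{t})}{D^{t+1}(z_{t})}},\qquad
\mathrm{TFPCH} = \mathrm{EFFCH}\times\mathrm{TECH},
$$

and with own-period VRS scores $V$,
$\mathrm{PECH} = V^{t+1}(z_{t+1}) / V^{t}(z_{t})$ and
$\mathrm{SECH} = \mathrm{EFFCH}/\mathrm{PECH}$, so both product identities
hold by construction on every complete record. An index above 1 signals
improvement, exactly 1 no change, below 1 decline (`classify_change()`).

Two conventions needed deciding, because only the two product identities
are pinned down by the tradition this package follows:

* **Own-period distances are plain (self-inclusive) SBM scores**, not
  super-efficiency scores. This is the conventional distance function, and
  it is what makes the single-input/single-output CRS case collapse to
  productivity ratios — $\mathrm{TFPCH} = p_{t+1}/p_t$ and
  $\mathrm{TECH} = p^*_{t+1}/p^*_t$ for *every* unit, including the
  frontier-defining one — which the test suite exploits as an exact closed
  form on randomized data. Had the super-efficiency score been used
  own-period, the closed form would fail precisely for the best unit of
  each period.
* **Cross-period distances switch program by envelopment.** A unit
  enveloped by the other period's frontier gets the plain score ($\le 1$);
  a unit beyond it — where the plain program is infeasible — gets the
  expansion (super-efficiency) score ($> 1$). This is the only way a
  cross-period SBM distance can exceed 1 at all.

* **Aggregation is the arithmetic mean**, per interval across DMUs and per
  DMU across intervals. The product identities do *not* survive arithmetic
  averaging and are deliberately not asserted on aggregates; published
  tables built this way can show mean rows where
  $\mathrm{EFFCH} \ne \mathrm{PECH}\times\mathrm{SECH}$ without being
  wrong. (The packaged per-region fixture shows exactly this.) Incomplete
  records are excluded from means and counted, never imputed.

## The synthetic generator

Real yearbook panels of this kind are not redistributable, so validation
rests on a generator whose truth is known. It emulates the study shape —
by default 15 DMUs × 5 periods, 3 inputs, 3 outputs — via:

* a Cobb–Douglas CRS frontier $y^* = A_t \prod_i x_i^{\alpha_i}$,
  $\sum \alpha_i = 1$ (equal shares by default). Concavity plus CRS
  guarantee that no convex combination of observed bundles dominates a
  frontier point, so a unit generated *on* the frontier is DEA-effective
  exactly, not approximately;
* log-normal inputs (meanlog $\log 10$, sdlog 0.5 — dispersion comparable
  to regional resource stocks, though the magnitudes are irrelevant by unit
  invariance);
* multiple outputs as fixed positive multiples ($2^{-(r-1)}$) of the scalar
  frontier aggregate, keeping the true frontier one-dimensional and the
  truth record interpretable;
* half-normal inefficiency $u \ge 0$ with scale 0.3 (median efficiency
  $e^{-u} \approx 0.85$, occasional units near 0.5), redrawn per
  DMU-period; a fixed fifth of the units is placed exactly on the frontier
  ($u = 0$ in every period);
* geometric frontier drift $A_{t+1} = A_t(1 + g)$, default $g = 0.05$ per
  period — the magnitude of technical change typical of the application;
* one root seed feeding a single RNG stream (`withr::with_seed`), so a
  configuration reproduces bit-identically.

Flags exist to freeze the inefficiency draws and the input draws across
periods; with $g = 0$ both frozen give the no-change null in which every
Malmquist component must equal 1 to $10^{-6}$ — with several inputs the
null needs frozen inputs too, because the empirical hull otherwise shifts
with the draws even when the true technology is unchanged.

What the generator does *not* emulate: correlated inputs, measurement
error, serially correlated inefficiency, genuinely multi-dimensional output
mixes, or the magnitudes of any real region. Passing tests therefore
demonstrate that the estimators recover a data-generating process they are
correctly specified for; they say nothing about misspecification bias on
real data, where DEA's small-sample upward bias near the frontier and its
sensitivity to outliers remain.

## Problem sizes and checks in the shipped tests

The test suite runs entirely on generated data and the packaged fixture
tables. Sizes were chosen so the full suite completes in well under a
minute on one core: vertex-enumeration oracle comparisons on all shapes up
to $4 \times (2,2)$; decomposition identities on ~1,000 records across 17
seeded study-shaped panels; drift recovery ($g = 0.05$, single ratio) over
20 seeds, where the interval-mean TECH must fall in $[1.02, 1.08]$ in at
least 18 — with a positive efficient fraction the observed best
productivity ratio identifies $1 + g$ exactly, so this holds with margin;
rank recovery of true efficiency by Spearman correlation (median $\ge 0.8$
over 20 seeds at inefficiency scale 0.3).

## Known limitations

* Scores, slack aggregates and the five index components are
  contract-stable; individual intensity weights $\lambda$ are not — ties
  admit alternate optima and only the optimum value is unique.
* DEA scores are biased toward 1 at small $n$; recovery of generative
  efficiency is rank-level, not value-level.
* No environmental/contextual adjustment (three-stage analyses, bootstrap
  confidence intervals, global or biennial Malmquist variants) is included.
* The effectiveness rule applies printed 3-decimal values as-is when
  operating on fixtures and full precision when operating on computed
  scores.
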