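---
title: "Model-based design of Beta-regression dose-response experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based design of Beta-regression dose-response experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadose)
```

## The design problem

A concentration-response experiment distributes a fixed budget of
experimental units (here: flasks of sea urchin embryos) over doses of a
test compound. Where those doses sit, and how many flasks each receives,
determines the precision of everything estimated afterwards. `betadose`
treats that choice as a formal optimization problem: given a statistical
model for the response, a dose interval, and a stated inferential goal, it
finds the *approximate design* - support doses $x_1 < \dots < x_k$ with
weights $w_i > 0$, $\sum w_i = 1$ - that optimizes the corresponding
criterion, certifies the optimum, and audits any competing design by its
efficiency.

The motivating application is a developmental-toxicity assay in purple sea
urchin embryos exposed to trimethoprim, scored at 96 h for two binaryised
endpoints: early developmental arrest or death (rate among all examined
embryos, dose range 0-1000 uM) and aboral radialization (rate among
surviving larvae, observable only up to 450 uM because beyond that every
embryo arrests).

## The model

Flask-level response rates $y \in (0,1)$ are modeled as Beta distributed
with both shape parameters log-linear in dose $x$ (in raw uM - no
standardization):

$$y \sim \mathrm{Beta}(a(x),\, b(x)), \qquad
  a(x) = e^{\alpha_1 + \alpha_2 x}, \quad b(x) = e^{\beta_1 + \beta_2 x}.$$

The mean response is the logistic curve
$E(y \mid x) = 1/\{1 + e^{(\beta_1-\alpha_1) + (\beta_2-\alpha_2)x}\}$ -
sigmoidal, increasing whenever $\beta_2 < \alpha_2$ - while the variance
$ab/\{(a+b)^2(a+b+1)\}$ changes freely with dose. That dose-dependent
("inhomogeneous") spread is exactly what flask-level toxicity rates show:
tight replication at the extremes, wide replication on the rising limb.

The lethal concentration $LC_p$ solves $E(y\mid x) = p$:

$$LC_p = \frac{\log\{(1-p)/p\} - (\beta_1 - \alpha_1)}{\beta_2 - \alpha_2},$$

with delta-method gradient
$c = (1, LC_p, -1, -LC_p)/(\beta_2-\alpha_2)$, the vector that drives
c-optimality. It is undefined for a flat curve
($\beta_2 = \alpha_2$), and [lcp()] errors there rather than clip.

## Information and design criteria

One observation at dose $x$ carries Fisher information
$m(x,\theta) = J^\top I_2 J$, where
$I_2 = \begin{pmatrix} \psi'(a)-\psi'(a+b) & -\psi'(a+b)\\
-\psi'(a+b) & \psi'(b)-\psi'(a+b)\end{pmatrix}$
is the Beta shape-space information ($\psi'$ the trigamma function) and
$J$ the Jacobian of $(a(x), b(x))$ in
$\theta = (\alpha_1,\alpha_2,\beta_1,\beta_2)$. Each dose contributes rank
2, so two distinct doses already make the design information
$M(\xi,\theta) = \sum_i w_i\, m(x_i,\theta)$ nonsingular. The package
cross-checks this matrix against a Monte-Carlo estimate of the expected
negative log-likelihood Hessian in its test suite.

Because all criteria depend on the unknown $\theta$, nominal values are
required. `betadose` works throughout with a finite *prior* of up to six
nominal sets with probabilities $\lambda_i$ (equal by default), giving the
pseudo-Bayesian ("robust") versions directly; a single-set prior recovers
the locally optimal design. The packaged `nominal_priors()` carry the six
published sets per endpoint from the sea urchin study.

* **D-optimality** (parameter estimation):
  maximize $\sum_i \lambda_i \log\det M(\xi,\theta_i)$.
* **c-optimality for $LC_p$**:
  minimize $\sum_i \lambda_i \log\{c_i^\top M(\xi,\theta_i)^{-} c_i\}$,
  the prior-averaged log asymptotic variance of the plug-in $LC_p$.
* **Dual-objective (compound)**: maximize
  $\sum_i \lambda_i\{ W \tfrac14 \log\det M - (1-W)\log(c_i^\top M^- c_i)\}$.

The compound scaling deserves a note, because several conventions
circulate. This package uses the log-efficiency convex combination: the
$1/4$ makes the D term the log of a per-parameter efficiency, so both
objectives enter on comparable scales, $W=1$ ranks designs exactly like
robust D, and $W=0$ exactly like robust c. $W = 0.5$ - both goals equally
important - is the default used for the packaged reproductions.

Singular information hits sentinels ($-\infty$ / $+\infty$) rather than
errors, so optimizers reject such designs gracefully; a c criterion under a
singular-but-estimable design uses the pseudo-inverse, accepted only when
the estimability residual $\|(I - MM^{+})c\|$ is below $10^{-8}\|c\|$.

## The exchange algorithm and its certificate

`find_optimal_design()` works on an equally spaced dose grid (default
step 1 uM, matching the integer-uM support points of published designs in
this system) and alternates:

1. full weight optimization over the current support - all three criteria
   are concave in the weights; the solver runs damped multiplicative
   updates to a $10^{-9}$ relative criterion change, then vertex-exchange
   steps that equalize the sensitivity across the support (the simplex KKT
   condition);
2. deletion of support points with weight under `weight_floor` ($10^{-4}$);
3. addition of the grid dose maximizing the sensitivity function, with a
   line search for its mass (ties break to the lowest dose, for
   determinism).

The sensitivity (directional derivative) functions are, per prior set and
normalized so optimality means "nowhere positive":
$\mathrm{tr}\{M^{-1}m(x)\} - 4$ for D,
$c^\top M^{-1} m(x) M^{-1} c / c^\top M^{-1}c - 1$ for c, and the
$W$-weighted combination of the two (D part divided by 4) for the compound
criterion. The general equivalence theorem makes these a *certificate*:
the search stops only when the maximum sensitivity over the whole grid is
at most `tol` ($10^{-3}$ by default), so a `converged` result is provably
within a known efficiency margin of the global optimum, independent of the
iteration path. Every converged result in the test suite re-verifies this
bound, and deliberately suboptimal designs (uniform $U_4$) are checked to
violate it by a wide margin.

The start is deterministic (four equally spaced grid points, equal
weights): with concave criteria and a certificate there is nothing for
random restarts to add, and two runs are bit-identical. Support points
ending closer than `dose_tol` (1 uM) are merged at their weight-weighted
mean and the certificate re-evaluated; merging never touches genuinely
separated optima (published aboral dual designs keep support pairs 5 uM
apart, and collapsing leaves them alone).

## Flat ridges and what "the" optimal design means

For these nominal sets the criteria are extremely flat in how interior
mass is arranged: moving interior weight between nearby doses (say,
splitting one interior dose at 290 uM into 250 and 300 uM) changes the
robust D criterion by under $10^{-3}$ - a D-efficiency difference below
0.1%. Two consequences matter in practice:

* different software, stopping rules, or grid resolutions will report
  visibly different interior supports and weights that are all, for every
  practical purpose, equally good designs; on a coarse grid the optimum is
  forced to split interior mass across the grid points straddling the
  continuous optimum. The boundary structure - the weights at the interval
  endpoints - is stable and reproduces tightly across all of these
  variants.
* comparisons with previously published solutions should be made in
  criterion value or efficiency, not support coordinates. The package's
  converged designs carry sensitivity certificates at $10^{-3}$; published
  interior layouts for this system evaluate to positive maximum
  sensitivity (0.004-0.017) under the same information matrix, i.e. they
  are slightly earlier stopping points on the same ridge (99.94-99.99%
  efficient relative to the certified optimum).

## Fitting grouped rate data

`beta_loglik()` sums Beta log densities of flask-level rates;
`fit_beta_mle()` maximizes it by BFGS from a data-driven start (an
empirical-logit regression pins the identified mean-curve contrasts, split
symmetrically between the $\alpha$ and $\beta$ intercepts and slopes) plus
a few jittered restarts, and reports the inverse negative numerical
Hessian as the covariance, an honest convergence flag, and
$AIC = 8 - 2\log L$.

**Boundary rates.** Observed rates of exactly 0 or 1 have zero Beta
density. Two treatments are provided, with the per-record tolerance
$\varepsilon = 1/(2\,n_\mathrm{examined})$ (0.005 fallback):

* *clamp* (the `beta_loglik()` default): move the rate to $\varepsilon$ or
  $1-\varepsilon$ and use the density - the standard continuity fix, fine
  for evaluating a likelihood at a given $\theta$;
* *censor* (the `fit_beta_mle()` default): boundary rates contribute the
  tail mass $P(Y \le \varepsilon)$ or $P(Y \ge 1-\varepsilon)$.

The fitter defaults to censoring because maximizing the clamped density is
inconsistent exactly where this assay lives: at 1000 uM the nominal arrest
model has $b(x)\approx 0.004$, nearly all rates are (numerically) 1, and
the clamp piles them at $1-\varepsilon$, a spike that a moderate-precision
Beta fits better than the truth - the fitted $\beta_2$ flips sign. The
censored likelihood matches the model's own prediction of how much mass
sits within $\varepsilon$ of the boundary and recovers the generating
parameters in simulation. Extreme shapes occasionally defeat `pbeta`'s
series; the tail then falls back to a normal approximation (accurate
there, since $a+b$ is huge).

**Identifiability edge case.** Rates placed *exactly* on the mean curve
(the generator's `zero_noise` mode) identify only the contrasts
$\beta_1-\alpha_1$ and $\beta_2-\alpha_2$; the likelihood rises without
bound along the precision ridge $a, b \to \infty$. Tests therefore check
recovery of the mean curve, the identified functional, in that mode.

## The synthetic-data generator

`simulate_rates()` draws one Beta rate per flask at its dose, seeded and
reproducible, and synthesizes counts at `n_examined = 100` embryos per
flask (about what a 96-h assay phenotypes per flask), with optional
binomial thinning of the latent rate (off by default - the model treats
the flask rate itself as the observation). It reproduces precisely the
structure the model asserts: the sigmoidal mean and the dose-dependent
Beta variance, verified against the closed forms in the tests. It does
*not* emulate batch effects between spawnings, fertilization-rate
variation, scorer disagreement, or any lack of fit of the Beta form
itself; passing tests demonstrate internal consistency of model, designs
and fitter, not field validity of the model for new data.

`mle_recovery_experiment()` closes the loop: repeated simulate-and-fit
cycles under a design report per-parameter bias and RMSE, Wald coverage,
and the empirical variance of the plug-in $LC_p$ next to its delta-method
prediction $c^\top M^{-1} c / n$ - the quantity the c criterion minimizes.
Validation in this package uses 200 replicates of 1000 flasks under the
robust arrest design (bias within 10% of each parameter or 0.001 on the
slopes; empirical-to-predicted LC50 variance ratio within 25%).

## Efficiency auditing

For a design $\xi$ against a reference $\xi^*$,
$\mathrm{eff}_D = \exp\{(\Phi_D(\xi) - \Phi_D(\xi^*))/4\}$ (the
determinant-ratio-to-the-$1/4$ reading; a design with 80% D-efficiency
needs $1/0.8 = 1.25$ times more observations to match the reference) and
$\mathrm{eff}_c$ is the corresponding variance ratio. Under a multi-set
prior both are geometric means of per-set efficiencies;
`efficiency_table()` reports the per-set values.

One genuinely open choice is the reference: either the locally optimal
design *for each nominal set* (self-consistent; efficiencies in $(0,1]$)
or the locally optimal design at the MLE set used for every column (what
robustness figures in the source study plot; efficiencies can exceed 1
when another set is assumed). Both are implemented
(`reference_policy = "per-set"` / `"mle"`); per-set is the default as the
stricter audit. Rankings within a column agree between the two, because
the reference cancels.

The packaged ad-hoc comparison designs (`adhoc_designs()`) are a *curated
emulation* of the implemented laboratory design - 11 levels on
[0, 1000] uM with equal weights, restricted to [0, 450] uM for the aboral
endpoint - because per-level replicate counts are not reliably recoverable
from the publication; any CSV can be supplied instead.

## Numerical choices, in one place

* grid step 1 uM; sensitivity tolerance $10^{-3}$; `max_iter` 500;
  weight floor $10^{-4}$; support merge tolerance 1 uM.
* weight solver: damped multiplicative updates ($10^{-9}$ relative
  criterion change) + vertex-exchange KKT polish ($10^{-11}$ sensitivity
  spread); line search by `optimize()`.
* ties in the entering dose and in exact-design rounding break toward the
  lower dose; `round_to_exact()` guarantees one unit per support point and
  apportions remainders by largest remainder (or greedily by criterion
  when a specification is supplied).
* pseudo-inverse estimability tolerance $10^{-8}$; criterion sentinels
  $\pm\infty$; Beta tail fallback to a normal approximation on `pbeta`
  failure.
* validation problem sizes: 451- and 1001-point grids for the two dose
  ranges; a 21-point grid for the exhaustive-search cross-check of the
  exchange algorithm (all $\binom{21}{4}$ supports with inner weight
  optimization); 200x1000 flasks for the recovery study.

## Known limitations

* Criteria beyond D, c($LC_p$) and their $W$-compound (A-, E-, minimax,
  continuous-prior Bayesian) are out of scope, as is exact-design
  optimization beyond rounding.
* The aboral endpoint is modeled through its conditional rate among
  survivors; no joint model of the two endpoints is attempted.
* Interior support coordinates of reported optima are ridge-sensitive (see
  above); treat criterion values and efficiencies, not dose coordinates,
  as the comparable quantities.
* The generator and fitter share one Beta observation model; real data
  with overdispersion sources beyond it (batch, scorer) will show
  optimistic variances here.
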