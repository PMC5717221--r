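---
title: "Time-correlated random walks on lattice-gas cellular automata: models, theory, and how this package tests them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-correlated random walks on lattice-gas cellular automata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgcarw)
```

## The modelling problem

Migrating biological cells — *Dictyostelium*, T cells, epithelial and stem
cells — often diffuse *anomalously*: their mean-square displacement (MSD)
grows as $\langle r^2\rangle \propto t^{\varphi}$ with $\varphi \neq 1$, and
their velocity autocorrelation function (VACF) decays exponentially or as a
power law rather than instantaneously.  Lattice-gas cellular automata
(LGCA) are attractive substrates for modelling such motion because they are
cheap to simulate in large interacting populations and amenable to exact
analysis, but the standard LGCA walk is memoryless.  This package
implements a family of LGCA single-walker models with memory, together
with their complete analytic VACF/MSD theory, so that every analytic claim
is reproducible as a theory-versus-simulation test.

A walker lives on a regular lattice whose nodes carry $b$ unit velocity
channels $c_j = (\cos 2\pi j/b, \sin 2\pi j/b)$.  Each time step of
duration $\tau$ it adopts a channel with probability $P_{i,k}$ (the
*reorientation* step) and then moves a lattice spacing $\varepsilon$ in
that direction (the *migration* step).  Four reorientation kernels are
provided:

* **classical** — $P_i = 1/b$: memoryless, normal diffusion with
  $D_{rw} = \varepsilon^2/(2 d \tau)$;
* **persistent** — $P_i \propto \exp[\beta\, c_{i_{k-1}}\!\cdot c_i]$, a
  Boltzmann-like weight toward the previous direction whose sensitivity
  $\beta$ summarizes a torque-driven Langevin picture of cell
  repolarization (effective torque relaxation over rotational diffusion);
  the VACF decays exponentially, $g(k)=\lambda_1^k$ with
  $\lambda_1 = \tanh(\beta/2)$ on the square lattice;
* **time-correlated** — the kernel is *derived from a prescribed VACF*
  $g(t)$:
  $P_{i,k} = [1 + d\,(c_{i_0}\!\cdot c_i)\, g(k\tau)]/b$, which makes the
  ensemble VACF against the initial orientation equal $g(k\tau)$ exactly;
* **generalized** — maximum-caliber (path-entropy) inference under the same
  VACF constraint yields
  $P_{i,k} = \exp[d\, g(k\tau)\,(c_{i_0}\!\cdot c_i)]/z$, which is a valid
  distribution for *any* target amplitude; on the square lattice the
  realized VACF is $\tanh[C_0(\Delta/t)^{\varphi}]$ for a power-law target.

The prescribed-VACF families are `delta`, `exponential`,
`power_law` ($g(t) = C_0(\Delta/t)^{\varphi}$, $t \ge \Delta$),
`piecewise_ballistic` (fully correlated until
$t^* = \Delta C_0^{1/\varphi}$, the time at which the power law reaches 1),
and `tanh_power_law`.

## Parameters and defaults

| parameter | meaning | units | typical value |
|---|---|---|---|
| `b` | velocity channels per node | — | 4 (square lattice) |
| `d` | effective dimension (1 if `b = 2`, else 2) | — | 2 |
| `v` | instantaneous speed $\varepsilon/\tau$ | length/time | 16 |
| `D_rw` | random-walk diffusion coefficient | length²/time | 1 |
| `beta` | persistence sensitivity | — | 3–5 |
| `C0` | VACF amplitude (sign = correlated/anticorrelated) | — | 0.5 |
| `Delta` | crossover time where $g = C_0$ | time | 0.016 |
| `phi` | VACF decay exponent | — | 0.1–2 |

Scales are specified by $(v, D_{rw}, d)$, which fixes
$\varepsilon = 2 d D_{rw}/v$ and $\tau = 2 d D_{rw}/v^2$; the reference
point $v = 16$, $D_{rw} = 1$ gives $\varepsilon = 0.25$,
$\tau = 0.015625$.  These reference values — including $\beta \in \{3,5\}$,
$C_0 = 0.5$, $\Delta = 0.016$, $\varphi \in \{0.1, 1\}$ — are the
conditions under which the analytic curves were originally reported, and
they are the defaults of the test-fixture generator [make_fixtures()].

```{r example, eval = FALSE}
set <- channel_set(4)
sc <- lattice_scales(v = 16, D_rw = 1)
cfg <- model_config("persistent", set, sc, beta = 5)
ens <- simulate_ensemble(cfg, n_particles = 10000, n_steps = 200, seed = 1)
plot_curve_comparison(empirical_vacf(ens),
                      vacf_persistent((1:200) * sc$tau, 5, set, sc),
                      log_log = FALSE)
```

## Analytic theory and its regimes

The MSD follows from Taylor–Green–Kubo (TGK) representations over the
VACF.  Two forms arise, and the distinction matters:

* **stationary** (correlations depend on the lag only — persistent walk,
  and the pairwise-coupled generalized walk):
  $\langle r_t^2\rangle = 2 d D_{rw} t + 2v^2\int_0^t (t-s)\,g(s)\,ds$;
* **independent orientations** (time-correlated and generalized kernels,
  which condition on the initial orientation only):
  $\langle r_t^2\rangle = 2 d D_{rw}\,[t - 2\int g^2] + 2v^2\iint g\,g$.

Closed forms are implemented for the exponential VACF
(`msd_persistent()`), the power-law VACF with its $\varphi = 1/2, 1$
marginal cases (`msd_tc()`), the piecewise-ballistic VACF, and the
linearized stationary tanh family with marginals $\varphi = 1, 2$
(`msd_gtc_stationary()`); `msd_gtc()` evaluates the independent tanh form
by quadrature.  `msd_numeric_oracle()` evaluates either TGK representation
by adaptive quadrature for an arbitrary VACF callable and is the
independent cross-check: the test suite requires every closed form to
agree with it to $10^{-6}$ relative error on 20 log-spaced times.  The
double TGK integral is evaluated in the oracle by genuinely nested
quadrature precisely so that it does not share the algebraic shortcut
($\iint g g = \frac12 (\int g)^2$) used in the closed forms.

The regime taxonomy follows from the growth of the nonlinear MSD terms.
Time-correlated model: $\langle r^2 \rangle \sim t \pm t^{1-2\varphi} +
t^{2(1-\varphi)} - t^{1-\varphi}$ — superdiffusive for $\varphi < 1/2$,
transiently subdiffusive for $1/2 < \varphi < 1$, purely normal for
$\varphi > 1$.  Stationary generalized model: $\sim t \pm t^{2-\varphi}$ —
superdiffusive for $\varphi < 1$, transiently subdiffusive for
$1 < \varphi < 2$, purely normal for $\varphi > 2$.

A Markov-chain counterpart (`markov` tools) makes the contrast sharp: the
VACF of *any* homogeneous symmetric Markov orientation chain is delta,
alternating geometric, or exponential — never a power law — so power-law
memory genuinely requires the non-homogeneous (time-dependent) kernels.
`chain_vacf()` computes chain VACFs exactly by matrix powers and
`classify_decay()` certifies the trichotomy; "symmetric" is implemented as
circulant plus reflection-symmetric, the natural reading for a regular
channel geometry, and asymmetric inputs are rejected rather than silently
classified.

## Numerical choices

* **Validity of the linear kernel.**  The time-correlated kernel is a
  probability vector only while $|g| \le 1/d$; a piecewise-ballistic VACF
  with a long crossover time passes through the window $g \in (1/d, 1)$
  right after $t^*$, where the kernel as written is invalid.  The default
  is to raise an error naming the offending step; the opt-in
  `ballistic_extension` mode extends the ballistic phase until
  $|g| \le 1/d$ and records every extended step in the returned ensemble —
  the model is never changed silently.  At the reference scales
  ($\Delta = 0.016 > \tau$ only marginally) the window is empty and the
  ballistic phase lasts exactly one step.
* **Ballistic step count.**  $\omega$ is the smallest integer with
  $\omega\tau \ge t^*$ (ceiling), guaranteeing $g \le 1$ at every sampled
  step.
* **Discrete versus continuum closed forms.**  The continuum expressions
  are $\tau \to 0$ limits; at any fixed $\tau$ they differ from the exact
  lag-domain TGK sums by a relative offset that depends on the memory
  parameter but *not* on $\tau$ (for the persistent walk the asymptotic
  slopes are $2dD_{rw}[1 + 2/|\alpha|]$ versus
  $2dD_{rw}[1 + 2\lambda_1/(1-\lambda_1)]$, about 5% apart at
  $\beta = 3$).  Simulations are therefore validated against the exact
  discrete forms (`msd_persistent_discrete()`,
  `msd_independent_discrete()` with the kernel's realized per-step first
  moments), and the continuum forms are tied to the discrete ones by a
  convergence test in which $\tau$ is decreased *with the continuum VACF
  held fixed* ($\alpha \propto \tau$) — the limit in which they are
  derived.  Comparing a finite-$\tau$ simulation directly to the continuum
  MSD at ensemble sizes where the standard error is below that offset
  would fail for reasons that have nothing to do with correctness.
* **Regime boundaries by bisection.**  `regime_boundary_tc()` and the two
  `regime_boundary_gtc_*()` functions locate the taxonomy thresholds by
  bisection on $\varphi$ (tolerance $10^{-3}$) of the measured log–log
  growth exponent of the relevant *nonlinear component* of the closed form
  — the $t^{2(1-\varphi)}$ transient term for the time-correlated model,
  and the exact remainder $b\,t^{2-\varphi}$ of the expanded stationary
  generalized MSD after removing its linear asymptote and additive
  constant.  The raw windowed slope of the full curve cannot recover the
  asymptotic thresholds at finite $\Delta$: near the lower limit the
  $-2\int g^2$ correction pins the local slope at $1 - 2C_0^2$ for every
  $\varphi$, and at long times the Green–Kubo-enhanced linear coefficient
  biases the slope by $O(1/\ln t)$.  Isolating the nonlinear component
  measures exactly the quantity the taxonomy is a statement about.
* **Quadrature.**  `stats::integrate()` with relative tolerance $10^{-10}$;
  the tanh integrands are integrated from 0, where they saturate at
  $\mathrm{sign}(C_0)$ and stay bounded; bare power laws are integrated
  from $\Delta$ (or $t^*$), below which they are not defined.
* **Sampling.**  One seeded RNG stream per ensemble; each step draws one
  uniform variate per particle and maps it to a channel by the inverse CDF
  in channel-index order, with draws exactly on a boundary going to the
  higher index.  Sampling is vectorized step-major (particles grouped by
  conditioning channel); the reproducibility contract is that identical
  `(config, n_particles, n_steps, seed)` give bit-identical channel
  matrices.  A particle-major stream would cost an R-level loop per
  particle for no statistical benefit.
* **Estimation.**  The VACF estimator conditions on each particle's own
  initial orientation, exactly the prescribed quantity (a time-averaged
  stationary variant is available, clearly labelled, for lag-stationary
  walks).  The power-law fit `fit_vacf_power_law()` is weighted *nonlinear*
  least squares on the linear scale: a log-domain fit must discard
  non-positive tail estimates and weight by the noisy values themselves,
  which biases the exponent by tens of percent in the low-SNR tail,
  whereas the linear-scale fit is unbiased there.  It reports
  $A = C_0\Delta^{\varphi}$ and $\varphi$ only — $C_0$ and $\Delta$ are
  not separately identifiable from a single power law.  Regime labels from
  empirical MSDs use the 95% CI of the log–log slope rather than a fixed
  epsilon.

## Design decisions on genuinely open points

* Simulations of the generalized model use the per-step kernel with
  independent orientations (conditioning on $i_0$), the only variant with
  a stated per-step rule; the pairwise-coupled path distribution (whose
  stationary MSD is the `msd_gtc_stationary()` family) is analyzed but not
  sampled — sampling it would require coupling every pair of steps along
  the path.
* `b = 2` is treated as the 1D lattice embedded on the x-axis with
  $d = 1$; all $b \ge 3$ use $d = 2$.  This is forced by the normalization
  identity $\sum_j (c_i \cdot c_j)^2 = b/d$ that makes the linear kernel
  reproduce its target.
* General-$b$ persistent decay rates are computed numerically from the
  cosine-mode eigenvalue of the circulant kernel; the square-lattice
  closed form $\tanh(\beta/2)$ serves as the regression test.
* The stationary generalized closed forms are evaluated for any $\Delta$,
  although the expansion behind them is controlled for $\Delta \to 0$;
  this matches how the analytic curves are used at moderate crossover
  times.

## What the synthetic ensembles do and do not emulate

The generator produces independent, non-interacting walkers with constant
speed on an unbounded regular lattice, initialized at the origin with
uniform (or fixed) initial orientation.  That is the idealized single-cell
setting of the theory.  It does not emulate: particle–particle exclusion
or interaction, rest channels or speed variability, boundary effects,
measurement noise in cell tracking, or non-Gaussian displacement
statistics beyond what the kernels induce.  Passing tests therefore
demonstrate internal consistency of simulator and theory under the models'
own assumptions — not that any particular cell type follows these kernels.

## Problem sizes used by the test suite

Theory-versus-simulation checks run $10^4$ walkers for 200 steps per
parameter point (the reference ensembles above), comparing VACF and MSD
lag-by-lag within 3 standard errors at $\ge 95\%$ of lags; parameter
recovery uses 20 seeded replicates of the same size; the Theorem-type
trichotomy suite classifies 200 random symmetric circulant chains; oracle
equivalence uses 20 log-spaced times per closed form.  These sizes give
per-lag standard errors of roughly 1% of the signal, small enough that a
systematic error of a few percent in any closed form would fail the
3-SEM bands.

## Known limitations

* The tanh (generalized) closed forms are square-lattice specific; other
  geometries fall back to numerical mode eigenvalues for the VACF and have
  no stationary MSD closed form here.
* The continuum MSD expressions carry the finite-$\tau$ offset described
  above; they should be compared to data only when $\tau \ll t$.
* Anticorrelated targets ($C_0 < 0$) are supported by the kernels and
  theory curves, but the regime-boundary machinery assumes $C_0 > 0$.
* 3D lattices, multispeed/rest channels, interacting walkers, and Lévy
  statistics are out of scope.
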