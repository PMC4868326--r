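---
title: "Microscopic kinetics of tumour-induced angiogenesis: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microscopic kinetics of tumour-induced angiogenesis: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`angiokin` implements a microscopic (reaction-level) description of
tumour-induced angiogenesis with three species: tumour cells $N$, the
pro-angiogenic protein VEGF $P$ secreted by them, and vessel
(endothelial) cells $V$. The effective vessel density $E \equiv V/N$
— vessel cells available per tumour cell — acts as a proxy for the
per-cell nutrient supply. Six reaction channels drive the dynamics:

* tumour-cell birth at rate $\alpha\, g_b\!\big(N/(K + f_1(E))\big) N$
  and death at rate $\delta_N\, g_d\!\big(N/(K + f_1(E))\big) N$, with
  $g_b(x) = 1/(1+x^{n_1})$ (crowding throttle) and
  $g_d(x) = x^{n_2}/(1+x^{n_2})$ (starvation switch). The carrying
  scale $K + f_1(E)$ combines a diffusion-limited baseline $K$ with a
  vasculature-dependent supply
  $f_1(E) = b_1 E^{n}/(c_1 + E^{n})$;
* VEGF secretion at rate $f_2(E)\,N$ with
  $f_2(E) = a_2 c_2/(c_2 + E)$ (well-nourished cells stop signalling)
  and first-order decay $\delta_P P$;
* vessel-cell birth and death at rates $f_{3b}(P) V$ and
  $f_{3d}(P) V$, with Hill forms rising from 0 to $b_3$ and falling
  from $a_3$ to 0 around the characteristic VEGF level $m_3$.

The deterministic (mass-action) limit is the ODE system

$$\dot N = N(\alpha g_b - \delta_N g_d), \qquad
  \dot P = N f_2(E) - \delta_P P, \qquad
  \dot V = V(f_{3b}(P) - f_{3d}(P)).$$

Two unit conventions are supported. In *concentration* mode the state
is dimensionless and a system size $\Omega$ converts to counts; in
*absolute* mode the scale constants are pre-multiplied
($\bar K = K\Omega$, $\bar b_1 = b_1\Omega$, $\bar m_3 = m_3\Omega$)
and the state is counts directly. `params_to_absolute()` performs the
fold-in; a property test asserts the two modes' drifts are exact
rescalings of each other.

For $N > 0$ the vessel equation can be rewritten for $E$ itself:
$\dot E = (f_{3b} - f_{3d} - \alpha g_b + \delta_N g_d)\,E$ (chain
rule on $V/N$). Note the whole bracket multiplies $E$, so $E = 0$ is
unconditionally invariant; `integrate_E_form()` uses this form and is
cross-checked against the full system.

## Steady states and folds

Equilibria are classified as

* $A = (0,0,0)$ — extinct; always an unstable equilibrium of the
  flow, yet absorbing for the stochastic dynamics;
* $B = (K\gamma,\ a_2 K\gamma/\delta_P,\ 0)$ — avascular, where
  $\gamma$ is the unique root of
  $\alpha g_b(\gamma) = \delta_N g_d(\gamma)$ (closed form
  $(\alpha/\delta_N)^{1/n_1}$ when $n_1 = n_2$); stable iff
  $f_{3b} < f_{3d}$ at its VEGF level;
* $C_i$ — vascularised morphologies, one per positive root of
  $h(E) = f_2(E)\,(K + f_1(E)) - \delta_P \tilde P^*/\gamma$, all
  sharing the VEGF level $\tilde P^*$ (root of
  $f_{3b} = f_{3d}$; $m_3 (a_3/b_3)^{1/n_3}$ for equal exponents)
  and $N = \gamma (K + f_1(E))$. A $C_i$ is stable iff
  $h'(E_{C_i}) < 0$; with the Hill forms used, $h$ has at most three
  positive roots and stability alternates in $E$, the largest always
  stable.

`enumerate_states()` applies the $h'$ rule and cross-checks every
verdict against the eigenvalues of a central-difference Jacobian
(step $10^{-6}(1 + |x|)$, neutrality band $10^{-9}$); a root on a
near-flat slope (relative slope below $10^{-12}$) is reported
`"marginal"` with no verdict — that is the fold point itself.

Because $h$ shifts rigidly with $\delta_P$, the fold (saddle-node)
levels of the VEGF degradation rate have the closed form
$\delta_{P,cr} = \Phi(E_{\mathrm{ext}})\,\gamma/\tilde P^*$ with
$\Phi(E) = f_2(E)(K + f_1(E))$ and $E_{\mathrm{ext}}$ a local
extremum of $\Phi$. `bifurcation_scan()` detects stable-count
transitions on a sweep and refines them by bisection to a relative
width of $10^{-4}$; for $\delta_P$ sweeps it reports the closed form
alongside. On the fitted Lewis-lung constants the two routes agree to
four digits: the lower fold sits at $1.6\times 10^2\,$day$^{-1}$.
The upper fold computed from the published (3-significant-figure)
constants lands near $1.9\times 10^4\,$day$^{-1}$, whereas the
published figure is $\simeq 1.2\times 10^4\,$day$^{-1}$; the rounding
of the constants cannot be ruled out as the source of the gap, so the
scan report prints both numbers rather than forcing agreement.

Root search uses 600 log-spaced points over
$E \in [10^{-12}, 10^{12}]$ (the Lewis-lung roots span
$E \sim 10^{-4}$ to $10^5$), bracketed `uniroot()` refinement, and
merges duplicates within $10^{-8}$ relative. All Hill functions are
evaluated in log space (`plogis`), so arguments up to $10^{300}$
cannot overflow and tails retain full relative precision.

## Stochastic engines

`run_ssa()` is the exact (direct-method) Gillespie algorithm over the
six channels: exponential waiting times with the total-propensity
parameter, channel choice proportional to propensity, integer counts.
`run_cle()` integrates the chemical Langevin equation by
Euler–Maruyama: each species' increment is its net drift plus an
independent Gaussian with standard deviation
$\sqrt{\text{(sum of that species' channel rates)}\,dt}$, scaled by
$\Omega^{-1/2}$ in concentration mode. The default step
$dt = 10^{-3}$ day resolves the fastest fitted scales (VEGF decay
$\approx 9$/day, vessel growth $11.5$/day); stepping is fixed, not
adaptive, for bit-reproducibility. The diffusion argument is clipped
at zero before the square root.

**Absorption.** A species whose update lands at or below the
absorption threshold is absorbed: $N$-absorption zeroes the whole
system (state $A$); $V$-absorption is permanent (the avascular trap
$(N, P, 0)$, where both the drift and the noise of $V$ vanish). The
threshold defaults to 0 — the Langevin equation's own absorbing
boundary, which Euler–Maruyama paths do cross because the noise
scales as $\sqrt{V}$. A threshold of one individual is sometimes used
with continuous approximations, but here it would sit exactly on the
Lewis-lung initial vessel count $V(0) = 1$ and absorb roughly half
the ensemble on the first Euler step — a discretization artifact with
no continuous-time counterpart — so it is not the default; the
`absorb_threshold` argument exposes the choice.

**Randomness** is self-contained: each realization draws from its own
xoshiro256++ stream seeded by `(base_seed, index)` through splitmix64,
with an explicit Box–Muller transform. Ensembles are therefore
bit-reproducible for a given base seed, independent of R's RNG state,
evaluation order, or platform maths libraries.

**Engine domains.** At Lewis-lung population sizes
($N \sim 10^9$–$10^{13}$) the exact simulation would need
$\sim 10^{13}$ events per day and is impractical; the CLE is the
supported engine there, and the SSA is exercised on the benchmark
parameter set, where the two engines' stationary marginals agree at
large $\Omega$ and the CLE — a diffusion approximation —
overestimates switching at $\Omega \sim 10$, an ordering the tests
assert rather than equality.

**What "tumour loss" means here.** The fitted Lewis-lung death rate
is $\delta_N = 3.58\times 10^{-8}$/day, so the extinct state $A$ is
unreachable from $8.29\times 10^8$ cells on any observable timescale
(the decay timescale is $\sim 3\times 10^7$ days). The only
stochastic loss pathway the fitted model supports within weeks is
vascular collapse while the nascent vessel population is of order
one: a birth–death (Feller) argument for $V$ with
$f_{3b} \approx b_3$, $f_{3d} \approx 0$ from $V_0 = 1$ gives a
collapse probability $\approx e^{-2b_3/(b_3+0)} = e^{-2} = 13.5\%$,
and the simulated ensembles land at 13–14% by day 7, essentially
flat to day 50 and insensitive to $dt$ over
$2\times10^{-4}$–$2\times10^{-3}$. `absorbed_fraction()` accordingly
reports absorption into the whole non-growing basin ($A$ plus the
avascular trap) as the tumour-loss fraction, while
`run_ensemble()` tracks the extinct-at-$A$ and avascular fractions
separately.

The analytic relative noise intensity along a deterministic
trajectory — diffusion coefficient over population,
$\sqrt{\sum_{\text{channels of } X} a_i}/X$ — is provided by
`noise_intensity()`. For the tumour cells it is
$\sqrt{(\alpha g_b + \delta_N g_d)/N}$: negligible in the first two
days (crowding keeps $g_b \approx 0$), surging between days 2 and 4
as the fast vascularisation raises $f_1(E)$ and releases the birth
rate, then decaying as $N$ grows — the survival window of the tumour.

## Fitting and sensitivity

The objective is the dimensionless relative mean-square error
$\mathrm{MSE} = \frac1M \sum_i \big((x_i^{data} -
x_i^{model})/x_i^{data}\big)^2$, scale-invariant and zero only for
identical series. Volume measurements convert to cell counts by
dividing by the volume of a 3.5-µm-radius sphere (no packing-fraction
correction), so a 2-mm tumour is $2.33\times10^7$ cells and a 3-mm
one $7.87\times10^7$.

`pso_fit()` searches in $\log_{10}$ parameter space with a particle
swarm: inertia 0.72, cognitive = social = 1.49 (standard
constriction-style values — the original analysis reports no swarm
settings), reflective bounds, and a *ring* (lbest) neighbourhood of
one particle per side. The ring's slower information flow keeps
multiple basins alive: the growth objective is genuinely multimodal
(a secondary basin with $\sim 0.5\%$ MSE traps global-best swarms).
After the swarm, the top distinct personal bests (default 5, at least
0.5 apart in log space) are polished by Nelder–Mead; the objective
has long curved valleys that the swarm locates but does not descend
to machine precision. With 40 particles and 150 iterations the
noiseless three-parameter recovery
($\alpha, \delta_P, b_3$ free, $10\times$ bounds) lands on the
generator truth to $\sim 10^{-6}$ relative across seeds.

Identifiability has sharp edges worth knowing: with 10%
multiplicative noise on 15 volume points, $\delta_P$ and $b_3$ are
individually poorly determined (a compensating valley — faster VEGF
decay can be traded against faster vessel growth) even while the fit
reaches the noise floor. The noiseless recovery is therefore the
acceptance property; noisy recovery is reported, not asserted.

Initial conditions follow the fitted protocol: $P(0) = 10$,
$V(0) = 1$ (absolute counts — the original table does not state
units; counts are consistent with the absolute-number equations used
for the fit) and $N(0)$ from the data's first point for external
datasets. Synthetic datasets carry their generator's exact initial
state and start time in metadata, and `pso_fit()` uses those, making
recovery a pure parameter-estimation problem. Unbounded-above
literature ranges (e.g. the VEGF secretion rate's "$939$–$\infty$")
are given a ceiling of $10^4\times$ the lower bound when used.

`sensitivity()` perturbs each continuous constant independently and
uniformly within ±2% (Hill exponents stay fixed, as in the original
fitted/fixed split), integrates the deterministic system, and
reports the Pearson correlation between relative perturbation and
each output ($N$, $P$, $E$) at days 5, 15 and 30 — early, mid and
late growth, since the VEGF sensitivities change over the
trajectory. Parameters with all $|r| < 0.2$ are flagged
low-influence. On the fitted set, $\delta_P$ and $b_3$ dominate $N$
and $E$, $m_3$ and $a_3$ matter most for $P$, and $K$ and $\delta_N$
are low-influence. The exact estimator of the original supplementary
analysis is not published; plain Pearson correlation on the sampled
design is used and documented here.

## The synthetic-data generator

No public accession exists for the Lewis-lung volume series the model
was originally fitted against, so `generate_growth_data()` emulates
that kind of experiment: deterministic growth from the implantation
state $(8.29\times10^8, 10, 1)$, sampled at 15 points over days 7–35
(a typical monthly measurement horizon), optionally converted to
mm³, with mean-one multiplicative lognormal noise (volumes are
positive and measurement error scales with size; default CV 10%).
The generator reproduces the *shape* of such data — monotone
sigmoidal volume growth with multiplicative scatter — but not
inter-animal variability, cohort structure, or measurement-schedule
irregularities; passing round-trip tests therefore demonstrates that
the estimation machinery recovers known kinetics from data of this
form, not that the model fits any particular experiment.

## Numerical choices

* ODE integration: `deSolve::lsoda` on a compiled right-hand side,
  rtol $10^{-8}$, per-species atol $10^{-12}\max(1, |x_0|)$; the
  fitted constants span 12 orders of magnitude and the first-day VEGF
  transient is stiff. Output lands exactly on the caller's grid, so
  CSV artifacts are bit-reproducible at fixed tolerances. Small
  undershoots below zero (within one atol) are clipped.
* Steady-state arrival: $\|\dot x\|_\infty <
  \mathrm{tol}\,(1 + \|x\|_\infty)$ sustained over one time unit,
  checked on doubling windows (`run_to_steady()`).
* Two timescale regimes deserve care. The benchmark set relaxes in
  $\sim 10^2$ days and converges fully within the $10^4$-day test
  horizon. The fitted Lewis-lung set approaches its vascular
  attractor along a slow manifold — per-capita net growth collapses
  as $\alpha/x^2$ once crowding builds — so full drift convergence
  would take $\sim 10^{10}$ days; the tests therefore assert
  boundedness, non-negativity and smallness of per-capita rates
  ($< 10^{-3}$/day by $t = 10^4$) there, plus the fixed-point
  property of the enumerated attractor itself.
* Problem sizes in the test-suite (chosen to keep the default run a
  few minutes while leaving each property statistically sharp):
  Latin-hypercube boundedness over 60 benchmark + 12 Lewis-lung
  starts; 1000 random parameter sets for the root-count bound and 100
  for the stability cross-check; SSA–ODE convergence with 300–400
  realizations per system size; the extinction ensemble at the full
  2000 realizations; swarm recovery with 40 particles × 150
  iterations.

## Known limitations

* Vessel–vessel competition for VEGF is deliberately absent (a
  first-approximation choice inherited from the modelled reaction
  scheme); the unrealistically fast early vascularisation — and with
  it the sharpness of the first-week survival window — is sensitive
  to that simplification.
* The CLE is a diffusion approximation: at system sizes of order 10
  it overstates basin switching, and near absorbing boundaries its
  behaviour depends on the (documented) absorption convention.
* The fitted-parameter folds are computed from constants published to
  3 significant figures; the upper VEGF-degradation fold is
  correspondingly uncertain (see above).
* Master-equation numerics, delay and spatial variants, and
  pharmacokinetics beyond treating $\delta_P$ as a dial are out of
  scope.
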