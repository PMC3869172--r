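---
title: "Stability, oscillations and model discrimination in three-variable negative-feedback networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability, oscillations and model discrimination in three-variable negative-feedback networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triloop)
```

## The model family

`triloop` analyses a generic three-variable biochemical negative-feedback
loop: a sensor $x$ driven by a stimulus $s = k_0 + \text{input}$, a
transducer $y$, and an integrating response $z$ that closes the loop by
inhibiting the sensor:

$$
\begin{aligned}
\dot x &= s\,q(z) - k_1 x - k_2 f_1(x) f_3(z),\\
\dot y &= k_3\, x\,(y_T - y)\,g(y,\kappa_y) - k_4 y,\\
\dot z &= k_5\, y\, H(z,\kappa_z) - k_6 h(z).
\end{aligned}
$$

The overall feedback can act in two mutually exclusive ways.
*Input-inhibition* multiplies the sensor inflow by a smooth decreasing
$q(z) = 1/(1 + (z/K_q)^{h_q})$ with $q(0)=1$ and removes the outflow term
($k_2 = 0$); this is the classical Goodwin wiring. *Output-activation*
instead activates the sensor's outflow through $k_2 f_1(x) f_3(z)$ with
$q \equiv 1$. The kinetic slots are exchangeable: $f_1$ and $h$ are either
mass-action ($v$) or Michaelis--Menten ($v/(K+v)$), and $f_3$ is linear or an
activating Hill function. A Michaelis--Menten form with small half-saturation
constant is effectively *zero-order* (saturated) at the operating point; we
use that smooth representation throughout rather than a piecewise-constant
idealization, since for every statement of interest it suffices that $K$ be
small compared with the operating level.

Two optional *nested autoinhibitory feedbacks* act on single components:
$g(y,\kappa_y) = 1/(1+(\kappa_y y)^{m_g})$ on the transducer and
$H(z,\kappa_z) = 1/(1+(\kappa_z z)^{m_H})$ on the response. Both equal 1 when
$\kappa = 0$ and are smooth, positive and decreasing in both arguments, which
is all the theory requires; the exponents are configurable (defaults
$m_g = 1$, $m_H = 2$). The factor $(y_T - y)$ models mass conservation of a
post-translationally modified pool (e.g. a phosphorylation cycle) and keeps
$y \in [0, y_T]$; the non-negative orthant is forward-invariant for every
structure, which the test suite checks by simulation on randomly drawn
models.

Two biological interpretations are built in as enumerable families.
For yeast osmoadaptation (HOG), $x$ is the volume/turgor signal, $y$
phosphorylated Hog1 and $z$ glycerol; all variants keep mass conservation,
$f_3(z) = z$ and $H \equiv 1$, and four binary switches (feedback type,
$f_1$ kinetics, transducer autoinhibition, $h$ kinetics) yield exactly 12
admissible structures, because the $f_1$ switch multiplies a term that is
absent under input-inhibition. For the p53--Mdm2 loop, $x$ is active p53,
$y$ Mdm2 RNA (no mass conservation, $g \equiv 1$) and $z$ Mdm2 protein; five
switches yield 20 admissible structures.

## Equilibria and the Hopf machinery

At constant stimulus the steady state solves, equation by equation,
$\bar y = k_6 h(\bar z)/(k_5 H(\bar z))$,
$\bar x = k_4 \bar y/(k_3 G(\bar y))$ with $G(y) = (y_T - y)g(y)$, and a
remaining scalar equation in $\bar z$. `steady_state()` scans $\bar z$ on a
log grid, brackets sign changes with `uniroot`, and polishes on the full
3-d system with damped Newton steps using the analytic Jacobian; when several
roots coexist the one reached by relaxation from the unstimulated state is
returned, and when no non-negative root exists (a saturable removal term can
simply be outrun by its inflow) an explicit no-steady-state result is
produced, which the stability-region maps display as their own class.

The characteristic polynomial of the Jacobian at an interior equilibrium is
$\lambda^3 + a_1\lambda^2 + a_2\lambda + a_3$ with all three coefficients
positive, so real eigenvalues are always negative and instability can only
arise through a complex pair: a Hopf bifurcation, which occurs exactly when
$a_1 a_2 = a_3$, at frequency $\omega = \sqrt{a_2}$.

For bifurcation analysis the system is *parametrized from the equilibrium*:
choose the response level $\bar z$ and the sensor turnover $k_1$, solve
$\bar y$ and $\bar x$ as above, and read off the basal stimulus
$k_0 = (k_1\bar x + k_2 f_1(\bar x) f_3(\bar z))/q(\bar z)$ that makes this
an equilibrium. With $k_0$ eliminated this way, every Jacobian entry is
affine in $k_1$, and the Hopf condition
$\Phi(k_1) = a_1 a_2 - a_3$ is *exactly* quadratic in $k_1$. We exploit this
rather than carry the lengthy closed-form coefficients: `hopf_k1()`
evaluates $\Phi$ at $k_1 \in \{0, 1, 2\}$, interpolates the quadratic
exactly, and takes roots. This is mathematically equivalent to the closed
form and self-validating — the tests confirm the interpolated quadratic
reproduces $\Phi$ at random $k_1$ to $10^{-9}$ and that a dense sign-scan
brackets the same root to $10^{-6}$.

When both quadratic roots are positive (which happens for Goodwin-type
input-inhibition, where the oscillatory $k_1$-interval is bounded on both
sides) the reported critical value $k_1^*$ is the larger root, i.e. the
boundary below which the equilibrium is unstable; all roots are attached to
the returned object. A degenerate (effectively linear) $\Phi$ is solved
linearly. Transversality of the eigenvalue crossing is spot-checked by
finite differences of $\max \mathrm{Re}\,\lambda$ along $k_1$.

`classify_state()` labels a parameter point `stable`, `oscillatory`
(equilibrium exists, complex pair with positive real part) or
`no_steady_state`; eigenvalues with $|\mathrm{Re}\,\lambda| < 10^{-9}$ are
reported stable but flagged marginal. The independent oracle used in the
tests is simulation: integrate well past a transient and declare a limit
cycle when the final-cycle amplitude of $z$ exceeds $10^{-4}$ of its mean
level *and* successive peak heights differ by less than 1% of that
amplitude. Requiring the amplitude criterion on the final cycle (not a
window average) is what distinguishes a slowly decaying spiral from a
genuine limit cycle.

### Perfect adaptation and the minimal-cooperativity result

With zero-order removal of the response ($h$ saturated, $H \equiv 1$) the
transducer's steady state $\bar y = k_6/k_5$ is independent of the stimulus:
the response $z$ acts as an integral controller and $y$ adapts perfectly.
The suite verifies invariance of $\bar y$ to one part in $10^6$ over a
100-fold stimulus range.

For the classical repression loop — input-inhibition with Hill exponent $p$,
three linear degradations, no mass conservation, no autoinhibition —
`goodwin_min_hill()` recovers the textbook secant bound numerically: with
equal rates, purely imaginary eigenvalues require the log-slope of the
repression function to reach $\sec^3(\pi/3) = 8$, so the infimum
cooperativity is 8. The implementation sweeps $\bar z$, asks whether the
quadratic Hopf condition admits a positive $k_1$ root, and bisects the
admissibility boundary in $p$. Treating $k_1$ as free is equivalent to
imposing equal rates: writing $\kappa = k_1/\alpha$, the Hopf condition
reduces to $2(\kappa+1)^2 = \kappa\rho$ with $\rho$ the attainable log-slope,
and the left side over $\kappa$ is minimized exactly at $\kappa = 1$ with
value 8. With unequal degradation rates the threshold is strictly larger,
which the tests confirm. By contrast, the framework's own input-inhibition
variants with mass conservation and zero-order removal oscillate already at
cooperativity 4 — saturation substitutes for cooperativity.

### Autoinhibition shrinks the oscillatory region

Along the $(\bar z, k_1^*)$ bifurcation curve, increasing either
autoinhibition strength lowers $k_1^*$ pointwise, so the region of the plane
permissive for oscillations shrinks; the distance of an operating point to
the curve is a natural measure of the system's *resistance* to being pushed
into the oscillatory regime. For input-inhibition structures this
monotonicity is unconditional; for output-activation it is guaranteed when
$f_1$ is effectively zero-order at the equilibrium ($K_x \ll \bar x$), and
the property tests cover exactly these regimes. The reference
output-activation configuration used throughout the tests
($k_2 = 0.3$, $k_3 = k_5 = 0.1$, $k_4 = k_6 = 0.02$, $K_x = 10^{-4}$,
$K_z = 0.05$, $y_T = 1$) has, at $(\bar z, k_1) = (0.4, 0.2)$, a single
complex eigenvalue pair with positive real part and a sustained limit cycle
when $\kappa_y = 0$, and is stabilized by $\kappa_y = 40$ — with its
$\kappa_y = 40$ curve pointwise below the $\kappa_y = 0$ curve.

## Simulation

Trajectories are integrated piecewise between protocol events
(stimulus steps added to $k_0$; inhibitor events that rescale a named rate
constant from the event time on) with `deSolve::lsoda`, relative tolerance
$10^{-8}$ and absolute tolerance $10^{-10}$, using the analytic Jacobian.
The identical right-hand side is also implemented in C and driven through
deSolve's compiled-model interface; the fitting objective uses the compiled
path (at $10^{-6}/10^{-8}$ tolerances, ample against measurement noise)
while user-facing simulation uses the interpreted reference path, and a test
integrates both along the same trajectory and requires agreement.
Halving solver tolerances changes reported oscillation amplitudes by less
than 0.1%.

The default inhibitor semantics — a multiplicative factor on $k_5$, the
transducer-to-response production — encodes loss of Hog1 kinase activity
under a kinase inhibitor: glycerol production stops, the feedback signal
decays, and phospho-Hog1 rises without any osmotic shock. Both the target
rate and the factor are configurable, since mapping an inhibitor onto a
model reaction is a modeling choice.

## Fitting and ranking

The objective is the weighted sum of squared residuals
$\sum_i w_i (y_i - s_{o(i)}\,\hat y_i)^2$ with $w_i = 1/\sigma_i^2$ when
per-point standard deviations are available and $1/\overline{y}_o^2$ per
observable otherwise. Observables declared relative-scale carry one
multiplicative factor $s_o$, profiled analytically at its weighted
least-squares optimum and counted as a fitted parameter.

Global search is by evolutionary programming — Gaussian mutation with
self-adaptive per-coordinate step sizes, truncation selection, parameters
searched in $\log_{10}$ space within bounds, population and generation
counts defaulting to ten times the number of free parameters — followed by a
Levenberg--Marquardt polish (`minpack.lm::nls.lm`) of the residual vector.
When the optimum lands on a parameter bound, the bound is relaxed and the
model refitted, up to a configured number of rounds. Every fit takes a
mandatory seed and restores the caller's RNG state.

Model ranking uses the small-sample corrected Akaike criterion in its
constant-inclusive Gaussian form,
$$\mathrm{AICc} = n\ln\!\frac{2\pi\,\mathrm{SSR}}{n} + n + 2k +
\frac{2k(k+1)}{n-k-1},$$
and Akaike weights $w_i \propto e^{-\Delta_i/2}$. This AICc variant is fixed
by the package's reference checks — e.g. $(\mathrm{SSR}, n, k) =
(15.3, 67, 6) \mapsto 104.6$ — and the weights are translation-invariant, so
the choice of constants never affects a ranking. The best-approximating set
is flagged at a configurable weight threshold (default 0.05).

### Identifiability and the synthetic recovery experiments

The packaged synthetic datasets are emitted in absolute model units, so
their observable scales are pinned at 1; the relative-scale machinery
remains available for external data, which in signalling applications is
typically unitless. With the sensor $x$ unobserved, its unit is a pure gauge
freedom — $x \to a x$ with $k_0, k_2, K_x \to /a$ and $k_3 \to a k_3$ leaves
every observable trajectory unchanged — so the recovery experiments fix
$k_3$ to pin that gauge. Remaining parameters are identifiable to varying
degrees from 55 noisy points; the acceptance experiment requires the median
relative error over the free set (median over 5 optimizer seeds) to be
within 20%, and the fitted SSR to be within 1.2 times the noise floor.

## Synthetic study conditions

`hog_scenario()` packages an osmoadaptation ground truth with the
output-activation + Michaelis--Menten $f_1$ + transducer autoinhibition +
mass-action $h$ structure. Time is in minutes over a 2-hour horizon; step
doses 0.1, 0.4 and 0.8 (in the stimulus units of $k_0$) are observed through
phospho-Hog1 ($y$), one condition applies a 10-fold $k_5$ knock-down at
$t = 10$ min without shock, and one glycerol condition ($z$) uses a 0.5
dose. The parameters ($k_0 = 0.05$, $k_1 = 0.5$, $k_2 = 1$, $K_x = 0.01$,
$k_3 = 1$, $k_4 = 0.1$, $y_T = 1$, $\kappa_y = 4$, $k_5 = 0.02$,
$k_6 = 0.002$) were chosen, once, to give a transient phospho-Hog1 pulse
peaking near 10 min with substantial decline by 2 h and a slow glycerol
rise — they are plausible illustrative values, *not* the fitted values of
any published model, which are not available to this package. Noise is
additive Gaussian with per-point $\sigma = 0.02 + 0.05\,|y_\text{true}|$.

`p53_scenario()` packages an oscillatory ground truth with mass-action
$f_1$, Hill $f_3$ ($m = 6$) and near-zero-order Mdm2 removal
($K_z = 0.05$); time is in hours. On its limit cycle the p53 ($x$) and Mdm2
($z$) observables oscillate with period $\approx 5.9$ h and Mdm2 lags p53 by
$\approx 2$ h. The generator refuses a configuration whose truth is not
classified oscillatory.

What these generators deliberately do not emulate: measurement-specific
artifacts (blot saturation, digitization error), cell-to-cell variability,
and the amplitude decoherence of population-averaged oscillation data. A
passing recovery test therefore demonstrates the estimator and ranking
machinery under the stated noise model, not performance on any particular
published dataset.

## Monte-Carlo robustness

`robustness_study()` perturbs every free parameter independently and
uniformly on $[p/2, 2p]$, recomputes the post-stimulus steady state per
sample, and compares the per-component distributions of
$|\bar u_\text{perturbed} - \bar u_\text{reference}|$ between two model
variants, by default with the Brown--Forsythe/Levene test (robust to the
strong skew of distance distributions); the classical F ratio is available
by flag. Samples without a steady state are excluded and counted. An
aggregate Euclidean distance across components is reported alongside the
per-component ones.

`hog_variants()` provides the packaged comparison pair: the autoinhibited
truth and a matched variant without autoinhibition whose $k_3$ is rescaled
by $g(\bar y)$ so both share the same basal operating point. In this matched
comparison the *transducer* steady state is consistently less variable with
autoinhibition — the autoinhibited transducer equation is stiffer in $y$, so
perturbations of the transducer parameters displace $\bar y$ less. The
*sensor* component behaves differently: its perturbed-steady-state variance
is dominated by the feedback-strength ($k_2$) and response-gain ($k_5/k_6$)
perturbation channels, which reach $x$ through
$\bar x = (s - k_2\bar z)/k_1$ and are not buffered by transducer
autoinhibition, while autoinhibition simultaneously lowers the loop gain and
with it the loop's own suppression of sensor-direct perturbations. Across
every matched construction we examined (equilibrium-matched,
equilibrium-plus-relaxation-matched, and an independently fitted
non-autoinhibited variant) the sensor direction is at best neutral under the
half-to-double protocol; whether autoinhibition also protects the sensor
depends on the specific operating point and on which parameters are
considered free, and the package reports whatever the data say rather than
asserting the favourable direction.

## Problem sizes and numerical defaults

The shipped experiments use deliberately modest sizes chosen as a matter of
design: 55-point HOG datasets over five conditions, evolutionary budgets of
population 40--60 and 10--15 generations with an LM polish (the polish, not
the budget, sets the final precision), 5 optimizer seeds for recovery, 3 for
family ranking, and 250 Monte-Carlo samples per robustness arm. Steady-state
residual tolerance is $10^{-13}$ (scaled) with acceptance at $10^{-6}$;
stability classification uses a $10^{-9}$ marginality band; bifurcation
roots are confirmed to $10^{-8}$ on $|a_1a_2 - a_3|$ and $10^{-6}$ on
eigenvalues. All random draws in the package go through seed-scoped wrappers
that restore the caller's RNG state.

## Known limitations

Limit cycles are characterized by simulation, not numerical continuation
(no Floquet multipliers, no codimension-2 analysis). The steady-state solver
returns one equilibrium (the relaxation-selected root) per call; systems
engineered to be multistable should be explored by scanning initial
conditions. Free-parameter counts per family variant are derived
mechanically from the active structure and need not coincide with any
particular published table's accounting. The piecewise-constant zero-order
idealization is deliberately not implemented; all results use its smooth
Michaelis--Menten counterpart.
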