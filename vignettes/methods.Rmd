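---
title: "Model calibration and experiment selection for gene-network ODEs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model calibration and experiment selection for gene-network ODEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grndesign)
```

## The model

A network of $G$ genes is described by $2G$ state variables, one mRNA and
one protein per gene. Transcription of a regulated gene follows Hill
kinetics in its regulator proteins: an activator contributes
$\mathrm{pro}_g \, (x/K_d)^h / (1 + (x/K_d)^h)$ and a repressor
$\mathrm{pro}_g / (1 + (x/K_d)^h)$, where $x$ is the regulator protein
level, $h$ the Hill coefficient and $K_d$ the half-saturation constant.
When several transcription factors act on one gene their rate terms are
summed, all sharing the gene's single production strength
$\mathrm{pro}_g$; no AND-type multiplicative gating is implemented, and
regulated genes have zero basal transcription by default (configurable per
gene through the network's `basal` field). Translation is mass action with
rate constant $\mathrm{rbs}_g$ (the ribosomal-binding-site strength), so

$$\dot m_g = \mathrm{transcription}_g(p) - \delta_{m,g}\, m_g, \qquad
  \dot p_g = \mathrm{rbs}_g\, m_g - \delta_p\, p_g .$$

mRNA degradation rates are fixed at $\delta_m = 1$ and not estimated;
all proteins share one degradation rate $\delta_p$. The free parameters
are therefore $2G + 1 + 2I$ for $I$ interactions — 29, 35 and 49 for the
bundled 6-, 7- and 9-gene example topologies. Perturbations rewrite
parameters before simulation: a knockout zeroes both production steps of
its gene, an siRNA knock-down multiplies the gene's mRNA degradation rate
by 5, and an rbs perturbation doubles the translation strength. Keeping
the state dimension fixed under knockouts (zeroed production rather than
deleted species) keeps sensitivities and data alignment uniform across
conditions.

All species start at $10^{-6}$ by default. A strictly positive start is
deliberate: at exactly zero the sensitivity system is numerically fragile
(zero is a degenerate point of the Hill terms), and a reset to a small
positive value is the standard remedy.

## Measurement error and likelihood

A measurement of a true level $x$ is
$y = \max(0,\; x + \varepsilon_{abs} + \varepsilon_{rel})$ with
$\varepsilon_{abs} \sim N(0, \sigma_{abs}^2)$ and
$\varepsilon_{rel} \sim N(0, (\sigma_{rel}\, x)^2)$. The relative error is
scaled by the noise-free model value, which makes the sum exactly Gaussian
with variance $\sigma^2(x) = \sigma_{abs}^2 + (\sigma_{rel} x)^2$ — the
alternative convention (noise scaled by the noisy value) would not combine
in closed form. Defaults are $\sigma_{rel} = 0.2$ and
$\sigma_{abs} = 0.1$; the absolute component is a package default and
prominently configurable, since realistic values depend on the platform.

The unclipped Gaussian log-likelihood (including the
$-\log \sigma(x)$ terms, which depend on the parameters through $x$) is
the working objective for estimation and design. Clipping puts a
probability atom at zero; the clipped form adds
$\log \Phi(-x/\sigma(x))$ for records with $y = 0$ and is available as a
flag, intended for final fits on data that actually contain zeros. On
zero-free data the two are identical.

Two practical consequences of the $\sigma(x)$ dependence are documented
because they are easy to trip over:

* the per-record likelihood in $x$ peaks slightly *below* the observed
  value (shrinking $x$ shrinks $\sigma$), so even noise-free data are not
  recovered exactly by the full maximum-likelihood objective — the bias is
  of order $\sigma_{rel}^2 x$;
* a genuine weighted-least-squares mode (`variance = "frozen"`, with each
  record's variance fixed at $\sigma^2(y)$) is provided; it recovers
  noise-free truth to machine precision and is the right tool for
  exact-recovery checks and for speed.

## Estimation

All estimation happens in $\log_{10}$ parameter space: parameters are
positive, act multiplicatively, and their search ranges span orders of
magnitude. Default box constraints are $\log_{10}\theta \in [-2, 3]$
(about five orders of magnitude) for all parameters except Hill
coefficients, which use $[1, 10]$ ("wide") or $[1, 8]$ ("narrow"); the
narrow upper end is a package choice — profiles and direct interaction
measurements usually support a single-digit range, but the exact cut-off
is not canonical.

Multi-start local optimization: starting points come from latin hypercube
sampling (each component's range split into $n$ equal log-width strata,
each used exactly once), and each start is optimized with the PORT
trust-region quasi-Newton code (`nlminb`). The objective evaluates one
forward-sensitivity integration per measurement condition and returns
value, gradient and a Gauss–Newton Hessian approximation
($\sum_r w_r S_r S_r^\top$ with $w_r$ the per-record curvature weight)
from the same solve. Three details matter:

* gradients come from forward sensitivity equations, never from finite
  differences across the adaptive solver (step-size adaptation makes such
  differences unreliable);
* value and gradient derive from a single integration, so they are
  mutually consistent at the solver tolerance — two separate adaptive
  solves would disagree at that level and stall tight convergence;
* the Gauss–Newton Hessian is what makes the long curved valleys of these
  likelihoods tractable; without it the quasi-Newton iteration crawls.

A start whose integration fails yields a failed fit result, not an error —
remote corners of the box routinely break the ODE solve, and the
multi-start machinery simply records them. Competing local optima are
clustered in parameter space (max-norm radius 0.1 by default) and judged
against the joint threshold $\chi^2_{0.95}(\#\text{parameters})$ on the
$-2\Delta\log L$ scale: an optimum above it is statistically
distinguishable from the best fit. Convergence is accepted on the
optimizer's own codes or on a projected-gradient norm below `grad.tol`
(default $10^{-3}$), since PORT reports "false convergence" pessimistically
when driven with an approximate Hessian.

## Profile likelihood and identifiability

The profile of parameter $i$ re-maximizes the likelihood over all other
parameters while $\theta_i$ walks a grid. Implementation choices, since no
canonical stepping rule exists:

* the initial step is curvature-scaled — a quarter of the Wald-type
  half-width from the Gauss–Newton Hessian — falling back to the step cap
  (0.2 log units) in flat directions;
* steps adapt towards a target profile drop of `target_frac` (default
  1/10) of the confidence threshold per step, halving on overshoot;
* when a step crosses the threshold by more than 30% it is retried at half
  length, so the crossing is bracketed tightly;
* re-optimizations are warm-started from the neighbouring companion
  vector; failed grid points are flagged and skipped, and excluded from
  the design parameter set;
* interval endpoints interpolate on the square root of the log-likelihood
  drop, which is exact for a quadratic profile (linear interpolation
  systematically underestimates the crossing there).

Confidence intervals at level $\alpha$ collect the values with
$\mathrm{PL} \ge \log L^* - \tfrac12 \chi^2_\alpha(1)$. A parameter is
*identifiable* when both interval ends are interior crossings,
*practically non-identifiable* when the profile reaches a box bound while
still above the threshold (one-sided information), and *structurally
non-identifiable* when the profile is flat to within $10^{-3}$
log-likelihood units across the domain. Counting non-identifiabilities can
exclude Hill coefficients: their box is deliberately narrow, so a true
value at the boundary produces a profile minimum at the border that mimics
non-identifiability.

The design machinery consumes the pooled set of companion vectors along
all profiles that stay within the threshold — up to `max_per_profile`
(default 10) per profile, evenly spaced along the grid, always including
the estimate.

## Scoring experiments

Each purchasable experiment couples a perturbation condition (wildtype
plus knockout/siRNA/rbs per gene) with a readout (an unordered protein
pair at 40 points per protein, or a whole-mRNA microarray at 20 or 10
points per mRNA); gel-shift experiments, one per interaction, return the
interaction's $h$ and $K_d$ exactly. That yields
$(3G+1)(\binom{G}{2}+2)+I$ designs — 331, 516 and 1079 for the bundled
topologies.

A design's score is the noise-normalized spread of predictions across the
profile-derived parameter set:
$$R(D) = \max_{i,t}\; \frac{\max_\theta x_i(t;\theta) -
\min_\theta x_i(t;\theta)}{\sigma_i(t)},$$
with $\sigma_i(t)$ evaluated on the current estimate's trajectory so all
candidates are compared on one scale (normalizing per-$\theta$ would
distort comparisons between candidates whose trajectories differ in
magnitude). The maximum is taken over both readout species and time
points; summation over time points is available as an alternative
aggregation flag, and in practice ranks designs very similarly. Ranking is
by descending score with cost as tie-breaker: among designs within 10%
relative score, the cheaper one wins. Designs beyond the remaining budget
are excluded but reported. Gel-shift designs are not trajectory-scored —
they resolve their two parameters outright — so they rank with $R=\infty$
exactly when at least one of their parameters is currently classified
non-identifiable, and 0 otherwise.

`design_step()` wires the pieces together — fit, profiles, parameter set,
scores, ranking — and emits a report without purchasing anything: the
final choice stays with the user. `extrapolation_uncertainty()` applies
the same spread measure per-parameter to a prediction-only condition, to
see which parameter uncertainties dominate an extrapolation.

## The virtual laboratory

`challenge_init()` hides a truth parameter vector behind a budget: data
are vended with fresh noise per purchase, deterministically derived from
the lab seed and the purchase index, so a serialized ledger replays
bit-identically. Default prices follow the challenge arithmetic — 400
credits for a two-protein time course (80 points, 0.2 points/credit),
1000 for a high-density microarray, 1600 for a gel-shift, surcharges of
350 (siRNA) and 450 (rbs) — while the low-density microarray price (600)
and the knockout surcharge (550) have no published counterpart and are
clearly-marked package defaults. Two further package choices:

* the start-up dataset is a free wildtype mRNA time course on the
  low-density grid — the minimal "free glimpse" interpretation;
* the measurement horizon is 20 time units with evenly spaced points on
  $(0, 20]$ — long enough to cover both the fast mRNA timescale
  ($\delta_m = 1$) and slower protein dynamics; $t = 0$ is excluded since
  initial conditions are known;
* gel-shifts are sold per interaction (both parameters at once), matching
  the paired bookkeeping of the budget arithmetic.

`synth_network()` generates random topologies (spanning arborescence plus
extra edges, signs uniform) with truth parameters log-uniform over the
default search box and Hill coefficients uniform on the integers 1–8, so
boundary values occur. One structural guard: gene 1 stays constitutive
(no incoming regulation) whenever the edge budget allows, because an
activation-only circuit with zero basal transcription and no constitutive
source never switches on and produces identically dark, uninformative
data — a degenerate fixture rather than a hard instance.

`run_benchmark_loop()` automates the interactive loop for benchmarking:
fit, profile, score, purchase by a strategy (`greedy_R`, `random`,
`cheapest`), repeat; it records the remaining credits, the
non-identifiability count and the parameter distance
$d = \sum_i (\log_{10}\hat\theta_i - \log_{10}\theta^*_i)^2$ per step.
The squared-log form is a package choice (scale-invariant, heavily
penalizes order-of-magnitude misses); an absolute-deviation mode exists.
The challenge's own "mean deviation in percent" is ambiguous between a
linear-scale relative error and a log deviation, so `mean_deviation()`
reports both readings and neither is used as a benchmark.

## Numerics

No ODE solver library is available to this package, so it ships two
integrators implemented in C++:

* an adaptive, L-stable Rosenbrock(2,3) pair with analytic state
  Jacobians — the robust choice for the stiff corners of the parameter
  box (protein degradation up to $10^3$, steep Hill terms);
* an adaptive Dormand–Prince 5(4) pair, much faster on the mildly stiff
  majority of trajectories because of its higher order.

The default `method = "auto"` runs Dormand–Prince with a bounded step
budget and falls back to the Rosenbrock scheme on failure, so stiff cases
degrade to the slower, stable path rather than erroring. A fixed-step
solver is deliberately not offered. Forward sensitivities (w.r.t. log10
parameters, chain rule $\theta \ln 10$ applied to the parameter Jacobian)
are propagated alongside the states; step-error control covers the states
only, mirroring the common solver default, so sensitivity accuracy rides
on the state tolerance. Defaults are `rtol = 1e-8`, `atol = 1e-10`; both
kernels are validated in the test suite against closed forms, against each
other, and against a central finite-difference oracle for the
sensitivities.

## What the tests do and do not establish

The synthetic generator reproduces the structure of the benchmark world —
network sizes, noise law, prices, perturbation semantics — but not any
particular published network: the bundled 6/7/9-gene topologies are
stand-ins with the right sizes, since the original wirings are not
reproducible from text. Green tests therefore establish that the
machinery behaves as specified on that world (counts, likelihood algebra,
profile geometry, coverage, and the qualitative design-loop claims), not
that any published headline deviation is reproduced; those depend on
unreleased truths, noise realizations and interactive choices.

The design-loop acceptance check is scaled down to fit a desk run: a
reduced budget (about two purchases), a handful of multistart starts with
warm-started refits, capped optimizer iterations, coarse profile stepping
and two profile companions per parameter. Scaling costs contrast: after
one or two purchases, most of the parameter distance of a 29-parameter
model is residual non-identifiability — the under-determined refit parks
flat parameters wherever its basin happens to lie, in both arms — so the
distance comparison between strategies is noisy even with paired seeds,
while the decrease of the non-identifiability count under profile-guided
purchasing is the robust signal at this scale. The full-budget loop, where
non-identifiabilities actually resolve and the distance becomes
informative, costs hours of compute and is out of reach of a desk test;
`run_benchmark_loop()` runs it unchanged when given the default budget.
A second scale-dependent effect is worth knowing about: gel-shift
purchases carry an infinite score while any of their parameters is
non-identifiable, so at budgets between one and two gel-shift prices the
greedy arm spends most of its credits pinning two parameters exactly
instead of buying trajectory data — locally optimal per the ranking rule,
but weaker for the summed distance than the same credits spent on
perturbation time courses. At full budget both happen; at desk scale the
budget choice decides the mix.

## Known limitations

Stochastic (SSA) simulation, delay terms and topology inference are out
of scope. The error model is the benchmark's clipped Gaussian; for real
intensity data a log-normal model is more appropriate and deliberately not
implemented here. Noise parameters are taken as known, not estimated.
Observation functions (scalings, compound readouts) are not modelled:
every species is directly observable. Design variables are discrete — no
dose–response optimization — and planning is one step at a time, with no
multi-step lookahead.
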