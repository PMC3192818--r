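---
title: "Steady-state distributions of stochastic gene circuits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state distributions of stochastic gene circuits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cmenoise computes steady-state probability distributions of molecule numbers
in stochastic biochemical reaction networks, the quantity that flow cytometry
and fluorescence microscopy measure across a population of cells. This
vignette is the package's own account of the science: the models and
approximations it implements, the parameters that matter, and the design
choices made where the methods left genuine freedom.

## The chemical master equation and its truncation

A reaction network with species counts $x = (x_1, \dots, x_d)$, reaction
propensities $a_j(x)$ (probability per unit time, molecular units) and state
changes $v_j$ evolves according to the chemical master equation (CME)

$$\frac{dP(x)}{dt} = \sum_j \big[ a_j(x - v_j) P(x - v_j) - a_j(x) P(x) \big],$$

which at steady state is a sparse linear system $MP = 0$ over the enumerated
states, with $M$ the rate (generator) matrix. cmenoise enumerates a
rectangular box $[0, u_i]$ per species and assigns zero rate to transitions
that would leave it. This *reflecting truncation* keeps every column of $M$
summing to zero, so the truncated chain is a proper Markov chain and the
solution is a genuine probability vector; truncation error is controlled by
enlarging the bounds, and the suite checks that doubling the toggle-switch
bounds moves its summary statistics by less than $10^{-4}$.

The null space is computed by replacing one balance row with the
normalization row $\sum_x P(x) = 1$ and solving the resulting nonsingular
sparse system (Matrix package LU). This is deterministic and requires no
eigensolver tuning; the residual $\max |MP|$ is checked against $10^{-9}$
after every solve. Reactions may carry, instead of a fixed change vector, a
*jump kernel* — a probability distribution over destination states — which is
how cell division enters the T7 circuit below; a fixed change is just the
degenerate kernel.

For one species with synthesis rate $a_s(n)$ and degradation rate $a_d(n)$,
detailed balance is exact and the steady state is the product recursion
$P(n) \propto \prod_{j \le n} a_s(j-1)/a_d(j)$ (`birth_death_analytic()`),
which for constitutive expression ($a_s = k_s$, $a_d = k_d n$) is Poisson
with mean $k_s/k_d$. These closed forms double as oracles for the linear
solver in the test suite.

## Rescaled CME for large molecule numbers

When molecule numbers are large but not large enough for deterministic rate
equations, the lattice can be coarsened by an integer scale factor $S$: the
solver keeps only states on the multiples of $S$ and each reaction moves
$x \to x + S v_j$ at rate $a_j(x)$, evaluated at the coarse source point.
This finite-difference construction was chosen because it (a) reduces
*bit-exactly* to the unscaled generator at $S = 1$ (the suite asserts
identity of the sparse structures) and (b) preserves the qualitative
structure of the solution: for birth–death the coarse ratio
$P(n)/P(n-S) = k_s/(k_d n)$ still crosses 1 exactly at $n = k_s/k_d$, so the
peak sits at the right molecule number for every $S$. Keeping the problem on
a discrete lattice avoids the boundary and discretization error a continuous
(Fokker–Planck-style) approximation would introduce. A single global $S$ is
supported; region-dependent scales are out of scope. Raw coarse masses are
interpreted by `normalize_scaled()`: each coarse point aggregates the mass of
the $S^d$ underlying fine states (total 1), with the per-fine-state density
view exposed alongside.

Propensities are evaluated at the coarse source point, not a midpoint;
midpoint evaluation would break the exact peak-location property above.

## Modified Gibbs sampling

Direct solution scales poorly with dimension, so the package also samples the
steady state. Ordinary Gibbs sampling cycles through the species, drawing
each count from its conditional distribution given the others. The exact
conditionals of a CME steady state are unavailable in general, so the sampler
assumes *detailed balance per species*: along a lattice line, the ratio
between neighbouring states is approximated by
$P(x + e_i)/P(x) \approx a_{s,i}(x) / a_{d,i}(x + e_i)$, where $a_{s,i}$
($a_{d,i}$) is the summed propensity of reactions increasing (decreasing)
species $i$ by one. Chaining these ratios along a line gives a 1-D
distribution that can be sampled exactly. For a 1-D birth–death chain this
is not an approximation at all; in higher dimensions it errs exactly to the
extent that probability flux circulates.

Two design points deserve explanation:

**Rotated sampling lines.** Axis-aligned Gibbs gets trapped in isolated
modes: in a bistable toggle switch initialized in one mode, reaching the
other requires an improbable excursion in a single coordinate. The sampler
therefore rotates the coordinate system: it draws a slope $m$ with
$\tan^{-1}(m)$ uniform on $(-90^\circ, 90^\circ)$ and samples along the two
rounded lattice lines with slopes $m$ and $-1/m$ through the current point
(near-vertical draws degenerate to the axis-aligned pair). A line of slope
$\approx -1$ passes through both modes of a symmetric toggle, so mode hopping
becomes routine. Inter-point steps along a rotated line are decomposed into
unit axis moves in fixed species order (first species first); the
path-dependence this introduces is part of the method's approximation error,
and a path-symmetrized variant (averaging both species orders) was measured
not to reduce it.

**Cycle structure.** Each cycle first sweeps the $d$ coordinate axes (the
basic Gibbs cycle) and then, with rotation enabled, rotates a species pair
and samples the two rotated lines. The axis sweep carries very little
stationary bias — on the reference toggle switch, the *exact* stationary
distribution of the axis-aligned kernel (computed by power iteration on the
explicit conditionals) differs from the true solution by an SSD of only
$3 \times 10^{-4}$ — while the rotated lines contribute the mode mixing and
also most of the bias (a rotated-lines-only cycle roughly quadruples the
sampling SSD on the reference toggle). Interleaving both keeps the escape
property at a bias of a few $10^{-3}$ in SSD at 10,000 samples.

The sampler is seeded and fully reproducible; burn-in defaults to 1,000
cycles; initialization defaults to the deterministic fixed point found by
damped Euler descent of the reaction-rate drift, and genuinely isolated
modes (where even rotation mixes slowly) can be sampled separately and
pooled with user-supplied `mode_weights`, one chain per mode.

**What stationarity means here.** Because the conditionals are approximate,
one sampling cycle started from the exact distribution does *not* preserve
it exactly. The bias is small — total-variation distance around 1.5% per
marginal on the reference toggle — but it is a real property of the method,
and at 50,000 one-cycle draws a goodness-of-fit test has the power to detect
it (computed chi-square noncentrality ≈ 95 for the U marginal against a 1%
critical value of ≈ 88). The corresponding stationarity check in the test
suite is therefore expected to reject, and is retained as an honest record
of the approximation rather than softened. The per-species
`detailed_balance_error()` diagnostic quantifies the same approximation from
the exact solution: it is the probability-weighted average relative error
between the true neighbour ratio and the detailed-balance ratio, zero for
any 1-D chain, about 0.25 (U) and 0.58 (V) for the asymmetric reference
toggle. The weighting convention (by source-state probability) is declared
in the documentation, and the destination-weighted alternative is reported
alongside, since conventions differ.

## Extrinsic noise by convolution

Intrinsic noise — stochasticity of the modeled reactions — is what the CME
captures. Everything else (unmodeled reactions, rate-constant fluctuation,
measurement noise) tends to *shift* the distribution, so the package models
the observed distribution as a convolution:

$$P = (1 - a) \, (P_{\text{intrinsic}} \ast M_0) + a B,$$

with $M_0$ a zero-mean (discrete) Gaussian with given covariance, $B$ a
background distribution (default: uniform over the box) with small weight
$a$, representing mass far from any intrinsic prediction. Two routes are
provided and must agree: `convolve_grid()` convolves a solved distribution
by direct summation, renormalizing the kernel over the box per source state
so no mass is lost at the boundary; `shift_samples()` adds an independent
Gaussian draw to each sample (clipping negative values to zero — a
*different* boundary convention, and the documented reason the two routes
deviate slightly near the origin), appending $na/(1-a)$ background draws
when $a > 0$. Per-mode covariances are supported by partitioning mass by
nearest mode center (Euclidean distance scaled by each mode's width) and
convolving each part with its own kernel.

A complementary, fully analytic model of extrinsic noise draws the
constitutive-expression mean $y = k_s/k_d$ from a gamma distribution with
shape $\alpha$ and scale $\theta$; the Poisson–gamma mixture integrates to a
negative binomial (mean $\alpha\theta$, variance $\alpha\theta +
\alpha\theta^2$), and the suite checks the closed form against numerical
quadrature to $10^{-8}$. `fit_extrinsic_sigma()` recovers a Gaussian width
(optionally with a co-fitted mean shift) by least squares on probabilities;
the objective is a package choice — unweighted squared error is simple and
treats all states alike — so width fits to non-Gaussian targets (like the
gamma mixtures) are soft characterizations, not sharp estimands: the
best-fit widths for the two reference gamma mixtures come out at 4.2 and
5.9 against moment-matching values of 4.5 and 6.3.

## The reference circuits

**Toggle switch.** Two mutually repressing proteins with Hill synthesis and
linear degradation: U synthesis $r_u / (1 + (v/K_v)^\beta)$, degradation
$d_u u$, and symmetrically for V. The reference parameterizations (set 1:
$K_u = K_v = 1$, $r_u = 10$, $r_v = 9$, $\beta = \gamma = 2$, $d = 1$;
set 2: $r_u = r_v = 5$, $\beta = 1$) are bistable, and the direct solve on
$[0,60]^2$ — chosen so boundary mass is below $10^{-8}$ — reproduces the
reference means, standard deviations and the 69%/70% U-dominant fractions to
a fraction of a percent. An optional antibiotic block replaces V's
degradation constant by $d_{v0} + d_{v1} A/(A + k_A)$, the SOS-response
perturbation that raises repressor turnover. The convention that $K_v$ gates
repression *of U* (and $K_u$ of V) matters only for asymmetric parameter
sets and is documented at the constructor.

**T7 RNAP positive-feedback circuit.** A polymerase activates its own
transcription from $M$ promoters while its expression slows cell growth;
growth dilutes the polymerase by division. State $(n, m)$: free polymerase
and inactive promoters. Five chemical reactions (synthesis from inactive
promoters at $k_0 m$ and active ones at $k_1 (M - m)$, activation
$k_f m n$, deactivation $k_b (M - m)$, degradation $d_{x0} n$) plus
division as a jump kernel with propensity $\mu / (1 + n/\theta)$ — the
effective growth rate $\mu$ already folds in the population's distance from
carrying capacity, and $\theta$ (molecules) sets how expression burden slows
growth. Steady state here is a *pseudo-steady state*: log-phase growth with
intracellular kinetics fast relative to the growth curve; with division
removed ($\mu = 0$) the model correctly collapses to a single mode.

Two conventions in the division kernel were genuinely open, and were fixed
by requiring the model to reproduce all three reference ON fractions
simultaneously:

* the active-promoter synthesis term is $k_1 (M - m)$, since $m$ counts
  *inactive* promoters and the $k_0 m$ term is explicitly tied to them;
* at division the promoters reset to the inactive state and the *free* pool
  is split binomially with $p = 1/2$; promoter-bound polymerase is not
  returned to the tracked daughter's free pool. Returning it makes the OFF
  mode essentially disappear at the reference parameters (the solution
  becomes ON-monomodal and the ON fraction insensitive to $\mu$), while the
  discard convention yields 93.8% / 49.6% / 44.0% ON for the three reference
  conditions — matching the reference 94% / 48% / 49% — so the model treats
  promoter-bound polymerase as staying with the chromosome rather than the
  cytoplasm of the tracked daughter.

A population-balance variant (doubling the division influx and solving the
growth eigenproblem, which over-weights fast-dividing OFF cells) was also
examined and rejected: it inverts the base case to OFF-heavy.

## Partitioning rules and distances

Distributions are compared throughout by the sum of squared deviations,
$\mathrm{SSD}(P, Q) = \sum_x (P - Q)^2$, bounded by 2 (disjoint point
masses). Two ON/OFF rules are provided. The *dominant-species* rule (toggle)
calls a state ON when the first protein outnumbers the second; mass on the
tie diagonal is split 50/50 — the reference tables don't state a tie
convention, the choice shifts the reference ON fractions by well under a
percentage point, and the option is exposed. The *valley* rule (T7) finds
the two most prominent peaks of a 1-D histogram and places the border at
the lowest bin strictly between them, the border bin counting as OFF (this
assignment is fixed by the worked example in the rule's documentation); a
single-peak histogram falls back to the shoulder rule, bordering at the
smallest absolute finite difference. Peaks are ranked by topographic
prominence rather than raw height: on smooth bimodal solutions the two are
identical, but on noisy simulation histograms height-ranking can pick two
wiggles riding on the same mode (observed to misread a 94%-ON occupancy
histogram as 31% ON), whereas prominence discounts them.

## The Gillespie oracle

An independent check on every solver is exact stochastic simulation
(direct-method Gillespie, with jump-kernel reactions sampling their
destination). Propensities and destinations are tabulated per state once
and the event loop runs in compiled code, so horizons of $10^5$ time units
(millions of events) take under a second. The simulator runs on the same
reflecting-truncated chain as the direct solver, which makes the long-run
occupancy and the solved steady state estimates of the same distribution —
the suite requires SSD agreement within 0.01 at $t = 10^5$ on every shipped
model. Occupancy is time-weighted (not event-weighted), with the first 10%
of the horizon discarded by default.

## Problem sizes, tolerances and limitations

The test suite exercises the reference toggle on its $61^2$ lattice, the T7
circuit on $121 \times 11$, sampling runs of $10^3$–$4 \times 10^4$ points,
simulation horizons of $10^5$ time units, and moment-convergence checks at
$n = 500/4500/40500$; these sizes were chosen so each check isolates one
property while the whole suite stays comfortably rerunnable on a laptop.
Key numerical tolerances: steady-state residual $10^{-9}$; probability
normalization $10^{-10}$; kernel row sums $10^{-12}$; Gaussian kernels
truncated at $6\sigma$ (then boundary-renormalized).

What the shipped models do and do not establish: they are exact small
networks with known parameters, so passing tests demonstrate correctness of
the numerics and the internal consistency of the three routes (direct,
scaled, sampled) plus the noise model — not that any real circuit follows
Hill kinetics, that extrinsic noise is Gaussian, or that a fitted $\sigma$
is mechanistically interpretable. Known limitations: the direct solver is
memory-bound near $5 \times 10^6$ states; jump kernels are not supported on
coarse lattices ($S > 1$); the sampler requires unit-step reactions and
inherits the detailed-balance bias discussed above; grid convolution is
implemented for one and two species (marginalize first in higher
dimensions); and the T7 division conventions, while validated against all
three reference conditions, remain a reconstruction of an under-specified
model.
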