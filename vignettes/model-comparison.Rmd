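---
title: "Comparing continuum and lattice models of angiogenic sprouting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing continuum and lattice models of angiogenic sprouting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(snailtrail)
```

## The models

`snailtrail` implements and cross-validates two one-dimensional continuum
descriptions of angiogenic sprouting together with the lattice agent-based
model (ABM) that underlies one of them. Both continuum systems track a
tip-cell density $N(x,t)$ and a stalk-cell density $E(x,t)$ on $x \in
[0,L]$, driven by a tumour angiogenic factor (TAF) whose concentration is
taken at quasi-steady state as the linear ramp $C(x) = \nu x$.

**Snail-trail model (ST-PDE).** Tips move by random motility $D$ and
chemotaxis $\chi$, branch at rate $\lambda N C$, and are removed by
tip-to-tip ($a_n \mu N^2$) and tip-to-sprout ($a_e \mu N E$) anastomosis:

$$
N_t = D N_{xx} - \chi (N C_x)_x + \lambda N C - a_n \mu N^2 - a_e \mu N E .
$$

Stalk cells are laid along the tips' paths at a rate proportional to the
magnitude of the *net* tip flux, with the correction factor
$\kappa = \mu / (\chi |C_x|)$ converting net flux into total path length:

$$
E_t = \kappa(x) \left| D N_x - \chi N C_x \right| .
$$

**Coarse-grained model (P-PDE).** Derived from the lattice ABM by a
mean-field closure, it multiplies the movement terms by the
volume-exclusion factor $(1 - a_n N - a_e E)$ and produces stalk directly
from movement and tip-to-tip fusion:

$$
N_t = \left( D N_{xx} - \chi (N C_x)_x \right)(1 - a_n N - a_e E)
      + \lambda N C - a_n \mu N^2 - a_e \mu N E ,
\qquad
E_t = \mu N + a_n \mu N^2 + a_n N \left( D N_{xx} - \chi (N C_x)_x \right).
$$

The movement factor can turn the tip equation backward-parabolic when
$a_n N + a_e E > 1$; solutions are therefore started at $t_0 > 0$ (default
$0.2$), by which time anastomosis has pruned the high-density seed region,
and the factor is clamped at zero with a warning if the guard is ever
violated during integration.

**Lattice model.** Tips perform a biased random walk on a 2-D lattice with
spacing $h$ and step $\delta t$: right/left with probability $1/4 \pm b$,
$b = (k/4)\,(C(x{+}h)-C(x{-}h))$, up/down with $1/4$. The continuum
constants follow from $D = \mu h^2/4$, $\chi = \mu k h^2$, $\mu = P_m /
\delta t$, $\lambda = P_p\, \mu$. Vacated sites become stalk; branching
occurs with probability $P_p C(x)$ onto a vacant neighbour. Validity
requires $0 \le b \le 1/4$; the standard rescaled parameter set sits
exactly at $b = 1/4$.

### Anastomosis rules and sprout identity

The verbal rule "anastomosis occurs when a tip moves into an occupied
site" leaves open what happens when a tip meets *its own* trail. The
package resolves this with a sprout-identity rule: every seeded tip (and
its subsequent trail) carries an id; moving onto a *foreign* sprout's
stalk is a fusion event that removes the tip, while re-entering one's own
trail is simply a blocked move, and tip-to-tip collisions remove the
moving tip when $a_n = 1$. Branched tips inherit the parent's identity: at
birth a daughter is surrounded by the parent's trail, and a new branch
remains part of the same vascular tree until it fuses with *another*
vessel.

This choice is parameter-free and fixes the two failure modes of the
obvious alternatives, which we measured during development. Unconditional
removal on any stalk contact annihilates the seeded population (about one
surviving tip per realisation by $t_0$), which is incompatible with the
early-time $\tau^{-1}$ amplitude decay of the continuum solutions and
degenerates the calibration study. Removing tips with a fixed probability
per stalk contact leaves tips embedded in the dense wake near the parent
vessel, which inflates the inter-model differences in the
weak-gradient regime by an order of magnitude. Under the sprout-identity
rule the ensemble reproduces the published scales in both regimes. The
continuum $a_e$ remains what it is in the theory: a *fitted* effectiveness
of tip-to-sprout fusion, not a lattice probability. The unconditional
variant is retained as `abm_params(self_fuse = TRUE)`, and fresh-identity
branching as `branch_new_sprout = TRUE`.

### Seeding and boundaries

Every site of the column at $x = 0$ starts tip-occupied; early anastomosis
prunes the excess before $t_0$. Lattice edges reflect (out-of-range moves
abort). Simulations are run on a lattice truncated at `Lx` chosen so that
no appreciable cell mass reaches the truncation wall within the simulated
window; the models stop being meaningful once mass reaches the TAF source
anyway.

## Dimensionless groups and the asymptotic reduction

With $u = (a_n\mu/\lambda) N$, $w = (a_e\mu/\lambda) E$, $\tau = \lambda
t$, $X = x\sqrt{\lambda/D}$, the comparison is governed by

$$
\epsilon = \frac{\sqrt{D\lambda}}{\chi\nu}, \qquad
\alpha = \frac{\lambda}{\mu}, \qquad
\beta = \frac{a_e \mu}{a_n \lambda}, \qquad
\Psi = \alpha/\epsilon^2 .
$$

When chemotaxis dominates ($\epsilon \ll 1$) and branching is rare
($\alpha = \epsilon^2 \Psi \ll 1$), both PDE systems share the same
leading-order dynamics in a frame travelling with the chemotactic drift,
$y = X - (\tau + X_0)/\epsilon$:

$$
\partial_\tau U_0 = \partial_y^2 U_0 + U_0(\tilde C - U_0 - W_0),
\qquad \partial_\tau w_0 = \beta\, U_0 \ \ \text{(at fixed } X\text{)},
\qquad U_0 \to 0 \text{ as } y \to \pm\infty .
$$

`solve_leading_order()` integrates the equivalent laboratory-frame form
($u_{0,\tau} = u_{0,XX} - u_{0,X}/\epsilon + u_0(c - u_0 - w_0)$,
$w_{0,\tau} = \beta u_0$) with far-field Dirichlet conditions. The two
forms are related exactly by the frame map, and the laboratory form keeps
the stalk accumulation at fixed position — which is what the full model's
stalk field is compared against — exact instead of re-interpolated.
Solutions carry both coordinates. $X_0$ defaults to placing the initial
pulse centroid at $y = 0$, subject to the right boundary image $y^*$
staying positive. $\tilde C$ is clipped to $[0,1]$, the physical range of
the scaled TAF concentration.

The reduction is only valid in the domain interior: once the front reaches
the no-flux wall at the TAF source, the full models grow an
$O(\epsilon)$-wide boundary layer (the brush-border pile-up) that a
far-field problem cannot carry. Leading-order comparisons therefore
exclude a margin of $10\epsilon$ at the right wall.

## Early-time self-similar profiles

For $\beta \lesssim O(1)$ the leading-order tip density behaves at early
times as $U_0 = \tau^{-1} \tilde U_0(z)$, $z = \tau^{-1/2} (y -
\sigma(\tau)\tau)$, where the profile solves the two-point boundary-value
problem

$$
\tilde U_0'' + \tfrac{z}{2} \tilde U_0' + \tilde U_0 = \tilde U_0^2,
\qquad \tilde U_0(\pm\infty) = 0 .
$$

`solve_similarity_bvp()` computes the nontrivial branch by damped Newton
iteration on a central-difference collocation, started from a unit-height
Gaussian; the trivial branch is detected (maximum below $10^{-3}$) and
rejected. The default truncation $z \in [-12, 12]$ with homogeneous
Dirichlet ends is checked by interval doubling (the peak moves by less
than $10^{-8}$), and the solution is verified in the test suite against an
independent shooting integration that exploits the equation's reflection
symmetry (integrate from $z = 0$ with $\tilde U_0'(0) = 0$, bisect on the
peak value). Both approaches give a bell curve with peak $\tilde U_0(0)
\approx 0.6898$.

For $\beta \gg 1$ tip-to-tip fusion drops from the balance, the equation
linearises to $\tilde U_0'' + (z/2)\tilde U_0' - A \tilde U_0 = 0$ with
$U_0 = \tau^{A}\tilde U_0$, and decay at both ends with non-negativity
forces $A = -1/2$ and the Gaussian $\tilde U_0 = C_1 e^{-z^2/4}$
(`similarity_gaussian()`).

`similarity_to_lab()` maps profiles back through $X = z\sqrt{\tau} +
\phi(\tau)\tau + X_0/\epsilon$ with $\phi = 1/\epsilon + \sigma$. The wave
speed $\sigma(\tau)$ is estimated from the full solution's peak trajectory
(piecewise over output times), and the amplitude is pinned by a one-point
normalisation: the mapped maximum at the earliest output time is set equal
to the full model's. The self-similar description degrades as $\tau$
grows — branching ($\tilde C U_0$) and tip-to-sprout fusion ($U_0 W_0$)
scale with $\tau$ — so late-time curves fall below the full solutions.

## Numerical choices

* **Space.** Finite volumes; central diffusion; the chemotactic advection
  uses a van Leer flux limiter (MUSCL) by default. First-order upwinding
  (`scheme = "upwind"`) carries numerical diffusion $\chi\nu\,\Delta x/2$,
  which at practical grids is comparable to $D$ itself in the rescaled
  regimes and would contaminate the comparisons; the limited second-order
  flux removes this while preserving positivity at steep fronts. A
  `"central"` variant exists for smooth, diffusion-dominated checks.
* **Time.** `deSolve::lsoda` with a banded numeric Jacobian (the state
  interleaves $N$ and $E$ so the band stays narrow); default tolerances
  `rtol = 1e-8`, `atol = 1e-10`. Solvers verify non-negativity to
  tolerance and signal integrator failure.
* **Grids and study sizes.** The shipped experiment configurations use
  2001–4001 nodes (grid-convergence is part of the test suite: refining
  from $\Delta x = 1/200$ to $1/400$ changes the headline differences by
  under 2% of their values) and ensembles of 100–200 lattice realisations
  (the published study used 1000; at 200 the Monte-Carlo error of the
  ensemble means is already well below every comparison bound). The
  acceptance script reports the sizes it used alongside each value.
* **Determinism.** All lattice randomness flows through R's RNG from a
  single seed; ensembles are reproducible bit-for-bit given `(seed, n)`.

## What the generator does and does not emulate

The lattice ensemble reproduces the study conditions: full-column seeding,
the exact parameter mappings, anastomosis-driven pruning to a detached
unimodal pulse by $t_0 = 0.2$, branching proportional to the local TAF,
and ensemble column averages as the continuum's initial and calibration
data. It does not emulate TAF uptake or time dependence, off-lattice or
Potts-style motility, lateral-inhibition patterning of tip selection, or
any feature of real vascular data (vessel radii, perfusion, 3-D
architecture); agreement of the two PDEs initialised from these ensembles
is therefore evidence about the model family, not about vasculature.

Two quantitative limits of the mean-field correspondence are worth
knowing. First, the ensemble's pulse *position* and cell *masses* track
the coarse-grained PDE closely, but the pulse *height* agrees only to
roughly 25% — anastomosis introduces exactly the occupancy correlations
the mean-field closure neglects, and the published calibration figure
makes the same point (the fitted amplitudes differ visibly from the
ensemble's). Second, the mapping $D = \mu h^2/4$ holds in the diffusion
limit; at finite step the biased walk's $x$-variance per step is
$h^2/2 - (2bh)^2$, so at the bias bound $b = 1/4$ the realised spreading
is about half the nominal $D$. The mean-field test in the suite therefore
runs at $P_m < 1$ (smaller $\delta t$ at fixed $D$, $\chi$), where the
correction $(\chi\nu)^2\delta t / D$ is small.

## The experiment regimes

`regime()` pins five configurations, each reproducing the dimensionless
groups of its published comparison at load time:

```{r regimes}
dimensionless_groups(regime("fig3")$params)
```

* `fig1` — dimensional presentation, $D = 5\times10^{-4}$, $\chi = 0.425$,
  $\mu = 150$, $\lambda = 0.1$, $a_e = 0.05$ on $x \in [0, 10]$. The PDEs
  use $\nu = 1$ ($\epsilon \approx 0.017$): with $\nu = 1/L$ the regime
  would sit at $\epsilon \approx 0.17$, where the two models are visibly
  distinguishable and the pulse would traverse a tenth of the domain over
  the simulated window — neither consistent with how this comparison is
  reported. No lattice walk exists at $\nu = 1$ here (it would need
  $b = 0.39 > 1/4$), so the initial data are generated with the steepest
  admissible lattice TAF ramp, $\nu_{\text{lattice}} = 1/L$.
* `fig2` — leading-order validation at $\epsilon = 10^{-3/2}$, $\alpha =
  10^{-3}$, $\beta = 39.1$ over $\tau \in [0.2\lambda, 2\lambda]$.
* `fig3` — the same groups on the long window $\tau \in [0.2\lambda,
  19.4\lambda]$, with pulse-speed and early-decay measurements.
* `fig4` — self-similar overlay for the `fig3` parameters over $\tau \in
  [0.2\lambda, 5\lambda]$.
* `fig5` — high branching ($P_p = 5\times10^{-2}$): calibrate $(\lambda,
  a_e)$ per model against the ensemble by nonlinear least squares
  (stacked tip and stalk residuals, equal weights; Gauss-Newton
  confidence intervals), then compare the calibrated models with each
  other and their leading-edge speeds with the ensemble's. The tip edge
  uses the half-maximum crossing; the stalk edge is tracked on newly
  deposited stalk $E - E(t_0)$, because the frozen wake plateau otherwise
  pins the half-maximum at the seed column for every model.

```{r fig2-run, eval = FALSE}
r2 <- run_regime("fig2", seed = 1)
plot_comparison(r2$comparison)
```

## Known limitations

* The measured early-decay slope and the absolute inter-model difference
  levels depend on the initial pulse amplitude the generator delivers at
  $t_0$, which in turn depends on update-rule details that admit several
  defensible choices; the package's measured slope (about $-1.12$) is
  steeper than the published $-1.02$ because its initial amplitude sits
  somewhat above the self-similar attractor $u\tau \approx 0.41$.
* The calibration study's fitted $(\lambda, a_e)$ are reproducible in
  order of magnitude but not in digit: they compensate for whatever the
  lattice rules do at high branching density, and are reported as soft
  checks only.
* No boundary-layer analysis: comparisons stop where the brush-border
  layer begins.
* The P-PDE stalk equation is integrated as written; its density is not
  capped at the lattice occupancy bound, so late-time stalk fields may
  exceed 1 where the lattice saturates.
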