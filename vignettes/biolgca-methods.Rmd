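---
title: "BIO-LGCA models of cell migration: methods and design notes"
author: "biolgca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BIO-LGCA models of cell migration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biolgca)
```

## The model class

A biological lattice-gas cellular automaton (BIO-LGCA) represents migrating
cells on a regular periodic lattice (a 1D chain or 2D square lattice here).
Each node carries $b$ *velocity channels* — one per nearest-neighbour
direction — and $a$ zero-velocity *rest channels*, for a node capacity of
$K = a + b$ cells per phenotype. The *exclusion principle* allows at most
one cell per channel; the node state is the occupation vector
$\mathbf{s} \in \{0,1\}^{|\Sigma| K}$. Two derived observables recur
throughout: the cell number $n(\mathbf{s}) = \sum_j s_j$ and the node flux
(momentum) $\mathbf{J}(\mathbf{s}) = \sum_j s_j \mathbf{c}_j$.

Channel order is normative in this package: velocity channels come first in
counterclockwise angular order (1D: $+1,-1$; 2D: $+x,+y,-x,-y$), then rest
channels. With this order channels $j$ and $j + b/2$ are opposite, and the
nematic alignment vector
$\mathbf{N}(\mathbf{s}) = \tfrac12\sum_{p=1}^{b}
\mathbf{c}_{[2(p-1)\bmod b]+1}\, s_p$
is exactly the angle-doubled (orientation-only) analogue of the flux:
opposite channels contribute along the *same* direction, which is what an
orientational (nematic) interaction requires. An ordering that interleaves
opposite pairs (e.g. $+x,-x,+y,-y$) would break this index arithmetic,
which is why we fix the angular convention.

One time step applies, synchronously at every node,

1. **reorientation** $O$: the node's cells are redistributed among its
   channels with Boltzmann probabilities
   $P(\mathbf{s}\to\mathbf{s}^O) =
   \frac{1}{Z}\, e^{E(\mathbf{s}^O, \mathbf{s}_N)}\,
   \delta_{n(\mathbf{s}), n(\mathbf{s}^O)}$,
   where $E$ is the rule's interaction energy, $\mathbf{s}_N$ the
   configuration of the von Neumann neighbourhood (the $b$ adjacent nodes,
   the centre excluded), and the Kronecker delta enforces exact mass
   conservation;
2. **birth/death** $R$ and **phenotypic switching** $S$ (optional);
3. **propagation** $P$: every cell in a velocity channel moves one node
   along its channel direction, $s_j(r + c_j, k+1) = s^{S\circ R\circ O}_j(r, k)$.

The synchronous update and the explicit velocity channels are what let the
model sustain collective motion at high density, where asynchronous
exclusion models jam.

## Built-in reorientation rules

All directional rules share the director-field form
$E = \beta\, \mathbf{G} \cdot \mathbf{J}(\mathbf{s}^O)$ with different
neighbourhood fields $\mathbf{G}$:

| rule | field | behaviour |
|---|---|---|
| `randomWalkRule()` | $E \equiv 0$ | unbiased walk |
| `chemotaxisRule(beta)` | signal gradient $\mathbf{G}_{sig}=\sum_p \mathbf{c}_p\, c_{sig}(r+\mathbf{c}_p)$ | drift up a signal gradient |
| `haptotaxisRule(beta)` | static vector field $\mathbf{E}(r)$ | drift along an ECM gradient |
| `contactGuidanceRule(beta)` | $E=\beta\,\lvert\mathbf{E}\cdot\mathbf{J}\rvert$ | axis-aligned, sign-free |
| `alignmentRule(beta)` | local momentum $\mathbf{D}=\sum_p \mathbf{J}(\mathbf{s}_p)$ | polar alignment |
| `adhesionRule(beta)` | density gradient $\mathbf{G}=\sum_p n(\mathbf{s}_p)\,\mathbf{c}_p$ | agglomeration |

The 1D `invasionRule()` combines three independent mechanisms:
aggregation with a logistic (carrying-capacity) density gradient
$g_{agg} = \sum_j n(r+c_j)\,[1 - n(r+c_j)/n_{crit}]\,c_j$ whose parameter
$n_{crit}$ (> 0, non-integers allowed, no normalisation by $K$) models the
homeostatic density; alignment with the neighbourhood flux
$g_{align} = \sum_j j(r+c_j)$ (the central node's own flux is not
included); and a resting energy
$\beta_{rest}\, n_{rest}(\mathbf{s}^O)\, n_{rest}(\mathbf{s}_N)$ that makes
cells rest next to resting neighbours (steric interaction). With
$(\beta_{agg}, 0, 0)$ and $n_{crit}\to\infty$ it reduces to the adhesion
rule.

The density-gradient sum runs over the $b$ lattice neighbours; since rest
channels have zero velocity, extending the sum to $K$ terms would change
nothing, and the neighbourhood template has exactly $b$ members.

## Deriving rules instead of postulating them

**From a biophysical potential.** For an overdamped self-propelled
particle whose orientation $\theta$ relaxes in a potential $U$ under
rotational noise, the stationary orientation density is
$P(\theta) \propto e^{-\beta U(\theta)}$ with $\beta = \gamma/D_\theta$
(`stationaryOrientationDistribution()`). Discretising orientations onto
the lattice directions and assuming independent channel occupations gives
outcome weights $e^{-\beta \sum_j U(c_j) s^O_j}$
(`reorientationFromPotential()`; rest channels get zero potential unless
supplied, with the integration constant absorbed into $Z$). Cosine
potentials $U = -C\cos^n(\theta - \varphi)$ map onto the director-field
form: $n=1$ gives $\beta\,\mathbf{J}\cdot\mathbf{G}$ (polar), $n=2$ gives
$\beta\,\mathbf{N}\cdot\mathbf{G}$ (nematic), with
$\lVert\mathbf{G}\rVert = C$ and $\arg\mathbf{G} = \varphi$
(`directorFieldRule()`). The time-dependent orientation dynamics itself is
deliberately not simulated: only the stationary solution enters the rule.

**From data (maximum caliber).** Given a per-channel observable
$\tilde U$ and measured targets $E_j$, the maximum-path-entropy channel
distribution is $P_j(i) \propto e^{\beta(j)\tilde U_i}$ with $\beta(j)$
fixed by $\langle \tilde U\rangle_{P_j} = E_j$. The expectation is
strictly increasing in $\beta$, so `maxcalMultipliers()` solves a
bracketed monotone root problem per time step (bracket expanded
geometrically until a sign change, tolerance $10^{-10}$); a
time-independent target yields a constant multiplier, and a target outside
the open range of the observable is reported as infeasible together with
the feasible interval. For $\tilde U_i = \mathbf{c}_i\cdot\mathbf{G}$ the
two routes coincide — the test suite checks this equivalence against a
directly enumerated oracle to $10^{-10}$. For a velocity autocorrelation
series $g(k)$, `persistenceFromAutocorrelation()` returns the per-step
direction probabilities $\propto e^{d\,g(k)\,(\mathbf{c}_{i_0}\cdot\mathbf{c}_i)}$.

## Mean-field analysis

**Adhesion in 1D.** Linearising the low-density mean-field
finite-difference equation (`adhesionFdeTrajectory()`) about a homogeneous
density $\bar\rho$ gives a per-step growth factor per wavenumber

$$F(\kappa) = \frac{2}{K}\left[2\beta\bar\rho - 1 + \cos\kappa
  - 2\beta\bar\rho\cos^2\kappa\right],$$

implemented in the factored form
$\frac{2}{K}(1-\cos\kappa)\,[2\beta\bar\rho(1+\cos\kappa) - 1]$ so that
$F(0) = 0$ holds exactly in floating point for any parameters (the
conserved total-mass mode). The fastest-growing mode satisfies
$\cos\kappa_c = 1/(4\beta\bar\rho)$, which has a solution only above the
critical combination $(\beta\bar\rho)_c = 1/4$; the critical wavelength
$\lambda_c = 2\pi/\kappa_c$ diverges at threshold and decreases to the
limit 4 lattice sites as $\beta\bar\rho \to \infty$
(`adhesionCritical()`). Wavenumbers are treated as quasi-continuous on
$(0, \pi]$; finite-lattice modes $2\pi m/L$ are used only when comparing
with simulations. Note what the linear result does and does not promise:
it describes the onset of the instability from a near-homogeneous state.
At strong sensitivity the growth spectrum is almost flat across
mid-$\kappa$, the pattern saturates within a few steps, and the realised
cluster spacing is set by nucleation from the initial noise — close to,
but systematically a little above, $\lambda_c$.

**Invasion model.** The mean-field dynamics of the combined rule is the
lattice-Boltzmann equation $f_j(r+c_j, k+1) = \rho(r,k)\, T_j$
(`lbeMap()`), whose homogeneous steady state solves
$\bar\rho = 2 f_v + a f_r$, $f_v = \bar\rho/(2 + a\Pi_r)$,
$\Pi_r = e^{2\beta_{rest} a f_r}$. `invasionSteadyState()` uses a damped
fixed-point iteration (damping 0.5) with a bracketed root search plus
Newton polish as fallback, to residual $< 10^{-12}$; $\Pi_r$ is evaluated
through $e^{-x}$ forms so that very large $\beta_{rest}$ cannot overflow.
Stability is read off the Boltzmann propagator
$\Gamma_{m,n}(q) = e^{-i c_m q}\big[T_m + \sum_{\ell=1,2} e^{i c_\ell q}\,
\partial f_m(r+c_m,k+1)/\partial f_n(r+c_\ell,k)\big]$, built from
analytic derivatives of the LBE map at the steady state. The derivatives
are cross-validated against central finite differences of `lbeMap()`
(step $10^{-6}$, tolerance $10^{-5}$) by `validatePropagator()`, which
raises a validation error rather than proceeding on disagreement. At
$q = 0$ one eigenvalue equals 1 (density conservation), and the spectra at
$q$ and $2\pi - q$ are complex conjugates.

## Phase classification: a design note

`classifyPhase()` labels a parameter point diffusive, collective,
aggregation or jammed. Two spectral facts shaped the algorithm, and both
are worth recording because a naive classifier gets them wrong:

* the alignment instability's fastest modes are the *uniform-flux* mode at
  $q \to 0$ and a degenerate staggered mode at $q = \pi$, and both carry
  real eigenvalues (the travelling, complex-eigenvalue band lies at
  intermediate $q$ with smaller modulus). Distinguishing collective motion
  purely by the argument of the dominant eigenvalue therefore fails.
  Instead, collective motion is recognised when the $q = 0$ spectrum —
  with the conservation eigenvalue removed — dominates: a growing
  homogeneous flux is precisely spontaneous collective migration. A
  travelling dominant interior mode (appreciable argument) also counts as
  collective.
* wherever the resting fraction $a f_r/\bar\rho$ is high, the
  rest-feedback mode is very weakly unstable (spectral radius
  $1 + 10^{-3}$ to $1 + 10^{-2}$, tending to $1^+$ as
  $\beta_{rest}\to\infty$ because the transition-probability derivatives
  saturate); a strictly-stable definition of the jammed phase would be
  empty. The jammed label is therefore assigned by the frozen-state
  criterion itself — resting fraction at least `restThreshold` (default
  0.75) — and takes precedence.

Remaining points: stable everywhere means diffusive; an unstable
stationary interior mode means aggregation. The thresholds
(`restThreshold`, `argTol`, stability slack `eps` $= 10^{-9}$) are
configuration, not physics, and are exposed as arguments.

`phaseDiagram()`'s default window was chosen once from the linear theory
and then fixed: $\bar\rho = 0.2$ (the analysis assumes the low-density,
at-most-one-cell-per-node regime), $a = 1$, $n_{crit} = K = 3$,
$\beta_{agg}, \beta_{align} \in [0, 6]$ (the collective onset
$4\beta_{align}\bar\rho > 2 + a\Pi_r$ sits near $\beta_{align} \approx 4$
there, and the aggregation onset is in-window), and
$\beta_{rest} \in \{0.5, 8\}$ (resting fractions $\approx 0.35$ and
$0.90$, cleanly on either side of the jamming threshold).

```{r phase-demo, eval = FALSE}
pd <- phaseDiagram()
table(pd$phase, pd$betaRest)
```

## Numerical choices

* **Log-space Boltzmann weights.** All outcome probabilities are computed
  as $e^{E - \max E}$ before normalisation, so sensitivities of order
  $10^2$ (used in the aggregation demonstrations) cannot overflow.
* **Exact enumeration.** The reorientation support is enumerated exactly
  ($\prod_\sigma \binom{K}{n_\sigma}$ outcomes, cached per count/geometry);
  no Monte-Carlo estimate of $Z$ is ever used. $K$ is capped at 16 to
  bound the enumeration.
* **Reproducibility.** One seeded generator; node updates consume draws in
  canonical node order, so a (configuration, seed) pair reproduces a
  trajectory bit for bit. Exports embed the seed and a configuration hash.
* **Degenerate inputs.** Empty and saturated nodes have a single outcome
  and are skipped; a birth into a full node fails; a phenotype switch into
  an occupied channel fails; all such rules preserve exclusion by
  construction rather than by rejection sampling.
* **Reorientation conserves per-phenotype counts.** The switch operator is
  the only mechanism that changes phenotypes; letting reorientation mix
  phenotype blocks would duplicate its role.

## What the synthetic initial states do and do not emulate

`initializeRandom()` occupies every channel independently with probability
$\bar\rho/K$: a spatially homogeneous, uncorrelated population — the
standard initial condition for studying pattern *onset*, and the
assumption under which the mean-field linearisation applies. Real tissues
are not uncorrelated: they carry pre-existing spatial structure,
correlated velocities, and heterogeneous phenotypes. Tests built on these
states therefore validate the model's internal consistency
(conservation laws, Boltzmann statistics, linear-regime growth), not the
claim that any particular tissue is well described by a given rule.

## Problem sizes used by the test suite

The shipped tests run simulations sized for laptop-scale wall time, chosen
as the smallest systems in which each effect is cleanly measurable: chains
of 100 nodes over 500 steps for aggregation patterns (10 seeds), 1000-step
conservation checks on 30 nodes, $10^5$-sample chi-square comparisons of
sampled against enumerated reorientation outcomes, $10^4$ synthetic
channel choices for multiplier recovery, and a $20\times20\times2$
parameter grid with 256 wavenumbers for the phase diagram.

## Known limitations

* Hexagonal and 3D lattices, non-periodic boundaries, and off-lattice
  positions are out of scope; the square lattice carries the usual
  discretisation artefacts (e.g. the staggered $q=\pi$ mode above).
* Environment fields are static; there is no coupled signal dynamics.
* The mean-field machinery assumes the low-density single-particle
  regime; its predictions degrade as $\bar\rho$ approaches 1 and say
  nothing about deep-quench coarsening.
* Birth/death and switching use the simplest exclusion-respecting forms;
  the model class itself does not prescribe them, and the operators are
  pluggable.
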