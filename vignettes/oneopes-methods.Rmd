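---
title: "OneOPES in oneopes: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OneOPES in oneopes: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the bias
potentials, the replica ladder, the funnel post-processing, what the toy
systems do and do not establish, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The sampling problem

Absolute binding free energies from molecular dynamics require crossing
binding/unbinding barriers of tens of kJ/mol many times, which plain MD does
not do on affordable time scales. Adaptive-bias methods flatten those
barriers along a few collective variables (CVs), but any slow degree of
freedom *not* captured by the CVs (a buried water, a ligand torsion) leaves
hysteresis that converges slowly. OneOPES addresses this with a ladder of
eight replicas: replica 0 carries only the main bias and is used for all
estimates; replicas 1–7 add progressively more auxiliary biases on
"forgotten" degrees of freedom plus an expanded-temperature bias, and feed
decorrelated configurations to replica 0 through Metropolis exchanges.

## OPES Explore

Each bias instance targets the well-tempered distribution
$p^{tg}(\mathbf{s}) \propto P(\mathbf{s})^{1/\gamma}$ with bias factor
$\gamma = \Delta E/(k_B T)$, where $\Delta E$ is the BARRIER parameter. The
Explore variant estimates $p^{tg}$ *directly* from the biased samples by
depositing unit-weight Gaussian kernels every PACE steps, and applies

$$ V(\mathbf{s}) = (\gamma - 1)\, k_B T \,
   \ln\!\left( \frac{\hat p^{tg}(\mathbf{s})}{Z} + \varepsilon \right). $$

Two conventions here deserve a note:

* **Prefactor.** With the kernel estimate of the *target* distribution in
  the logarithm, the self-consistent prefactor is $(\gamma - 1) k_B T$:
  at convergence $\hat p^{tg} = P^{1/\gamma}$ gives
  $V = -(1 - 1/\gamma) F + \text{const}$, the well-tempered bias. (The
  $(1 - 1/\gamma) k_B T$ prefactor pairs with an estimate of the *unbiased*
  $P$, the original variant's construction.) The distinction matters: with
  the wrong pairing the bias feedback is $\gamma$-fold too weak and a
  15 $k_BT$ barrier never flattens, which is directly visible in the
  double-well validation runs.
* **Normalization and the BARRIER contract.** $Z$ is maintained as the
  running supremum of the kernel density over deposited kernel centers, and
  the density ratio is clamped to $[0, 1]$. With
  $\varepsilon = 1/\mathrm{expm1}\!\left(\Delta E / ((\gamma-1) k_B T)\right)$
  this makes $\max V - \min V \le \Delta E$ an exact algebraic bound (tested
  to $10^{-6}$ relative on dense grids at every checkpoint), not an
  asymptotic property. The bias is gauged to $[-\Delta E, 0]$: untouched
  regions sit at the $\varepsilon$ floor $-\Delta E$, which is what makes
  newly discovered states attractive — the exploration mechanism. The more
  common convention $\varepsilon = e^{-\Delta E/((\gamma-1) k_B T)}$ exceeds
  the bound by a $\ln(1+\varepsilon)$ term; ours is asymptotically identical
  and exactly bounded.

Kernel widths (SIGMA) come from the CV standard deviations of a short
unbiased run, exactly as the real protocol prescribes; periodic CVs
(torsions) use wrapped kernels with minimum-image distances. By default
every deposit is kept (exact KDE); for long runs an optional
`merge_threshold` compresses kernels landing within a scaled distance of an
existing center into it (weight-averaged, as production OPES codes do).
The desk-scale presets use threshold 1, which keeps kernel lists at around a
hundred entries over millions of steps with no measurable change in the
estimated profiles.

## OPES MultiThermal

Replicas 4–7 additionally bias the potential energy $U$ so one trajectory
samples a geometric grid of `n_temps = 8` temperatures between the 298 K
thermostat and the replica's top temperature (310/330/350/370 K):

$$ V(U) = -k_B T_0 \ln \frac{1}{N_T} \sum_\lambda
   e^{-(\beta_\lambda - \beta_0) U - c_\lambda},
   \qquad c_\lambda = \ln \left\langle
   e^{-(\beta_\lambda - \beta_0) U} \right\rangle_{T_0}, $$

with the gauge $c_{\lambda=0} = 0$ so the bias vanishes for a single-member
ensemble. The $c_\lambda$ are free-energy-perturbation constants estimated
on the fly from a running log-sum-exp over (bias-reweighted) energy samples
and refreshed every PACE = 100 steps. The geometric grid with eight rungs is
a choice — only the endpoints are prescribed by the protocol — made so that
neighboring rungs overlap comfortably for the toy systems' energy
fluctuations. A constant-energy record leaves the bias at zero with a
one-time warning.

## The replica ladder and exchanges

`build_default_ladder()` reproduces the published scheme: replica $k$
carries auxiliary multi-CV biases $1..k$ (hydration CVs in the order WL4,
WH1, WL1, WH3, WH8, WH5, WH10), each with BARRIER 3 kJ/mol and PACE 20000;
the main bias on (z, COS) uses BARRIER 100 kJ/mol and PACE 10000; torsions
join every auxiliary roster, cycling in pairs when there are three so each
roster holds exactly 3 CVs and every pair occurs. Exchanges are attempted
every 1000 steps between alternating even/odd neighbor pairs with the
standard Hamiltonian-replica-exchange rule at the common thermostat
temperature,

$$ p_{acc} = \min\left(1, e^{\beta[(V_i(x_i)+V_j(x_j)) -
   (V_i(x_j)+V_j(x_i))]}\right), $$

configurations swapping while bias states stay with their replica slot.
Neighbor-only attempts and the even/odd sweep pattern are standard practice;
the protocol text does not specify them.

## Funnel post-processing

Replica-0 frames are reweighted with $e^{+V_{tot}/k_B T}$ (instantaneous
total bias), histogrammed along the funnel axis z (fixed-width bins, default
0.05 nm for the toy systems), and turned into the absolute binding free
energy with the standard-state funnel correction

$$ \Delta G_B = -k_B T \ln\!\left[ C^0 \pi R_{cyl}^2
   \sum_{z \in \text{bound}} e^{-(G(z) - G_U)/k_B T} \, \Delta z \right], $$

with $C^0 = 1/1660\,\text{Å}^{-3}$ and $G_U$ the mean of $G$ over a
configured unbound plateau window. Errors come from 3 contiguous blocks of
the post-equilibration trajectory (sample standard deviation, $n-1$
denominator), or from treating independent runs as blocks. For dual funnels
the two sides' per-block estimates are averaged block-by-block before the
block statistics; a side with less than 1% post-discard occupancy of its
unbound window is dropped and the other side's estimate passes through.
Both the plateau and bound windows are explicit configuration: the protocol
defines neither, and the defaults (outer cylinder stretch for the plateau,
the basin for the bound window) are recorded in the analysis presets.

## Toy systems: what they emulate and what they do not

The compiled engine integrates overdamped Langevin dynamics (BAOAB-limit
discretization, $O(\Delta t^2)$ configurational accuracy) at 298 K in
kJ/mol–nm–ps units. Two stated worlds:

* **Double well:** symmetric quartic, barrier 15 $k_BT$, minima 2 nm apart.
  Biased with one Explore instance (BARRIER 80 kJ/mol — roughly twice the
  physical barrier, mirroring the 100-vs-typical-barrier margin of the real
  protocol — PACE 100, SIGMA from an unbiased pre-run). Exact references
  come from 1-D quadrature.
* **Toy host–guest:** a Gaussian basin of depth 20 kJ/mol and width 0.25 nm
  at the funnel origin, a single funnel (R_cyl 0.2 nm, cone half-angle 0.6
  rad to z = 0.4 nm, wall 1000 kJ/mol/nm², axial walls at −0.6 and 1.3 nm),
  and a slow solvent-occupancy coordinate q in a symmetric double well of
  barrier 20 kJ/mol coupled to the bound state with 8 kJ/mol — the
  hidden-degree-of-freedom trap. The z-only single replica shows exactly the
  pathology the ladder exists to cure: q barely ever flips (the validation
  runs count the transitions), so its $\Delta G$ is hysteretic, while the
  ladder's auxiliary q biases and MultiThermal replicas flip q constantly
  and hand equilibrated configurations down to replica 0. The auxiliary CV
  q is reused across all seven rosters (distinct hydration CVs only exist
  in real systems); reusing one CV across rosters mirrors the torsion
  cycling of the real protocol. All references are 3+1-D quadratures
  (radially symmetric cross-section integrals times a 1-D q partition
  function).

A green toy test establishes that the estimators are correct and that the
ladder mechanism works as designed on a system with one hidden slow mode.
It does not establish force-field accuracy, water-model behavior, finite
exchange acceptance across 8 realistic replicas, or any of the benchmark
numbers of real host–guest systems, which require microsecond-aggregate MD.

### The soft-wall subtlety

With a half-harmonic funnel wall, thermal penetration beyond $R_{cyl}$
inflates the effective cylinder cross-section by
$\approx 2\sqrt{\pi k_B T / (2k)}/R_{cyl}$ — over half of $\pi R_{cyl}^2$
for k = 1000 kJ/mol/nm² at R_cyl = 0.2 nm. This is a property of the
restraint, not the estimator: the profile formula with the literal
$\pi R_{cyl}^2$ then differs from the hard-wall standard state by about
−kT ln(A_eff/πR²). The formula-validation test therefore runs the
quadrature with a stiff wall (10⁶ kJ/mol/nm², assumption regime), while the
sampling-convergence tests compare the simulated estimate against the exact
value of the *same* soft-wall estimator, isolating sampling error. Real
systems with stiff restraints or larger R_cyl sit much closer to the
assumption regime.

## Numerical choices

* Time step 10⁻³ ps with unit friction: the stiffest toy curvature
  (320 kJ/mol/nm²) gives $\Delta t\, U''/\gamma \approx 0.3$, where the
  BAOAB-limit integrator's configurational error is well under 1%.
* Kernel evaluation truncates Gaussians at $e^{-30}$; far below the
  $\varepsilon$ floor everywhere it matters.
* Histogram (not KDE) profiles, bin centers on a fixed grid, for exact
  reproducibility; unsampled bins are NA and excluded.
* Reweighting uses the instantaneous bias; the first 20–30% of frames are
  discarded as equilibration in the presets (the real protocol discards
  50–100 ns depending on the host).
* All randomness flows through R's RNG (the compiled engine draws from the
  same stream), so a seed fixes ladders bitwise; solvent-shell generation
  saves and restores the caller's RNG state.
* Kendall τ is tau-b (tie-corrected); the linear fit regresses predicted on
  experimental (switchable); bootstrap CIs are percentile intervals over
  resampled system sets with optional Gaussian noise at each system's
  reported uncertainty, following the SAMPL-style analyses.
* The coordination switching function is the stretched-and-shifted rational
  (exact 1 at contact, exact 0 at d_max). The printed protocol values
  (r0 = 2.5 Å, d_max = 0.8 Å, r_nl = 1.5 Å) are stored verbatim although
  they are mutually inconsistent as printed (d_max < r0 and r_nl < d_max
  would zero the CV and starve the neighbor list — plausibly nm misprinted
  as Å); every value is overridable and the self-consistent toy tests
  override them. They are deliberately not "fixed" silently.

## Known limitations

* The toy guest is a point particle: the orientation CV (COS) is exercised
  by the CV module and the emitted protocol, not by the toy dynamics.
* The compiled engine supports at most 16 coordinates and 8 CVs per bias —
  ample for the toys, not for real systems (which run through the emitted
  PLUMED inputs instead).
* MultiThermal FEP constants come from a single running estimator;
  no bin-wise or weighted-histogram refinement across rungs.
* Exchange bookkeeping is sequential (desk scale); no MPI contract.
* The emitted PLUMED dialect follows 2.9 keyword spellings but is not
  validated against a PLUMED build here; the funnel-wall composition is
  documented in each emitted file header.
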