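---
title: "Mesoscopic stochastic reaction-diffusion with concentration-dependent rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscopic stochastic reaction-diffusion with concentration-dependent rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesosim)
```

## The problem

Reaction-diffusion master equation (RDME) simulations discretize space into
voxels of side $h$: molecules jump between neighboring voxels with propensity
$nD/h^2$ per direction, and react within a voxel with propensity proportional
to a *mesoscopic* rate constant $k_{meso}$. For diffusion-influenced
bimolecular reactions the results depend on $h$, and naive use of the
microscopic rate constant $k_{micro}$ underestimates reaction rates on coarse
grids. This package implements two principled choices of $k_{meso}$ for 2D
periodic membranes, a microscopic Brownian-dynamics engine that serves as
ground truth, the stochastic Cdc42 polarity circuit of budding yeast as the
motivating application, and the spatial statistics used to quantify polarity
cluster behavior.

## Microscopic model and rate conversions

Particles are points diffusing by Euler-Maruyama steps; a reactant pair within
the reactive radius $\rho$ reacts with probability rate $\lambda$
(the $\lambda$-$\rho$, or Doi, picture). The equivalent contact-rate
(Smoluchowski-style) constant in 2D is $k_{micro} = \lambda \pi \rho^2$
(`lambda_from_kmicro_2d()` and its inverse). For a cytosolic molecule binding
a membrane molecule in a 3D parameterization the reactive volume is a half
sphere, $\lambda = 3 k_{micro} / (2\pi\rho^3)$.

The polarity model lives in a purely 2D representation: membrane and cytosol
are coincident periodic squares of side $L = \sqrt{A_m}$ distinguished only by
the diffusion coefficient of the species ($D_{cyto} = 10$, $D_{memb} =
0.0045\ \mu m^2/s$). Rates from a volumetric macroscopic model are rescaled
per reaction class (`scale_macroscopic_to_2d()`): cytosol-to-membrane
first-order rates by $\eta = V_m/V_c$, membrane bimolecular rates by
$1/\Delta z$, cytosol-membrane bimolecular rates by $A_m/V_c$; membrane-only
and membrane-to-cytosol rates are unchanged. `convert_2d_to_3d()` promotes the
cytosol-binding rates by $V_c/A_m$ for spherical-cell particle simulations.
These conversions reproduce the reference parameter table to its printed
precision (see `tests/testthat/test-model.R`).

## The scale-dependent rate $k_h$

$k_h$ is defined so that the mean association time of a single molecule pair
on the $L \times L$ grid matches the microscopic mean association time on a
disk of equal area,

$$\tau_{micro} = \frac{\pi R^2}{k_{micro}}\left(1 + \alpha F(\rho/R)\right),
\qquad \alpha = \frac{k_{micro}}{2\pi D},$$

with $F(\nu) = \ln(1/\nu)/(1-\nu^2)^2 - (3-\nu^2)/(4(1-\nu^2))$ and $D$ the
summed diffusion coefficient. The mesoscopic time on the grid is
$\tau_{meso} = \frac{L^2}{2\pi D}\ln\frac{L}{h} + 0.1951\frac{L^2}{4D} +
\frac{L^2}{k_{meso}}$ (the constant 0.1951 comes from the pseudo-Green's
function of the discrete 2D Laplacian). Equating the two at $L^2 = \pi R^2$
gives

$$k_h = k_{micro}\left[1 + \frac{k_{micro}}{D} G\right]^{-1},\qquad
G = \frac{1}{2\pi}\ln\frac{h}{\sqrt{\pi}\rho} -
\frac{1}{4}\left(\frac{3}{2\pi} + 0.1951\right).$$

Two numerical points deserve care:

* The identity $\tau_{meso}(k_h) = \tau_{micro}$ is exact against the
  *small-$\nu$ asymptote* $F(\nu) \approx \ln(1/\nu) - 3/4$ (that is how the
  closed form arises); against the full $F$ it holds to $O(\nu^2\ln\nu)$.
  `tau_micro(..., asymptotic = TRUE)` exposes the asymptotic form, and the
  test suite asserts the identity at $10^{-10}$ against it and at $10^{-3}$
  against the exact form.
* $G < 0$ for $h$ near the lower bound, so $k_h > k_{micro}$ there: the
  mesoscopic rate *compensates* for the encounter statistics lost on a coarse
  grid. $k_h$ exists only for
  $h > h_{min} = \sqrt{\pi}\, e^{(3 + 2\cdot 0.1951\pi)/4 - 2\pi D/k_{micro}}
  \rho$; for the benchmark parameters $h_{min} \approx 4.50\rho$ and for the
  fastest membrane association of the polarity model $h_{min} \approx
  4.96\rho$, i.e. the familiar "about $5\rho$" rule. Requests below the bound
  raise an error that reports $h_{min}$ in both $\mu m$ and multiples of
  $\rho$.

All logarithms are natural; this is forced by the construction identity and
verified by it.

## The concentration-dependent rate $k_c$

At high local density the association rate within a voxel is governed by the
mean free area per reactant, not by the voxel size. With $n = \max(n_A, n_B)$
molecules of the more abundant reactant, $A_c = h^2/n$ and

$$k_c(n) = k_{micro}\left[1 + \alpha F(\rho/R_c)\right]^{-1},\qquad
R_c = \frac{h}{\sqrt{\pi n}},$$

capped at $k_{micro}$ when $R_c \le \rho$ (crowding). $k_c$ is positive,
non-decreasing in $n$, bounded by $k_{micro}$, and requires only $h > \rho$.
Because $k_c$ is a pure function of local occupancy, the engine precomputes a
lookup table over $n = 1 \dots n_{cap}$ (the first occupancy at which the cap
applies) per reaction and grid, and reads it during simulation.

Dissociation rates are paired to the association mode by the equilibrium
condition $k^d_{meso} = k^d_{micro}\, k_{meso}/k_{micro}$. In $k_c$ mode the
ratio is evaluated at the voxel occupancy of the forward reactants at
propensity-update time, floored at $n = 1$ when no forward reactants are
present; this is an interpretation (the occupancy at which the
dissociation-side $k_c$ should be evaluated is not prescribed) and is
isolated in one place in the engine.

## Engines

`simulate_rdme()` implements the Next Subvolume Method: each voxel keeps its
total propensity and its next event time in an indexed binary min-heap; after
an event only the one or two affected voxels are rescanned, the firing voxel
draws a fresh exponential, and a voxel whose propensity changed without
firing has its key rescaled by the propensity ratio (valid by memorylessness).
Within a voxel the event channel is chosen proportionally to channel
propensities. Bimolecular products are placed in the reacting voxel. The
compiled kernel sustains several million events per second on one core, which
makes 60-300 s of polarity-model time (about $2\times 10^7$ events per
simulated second on the $h = 5\rho$ grid) a desk-scale computation.

`simulate_particles()` is the microscopic oracle: per step it diffuses all
molecules, then fires first-order reactions as independent per-molecule
Bernoulli trials ($P = 1 - e^{-k\Delta t}$), then enumerates reactant pairs
within $\rho$ (cell list above 64 molecules, all-pairs below; the two agree
exactly, which is tested), shuffles the candidate pairs, and processes them
sequentially with $P = 1 - e^{-\lambda\Delta t}$, at most one reaction per
molecule per step. The random processing order removes positional bias; the
paper-style operator ordering (diffuse, first-order, bimolecular) is a
documented choice guarded by a time-step-halving convergence test.
Dissociation places one product at the complex position and the other at
$\rho(1+\varepsilon)$ ($\varepsilon = 10^{-3}$ by default) in a uniform
random direction, which keeps the fresh pair ineligible for immediate
rebinding. Benchmark time steps follow
$\Delta t = (0.1\rho)^2/(4 D_{tot})$; polarity-scale particle runs use
$\Delta t = \rho^2/(4 D_{cyto})$.

Both engines use one xoshiro256++ stream per realization derived from the
user seed, so ensembles are reproducible and identical seeds give
byte-identical trajectories.

### A note on reversible reactions

The RDME with the paired dissociation rates is exactly detailed balanced: the
per-voxel equilibrium constant is $k_{meso}/k^d_{meso} = k_{micro}/k^d_{micro}$
regardless of grid or mode. The $\lambda$-$\rho$ microscopic model with
contact placement is *not* reversible in the strongly diffusion-controlled
regime: the region within $\rho$ is depleted by reaction while dissociation
deposits pairs exactly at contact, and the two fluxes do not balance the way
a well-mixed equilibrium would. The two descriptions therefore agree on
irreversible kinetics and on reaction-limited equilibria, but mesoscopic
reversible equilibria sit above the microscopic ones at strong diffusion
control. This mirrors the "small differences for the reversible reaction"
noted in the source analysis. The test suite pins each engine to an
independent oracle (detailed-balance closed form for the RDME; a well-mixed
CME equilibrium for the particle engine in the reaction-limited regime) and
checks the direction and a bounded ratio for the cross-engine comparison
rather than asserting exact agreement.

## The polarity model

`build_polarity_model()` constructs the Cdc42 circuit: GEF shuttling
(R-1a/R-1b), activation of membrane Cdc42D by membrane GEF (R-2a) and by the
Cdc42T-GEF complex (R-3), deactivation (R-2b), complex formation with
membrane (R-4a/R-4b) or cytosolic GEF (R-6), Cdc42D membrane shuttling
(R-5a/R-5b), and optionally direct recruitment of cytosolic Cdc42D by the
complex (R-7, the "updated model"). Positive feedback arises because the
complex activates neighboring Cdc42D. Defaults follow the reference
parameterization (5000 Cdc42, 15-700 GEF, $\rho = 0.02\ \mu m$,
$A_m = 64\ \mu m^2$). Two parameters are deliberately explicit rather than
defaulted:

* `k_4a` spans 0-2 $\mu m^2/s$ in the source analysis with no single base
  value, so the factory requires it. Desk-scale demonstrations in this
  package use $k_{4a} = 1\ \mu m^2/s$ — mid-range, diffusion-influenced, and
  in the stable-patch regime.
* `gef_total` defaults to 700, the top of the admissible range, where
  polarization is robust for all three simulation methods.

Tagged shadow species for dwell-time washout experiments are generated
mechanically (`tag_model()`): every membrane species carrying the chosen
moiety (Cdc42 or GEF) gets a `_tag` twin; reactions are rewritten for every
tagged/untagged reactant combination with products inheriting the tag from
the reactant they descend from. Cytosolic species have no shadows, so
membrane detachment of a tagged species automatically produces the untagged
cytosolic form — the washout rule — and tagged kinetics are provably
identical to untagged kinetics because they are copied, not re-typed by hand.

## Analysis statistics

* **$H(r)$** (`H_of_r()`): with $P(r)$ the pairwise-distance density
  normalized by $N(N-1)$ ordered comparisons,
  $H(r) = \sqrt{(A/\pi)\int_0^r P} - r$. Zero for uniform patterns, positive
  maxima locate the cluster scale. Distances are minimum-image, so
  $r_{max} = L/2$; the default bin width is 0.05 $\mu m$, well below the
  1.1 $\mu m$ feature used as the polarization metric
  (`polarization_metric()` evaluates $H(1.1\,\mu m)$ on pooled active Cdc42).
  RDME snapshots enter through pseudo-coordinates sampled uniformly within
  voxels so grid and particle data share one code path.
* **Centroid on the torus** (`centroid_torus()`): per-axis circular means;
  exact for boundary-straddling clusters and translation-equivariant. A
  pattern with no directional concentration is flagged undefined.
* **$D_{patch}$ and $\beta$** (`msd_and_dpatch()`): centroid tracks sampled
  every minute are broken at single-step jumps above `max_jump` (6 $\mu m$),
  unwrapped by minimum-image increments, and pooled over all interval pairs
  per lag. The lag-1 MSD (fast within-patch wobble) is subtracted, and
  $\log MSD$ is fit against the log of the lag elapsed *beyond the baseline
  interval*. The abscissa choice matters: subtracting MSD(1 min) removes
  that interval's genuine displacement along with the wobble, so fitting
  against the raw lag would read a pure Brownian centroid as superdiffusive
  ($\beta \approx 1.3$ on the default window). The elapsed-lag abscissa
  recovers $\beta = 1$ and $D$ exactly for Brownian tracks and carries a
  systematic of about $+0.07$ for strongly anomalous tracks
  ($\beta = 0.85$), which the parameter-recovery tests account for. The
  default fit window is lags 2-10 (minutes), configurable and recorded in
  the fit object.
* **$CV_{patch}$** (`cv_patch()`): abundance-weighted spatial average of the
  temporal coefficient of variation of local Cdc42T counts over a 60 s
  window sampled every second. The conventional SD/mean is used (the
  source text's phrasing inverts it, which would not produce the reported
  positive correlation with patch mobility); for independent Poisson counts
  of mean $\mu$ the statistic is $1/\sqrt{\mu}$, which is tested.
* **Dwell times** (`dwell_time()`): from a steady-state snapshot, membrane
  species carrying the moiety are converted to tagged twins inside a disk
  around the patch centroid; the tagged total decays as molecules detach and
  untag, and a single exponential fitted after a configurable transient
  (`t_min`) gives the dwell time. The tagging radius and transient length
  are exposed as parameters because the source analysis leaves both to
  inspection.

## What the built-in scenarios emulate

`make_fixture()` reproduces the study conditions: the low-density
(A = B = 5) and high-density (A = B = 5000) association benchmarks at
diffusion control $\lambda\pi\rho^2/D_{tot} = 50$ on $L = 1\ \mu m$, the
domain-size sweep at A = B = 2000, and the polarity model in base and
updated form. These synthetic systems exercise diffusion-limited kinetics,
crowding, and self-organized clustering, but they do not emulate features of
real cells such as 3D cytosolic gradients, heterogeneous membrane
microdomains, GAP spatial regulation, or vesicle traffic — passing tests
establish fidelity to the stated microscopic model, not to yeast.

Problem sizes used by the automated checks are chosen for desk-scale
reproducibility: the two-molecule association oracle uses $10^4$
realizations on an $8\times 8$ grid; the low-density benchmark comparison
uses 200 replicates of 20 s; the scaled high-density benchmark
(A = B = 1000, $L = 0.45\ \mu m$) compares mean curves over the first 25 ms
where the density effect is strongest; and the polarity demonstration runs
the full reference domain for 60 s of simulated time, enough to observe
monotone growth of $H(1.1\ \mu m)$. The long-horizon claims (polarization
times of 130-240 s, loss of polarity below about 450 GEF, the abrupt
mobility transition near $k_{4a} = 0.003\ \mu m^2/s$, the steady-state
$H$ maximum at 1.1 $\mu m$) require hour-scale ensembles; the engines and
statistics support them unchanged via `batch_run()`, but they are outside
the default test runs.

## Known limitations

* 2D only: the 3D spherical-cell particle simulation is out of scope; only
  the 2D-to-3D parameter conversions are provided.
* No same-species (A+A) bimolecular reactions and at most two reactants and
  two products per reaction — the networks of interest never need more.
* $\tau_{meso}$ (and hence $k_h$) assumes square domains and square grids.
* The reversible-equilibrium mismatch between the mesoscopic and the
  contact-placement microscopic model discussed above is inherent to the
  model definitions, not a numerical artifact; treat mesoscopic reversible
  equilibria at strong diffusion control with care.
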