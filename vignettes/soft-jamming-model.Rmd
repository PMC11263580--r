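---
title: "The soft-jamming transport model and its estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The soft-jamming transport model and its estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porejam)
```

## The phenomenon and the model

When virus-sized particles are driven by a pressure difference through
cylindrical nanopores whose diameter is only a few times the particle size,
the translocation frequency does not grow linearly with pressure as simple
advection would predict. Two features appear: a *critical pressure* below
which almost no particles exit the pore, and a *frequency plateau* at high
pressure that decreases as the particle concentration increases. Crucially
the frequency never drops to zero — the pore is partially, reversibly
clogged. This is soft jamming: a quasi-stationary accumulation of particles
inside the channel that gates the admission of new ones without ever sealing
the pore.

porejam models a translocation as two sequential, independent waits:

$$f(C, P) = \frac{1}{\tau_1(C) + \tau_2(C, P)}$$

**Entry time** $\tau_1$. The pore mouth is blocked whenever clog-bound
particles occupy it. Treating the exchange between free particles (upstream
concentration $C$) and the clog as a Langmuir equilibrium with dissociation
constant $K_d^{clog}$ and detachment rate $k_{off}^{clog}$,

$$\tau_1(C) = \frac{1}{k_{off}^{clog}} \cdot \frac{C}{C + K_d^{clog}},$$

which is independent of pressure, vanishes at $C = 0$, and saturates at
$1/k_{off}^{clog}$ — the origin of the concentration-ordered plateaus.

**Transit time** $\tau_2$. Inside the channel, advection at the mean
Poiseuille speed $v = P R^2 / (8 \eta L)$ competes with sticking to the wall
at rate $k_{on}^{pore}$. The stationary concentration of free particles
decays as $C_n(x) = C \exp(-k_{on}^{pore} x / v)$, so a fraction
$\exp(-P_c/P)$ survives to the exit, where
$P_c = 8 \eta k_{on}^{pore} L^2 / R^2$ is the critical pressure. The
resulting mean transit time is

$$\tau_2(C, P) = \frac{1}{k} \cdot \frac{P_c}{P} e^{P_c/P}, \qquad
  k = \pi k_{on}^{pore} C L R^2 .$$

The package stores only the fundamental triple
($k_{on}^{pore}$, $k_{off}^{clog}$, $K_d^{clog}$) plus the geometry; $k$ and
$P_c$ are always derived, so inconsistent states cannot be constructed.

Two limiting cases are used as experimental controls and fall out of the
same implementation: particles with no interactions at all translocate at
the advective rate $f = C v \pi R^2$ (carboxyl-functionalized beads), and
particles that stick to the wall but not to each other have $\tau_1 = 0$,
giving a critical pressure followed by a linear regime with no plateau
(amino-functionalized beads).

## The master curve

Writing $\tau = 1/f$ and $\alpha = (P_c/P)\exp(P_c/P)$, the model predicts

$$y \equiv \frac{k_{off}^{clog}}{k}\,(k \tau - \alpha)
      = k_{off}^{clog}\,\tau_1
      = \frac{C}{C + K_d^{clog}} \equiv x ,$$

so data from any particle, pore size and surface condition should collapse
onto the identity line once each dataset's fitted parameters are known. We
chose this specific rescaling of the excess time because it is the unique
dimensionless form that makes $y = x$ exact under the model; a raw
"excess time over dissociation time" is not dimensionless. The collapse RMS
of $(y - x)$ is the package's goodness diagnostic (`collapse_metric()`).

Two numerical caveats are documented here deliberately. First, computing
$y$ subtracts two nearly equal numbers when $\tau_2 \gg \tau_1$; in double
precision the noiseless identity holds to ~$10^{-13}$ only when operating
points are taken at $P \gtrsim P_c$ (which is also the only regime where
events are observable). Second, measurement noise on $f$ is amplified in
$y$ by the factor $\tau/\tau_1$; the analysis scripts therefore place
probe pressures where $\tau_2$ is between about an eighth and four times
$\tau_1$, mirroring what an experimenter plotting such a collapse would
measure.

## Probing the clog with DNA

The clog's geometry is measured with a polymer caliper: flow-driven DNA
translocation follows the suction (barrier-crossing) model
$f_{DNA} = f_{suc} (P/P_{suc}) \exp(-P_{suc}/P)$, and for Poiseuille flow
the critical suction pressure is tied to the pore's hydraulic resistance,
$P_{suc} = (k_B T/\eta) \cdot 8 \eta L / (\pi R^4)$, in which the viscosity
cancels. Comparing fitted $P_{suc}$ for a naked pore and for the same pore
clogged with particles, and assuming a compact annular particle layer with
an open cylindrical lumen, the layer thickness is

$$R_e = R \left(1 - \left(\frac{P_{suc}^{virus}}{P_{suc}}\right)^{-1/4}\right).$$

A 16-fold resistance ratio corresponds to $R_e = R/2$. We treat $f_{suc}$
purely as a fit amplitude: the model value of the frequency at
$P = P_{suc}$ is $f_{suc}/e$, and we follow the formula rather than the
looser verbal reading of $f_{suc}$ as "the frequency at $P_{suc}$".
Alternative clog geometries (plugs, percolating aggregates) are out of
scope; the annular layer is assumed literally.

From $R_e/R$ the effective in-pore concentration follows by dividing the
annular particle volume by the particle volume and the pore volume —
depending only on $R_e/R$ and the particle radius — and rescales the
apparent $K_d^{clog}$ (fitted against the upstream concentration axis) to
the concentration scale the clog actually experiences
(`effective_pore_concentration()`, `corrected_kd()`). The wall on-rate can
be read as barrier crossing, $\Delta F^* = \ln(\nu / k_{on}^{pore})\,k_BT$.
The transport data do not constrain the attempt rate $\nu$; the default is
$10^3\,\mathrm{s^{-1}}$, every result carries the $\nu$ it assumed, and
changing $\nu$ shifts all barriers by $\ln$-additive constants only.

Clog formation after a high-pressure flush relaxes as
$\exp(-t/t_{clog})$. The fitted $t_{clog}$ sits near the diffusive scale
$t_{diff} = L^2/D$, not the millisecond advective scale; the package
exposes both numbers (`diffusion_time()`, `advection_time()`) without
asserting their equality, since the order-of-magnitude argument does not
identify the mechanism.

## Parameters, units and defaults

| Parameter | Meaning | Units | Typical scale |
|---|---|---|---|
| $R$, $L$ | pore radius, length | m | 40–200 nm, 6–10 µm |
| $\eta$, $T$ | viscosity, temperature | Pa·s, K | $10^{-3}$, 295 |
| $k_{on}^{pore}$ | wall sticking rate | s$^{-1}$ | 0.3–0.8 |
| $k_{off}^{clog}$ | clog detachment rate | s$^{-1}$ | $0.8{-}1.7\times10^{-4}$ |
| $K_d^{clog}$ | clog dissociation constant | particles·m$^{-3}$ | $10^{-14}$–$10^{-13}$ M |
| $f_{suc}$, $P_{suc}$ | suction amplitude, threshold | s$^{-1}$, Pa | — , ~1 kPa (200 nm pore) |

Everything internal is strict SI (Pa, m, s, K, particles·m$^{-3}$). The
experimental literature mixes nm, µm, particles/mL and molar units; the
I/O layer converts at the boundary (`per_ml_to_per_m3()`,
`molar_to_per_m3()`), which removes a whole class of silent unit bugs. The
temperature default of 295 K is an assumption (room temperature) and is
configurable through `fluid_env()`. The Péclet number uses the pore length
as its length scale, $Pe = vL/D = t_{diff}/t_{adv}$, because the
advection–diffusion comparison relevant to clog formation is over the
channel length; this is a convention and is stated as such.

## What the synthetic generator emulates — and what it does not

Scenarios (`preset_scenario()`) reproduce the statistical structure of
zero-mode-waveguide translocation assays: a membrane with $\sim 10^4$
pores observed in parallel, event counts pooled over the field of view
during a fixed acquisition window, technical replicates (36 for exit
sweeps, 24 for entry/bead experiments, 18 for concentration sweeps,
matching typical practice), and SEM error bars. The default noise model is
Poisson counting over a 60 s window; with $\sim10^4$ pores and per-pore
plateau rates of order $10^{-4}\,\mathrm{s^{-1}}$ this yields tens of
counts per point, the regime in which such experiments operate. A faster
Gaussian-relative model (`noise = "gaussian_relative"`) is used for the
large seeded recovery studies. Zero-count points receive a floor SEM of one
count per total observation, so weighted fits remain defined.

Preset parameter values are assembled from the experimentally reported
ranges for HIV-like particles in 200 nm pores — critical pressure 50 Pa
(hence $k_{on}^{pore} = 0.625\,\mathrm{s^{-1}}$), $k_{off}^{clog} =
1.2\times10^{-4}\,\mathrm{s^{-1}}$, $K_d^{clog} = 1.5\times10^{-13}$ M —
and are flagged as synthetic in the preset metadata. The 83 nm HIV
hydrodynamic radius is itself back-derived from the 38 s diffusion time
over a 10 µm channel, not an independently printed value. Entry-side
scenarios replace the on-rate by the value giving $P_c = 10^{-3}$ Pa (no
adhesion at the entrance), leaving the entry branch untouched.

The generator does **not** simulate raw fluorescence movies, event
detection, photobleaching, pore-to-pore heterogeneity, or clog aging beyond
the single-exponential transient. Passing recovery tests therefore
demonstrates that the estimation machinery is correct and well-conditioned
under the model's own noise structure — not that the model is true of any
particular dataset.

## Estimation: numerical choices

All fitters minimise the SEM-weighted chi-square with Levenberg–Marquardt
on **log-transformed parameters** (positivity by construction, and the
parameters span decades), with a seeded multistart: the box midpoint plus
7 log-uniform draws over data-driven boxes (default 8 starts; deterministic
given the seed). Search boxes are tied to the data — e.g. the critical
pressure box spans $[0.02\,P_{min},\,20\,P_{max}]$ — never to the truth.
Where several starts reach objectives equal within a relative $10^{-6}$,
the tie is broken towards the smallest $K_d^{clog}$, and the tie-break is
recorded in the result. Convergence tolerances are `ftol = ptol = 1e-12`;
noiseless data are recovered to better than $10^{-6}$ relative, which the
test suite asserts for every fitter, alongside agreement with dense
grid-search oracles (for the two-parameter barrier law the amplitude is
profiled out in closed form, making the oracle exact up to the
$P_{suc}$ grid).

Particular choices worth knowing:

* **Low-pressure window.** `fit_low_pressure()` fits $f = 1/\tau_2$ to the
  points whose frequency is below 50% of the running plateau estimate (the
  mean of the three highest-pressure frequencies). The source experiments
  do not state their window; this rule is simple, data-driven and
  reproducible. For curves with no plateau (wall-only beads) use
  `window = "all"`.
* **Global versus per-curve fits.** Whether multi-concentration sweeps
  should share one parameter triple is not settled by the source
  experiments; `fit_pressure_sweep()` fits shared parameters (the default
  and the better-conditioned choice), while freezing any subset via
  `fixed` provides the per-branch analyses, including the
  $\tau_1$/$\tau_2$ separability check.
* **Identifiability guards.** A concentration sweep entirely below
  $K_d/10$ never reaches saturation, so $k_{off}$ and $K_d$ are only
  jointly constrained; the fitter rejects such designs explicitly rather
  than returning a ridge point. Parameters landing on a search-box
  boundary are flagged with a warning.
* **Error bars.** For SEM-weighted fits the covariance is $(J'J)^{-1}$ in
  log-space, delta-transformed; for the unweighted contrast fit of
  `fit_clog_dynamics()` the residual variance is estimated from RSS/dof.
* **$K_d$ is the soft direction.** With concentrations spanning only a
  factor 100 below $K_d$ (as in the default exit preset), $K_d$ carries
  large uncertainty while $P_c$ remains tightly determined; the seeded
  recovery studies in the test suite quantify this (median relative error
  under 30% at 5% noise once the grid spans $K_d$).

## Problem sizes

The shipped studies use sizes chosen to make sampling error small relative
to the tolerances they are compared against: recovery studies run 100
seeded replicates (20 pressures × 3 concentrations for sweeps; 30 time
points over 300 s for clog traces); oracle comparisons use 2000-point
profiled grids or $25^3$ grids with three zoom refinements; the Poisson
calibration check uses 1000 replicate draws.

## Known limitations

The model is phenomenological: it does not resolve the clog's particle
packing, time-dependent clog growth, multi-pore coupling, entrance/access
resistance, electro-osmotic flow, or polymer-physics corrections to the
DNA caliper (persistence length, partial insertion). The annular-layer
inversion is exact only under the compact-layer and Poiseuille assumptions.
Within those limits, every quantity the package reports is reproducible
from a seed, and every estimator is cross-checked against an independent
brute-force oracle in the test suite.
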