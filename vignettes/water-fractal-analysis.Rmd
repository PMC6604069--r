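---
title: "Fractal analysis of water dynamics: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal analysis of water dynamics: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquafrac)
```

## The science in brief

Bulk-like water shows a large dielectric relaxation near 20 GHz
(relaxation time about 8.2--8.3 ps at 25 °C) produced by cooperative
exchange of hydrogen bonds in the hydrogen-bonding network (HBN). In
aqueous mixtures and biological materials, decreasing water content slows
this process (larger $\tau$) and broadens its relaxation-time distribution
(smaller Cole--Cole $\beta$) — the plasticizer effect. Plotting $\beta$
against the normalized relaxation time $\tau/\tau_0$ (pure water:
$\tau_0$ = 8.3 ps, $\beta = 1$ at 25 °C) turns each material into a
trajectory in the $\tau$--$\beta$ diagram, and the shape of that
trajectory encodes the fractal organization of water structures:
mutually penetrating solute/HBN networks (solutions) keep $1 \le D \le 2$,
while dispersed particles that fragment the HBN (dispersions) push
$0 \le D \le 1$.

This package implements the four computational layers of that analysis:
spectrum modeling and fitting, the $\tau$--$\beta$ fractal relation,
box-counting on geometric models and images, and the electrostatics of the
open-ended coaxial probes used to measure such spectra.

## Relaxation models and spectrum fitting

The relaxation function is the Havriliak--Negami family

$$\frac{\varepsilon^*(\omega)-\varepsilon_\infty}{\Delta\varepsilon}
  = \frac{1}{\left[1+(j\omega\tau)^{\beta}\right]^{\alpha}},
  \qquad 0 < \alpha, \beta \le 1,$$

with $\beta$ the *symmetric* and $\alpha$ the *asymmetric* broadening
exponent. Note that this exponent placement is the reverse of the most
common literature convention for the HN function; the field names
`beta_sym` / `alpha_asym` (and the JSON labels `symmetric_beta` /
`asymmetric_alpha`) pin the convention so the two cannot be confused.
Debye is $\alpha=\beta=1$, Cole--Cole is $\alpha=1$, Cole--Davidson is
$\beta=1$. We use the physics sign convention
$\varepsilon^* = \varepsilon' - j\varepsilon''$ with the loss stored
positive, the principal branch of the complex power, and vacuum
permittivity $8.8541878128\times 10^{-12}$ F/m. An optional conductivity
term $\sigma_{dc}/(j\omega\varepsilon_v)$ (default 0) stands in for
unresolved low-frequency processes.

Fitting minimizes $\sum_i w_i\,|\varepsilon^*_{model}(f_i) -
\varepsilon^*_{data}(f_i)|^2$ with bounded Levenberg--Marquardt
(minpack.lm). Choices that matter:

* **Weights** default to *relative*, $w_i = 1/|\varepsilon^*(f_i)|^2$,
  because TDR spectra span decades in loss; uniform weighting is available.
* **Scales and bounds.** $\tau$ and $\Delta\varepsilon$ are optimized as
  $\log_{10}$ quantities ($\tau \in [10^{-14}, 10^{-6}]$ s), exponents on
  their natural scale in $(0, 1]$ with the upper bound attainable — a
  Debye spectrum fitted in Cole--Cole mode must be able to return exactly
  $\beta = 1$ — and $\varepsilon_\infty \ge 1$.
* **Initialization.** $\tau$ from interior loss maxima via
  $1/(2\pi f_{peak})$, $\varepsilon_\infty$ from the highest-frequency
  $\varepsilon'$, the dielectric decrement split between processes in
  proportion to peak heights; with no interior maximum the geometric band
  center is used and a warning is recorded.
* **Identifiability conventions.** Fitted processes are reported sorted by
  ascending $\tau$ (ties broken by larger $\Delta\varepsilon$), and when no
  process index is given, `extract_tau_beta()` picks the process whose
  $\tau$ is log-closest to 8.3 ps — the GHz water process.
* **Uncertainties** are 1-$\sigma$ values from the Gauss--Newton curvature
  at the optimum, delta-mapped to the natural scale; they collapse to zero
  for noise-free exact fits.

On noise-free synthetic spectra (100 points, 100 MHz--65 GHz) all four
special cases are recovered to $10^{-6}$ relative error; with 1% relative
noise, $\tau$ and $\beta$ of a Cole--Cole process are recovered within a
few percent (see the test suite, which runs exactly these studies).

## The tau--beta fractal relation

The Cole--Cole parameter and the mean relaxation time are linked through

$$\beta = \frac{D}{2}\,
  \frac{\ln(\tau\,\omega_S)}{\ln(\tau/\tau_{0s})},
  \qquad \omega_S = 2\,d_E\,G^{2/D} D_s / R_0^2,$$

where $D$ is the fractal dimension of the set of relaxing units
interacting with the statistical reservoir, $\omega_S$ the characteristic
frequency of self-diffusion ($d_E$ Euclidean dimension, $D_s$
self-diffusion coefficient, $R_0$ spatial scaling cutoff, $G \approx 1$),
and $\tau_{0s}$ the cutoff time of the time-domain scaling. Two properties
anchor the implementation: $\beta(1/\omega_S) = 0$ exactly, and
$\beta \to D/2$ as $\tau \to \infty$. We deliberately name the scaling
cutoff `tau0_s` because the same symbol $\tau_0$ is conventionally used
for the *pure-water normalization constant* of the diagram (8.3 ps;
the 8.2 ps loss-peak variant is also exposed) — two distinct constants.

**Fitting.** `fit_trajectory()` fits $(D, \omega_S, \tau_{0s})$ to
$(\ln\tau, \beta)$ points by bounded Levenberg--Marquardt with
deterministic multi-starts. The three parameters are weakly identifiable
from the short arcs real data provide — measured trajectories are only a
part of the whole hyperbolic curve — so the nuisance parameters are kept
in data-driven boxes: $\tau_{0s} \in [0.01, 1]\cdot\tau_{min}$ and
$1/\omega_S \in [\tau_{min}/10, \tau_{min}]$, with $D \in [0, 3]$.

**Uncertainty.** `D_uncertainty` is a profile-likelihood interval: the
profile RSS is traced on a $D$ grid (step 0.025), refitting
$(\omega_S, \tau_{0s})$ from several starts at each step, until it crosses
the 1-$\sigma$ F-threshold; the half-width of that interval is reported.
We use this instead of local curvature because near-vertical trajectories
have locally curved but globally flat (even multimodal) profiles, and a
curvature-based standard error badly under-covers there. This is exactly
the regime of dispersion systems: their arcs sit far from the horizontal
asymptote whose level *is* $D/2$, so the extrapolation is ill-determined
and the reported uncertainty is large — reproducing the qualitative error
asymmetry between solution and dispersion systems.

**Classification** calls a structure *solution* only when $D - u \ge 1$
and *dispersion* only when $D + u \le 1$; everything else (including the
boundary tie $D = 1$, $u = 0$) is *indeterminate*, since the two regimes
genuinely overlap near $D = 1$. Absolute $D$ values are observation-scale
dependent, so `fractal_fit` objects always carry the $\tau$ range of the
fit.

**Gel normalization.** For mixed-solvent gels, the bulk solvent itself
moves (sometimes reentrantly) in the diagram as composition changes;
`normalize_by_bulk()` divides the gel $\tau$ by the bulk $\tau$ at the
same composition (linear interpolation, no extrapolation — out-of-range
points get per-point error records), isolating the restriction exerted by
the polymer network and straightening reentrant raw trajectories.

### What the trajectory generator emulates

`synth_trajectory()` produces log-spaced $\tau$ points on the relation
with optional Gaussian $\beta$-noise. Its defaults are chosen once as a
realistic concentration series: 12 points, $\tau$ from 12 ps to 1.2 ns
(i.e. $\tau/\tau_0$ up to $\approx 145$), $\beta$-noise 0 unless stated;
recovery studies in the tests use $\sigma_\beta = 0.02$, typical of
well-measured GHz fits. The `"rising"` branch
($\tau_{0s} < 1/\omega_S$, $\beta$ growing toward $D/2$) never clips and
is used for blanket recovery studies across $D \in [0.2, 1.9]$; the
`"descending"` branch ($\tau_{0s} > 1/\omega_S$) mimics the
plasticizer-effect arcs of real systems, starting near the pure-water
point and falling toward $D/2$, and restricting its $\tau$ window just
above $\tau_{0s}$ yields the near-vertical dispersion-type arcs. The
generator makes exact-model data: it does not emulate correlated
fit-parameter errors across concentrations, electrode-polarization
artifacts, or deviations from the relation itself, so passing recovery
tests demonstrate estimator correctness, not field performance on real
spectra.

## Box counting and regime segmentation

`box_count()` tiles the array from its origin into $s$-cell boxes
(partial far-edge boxes included) and counts boxes containing at least
one occupied cell; the dimension is the absolute log--log slope. Design
choices: the tiling is anchored at the array origin with no offset
averaging by default (a deterministic convention; offset-averaged counts
are available as an option for robustness comparisons), the default size
ladder is dyadic $\{1, 2, 4, \ldots\}$ capped at half the largest grid
dimension, and non-dyadic sizes use ceiling tiling.

`segment_regimes()` detects a characteristic size as a breakpoint:
every interior size is tried, two independent log--log regressions are fit
to the sizes at-or-below and at-or-above it (the breakpoint belongs to
both segments, so each keeps $\ge 2$ sizes), and the breakpoint minimizing
the total residual wins. When the improvement over a single regression is
below 5% (or the single fit is already machine-perfect), a single-regime
flag is set. For the validation images this gives exact results: a
512² full box is one regime of slope 2; the half-filled box shifts the
intercept, not the slope; a 2-pixel line splits at breakpoint 2 px into
slope 2.0 below (box sizes inside the line width see a filled plane) and
1.0 above (the line is one-dimensional at larger scales). The line is
rasterized with its edge on the image midline so that dyadic tilings see
the ideal geometry; this is the rasterization a breakpoint *at the line
width* presupposes.

### Known limitation: gradual crossovers

A two-segment model assumes the counting curve has two straight regimes
with a sharp knee. Physical objects cross over gradually: for the
100-sphere chain (spacing 1.5, radius $R = 20$, voxel 0.5 — a rod 377
voxels long and 80 voxels across), the volume regime (slope 3) holds for
box sizes well below $R$, the line regime (slope exactly 1.0) only for
the two dyadic sizes above the rod diameter, and the two octaves in
between are a smooth shoulder. With the default size ladder the
minimal-residual breakpoint lands at $s = 8$ and the small-box dimension
is 2.93; the large-box segment, however, spans the whole shoulder and
reports $\approx 2.5$ rather than the asymptotic 1.0 — the rod's 4.7:1
aspect ratio simply provides less than one decade of line-like scaling,
and no two-segment fit of these counts can report both asymptotes at
once. `fit_dimension()` with an explicit `size_range` is the honest tool
when the scales of interest are known (e.g. sizes $\ge$ the rod diameter
give exactly 1.0); the blind segmentation is still reported as specified.
The same caution applies to micrograph analysis, where the breakpoint is
the characteristic size of the white regions but slopes next to it are
shoulder-contaminated.

## Electrode fields

`solve_potential()` solves the quasi-static axisymmetric problem
$\nabla\!\cdot(\varepsilon\nabla V) = 0$ in $(r, z)$ for an open-ended
coaxial probe against a sample half-space: conductors Dirichlet (inner
0.2 V, outer and ground flange 0 V), analytic coax profile at the cable
mouth, symmetry at $r = 0$, far boundaries 0 V. The geometry follows from
the line impedance: $b/a = \exp(Z\sqrt{\varepsilon_{ins}}/59.96)$
(PTFE $\varepsilon = 2.1$, $Z = 50\ \Omega$; wall thickness is not a
published quantity, so it is configurable with a 0.3 mm default). The
discretization is a finite-volume 5-point stencil with radial face
weights $r \pm h/2$ and arithmetic face permittivities, assembled sparse
and solved *directly* (Matrix Cholesky/LU) rather than by relaxation
sweeps: on these grids ($10^4$--$10^6$ unknowns) the direct solve is
faster, deterministic, and cannot fail to converge; the algebraic
residual is still reported (typically $10^{-14}$).

`penetration_depth()` reads the axial profile $V(z)$, $z \ge 0$ and
reports (i) the decay length of a single-exponential fit over the near
region (down to 10% of the surface potential) and (ii) the depth where
the potential first falls to 54% of the inner-conductor surface
potential — an empirical criterion adopted as a defined constant, not
re-derived here. The 54% crossing is interpolated *log-linearly* between
grid nodes (exact for an exponential decay and far less grid-sensitive
than linear interpolation). For an ideal exponential profile the two
definitions are locked: $\delta_{54}/\delta_{exp} = -\ln 0.54 \approx
0.616$. The solved fields reproduce the analytic coax logarithmic profile
deep in the cable within 1%, obey the discrete maximum principle, scale
linearly with geometry, and order the standard probes
(2.2 < 3.6 < 6.3 mm) in both depth definitions. Default resolution is
$a/10$; the convergence study in the tests runs $a/16$ vs $a/32$ on a
fixed reduced domain, where both depths move by under 5%. Being
electrostatic, the model says nothing about radiation, frequency-dependent
probe admittance, or double-layer effects; it characterizes the fringing
potential pattern and sensing depth only.

## Problem sizes and determinism

The validation suite uses 512² images, the 457×160×160-voxel sphere chain,
100-point spectra, 100-trajectory recovery batches, and electrode grids of
roughly 200×300 to 600×800 nodes — sizes chosen so every study a reader
may want to re-run finishes in seconds to a couple of minutes on one CPU.
All stochastic steps (noise injection, recovery batches) flow through
explicit integer seeds, and every generator of geometric models is fully
deterministic.
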