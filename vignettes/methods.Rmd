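---
title: "Methods: Green's-function transport of CTC-generated concentration fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Green's-function transport of CTC-generated concentration fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctcfields)
```

## The model and its assumptions

`ctcfields` treats each circulating tumor cell as a point source of a passive
scalar (thrombin / tissue-factor activity) in an incompressible background
flow above a single plane vessel wall. The governing equation for each
per-cell field is the linear advection-diffusion equation with a Dirac source
at the cell's release point and a zero-flux (no-penetration) condition at the
wall. Everything downstream of that statement is exact:

* the wall is handled by the **method of images** — a mirror source across
  the wall makes the wall-normal derivative vanish identically, with no
  other boundary conditions needed;
* multi-cell fields are **exact superpositions** of single-cell kernels, so
  field values are linear and homogeneous in the source strengths, and the
  expected spatial mean is exactly proportional to the cell count;
* all diagnostics (slice profiles, peak series) sample the analytic kernels
  directly — there is no interpolation error to manage.

The deliberate physical simplifications: the flow is either quiescent (2D
half-plane) or a constant unidirectional speed `u` along x (3D half-space).
The full viscous flow problem is never solved — with `u` constant,
incompressibility holds trivially and pressure and viscosity never enter.
Cells are points (no finite radius, no margination or lift), they do not
interact, and the scalar is passive (no coagulation-cascade kinetics). All
quantities are dimensionless throughout.

## The two 3D normalizations

The package's reference 3D form (`normalization = "as_printed"`) is a hybrid:
it carries a travelling-puff Gaussian `exp(-(s - u t)^2 / 4r)` in the
downstream coordinate `s = x - x0`, but scales all Gaussians with the
plume-like variable `r = alpha * s / u` (proportional to downstream distance,
not time) and normalises by `8 pi r^{3/2}`. Three consequences worth knowing:

1. `r` is undefined upstream, so the field is defined as 0 for `s <= 0`
   (the standard plume/puff convention).
2. The prefactor differs from the instantaneous-puff normalisation
   `(4 pi r)^{3/2}` by a factor `sqrt(pi)`.
3. It is *not* an exact solution of the advection-diffusion equation, which
   is visible in validation: the finite-difference oracle quantifies its
   discrepancy rather than gating it.

`normalization = "textbook_puff"` is the exact Green's function of
`dc/dt + u dc/dx = alpha Laplacian(c)` for an instantaneous release —
`r = alpha * t`, prefactor `(4 pi r)^{3/2}`, centre advected to `x0 + u t`,
defined for all x. This is the mode the finite-difference oracle *is* gated
against, and the convergence study confirms first-order convergence (upwind
advection) onto it. Both modes satisfy the no-flux wall identity exactly,
because the image construction is independent of the radial scaling. The
as-printed mode stays the default because it is the reference formulation
this package implements; the switch exists so users can see exactly how much
the two differ (the acceptance script reports both numbers).

A related notational wrinkle: the published 2D kernel is written with a
coefficient `v` where every simulation statement uses the per-cell diffusion
coefficient `alpha_i`. The package resolves the collision in favour of the
per-source `alpha` (1.5 in all packaged runs).

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `alpha` | per-cell diffusion coefficient (dimensionless) | 1.5 | the value used by all published runs |
| `strength` | lumped emission (total TF expressed by a cell) | 1 | only relative levels matter in a linear model |
| `u` | constant flow speed (3D) | 1 in field fixtures, 0.1 in the tracker fixture | unit speed for fields; trackers must out-pace the drift (step 2 per unit time vs 0.1) |
| `eps` | tracker probe *and* step distance | 2 (3D fixture) | small against the 600-wide domain, large enough to traverse it in ~10^2 steps |
| `tol` | tracker no-improvement tolerance | 1e-15 | treats differences at round-off as "flat" so far-field trackers do not jitter |
| `dt` (tracker cadence) | time between tracker polls | 1 | one hop per unit time; the tracking timescale is governed by eps/dt |
| grid resolution | figure rasters | 256 x 256 | figure quality only — no assertion depends on it, peak diagnostics re-verify maxima by local refinement |

Probe distance and step distance are the same `eps` (the simplest reading of
the six-neighbour polling scheme); ties among equally good neighbours are
broken by the fixed polling order `+x, -x, +y, -y, +z, -z` (first maximum
wins), and probes or moves that would cross the wall are clamped to the wall
plane, where the field is still defined. Trackers are not advected by
default; the flag `advect = TRUE` exists because the published description
leaves it open.

## What the synthetic generator emulates — and what it does not

`place_sources()` draws cells i.i.d. uniform over an axis-aligned box with a
pinned RNG (`Mersenne-Twister`), so a `(recipe, seed)` pair is a complete,
portable description of a cell population. The packaged fixtures are the
package's reconstruction of the published runs:

* **3D four-cell run** — the four printed positions (300, 300, 45),
  (180, 400, 30), (300, 100, 30), (275, 200, 60), `alpha = 1.5`, shipped as
  `reference_sources_3d()`. The published account never states `u`; the
  fixture uses `u = 1`.
* **3D 100-cell run** — 100 cells uniform over
  `[0, 600] x [0, 600] x [0, 90]`, bracketing the explicit positions and the
  z-slices at 0/45/90.
* **2D 100-cell run** — the published description never states the placement
  box, and its stated numbers cannot all hold at once: 100 cells spread over
  a 600-wide square with `alpha = 1.5` would take hundreds of time units to
  merge, yet the reported fast-mixing crossover is T ≈ 3. Merging by T ≈ 3
  requires nearest-neighbour spacing ≈ sqrt(16 * alpha * 3) ≈ 8.5, so the
  fixture keeps the figure's in-plane extent `x in [0, 600]` and sets the
  wall-normal extent to `y in [0, 12]` (spacing sqrt(600*12/100) ≈ 8.5).
  With that box the wall-peak series reproduces both published observations:
  a breakpoint within (1, 10) and wall dominance at T = 500.
* **3D tracker run** — tracker output times 8…220 are published; heights are
  not. A tracker sitting on a puff released at height H starts its descent
  when `alpha * t` grows past ~H²/2, so descent visible by T ≈ 220 with
  `alpha = 1.5` requires H ≲ 20; the fixture places cells and trackers in
  `z in [0, 20]`, 200 trackers per polarity.

What passing tests on these populations do **not** show about real blood:
uniform placement ignores margination and the cell-free layer; strengths are
identical across cells whereas TF expression is heterogeneous; the scalar
does not react, so absolute levels cannot be mapped to clotting times; and a
single flat wall says nothing about curvature, branching or pulsatility.

## Numerical choices

* **t = 0 is rejected**, everywhere: the kernels start from a Dirac release
  and are singular there. Config validation names the `t > 0` contract.
* **Degenerate inputs**: an empty source set yields a zero field (documented,
  not an error); a zero-row tracker table is refused; slice offsets not on a
  stored grid resolve to the nearest line with the actual offset recorded.
* **Peak series** are evaluated on dense analytic sample lines (1201 points
  per slice by default, 161² for planar slices) followed by two local
  refinement passes (window of ±1 cell, 41 resample points) around the
  argmax, so orderings between slices cannot be flipped by sampling
  coarseness. The sampling density travels with the result as an attribute.
* **Two-regime fit**: a continuous two-piece linear model in log-log
  coordinates, breakpoint searched over the sampled time grid only — the
  published split at T = 3 is a visual annotation, so sub-sample precision
  would be spurious. Candidates keep at least 4 samples per side. For a pure
  power law the two slopes agree and the breakpoint is not meaningful; the
  fitted slopes, not `t_split`, are the trustworthy output there.
* **Quadrature**: half-plane mass uses nested adaptive 1D quadrature
  (rel.tol 1e-10) over a ±14-sigma truncated support; truncation error is
  below the tolerance by construction.
* **Tracker tolerance** 1e-15 (absolute) defines "no improving neighbour";
  with it, trackers freeze in numerically flat far fields instead of walking
  on noise.

## The finite-difference oracle

The solver exists to *check* the kernels, never to compete with them. Design:

* **cell-centred grids** with the wall-adjacent cell at h/2 and a mirror
  ghost below the wall, which makes the discrete wall-normal flux exactly
  zero at every step;
* **explicit FTCS diffusion** plus **first-order upwind advection** (3D),
  with stability guarded before stepping (`alpha dt sum(1/h²) <= 1/2`,
  Courant `u dt / h <= 1`);
* **initialisation from the analytic kernel at t_init = 1** rather than a
  discrete delta, so the comparison is a pure propagator test with no
  mesh-dependent delta regularisation;
* **absorbing far boundaries with exact leakage bookkeeping**: the analytic
  solution lives on an unbounded half-space, so truncation loss is measured
  (interior mass + recorded leakage equals initial mass to round-off), never
  hidden.

Study conditions (chosen once, from the pre-implementation error estimate
that upwind numerical diffusion `u h / 2` must stay well below `alpha`):
2D — the packaged `alpha = 1.5`, source at (0, 2), domain
`[-12, 12] x [0, 12]`, t: 1 → 2, `h in {0.4, 0.2, 0.1}` (second-order
convergence); 3D — `alpha = 0.3`, `u = 0.25`, H = 1, domain
`[-4, 5] x [-4.5, 4.5] x [0, 4.5]`, same times and spacings (first-order
convergence, ~0.9% relative L2 at h = 0.1). These problem sizes keep the full
oracle study under a minute of desk time while leaving an order of magnitude
of headroom under the 2% acceptance gate.

## Known limitations

* The as-printed 3D kernel's plume/puff hybrid is reproduced faithfully,
  including its ~sqrt(pi) normalisation offset and its upstream cutoff; users
  needing a conservative travelling puff should select `textbook_puff`.
* Whether the lumped strength is an emission *rate* or a *total released
  amount* is not disambiguated by the reference formulation; the package
  treats it as a single multiplicative constant, which is all the linear
  model requires.
* Tracker trajectories are lattice polylines (hops of exactly eps); they
  approximate gradient ascent only as eps shrinks, and the tracking
  timescale scales with eps.
* The engine's determinism contract is bit-level only for fixed package and
  dependency versions; floating-point reductions are not reordered anywhere,
  but no cross-platform bit guarantee is claimed beyond the pinned RNG.
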