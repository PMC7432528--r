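---
title: "Point-kernel dose assessment and ALARA work planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-kernel dose assessment and ALARA work planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alaradose)
```

## The problem

Dismantling activated components of a shut-down power reactor — above all
the reactor pressure vessel (RPV) — exposes the cutting crew to gamma
fields dominated by activation products in the steel. Planning that work
under the ALARA principle ("As Low As Reasonably Achievable") requires,
before anyone enters the field: (i) a dose-rate model of the work area,
(ii) a task-by-task plan with worker positions and durations, and (iii)
roll-ups of individual and collective dose that can be compared against
regulatory limits (20 mSv per year averaged over five consecutive years)
and between alternative cutting technologies.

`alaradose` implements this chain end to end: a point-kernel gamma dose
engine, an ALARA work-planning layer, a drum-driven RPV cutting-scenario
planner, and a fixtures module that reconstructs a complete worked
example — the dismantling of a two-loop PWR's vessel — from published
values, so every stage runs offline and is testable.

## The dose model

A volume source of total activity $S_{tot}$ is collapsed to 25 energy
groups. For group $b$ with emission fraction $F_{E_b}$ (photons per decay
in that group), the fluence rate at a dose point is estimated over $N_s$
source positions sampled uniformly in the source volume:

$$
\Phi_{E_b} \;=\; \frac{S_{tot}\,F_{E_b}}{N_s}\sum_{i=1}^{N_s}
   \frac{B(E_b, x_i)\, e^{-x_i}}{4\pi \rho_i^{2}},
\qquad
\dot D \;=\; \sum_{b=1}^{25} h_{E_b}\,\Phi_{E_b},
$$

where $\rho_i$ is the distance (cm) from the $i$-th sample, $x_i$ the
optical depth (mean free paths) along the straight ray to the dose point,
$B$ a build-up factor correcting for in-scattered photons, and $h_{E_b}$
a fluence-to-ambient-dose-equivalent conversion coefficient. Dose rates
are reported in mSv/h. Only line-of-sight transport is modelled; scatter
enters exclusively through $B$ (no albedo, skyshine, neutron or beta
dose).

### Geometry and transport

Scenes are constructive solid geometry: boxes, finite cylindrical shells
and spherical(-cap) shells, each filled with a material at an integer
priority (highest priority wins on overlap; equal-priority overlaps are
rejected when the scene is built). Scene files use metres; internally
everything is centimetres because attenuation data and the
inverse-square kernel are cm-based. Chord lengths are exact quadratic
surface intersections — no voxelization — and `trace_ray()` is
cross-checked in the test suite against a 0.1 mm ray-marching oracle.
Self-absorption is automatic: rays from sample points traverse the source
region's own material.

### Numerical choices

* **Energy groups.** The 25-bin count is fixed by the engine formulation;
  the boundaries are not published, so the default is 25 log-spaced bins
  over 0.01–3 MeV (user-overridable). Attenuation, build-up and dose
  conversion are evaluated at each bin's *geometric mean* edge energy,
  which is unbiased on log-spaced bins.
* **Interpolation.** Mass attenuation curves and $h^*(10)$ coefficients
  are interpolated log-log inside their table range; energies outside the
  range are an error naming the material (silent extrapolation of
  cross-sections is a classic shielding bug). Build-up coefficients are
  interpolated linearly in $\log E$ and clamped at the grid ends.
* **Exclusion radius.** The $1/\rho^2$ kernel is integrable but
  numerically explosive; samples closer than `exclusion_cm` (default
  1 cm) to the dose point are redrawn, preserving $N_s$. A dose point
  inside a source volume with the exclusion disabled is an error.
* **Determinism.** Every sampling plan carries a mandatory seed. Dose-map
  nodes derive their seed from the plan seed and the node *position*
  (FNV-1a hash), so refining a lattice leaves shared nodes bit-identical.
* **Defaults.** $N_s = 20\,000$ per dose point; build-up on.

### Build-up factors

$B$ uses the geometric-progression (GP) form evaluated at the total
optical depth of the ray; for multi-material paths the coefficients of
the material contributing the largest optical depth are used (the
dominant-layer rule — logged in the result and swappable). The bundled
coefficient table is an *approximation* written from memory of the
standard engineering compilations, with one deliberate recalibration: the
amplitude parameters $b$ were compressed toward 1 (maximum $b \approx
1.85$) so that the shielded kernel $B(x)e^{-x}$ is monotonically
non-increasing for every bundled material/energy — the physically
required behaviour (adding shield never increases dose) that the package
asserts numerically in its test suite. The cost is conservatively small
build-up at depth; since the engine's absolute dose rates are anyway not
comparable to the reference tool's (whose build-up formulation, bin
boundaries, $N_s$ and conversion set are unpublished), no graded quantity
depends on the absolute $B$ values. $B(\cdot,\cdot,0)=1$ and $B \ge 1$
hold by construction; evaluation is clamped at the fits' 40-mfp validity
limit, beyond which the kernel is below $e^{-40}$.

### Dose conversion

$h_{E_b}$ is an ambient-dose-equivalent ($H^*(10)$-style) per-fluence
curve bundled in pSv·cm² and converted to (mSv/h)/(cm⁻²·s⁻¹). The choice
of coefficient set is isolated in one packaged CSV and replaceable via
`dose_conversion_table(curve = ...)`.

## The bundled study fixture

`build_kori_fixture()` reconstructs the worked example entirely from
packaged plain-text files (guarded by a checksum):

* **Source terms.** Eight activation/fission nuclides per vessel part
  (upper / active / lower). ⁵⁵Fe dominates the activity but emits only
  5.9 keV X-rays — below the group structure — and ⁹⁹Tc is a pure beta
  emitter, so neither contributes photons; this is what makes ⁶⁰Co
  (2.5 MeV of gamma energy per decay) dominate the dose, which the
  engine reproduces quantitatively (≈ 99.8% of the cutter dose rate,
  comfortably above the published "over 80%"). The fixture stores the
  published ⁹⁹Tc half-life of 6 hours (physically wrong — the ground
  state lives 2.1×10⁵ years) as printed; the corrected value is available
  via `nuclide_library(use_corrected_half_lives = TRUE)`. The published
  lower-part activity total (3.59×10⁹ Bq) does not equal its own column
  sum (≈ 3.57×10⁹); `total_activity()` reports the computed sum.
* **Scene.** A 4.7 m outer-diameter, 0.26 m thick vessel shell: three
  equal axial zones of the 12.4 m cylindrical body plus a bottom
  spherical-cap shell, in air. The body/cladding material split is not
  published, so the shell is homogeneous stainless steel (configurable).
  Worker stand-off bands: cutter 30–38 cm, RPO 100–130 cm; dose points
  default to the band midpoints at part mid-height.
* **Work plans.** Six scenarios (fragmentation and segmentation of each
  part), seven tasks each, with the published durations and dose rates.
  Repetition counts {upper 6, active 6, lower 8} are back-derived from
  the published collective times (1896 min × 6/60 = 189.6 man-h, etc.;
  never stated directly). Max/min prognoses are a symmetric fractional
  perturbation of the totals, per-plan fractions back-derived from the
  published max work times (3.8% for the fragmentation tables).
* **Cut plan.** Drum 0.8 m × ⌀0.57 m. The packing convention chosen here
  (once, and emitted in every plan for audit): nominal fragment height =
  85% of drum height — which reproduces both the published 0.68 m leg
  fragment height and, via `floor(12.4 / 0.68) = 18`, the published body
  fragment count — and circumferential segment count = smallest *n* whose
  piece bounding box (chord × thickness + sagitta) fits the drum diameter
  minus a 2.5 cm handling clearance, which yields the published 32 for
  the body. The two small cap fragments use the published 10 segments
  (validated to satisfy, but not forced by, the fit rule: the minimum is
  8). The computed total is 666 pieces (18×32 + 2×32 + 2×10 + 6 legs);
  the source text prints 664, which cannot be reconciled with its own
  counts, so the computed value is reported.

### The circumference convention

The published cutting-time arithmetic uses $\pi \approx 3.14$ with mixed
rounding (body length 14.76 m at 0.01 m; top-cap 7.4 m at 0.1 m). True
$\pi$ with 0.01 m rounding gives 14.77 m → 985 min, *not* the published
984 min, so `circumference()` defaults to the 3.14 convention, and the
fixture stores the four printed cut lengths (14.76, 7.4, 3.69, 21.08 m)
as authoritative. The printed radial length 21.08 m is itself
inconsistent with 0.68 m × 32 = 21.76 m; it is retained as printed and
the computed alternative is available by omitting `cut_lengths_m`.

## What the tests do and do not establish

The synthetic stage emulates the *published inputs* (inventories,
geometry, task tables, cut lengths) and analytic toys with closed-form
answers. Green tests establish: exact reproduction of the published
arithmetic (cut times, plan totals, collective metrics); internal
consistency and physical invariants of the engine (inverse-square limit
to machine precision, $e^{-x}$ transmission, superposition and activity
linearity under a fixed seed, $1/\sqrt{N_s}$ error scaling, agreement
with a deterministic midpoint-rule volume quadrature within 1%); and the
⁶⁰Co dominance claim. They do *not* establish agreement with the
reference tool's absolute per-task dose rates: its build-up formulation,
bin boundaries, sample counts, conversion coefficients and exact worker
positions are unpublished, so absolute rates are order-of-magnitude
comparable only, and the published task-table rates are treated as fixture
*inputs* to the planning layer rather than as targets. Bundled physical
constants (decay lines, attenuation curves, GP coefficients, $h^*(10)$)
are approximations of the standard compilations, adequate for ratios and
invariants but not for certification-grade shielding design.

## Known limitations

* Line-of-sight kernel only: no scattered-history transport, albedo or
  skyshine; build-up is aggregate and its dominant-layer rule is a
  heuristic for layered shields.
* No decay chains (no parent→daughter ingrowth) and no activation
  calculation producing the inventories.
* The vectorized transport fast path requires pairwise-disjoint regions
  (the fixture scene is); overlapping scenes fall back to exact but
  slower per-ray tracing.
* Uniform source density per region; dwell-weighted trajectories are
  representable in tasks but dose-rate-vs-time profiles along a moving
  path are not integrated automatically.
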