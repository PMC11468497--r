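---
title: "Models and methods behind micromix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind micromix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`micromix` covers the computational side of a printed-micromixer workflow:
parametric channel design, variable-width extrusion toolpaths, a steady 2D
laminar flow and species-transport model, and two mixing-index estimators
(one from concentration fields, one from RGB micrographs). This vignette
records the models, the defaults and the design choices that were genuinely
open, so that a user can judge what the package's numbers do and do not
mean.

## Geometry model

Channels are plan-view (x, y) centerlines in mm with a per-vertex width
w(s) in µm; the junction of the Y-channel is the origin and arc length s is
measured from it. The mixer body is the sinusoid

y = A sin(2 π x / λ),

with defaults A = 1.5 mm and λ = 3.3 mm, nominal width w0 = 400 µm and a
printed layer height of 300 µm. The sinusoid is sampled to a chord
tolerance (default 5 µm), so discrete arc lengths converge to the true
curve length (checked in the tests against adaptive quadrature of
√(1 + y′²)).

One published formula writes the sinusoid argument as λx while also calling
λ a wavelength of 3.3 mm; taken literally the two readings disagree
dimensionally. `micromix` resolves this in favor of the stated wavelength,
i.e. the argument is 2πx/λ, which reproduces the drawn device layouts.

The variable-width design (V-zigzag) widens the channel by a factor
f = 1.5 in pockets placed at the sinusoid extrema. Published sources give
the factor but not the pocket geometry; the package defaults to one
plateau per apex of length λ/4 with linear ramps of λ/12, all
configurable. Plateau samples hit f·w0 exactly (width is piecewise linear
with vertices inserted at every ramp break), and applying a width profile
never moves centerline vertices.

Hex and diamond mixers are unit-cell loops: each repeat traces the full
cell outline and returns along the bottom edges to the next cell's start
vertex, so the whole mixer is one continuous stroke (the printer never
lifts) and total path length is exactly the repeat count times the unit
length. Cell sizes are not published; defaults are side 0.8 mm (hex) and
diagonal 1.6 mm (diamond). Whether the real devices fill the interior or
trace walls only is ambiguous in the imagery; the loop-plus-return choice
deposits a seamless wall with a doubled bottom pass and is documented
rather than claimed to match the hardware.

Channel outlines are produced by offsetting the centerline ±w(s)/2 along
its normals after densification (which rounds joins). At the default
amplitude the apex curvature radius (≈ 0.18 mm) is smaller than the half
width, so the inner offset self-intersects; the offsetting routine excises
these loops (or errors, if asked to). Polygon area converges to ∫w ds for
gentle curvature (tested < 1 % at A = 0.6 mm) — at the default amplitude
the polygon is still valid but its area is genuinely smaller than ∫w ds
because the apex pockets overlap themselves.

## Extrusion model (variable-width toolpaths)

A deposited bead is modeled as a rectangle w × h in cross-section: the
filament volume needed for a segment of length L is L·w·h, so the E word
is

E = L w h / (π (d_f/2)²),

with d_f = 1.75 mm. A rounded-rectangle correction (subtracting
h²(1 − π/4)) is available behind `cross_section = "rounded"`; the
rectangle is the default because it is the simplest volume-consistent
choice and no published cross-section model exists. Volume conservation of
generated programs against ∫w·h ds holds to machine precision because
segment E uses the mean of the endpoint widths of a piecewise-linear width
profile — the same trapezoid integral.

Width changes can be realized two ways, and sources only say speed and
extrusion rate were varied "simultaneously": `constant_volumetric` keeps
the melt flow through the nozzle constant and slows the carriage
(F = base·w0/w, i.e. 200 → 133 mm/min at 1.5×), while `constant_feed`
keeps F and scales E per mm. Both are provided; the default is
`constant_volumetric` because a constant melt flow is gentler on thin
nozzles. Machine defaults reproduce the published print settings (240 °C
nozzle, 100 °C bed, 200 mm/min, 400 µm width, 300 µm layer). Segments are
capped at 0.2 mm so ramps are resolved. The dialect is Marlin-style
(absolute XY, relative E by default, `G92 E0` at start); programs
round-trip through the parser field-for-field.

## Flow model

The simulation is plan-view 2D, like the reference CFD for these devices:
the out-of-plane height H = 300 µm enters only through the mean speed
ū = Q/(W·H). No Hele-Shaw drag term is added — the published peak speed
(~10.5 mm/s at 50 µL/min) matches the pure-2D profile peak 1.5·ū, so the
2D reading is the one consistent with the reported numbers. Fluids are
water-like (ρ = 998 kg/m³, µ = 1 mPa·s), gravity off, and the regime is
laminar throughout (Re = ρūD_h/µ ≈ 0.047–47 over 1–1000 µL/min, with
D_h = 2WH/(W+H)).

Steady incompressible flow is solved on a uniform staggered grid masked by
the channel outline (a cell is in-channel when its center lies within
w(s)/2 of the centerline). The solver marches artificial-compressibility
pseudo-time: explicit first-order upwind momentum advection, central
viscosity with reflected no-slip ghosts, and a pressure update
∂p/∂τ = −ρc²∇·v with pseudo-sound speed c = max(6·u_in, 4ν/h) — the
second term keeps pressure waves resolved on low-Reynolds grids where the
viscous step limit dominates. Inlets are plugs on the west boundary (each
inlet carries Q/2 of the species-split co-flow; developed profiles form
within the lead-in), the outlet is zero-gradient with an exact global
mass-balance rescale, and the reference pressure is anchored at the outlet
column. Convergence demands a dimensionless continuity residual
(max|∇·v|·h/u_in) below 1e-3 — which bounds cross-section flux errors
well under 0.5 % — and a per-step velocity change below 2e-7·u_in.
Warm starts (local slot profile plus integrated slot-flow pressure) cut
the march several-fold; a `zero` start is available and converges to the
same field.

The default resolution is 20 cells across the nominal width (20 µm
cells). Grid convergence rather than a fixed node count is the accuracy
argument: halving the cell size changes reported mixing indices by < 3 %
(tested), and the developed centerline peak matches the analytic slot
parabola to < 2 %.

Species transport is steady Fickian advection–diffusion
(D = 2.3e-9 m²/s, the self-diffusion coefficient of water) marched to
steady state with a van-Leer TVD-limited second-order upwind scheme.
A bounded, second-order scheme is essential here: spurious numerical
diffusion directly inflates the mixing index, which is why plain
first-order upwind was rejected as the default. The zero-diffusion limit
keeps a step profile sharp to within a few cells over hundreds of cells
traveled (tested), and the plug-flow solution matches the eigenmode
series below to < 5 %.

## Mixing indices

**Field form.** At a station s the index is MI = 1 − σ(s)/σ_max, where σ
is the standard deviation of the mass fraction over the in-channel samples
of the cross-section normal to the local centerline tangent and σ_max is
the same quantity at the channel entrance. Whether the published σ is
area- or flow-weighted is not stated; `micromix` uses unweighted
(area) sampling, the plainer reading, and the index is invariant to which
species is chosen (Y or 1 − Y).

A closed-form oracle exists for plug flow in a straight channel: an
initial half/half step between no-flux walls decays on cosine eigenmodes,
σ²(t) = Σ_k odd (2/(kπ))² e^(−2D(kπ/W)²t) / 2 with t = s/ū. The series
(summed to k = 199 and normalized by its own t = 0 value) anchors both the
solver tests and expectations like "a straight channel at 1 µL/min is
essentially fully mixed 20 mm downstream" (Fourier number ≈ 2 there, so
MI ≈ 1; the published experimental value at that operating point is 91 %).

An important caveat the package makes no attempt to hide: at 50 µL/min
and above, transverse diffusion alone cannot complete mixing within
15 mm in this 2D model — the near-complete experimental mixing at those
rates must involve mechanisms (3D secondary flows, printing-induced
roughness, or numerical diffusion in the reference CFD) that a desk-scale
2D model deliberately excludes. The package therefore targets the
low-rate diffusion regime and the velocity-field claims, not the
high-rate mixing-distance table.

**Image form.** MI = N_mixed/(N_mixed + N_unmixed), where a pixel is
mixed when all three RGB channels fall inside the calibrated mixed
(green) box and unmixed when they fall in the blue or yellow boxes
(mixed box takes precedence on overlap). Published work classifies every
pixel implicitly; real images contain out-of-range pixels, so the package
excludes unclassified pixels from the denominator, reports their
fraction, and warns above 10 %. The actual RGB bounds used for the
devices were never printed, so calibration is part of this artifact:
per-class [p, 100−p] percentile boxes (p = 1) from reference images,
widened by 5 levels. The ROI protocol follows the measurement setup: a
380 µm square inset inside the 400 µm channel (avoiding wall shadows),
three ROIs per station placed in axial succession centered on the channel
axis (their exact published placement is unknown), stations at
0/10/15/20/25/40 mm from the junction.

## Synthetic fixtures

The micrograph generator renders a channel band whose per-pixel class is
driven by a transverse mixing profile m(y): below 0.35 unmixed blue,
above 0.65 unmixed yellow, otherwise mixed. Those thresholds are the
fixture's own convention — the fixtures exist to test pixel counting with
exact ground truth, not dye photophysics. Color anchors (blue 40/70/200,
yellow 230/215/60, mixed 90/170/110) keep the calibration boxes disjoint
under the default noise (σ = 4, clipped to ±margin so no pixel can leak
out of its class box). Downstream stations use an erf-shaped m(y) whose
diffusion length grows as √(2Ds/ū), so the series is monotone by
construction. Fixtures are deterministic per seed and ship with an MD5
manifest. What passing these tests shows is that counting, calibration
and ROI placement are exact; it says nothing about illumination
gradients, wall shadows or dye rheology in real micrographs.

Analytic velocity fields (plug and parabolic slot) provide the oracles
for the flow solver and the particle tracker.

## Particle tracking

Beads are passive point tracers (7 µm beads in a 400 µm channel; no
inertia, Brownian kicks optional and seed-controlled). Tracks integrate
the interpolated velocity with classical RK4 at 10 sub-steps per frame
and are sampled at 100 Hz, mirroring a light-sheet acquisition (5 ms
exposure, so a 10.4 mm/s bead leaves a 52 µm streak). Steps that would
leave the domain are bisected onto the boundary and the track ends.
In analytic fields, per-track speeds seeded at cell centers match the
profile to < 0.5 % and a parabolic fit of the binned profile has
R² > 0.999.

## Problem sizes and runtimes

The shipped configurations are desk-scale by design: two sinusoid periods
with 1.5 mm straight leads for the mixer comparisons (~480 × 180 cells at
20 µm) and a 22 mm straight channel (1100 × 24 cells) for the co-flow
diffusion case. These sizes demonstrate grid convergence and keep the
whole suite and the acceptance script comfortably reproducible on a
single CPU; refining further changes reported indices by under 3 %.

## Known limitations

- 2D plan-view only; no out-of-plane routing, no Hele-Shaw drag, no
  turbulence (irrelevant below Re ≈ 50), no non-Newtonian rheology, no
  droplet/gelation physics.
- The high-flow-rate mixing-distance observations are not reproduced by
  design (see above); fabrication tolerances, surface roughness and cell
  viability are hardware results outside a simulation package.
- The offset polygon at the default amplitude legitimately self-intersects
  at apexes before repair; local widths measured there are
  reported as-is rather than forced to w(s).
- The G-code dialect covers single-layer continuous extrusion only: no
  retraction, z-hop or multi-layer logic.
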