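---
title: "Models and methods behind capsnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind capsnav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsnav)
```

`capsnav` is a desk-scale simulation twin of an actively controlled magnetic
capsule endoscope: a ten-coil electromagnetic actuation (EMA) system steers
and propels a capsule carrying an axially magnetized permanent magnet, while
a planar array of mono-axis Hall sensors beneath the workspace recovers the
capsule's 5-DOF pose in real time, even while the coils are energized. This
vignette explains the models, the tunable parameters, and the design
decisions; the README shows the worked example.

## The capsule magnet

The magnet (default: a 10 mm x 12 mm NdFeB cylinder, remanence 1.48 T) is
modelled as a point dipole. With heading $\mathbf{D}$ (unit vector),
position $\mathbf{M}$, and dipole strength
$B_T = \mu_0 m / 4\pi$ (with moment $m = B_r V / \mu_0 \approx
1.11\,\mathrm{A\,m^2}$, so $B_T \approx 1.11\times10^{-7}\,\mathrm{T\,m^3}$),
the field at a point $\mathbf{S}$ is

$$\mathbf{B} = B_T\left(\frac{3(\mathbf{D}\cdot\mathbf{P})\,\mathbf{P}}{\lVert\mathbf{P}\rVert^5}
 - \frac{\mathbf{D}}{\lVert\mathbf{P}\rVert^3}\right),\qquad
 \mathbf{P} = \mathbf{S}-\mathbf{M}.$$

The sensors measure only the board-normal component $B_z$. A grid-of-dipoles
model of the finite cylinder agrees with the point-dipole field to better
than 1 % at the 60 mm-plus ranges the sensors operate at, which is why the
far-field form is used throughout. Evaluation inside 1 mm of the dipole
centre is refused: the model diverges there and no sensor ever sits that
close.

Torque and force on the magnet follow the standard laws
$\boldsymbol{\tau} = V\mathbf{M}\times\mathbf{B}$ and
$\mathbf{F} = V(\mathbf{M}\cdot\nabla)\mathbf{B}$: a uniform field aligns
the capsule, a gradient pushes it. Roll about the magnetization axis leaves
every field value unchanged, so only five degrees of freedom
(position + yaw + pitch) exist to be controlled or estimated.

## The coil system

The physical system's coil geometry is not part of the public record, so the
package ships a declarative ten-channel layout with the same capability
envelope:

* a Helmholtz pair along z (radius 0.25 m, separation = radius, 200 turns)
  for uniform $B_z$;
* Maxwell (anti-Helmholtz) pairs along x and y (radius 0.20 m, separation
  $\sqrt3 R$, 400 turns) for controllable gradients;
* rectangular pairs along x and y (0.20 m wide x 0.30 m tall, 150 turns)
  for uniform $B_x$, $B_y$.

Everything is computed from filament models: circular loops use the exact
complete-elliptic-integral closed form, rectangles the exact four-segment
finite-wire formula. Two sizing choices matter and were fixed once, by
inspection of the allocation problem rather than of any test outcome:

* **Maxwell pairs at 0.20 m / 400 turns** deliver ~8 mT/m per ampere, so the
  50 mT/m propulsion preset needs ~12 A at the worst in-plane heading --
  inside the ±20 A per-channel limit. A 0.25 m / 200-turn pair would need
  ~39 A.
* **Rectangles stand tall along z.** With the wide-flat orientation the
  minimum-norm allocation has narrow hotspots on the workspace centre plane
  demanding over 40 A; the tall orientation keeps the worst case near 14 A
  everywhere on that plane.

Field gradients are evaluated by fourth-order central differences (five-point
stencil, step $h = 10^{-4}$ m). The free-space Maxwell conditions -- the
gradient tensor is symmetric and traceless -- then hold to about $10^{-12}$
relative, comfortably below the $10^{-6}$ tolerance asserted in the test
suite; a second-order stencil at the same $h$ leaves ~$2\times10^{-7}$
relative truncation, which is why the higher-order stencil is used.

An optional gridded-basis mode (`build_field_grid()` + trilinear
interpolation) mimics the measured unit-current database a physical system
would use; it agrees with the analytic basis to better than 0.5 % over the
workspace at the default resolution.

## Current allocation and the operator command

At capsule position $P$ with heading $\hat{\mathbf{M}}$, the actuation matrix
$X(P)$ (6 x 10) maps coil currents to the field triple and the
heading-projected gradient triple. Requests are solved by the Moore--Penrose
pseudoinverse (SVD), giving the minimum-norm current vector; singular values
below $10^{-10}$ of the largest are truncated and rank deficiency is
reported, never raised.

The end-user command is the three-parameter triple (yaw, pitch, push $F$ in
T/m), expanded with a fixed field:gradient ratio $\gamma$ (default 0.1 m,
the 1:10 ratio of field in Tesla to gradient in T/m):
field $= \gamma F\,\hat{\mathbf{u}}$, gradient $= F\,\hat{\mathbf{u}}$ with
$\hat{\mathbf{u}}$ the commanded heading. The implementation multiplies one
vector by $\gamma$, so the ratio is exact in floating point, not just to
rounding.

One structural fact shapes the controller: at points of coil symmetry the
achievable gradient tensor is diagonal and traceless, so a force parallel to
a heading with all three components nonzero would need
$g_{xx}=g_{yy}=g_{zz}=F$ -- impossible with zero trace. Micrometres away
from such points the pseudoinverse *can* synthesize the request, but only by
spending tens of amperes on a nearly null direction. The closed-loop
controller therefore (a) allocates with a coarser relative cutoff
($10^{-3}$), a standard truncated-pseudoinverse guard for ill-conditioned
allocation, and (b) holds the pitch command at zero on planar paths. The
paper-style planar trials are unaffected; fully 3-D force tracking near the
centre plane is a genuine limitation of this coil topology, not of the
solver.

## Sensor array and synthetic frames

The sensing board is a 6 x 6 grid of linear mono-axis Hall sensors at 20 mm
pitch (spanning 100 mm x 100 mm at $z=0$), each reading the z-field as a
ratiometric voltage: $v = 2.5\,\mathrm{V} + (12.5\,\mathrm{mV/mT})\,B_z$,
clipped at ±169 mT and quantized by a 16-bit ADC over 0--5 V (one LSB is
about 6 µT). The synthetic frame generator composes, in order: dipole field
+ superposed coil fields, additive Gaussian noise (default
$\sigma = 0.05$ mT), range clipping, quantization. The defaults are the
study conditions; they were set once and are not tuning knobs. "Noiseless"
in tests means $\sigma = 0$ *and* quantization off -- the ADC word length is
a separate, configurable mechanism.

What the generator does *not* emulate: sensor gain/offset mismatch,
temperature drift, cross-axis sensitivity, Earth's field, or timing skew
between the multiplexed channels. Passing tests therefore validate the
algorithms under the stated noise model, not robustness to a miscalibrated
physical board (calibration is explicitly out of scope).

## Localization

With currents $i_k$ known and the unit-current basis $H_k$ precomputed at
each sensor, compensation is the subtraction
$H_M = H_S - \sum_k H_k i_k$ -- exact to machine precision on synthetic
frames by construction, and requiring no knowledge of coil geometry beyond
the basis table itself. The pose is then the minimizer of the squared
z-field residual over $(a, b, c, \mathrm{yaw}, \mathrm{pitch})$.

The solver is a damped Gauss--Newton (Levenberg--Marquardt) iteration with
the analytic Jacobian of the dipole z-field:

* damping $\lambda$ starts at $10^{-3}$, x10 on rejection, /10 on
  acceptance (Marquardt diagonal scaling);
* stop on step norm $< 10^{-10}$, relative cost drop $< 10^{-12}$, or 200
  iterations; the cost criterion only counts when the damping is relaxed,
  because a microscopic forced step under heavy damping is a stall, not
  convergence;
* the z coordinate is clamped 5 mm above the board (the capsule cannot be
  below it);
* five parameters, not six: the unit-norm constraint and the unobservable
  roll are eliminated by the yaw/pitch parameterization, keeping the
  Jacobian full rank. Heading polarity *is* observable (flipping the heading
  negates every reading), so no sign disambiguation is needed. At pitch
  ±90° yaw is degenerate; the convention is yaw = 0 with a flag.

Cold starts use a coarse grid search: 10 mm position pitch over the
workspace x 14 candidate headings (six axis-aligned + eight body
diagonals), polishing the three lowest-cost candidates and keeping the best.
Warm starts (tracking) use the previous estimate. Saturated sensors are
dropped (at least six must remain for identifiability) and reported.

## The quasi-static plant and the closed loop

The capsule moves in the overdamped regime: no inertia. The heading relaxes
toward the local field direction with time constant `tau_align` (default
50 ms *at the 5 mT reference field*; the rate scales with $|B|$ because the
torque does). Translation is at terminal velocity
$v = \max(0, (|F| - F_\mathrm{fric})/c_d)$ along the net force
(drag $c_d = 3.5$ N s/m, chosen once so the 50 mT/m preset gives
~16 mm/s, the order of the visible speeds in bench trials of such systems;
friction threshold 0 in free space). In tube mode, motion is projected onto
the tube centreline and confined to its radius.

The human joystick operator is replaced by a deterministic path-following
policy with the same three controls: project the *estimated* position onto
the desired polyline, aim at a 4 mm lookahead point plus three times the
cross-track error vector, command (yaw, pitch, $F$) at 20 Hz. Plain
waypoint-capture steering was rejected because pure-pursuit corner-cutting
on the 20 mm turn radius is ~0.6 mm -- an order of magnitude worse than
what the noiseless loop should achieve; with cross-track feedback the
noiseless mean path error is a few hundredths of a millimetre. The default
U-shaped path (80 mm extent, 40 mm leg gap, 5 mm waypoint spacing) lies on
the workspace centre plane at $z = 25$ mm, where the allocation is best
conditioned; the capsule height in the physical trials is not on record.

The comparison between the proper 1:10 field:gradient ratio and the 1:20
misuse case holds the *field magnitude* fixed and doubles the push, which is
the protocol the bench experiments used (alignment field constant, gradient
varied); halving the field at fixed push instead changes the tracking error
by less than run-to-run jitter.

## Problem sizes and runtime choices

The bundled studies use sizes that make the whole suite comfortably
reproducible on a laptop core: four seeded closed-loop trials of ~230 ticks
each for the tracking statistics; 60 poses per noise level for Monte-Carlo
recovery in the acceptance checks (the `recovery_study()` default is 100);
50 random cases for the grid-search-vs-optimizer comparison; 300 frames for
the noise-calibration check. Every run is reproducible from its integer
seed alone, and trial $k$ of a repeated study uses seed $\texttt{base} +
k - 1$.

## Known limitations

* The coil layout is representative, not the physical system's; absolute
  field-per-ampere values are therefore this package's own, while every
  requested (field, gradient) set-point is met by construction through the
  allocation layer.
* Near coil-symmetry points, force requests with all three heading
  components nonzero are unattainable at reasonable currents (trace-free
  gradient); planar scenarios avoid this by construction.
* Tissue mechanics, fluid drag fields, wire tether forces, rolling, and
  peristalsis are not modelled; the lumped surrogate is sensor noise.
* The detection hook tags poses for an *external* event stream; no imaging
  or detection model is included.
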