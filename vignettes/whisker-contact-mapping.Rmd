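---
title: "Mapping base mechanics to the 3D whisker-object contact point"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping base mechanics to the 3D whisker-object contact point}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A rodent whisker (vibrissa) is a tapered, intrinsically curved cantilever
with no sensors along its shaft: everything the animal learns about a
contact arrives as forces and moments at the whisker base, inside the
follicle. `whiskmap` asks and answers the forward and inverse questions for
this system:

* **Forward**: if the whisker is bent quasistatically so that it touches an
  object at the point $(r_{\mathrm{wobj}}, \theta_{\mathrm{wobj}},
  \varphi_{\mathrm{wobj}})$ (radial distance, azimuth, elevation in
  whisker-centred coordinates), what six reactions $(F_x, F_y, F_z, M_x,
  M_y, M_z)$ appear at the base?
* **Inverse**: which *triplets* of base signals suffice to recover the 3D
  contact point, and how well does reading such a triplet backwards through
  a lookup table reconstruct an object (a vertical peg) during whisking?

The six raw reactions are rewritten as the signal set used throughout:

$$F_T = \sqrt{F_y^2 + F_z^2}, \quad F_D = \operatorname{atan2}(F_z, F_y),
\quad M_B = \sqrt{M_y^2 + M_z^2}, \quad M_D = \operatorname{atan2}(M_z, M_y),$$

with the axial force $F_x$ and twisting moment $M_x$ passed through.
Directions are quadrant-aware and mapped to $[0, 2\pi)$; magnitudes below
$10^{-9}$ internal units leave the direction flagged undefined rather than
numerically meaningless. Because the base moment of a point force is
$\mathbf{p} \times \mathbf{F}$, the offset $M_D - F_D$ is exactly
$\pm 90^\circ$ whenever $F_x = 0$, and close to $90^\circ$ everywhere else;
this is one of the package's acceptance quantities.

### Sign convention for the base loads

`base_reactions()` reports the load the whisker *transmits into the
follicle*: $\mathbf{F} = \mathbf{f}_{\mathrm{applied}}$ and
$\mathbf{M} = \mathbf{p}_c \times \mathbf{f}_{\mathrm{applied}}$ (the
support reaction is the negative of both). With this convention $F_x$ is
the axial tension at the base: negative when the contact pushes the whisker
into the follicle — the usual situation during bending — and positive only
where the contact straightens the intrinsic curvature (distal,
concave-forward, small-deflection contacts). On the default mapping table
only a small fraction of records have $F_x > 0$, which is what makes the
axial force informative.

## The rod model

The whisker centreline is a chain of ~100 rigid links joined by elastic
joints. Joint $j$ carries bending stiffness $E I(s_j) / \Delta s_j$ about
the two local normals and torsional stiffness $G J(s_j)/\Delta s_j$ about
the local tangent, with $I = \pi r^4/4$, $J = 2I$, $G = E/(2(1+\nu))$, and a
half-weight joint at the clamp (a trapezoidal end correction without which a
100-node cantilever under-predicts tip deflection by about 1.5%; with it the
Euler–Bernoulli closed form is matched to better than 0.1%). The radius
tapers linearly from 100 µm at the base by a base-to-tip ratio of 15
(tip 6.67 µm); Young's modulus defaults to 3 GPa and Poisson's ratio to
0.38. Internally everything is mm / µN / µN·mm.

A contact is a single frictionless point load: the force lies in the plane
normal to the deflected tangent at the contact. Given a load at material
coordinate $s_c$, the joint rotations are fully determined by the contact
position $\mathbf{p}_c$ (internal moment $(\mathbf{p}_c - \mathbf{p}_j)
\times \mathbf{f}$), so the equilibrium shape is the fixed point of a
three-variable map $\mathbf{p}_c \mapsto \mathrm{forward}(\mathbf{p}_c)$,
solved by damped Newton iteration with a finite-difference Jacobian — this
stays convergent at large deflections where plain successive substitution
oscillates.

The contact problem itself solves three unknowns — the two in-plane force
components and the contact arc length $s_c$ — against the three-component
residual "material point $s_c$ reaches the target", again by damped Newton
with continuation: targets are approached along a path in spherical
coordinates from the undeflected whisker outward, warm-starting force,
$s_c$, and shape at each step. Newton convergence to within 10 µm of the
target defines success. Non-convergence is reported as *slip*: past the
fold of the force–position map no equilibrium holds the whisker on the
point, which is exactly the configuration in which a frictionless whisker
slides off. A force-driven exploration of the same rod (applying
frictionless loads of growing magnitude and recording where the contact
point lands) reproduces the same reachable envelope, so the fold is a
property of the mechanics, not of the solver.

Grid sweeps (`reachable_space()`) walk each radius outward in azimuth at
fixed elevation, warm-starting every solve from its neighbour and
propagating branch seeds across elevations; once a branch slips, points
further out on the same branch are recorded as slip without re-solving
(the envelope is monotone along a push).

## The mapping table and its inversion

`build_mapping()` sweeps a spherical grid (defaults: $r$ 6–20 mm in 2 mm
steps, $\theta$ −65°…65° and $\varphi$ −60°…60° in 3° steps; the
full-resolution 1 mm / 1° grid of 237,765 points is a configuration away),
decomposes the loads, and flags two kinds of records:

* **small-deflection exclusion**: any target closer to the whisker than
  $s_{\mathrm{closest}} \tan 2^\circ$ is excluded — deflections that small
  produce signals the table cannot resolve into a radial distance;
* **regions**: concave-forward ($\theta < 0$, pushing with the intrinsic
  curvature), concave-backward ($\theta \ge 0$), and large-deflection
  (contact tangent at or past the $y$–$z$ plane, i.e. past the tube where
  $F_T \to 0$ and $F_D$ flips by 180°). The large-deflection label is
  computed directly from the deflected tangent the solver already carries,
  rather than from the $F_D$ flip it implies; the flip itself is
  demonstrated in the test suite by force-driven continuation through the
  tube. Under the default whisker and grid the converged cloud contains no
  large-deflection records: for this geometry the frictionless slip fold
  nearly coincides with the tube, so contacts beyond it cannot be held.

Inversion (`invert_triplet()`) is a lookup: the query's triplet values are
standardised (magnitudes z-scored with the table's statistics, directions
embedded as $(\cos, \sin)$ to avoid the $0/2\pi$ seam), an exact match
returns that record verbatim, and otherwise the $k = 8$ nearest records are
combined by inverse-distance weighting. Queries farther from the table than
three times the median nearest-neighbour spacing are flagged as
extrapolation but still answered.

## Uniqueness testing

All $\binom{6}{3} = 20$ triplets are tested (`uniqueness_census()`), each
with two independent evidence streams:

1. **Function solvability.** A small feed-forward network (`nnet`, one
   hidden layer of 32 units — the installed approximator; directions enter
   as $(\cos,\sin)$) is fit from the triplet to $(r, \theta, \varphi)$ on
   an 80/20 split, three seeded replicates with majority vote. The mapping
   counts as solvable when held-out median absolute errors fall below
   1 mm / 2° / 2°. A network that fails to train is reported as
   inconclusive, never as unique.
2. **Geometric overlap.** For an invertible, well-sampled mapping each
   record's nearest neighbour in signal space is also its neighbour in
   contact space. An overlap witness is a record whose nearest signal-space
   neighbour lies more than 4 mm away in contact space (20% of the whisker)
   *while* being closer in signal space than half the typical
   nearest-neighbour spacing — the second condition distinguishes a genuine
   intrusion by another sheet of the mapping from mere isolation at the
   edge of the reachable cloud.

A triplet is judged `unique` only when the network solves it *and* the
overlap count is zero. On clean synthetic tables (signals an analytic
bijection of the coordinates) the two streams agree exactly: a bijective
triplet is unique with zero witnesses, a $\varphi$-blind triplet is
non-unique with many. On solver-built tables the overlap stream is
conservative: a band of witnesses survives just outside the 2° exclusion
cone, where the mapping is invertible in principle but resolution-limited —
so strict zero-overlap verdicts understate uniqueness there. The census
report keeps both streams visible so this tension is inspectable rather
than hidden; region-conditioned censuses (`ELD`, `CF`, `CB`, combinations)
use the same machinery after filtering.

## The synthetic whisking trial

No behavioural video ships with the package; `synth_whisk_trial()`
generates the study's trial structure instead: a 1 kHz pose series over one
whisk cycle (default 2 Hz — slow, exploratory whisking — protraction
72° ± 30°, an in-phase elevation sweep of ±10° that spreads contacts
vertically on the peg, fixed basepoint), with seeded Gaussian jitter on
basepoint (0.06 mm ≈ one tracking pixel) and orientation (0.5°). The posed
*rigid* whisker is intersected with a vertical 2.7 mm peg placed 11 mm out
near the top of the sweep; the contact point is the deepest-penetrating
node projected radially to the peg surface, contact is held while the
penetration grows and is shallower than 1 mm, and deeper penetration means
the whisker has slipped past. One cycle therefore yields a forward episode
pressing the caudal (back) surface and a backward episode pressing the
rostral (front) surface, a few tens of milliseconds each, with the bending
direction $M_D$ flipping by about 180° between them.

`lowpass_basepose()` smooths the pose channels with a zero-phase 4th-order
Butterworth filter at 85 Hz (the cutoff used for video-tracking jitter) and
recomputes contact geometry from the smoothed pose. `trial_to_signals()`
runs the contact solver frame by frame (warm-starting along each episode),
and `reconstruct_peg()` inverts the chosen triplet against a lookup table.
For the peg demonstration the table is swept on a focused
behavioural-region grid (`peg_demo_grid()`, 8–14 mm at 1 mm / 1.5°):
near the whisker the global reduced grid retains too few records after the
exclusion cone to resolve radial distance, and the finer focused grid
costs about the same as the global one. The reconstruction then inverts
the triplet — (F_x, M_B, M_D) by
default — frame by frame, transforms the whisker-frame estimates into the
lab frame with each frame's pose, and splits errors against the
ground-truth contact points into radial (along the base-to-contact ray)
and angular components. Radial errors dominate, mirroring where the
mapping's resolution is poorest.

What the generator does *not* emulate: head motion, whisker roll/torsion
kinematics of real whisking, multi-whisker interactions, collision
dynamics and friction (the mechanics model is quasistatic and
frictionless), and tracking artefacts beyond white pose jitter. Passing
tests therefore demonstrate internal consistency of the pipeline under
these idealised conditions, not performance on behavioural video.

## Sensitivity analysis

`jacobian_at()` evaluates the nine elements of
$\partial(r, \theta, \varphi) / \partial(M_D, M_B, F_x)$ by central
differences through a scattered-data interpolant, holding the other two
variables fixed — 18 interpolations per probe. Steps are 0.05% of each
variable's range over the behavioural envelope (`step_from_range()`), the
envelope defaulting to the synthetic trial's signal ranges. The
interpolant is a distance-weighted local-linear (moving least squares) fit
over the 24 nearest samples; natural-neighbour interpolation, the usual
choice for scattered data of this kind, has no installed R implementation,
and the local-linear fit shares its key property of smooth first
derivatives. The method is recorded in the output metadata.
`trim_and_bin()` drops values outside the central 99% interval per element,
bins the remainder 50 × 50 over (variable value × element value), and
assigns display weights proportional to bin counts, floored at 0.05 for
bins under 5% of the maximum. `spread_by_magnitude()` compares
interquartile spreads between the bottom and top quartiles of $|M_B|$ or
$|F_x|$: spread contracts as loading grows, i.e. the mapping is most
error-prone where forces are small.

## Numerical choices, in one place

* Solver: contact tolerance 10 µm; inner Newton tolerance $10^{-10}$;
  damped line searches with at most 8 halvings; continuation steps of ~3°
  of deflection; failures near the end of a continuation path are reported
  as slip without refinement (a finer path cannot cross a fold).
* Problem sizes: 100 nodes per whisker; the reduced 8 × 44 × 41 grid
  (14,432 candidate points, of which roughly 2,500 converge and survive
  exclusion) drives the census and the demo; tests use the same or smaller
  grids.
* Ties and degeneracies: direction signals with magnitude below $10^{-9}$
  are undefined-flagged; inversion ties broken by inverse-distance weights;
  the frame alignment fixes its sign conventions by pointing the tip
  toward $+y$.
* Seeds: the solver is deterministic; network splits/initialisation and
  trial jitter derive from explicit seeds, and `run_pipeline()` fans a
  single global seed out to its stages.

## Known limitations

* The quasistatic, frictionless model omits dynamics, friction, follicle
  compliance, and multi-point contact; all results are conditional on it.
* The reachable cloud is bounded by the frictionless slip fold; for the
  default 20 mm whisker this leaves no large-deflection records, so
  region-conditioned verdicts that depend on that branch cannot be
  exercised under the defaults. (Reported arc lengths for this whisker
  type are uncertain — roughly 20 to 40 mm — so arc length is an explicit
  parameter here, with 20 mm the default; a longer whisker widens the
  reachable cloud substantially because the same grid then touches only
  its stiffer proximal half.)
* Strict zero-overlap uniqueness verdicts are conservative near the
  small-deflection exclusion cone, where the binding constraint is
  resolution rather than invertibility.
* The lookup inversion interpolates between grid records; its radial
  accuracy is limited by the grid step and degrades for distal,
  small-deflection contacts, which is visible in the peg reconstruction's
  radially-dominated errors.
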