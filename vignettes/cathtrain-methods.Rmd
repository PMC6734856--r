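---
title: "Simulating epiduroscopy training: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating epiduroscopy training: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathtrain)
```

## The training problem

Epiduroscopy steers a thin catheter through the epidural space — the narrow
gap between the dural sac and the bony canal — from the sacral hiatus up to a
lesioned disc, under 2D fluoroscopic guidance. Serious-game simulators teach
the *spatial* part of this skill: which landmarks to pass, on which side of
the dura to travel, and where to cross from the dorsal to the ventral side.
`cathtrain` is a headless, scriptable re-implementation of such a trainer's
computational core: everything except rendering and input hardware. It
simulates training sessions, scores them by the two standard surgical metrics
(number of collisions and completion time), and analyzes cohorts of synthetic
trainees with the statistics used in simulator-validation studies.

The package is organized around a cognitive-map view of the task. *Primary*
landmarks are the decision points: A, the entry at the sacral hiatus where the
path splits into a dorsal and a ventral side; B, the point where a dorsal
approach detours to the ventral side; C, the destination (the lesion disc).
*Secondary* landmarks are the sacral nerve roots S1–S4, reference points for
the detailed path. Four guided scenarios differ in whether B is present
(scenarios 1–2) or absent (3–4, a direct ventral approach) and in which
secondary landmarks the detailed path visits; scenario 1's canonical detailed
route is A → S4 → S3 → B → S2 → S1 → C. A fifth, *free* scenario has no
guidance tube at all — collisions there are real organ contacts — and is the
setting of the simulated validation study.

## The synthetic scene

The original trainer used a hand-modeled 3D scene. Since no dimensions of
that scene are published, `generate_environment()` builds a procedural
stand-in from analytic collision primitives (spheres, capsules, axis-aligned
boxes), so that every distance used in collision scoring has an exact closed
form. All defaults are *synthetic but anatomically plausible magnitudes*,
chosen once and documented here; none is a measured human dimension.

Coordinates are right-handed millimetres: +z runs from the sacral hiatus
toward the head, +y is dorsal.

| element | model | default |
|---|---|---|
| canal length (A to C) | — | 200 mm |
| dural sac | capsule on the canal axis | radius 8 mm |
| insertion paths | chains on a cylinder around the dura | radius 11 mm |
| bony canal | four box walls | inner face at 14.5 mm |
| tube fixture | tube around the scenario centerline | radius 3 mm |
| nerve roots S1–S4 | lateral capsules at the S landmarks | radius 2 mm |
| narrowings | spheres near the path (bone spurs dorsally, disc protrusions ventrally) | clearance 0.6 mm |
| landmark jitter | uniform shift of S-landmark z positions | ±2 mm |

S4…S1 are equally spaced along the canal (exactly so at `jitter = 0`, a
tested closed form); B sits midway between S3 and S2, where the dorsal chain
crosses to the ventral side by sweeping half-way around the dura cylinder —
the crossing never intersects the dura because every chain point stays at
cylinder radius 11 mm.

Two deliberate features shape the collision statistics:

* **Nerve contacts are unavoidable.** The nerve capsules are centered on the
  S landmarks, and the detailed route passes through those landmarks, so every
  full traversal brushes all four nerves: any agent's free-scenario collision
  count has a deterministic baseline of 4. Group differences ride on top of
  this baseline. (In guided scenarios collisions are tube excursions, and a
  perfect follower scores 0.)
* **Narrowings make counts noise-sensitive.** With ~3 mm of clearance
  everywhere, plausible steering noise almost never produces a contact, and
  beginner and expert would tie at the baseline. The five narrowing spheres
  (0.6 mm clearance) are where the epidural space is tight — disc protrusions
  ventrally, spurs dorsally — and they give the collision count a
  well-behaved, monotone response to the agent's noise level. The 0.6 mm
  value was fixed a priori from the stationary lateral-error analysis below,
  not tuned against test outcomes.

## Fixture geometry and collision semantics

The tube virtual fixture is an arc-length-parameterized polyline plus a
radius. `distance_to_centerline()` is the exact minimum over point-to-segment
closed forms, with ties broken toward the smaller segment index and capped
ends (beyond the terminal vertices, distance is to the vertex). It is the
single geometric primitive behind containment, collision detection, position
correction, and the guidance force.

**Collisions are excursions, not frames.** One `CollisionEvent` is emitted
per contiguous inside→outside transition of the containment signal (tube
containment in guided mode; "outside every organ" in free mode). This
matches the visual reading of the feedback — the tooltip turns red when it
leaves the path and white when it returns — and makes counts invariant to
the timestep at fine `dt`. Motion is checked at step endpoints only;
sub-step continuous collision detection is out of scope, which is safe
because a step (0.5 mm at defaults) is small against every feature of the
geometry. Whether the original system counted per excursion, per frame, or
per discrete touch is not published; the excursion rule is this package's
documented choice.

**Force contract.** The fixture force is a linear penalty spring: zero
inside the tube, `stiffness × penetration` outside (default 0.2 N/mm),
directed from the tip to its nearest centerline point. Magnitude is
continuous across the wall. Only the force *law* is this package's choice;
that a force is computed on collision and sent to a haptic master is part of
the re-implemented processing contract, but no hardware I/O exists here.

## Sessions and kinematics

A session is the loop: start at A, ask the controller for a direction, move
`normalize(command) × base_speed × multiplier × dt`, update containment /
color / events, optionally snap the tip back to the path (position
correction), stop when the tip is within `completion_epsilon` of C or at
`max_time`. Defaults — `dt` 0.05 s, `base_speed` 10 mm/s, speed multiplier
1× or 2×, `completion_epsilon` 5 mm, `max_time` 300 s, correction threshold
2 × tube radius — are unpublished in the reference design and are declared
here once. Completion by proximity to the destination is a proxy: the
original's completion rule is not stated.

One timing subtlety: a follower that walks the centerline stops at the first
`dt` multiple where the remaining path is inside `completion_epsilon`, so its
completion time is `(L − ε)/v` rounded up to `dt`, not `L/v`; the tests
assert the ε-corrected form since it is what the stated defaults imply.

The heading field tracks the last nonzero command. Orientation dynamics
(catheter bending, torsion) and kinesthetic realism are out of scope — the
tip-pose contract (position + heading) is the interface a renderer or haptic
layer would consume.

## Synthetic trainees

An agent is a noisy pure-pursuit controller: at each step it aims at the
path point `lookahead` mm ahead of its current arc length, then rotates the
aim by an angle drawn from N(0, σ_k²) about a uniformly random perpendicular
axis. Skill is the noise level; learning is its exponential decay across
repetitions,

σ_k = σ_∞ + (σ_0 − σ_∞)·exp(−r·(k − 1)),

the standard skill-acquisition form (the study reports only monotone
improvement, not a functional form). Default profiles: beginner σ 0.45 →
0.15 rad at rate 0.12 per repetition; expert constant 0.15 rad — i.e. the
expert starts at the beginner's asymptote, which is exactly the published
qualitative pattern (experts better throughout, only beginners improve).

Two parameters were fixed by analysis rather than left free:

* **Lookahead = 8 mm.** Pure pursuit cuts corners by roughly d²/8R on a
  curve of radius R. The dorsal→ventral crossing has R ≈ 30 mm; at 8 mm
  lookahead the cut is ≈ 0.3–1 mm, safely inside the 3 mm tube, so a
  zero-noise agent is collision-free on every guided scenario (a tested
  requirement). Lookaheads ≳ 12 mm violate it.
* **Narrowing clearance = 0.6 mm.** With per-step lateral noise ≈ 0.5·σ mm
  and pursuit gain γ = step/lookahead, the stationary lateral error per
  component is ≈ 0.5σ/√(2γ)/√2 ≈ σ mm at defaults. A 0.6 mm gate then sits
  at z ≈ 1.3 sd for a fresh beginner (frequent contacts), z ≈ 4 for an
  expert (rare), giving the observed-in-study shape: beginners start near
  4.5–5 collisions and decay to the expert's ~4; experts are flat.

In the free scenario the agents still navigate the full scenario-1 route
(the free scenario removes the fixture, not the task), and collisions are
organ contacts.

Determinism is structural: each session's seed is a pure hash of
`(base_seed, group, subject, repetition)`, so cohorts can be reordered or
extended without perturbing any session. `simulate_cohort()` runs sessions
in compiled code with a private PCG32 generator (platform-independent);
`engine = "r"` runs the same semantics through the R `step()` loop — the two
agree exactly in the noise-free case and statistically otherwise, since
their RNG streams differ by construction.

## Fluoroscopic projection

The survey-map view is an orthographic C-arm-style raster: the view axis
coordinate is dropped (lateral = along +x, the default, since the published
views do not state the C-arm orientation; anteroposterior = along +y), the
remaining planar mm coordinates map affinely to pixels with half-up
rounding, and the scene is painted at fixed gray levels with bone brightest.
Output is binary 8-bit PGM — dependency-free and byte-reproducible, which
the determinism tests exploit.

## Evaluation statistics

`rm_anova()` implements the classical balanced mixed-design decomposition
from its sums-of-squares definitions (the reference analysis was run in a
commercial stats package; no formulas are published): the group effect is
tested against subjects-within-groups, repetition and group×repetition
against the within-subject error. Identities `SS_total = ΣSS` and
`Σdf = N·m − 1` are property-tested; the implementation is verified against
an independently coded definitional oracle and `stats::aov` with an error
stratum. The Greenhouse–Geisser ε is computed from the pooled within-group
covariance and applied only on request — sphericity handling is not
described in the reference analysis, so the uncorrected test is the default.

`power_rm_anova()` uses the conventional noncentral-F forms: for the
between-group effect λ = f²Nm/(1+(m−1)ρ) with (g−1, N−g) df; for
within/interaction effects λ = f²Nmε/(1−ρ) with ε-scaled df. At f = 0 the
power is exactly α. The between-group convention is validated against
Monte-Carlo simulation under the model it assumes (compound symmetry,
correlation ρ, unit total variance): analytic 0.303 vs. simulated 0.302 at
f = 0.3, N = 16, g = 2, m = 5, ρ = 0.5. The reference study's sample-size
computation (n = 16 at α .05, power .9, f .3) cannot be reproduced exactly
because its configuration (which effect, which correlation) is unpublished;
the power function is therefore validated by simulation instead, and all
three effect conventions are exposed.

`fit_learning_curve()` fits y_k = b + a·exp(−λ(k−1)) by profiling λ over a
grid (the conditionally linear a, b solved in closed form per λ) and
refining the best cell with one-dimensional optimization — robust to the
flat-series degenerate case, which returns λ = 0, a = 0 rather than failing.

Both metrics (collisions, completion time) are analyzed separately with no
multiplicity correction, mirroring how such studies report them.

## Numerical choices

* Distance ties: toward the smaller segment index; route ties: shorter
  length, then fewer nodes, then lexicographic ids (no route cost is
  published; total chain length is this package's metric).
* JSON round trips write 17 significant digits, so environments and
  scenarios reload bit-exactly.
* The RM-ANOVA uses means-based SS on the wide matrix; with ≤ a few hundred
  cells the conditioning is harmless (verified to 1e-8 relative against the
  definitional oracle).
* `dt` accumulates as `steps × dt`, never by repeated addition.

## What the tests do and do not establish

The synthetic cohorts reproduce the *direction and shape* of the published
findings — experts collide less than beginners, only beginners improve, and
group completion times are close — because the agent model was designed to
have those properties. A green suite therefore establishes that the
simulator, scoring, and statistics behave correctly and reproducibly, not
that the agent parameters describe human surgeons: the published per-subject
data would be required to fit them, and deliberately were not used as
targets. Collision counts include the deterministic 4-nerve baseline of the
synthetic anatomy; only differences and trends, not absolute counts, are
meaningful. Rendering is orthographic and schematic; endoscopic perspective
views, deformable tissue, and haptic hardware are explicitly out of scope.
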