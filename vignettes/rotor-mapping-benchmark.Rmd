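---
title: "Benchmarking electrogram-guided rotor mapping and ablation in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking electrogram-guided rotor mapping and ablation in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rotorbench` implements a complete virtual pipeline for rotor-guided
ablation of atrial fibrillation: excitation propagation, electrogram
acquisition, phase mapping, rotor-tip tracking, trajectory-density
targeting, and virtual radiofrequency therapy. This vignette explains the
models, the parameters that matter, the numerical choices, and what the
synthetic fixtures do and do not show about real atria.

## The excitation model

Tissue is a 2D triangulated surface (the atrial wall is a few mm thick and
here treated as transmurally homogeneous, so every lesion is transmural by
construction). Transmembrane voltage obeys the monodomain equation

$$\partial_t V = \nabla\!\cdot\!\big(D\,\nabla V\big) - I_\mathrm{ion}(V, h),$$

with the anisotropic tensor $D = d_t I + (d_l - d_t)\, f f^\top$ built from
the per-element fiber direction $f$. Conductivities are stored in mS/m;
the remodeled-substrate defaults are $\sigma_l = 8.9$ mS/m with a 10:1
longitudinal-to-transverse ratio (the standard "AF-remodeled" description:
slowed conduction, increased anisotropy; the anisotropy figure is read as a
conductivity ratio, with both values overridable per element). Conversion to
diffusivity (mm²/ms) uses a lumped surface-to-volume × capacitance scale
(`DEFAULT_DIFFUSIVITY_SCALE = 0.02` mm²·m/(ms·mS)), chosen once so that the
remodeled substrate conducts at ≈0.4 m/s along fibers with the default cell
model — the package's cable tests measure this directly.

The default membrane model is a two-variable Mitchell–Schaeffer-class
model (`tau_in = 0.3`, `tau_out = 6`, `tau_open = 120`, `tau_close = 80` ms,
`v_gate = 0.13`), giving an action-potential duration of ~130–170 ms at a
basic cycle length of 800 ms — a short-refractoriness substrate that
sustains desk-scale spiral waves. The gate has piecewise-linear dynamics, so
its update per step is the exact exponential relaxation (the Rush–Larsen
scheme); the voltage uses forward Euler. Any model exposing the same
interface (`rest_state`, `rates`, `step`, `recommended_dt_ms`) can be
plugged in; a stiff ionic model should set `recommended_dt_ms = 0.02`
(20 µs), while the phenomenological default is accurate and stable at
0.1 ms (verified by the dt-halving convergence test).

Numerics: P1 finite elements with mass lumping; operator splitting per step
(reaction first, then explicit diffusion); no-flux boundaries arise
naturally at sheet edges and hole rims. The solver is deterministic —
there is no randomness anywhere in the numerical core; seeds only enter the
fixture generators.

Stimuli are discs (center, radius, onset, duration) with amplitude in model
units added to $dV/dt$; the default amplitude is twice the diastolic
threshold found by bisection on a single cell, with a 2 ms pulse. Sinus
activation is modeled as two disc stimuli (Bachmann-bundle insertion and
fossa ovalis) separated by a physiological 26 ms delay.

## Inducing reentry

`induce_reentry` runs an S1 protocol (a planar wave on the sheet fixture),
then scans the onset of a premature 5 mm-radius S2 disc across the
vulnerable window, coarse-to-fine (10 ms, then 5 ms). A candidate is
screened with a short continuation (350 ms — activity must outlive the time
a non-reentrant wave needs to clear the sheet) before the full criterion is
evaluated: at least 3 activations at the S2 site within a 1.2 s probe (the
S2 response plus two reactivations) *and* persisting activity at the probe's
end. The persistence clause matters: transient figure-of-eight reentries
that self-annihilate within a second would otherwise count as induced. The
S2 pulse is stronger than the default stimulus (5 ms at twice the default
amplitude) because tissue near the end of its refractory period has a
partially recovered gate and a correspondingly higher threshold; clinical
S1-S2 protocols only fix the electrode/pulse geometry, not the amplitude.

The `SHEET_ROTOR` fixture (81 × 81 nodes at 1 mm, fibers along +x,
conductivity ratio 4) draws up to four jittered S2 centers from its seed and
returns the first that induces sustained reentry — the usual
relocate-and-retry procedure for S1-S2 induction on a homogeneous
substrate. The fixture uses a 4:1 (not 10:1) conductivity ratio: at 1 mm
spatial resolution a 10:1 ratio pushes the cross-fiber wavefront width below
one element and the discretization itself starts to block conduction. The
4:1 ratio keeps the anisotropy that drives wavebreak while staying
numerically resolved; the 10:1 substrate remains the mesh default and is
exercised by the planar-wave anisotropy test at coarse resolution.

## Catheters and electrograms

Grid catheters are n × n square lattices (9×9/3 mm and 5×5/6 mm, both
24 × 24 mm). Placement fits a least-squares plane to the wall nodes within
5 mm of a chosen endocardial point, orients the normal toward the cavity
("inwards"; on open sheets the sign is supplied explicitly), snaps each
electrode to its closest point on the triangulated surface, then translates
the whole grid rigidly along the inward normal by the wall distance
(0/5/10/15 mm). The in-plane axes are anchored to the farthest neighborhood
node (distances rounded to 1 µm before ordering), which makes placement
exactly equivariant under rigid motions even when the plane fit is
rotationally degenerate.

The basket surrogate is a sphere of 48 mm diameter with 8 meridian splines
and 8 electrodes per spline (64 total) equally spaced in arc length;
wherever the nominal sphere exits the cavity, electrodes contract radially
to 1 mm inside the wall, preserving spline order. The full tension-energy
deformation of a real Constellation catheter is out of scope; the nominal
4 mm inter-electrode figure quoted for that catheter is not geometrically
consistent with 8 electrodes on a 75 mm meridian, so uniform arc-length
spacing is used and configurable.

Electrograms are unipolar potentials in an unbounded volume conductor
($\sigma_\mathrm{blood} = 0.7$ S/m, configurable; the absolute scale is
irrelevant because only phase is used downstream). The source of element
$i$ is its element-integrated transmembrane current, obtained by applying
the conductivity-weighted FEM diffusion operator to $V$ and redistributing
the nodal integrated currents to elements by area weighting — on a closed,
lesion-free surface the sources sum to zero at every instant (discrete
divergence theorem), and zero-conductivity elements are exactly silent.
Denominators are clamped at 0.5 mm so contact electrodes cannot sit on a
singularity. Output is decimated (sample picking) to 1 kHz; the solver step
is an integer divisor of 1 ms.

## Phase mapping and tracking

Electrograms are converted to phase by sinusoidal recomposition: activations
are local minima of $dV/dt$ below 0.2 × the trace's steepest downstroke with
50 ms blanking; each activation is replaced by one cosine period at the
local cycle length (clamped to 100–400 ms) and amplitude $|dV/dt|$, and the
wavelets are summed. The analytic-signal phase
$\arg(V + j\,\mathcal{H}\{V\})$ is computed by the standard
frequency-domain construction on the full window with the mean removed; the
first and last 5% of samples are flagged invalid rather than tapered.
Ground-truth phase applies the same transform to the transmembrane voltage
of every node.

Electrode phases are pushed onto the wall by nearest-neighbor assignment
with a 13 mm cutoff — deliberately no interpolation, which is known to
create phantom rotors. Phase singularities are detected on elementary
closed loops (the ordered one-ring of every interior node): a loop counts
when its wrapped phase differences wind by ±2π (tolerance 1e-6), contain at
least one raw jump ≥ π, and the remaining steps share the winding's sign
(tolerance 1e-9 — masked or tied steps excepted). Adjacent detections of
equal chirality merge at their mean position within two median edge
lengths, standing in for the "extend to neighboring regions" search.
Detection runs on frames downsampled to 100 Hz (configurable), and greedy
frame-to-frame association with catheter-specific distance thresholds
(8 mm for the 3 mm grid, 17 mm for the 6 mm grid, 20 mm for the basket)
builds rotor tracks; a track survives one empty frame, charge flips are
never allowed, and the longest-lived track is the ablation target.

## Density maps and the localization benchmark

The trajectory density at node $x_i$ is
$d_i = A \sum_{t_j \in \Delta t} \exp(-\|y(t_j) - x_i\|^2 / 2\sigma^2)$
with $\sigma = 3$ mm over the trailing $\Delta t = 2$ s of the track,
peak-normalized to 1 (ties resolve to the lowest node index). Localization
error is the Euclidean distance between the estimated and ground-truth
peaks; both maps run through the identical code path, the ground truth
using the per-node Hilbert-phase track.

`grid_localization_benchmark` centers each grid on the ground-truth
target's mean tip position and evaluates both grid resolutions at wall
distances 0/5/10 mm. Two desk-scale specifics deserve note. First, at
15 mm wall distance a flat single-wall sheet leaves every node beyond the
13 mm cutoff, so the map is fully masked — in a closed atrium other wall
regions remain in range, which is why clinical-scale tables report 15 mm
entries. Second, the sheet's S1–S2 protocol creates a figure-of-eight, so
*both* coupled rotors (~10 mm apart) sit inside the catheter's field of
view; the benchmark therefore selects the estimated track among those with
the ground-truth target's chirality. Without this, runs would randomly
lock onto either of two equally valid sources and the error would be
bimodal at the inter-rotor distance — an artifact of the fixture's size,
not of mapping resolution, which is what the benchmark is meant to measure.
The therapy path (`select_target`) keeps the pure longest-lifespan rule.

## The virtual therapy protocol

`run_protocol` repeats up to three times: record 2 s of electrograms,
reconstruct tracks, build the selected target's density map, apply a
circular zero-conductivity lesion (default radius 7 mm, elements whose
centroids lie within the closed ball — Euclidean, not geodesic, which on
convex fixture geometry cannot bridge folds) centered exactly at the density
peak. The electrical state carries over continuously between iterations.
Termination is declared when no node activates for 500 ms (the source
study judged this by inspection; a fixed silence window makes it
reproducible). After the final lesion one more recording window doubles as
the observation window; if activity persists, the run is classified
SUSTAINED and the lesion is tested for anchored reentry: the ground-truth
phase must wind by ~2π around a node ring just outside the lesion rim in
most late-window frames. `lesion_size_sweep` repeats the single-ablation
protocol from identical initial conditions across radii and classifies
ANCHORED / UNANCHORED / TERMINATED.

## What the fixtures emulate — and what they do not

The generators stand in for an unavailable patient anatomy: `make_sheet`
(remodeled 2D tissue), `make_cable` (conduction-velocity measurements),
`make_sphere` / `make_ellipsoid_atrium` (closed cavities with PV/MVR-like
holes, circumferential fibers, adult-LA scale ≈ 90 × 60 × 55 mm),
`analytic_vortex_field` (exact phase fields with known singularities — the
oracle for the detector), and `make_reentry_fixture` (seeded sustained
spiral waves). Passing tests on these fixtures demonstrate that the
pipeline is internally correct and reproduces the *structure* of the
clinical-scale findings (resolution and wall-distance degradation, lesion
anchoring); they do not demonstrate accuracy on patient-specific geometry,
heterogeneous fibrosis, transmural uncoupling, fractionated electrograms,
or realistic basket deformation — all deliberately out of scope. Problem
sizes (81 × 81 sheet, 2 s windows, five replicate seeds) were chosen as the
smallest configuration on which the spiral wave is stable and the trends
are measurable.

## Numerical and tie-break conventions

- Lesion membership: closed ball (centroid distance ≤ radius).
- Density peak ties: lowest node index.
- Target-track ties: longest lifespan, then earliest birth, then list order.
- Plane-fit neighborhood and anchor: distances rounded to 1e-6 mm before
  membership and ordering, so placement is stable under rigid motion.
- Degenerate linear lesions (zero-length polyline) behave as circular
  lesions of radius `half_width`; a non-contiguous linear lesion reports the
  minimal contiguous half-width in a warning.
- Fully masked phase maps are allowed (warning, no detections), as happens
  at 15 mm wall distance on the sheet.
- `analytic_vortex_field` on closed surfaces builds ±1 pairs as azimuthal
  angle about the axis through each pair, since a single-valued phase field
  on a closed surface must carry zero net charge.

## Known limitations

The solver is explicit and single-threaded R; it is sized for desk-scale
meshes (≤ ~10⁴ nodes), not clinical 3D volumetric models. The basket
deformation is a radial surrogate. Electrogram amplitudes are relative
(the monodomain-to-volume-conductor source normalization is left on an
arbitrary scale), so only phase-based downstream analysis is meaningful.
Sinusoidal recomposition assumes one deflection per activation and will
misread strongly fractionated electrograms.
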