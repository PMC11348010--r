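---
title: "Generating 3D-printable head caps: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating 3D-printable head caps: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Functional near-infrared spectroscopy (fNIRS) and EEG both need sensors
held at precise scalp positions. Textile caps place holders by hand and
drift between sessions; a 3D-printed flexible cap can instead carry its
optode and electrode holders ("grommets") at positions derived directly
from a head model and a probe design. `capgen` turns three inputs — a
scalp surface mesh with the four anatomical fiducials (nasion Nz, inion
Iz, left/right pre-auricular LPA/RPA), a probe design (optodes, spring
constraints, anchors to 10-5 landmarks, grommet types), and a target
head circumference — into four printable flat panels (left, right,
mid-front, mid-back) as STL files. Welding the printed panels along
their overlapping tabs reassembles the curved scalp geometry, so each
grommet lands at its intended anatomical position.

# Pipeline and models

## Head model and 10-5 landmarks

Any watertight-enough scalp surface works; the built-in generator makes
a superellipsoid upper hull (default exponent 2, i.e. an ellipsoid) with
a short 25 mm vertical skirt below the fiducial plane so the axial cut
has material to discard. Default axis ratios are (1, 1.25, 1.1)
(ear-to-ear : front-to-back : height) — an adult head is longer than it
is wide and about as tall above the ear plane as it is wide — and the
mesh is scaled so the circumference measured through Nz–LPA–Iz–RPA
equals the request (the calibration uses the discretized equator, so the
measured value matches the target at any refinement).

The EEG 10-5 grid is built by the classical iterative arc subdivision,
realized as plane–surface slices (reproducible and directly checkable
against closed forms on a sphere):

* Cz by fixed-point iteration: alternately the arc midpoint of
  Nz–Cz–Iz and of LPA–Cz–RPA, to 0.1 mm.
* The midline and coronal arcs subdivided at 5% increments.
* A circumferential ring through Fpz–T7–Oz–T8, intermediate coronal
  chains (AF, F, FC, CP, P, PO) at sixteenth-arc spacing, and a lowest
  ring through Nz and Iz carrying the near-midline reference points
  NFp1/2(h) and I1/2(h).

Head size is scaled linearly by circumference only; nasion–inion or
ear-to-ear based scaling are recognised option names but intentionally
unimplemented.

## Probe registration

Optodes are projected onto the scalp by damped spring relaxation:
anchored optodes sit exactly on their landmark (bit-identical
coordinates), free optodes move under Hookean forces of the rigid
springs (unit spring constant; flexible springs exert none) and are
reprojected to the nearest surface point after every simultaneous
(Jacobi) step, so the result is deterministic and invariant to optode
ordering. Spring lengths are 3D Euclidean distances, matching
source–detector separation semantics. Initialization is a least-squares
rigid fit of the design onto the anchors, which avoids wrong-hemisphere
local minima. Convergence: largest displacement below 0.01 mm; an
infeasible rigid length surfaces as a reported residual or a
convergence error, never silently.

## Cutting

Landmarks and registered optodes are embedded as exact mesh vertices
(area-preserving 1-to-3 face splits, edge splits, or vertex reuse).
The head is then cut by an axial plane through Iz and 15 mm above Nz
(anything below is discarded; a registered optode below this plane is
an error) and two sagittal planes at X = ±x₀, with x₀ chosen so the
coronal arc between the planes is 3/7 of the LPA–Cz–RPA arc ("through
Cz" is read as the over-the-head path; a chord interpretation is
available as an option). On a sphere this gives x₀ = r·sin(3π/14),
which the tests verify. Cutting retriangulates exactly along the
planes, so panel areas plus discarded area equal the original area to
float precision, and cut-line vertices are duplicated with identical
coordinates on both neighbouring panels — that shared 3D polyline later
parameterizes the welding-tab correspondence.

Note that the lowest 10-5 ring (through Nz and Iz) lies mostly below
the axial cut and is deliberately dropped from the panels; only optodes
are guaranteed above the cut.

## Flattening

Each panel flattens by the iterative scheme: (1) a normalized gravity
step toward Z = 0, at most 0.1 mm displacement per step (the largest
vertex moves 0.1 mm, others proportionally); (2) damped spring steps
over the mesh edges with rest lengths equal to the 3D edge lengths
(k = 1, damping 0.5, per-substep displacement cap 0.1 mm, 8 substeps
per gravity step); (3) repeat until every |Z| ≤ 0.1 mm. Those constants
are configuration with the stated defaults.

Three numerical choices matter and were made after measurement:

* **Spring force direction.** With full 3D spring forces the descent
  stalls: the springs' Z-restoration balances the capped gravity pull
  at an amplitude of a few millimetres and the Z criterion is never
  met. The default is therefore a hybrid: 3D forces while the descent
  progresses (they let the shell spread naturally), switching to
  planar (X–Y) forces once progress stops so gravity owns Z
  monotonically. Pure `"planar"` and `"3d"` modes remain selectable.
* **In-plane polish.** The printed criterion is about Z only; stopping
  there leaves in-plane strain far above what area conservation
  requires. After Z convergence an in-plane relaxation (Z frozen, so
  the termination criterion still holds at output) runs until spring
  displacements fall below 10⁻⁴ mm, accelerated by a periodic global
  anisotropic rescale (two-parameter Gauss–Newton) that removes the
  low-frequency compression a pointwise Jacobi iteration removes only
  slowly. A developable cylinder strip then unrolls with < 0.5% edge
  strain.
* **Initial pose.** Side panels start from their area-weighted
  best-fit plane (rigid). The mid panel is a band whose front and back
  ends drop almost vertically to the axial cut; pressing that band
  straight down folds the ends irrecoverably, so it starts from a
  cylindrical unroll about the ear-to-ear axis instead (the band is
  nearly developable about that axis).

Triangle inversions ("flips") are handled by an anti-inversion pass —
a Newton step on the 2D signed area of any triangle inverted against
the majority orientation — applied every iteration so in-plane buckling
is ironed out as it appears. At output, an inverted triangle is
tolerated only if its 2D altitude is below 0.1 mm (a hairline overlap
under print resolution, the same threshold used for slivers created by
cutting); larger folds are locally untangled and re-relaxed, and the
panel is refused if they persist.

Each free probe-node keeps its 3D distances to its three nearest 10-5
vertices: the distances join the relaxation as stiff springs (weight
10) and are re-imposed exactly at the end by trust-region trilateration
followed by a short relaxation with the probe nodes pinned, so the
membrane accommodates without folding. Partners are the closest three
landmarks whose triangle is not nearly collinear (trilateration is
ill-posed along a 10-5 chain). An anchored optode embedded at its
landmark *is* a 10-5 vertex and is carried exactly by the grid itself;
coupling it to neighbours would be degenerate and is skipped. The
output contract — each kept distance within 0.2 mm — is checked by
`distortion_report()` and the test suite.

## 2D panel design

The mid panel's outline is the flattened image of its cut lines; it is
halved along the flattened image of the coronal plane through Cz into
mid-front and mid-back (the halves share that polyline exactly).
Grommets go to the half containing them; one exactly on the line goes
to the front half and is flagged. Side panels take their upper outline
from the flattened sagittal cut line and close it with a parametric
template curve (chin dip, ear clearance, neck rise) stretched laterally
between the upper outline's endpoints; the published cap uses a
hand-tuned curve, so ours is an editable set of control points with the
same structure, not a claimed replica.

Outlines fill with a pointy-top hexagonal lattice, edge 10 mm, beam
width 0.85 mm; boundary-crossing beams are trimmed at the outline and
connected to it (the outline itself prints as a ring of beams), so
interior beams measure exactly one edge.

Welding tabs: lattice beams ending on a seam are paired across the two
panels by the shared arc-length parameter of the 3D cut line; each pair
is repositioned to the midpoint parameter and extended past the seam by
the partner's beam length, rendered at 2 mm width. Unequal counts merge
two-to-one (the two merged beams land 1.5 mm apart so they do not
collapse onto one junction); a grommet within one hex edge (10 mm) of
the seam extends the overlapping tab by another hex edge; a candidate
with no counterpart within one reach stays unpaired with a warning (the
cap is still assemblable there). Candidates must be at least 3 mm long
and not run along the seam, and a tab may not slant more than 60° from
the beam it replaces — all three rules exist because their violations
produce physically meaningless slivers along jagged flattened seams.

## Solids and STL

The beam graph (lattice + outline ring + tabs) is stroked exactly:
each beam contributes a quad bounded by its side lines trimmed by
miter/bevel joins against its angular neighbours at each node
(mixed-width joins allow the bounded negative miter parameter the
geometry requires), and the leftover wedge at each node becomes a small
join polygon. These polygons tile the stroke union, so the extruded
volume is exactly (tiled area) × thickness (0.9 mm default; the 0.8 mm
printed-wall figure reported for finished caps is exposed as
configuration). Each polygon is emitted as its own closed prism:
neighbouring prisms share exactly coincident internal walls, which is
the union-of-shells form slicers consume, and makes every output
watertight by construction (`is_watertight()` checks that every
directed half-edge is matched by its reverse, i.e. the surface bounds a
solid). A single merged boundary surface was tried first and abandoned:
it is numerically brittle exactly at the degenerate junctions real
flattened seams produce.

Grommets are loaded from a library directory (`<id>/grommet.stl`, ids
are the `#name` tokens from the probe design; a watertight annular
default is generated when no vendor library is given), rotated about
+Z, and seated with their base flush on the panel's top surface as an
additional touching closed component. Ear slits are stadium-shaped
holes slanted 20° backward, centered 15 mm above the (flattened)
pre-auricular point — since LPA/RPA themselves fall below the axial
cut, the anchor is the boundary point nearest them in 3D and the offset
is reduced by that distance — punched out of the lattice with a
reinforcing ring, every cut beam reconnected to the ring. Chin/neck
strap holders are slotted loops attached at configurable fractions of
the template outline.

# What the synthetic generator does and does not emulate

The generator reproduces the geometric regime that matters to the
pipeline: head-sized curvature (56 cm circumference), realistic
anteroposterior elongation, a fiducial plane with the standard four
points, and non-developable panels that force a few percent of
flattening strain. It does not emulate: anatomical asymmetry, local
scalp features (ears, occipital bun, inion bump), mesh noise or holes
from photogrammetry, or atlas-specific vertex densities. A green test
therefore establishes the correctness of the geometry pipeline, not
fit or comfort on a real head — the published physical validation
(millimetre-scale grommet placement on printed heads) has no desk-scale
equivalent and is deliberately out of scope; its computational analog
is the coupling-residual and distortion suite.

# Parameters at a glance

| parameter | default | unit | meaning |
|---|---|---|---|
| `HC` | 56 | cm | target head circumference (linear scaling) |
| `hex_edge` | 10 | mm | hexagon edge length of the lattice |
| `lattice_width` | 0.85 | mm | printed beam width |
| `tab_width` | 2 | mm | welding tab width |
| `extrude` | 0.9 | mm | extrusion thickness of the panels |
| `gravity_step` | 0.1 | mm | max vertex displacement per gravity step |
| `z_tol` | 0.1 | mm | flattening convergence bound on |Z| |
| `axial_cut_offset` | 15 | mm | axial cut passes this far above Nz |
| `mid_fraction` | 3/7 | – | coronal-arc share of the mid panel |
| `ear_slit_offset` | 15 | mm | slit center above the pre-auricular point |
| `tab_reach` | 10 | mm | seam search distance for tab candidates |
| `area_tol` | 0.05 | – | allowed flat/3D panel area deviation |

# Known limitations

* Panels are unions of touching closed shells, not a single manifold
  boundary; slicers handle this, strict mesh-repair tools may complain.
* The side-panel template and strap-holder geometry are parametric
  stand-ins, not replicas of the hand-optimized originals.
* Flattening accuracy degrades on strongly non-developable regions
  (a few percent strain on the mid band is inherent); distortion is
  always reported rather than hidden.
* Only circumference-based head scaling is implemented.
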