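# capgen

Generation of 3D-printable flexible head caps for fNIRS and EEG.

fNIRS and EEG measurements stand or fall with sensor placement. `capgen`
turns a scalp surface mesh (or a built-in synthetic head), a probe design
(optodes, spring constraints, anchors to EEG 10-5 landmarks, grommet
types) and a target head circumference HC into **four printable flat cap
panels** (left, right, mid-front, mid-back) as STL files. Printed in
flexible TPU and welded along their overlapping tabs, the panels
reassemble the scalp geometry so every grommet lands on its intended
anatomical position.

The pipeline:

1. **Head model** — scalp mesh with fiducials Nz, Iz, LPA, RPA, scaled
   linearly to HC.
2. **10-5 landmarks** — classical iterative arc subdivision on plane
   slices: Cz is the fixed point of alternating midline/coronal arc
   midpoints; both arcs are subdivided at 5% increments, then a
   circumferential ring and intermediate coronal chains complete the
   grid.
3. **Probe registration** — spring relaxation: anchored optodes sit
   exactly on their landmarks, free optodes relax under rigid-spring
   forces (rest length = source–detector separation, in 3D mm) with
   reprojection to the scalp each step.
4. **Cutting** — an axial plane through Iz and 15 mm above Nz, plus two
   sagittal planes placed so the mid panel spans 3/7 of the coronal
   LPA–Cz–RPA arc (on a sphere: x0 = r·sin(3π/14)).
5. **Flattening** — iterative gravity + spring relaxation: a normalized
   gravity step (max 0.1 mm) pulls vertices toward Z = 0, spring steps
   restore the 3D edge lengths, until all |Z| ≤ 0.1 mm; each probe node
   keeps its distances to its three nearest 10-5 vertices.
6. **Panel design** — outlines from the flattened cut lines (the mid
   panel halved at the coronal line through Cz; side panels closed by a
   parametric chin/ear/neck template), hexagonal lattice (edge 10 mm,
   width 0.85 mm), welding tabs (2 mm) paired across each seam.
7. **Solids** — exact extrusion to 0.9 mm, grommets from a library
   directory (`#id/grommet.stl`), slanted ear slits 15 mm above the
   pre-auricular points, chin/neck strap holders, STL output.

See `vignettes/capgen-methods.Rmd` for the models, parameters and design
choices in detail.

## Worked example

```r
library(capgen)

# a probe: three dummies anchored to Fz/Cz/Pz plus a small rigid patch
op <- data.frame(x = c(0, 0, 0, -30, 0, 30), y = c(60, 0, -60, 80, 85, 80),
                 z = c(60, 95, 60, 30, 35, 30),
                 kind = c("dummy", "dummy", "dummy", "source", "detector", "source"),
                 grommet = "#default", rotation = 0)
probe <- probe_design(op,
                      springs = data.frame(i = c(4, 5, 2), j = c(5, 6, 5),
                                           rest = c(30, 30, NA)),   # NA = flexible
                      anchors = data.frame(optode = 1:3,
                                           landmark = c("Fz", "Cz", "Pz")))

res <- generate_cap("synthetic:56", probe, cap_config(out_dir = "cap_out"))
verify_cap(res)
```

which logs (numbers from an actual run on the default synthetic head):

```
[capgen] head: 1217 vertices, HC 56.0 cm
[capgen] landmarks: 149 10-5 positions
[capgen] probe: 6 optodes registered, rigid-spring residual 0.010 mm
[capgen] cut: x0 = 50.7 mm; panel faces L/M/R = 361/1796/359
[capgen] flatten left: 435 iters, max|Z| 0.020 mm, area ratio 0.997
[capgen] flatten mid: 442 iters, max|Z| 0.026 mm, area ratio 0.977
[capgen] flatten right: 436 iters, max|Z| 0.096 mm, area ratio 0.997
[capgen] tabs: 48 total, 12 merged pairs, 1 near-grommet extensions
[capgen] solid left: 8084 triangles, 1849 mm^3, watertight
[capgen] solid mid-front: 9384 triangles, 5943 mm^3, watertight
[capgen] solid mid-back: 8040 triangles, 2622 mm^3, watertight
[capgen] solid right: 8416 triangles, 1863 mm^3, watertight
```

Reading: the head was scaled to the requested 56 cm circumference; the
sagittal cuts sit 50.7 mm off the midline so the mid panel spans 3/7 of
the coronal arc; every panel flattened to |Z| below the 0.1 mm bound
with flat area within 5% of its curved area (the mid band is the least
developable, hence 0.977); rigid source–detector separations survived
registration to 0.01 mm; and all four emitted solids are watertight.
`verify_cap()` re-checks area tolerance, probe-to-landmark coupling
residuals (≤ 0.2 mm), tab pairing and watertightness, and `cap_out/`
contains `panel_left.stl`, `panel_mid-front.stl`, `panel_mid-back.stl`,
`panel_right.stl` plus `cap_report.json` with distortion metrics, the
grommet manifest, the tab table and the run log.

A command-line interface wraps the same pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "capgen.R", package = "capgen"))')
Rscript "$CLI" generate --head synthetic:56 --probe probe.json --out cap_out
Rscript "$CLI" verify --report cap_out/cap_report.json
Rscript "$CLI" fixtures --make-head head.stl --hc 56
```

Probe designs are read from an AtlasViewer-style `.SD` MAT-file dialect
or the mirrored JSON schema (`?read_probe_design`).

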