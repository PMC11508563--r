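---
title: "Quantifying, planning and guiding curved intra-articular osteotomies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying, planning and guiding curved intra-articular osteotomies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A tibial plateau fracture that heals in a displaced position (a
malunion) leaves the knee with an incongruent joint surface, valgus
instability and early osteoarthritis risk. A corrective osteotomy
re-cuts the bone along the old fracture line and repositions the
fragment anatomically. Because the original fracture surface is curved,
an oscillating saw (a planar tool) cannot reproduce it; the approach
implemented here composes the cut from many small drill trajectories
("Panflute" concept) whose individually controlled depths protect the
posterior neurovascular structures, and steers the freed fragment to its
planned pose with a sequence of three 3D-printed patient-specific
guides.

`panflute` implements the full planning chain on surface meshes and
simulated CT, with a synthetic proximal-tibia phantom that carries exact
ground truth for every stage.

## Deformity model (Q3DCT)

The fragment's malposition is expressed as six parameters measured
against the mirrored contralateral bone: translations `x`
(anterior-posterior), `y` (medial-lateral), `z` (cranial-caudal) in mm,
and rotations `zeta` (sagittal), `theta` (coronal), `phi` (axial) in
degrees. The package fixes the conventions the source imaging chain
leaves open:

* **Axes.** Right-handed patient-like frame: x anterior(-) to
  posterior(+), y lateral(-) to medial(+) for a right leg, z caudal(-)
  to cranial(+). `anatomical_frame(side = "left")` flips the reading of
  the y direction labels.
* **Euler order.** Intrinsic z-x-y: `R = Rz(phi) Rx(theta) Ry(zeta)`.
  Recomposition through `deformity_transform()` inverts
  `decompose_transform()` to machine precision away from `theta` near
  90 degrees, where the gimbal convention `phi = 0` is reported and
  flagged.
* **Rotation centre.** The area-weighted surface centroid of the
  template fragment patch (`mesh_centroid()`). The reported
  translations depend on this choice; an area-weighted centroid is a
  tessellation-independent surface integral, whereas a plain vertex
  mean shifts by millimetres between meshing routes (vertex density is
  not comparable between a marching-cubes CT surface and an analytic
  mesh). The phantom implants deformities about the same construct, so
  recovery is well defined.
* **Mirroring plane.** Any valid mirror plane differs from any other by
  a rigid motion, which the shaft registration absorbs; the default is
  the mid-sagittal plane through the contralateral centroid.

## Registration

Two registrations implement the pipeline:

* `align_shaft()`: point-to-plane ICP of the moving bone's shaft region
  (default: faces below 40 percent of the proximal-distal extent) onto
  the fixed bone. Deterministic: centroid initialization, a PCA
  axis-sign fallback when badly seated, iteration cap 100, convergence
  1e-6 mm.
* `fit_fragment_transform()`: point-to-point ICP between the fragment
  patches, trimmed to 90 percent inliers, with one refinement that
  matters in practice: the trim threshold never cuts below five times
  the median residual. On outlier-free surfaces residuals are spatially
  correlated (voxel discretization, partial volume), and a plain
  quantile cut then discards coherent *regions* rather than outliers,
  dragging the fit about a degree along the patch's sloppiest rotation
  mode. With the noise-floor guard the trim only engages on genuine
  mismatches (e.g. the depression defect), where it restores the
  intended robustness (a fragment with 10 percent of its surface
  deleted is still recovered to about 0.1 mm / 0.2 deg).

Both run coarse-to-fine (a 1000-point subsample to convergence, then
the full subsample for 30 iterations), which is faster *and* slightly
more accurate than a single long full-resolution run. Everything is
deterministic; there is no random sampling anywhere in the pipeline.

Registration quality on clean meshes is essentially exact (errors below
0.02 mm / 0.02 deg); through the full simulated-CT chain at 0.5 mm
voxels the six parameters come back within about 0.1-0.25 mm and
0.1-0.45 deg.

## Segmentation

`threshold_bone()` implements the clinical recipe: Hounsfield threshold
at 226 (inclusive), `region_grow()` with 26-connectivity (keeps thin
cortical shells connected), `split_mask()` for bones touching through
thin bridges (erode, relabel, constrained regrowth). Metal voxels (HU
>= 3000 by default) are excluded with a warning; no artifact correction
is attempted.

`extract_surface()` is the contract surface: the 0.5 iso-level of the
binary mask. `segment_bone()` additionally offers the `"iso"` route
used by the quantification pipeline: the surface is placed at the
cortical half-maximum iso-level of the HU field restricted to the grown
component. On volumes with partial-volume information this is the
standard sub-voxel bone-surface localization; unlike the binary-mask
surface (or any fixed low threshold) its position is unbiased with
respect to surface orientation, which matters because the displaced
fragment samples orientations differently from the intact template.
Smoothing (`taubin_smooth()`) is exposed but off by default.

## Osteotomy planning

The old fracture line is an input polyline (`fracture_trace()`), not a
detected feature. `plan_trajectories()` resamples it at uniform arc
length (2.5 mm centre-to-centre by default: the drill holes need not
overlap because the osteotome completes the cut between them) and
orthogonalizes the user-chosen approach vector against the local trace
tangent so adjacent drill segments rule a smooth sheet.
`compute_depth()` measures the in-bone chord to the far cortex and
subtracts the posterior safety margin (2 mm default; the clinical goal
is stated, the number is this package's choice), clamping to at least
1 mm and never beyond the exit; chords shorter than margin + 1 mm are
flagged `too_shallow` and dropped from plans. The drilling direction in
the bundled pipeline runs anterior to posterior, so the margin is
genuinely posterior.

## Guide generation

All three guides are built from one composite continuous level-set
field - signed distance of the bone (and in-situ plate) for the
conforming shell, analytic cylinders for tubes and channels - and
surfaced once. This is more accurate than iterated mesh booleans and
cannot produce the accumulation artifacts of pairwise CSG. Key
parameters (exposed, with defaults from common FDM/SLS practice):
print clearance added to drill/wire bores 0.1 mm, bone/plate fit gap
0.2 mm, shell thickness 3 mm.

* **Cutting guide**: bone-conforming shell over the footprint region
  (including an anterior-shaft extension and the in-situ plate's
  imprint), plus one tube per trajectory with the Panflute length
  `L_i = working_length - depth_i - standoff`, so a fixed drill
  bottoms out exactly at its planned depth; `standoff` is the fit gap
  plus shell thickness. Conservation (`standoff + L_i + depth_i`
  constant) is asserted per hole. Because adjacent bores at 2.5 mm
  spacing leave under half a millimetre of wall, the interference check
  guards the *channels*: neighbouring bore axes must stay a wall's
  width apart, and the merged outer tube bodies are legitimate (the
  physical guide's tubes fuse into one flute body).
* **Intermediate guide**: shaft shell with drill channels replicating
  the new plate's distal screw-hole axes and K-wire channels identical
  (bitwise) to the cutting guide's - the shared physical reference.
* **Reposition guide**: negative imprint of the new plate with fit
  clearance, kept off the bone, carrying the same K-wire channels.
  Seating is verified by a linearized contact solve
  (`pose_from_constraints()`): plate surface samples contribute
  area-weighted point-to-plane constraints (end caps excluded - the
  guide slides onto the plate), each wire two lateral constraints per
  sample. A rank-deficient 6-dof constraint matrix (straight plate, no
  wires) is reported `underdetermined`; otherwise a pose perturbed by
  millimetres returns to the planned pose to numerical precision.

Two audit conventions deserve a note. A "through-channel" is checked as
an unobstructed axis ray over the channel span *plus* wall material on
a radially offset parallel ray (a literal reading - the axis ray
crossing the boundary exactly twice - would describe a blocked bore).
And where a guide's modelled extent reaches the sampling-grid edge
(e.g. a plate extension truncated by the region of interest), the field
is closed at the boundary so the solid ends in a flat face and remains
watertight.

## The phantom

`phantom_spec()` / `induce_malunion()` build a stylized proximal-tibia
surrogate - **not** a statistical tibia. The pipeline's contracts are
geometric, so anatomical realism is unnecessary; what *is* reproduced
are the features registration legitimately relies on: a triangular
shaft cross-section (the anterior crest, which pins axial rotation of
the shaft alignment), mild plateau torsion, posterior slope and varus
inclination, a tuberosity bump, and shallow condylar dishes (which pin
the fragment's rotations). The lateral split fragment is cut off by a
bicubic Bezier sheet; the deformity is implanted with exactly the
decomposition's Euler convention about the template patch centroid, so
every parameter is recoverable by construction. Defaults are the study
conditions: the case deformity (5.4 / 2.9 / 5.9 mm, 10.2 / 23 / 0.8
deg, signed into the package's axis conventions), zero contralateral
asymmetry noise, no depression defect (the depression is exercised
separately, since the split-depression case's central fragment
elevation is out of scope).

`voxelize_ct()` simulates acquisition: exact per-voxel occupancy
fractions (sub-column sampling with analytic z-integration) mix
boundary HU as partial volume does, a separable binomial blur stands in
for the scanner point-spread function, and tissues map to cortical 700
/ trabecular 300 / soft 40 / air -1000 HU, so the 226 threshold
separates bone from soft tissue exactly as intended. The optional metal
plate rasterizes at 8000 HU with deterministic radial streak noise -
a *stylized* stand-in for scatter used only to demonstrate monotone
segmentation degradation, not a physical artifact model.

`label_against_truth()` / `label_template()` stand in for the manual
region marking a surgeon performs in planning software, with the
phantom's exact truth as the marker. They deliberately exclude two
bands a careful human would also avoid: faces within 1.2 mm of other
bone in the displaced position (partial volume corrupts surfaces in
near-contact) and the crease band within 1.5 mm of the fracture line
(CT rounds sharp edges; the intact template has no edge there at all).

What passing these tests does *not* show: performance on real anatomy
with cartilage, osteophytes and genuine metal artifacts, on scanners
with anisotropic resolution, or with the inter-operator variability of
manual segmentation. The phantom isolates the geometry; it cannot
validate the imaging physics.

## Numerical choices

* Iso-surfaces by marching tetrahedra (six-tetrahedra cube subdivision
  sharing the main diagonal), which is watertight and consistently
  wound by construction; coincident vertices from field creases are
  welded and the collapsed slivers dropped, preserving closure.
* Sampling grids carry a small fixed irrational origin offset so grid
  points never land exactly on feature tangencies (deterministic
  tie-breaking; the package uses no randomness outside the phantom's
  seeded noise).
* Degenerate ray hits (edge/vertex grazes) re-cast from an origin
  jittered 1e-6 mm along a fixed direction.
* Mesh booleans are voxel CSG at 0.3 mm by default (volumes within
  about 2 percent for guide-sized parts); guide fields use exact
  point-to-triangle distances in a one-voxel band and chamfer
  propagation elsewhere (error of a few percent of the distance, which
  only matters millimetres away from any emitted surface).
* Default problem sizes: phantom meshes at 0.8 mm marching grids
  (about 240k faces), simulated CT at 0.5 mm, guide fields at 0.2 mm
  (0.25-0.4 mm in the test suite's smaller configurations), ICP on
  4000-8000 point subsamples. The test suite's property loops use a
  1.2 mm phantom; accuracy there is limited by the method, not the
  mesh.

## Known limitations

* The quantification reports the fragment's 6-dof pose error only; no
  articular step-off/gap map, no statistical shape model.
* The fracture trace is an input; the package does not detect the old
  fracture line.
* The parametric slab plate is a geometric stand-in for anatomical
  locking plates; old and new plates share the proximal hole pattern so
  the new plate can reuse the old proximal screw holes.
* Guide printability is geometric (watertight, clearances); slicing,
  supports and sterilization are out of scope, as are soft-tissue
  collisions (e.g. patellar tendon interference over an anterior
  footprint).
* `assess_postop()` reports are invariant to moving both models
  rigidly to within the registration's numerical repeatability (about
  5e-3 mm / deg), not to machine precision: ICP correspondences are
  re-formed in the moved frame.
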