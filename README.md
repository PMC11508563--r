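# panflute

Planning toolkit for **curved intra-articular corrective osteotomies**
of tibial plateau malunions.

A tibial plateau fracture that heals displaced leaves an incongruent
joint. Correcting it means re-cutting the bone along the *old fracture
line* — a curved surface no oscillating saw can follow — and moving the
freed fragment back to its anatomical position. `panflute` implements
the whole planning chain:

* **Quantify** the malunion against the mirrored contralateral bone
  (quantitative 3D CT, "Q3DCT"): segment both bones from CT
  (Hounsfield threshold ≥ 226, region growing, surface extraction),
  mirror and shaft-register the intact side as a template, fit the
  fragment's rigid displacement by trimmed ICP, and decompose it into
  six parameters — translations (x, y, z) in mm along the
  anterior-posterior / medial-lateral / cranial-caudal axes and
  rotations (ζ sagittal, θ coronal, φ axial) in degrees, with the
  intrinsic z–x–y convention `R = Rz(φ) Rx(θ) Ry(ζ)` about the
  template-fragment centroid.
* **Plan** the curved osteotomy as an ordered set of drill
  trajectories along the old fracture line ("Panflute" concept), each
  with a depth computed to stop a posterior safety margin short of the
  far cortex.
* **Generate** the three printable patient-specific guides: the
  Panflute cutting guide whose per-hole tube lengths
  `L_i = working_length − depth_i − standoff` make a fixed drill
  bottom out at each planned depth, the intermediate pre-drill guide
  for the new plate's distal screws, and the reposition guide that
  envelops the new plate to steer the fragment to its planned pose —
  all three referencing one shared K-wire set.
* **Assess** the achieved position against the plan (planned vs
  postoperative six-parameter residual).

Everything is exercised on a parametric **synthetic proximal-tibia
phantom** with exactly known ground truth (implanted deformity, cut
surface, fracture trace, simulated CT with partial volume and scanner
blur), so each pipeline stage — and the chain end-to-end — is validated
against truth, not against itself.

## Worked example

```r
library(panflute)

# the case fixture: a right proximal tibia whose lateral split fragment
# is displaced by a known six-parameter deformity, plus the intact
# mirrored contralateral side
case <- phantom_fixture("paper_case")
#> <phantom_case: deformity (5.4, -2.9, -5.9) mm / (10.2, 23.0, 0.8) deg, noise sigma 0 mm>

report <- quantify_malunion(case$affected, case$contralateral,
                            mirror_plane = case$mirror_plane)
print(report)
#> Deformity report (pre)
#>   x (anterior-posterior):    5.40 mm posterior
#>   y (medial-lateral):        2.90 mm lateral
#>   z (cranial-caudal):        5.90 mm caudal
#>   zeta  (sagittal):         10.20 deg
#>   theta (coronal):          23.00 deg
#>   phi   (axial):             0.81 deg
```

The report reads: the fragment sits 5.4 mm posterior, 2.9 mm lateral
and 5.9 mm caudal of its anatomical position, tilted 10.2° in the
sagittal plane, 23° in the coronal plane and 0.8° axially — the
implanted ground truth, recovered through mirroring, registration and
decomposition. `coef(report)` returns the six signed values; from
here, `plan_osteotomy()` builds the depth-controlled drill plan,
`design_cutting_guide()` / `design_intermediate_guide()` /
`design_reposition_guide()` produce printable STL solids
(`export_guides()`), and `assess_postop()` closes the loop after
reduction. `run_pipeline(pipeline_config())` chains all stages and
writes a provenance manifest.

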