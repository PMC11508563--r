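test_that("the contralateral side is an exact mirror at zero noise, and
           generation is deterministic", {
  spec <- phantom_spec(mesh_resolution = 1.5)
  p1 <- generate_tibia_pair(spec)
  p2 <- generate_tibia_pair(spec)
  expect_identical(p1$right$vertices, p2$right$vertices)
  expect_identical(p1$left$vertices, p2$left$vertices)
  back <- mirror_mesh(p1$left, p1$mirror_plane)
  expect_lt(max(abs(back$vertices - p1$right$vertices)), 1e-9)
  expect_true(is_watertight(p1$right))
  expect_true(is_watertight(p1$left))
})

test_that("asymmetry noise produces the expected mean surface offset", {
  # |N(0, sigma)| has mean sigma * sqrt(2/pi) ~= 0.24 mm at sigma 0.3
  ds <- vapply(0:9, function(s) {
    spec <- phantom_spec(seed = 100L + s, asymmetry_noise_sigma = 0.3,
                         mesh_resolution = 2)
    p <- generate_tibia_pair(spec)
    back <- mirror_mesh(p$left, p$mirror_plane)
    idx <- seq(1, nrow(back$vertices), by = 7)
    mean(mesh_closest(p$right, back$vertices[idx, , drop = FALSE])$distance)
  }, 0)
  expect_gt(mean(ds), 0.2)
  expect_lt(mean(ds), 0.3)
})

test_that("the malunion cut conserves volume and zero deformity leaves
           the bone intact", {
  case <- coarse_clean()
  v <- mesh_volume(case$fragment) + mesh_volume(case$remainder)
  expect_equal(v, mesh_volume(case$intact), tolerance = 0.02)
  # affected free surface == intact surface when no deformity is
  # implanted (the interface walls are interior and excluded)
  free <- submesh(case$affected,
                  which(case$affected$regions != "interface"))
  d <- mesh_closest(case$intact, free$vertices)$distance
  expect_lt(stats::quantile(d, 0.99), 0.3)
  # applying the inverse truth restores the fragment onto the intact bone
  case2 <- coarse_case()
  back <- transform_mesh(
    transform_mesh(case2$fragment, case2$true_transform),
    rt_inverse(case2$true_transform))
  expect_lt(max(abs(back$vertices - case2$fragment$vertices)), 1e-9)
})

test_that("the depression defect carves the articular surface", {
  spec0 <- phantom_spec(mesh_resolution = 1.5)
  spec1 <- phantom_spec(mesh_resolution = 1.5, depression_depth = 4,
                        depression_radius = 8)
  f0 <- induce_malunion(spec0)$fragment
  f1 <- induce_malunion(spec1)$fragment
  expect_lt(mesh_volume(f1), mesh_volume(f0))
})

test_that("the fracture trace lies on the bone surface along the cut", {
  case <- coarse_case()
  p <- case$trace$points
  expect_true(case$trace$closed)
  d <- mesh_closest(case$intact, p)$distance
  expect_lt(max(d), 1)
  ns <- asNamespace("panflute")
  sv <- abs(ns$.cut_field(case$spec, p))
  expect_lt(max(sv), 0.5)
})

test_that("simulated CT maps tissue HU faithfully", {
  case <- memo("ct_coarse", {
    induce_malunion(phantom_spec(mesh_resolution = 1.5))
  })
  vol <- voxelize_ct(case, spacing = 1.2, side = "contralateral",
                     psf = FALSE)
  # exterior corners are air, bone interior is trabecular
  expect_equal(vol$voxels[1, 1, 1], -1000)
  expect_true(any(vol$voxels == 300))
  expect_true(any(abs(vol$voxels - 40) < 1e-9))
  expect_lte(max(vol$voxels), 700)
})

test_that("plate scatter degrades segmentation overlap monotonically", {
  spec_clean <- phantom_spec(mesh_resolution = 1.5)
  spec_scatter <- phantom_spec(mesh_resolution = 1.5, with_plate = TRUE,
                               scatter_amplitude = 400)
  c1 <- induce_malunion(spec_clean)
  c2 <- induce_malunion(spec_scatter)
  truth <- voxelize_ct(c1, 1.0, "affected", psf = FALSE)
  gt <- truth$voxels >= 226
  seg <- function(case) {
    v <- voxelize_ct(case, 1.0, "affected")
    suppressWarnings(threshold_bone(v)$labels == 1L)
  }
  d_clean <- dice(seg(c1), gt)
  d_scatter <- dice(seg(c2), gt)
  expect_gt(d_clean, d_scatter)
})

test_that("named fixtures carry the transcribed ground truth exactly", {
  case <- paper_case_full()
  expect_equal(unname(case$deformity),
               c(5.4, -2.9, -5.9, 10.2, 23, 0.8))
  pc <- memo("paper_postop", phantom_fixture("paper_postop"))
  expect_equal(unname(pc$residual), c(0.5, -1.0, 0.6, 3.8, 1.3, 0.1))
  cl <- coarse_clean()
  expect_true(all(cl$deformity == 0))
  expect_error(phantom_fixture("nonsense"))
})

test_that("set_deformity re-implants consistently with the truth
           transform", {
  base <- coarse_clean()
  case <- set_deformity(base, c(dx = 3, theta = 12))
  expect_equal(unname(case$deformity["dx"]), 3)
  rep <- decompose_transform(case$true_transform,
                             center = case$center)
  expect_equal(unname(coef(rep)), unname(case$deformity),
               tolerance = 1e-9)
})
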