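test_that("voxel CSG reproduces closed-form volumes", {
  cube <- mesh_box(c(0, 0, 0), c(20, 20, 20))
  # idempotence
  u <- boolean_op(cube, cube, "union")
  expect_true(is_watertight(u))
  expect_equal(mesh_volume(u), 8000, tolerance = 0.02)
  # additivity of a disjoint union
  cube2 <- mesh_box(c(40, 0, 0), c(10, 10, 10))
  u2 <- boolean_op(cube, cube2, "union")
  expect_equal(mesh_volume(u2), 9000, tolerance = 0.02)
  # cube minus a through-cylinder
  cyl <- make_tube(c(0, 0, -15), c(0, 0, 1), 30, 0, 8)
  d <- boolean_op(cube, cyl, "difference")
  expect_true(is_watertight(d))
  expect_equal(mesh_volume(d), 8000 - pi * 16 * 20, tolerance = 0.02)
})

test_that("booleans reject non-watertight operands with diagnostics", {
  cube <- mesh_box(c(0, 0, 0), c(5, 5, 5))
  open <- trimesh(cube$vertices, cube$faces[-1, , drop = FALSE])
  expect_error(boolean_op(open, cube), "watertight")
  expect_error(boolean_op(cube, open), "open")
})

test_that("offset shells sit at clearance and thickness off the bone", {
  sp <- mesh_sphere(c(0, 0, 0), 20, n = 96)
  fc <- face_centers(sp)
  sp <- set_region(sp, which(fc[, 3] > 14), "patch")
  sh <- offset_shell(sp, "patch", clearance = 0.2, thickness = 3,
                     resolution = 0.25)
  expect_true(is_watertight(sh))
  r <- sqrt(rowSums(sh$vertices^2))
  # away from the lateral rim, vertices live on the two concentric
  # spherical surfaces
  core <- sh$vertices[, 3] > 0.85 * r
  expect_lt(min(r[core]), 20.2 + 0.2)
  expect_gt(max(r[core]), 23.2 - 0.2)
  expect_gt(min(r), 20.2 - 0.2)
  expect_lt(max(r), 23.2 + 0.25)
  # signed-distance contract: inner surface about `clearance` off the
  # bone, sampled away from the lateral rim wall
  inner <- r < 21 & sh$vertices[, 3] > 0.92 * r
  cl <- mesh_closest(sp, sh$vertices[inner, , drop = FALSE])
  expect_true(all(cl$distance > 0.2 - 0.2 & cl$distance < 0.2 + 0.25))
})

test_that("offset shell of a plane patch is a slab of set thickness", {
  slab <- slab_bone()
  sh <- offset_shell(slab, "footprint", clearance = 0, thickness = 3,
                     resolution = 0.3)
  expect_true(is_watertight(sh))
  top <- max(slab$vertices[, 3])
  z <- sh$vertices[, 3]
  expect_lt(max(z), top + 3 + 0.3)
  expect_gt(max(z), top + 3 - 0.3)
})

test_that("offset shell rejects empty or unstable footprints", {
  sp <- mesh_sphere(c(0, 0, 0), 20, n = 48)
  sp <- set_region(sp, 1L, "tiny")
  expect_error(offset_shell(sp, "tiny", 0.2, 3), "small")
  expect_error(offset_shell(sp, integer(), 0.2, 3), "empty")
})
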