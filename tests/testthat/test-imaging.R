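test_that("bone thresholding is inclusive and excludes metal", {
  vol <- ct_volume(array(-1000, c(8, 8, 8)), rep(1, 3))
  expect_equal(sum(threshold_bone(vol)$labels), 0)
  vol2 <- ct_volume(array(226, c(8, 8, 8)), rep(1, 3))
  expect_equal(sum(threshold_bone(vol2)$labels), 8^3)
  hu <- array(40, c(6, 6, 6))
  hu[2:5, 2:5, 2:5] <- 700
  hu[3, 3, 3] <- 8000
  vol3 <- ct_volume(hu, rep(1, 3))
  expect_warning(m <- threshold_bone(vol3), "metal")
  expect_equal(sum(m$labels), 4^3 - 1)
  expect_equal(sum(threshold_bone(vol3, exclude_metal = FALSE)$labels),
               4^3)
})

test_that("thresholding a phantom CT matches generator ground truth", {
  hu <- array(40, c(12, 12, 12))
  hu[3:10, 3:10, 3:10] <- 300
  hu[5:8, 5:8, 5:8] <- 700
  vol <- ct_volume(hu, rep(0.7, 3))
  m <- threshold_bone(vol, 226)
  expect_equal(sum(m$labels), sum(hu >= 226))
})

test_that("region growing keeps exactly the seeded 26-component", {
  a <- array(0L, c(12, 12, 6))
  a[2:4, 2:4, 2:4] <- 1L
  a[8:10, 8:10, 2:4] <- 1L
  m <- label_mask(a, rep(1, 3))
  g <- region_grow(m, c(3, 3, 3))
  expect_equal(sum(g$labels), 27)
  expect_equal(sum(g$labels[8:10, 8:10, 2:4]), 0)
  # idempotence on a single blob
  g2 <- region_grow(g, c(3, 3, 3))
  expect_identical(g2$labels, g$labels)
  expect_error(region_grow(m, c(6, 6, 3)), "background")
})

test_that("split_mask separates seeded bones, even across thin bridges", {
  a <- array(0L, c(20, 10, 10))
  a[2:8, 3:8, 3:8] <- 1L
  a[12:18, 3:8, 3:8] <- 1L
  m <- label_mask(a, rep(1, 3))
  s <- split_mask(m, rbind(c(4, 5, 5), c(15, 5, 5)))
  expect_equal(sort(unique(as.vector(s$labels))), c(0L, 1L, 2L))
  expect_true(all(s$labels[2:8, 3:8, 3:8] == 1L))
  expect_true(all(s$labels[12:18, 3:8, 3:8] == 2L))
  # one-voxel bridge between the blobs
  a2 <- a
  a2[9:11, 5, 5] <- 1L
  m2 <- label_mask(a2, rep(1, 3))
  s2 <- split_mask(m2, rbind(c(4, 5, 5), c(15, 5, 5)))
  truth1 <- a
  truth1[12:18, , ] <- 0L
  truth2 <- a
  truth2[2:8, , ] <- 0L
  expect_gt(dice(s2$labels == 1L, truth1 == 1L), 0.99)
  expect_gt(dice(s2$labels == 2L, truth2 == 1L), 0.99)
  # foreground is partitioned
  expect_equal(sum(s2$labels != 0L), sum(a2))
})

test_that("surface extraction recovers solids at voxel accuracy", {
  sp <- mesh_sphere(c(0, 0, 0), 15, n = 96)
  vm <- voxelize_mesh(sp, 0.5)
  surf <- extract_surface(vm, 1L)
  expect_true(is_watertight(surf))
  expect_equal(mesh_volume(surf), 4 / 3 * pi * 15^3, tolerance = 0.02)
  # mean surface error below half a voxel
  d <- mesh_closest(sp, surf$vertices)$distance
  expect_lt(mean(d), 0.25)
  # single voxel: a watertight hull of roughly one voxel volume
  one <- array(0L, c(5, 5, 5))
  one[3, 3, 3] <- 1L
  s1 <- extract_surface(label_mask(one, rep(1, 3)), 1L)
  expect_true(is_watertight(s1))
  # tetrahedral hull of a lone voxel: half the voxel volume is the
  # discretization floor
  expect_gte(mesh_volume(s1), 0.45)
  expect_lte(mesh_volume(s1), 1.55)
  expect_error(extract_surface(label_mask(one, rep(1, 3)), 7L),
               "not present")
})

test_that("voxelize -> extract -> voxelize closes at high Dice", {
  sp <- mesh_sphere(c(0, 0, 0), 12, n = 96)
  vm <- voxelize_mesh(sp, 0.5)
  surf <- extract_surface(vm, 1L)
  vm2 <- voxelize_mesh(surf, 0.5, origin = vm$origin,
                       dims = dim(vm$labels))
  expect_gte(dice(vm$labels, vm2$labels), 0.98)
})

test_that("volume I/O round-trips NIfTI and MetaImage", {
  arr <- array(rnorm(6 * 5 * 4, 100, 300), c(6, 5, 4))
  vol <- ct_volume(arr, c(0.5, 0.5, 1), c(1, 2, 3))
  fn <- tempfile(fileext = ".nii.gz")
  write_ct_volume(vol, fn)
  back <- read_ct_volume(fn)
  expect_equal(dim(back$voxels), dim(arr))
  expect_equal(as.vector(back$voxels), as.vector(arr), tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing)
  fm <- tempfile(fileext = ".mha")
  write_ct_volume(vol, fm)
  back2 <- read_ct_volume(fm)
  expect_equal(back2$voxels, arr)
  expect_equal(back2$origin, c(1, 2, 3))
})
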