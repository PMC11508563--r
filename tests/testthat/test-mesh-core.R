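test_that("rigid transforms compose, invert and round-trip", {
  set.seed(11)
  for (i in 1:20) {
    R <- euler_zxy(runif(1, -180, 180), runif(1, -80, 80),
                   runif(1, -180, 180))
    T <- rigid_transform(R, rnorm(3, sd = 20))
    v <- matrix(rnorm(30), 10)
    back <- apply_transform(rt_inverse(T), apply_transform(T, v))
    expect_lt(max(abs(back - v)), 1e-9)
  }
  # composition associativity
  Ts <- replicate(3, rigid_transform(euler_zxy(runif(1, -90, 90), 10, 5),
                                     rnorm(3)), simplify = FALSE)
  a <- rt_compose(rt_compose(Ts[[1]], Ts[[2]]), Ts[[3]])
  b <- rt_compose(Ts[[1]], rt_compose(Ts[[2]], Ts[[3]]))
  expect_lt(max(abs(a$rotation - b$rotation)), 1e-12)
  expect_lt(max(abs(a$translation - b$translation)), 1e-12)
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
})

test_that("transform_mesh moves vertices rigidly and keeps topology", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  same <- transform_mesh(cube, rigid_transform())
  expect_equal(same$vertices, cube$vertices)
  shifted <- transform_mesh(cube, rigid_transform(diag(3), c(1, 2, 3)))
  expect_equal(colMeans(shifted$vertices) - colMeans(cube$vertices),
               c(1, 2, 3))
  expect_identical(shifted$faces, cube$faces)
})

test_that("mirroring reflects points, preserves closure, is involutive", {
  p <- plane(c(0, 3, 0), c(0, 2, 0))   # normal normalized internally
  expect_equal(sum(p$normal^2), 1)
  sp <- mesh_sphere(c(5, -2, 1), 8, n = 32)
  m <- mirror_mesh(sp, p)
  # reflection: distances to the plane flip sign
  d0 <- (sp$vertices %*% p$normal) - sum(p$point * p$normal)
  d1 <- (m$vertices %*% p$normal) - sum(p$point * p$normal)
  expect_lt(max(abs(d0 + d1)), 1e-12)
  # windings flipped so the solid stays outward-oriented
  expect_gt(mesh_volume(m), 0)
  expect_true(is_watertight(m))
  twice <- mirror_mesh(m, p)
  expect_lt(max(abs(twice$vertices - sp$vertices)), 1e-9)
})

test_that("ray casting matches the analytic sphere and reports misses", {
  sp <- mesh_sphere(c(0, 0, 0), 10, n = 96)
  h <- ray_intersect(sp, c(-20, 0, 0), c(1, 0, 0))
  expect_equal(nrow(h), 2)
  expect_equal(h$distance, c(10, 30), tolerance = 0.01)
  expect_equal(nrow(ray_intersect(sp, c(-20, 15, 0), c(1, 0, 0))), 0)
})

test_that("ray parity is even for exterior origins on watertight solids", {
  tube <- make_tube(c(0, 0, 0), c(0, 0, 1), 20, 3, 8)
  set.seed(7)
  for (i in 1:50) {
    o <- c(30, 0, 10) + rnorm(3)
    d <- rnorm(3)
    h <- ray_intersect(tube, o, d)
    expect_equal(nrow(h) %% 2, 0)
  }
})

test_that("ray distances agree with a voxel ray-marching oracle", {
  sp <- mesh_sphere(c(0, 0, 0), 10, n = 96)
  mask <- voxelize_mesh(sp, 0.2)
  set.seed(3)
  n_checked <- 0
  for (i in 1:100) {
    o <- c(-25, 0, 0) + rnorm(3, sd = 4)
    tgt <- rnorm(3, sd = 3)          # aim well inside the sphere
    d <- tgt - o
    d <- d / sqrt(sum(d^2))
    hits <- ray_intersect(sp, o, d)
    oracle <- voxel_ray_oracle(mask, o, d, step = 0.05, tmax = 60)
    if (nrow(hits) == length(oracle) && nrow(hits) > 0) {
      expect_lt(max(abs(hits$distance - oracle)), 0.3)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 80)
})

test_that("tube meshes are watertight with near-analytic volume", {
  tb <- make_tube(c(0, 0, 0), c(0, 0, 1), 10, 1.9, 5)
  expect_true(is_watertight(tb))
  expect_equal(mesh_volume(tb), pi * 10 * (2.5^2 - 0.95^2),
               tolerance = 0.01)
  solid <- make_tube(c(1, 2, 3), c(1, 1, 0), 10, 0, 4)
  expect_true(is_watertight(solid))
  expect_equal(mesh_volume(solid), pi * 10 * 4, tolerance = 0.01)
  set.seed(21)
  for (i in 1:20) {
    L <- runif(1, 2, 40)
    ro <- runif(1, 2, 8)
    ri <- runif(1, 0, ro - 0.5)
    d <- rnorm(3)
    tb <- make_tube(rnorm(3), d, L, 2 * ri, 2 * ro)
    expect_equal(mesh_volume(tb), pi * L * (ro^2 - ri^2),
                 tolerance = 0.01)
  }
  expect_error(make_tube(c(0, 0, 0), c(0, 0, 1), -1, 1, 2))
  expect_error(make_tube(c(0, 0, 0), c(0, 0, 1), 5, 3, 2))
})

test_that("watertightness diagnostics detect open meshes", {
  cube <- mesh_box(c(0, 0, 0), c(2, 2, 2))
  expect_true(is_watertight(cube))
  open <- trimesh(cube$vertices, cube$faces[-1, , drop = FALSE])
  expect_false(is_watertight(open))
  expect_gt(nrow(open_edges(open)), 0)
})

test_that("region utilities extract and label face subsets", {
  cube <- mesh_box(c(0, 0, 0), c(2, 2, 2))
  cube <- set_region(cube, 1:4, "side")
  expect_equal(length(region_faces(cube, "side")), 4)
  sub <- submesh(cube, "side")
  expect_equal(nrow(sub$faces), 4)
  expect_lt(max(abs(mesh_centroid(cube) - c(0, 0, 0))), 1e-9)
})

test_that("STL round-trips preserve geometry, labels and bytes", {
  tb <- make_tube(c(0, 0, 0), c(0.3, 0.1, 1), 12, 2, 6, segments = 32)
  tb <- set_region(tb, 1:10, "marked")
  f1 <- tempfile(fileext = ".stl")
  write_stl(tb, f1)
  back <- read_stl(f1)
  expect_equal(nrow(back$vertices), nrow(tb$vertices))
  expect_equal(nrow(back$faces), nrow(tb$faces))
  expect_equal(mesh_volume(back), mesh_volume(tb),
               tolerance = 1e-6)
  expect_equal(region_faces(back, "marked"), 1:10)
  # re-export is bit-identical
  f2 <- tempfile(fileext = ".stl")
  write_stl(back, f2)
  f3 <- tempfile(fileext = ".stl")
  write_stl(read_stl(f2), f3)
  expect_identical(unname(tools::md5sum(f2)), unname(tools::md5sum(f3)))
  # ASCII route
  fa <- tempfile(fileext = ".stl")
  write_stl(tb, fa, ascii = TRUE)
  back2 <- read_stl(fa)
  expect_equal(mesh_volume(back2), mesh_volume(tb), tolerance = 1e-6)
})
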