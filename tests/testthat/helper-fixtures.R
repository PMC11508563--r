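# Shared fixtures, memoized across test files (phantom generation is the
# expensive step; everything is deterministic).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# coarse mesh-route phantom with the case deformity
coarse_case <- function() {
  memo("coarse_case", induce_malunion(phantom_spec(mesh_resolution = 1.2)))
}

# coarse phantom with zero deformity (basis for set_deformity loops)
coarse_clean <- function() {
  memo("coarse_clean", induce_malunion(
    phantom_spec(deformity = c(dx = 0, dy = 0, dz = 0, zeta = 0,
                               theta = 0, phi = 0),
                 mesh_resolution = 1.2)))
}

# full-resolution case fixture used by the acceptance suite
paper_case_full <- function() {
  memo("paper_case_full", phantom_fixture("paper_case"))
}

# slab "bone" with a labelled top footprint, for guide unit tests
slab_bone <- function() {
  memo("slab_bone", {
    m <- mesh_box(c(0, 0, 0), c(60, 40, 30))
    # refine the top so the footprint region has usable area
    g <- list(origin = c(-32, -22, -17), spacing = rep(1, 3),
              dims = c(65L, 45L, 35L))
    vm <- voxelize_mesh(m, 1, g$origin, g$dims)
    s <- extract_surface(vm, 1L)
    fc <- face_centers(s)
    set_region(s, which(fc[, 3] > 14.2), "footprint")
  })
}

# snap a vertical line at (x, y) onto the slab's top surface
slab_top_point <- function(x, y) {
  h <- ray_intersect(slab_bone(), c(x, y, 40), c(0, 0, -1))
  c(x, y, 40 - h$distance[1])
}

# straight three-trajectory plan into the slab top (approach -z)
slab_plan <- function(n = 3, spacing = 8) {
  bone <- slab_bone()
  xs <- (seq_len(n) - (n + 1) / 2) * spacing
  trajs <- lapply(xs, function(x) {
    tr <- drill_trajectory(slab_top_point(x, 0), c(0, 0, -1))
    tr$depth <- as.numeric(compute_depth(bone, tr, posterior_margin = 2))
    tr
  })
  osteotomy_plan(trajs, build_osteotomy_surface(trajs),
                 posterior_margin = 2)
}

slab_kwires <- function() {
  kwire_set(rbind(slab_top_point(-15, 12), slab_top_point(0, -12),
                  slab_top_point(18, 10)),
            rbind(c(0, 0, -1), c(0, 0, -1), c(0.15, 0, -1)))
}

# voxel ray-marching oracle: entry/exit distances along a ray by dense
# sampling of a voxelized solid (independent of the ray-casting path)
voxel_ray_oracle <- function(mask, origin, dir, step = 0.05,
                             tmax = 100) {
  dir <- dir / sqrt(sum(dir^2))
  ts <- seq(0, tmax, by = step)
  p <- outer(ts, dir)
  p <- sweep(p, 2, origin, "+")
  idx <- sweep(p, 2, mask$origin, "-")
  idx <- sweep(idx, 2, mask$spacing, "/")
  ii <- round(idx) + 1
  d <- dim(mask$labels)
  ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] & ii[, 2] >= 1 & ii[, 2] <= d[2] &
    ii[, 3] >= 1 & ii[, 3] <= d[3]
  inside <- logical(length(ts))
  inside[ok] <- mask$labels[cbind(ii[ok, 1], ii[ok, 2], ii[ok, 3])] != 0L
  flips <- which(diff(inside) != 0)
  ts[flips] + step / 2
}

expect_transform_close <- function(T, R_true, t_true, tol_deg = 0.05,
                                   tol_mm = 0.05) {
  dR <- T$rotation %*% t(R_true)
  ang <- acos(min(1, max(-1, (sum(diag(dR)) - 1) / 2))) * 180 / pi
  expect_lt(ang, tol_deg)
  expect_lt(sqrt(sum((T$translation - t_true)^2)), tol_mm)
}
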