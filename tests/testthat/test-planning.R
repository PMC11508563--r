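test_that("trace resampling is arc-length uniform and shape-preserving", {
  tr <- fracture_trace(rbind(c(0, 0, 0), c(10, 0, 0)))
  rs <- resample_trace(tr, 2.5)
  expect_equal(rs$points[, 1], c(0, 2.5, 5, 7.5, 10))
  # closed circle: ceiling(2*pi*r/s) points with uniform chords
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  circ <- fracture_trace(cbind(10 * cos(th), 10 * sin(th), 0),
                         closed = TRUE)
  rc <- resample_trace(circ, 2)
  expect_equal(nrow(rc$points), ceiling(2 * pi * 10 / 2))
  chords <- sqrt(rowSums((rc$points -
                            rc$points[c(2:nrow(rc$points), 1), ])^2))
  expect_lt(diff(range(chords)) / mean(chords), 0.01)
  # smooth space curve: arc length preserved on resampling
  tt <- seq(0, 3 * pi, length.out = 400)
  helix <- cbind(8 * cos(tt), 8 * sin(tt), 2 * tt)
  tr2 <- fracture_trace(helix)
  rs2 <- resample_trace(tr2, 1)
  expect_equal(trace_length(rs2), trace_length(tr2), tolerance = 0.005)
  expect_warning(resample_trace(tr, 25), "exceeds")
})

test_that("trajectories are planned orthogonal to the trace with snapped
           entries", {
  bone <- slab_bone()
  tr <- fracture_trace(rbind(c(-12.5, 0, 15.3), c(12.5, 0, 15.3)))
  trajs <- plan_trajectories(bone, tr, approach = c(0, 0, -1),
                             spacing = 2.5)
  expect_equal(length(trajs), 11)
  ent <- t(vapply(trajs, `[[`, numeric(3), "entry"))
  # entries collinear on the top surface, directions parallel
  expect_lt(diff(range(ent[, 2])), 1e-6)
  expect_lt(diff(range(ent[, 3])), 0.05)
  for (t in trajs) expect_equal(t$direction, c(0, 0, -1))
  # entries snapped onto the surface
  d <- mesh_closest(bone, ent)$distance
  expect_lt(max(d), 0.5)
})

test_that("depth control respects the posterior margin", {
  bone <- slab_bone()
  tr <- drill_trajectory(slab_top_point(0, 0), c(0, 0, -1))
  d <- compute_depth(bone, tr, posterior_margin = 2)
  # 30 mm slab minus margin (voxelized surface sits within half a voxel)
  expect_equal(as.numeric(d), 28, tolerance = 0.6)
  d0 <- compute_depth(bone, tr, posterior_margin = 0)
  expect_equal(as.numeric(d0) - as.numeric(d), 2, tolerance = 1e-6)
  # margin nearly the full slab: flagged too shallow
  full <- as.numeric(compute_depth(bone, tr, posterior_margin = 0))
  dshallow <- compute_depth(bone, tr, posterior_margin = full - 0.5)
  expect_identical(attr(dshallow, "flag"), "too_shallow")
})

test_that("ruled cut surfaces have analytic area and reject crossings", {
  t1 <- drill_trajectory(c(0, 0, 0), c(0, 0, -1), depth = 10)
  t2 <- drill_trajectory(c(5, 0, 0), c(0, 0, -1), depth = 10)
  s <- build_osteotomy_surface(list(t1, t2))
  expect_equal(attr(s, "area"), 50, tolerance = 1e-6)
  # coplanar fan: area matches the shoelace value of the outline
  f1 <- drill_trajectory(c(0, 0, 0), c(1, 0, 0), depth = 10)
  f2 <- drill_trajectory(c(0, 0, 0), c(0.6, 0.8, 0), depth = 10)
  f3 <- drill_trajectory(c(0, 0, 0), c(0, 1, 0), depth = 10)
  s2 <- build_osteotomy_surface(list(f1, f2, f3))
  # two triangles of a unit fan: 2 * (1/2 r^2 sin(angle))
  expect_equal(attr(s2, "area"),
               100 * sin(acos(0.6)) / 2 + 100 * sin(acos(0.8)) / 2,
               tolerance = 1e-6)
  x1 <- drill_trajectory(c(0, 0, 0), c(0, 1, 0), depth = 10)
  x2 <- drill_trajectory(c(-5, 5, 0), c(1, 0, 0), depth = 10)
  expect_error(build_osteotomy_surface(list(x1, x2)), "crossing")
})

test_that("planned trajectories on the phantom stay clear of the
           posterior cortex", {
  case <- coarse_case()
  ns <- asNamespace("panflute")
  tr <- ns$.planning_trace(case)
  plan <- suppressWarnings(
    plan_osteotomy(case$affected, tr, approach = c(1, 0, 0),
                   spacing = 2.5, posterior_margin = 2))
  expect_gte(length(plan$trajectories), 5)
  for (t in plan$trajectories) {
    hits <- ray_intersect(case$affected, t$entry - 1e-3 * t$direction,
                          t$direction)
    exit <- hits$distance[2] - 1e-3
    # drill tip at least the margin short of the exit cortex
    expect_gte(exit - t$depth, 2 - 1e-6)
    # entries on the bone surface
    expect_lt(mesh_closest(case$affected, t$entry)$distance, 0.5)
  }
  # adjacent drill directions change smoothly along the curved trace
  dirs <- t(vapply(plan$trajectories, `[[`, numeric(3), "direction"))
  for (i in seq_len(nrow(dirs) - 1)) {
    ang <- acos(min(1, sum(dirs[i, ] * dirs[i + 1, ]))) * 180 / pi
    expect_lt(ang, 15)
  }
  # denser spacing gives more trajectories
  plan2 <- suppressWarnings(
    plan_osteotomy(case$affected, tr, approach = c(1, 0, 0),
                   spacing = 1.5, posterior_margin = 2))
  expect_gt(length(plan2$trajectories), length(plan$trajectories))
})

test_that("plan serialization round-trips through JSON", {
  plan <- slab_plan()
  f <- tempfile(fileext = ".json")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_equal(length(back$trajectories), length(plan$trajectories))
  expect_equal(back$trajectories[[2]]$entry, plan$trajectories[[2]]$entry)
  expect_equal(back$trajectories[[2]]$depth, plan$trajectories[[2]]$depth)
  expect_equal(back$posterior_margin, 2)
})

test_that("planned reduction closes the loop on the phantom", {
  case <- coarse_case()
  frag_cur <- submesh(case$affected, "fragment")
  tmpl <- mirror_mesh(case$contralateral, case$mirror_plane)
  Ts <- align_shaft(tmpl, case$affected)
  tmpl <- transform_mesh(tmpl, Ts)
  Tred <- plan_reduction(frag_cur, submesh(tmpl, "fragment"))
  # the reduction is the inverse of the implanted deformity
  err <- rt_compose(Tred, case$true_transform)
  expect_transform_close(err, diag(3), c(0, 0, 0), 0.1, 0.1)
  expect_s3_class(attr(Tred, "planned_model"), "trimesh")
  # applying it and re-assessing yields a near-zero report
  postop <- merge_meshes(case$remainder,
                         transform_mesh(transform_mesh(case$fragment,
                                                       case$true_transform),
                                        Tred))
  rep <- assess_postop(postop, case$intact)
  expect_lt(max(abs(coef(rep))), 0.05)
})
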