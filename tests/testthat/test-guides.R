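test_that("Panflute tube lengths obey the conservation law", {
  expect_equal(panflute_tube_length(60, 28, 2), 30)
  # two holes, same drill: tube difference mirrors depth difference
  expect_equal(panflute_tube_length(60, 20, 2) -
                 panflute_tube_length(60, 35, 2), 15)
  expect_error(panflute_tube_length(25, 28, 2), "drill too short")
  expect_error(panflute_tube_length(33, 28, 3), "3 mm minimum")
})

test_that("K-wire sets reject ambiguous (parallel, close) wires", {
  expect_error(
    kwire_set(rbind(c(0, 0, 0), c(2, 0, 0)),
              rbind(c(0, 0, 1), c(0, 0, 1))),
    "not unique")
  kw <- kwire_set(rbind(c(0, 0, 0), c(20, 0, 0)),
                  rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_s3_class(kw, "kwire_set")
})

test_that("plate solids are watertight slabs with labelled holes", {
  plate <- fit_plate(slab_bone(), z_range = c(-10, 8), role = "new")
  expect_equal(sum(plate$holes$set == "proximal"), 2)
  expect_equal(sum(plate$holes$set == "distal"), 4)
  ps <- plate_solid(plate)
  expect_true(is_watertight(ps))
  expect_gt(mesh_volume(ps), 0)
  # holes sit mid-thickness inside the slab
  hp <- as.matrix(plate$holes[, c("px", "py", "pz")])
  expect_lt(max(mesh_closest(ps, hp)$distance), plate$thickness / 2 + 0.1)
})

test_that("the cutting guide is printable with tailored tubes", {
  bone <- slab_bone()
  plan <- slab_plan()
  kw <- slab_kwires()
  cut <- design_cutting_guide(bone, plan, kwires = kw,
                              drill_working_length = 45,
                              resolution = 0.4, tube_outer_d = 6)
  expect_true(is_watertight(cut$solid))
  expect_true(all(check_channels(cut)))
  # equal depths on a slab: equal tubes, conservation per hole
  expect_lt(diff(range(cut$tubes$tube_length)), 1e-9)
  expect_equal(cut$tubes$standoff + cut$tubes$tube_length +
                 cut$tubes$depth,
               rep(45, nrow(cut$tubes)))
  # hole axes match the plan
  ent <- t(vapply(plan$trajectories, `[[`, numeric(3), "entry"))
  expect_equal(cbind(cut$channels$ex, cut$channels$ey,
                     cut$channels$ez)[seq_len(nrow(ent)), ],
               ent, tolerance = 1e-9)
  # guide does not invade the bone
  ns <- asNamespace("panflute")
  g <- ns$.csg_grid(ns$.mesh_bbox(cut$solid), 0.5)
  overlap <- sum(ns$.voxelize_grid(cut$solid, g) &
                   ns$.voxelize_grid(bone, g)) * 0.5^3
  expect_lt(overlap, 1)
})

test_that("staircase depths produce exactly staircase tube tops", {
  bone <- slab_bone()
  kw <- slab_kwires()
  xs <- c(-8, 0, 8)
  depths <- c(12, 18, 25)
  trajs <- Map(function(x, d) {
    tr <- drill_trajectory(slab_top_point(x, 0), c(0, 0, -1))
    tr$depth <- d
    tr
  }, xs, depths)
  plan <- osteotomy_plan(unname(trajs), posterior_margin = 2)
  cut <- design_cutting_guide(bone, plan, kwires = kw,
                              drill_working_length = 45,
                              resolution = 0.4, tube_outer_d = 6)
  # conservation: standoff + L_i + depth_i identical for every hole
  tot <- cut$tubes$standoff + cut$tubes$tube_length + cut$tubes$depth
  expect_lt(diff(range(tot)), 1e-9)
  # tube-top heights reproduce depth differences exactly
  ent <- t(vapply(plan$trajectories, `[[`, numeric(3), "entry"))
  tops <- ent[, 3] + cut$tubes$standoff + cut$tubes$tube_length
  expect_equal(tops[2] - tops[1], depths[1] - depths[2],
               tolerance = 0.02)
  expect_equal(tops[3] - tops[1], depths[1] - depths[3],
               tolerance = 0.02)
})

test_that("channel interference at tight spacing is rejected", {
  bone <- slab_bone()
  kw <- slab_kwires()
  trajs <- lapply(c(-1, 1), function(x) {
    tr <- drill_trajectory(slab_top_point(x, 0), c(0, 0, -1))
    tr$depth <- 20
    tr
  })
  plan <- osteotomy_plan(trajs, posterior_margin = 2)
  expect_error(design_cutting_guide(bone, plan, kwires = kw,
                                    drill_working_length = 45,
                                    resolution = 0.4),
               "interfere")
})

test_that("the intermediate guide replicates the distal screw pattern and
           shares the K-wire axes", {
  bone <- slab_bone()
  plan <- slab_plan()
  kw <- slab_kwires()
  cut <- design_cutting_guide(bone, plan, kwires = kw,
                              drill_working_length = 45,
                              resolution = 0.4, tube_outer_d = 6)
  plate <- fit_plate(bone, z_range = c(-10, 8), role = "new")
  hp <- as.matrix(plate$holes[plate$holes$set == "distal",
                              c("px", "py", "pz")])
  bone2 <- select_footprint(bone, rbind(hp, kw$entries), radius = 12)
  inter <- design_intermediate_guide(bone2, plate, kw, resolution = 0.4)
  expect_true(is_watertight(inter$solid))
  expect_true(all(check_channels(inter)))
  # exactly 4 drill channels + 3 K-wire channels
  expect_equal(sum(grepl("screw", inter$channels$what)), 4)
  expect_equal(sum(grepl("kwire", inter$channels$what)), 3)
  # shared reference: identical K-wire axes across guides
  kcut <- cut$channels[grepl("kwire", cut$channels$what), ]
  kint <- inter$channels[grepl("kwire", inter$channels$what), ]
  expect_equal(kcut[, c("ex", "ey", "ez", "ox", "oy", "oz")],
               kint[, c("ex", "ey", "ez", "ox", "oy", "oz")],
               tolerance = 1e-9, ignore_attr = TRUE)
  # predrilled positions: each channel axis meets the bone surface at
  # the plate's distal hole location (holes sit 1.5 mm off the bone)
  hn <- as.matrix(plate$holes[plate$holes$set == "distal",
                              c("dx", "dy", "dz")])
  for (i in seq_len(nrow(hp))) {
    ch <- inter$channels[i, ]
    into <- -c(ch$ox, ch$oy, ch$oz)
    hits <- ray_intersect(bone, c(ch$ex, ch$ey, ch$ez), into)
    surf <- c(ch$ex, ch$ey, ch$ez) + hits$distance[1] * into
    want <- hp[i, ] + 1.5 * hn[i, ]
    expect_lt(sqrt(sum((surf - want)^2)), 0.3)
  }
})

test_that("the reposition guide seats uniquely and recovers the planned
           pose from a perturbed start", {
  bone <- slab_bone()
  plate <- fit_plate(bone, z_range = c(-10, 8), role = "new")
  outd <- plate$normals[1, ]
  kst <- plate$centerline[c(2, 5, 8), ]
  kw <- kwire_set(kst + 20 * matrix(outd, 3, 3, byrow = TRUE),
                  -matrix(outd, 3, 3, byrow = TRUE) +
                    rbind(c(0, 0, 0.1), c(0, 0, -0.05), 0))
  repos <- design_reposition_guide(plate, bone, kw, resolution = 0.4)
  expect_true(is_watertight(repos$solid))
  expect_true(all(check_channels(repos)))
  # seating at the planned pose solves to the identity
  seat <- pose_from_constraints(plate, kw)
  expect_false(seat$underdetermined)
  expect_lt(seat$residual, 1e-9)
  # 3 mm / 3 deg perturbed start returns to the planned pose
  pert <- deformity_transform(2, -1.5, 1, 2, -3, 2,
                              center = colMeans(plate$centerline))
  seat2 <- pose_from_constraints(plate, kw, perturb = pert)
  expect_transform_close(seat2$transform, diag(3), c(0, 0, 0), 0.5, 0.2)
  # no wires: a straight slab plate can slide -> underdetermined
  expect_true(pose_from_constraints(plate, NULL)$underdetermined)
  # two parallel wires along the plate's slide direction, laterally
  # separated (a legal wire set) but still unable to pin the slide
  kw_par <- kwire_set(kst[c(1, 3), ] + 20 * matrix(outd, 2, 3,
                                                   byrow = TRUE) +
                        rbind(c(0, 0, 0), c(8, -3, 0)),
                      rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_error(design_reposition_guide(plate, bone, kw_par,
                                       resolution = 0.4),
               "underdetermined")
})

test_that("guide export writes valid STL plus a faithful manifest", {
  bone <- slab_bone()
  plan <- slab_plan()
  kw <- slab_kwires()
  cut <- design_cutting_guide(bone, plan, kwires = kw,
                              drill_working_length = 45,
                              resolution = 0.4, tube_outer_d = 6)
  dir <- tempfile("guides_")
  man <- export_guides(list(cut), dir)
  f <- file.path(dir, "cutting_guide.stl")
  expect_true(file.exists(f))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_stl(f)
  expect_equal(nrow(back$faces), nrow(cut$solid$faces))
  expect_equal(mesh_volume(back), mesh_volume(cut$solid),
               tolerance = 1e-6)
  expect_equal(man$guides$cutting$md5, unname(tools::md5sum(f)))
  expect_equal(nrow(man$guides$cutting$tubes),
               length(plan$trajectories))
  # a guide violating its invariants is refused
  broken <- cut
  broken$solid <- trimesh(cut$solid$vertices,
                          cut$solid$faces[-1, , drop = FALSE])
  expect_error(export_guides(list(broken), tempfile()), "watertight")
})
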