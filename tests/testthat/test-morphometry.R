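test_that("Euler decomposition inverts recomposition to 1e-6", {
  e <- euler_from_rotation(euler_zxy(10.2, 23, 0.8))
  expect_equal(c(e$zeta, e$theta, e$phi), c(10.2, 23, 0.8),
               tolerance = 1e-6)
  set.seed(4)
  for (i in 1:40) {
    a <- c(runif(1, -179, 179), runif(1, -89, 89), runif(1, -179, 179))
    e <- euler_from_rotation(euler_zxy(a[1], a[2], a[3]))
    expect_false(e$gimbal)
    expect_equal(c(e$zeta, e$theta, e$phi), a, tolerance = 1e-6)
  }
  expect_true(euler_from_rotation(euler_zxy(10, 89.95, 5))$gimbal)
})

test_that("deformity transforms decompose back exactly", {
  frame <- anatomical_frame()
  set.seed(9)
  for (i in 1:20) {
    p <- c(runif(3, -10, 10), runif(3, -40, 40))
    ctr <- rnorm(3, sd = 30)
    T <- deformity_transform(p[1], p[2], p[3], p[4], p[5], p[6],
                             center = ctr, frame = frame)
    rep <- decompose_transform(T, frame, center = ctr)
    expect_equal(unname(coef(rep)), p, tolerance = 1e-9)
  }
  # identity and pure translation
  rep0 <- decompose_transform(rigid_transform(), frame)
  expect_equal(unname(coef(rep0)), rep(0, 6))
  rept <- decompose_transform(rigid_transform(diag(3), c(1, 2, 3)),
                              frame, center = c(5, -5, 2))
  expect_equal(unname(coef(rept)), c(1, 2, 3, 0, 0, 0))
})

test_that("deformity reports print, coerce and plot", {
  rep <- decompose_transform(
    deformity_transform(5.4, -2.9, -5.9, 10.2, 23, 0.8,
                        center = c(0, -25, 110)),
    center = c(0, -25, 110))
  out <- capture.output(print(rep))
  expect_true(any(grepl("posterior", out)))
  expect_true(any(grepl("lateral", out)))
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 6)
  pdf(NULL)
  expect_silent(plot(rep))
  dev.off()
})

test_that("shaft alignment recovers known displacements", {
  case <- coarse_clean()
  bone <- case$intact
  # self-alignment is the identity
  T0 <- align_shaft(bone, bone)
  expect_transform_close(T0, diag(3), c(0, 0, 0), 0.02, 0.02)
  # displaced copy: the inverse displacement is recovered
  D <- deformity_transform(3, -4, 2, 2, -3, 4,
                           center = colMeans(bone$vertices))
  moved <- transform_mesh(bone, D)
  T1 <- align_shaft(moved, bone)
  Di <- rt_inverse(D)
  expect_transform_close(T1, Di$rotation, Di$translation, 0.05, 0.05)
})

test_that("fragment fitting is exact, and robust to missing surface", {
  case <- coarse_case()
  frag <- submesh(case$intact, "fragment")
  T0 <- fit_fragment_transform(frag, frag)
  expect_transform_close(T0, diag(3), c(0, 0, 0), 0.02, 0.02)
  # known translation (the case magnitudes)
  Tt <- rigid_transform(diag(3), c(5.4, 2.9, 5.9))
  T1 <- fit_fragment_transform(transform_mesh(frag, Tt), frag)
  expect_lt(max(abs(T1$translation + c(5.4, 2.9, 5.9))), 0.1)
  # 10 percent of faces deleted (depression-like defect)
  nf <- nrow(frag$faces)
  cur <- submesh(frag, which(seq_len(nf) <= 0.9 * nf))
  D <- deformity_transform(4, -3, 2, 8, 15, 3,
                           center = colMeans(frag$vertices))
  T2 <- fit_fragment_transform(transform_mesh(cur, D), frag)
  err <- rt_compose(T2, D)
  expect_transform_close(err, diag(3), c(0, 0, 0), 0.5, 0.3)
})

test_that("quantify_malunion recovers the implanted deformity", {
  case <- coarse_case()
  rep <- quantify_malunion(case$affected, case$contralateral,
                           mirror_plane = case$mirror_plane)
  expect_lt(max(abs(coef(rep) - case$deformity)[1:3]), 0.05)
  expect_lt(max(abs(coef(rep) - case$deformity)[4:6]), 0.05)
  expect_equal(rep$context, "pre")
  expect_lt(attr(rep, "shaft_rms"), 0.5)
})

test_that("an exactly mirrored pair quantifies to a near-zero report", {
  case <- coarse_clean()
  rep <- quantify_malunion(case$affected, case$contralateral,
                           mirror_plane = case$mirror_plane)
  expect_lt(max(abs(coef(rep))), 0.05)
})

test_that("axis-isolated depressions stay on their axis", {
  base <- coarse_clean()
  case <- set_deformity(base, c(dz = -5))
  rep <- quantify_malunion(case$affected, case$contralateral,
                           mirror_plane = case$mirror_plane)
  expect_equal(unname(coef(rep)["dz"]), -5, tolerance = 0.05)
  expect_lt(max(abs(coef(rep)[c("dx", "dy", "zeta", "theta", "phi")])),
            0.05)
})

test_that("postoperative assessment recovers implanted residuals and is
           invariant to global rigid motion", {
  pc <- coarse_clean()
  res <- c(dx = 0.5, dy = -1.0, dz = 0.6, zeta = 3.8, theta = 1.3,
           phi = 0.1)
  Tres <- deformity_transform(res["dx"], res["dy"], res["dz"],
                              res["zeta"], res["theta"], res["phi"],
                              center = pc$center)
  postop <- merge_meshes(pc$remainder,
                         transform_mesh(pc$fragment, Tres))
  rep <- assess_postop(postop, pc$intact)
  expect_lt(max(abs(coef(rep) - res)), 0.05)
  expect_equal(rep$context, "planned_vs_postop")
  # postop == planned -> zero report
  rep0 <- assess_postop(pc$intact, pc$intact)
  expect_lt(max(abs(coef(rep0))), 0.02)
  # translating both models together leaves the report unchanged
  Gt <- rigid_transform(diag(3), c(7, -9, 12))
  rep2 <- assess_postop(transform_mesh(postop, Gt),
                        transform_mesh(pc$intact, Gt))
  expect_lt(max(abs(coef(rep2) - coef(rep))), 5e-3)
  # under a rotation the measurement frame moves with the models
  G <- deformity_transform(7, -9, 12, 5, 8, -11, center = c(0, 0, 0))
  fr <- anatomical_frame(origin = as.numeric(apply_transform(G, c(0, 0, 0))),
                         x_axis = G$rotation[, 1],
                         y_axis = G$rotation[, 2],
                         z_axis = G$rotation[, 3])
  rep3 <- assess_postop(transform_mesh(postop, G),
                        transform_mesh(pc$intact, G), frame = fr)
  expect_lt(max(abs(coef(rep3) - coef(rep))), 5e-3)
})
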