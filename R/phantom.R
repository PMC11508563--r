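# Synthetic proximal-tibia phantom with exactly known ground truth. The
# anatomy is a stylized surrogate (tapered shaft + superellipsoid
# plateau + tuberosity bump), NOT a statistical tibia: every pipeline
# contract is purely geometric, so anatomical realism is unnecessary.
# The lateral split fragment is cut off by a bicubic Bezier sheet and
# displaced by a six-parameter deformity implanted with exactly the
# Euler convention the morphometry module decomposes, making recovery
# well defined.

#' Phantom specification
#'
#' Defaults reproduce the study conditions: a right proximal tibia with
#' a lateral split fragment displaced by the case deformity (5.4 mm
#' posterior, 2.9 mm lateral, 5.9 mm distal; 10.2 deg sagittal, 23 deg
#' coronal, 0.8 deg axial), an intact mirrored contralateral side, and
#' no depression defect or hardware.
#'
#' @param seed integer; fixes all generator randomness.
#' @param shaft_radius,shaft_flare shaft radius (mm) and metaphyseal
#'   flare (mm added over the top 40 mm).
#' @param plateau_semiaxes length-3 superellipsoid semi-axes (mm).
#' @param plateau_exponent superellipsoid exponent.
#' @param tuberosity_offset anterior offset of the tuberosity bump (mm).
#' @param asymmetry_noise_sigma contralateral surface noise (mm, along
#'   normals).
#' @param cut_offsets 4 x 4 matrix of Bezier control y-values (mm) for
#'   the cut sheet (rows: caudal to cranial; columns: anterior to
#'   posterior).
#' @param deformity named numeric: dx, dy, dz (mm), zeta, theta, phi
#'   (degrees).
#' @param depression_depth,depression_radius articular depression defect
#'   (mm; 0 disables).
#' @param hu HU map: cortical, trabecular, soft, air, metal.
#' @param with_plate attach the in-situ lateral plate.
#' @param scatter_amplitude metal scatter noise amplitude (HU; 0 = off).
#' @param mesh_resolution marching grid resolution for phantom meshes
#'   (mm).
#' @export
phantom_spec <- function(seed = 42L,
                         shaft_radius = 14, shaft_flare = 10,
                         plateau_semiaxes = c(24, 34, 13),
                         plateau_exponent = 3.5,
                         tuberosity_offset = 17,
                         asymmetry_noise_sigma = 0,
                         cut_offsets = NULL,
                         deformity = c(dx = 5.4, dy = -2.9, dz = -5.9,
                                       zeta = 10.2, theta = 23,
                                       phi = 0.8),
                         depression_depth = 0, depression_radius = 8,
                         hu = c(cortical = 700, trabecular = 300,
                                soft = 40, air = -1000, metal = 8000),
                         with_plate = FALSE, scatter_amplitude = 0,
                         mesh_resolution = 0.8) {
  if (is.null(cut_offsets)) {
    base <- c(-70, -48, -15, -10)
    xvar <- c(2, -2, -3, 1)
    cut_offsets <- outer(base, xvar, "+")
  }
  def <- c(dx = 0, dy = 0, dz = 0, zeta = 0, theta = 0, phi = 0)
  def[names(deformity)] <- deformity
  structure(list(seed = as.integer(seed), shaft_radius = shaft_radius,
                 shaft_flare = shaft_flare,
                 plateau_semiaxes = plateau_semiaxes,
                 plateau_exponent = plateau_exponent,
                 tuberosity_offset = tuberosity_offset,
                 asymmetry_noise_sigma = asymmetry_noise_sigma,
                 cut_offsets = cut_offsets, deformity = def,
                 depression_depth = depression_depth,
                 depression_radius = depression_radius, hu = hu,
                 with_plate = with_plate,
                 scatter_amplitude = scatter_amplitude,
                 mesh_resolution = mesh_resolution),
            class = "phantom_spec")
}

# implicit bone field (negative inside), vectorized over an n x 3 matrix
.bone_field <- function(spec, pts) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  sstep <- function(t) {
    t <- pmin(1, pmax(0, t))
    t * t * (3 - 2 * t)
  }
  r <- spec$shaft_radius + spec$shaft_flare * sstep((z - 60) / 40)
  # triangular shaft cross-section (anterior crest), vertex anterior
  th <- atan2(y, x)
  r_ang <- 1 - 0.15 * cos(3 * (th - pi))
  f_shaft <- pmax(sqrt(x^2 + y^2) - r * r_ang, -z, z - 100)
  a <- spec$plateau_semiaxes
  n <- spec$plateau_exponent
  # mild external torsion of the plateau relative to the shaft (~8 deg),
  # posterior slope (~7 deg) and slight varus inclination (~3 deg)
  ct <- cos(8 * pi / 180); st <- sin(8 * pi / 180)
  xp <- ct * x + st * (y - 2)
  yp <- -st * x + ct * (y - 2)
  zs <- z - 107 + 0.12 * xp + 0.05 * yp
  v <- (abs(xp / a[1])^n + abs(yp / a[2])^n +
          abs(zs / a[3])^n)^(1 / n)
  f_plat <- (v - 1) * min(a)
  tc <- c(-spec$tuberosity_offset, 0, 84)
  f_tub <- (sqrt(((x - tc[1]) / 9)^2 + ((y - tc[2]) / 11)^2 +
                   ((z - tc[3]) / 14)^2) - 1) * 9
  f <- pmin(f_shaft, f_plat, f_tub)
  # articular dishes: shallow spherical concavities of the lateral and
  # medial condyles, carved into the plateau top
  top <- 107 + a[3]
  for (cy in c(-18, 20)) {
    cd <- c(2, cy, top - 3 + 35 - 0.12 * 2 - 0.05 * (cy - 2))
    dish <- 35 - sqrt((x - cd[1])^2 + (y - cd[2])^2 + (z - cd[3])^2)
    f <- pmax(f, dish)
  }
  f
}

# cut-sheet signed value: s < 0 on the (lateral) fragment side
.cut_field <- function(spec, pts) {
  u <- pmin(1, pmax(0, (pts[, 1] + 40) / 80))    # anterior -> posterior
  v <- pmin(1, pmax(0, (pts[, 3] - 68) / 58))    # caudal -> cranial
  bu <- cbind((1 - u)^3, 3 * u * (1 - u)^2, 3 * u^2 * (1 - u), u^3)
  bv <- cbind((1 - v)^3, 3 * v * (1 - v)^2, 3 * v^2 * (1 - v), v^3)
  B <- rowSums((bv %*% spec$cut_offsets) * bu)
  pts[, 2] - B
}

# separable (1,2,1)/4 binomial blur per axis, edge-replicated
.psf_blur <- function(a) {
  d <- dim(a)
  sh <- function(x, axis, by) {
    idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
    switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
           x[, , idx, drop = FALSE])
  }
  for (axis in 1:3) {
    a <- 0.25 * sh(a, axis, -1L) + 0.5 * a + 0.25 * sh(a, axis, 1L)
  }
  a
}

.phantom_grid <- function(spec) {
  lo <- c(-38, -42, -3)
  hi <- c(32, 42, 127)
  res <- spec$mesh_resolution
  dims <- as.integer(ceiling((hi - lo) / res)) + 1L
  list(origin = lo, spacing = rep(res, 3), dims = dims)
}

.mesh_from_implicit <- function(fun, g) {
  pts <- .grid_points(g)
  .surface_from_field(fun(pts), g, iso = 0)
}

#' Generate a bilateral proximal-tibia pair
#'
#' The right bone is the affected-side template; the left bone is its
#' exact mirror plus optional Gaussian surface noise along vertex
#' normals (the contralateral asymmetry). Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `right`, `left` ([trimesh()]) and `mirror_plane`
#'   (the [plane()] used to build the left side).
#' @export
generate_tibia_pair <- function(spec = phantom_spec()) {
  g <- .phantom_grid(spec)
  right <- .mesh_from_implicit(function(p) .bone_field(spec, p), g)
  mp <- plane(c(0, 45, 0), c(0, 1, 0))
  left <- mirror_mesh(right, mp)
  if (spec$asymmetry_noise_sigma > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
    vn <- .vertex_normals(left)
    off <- stats::rnorm(nrow(left$vertices), 0,
                        spec$asymmetry_noise_sigma)
    left <- trimesh(left$vertices + vn * off, left$faces, left$regions,
                    clean = FALSE)
  }
  list(right = right, left = left, mirror_plane = mp)
}

.vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  fa <- face_areas(mesh)
  nv <- nrow(mesh$vertices)
  acc <- matrix(0, nv, 3)
  for (m in 1:3) {
    w <- rowsum(fn * fa, mesh$faces[, m], reorder = TRUE)
    idx <- as.integer(rownames(w))
    acc[idx, ] <- acc[idx, ] + w
  }
  acc / pmax(sqrt(rowSums(acc^2)), 1e-12)
}

.label_bone_mesh <- function(mesh, svals) {
  reg <- rep("", nrow(mesh$faces))
  reg[svals < -0.4] <- "fragment"
  zr <- range(mesh$vertices[, 3])
  fc <- face_centers(mesh)
  reg[fc[, 3] < zr[1] + 0.4 * diff(zr) & reg == ""] <- "shaft"
  mesh$regions <- reg
  mesh
}

#' Implant a malunion into the phantom
#'
#' Cuts the intact bone along the Bezier sheet, displaces the lateral
#' fragment by the specified deformity (rotation about the fragment
#' patch centroid, intrinsic z-x-y Euler convention, then translation
#' along the anatomical axes), optionally subtracts a spherical
#' articular depression, and records all ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param pair optional precomputed [generate_tibia_pair()] output.
#' @return object of class `"phantom_case"` with fields `affected`,
#'   `contralateral`, `intact`, `fragment`, `remainder`,
#'   `true_transform`, `deformity`, `center`, `trace`, `mirror_plane`,
#'   `spec`.
#' @export
induce_malunion <- function(spec = phantom_spec(), pair = NULL) {
  if (is.null(pair)) pair <- generate_tibia_pair(spec)
  g <- .phantom_grid(spec)
  pts <- .grid_points(g)
  fb <- .bone_field(spec, pts)
  s <- .cut_field(spec, pts)
  frag <- .surface_from_field(pmax(fb, s), g, iso = 0)
  rem <- .surface_from_field(pmax(fb, -s), g, iso = 0)
  if (nrow(frag$faces) == 0 || nrow(rem$faces) == 0)
    stop("cut sheet failed to split the bone into two components")
  vi <- abs(mesh_volume(frag)) + abs(mesh_volume(rem))
  v0 <- abs(mesh_volume(pair$right))
  if (abs(vi - v0) / v0 > 0.05)
    stop("cut sheet produced a degenerate split (volume not conserved)")
  if (spec$depression_depth > 0) {
    top <- max(frag$vertices[, 3])
    ctr <- colMeans(frag$vertices[frag$vertices[, 3] >
                                    top - 2, , drop = FALSE])
    cen <- c(ctr[1], ctr[2],
             top + spec$depression_radius - spec$depression_depth)
    gg <- g
    sph <- function(p) {
      d <- sqrt((p[, 1] - cen[1])^2 + (p[, 2] - cen[2])^2 +
                  (p[, 3] - cen[3])^2)
      pmax(pmax(fb, s), spec$depression_radius - d)
    }
    frag <- .surface_from_field(sph(pts), gg, iso = 0)
  }
  # labels: free surface vs cut interface, by the sheet value
  sf <- .cut_field(spec, face_centers(frag))
  frag$regions <- ifelse(abs(sf) > 0.4, "fragment", "interface")
  sr <- .cut_field(spec, face_centers(rem))
  rem <- .label_bone_mesh(rem, rep(1, nrow(rem$faces)))  # no fragment here
  rem$regions[abs(sr) <= 0.4] <- "interface"
  intact <- .label_bone_mesh(pair$right,
                             .cut_field(spec, face_centers(pair$right)))
  center <- mesh_centroid(intact, "fragment")
  d <- spec$deformity
  T <- deformity_transform(d["dx"], d["dy"], d["dz"], d["zeta"],
                           d["theta"], d["phi"], center = center)
  affected <- merge_meshes(rem, transform_mesh(frag, T))
  # contralateral labels through the mirror map
  mfc <- face_centers(pair$left)
  mirr <- function(p) {
    dd <- sweep(p, 2, pair$mirror_plane$point, "-") %*%
      pair$mirror_plane$normal
    p - 2 * dd %*% t(pair$mirror_plane$normal)
  }
  contral <- .label_bone_mesh(pair$left, .cut_field(spec, mirr(mfc)))
  trace <- .trace_from_mesh(intact, .cut_field(spec, intact$vertices))
  structure(list(affected = affected, contralateral = contral,
                 intact = intact, fragment = frag, remainder = rem,
                 true_transform = T, deformity = d, center = center,
                 trace = trace, mirror_plane = pair$mirror_plane,
                 spec = spec),
            class = "phantom_case")
}

#' Re-implant a different deformity into an existing phantom case
#'
#' The cut geometry is deformity-independent, so a case can be reused
#' across deformities without re-meshing (the affected model and stored
#' truth are rebuilt).
#' @param case a `phantom_case`.
#' @param deformity named numeric (subset of dx, dy, dz, zeta, theta,
#'   phi).
#' @export
set_deformity <- function(case, deformity) {
  d <- case$spec$deformity
  d[names(deformity)] <- deformity
  T <- deformity_transform(d["dx"], d["dy"], d["dz"], d["zeta"],
                           d["theta"], d["phi"], center = case$center)
  case$spec$deformity <- d
  case$deformity <- d
  case$true_transform <- T
  case$affected <- merge_meshes(case$remainder,
                                transform_mesh(case$fragment, T))
  case
}

#' @export
print.phantom_case <- function(x, ...) {
  d <- x$deformity
  cat(sprintf("<phantom_case: deformity (%.1f, %.1f, %.1f) mm / (%.1f, %.1f, %.1f) deg, noise sigma %g mm>\n",
              d["dx"], d["dy"], d["dz"], d["zeta"], d["theta"],
              d["phi"], x$spec$asymmetry_noise_sigma))
  invisible(x)
}

# fracture trace: surface-edge crossings of the cut sheet, ordered by
# angle in the (x, z) sheet parameter plane
.trace_from_mesh <- function(mesh, svert) {
  f <- mesh$faces
  e0 <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e0[, 1], e0[, 2]), pmax(e0[, 1], e0[, 2]))
  e <- e[!duplicated(e[, 1] * (nrow(mesh$vertices) + 1) + e[, 2]), ,
         drop = FALSE]
  sa <- svert[e[, 1]]
  sb <- svert[e[, 2]]
  cross <- (sa < 0) != (sb < 0)
  if (sum(cross) < 3) stop("cut sheet does not intersect the surface")
  w <- sa[cross] / (sa[cross] - sb[cross])
  p <- (1 - w) * mesh$vertices[e[cross, 1], , drop = FALSE] +
    w * mesh$vertices[e[cross, 2], , drop = FALSE]
  ctr <- colMeans(p)
  ang <- atan2(p[, 3] - ctr[3], p[, 1] - ctr[1])
  fracture_trace(p[order(ang), , drop = FALSE], closed = TRUE)
}

# free fragment surface away from the fracture-line crease (CT rounds
# the sharp edge, so the crease band is unreliable for registration)
.fragment_core <- function(case, crease_margin = 1.5) {
  sf <- .cut_field(case$spec, face_centers(case$fragment))
  submesh(case$fragment, which(case$fragment$regions == "fragment" &
                                 sf < -crease_margin))
}

#' Label a (segmented) affected-side mesh from phantom ground truth
#'
#' Faces close to the displaced fragment's free surface are labelled
#' `fragment`; distal faces get the `shaft` label. Used to mimic the
#' manual region marking a surgeon performs, with the phantom's exact
#' truth as the marker.
#'
#' @param mesh affected-side [trimesh()] (e.g. from CT segmentation).
#' @param case a `phantom_case`.
#' @param tol matching distance (mm).
#' @param seam_margin faces closer than this to the remainder bone (in
#'   the displaced position) are excluded: where the fragment lies
#'   against other bone, CT partial volume corrupts its surface.
#' @export
label_against_truth <- function(mesh, case, tol = 0.6,
                                seam_margin = 1.2) {
  frag_free <- transform_mesh(.fragment_core(case), case$true_transform)
  rem_free <- submesh(case$remainder,
                      which(case$remainder$regions != "interface"))
  fc <- face_centers(mesh)
  # only faces near the displaced fragment's bounding box can be fragment
  bb <- .mesh_bbox(frag_free)
  cand <- which(fc[, 1] > bb$lo[1] - 2 & fc[, 1] < bb$hi[1] + 2 &
                fc[, 2] > bb$lo[2] - 2 & fc[, 2] < bb$hi[2] + 2 &
                fc[, 3] > bb$lo[3] - 2 & fc[, 3] < bb$hi[3] + 2)
  reg <- rep("", nrow(mesh$faces))
  if (length(cand)) {
    df <- mesh_closest(frag_free, fc[cand, , drop = FALSE])$distance
    dr <- mesh_closest(rem_free, fc[cand, , drop = FALSE])$distance
    reg[cand[df < tol & df < dr & dr > seam_margin]] <- "fragment"
  }
  zr <- range(mesh$vertices[, 3])
  reg[fc[, 3] < zr[1] + 0.4 * diff(zr) & reg == ""] <- "shaft"
  mesh$regions <- reg
  mesh
}

#' Label a (segmented) contralateral mesh from phantom ground truth
#'
#' Applies the same proximity rule as [label_against_truth()] to the
#' mirrored face centres, so template and affected fragment patches get
#' congruent footprints.
#' @param mesh contralateral [trimesh()] in its native (left) position.
#' @param case a `phantom_case`.
#' @param tol matching distance (mm).
#' @param seam_margin same seam exclusion as [label_against_truth()],
#'   evaluated at the corresponding displaced position so both patches
#'   share one footprint.
#' @export
label_template <- function(mesh, case, tol = 0.6, seam_margin = 1.2) {
  mp <- case$mirror_plane
  fc <- face_centers(mesh)
  dd <- sweep(fc, 2, mp$point, "-") %*% mp$normal
  mfc <- fc - 2 * dd %*% t(mp$normal)
  frag_free <- .fragment_core(case)
  rem_free <- submesh(case$remainder,
                      which(case$remainder$regions != "interface"))
  bb <- .mesh_bbox(frag_free)
  cand <- which(mfc[, 1] > bb$lo[1] - 2 & mfc[, 1] < bb$hi[1] + 2 &
                mfc[, 2] > bb$lo[2] - 2 & mfc[, 2] < bb$hi[2] + 2 &
                mfc[, 3] > bb$lo[3] - 2 & mfc[, 3] < bb$hi[3] + 2)
  reg <- rep("", nrow(mesh$faces))
  if (length(cand)) {
    df <- mesh_closest(frag_free, mfc[cand, , drop = FALSE])$distance
    dr <- mesh_closest(rem_free, mfc[cand, , drop = FALSE])$distance
    disp <- apply_transform(case$true_transform, mfc[cand, , drop = FALSE])
    drs <- mesh_closest(rem_free, disp)$distance
    reg[cand[df < tol & df < dr & drs > seam_margin]] <- "fragment"
  }
  zr <- range(mesh$vertices[, 3])
  reg[fc[, 3] < zr[1] + 0.4 * diff(zr) & reg == ""] <- "shaft"
  mesh$regions <- reg
  mesh
}

#' Simulated CT acquisition of a phantom
#'
#' Rasterizes the bone (cortical shell over trabecular core, embedded
#' in soft tissue and air) on a voxel grid; optionally adds the metal
#' plate with radial scatter-like streak noise around it.
#'
#' @param case a `phantom_case`.
#' @param spacing voxel spacing (mm).
#' @param side `"affected"`, `"contralateral"`, or a [trimesh()] to
#'   rasterize directly.
#' @param supersample columns per voxel per transverse axis used for
#'   partial-volume mixing of boundary-voxel HU (occupancy is integrated
#'   exactly along z); emulates the partial-volume effect of real CT.
#' @param psf apply a separable binomial blur emulating the scanner
#'   point-spread function (default `TRUE`).
#' @return a [ct_volume()].
#' @export
voxelize_ct <- function(case, spacing = 0.5, side = "affected",
                        supersample = 2L, psf = TRUE) {
  spec <- case$spec
  if (inherits(side, "trimesh")) {
    meshes <- list(side)
  } else if (side == "affected") {
    meshes <- list(case$remainder,
                   transform_mesh(case$fragment, case$true_transform))
  } else {
    meshes <- list(case$contralateral)
  }
  bb <- do.call(.mesh_bbox, meshes)
  pad <- 5
  origin <- bb$lo - pad
  dims <- as.integer(ceiling((bb$hi + pad - origin) / spacing)) + 1L
  ss <- max(1L, as.integer(supersample))
  frac <- array(0, dims)
  for (m in meshes) {
    frac <- pmin(1, frac + array(
      voxelize_frac_cpp(m$vertices, m$faces, dims, rep(spacing, 3),
                        origin, ss), dims))
  }
  inside_i <- as.integer(frac >= 0.5)
  n2 <- max(1L, as.integer(round(2 / spacing)))
  core <- erode26_cpp(inside_i, dims, n2)
  n3 <- max(1L, as.integer(round(3 / spacing)))
  soft <- dilate26_cpp(inside_i, dims, n3)
  hu <- rep(spec$hu[["air"]], prod(dims))
  hu[soft == 1L] <- spec$hu[["soft"]]
  bnd <- frac > 0
  hu[bnd] <- spec$hu[["soft"]] +
    frac[bnd] * (spec$hu[["cortical"]] - spec$hu[["soft"]])
  hu[core == 1L] <- spec$hu[["trabecular"]]
  vol <- array(hu, dims)
  if (psf) vol <- .psf_blur(vol)
  if (isTRUE(spec$with_plate) && !identical(side, "contralateral")) {
    plate <- fit_plate(case$intact)
    ps <- plate_solid(plate)
    g <- list(origin = origin, spacing = rep(spacing, 3), dims = dims)
    pm <- array(as.integer(.voxelize_grid(ps, g)), dims)
    vol[pm == 1L] <- spec$hu[["metal"]]
    if (spec$scatter_amplitude > 0) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        .GlobalEnv))
      set.seed(spec$seed + 1000L)
      ctr <- colMeans(ps$vertices)
      ii <- which(pm == 0L)
      coord <- arrayInd(ii, dims)
      wx <- origin[1] + (coord[, 1] - 1) * spacing
      wy <- origin[2] + (coord[, 2] - 1) * spacing
      wz <- origin[3] + (coord[, 3] - 1) * spacing
      r <- sqrt((wx - ctr[1])^2 + (wy - ctr[2])^2)
      nearz <- abs(wz - ctr[3]) < 30
      sel <- which(r < 15 & nearz)
      th <- atan2(wy[sel] - ctr[2], wx[sel] - ctr[1])
      streak <- spec$scatter_amplitude * cos(8 * th) *
        exp(-r[sel] / 8) +
        stats::rnorm(length(sel), 0, spec$scatter_amplitude / 3)
      vol[ii[sel]] <- vol[ii[sel]] + streak
    }
  }
  ct_volume(vol, rep(spacing, 3), origin)
}

#' Fit the parametric lateral plate onto a bone
#'
#' Casts rays from anterolateral onto the bone surface to build the
#' plate centerline and normals; proximal holes sit on the upper
#' stations, distal holes on the shaft.
#'
#' @param bone bone [trimesh()].
#' @param z_range plate extent along z (mm).
#' @param role `"in_situ"` or `"new"`.
#' @param n_prox,n_dist screw holes per subset.
#' @export
fit_plate <- function(bone, z_range = c(60, 100),
                      role = c("in_situ", "new"), n_prox = 2,
                      n_dist = 4) {
  role <- match.arg(role)
  outd <- c(-0.35, -0.937, 0)
  outd <- outd / sqrt(sum(outd^2))
  zs <- seq(z_range[1], z_range[2], length.out = 10)
  cl <- matrix(NA_real_, 0, 3)
  nr <- matrix(NA_real_, 0, 3)
  for (z in zs) {
    o <- c(0, 0, z) + 60 * outd
    hits <- ray_intersect(bone, o, -outd)
    if (nrow(hits) == 0) next
    cl <- rbind(cl, o - outd * hits$distance[1])
    nr <- rbind(nr, outd)
  }
  if (nrow(cl) < 2) stop("could not seat the plate on the bone")
  zh <- cl[, 3]
  pick <- function(n, lo, hi) {
    tz <- seq(lo, hi, length.out = n)
    vapply(tz, function(t) which.min(abs(zh - t)), 0L)
  }
  prox_i <- pick(n_prox, max(zh) - 8, max(zh))
  dist_span <- max(0.5 * diff(range(zh)), 6 * (n_dist - 1))
  dist_i <- pick(n_dist, min(zh),
                 min(min(zh) + dist_span, max(zh)))
  hp <- cl[prox_i, , drop = FALSE] + 1.5 * nr[prox_i, , drop = FALSE]
  hd <- cl[dist_i, , drop = FALSE] + 1.5 * nr[dist_i, , drop = FALSE]
  holes <- data.frame(
    px = c(hp[, 1], hd[, 1]), py = c(hp[, 2], hd[, 2]),
    pz = c(hp[, 3], hd[, 3]),
    dx = -c(nr[prox_i, 1], nr[dist_i, 1]),
    dy = -c(nr[prox_i, 2], nr[dist_i, 2]),
    dz = -c(nr[prox_i, 3], nr[dist_i, 3]),
    diameter = 3.5,
    set = c(rep("proximal", n_prox), rep("distal", n_dist)))
  plate_model(cl, nr, width = 12, thickness = 3, holes = holes,
              role = role)
}

#' Named phantom fixtures
#'
#' Deterministic cases used across tests and the acceptance script:
#' `paper_case` implants the preoperative case deformity; `paper_postop`
#' offsets the fragment from its planned (anatomical) pose by the
#' achieved postoperative residual (0.5 mm posterior, 1.0 mm lateral,
#' 0.6 mm cranial; 3.8 / 1.3 / 0.1 deg); `clean` has zero deformity;
#' `scatter` adds the in-situ plate and scatter noise to `paper_case`.
#'
#' @param name fixture name.
#' @return a `phantom_case`; for `paper_postop` the fields `planned`
#'   and `postop` hold the two models to compare and `residual` the
#'   implanted truth.
#' @export
phantom_fixture <- function(name = c("paper_case", "paper_postop",
                                     "clean", "scatter")) {
  name <- match.arg(name)
  if (name == "clean") {
    spec <- phantom_spec(deformity = c(dx = 0, dy = 0, dz = 0,
                                       zeta = 0, theta = 0, phi = 0))
    return(induce_malunion(spec))
  }
  if (name == "paper_case") {
    return(induce_malunion(phantom_spec()))
  }
  if (name == "scatter") {
    spec <- phantom_spec(with_plate = TRUE, scatter_amplitude = 400)
    return(induce_malunion(spec))
  }
  # paper_postop: planned model is the anatomical reconstruction; the
  # postoperative model has the fragment offset by the achieved residual
  spec <- phantom_spec(deformity = c(dx = 0, dy = 0, dz = 0, zeta = 0,
                                     theta = 0, phi = 0))
  case <- induce_malunion(spec)
  res <- c(dx = 0.5, dy = -1.0, dz = 0.6, zeta = 3.8, theta = 1.3,
           phi = 0.1)
  Tres <- deformity_transform(res["dx"], res["dy"], res["dz"],
                              res["zeta"], res["theta"], res["phi"],
                              center = case$center)
  postop <- merge_meshes(case$remainder,
                         transform_mesh(case$fragment, Tres))
  case$planned <- case$intact
  case$postop <- postop
  case$residual <- res
  case$residual_transform <- Tres
  case
}
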