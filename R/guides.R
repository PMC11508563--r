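# Printable guide solids. All three guides (Panflute cutting guide,
# intermediate pre-drill guide, reposition guide) are built from one
# composite continuous level-set field -- signed distance of the bone
# (and plate) for the conforming shell, analytic cylinders for tubes and
# channels -- surfaced once by marching tetrahedra. K-wire axes are
# shared verbatim across guides so sequential guides reference the same
# physical wires.

#' K-wire reference set
#'
#' @param entries n x 3 matrix of wire entry points on the bone (mm).
#' @param directions n x 3 matrix of wire directions (into the bone).
#' @param diameter wire diameter (mm, default 2).
#' @export
kwire_set <- function(entries, directions, diameter = 2.0) {
  entries <- as.matrix(entries)
  directions <- as.matrix(directions)
  stopifnot(ncol(entries) == 3, all(dim(entries) == dim(directions)))
  directions <- directions / sqrt(rowSums(directions^2))
  n <- nrow(entries)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        par <- abs(sum(directions[i, ] * directions[j, ])) > 1 - 1e-6
        sep <- .seg_seg_dist(entries[i, ], entries[i, ] + 40 * directions[i, ],
                             entries[j, ], entries[j, ] + 40 * directions[j, ])$d
        if (par && sep < 5)
          stop("K-wires ", i, " and ", j,
               " are parallel and closer than 5 mm: seating not unique")
      }
    }
  }
  structure(list(entries = entries, directions = directions,
                 diameter = diameter), class = "kwire_set")
}

#' Parametric slab plate
#'
#' Stand-in for the proprietary anatomical plate: a constant-width slab
#' swept along a centerline on the bone surface, with ordered screw-hole
#' axes split into proximal and distal subsets. The in-situ and new
#' plates share the proximal hole pattern so the new plate can reuse the
#' old proximal screw holes.
#'
#' @param centerline n x 3 matrix of points on the bone surface (mm).
#' @param normals n x 3 outward surface normals at those points.
#' @param width,thickness slab width and thickness (mm).
#' @param holes data.frame with columns `px, py, pz` (hole point on the
#'   plate), `dx, dy, dz` (drill axis, into the bone), `diameter`, and
#'   `set` (`"proximal"` or `"distal"`).
#' @param role `"in_situ"` or `"new"`.
#' @export
plate_model <- function(centerline, normals, width = 12, thickness = 3,
                        holes, role = c("in_situ", "new")) {
  role <- match.arg(role)
  centerline <- as.matrix(centerline)
  normals <- as.matrix(normals)
  normals <- normals / sqrt(rowSums(normals^2))
  stopifnot(nrow(centerline) >= 2, all(dim(centerline) == dim(normals)),
            all(c("px", "py", "pz", "dx", "dy", "dz", "diameter",
                  "set") %in% names(holes)))
  structure(list(centerline = centerline, normals = normals,
                 width = width, thickness = thickness, holes = holes,
                 role = role),
            class = "plate_model")
}

#' @export
print.plate_model <- function(x, ...) {
  cat(sprintf("<plate_model (%s): %d stations, %g x %g mm, %d proximal + %d distal holes>\n",
              x$role, nrow(x$centerline), x$width, x$thickness,
              sum(x$holes$set == "proximal"), sum(x$holes$set == "distal")))
  invisible(x)
}

#' Solid mesh of a slab plate
#' @param plate a [plate_model()].
#' @return watertight [trimesh()].
#' @export
plate_solid <- function(plate) {
  cl <- plate$centerline
  nrm <- plate$normals
  m <- nrow(cl)
  hw <- plate$width / 2
  th <- plate$thickness
  v <- matrix(0, 4 * m, 3)
  for (i in seq_len(m)) {
    tang <- if (i == 1) cl[2, ] - cl[1, ]
            else if (i == m) cl[m, ] - cl[m - 1, ]
            else cl[i + 1, ] - cl[i - 1, ]
    tang <- tang / sqrt(sum(tang^2))
    b <- c(nrm[i, 2] * tang[3] - nrm[i, 3] * tang[2],
           nrm[i, 3] * tang[1] - nrm[i, 1] * tang[3],
           nrm[i, 1] * tang[2] - nrm[i, 2] * tang[1])
    b <- b / sqrt(sum(b^2))
    v[4 * i - 3, ] <- cl[i, ] - hw * b
    v[4 * i - 2, ] <- cl[i, ] + hw * b
    v[4 * i - 1, ] <- cl[i, ] + hw * b + th * nrm[i, ]
    v[4 * i, ]     <- cl[i, ] - hw * b + th * nrm[i, ]
  }
  f <- list()
  rid <- function(i, j) 4 * (i - 1) + ((j - 1) %% 4) + 1
  for (i in seq_len(m - 1)) {
    for (j in 1:4) {
      a <- rid(i, j); b2 <- rid(i, j + 1)
      c2 <- rid(i + 1, j + 1); d2 <- rid(i + 1, j)
      f[[length(f) + 1]] <- c(a, b2, c2)
      f[[length(f) + 1]] <- c(a, c2, d2)
    }
  }
  f[[length(f) + 1]] <- c(rid(1, 1), rid(1, 3), rid(1, 2))
  f[[length(f) + 1]] <- c(rid(1, 1), rid(1, 4), rid(1, 3))
  f[[length(f) + 1]] <- c(rid(m, 1), rid(m, 2), rid(m, 3))
  f[[length(f) + 1]] <- c(rid(m, 1), rid(m, 3), rid(m, 4))
  out <- trimesh(v, do.call(rbind, f), clean = FALSE)
  if (mesh_volume(out) < 0)
    out <- trimesh(out$vertices, out$faces[, c(1, 3, 2)], clean = FALSE)
  out
}

#' Per-hole Panflute tube length
#'
#' The drill tube above hole i is cut so that a drill of fixed working
#' length inserted to its stop reaches exactly the planned depth:
#' `L_i = drill_working_length - depth - base_standoff`, where the
#' standoff is the drill path between the bone surface and the tube
#' bottom (fit gap plus shell thickness). Tube lengths below 3 mm are
#' rejected.
#'
#' @param drill_working_length usable drill length below the stop (mm).
#' @param depth planned in-bone depth (mm).
#' @param base_standoff bone-surface to tube-bottom distance (mm).
#' @return tube length in mm.
#' @export
panflute_tube_length <- function(drill_working_length, depth,
                                 base_standoff) {
  if (drill_working_length <= depth + base_standoff)
    stop(sprintf(
      "drill too short: need working length > %.1f mm (depth %.1f + standoff %.1f)",
      depth + base_standoff, depth, base_standoff))
  L <- drill_working_length - depth - base_standoff
  if (L < 3)
    stop(sprintf(
      "tube length %.2f mm below the 3 mm minimum; use a drill with working length >= %.1f mm",
      L, depth + base_standoff + 3))
  L
}

#' Guide model container
#' @param solid watertight [trimesh()] of the printable guide.
#' @param kind `"cutting"`, `"intermediate"` or `"reposition"`.
#' @param tubes data.frame of drill-tube records (one per trajectory).
#' @param kwires data.frame of K-wire channel records.
#' @param channels data.frame of all through-channel audits.
#' @export
guide_model <- function(solid, kind, tubes = NULL, kwires = NULL,
                        channels = NULL) {
  structure(list(solid = solid, kind = kind, tubes = tubes,
                 kwires = kwires, channels = channels),
            class = "guide_model")
}

#' @export
print.guide_model <- function(x, ...) {
  cat(sprintf("<guide_model (%s): %d faces, %d drill tubes/channels, %d K-wire channels>\n",
              x$kind, nrow(x$solid$faces),
              if (is.null(x$tubes)) 0 else nrow(x$tubes),
              if (is.null(x$kwires)) 0 else nrow(x$kwires)))
  invisible(x)
}

# ---- level-set field machinery ------------------------------------------

# solid finite cylinder: negative inside; A = base centre, d = unit axis
.cyl_field <- function(pts, A, d, radius, len) {
  rel <- sweep(pts, 2, A)
  s <- rel %*% d
  rad <- sqrt(pmax(rowSums(rel^2) - s^2, 0))
  pmax(rad - radius, -s, s - len)
}

.grid_hi <- function(g) g$origin + (g$dims - 1) * g$spacing

# coordinates of selected linear grid indices (column-major)
.grid_index_points <- function(g, idx) {
  i <- (idx - 1) %% g$dims[1]
  j <- ((idx - 1) %/% g$dims[1]) %% g$dims[2]
  k <- (idx - 1) %/% (g$dims[1] * g$dims[2])
  cbind(g$origin[1] + i * g$spacing[1],
        g$origin[2] + j * g$spacing[2],
        g$origin[3] + k * g$spacing[3])
}

# voxels adjacent to the inside/outside interface (6-neighbourhood)
.mask_band6 <- function(arr) {
  d <- dim(arr)
  sh <- function(a, ax, by) {
    idx <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
    switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  out <- array(FALSE, d)
  for (ax in 1:3) {
    out <- out | (arr != sh(arr, ax, 1L)) | (arr != sh(arr, ax, -1L))
  }
  out
}

# faces whose bounding box overlaps an axis-aligned box (plus margin)
.crop_faces <- function(mesh, lo, hi, margin = 8) {
  fc <- face_centers(mesh)
  keep <- fc[, 1] > lo[1] - margin & fc[, 1] < hi[1] + margin &
          fc[, 2] > lo[2] - margin & fc[, 2] < hi[2] + margin &
          fc[, 3] > lo[3] - margin & fc[, 3] < hi[3] + margin
  if (!any(keep)) stop("mesh does not reach the target region")
  submesh(mesh, which(keep))
}

# signed distance on the grid: exact point-to-triangle distances in a
# one-voxel band at the surface, chamfer-propagated elsewhere (a few
# percent of the distance, which only ever matters millimetres away
# from any emitted surface). The inside test (parity) uses the full
# watertight mesh; distances use faces cropped to the grid.
.sdf_grid <- function(mesh, g) {
  inside <- array(.voxelize_grid(mesh, g), g$dims)
  band <- which(.mask_band6(inside))
  init <- rep(Inf, prod(g$dims))
  if (length(band)) {
    near <- .crop_faces(mesh, g$origin, .grid_hi(g))
    init[band] <- mesh_closest(near, .grid_index_points(g, band),
                               max_dist = 3 * max(g$spacing))$distance
  }
  d <- chamfer_cpp(init, g$dims, g$spacing)
  ifelse(as.vector(inside), -d, d)
}

# distance to an open patch, seeded exactly on `seed_idx` voxels and
# chamfer-propagated (used as the lateral footprint limiter)
.patch_dist_grid <- function(patch, g, seed_idx, cap) {
  init <- rep(Inf, prod(g$dims))
  if (length(seed_idx)) {
    init[seed_idx] <- mesh_closest(patch, .grid_index_points(g, seed_idx),
                                   max_dist = cap)$distance
  }
  chamfer_cpp(init, g$dims, g$spacing)
}

# ray audit of one channel: the bore must be clear along [s0, s1] from
# the entry (measured along `outward`), and a ray offset radially into
# the wall must find material
.channel_clear <- function(solid, entry, outward, s0, s1, bore_r) {
  o <- entry + (s0 - 5) * outward
  hits <- ray_intersect(solid, o, outward)
  d <- hits$distance - (5 - s0) + s0   # distances measured from s0-5
  sp <- hits$distance + (s0 - 5)
  blocked <- any(sp > s0 + 0.15 & sp < s1 - 0.15)
  # wall probe: offset perpendicular to the axis
  ref <- if (abs(outward[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- ref - sum(ref * outward) * outward
  perp <- perp / sqrt(sum(perp^2))
  wall_hit <- FALSE
  for (ang in c(0, pi / 2)) {
    pv <- cos(ang) * perp + sin(ang) * c(
      outward[2] * perp[3] - outward[3] * perp[2],
      outward[3] * perp[1] - outward[1] * perp[3],
      outward[1] * perp[2] - outward[2] * perp[1])
    h2 <- ray_intersect(solid, o + (bore_r + 0.2) * pv, outward)
    s2 <- h2$distance + (s0 - 5)
    # wall material present if any in/out interval overlaps the span
    np <- length(s2) %/% 2
    for (k in seq_len(np)) {
      if (s2[2 * k - 1] < s1 - 0.1 && s2[2 * k] > s0 + 0.1)
        wall_hit <- TRUE
    }
  }
  !blocked && wall_hit
}

#' Through-channel audit
#'
#' A channel counts as a through-channel when a ray along its axis
#' passes unobstructed over the channel span while an offset ray finds
#' the surrounding wall material.
#' @param guide a [guide_model()].
#' @return logical vector, one per recorded channel.
#' @export
check_channels <- function(guide) {
  ch <- guide$channels
  vapply(seq_len(nrow(ch)), function(i) {
    .channel_clear(guide$solid,
                   c(ch$ex[i], ch$ey[i], ch$ez[i]),
                   c(ch$ox[i], ch$oy[i], ch$oz[i]),
                   ch$s0[i], ch$s1[i], ch$bore_r[i])
  }, logical(1))
}

.channel_record <- function(entry, outward, s0, s1, bore_r, what) {
  data.frame(ex = entry[1], ey = entry[2], ez = entry[3],
             ox = outward[1], oy = outward[2], oz = outward[3],
             s0 = s0, s1 = s1, bore_r = bore_r, what = what)
}

#' Panflute cutting guide
#'
#' Bone-conforming base shell over the footprint region (including any
#' anterior-shaft and plate-conforming extension contained in the
#' footprint and plate), plus one drill tube per planned trajectory with
#' its individually tailored Panflute length, minus all drill and K-wire
#' channels.
#'
#' @param bone watertight bone [trimesh()] with a footprint region.
#' @param plan an [osteotomy_plan()] with depths assigned.
#' @param footprint region label on `bone` covering all entries.
#' @param plate the in-situ [plate_model()] (or `NULL`); the shell also
#'   conforms over its outer surface.
#' @param kwires a [kwire_set()].
#' @param drill_working_length usable drill length (mm).
#' @param clearance bone/plate fit gap (mm).
#' @param thickness shell thickness (mm).
#' @param channel_clearance added to drill/wire diameters for print fit
#'   (mm).
#' @param tube_outer_d drill tube outer diameter (mm).
#' @param resolution level-set grid resolution (mm).
#' @return a [guide_model()] of kind `"cutting"`.
#' @export
design_cutting_guide <- function(bone, plan, footprint = "footprint",
                                 plate = NULL, kwires,
                                 drill_working_length = 60,
                                 clearance = 0.2, thickness = 3,
                                 channel_clearance = 0.1,
                                 tube_outer_d = 2.9, resolution = 0.2) {
  if (!is.null(plate) && plate$role != "in_situ")
    stop("the cutting guide references the in-situ plate")
  trajs <- plan$trajectories
  nt <- length(trajs)
  fidx <- region_faces(bone, footprint)
  patch <- submesh(bone, fidx)
  ent <- t(vapply(trajs, `[[`, numeric(3), "entry"))
  dcover <- mesh_closest(patch, ent)$distance
  if (any(dcover > 3))
    stop("footprint does not cover trajectory entries ",
         paste(which(dcover > 3), collapse = ", "))
  standoff <- clearance + thickness
  bore_r <- (trajs[[1]]$diameter + 2 * channel_clearance) / 2
  L <- vapply(trajs, function(t)
    panflute_tube_length(drill_working_length, t$depth, standoff), 0)
  outward <- -t(vapply(trajs, `[[`, numeric(3), "direction"))
  # channel interference: neighbouring bores must stay clear of each
  # other (including minimal wall material between them)
  for (i in seq_len(nt - 1)) {
    for (j in seq(i + 1, nt)) {
      dd <- .seg_seg_dist(ent[i, ], ent[i, ] + (standoff + L[i]) * outward[i, ],
                          ent[j, ], ent[j, ] + (standoff + L[j]) * outward[j, ])$d
      if (dd < 2 * bore_r + 0.3)
        stop("drill channels ", i, " and ", j,
             " interfere at this spacing/diameter")
    }
  }
  tube_tops <- ent + outward * (standoff + L)
  ext <- trimesh(rbind(patch$vertices, tube_tops,
                       kwires$entries),
                 matrix(c(1L, 1L, 1L), 1), clean = FALSE)
  surfaces <- bone
  patches <- patch
  if (!is.null(plate)) {
    ps <- plate_solid(plate)
    surfaces <- merge_meshes(bone, ps)
    patches <- merge_meshes(patch, ps)
  }
  g <- .csg_grid(.mesh_bbox(ext), resolution,
                 pad = ceiling((clearance + thickness + 2) / resolution))
  pts <- .grid_points(g)
  sdf <- .sdf_grid(surfaces, g)
  seed_idx <- which(abs(sdf) <= 2 * max(g$spacing))
  dpatch <- .patch_dist_grid(
    .crop_faces(patches, g$origin, .grid_hi(g)), g, seed_idx,
    cap = clearance + thickness + 4)
  f <- pmax(clearance - sdf, sdf - clearance - thickness,
            dpatch - (clearance + thickness + 1.5))
  for (i in seq_len(nt)) {
    tube <- .cyl_field(pts, ent[i, ] + clearance * outward[i, ],
                       outward[i, ], tube_outer_d / 2,
                       standoff + L[i] - clearance)
    # keep the fit gap: tube material may not come closer than the
    # clearance to the bone
    tube <- pmax(tube, clearance - sdf)
    f <- pmin(f, tube)
  }
  channels <- list()
  for (i in seq_len(nt)) {
    ch <- .cyl_field(pts, ent[i, ] - 2 * outward[i, ], outward[i, ],
                     bore_r, standoff + L[i] + 4)
    f <- pmax(f, -ch)
    channels[[length(channels) + 1]] <-
      .channel_record(ent[i, ], outward[i, ], 0, standoff + L[i],
                      bore_r, sprintf("drill_%d", i))
  }
  kw_r <- (kwires$diameter + 2 * channel_clearance) / 2
  # wires over the in-situ plate exit through the plate-conforming
  # extension, a plate thickness further out
  kw_span <- standoff + if (is.null(plate)) 0 else
    plate$thickness + standoff
  for (i in seq_len(nrow(kwires$entries))) {
    ow <- -kwires$directions[i, ]
    ch <- .cyl_field(pts, kwires$entries[i, ] - 2 * ow, ow, kw_r,
                     kw_span + 6)
    f <- pmax(f, -ch)
    channels[[length(channels) + 1]] <-
      .channel_record(kwires$entries[i, ], ow, 0, kw_span, kw_r,
                      sprintf("kwire_%d", i))
  }
  solid <- .surface_from_field(.close_boundary(f, g$dims), g, iso = 0)
  tubes <- data.frame(trajectory = seq_len(nt), tube_length = L,
                      depth = vapply(trajs, `[[`, 0, "depth"),
                      standoff = standoff,
                      inner_d = 2 * bore_r, outer_d = tube_outer_d)
  kw <- data.frame(kwire = seq_len(nrow(kwires$entries)),
                   diameter = kwires$diameter, bore_d = 2 * kw_r)
  guide_model(solid, "cutting", tubes = tubes, kwires = kw,
              channels = do.call(rbind, channels))
}

#' Intermediate (pre-drill) guide
#'
#' Shell over the shaft footprint with drill channels replicating the
#' new plate's distal screw-hole axes, plus K-wire channels identical to
#' the cutting guide's (the shared physical reference).
#'
#' @param bone bone [trimesh()] with the footprint region.
#' @param new_plate the new [plate_model()] (`role = "new"`), distal
#'   holes labelled.
#' @param kwires the shared [kwire_set()].
#' @param footprint region label on `bone`.
#' @param tube_length short guide-tube length above the shell (mm).
#' @inheritParams design_cutting_guide
#' @return a [guide_model()] of kind `"intermediate"`.
#' @export
design_intermediate_guide <- function(bone, new_plate, kwires,
                                      footprint = "footprint",
                                      tube_length = 8, clearance = 0.2,
                                      thickness = 3,
                                      channel_clearance = 0.1,
                                      resolution = 0.25) {
  if (new_plate$role != "new")
    stop("the intermediate guide predrills for the new plate")
  holes <- new_plate$holes[new_plate$holes$set == "distal", , drop = FALSE]
  if (nrow(holes) == 0) stop("new plate has no labelled distal holes")
  fidx <- region_faces(bone, footprint)
  patch <- submesh(bone, fidx)
  hent <- as.matrix(holes[, c("px", "py", "pz")])
  hdir <- as.matrix(holes[, c("dx", "dy", "dz")])
  hdir <- hdir / sqrt(rowSums(hdir^2))
  kent <- kwires$entries
  reach <- mesh_closest(patch, rbind(hent, kent))$distance
  if (any(reach > 15))
    stop("K-wire or screw-hole axes not reachable from the footprint")
  standoff <- clearance + thickness
  ext <- trimesh(rbind(patch$vertices,
                       hent - (standoff + tube_length) * hdir, kent),
                 matrix(c(1L, 1L, 1L), 1), clean = FALSE)
  g <- .csg_grid(.mesh_bbox(ext), resolution,
                 pad = ceiling((clearance + thickness + 2) / resolution))
  pts <- .grid_points(g)
  sdf <- .sdf_grid(bone, g)
  seed_idx <- which(abs(sdf) <= 2 * max(g$spacing))
  dpatch <- .patch_dist_grid(
    .crop_faces(patch, g$origin, .grid_hi(g)), g, seed_idx,
    cap = clearance + thickness + 4)
  f <- pmax(clearance - sdf, sdf - clearance - thickness,
            dpatch - (clearance + thickness + 1.5))
  channels <- list()
  bore_r <- (holes$diameter[1] + 2 * channel_clearance) / 2
  # all tubes first, then all channels: carving must come last so a
  # neighbouring tube cannot refill an already-cut bore
  for (i in seq_len(nrow(holes))) {
    ow <- -hdir[i, ]
    tube <- .cyl_field(pts, hent[i, ] + clearance * ow, ow,
                       bore_r + 1.2, standoff + tube_length - clearance)
    tube <- pmax(tube, clearance - sdf)
    f <- pmin(f, tube)
  }
  for (i in seq_len(nrow(holes))) {
    ow <- -hdir[i, ]
    ch <- .cyl_field(pts, hent[i, ] - 2 * ow, ow, bore_r,
                     standoff + tube_length + 4)
    f <- pmax(f, -ch)
    channels[[length(channels) + 1]] <-
      .channel_record(hent[i, ], ow, 0, standoff + tube_length, bore_r,
                      sprintf("screw_%d", i))
  }
  kw_r <- (kwires$diameter + 2 * channel_clearance) / 2
  for (i in seq_len(nrow(kent))) {
    ow <- -kwires$directions[i, ]
    ch <- .cyl_field(pts, kent[i, ] - 2 * ow, ow, kw_r, standoff + 6)
    f <- pmax(f, -ch)
    channels[[length(channels) + 1]] <-
      .channel_record(kent[i, ], ow, 0, standoff, kw_r,
                      sprintf("kwire_%d", i))
  }
  solid <- .surface_from_field(.close_boundary(f, g$dims), g, iso = 0)
  guide_model(solid, "intermediate",
              tubes = data.frame(hole = seq_len(nrow(holes)),
                                 tube_length = tube_length,
                                 inner_d = 2 * bore_r),
              kwires = data.frame(kwire = seq_len(nrow(kent)),
                                  diameter = kwires$diameter,
                                  bore_d = 2 * kw_r),
              channels = do.call(rbind, channels))
}

#' Reposition guide
#'
#' Envelops the new plate (attached to the fragment in its planned
#' position) as a negative imprint with fit clearance, and carries the
#' shared K-wire channels: when the physical plate seats in the guide
#' and the wires engage, the fragment pose equals the planned pose.
#'
#' @param new_plate the new [plate_model()] at its planned position.
#' @param bone_planned planned bone model (used to keep the guide off
#'   the bone).
#' @param kwires the shared [kwire_set()].
#' @param shell envelope thickness (mm).
#' @inheritParams design_cutting_guide
#' @return a [guide_model()] of kind `"reposition"`; attribute
#'   `seating` holds the pose-constraint condition diagnostics.
#' @export
design_reposition_guide <- function(new_plate, bone_planned, kwires,
                                    shell = 3, clearance = 0.2,
                                    channel_clearance = 0.1,
                                    resolution = 0.25) {
  seat <- pose_from_constraints(new_plate, kwires)
  if (seat$underdetermined)
    stop("reposition guide seating is underdetermined (symmetric plate and insufficient K-wires)")
  ps <- plate_solid(new_plate)
  ext <- trimesh(rbind(ps$vertices, kwires$entries),
                 matrix(c(1L, 1L, 1L), 1), clean = FALSE)
  g <- .csg_grid(.mesh_bbox(ext), resolution,
                 pad = ceiling((clearance + shell + 2) / resolution))
  pts <- .grid_points(g)
  dplate <- .sdf_grid(ps, g)
  dbone <- .sdf_grid(bone_planned, g)
  f <- pmax(clearance - dplate, dplate - clearance - shell,
            clearance - dbone)
  channels <- list()
  kw_r <- (kwires$diameter + 2 * channel_clearance) / 2
  for (i in seq_len(nrow(kwires$entries))) {
    ow <- -kwires$directions[i, ]
    ch <- .cyl_field(pts, kwires$entries[i, ] - 60 * ow, ow, kw_r, 120)
    f <- pmax(f, -ch)
    # audit span: where the wire axis crosses the plate envelope
    s_rel <- sweep(new_plate$centerline, 2, kwires$entries[i, ]) %*% ow
    s_c <- s_rel[which.min(abs(s_rel))]
    half <- clearance + shell + new_plate$thickness + 1
    channels[[length(channels) + 1]] <-
      .channel_record(kwires$entries[i, ], ow, s_c - half, s_c + half,
                      kw_r, sprintf("kwire_%d", i))
  }
  solid <- .surface_from_field(.close_boundary(f, g$dims), g, iso = 0)
  out <- guide_model(solid, "reposition",
                     kwires = data.frame(
                       kwire = seq_len(nrow(kwires$entries)),
                       diameter = kwires$diameter, bore_d = 2 * kw_r),
                     channels = do.call(rbind, channels))
  attr(out, "seating") <- seat
  out
}

#' Rigid pose from seating constraints
#'
#' Software verification of the reposition principle: the plate's outer
#' surface is constrained to its imprint (point-to-plane contacts) and
#' each K-wire to its axis (two lateral constraints per sample). Solves
#' the linearized least-squares pose correction for a perturbed start
#' and reports the 6-dof constraint condition; a rank-deficient system
#' (e.g. a straight slab plate with no wires, free to slide) is flagged
#' underdetermined.
#'
#' @param plate a [plate_model()] at the planned pose.
#' @param kwires a [kwire_set()] or `NULL` to drop wire constraints.
#' @param perturb initial pose offset (a [rigid_transform()]); default
#'   identity.
#' @param iterations Gauss-Newton iterations.
#' @return list with `transform` (the seated pose of the assembly:
#'   identity when seating succeeds, whatever the starting `perturb`),
#'   `residual` (rms, mm), `eigenvalues` of the normalized 6x6
#'   constraint matrix, and `underdetermined`.
#' @export
pose_from_constraints <- function(plate, kwires,
                                  perturb = rigid_transform(),
                                  iterations = 10) {
  ps <- plate_solid(plate)
  fc <- face_centers(ps)
  fn <- face_normals(ps)
  fa <- face_areas(ps)
  # drop the end caps (the last four faces of the swept slab): the
  # guide slides onto the plate, so the imprint cannot bear on the ends
  ncap <- nrow(fc)
  keep <- fa > 1e-6 & seq_len(ncap) <= ncap - 4
  fc <- fc[keep, , drop = FALSE]
  fn <- fn[keep, , drop = FALSE]
  wts <- sqrt(fa[keep])
  pts <- fc
  nrms <- fn
  if (!is.null(kwires)) {
    for (i in seq_len(nrow(kwires$entries))) {
      d <- kwires$directions[i, ]
      ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      p1 <- ref - sum(ref * d) * d
      p1 <- p1 / sqrt(sum(p1^2))
      p2 <- c(d[2] * p1[3] - d[3] * p1[2], d[3] * p1[1] - d[1] * p1[3],
              d[1] * p1[2] - d[2] * p1[1])
      for (s in c(0, 10, 20)) {
        ax <- kwires$entries[i, ] + s * d
        pts <- rbind(pts, ax, ax)
        nrms <- rbind(nrms, p1, p2)
        wts <- c(wts, rep(mean(wts), 2))
      }
    }
  }
  # unit average weight and lever-scaled rotations: the 6x6 constraint
  # matrix then measures mean-square contact response per unit pose
  # motion, so a single absolute threshold detects rank deficiency
  wts <- wts / sqrt(mean(wts^2))
  scale_r <- max(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2)))
  T <- perturb
  for (it in seq_len(iterations)) {
    cur <- apply_transform(T, pts)
    r <- rowSums((cur - pts) * nrms) * wts
    cxn <- .cross_rows(sweep(cur, 2, colMeans(pts)), nrms)
    A <- cbind(cxn * scale_r, nrms) * wts
    AtA <- crossprod(A) / nrow(A)
    ev <- eigen(AtA, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-4) {
      return(list(transform = T, residual = sqrt(mean(r^2)),
                  eigenvalues = ev, underdetermined = TRUE))
    }
    x <- solve(AtA + 1e-12 * diag(6), -crossprod(A, r) / nrow(A))
    w <- x[1:3] * scale_r
    cm <- colMeans(pts)
    Rd <- .rodrigues(w)
    Td <- rigid_transform(Rd, as.numeric(x[4:6]) + cm -
                            as.numeric(Rd %*% cm))
    T <- rt_compose(Td, T)
    if (sqrt(sum(Td$translation^2)) < 1e-10) break
  }
  cur <- apply_transform(T, pts)
  r <- rowSums((cur - pts) * nrms)
  list(transform = T, residual = sqrt(mean(r^2)), eigenvalues = ev,
       underdetermined = FALSE)
}

#' Export guides as STL plus a JSON manifest
#'
#' Validates each guide (watertight solid, through-channels) before
#' writing; one binary STL per guide and a manifest with the tube and
#' K-wire tables and md5 checksums. Re-importing reproduces the solids
#' bit-identically.
#'
#' @param guides list of [guide_model()] objects.
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
export_guides <- function(guides, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (gd in guides) {
    if (!is_watertight(gd$solid))
      stop("guide '", gd$kind, "' failed the watertight invariant; export blocked")
    if (!all(check_channels(gd)))
      stop("guide '", gd$kind, "' has blocked channels; export blocked")
    fn <- file.path(dir, paste0(gd$kind, "_guide.stl"))
    write_stl(gd$solid, fn)
    entries[[gd$kind]] <- list(
      file = basename(fn),
      md5 = unname(tools::md5sum(fn)),
      n_faces = nrow(gd$solid$faces),
      volume_mm3 = mesh_volume(gd$solid),
      tubes = gd$tubes,
      kwires = gd$kwires)
  }
  manifest <- list(guides = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
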