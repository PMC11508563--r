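#' @useDynLib panflute, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm quantile sd
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Triangle surface mesh
#'
#' The universal geometry currency of the package: a triangle soup with
#' vertices in millimetres, 1-based face indices and an optional per-face
#' region label (e.g. `"fragment"`, `"shaft"`). Degenerate (zero-area)
#' faces are removed on construction.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param regions optional character vector of per-face region labels
#'   (length m), or `NULL`.
#' @param clean drop zero-area faces (default `TRUE`).
#' @return an object of class `"trimesh"`.
#' @export
trimesh <- function(vertices, faces, regions = NULL, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(regions)) {
    regions <- as.character(regions)
    stopifnot(length(regions) == nrow(faces))
  }
  if (clean && nrow(faces) > 0) {
    a <- vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 2], , drop = FALSE]
    cc <- vertices[faces[, 3], , drop = FALSE]
    n <- .cross_rows(b - a, cc - a)
    area2 <- sqrt(rowSums(n * n))
    keep <- area2 > 1e-14
    faces <- faces[keep, , drop = FALSE]
    if (!is.null(regions)) regions <- regions[keep]
  }
  structure(list(vertices = vertices, faces = faces, regions = regions),
            class = "trimesh")
}

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$regions))
                sprintf(", regions: %s",
                        paste(unique(x$regions[nzchar(x$regions)]),
                              collapse = ", "))
              else ""))
  invisible(x)
}

#' Face geometry helpers
#' @param mesh a [trimesh()].
#' @return `face_centers`/`face_normals` return m x 3 matrices,
#'   `face_areas` a numeric vector.
#' @export
face_centers <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

#' @rdname face_centers
#' @export
face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  n <- .cross_rows(b - a, cc - a)
  len <- sqrt(rowSums(n * n))
  n / pmax(len, 1e-300)
}

#' @rdname face_centers
#' @export
face_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  n <- .cross_rows(b - a, cc - a)
  0.5 * sqrt(rowSums(n * n))
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra to
#' the origin); positive for outward-oriented watertight solids.
#' @param mesh a [trimesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(rowSums(a * .cross_rows(b, cc))) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Surface centroid of a mesh (or of one region)
#'
#' Area-weighted mean of face centres: a tessellation-independent
#' surface integral, unlike a plain vertex mean (vertex density varies
#' between meshing routes).
#' @param mesh a [trimesh()].
#' @param region optional region label restricting the integral.
#' @export
mesh_centroid <- function(mesh, region = NULL) {
  idx <- if (is.null(region)) seq_len(nrow(mesh$faces))
         else region_faces(mesh, region)
  sub <- if (is.null(region)) mesh else submesh(mesh, idx)
  a <- face_areas(sub)
  colSums(face_centers(sub) * a) / sum(a)
}

#' Watertightness and edge diagnostics
#'
#' A mesh is watertight when every undirected edge is shared by exactly
#' two faces and the two directed copies run in opposite directions
#' (consistent winding).
#' @param mesh a [trimesh()].
#' @return `is_watertight` returns `TRUE`/`FALSE`; `open_edges` the
#'   undirected edges not shared by exactly two faces (k x 2 matrix).
#' @export
is_watertight <- function(mesh) {
  nrow(open_edges(mesh)) == 0 && .windings_consistent(mesh)
}

#' @rdname is_watertight
#' @export
open_edges <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(matrix(integer(), 0, 2))
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) +
    pmax(e[, 1], e[, 2])
  cnt <- table(key)
  bad <- as.numeric(names(cnt)[cnt != 2])
  if (!length(bad)) return(matrix(integer(), 0, 2))
  nv1 <- nrow(mesh$vertices) + 1
  cbind(bad %/% nv1, bad %% nv1)
}

.windings_consistent <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(TRUE)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- e[, 1] * (nrow(mesh$vertices) + 1) + e[, 2]
  !any(duplicated(key))
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric (mm).
#' @return object of class `"rigid_transform"`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm>\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose, invert and apply rigid transforms
#'
#' `rt_compose(a, b)` is the transform "apply `b`, then `a`".
#' @param a,b,T rigid transforms.
#' @param points n x 3 matrix or length-3 vector.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rt_compose
#' @export
rt_inverse <- function(T) {
  rigid_transform(t(T$rotation),
                  -as.numeric(t(T$rotation) %*% T$translation))
}

#' @rdname rt_compose
#' @export
apply_transform <- function(T, points) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  out <- points %*% t(T$rotation)
  sweep(out, 2, T$translation, "+")
}

#' Apply a rigid transform to a mesh
#'
#' Topology and region labels are unchanged.
#' @param mesh a [trimesh()].
#' @param T a [rigid_transform()].
#' @export
transform_mesh <- function(mesh, T) {
  stopifnot(nrow(mesh$vertices) > 0)
  trimesh(apply_transform(T, mesh$vertices), mesh$faces, mesh$regions,
          clean = FALSE)
}

#' Oriented plane
#' @param point a point on the plane (mm).
#' @param normal plane normal; normalized internally.
#' @export
plane <- function(point, normal) {
  n <- as.numeric(normal)
  len <- sqrt(sum(n^2))
  if (len < 1e-12) stop("plane normal must be nonzero")
  structure(list(point = as.numeric(point), normal = n / len),
            class = "plane")
}

#' Mirror a mesh across a plane
#'
#' Vertices are reflected; face windings are flipped so outward normals
#' remain outward (a reflection reverses orientation).
#' @param mesh a [trimesh()].
#' @param p a [plane()].
#' @export
mirror_mesh <- function(mesh, p) {
  d <- sweep(mesh$vertices, 2, p$point, "-") %*% p$normal
  v <- mesh$vertices - 2 * d %*% t(p$normal)
  trimesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE], mesh$regions,
          clean = FALSE)
}

#' Anatomical coordinate frame
#'
#' Right-handed frame with x anterior(-) to posterior(+), y lateral(-) to
#' medial(+) for a right leg (reading of y flips for the left side), and
#' z caudal(-) to cranial(+).
#' @param origin frame origin (mm).
#' @param x_axis,y_axis,z_axis orthonormal right-handed axes.
#' @param side `"right"` or `"left"` (controls direction annotations).
#' @export
anatomical_frame <- function(origin = c(0, 0, 0),
                             x_axis = c(1, 0, 0), y_axis = c(0, 1, 0),
                             z_axis = c(0, 0, 1),
                             side = c("right", "left")) {
  side <- match.arg(side)
  A <- cbind(as.numeric(x_axis), as.numeric(y_axis), as.numeric(z_axis))
  if (max(abs(crossprod(A) - diag(3))) > 1e-9)
    stop("frame axes must be orthonormal")
  cr <- c(A[2, 1] * A[3, 2] - A[3, 1] * A[2, 2],
          A[3, 1] * A[1, 2] - A[1, 1] * A[3, 2],
          A[1, 1] * A[2, 2] - A[2, 1] * A[1, 2])
  if (max(abs(cr - A[, 3])) > 1e-9)
    stop("frame must be right-handed (x cross y = z)")
  structure(list(origin = as.numeric(origin), x_axis = A[, 1],
                 y_axis = A[, 2], z_axis = A[, 3], side = side),
            class = "anatomical_frame")
}

.frame_basis <- function(frame) {
  cbind(frame$x_axis, frame$y_axis, frame$z_axis)
}

#' Ray / mesh intersection
#'
#' All intersections of a ray with a mesh, ordered by distance. Rays that
#' graze an edge or vertex are re-cast from an origin jittered by 1e-6 mm
#' along a fixed tie-break direction (deterministic, never random).
#'
#' @param mesh a [trimesh()].
#' @param origin ray origin (mm).
#' @param direction ray direction (normalized internally).
#' @return data.frame with columns `distance` (mm) and `face`.
#' @export
ray_intersect <- function(mesh, origin, direction) {
  d <- as.numeric(direction)
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("ray direction must be nonzero")
  d <- d / len
  o <- as.numeric(origin)
  # deterministic tie-break direction orthogonal to the ray
  ref <- c(0.12054, 0.29471, 0.94788)
  tb <- c(d[2] * ref[3] - d[3] * ref[2],
          d[3] * ref[1] - d[1] * ref[3],
          d[1] * ref[2] - d[2] * ref[1])
  if (sqrt(sum(tb^2)) < 1e-6) tb <- c(1, 0, 0)
  tb <- tb / sqrt(sum(tb^2))
  for (attempt in 0:3) {
    hits <- ray_mesh_cpp(mesh$vertices, mesh$faces, o + attempt * 1e-6 * tb, d)
    if (nrow(hits) == 0)
      return(data.frame(distance = numeric(), face = integer()))
    if (min(hits[, 3]) > 1e-9 || attempt == 3) break
  }
  # collapse duplicate hits (shared edges seen by both triangles)
  keep <- c(TRUE, diff(hits[, 1]) > 1e-9)
  hits <- hits[keep, , drop = FALSE]
  data.frame(distance = hits[, 1], face = as.integer(hits[, 2]))
}

#' Point-in-solid test by ray parity
#' @param mesh watertight [trimesh()].
#' @param points n x 3 matrix.
#' @return logical vector.
#' @export
points_in_mesh <- function(mesh, points) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  apply(points, 1, function(p) {
    nrow(ray_intersect(mesh, p, c(0.23579, 0.51731, 0.82245))) %% 2 == 1
  })
}

#' Merge two meshes into one (multi-component) mesh
#' @param a,b [trimesh()] objects.
#' @export
merge_meshes <- function(a, b) {
  off <- nrow(a$vertices)
  reg <- NULL
  if (!is.null(a$regions) || !is.null(b$regions)) {
    reg <- c(a$regions %||% rep("", nrow(a$faces)),
             b$regions %||% rep("", nrow(b$faces)))
  }
  trimesh(rbind(a$vertices, b$vertices), rbind(a$faces, b$faces + off),
          reg, clean = FALSE)
}

#' Region utilities
#'
#' `region_faces` returns the face indices carrying a label; `submesh`
#' extracts a face subset (re-indexing vertices); `set_region` assigns a
#' label to a set of faces.
#' @param mesh a [trimesh()].
#' @param label region label.
#' @param faces integer face indices.
#' @export
region_faces <- function(mesh, label) {
  if (is.null(mesh$regions)) stop("mesh has no region labels")
  which(mesh$regions == label)
}

#' @rdname region_faces
#' @export
submesh <- function(mesh, faces) {
  if (is.character(faces)) faces <- region_faces(mesh, faces)
  f <- mesh$faces[faces, , drop = FALSE]
  vid <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[vid] <- seq_along(vid)
  trimesh(mesh$vertices[vid, , drop = FALSE],
          matrix(remap[f], ncol = 3),
          if (!is.null(mesh$regions)) mesh$regions[faces],
          clean = FALSE)
}

#' @rdname region_faces
#' @export
set_region <- function(mesh, faces, label) {
  if (is.null(mesh$regions)) mesh$regions <- rep("", nrow(mesh$faces))
  mesh$regions[faces] <- label
  mesh
}

#' Annular (or solid) cylinder mesh
#'
#' Watertight tube used for drill tubes of the Panflute guide. With
#' `inner_d = 0` a solid cylinder is produced.
#'
#' @param axis_point centre of the bottom face (mm).
#' @param direction tube axis (normalized internally).
#' @param length tube length (mm), > 0.
#' @param inner_d,outer_d inner and outer diameters (mm), `outer_d >
#'   inner_d >= 0`.
#' @param segments circumferential segments (default 64; analytic volume
#'   matched within 1 percent at the default).
#' @export
make_tube <- function(axis_point, direction, length, inner_d, outer_d,
                      segments = 64) {
  if (length <= 0 || outer_d <= 0 || inner_d < 0 || outer_d <= inner_d)
    stop("make_tube: need outer_d > inner_d >= 0 and length > 0")
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  u <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- u - sum(u * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = segments + 1)[-(segments + 1)]
  circ <- function(r, h) {
    p <- outer(cos(th) * r, e1) + outer(sin(th) * r, e2)
    sweep(p, 2, as.numeric(axis_point) + h * d, "+")
  }
  ro <- outer_d / 2
  ri <- inner_d / 2
  n <- segments
  nxt <- c(2:n, 1)
  if (ri > 0) {
    v <- rbind(circ(ro, 0), circ(ro, length), circ(ri, 0), circ(ri, length))
    ob <- 1:n; ot <- n + (1:n); ib <- 2 * n + (1:n); it <- 3 * n + (1:n)
    f <- rbind(
      cbind(ob, ob[nxt], ot[nxt]), cbind(ob, ot[nxt], ot),      # outer wall
      cbind(ib, it[nxt], ib[nxt]), cbind(ib, it, it[nxt]),      # inner wall
      cbind(ob[nxt], ob, ib),      cbind(ob[nxt], ib, ib[nxt]), # bottom
      cbind(ot, ot[nxt], it[nxt]), cbind(ot, it[nxt], it))      # top
  } else {
    v <- rbind(circ(ro, 0), circ(ro, length),
               matrix(axis_point, 1), matrix(as.numeric(axis_point) +
                                               length * d, 1))
    ob <- 1:n; ot <- n + (1:n); cb <- 2 * n + 1; ct <- 2 * n + 2
    f <- rbind(
      cbind(ob, ob[nxt], ot[nxt]), cbind(ob, ot[nxt], ot),
      cbind(ob[nxt], ob, cb),
      cbind(ot, ot[nxt], ct))
  }
  trimesh(v, f, clean = FALSE)
}

#' Primitive meshes for tests and fixtures
#'
#' `mesh_box` builds an axis-aligned box; `mesh_sphere` a UV sphere.
#' @param center centre (mm).
#' @param size length-3 box edge lengths (mm).
#' @param radius sphere radius (mm).
#' @param n angular resolution (segments around the equator).
#' @export
mesh_box <- function(center = c(0, 0, 0), size = c(1, 1, 1)) {
  h <- size / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s) * rep(h, each = 8), 2, center, "+")
  f <- rbind(c(1, 3, 7), c(1, 7, 5),   # x-
             c(2, 8, 4), c(2, 6, 8),   # x+
             c(1, 5, 6), c(1, 6, 2),   # y-
             c(3, 4, 8), c(3, 8, 7),   # y+
             c(1, 2, 4), c(1, 4, 3),   # z-
             c(5, 7, 8), c(5, 8, 6))   # z+
  trimesh(v, f, clean = FALSE)
}

#' @rdname mesh_box
#' @export
mesh_sphere <- function(center = c(0, 0, 0), radius = 1, n = 48) {
  nth <- n
  nph <- max(8, n %/% 2)
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  ph <- seq(0, pi, length.out = nph + 1)[c(-1, -(nph + 1))]
  v <- do.call(rbind, lapply(ph, function(p) {
    cbind(radius * sin(p) * cos(th), radius * sin(p) * sin(th),
          radius * cos(p))
  }))
  np <- nrow(v)
  v <- rbind(v, c(0, 0, radius), c(0, 0, -radius))
  top <- np + 1
  bot <- np + 2
  idx <- function(i, j) (i - 1) * nth + ((j - 1) %% nth) + 1
  f <- list()
  nr <- length(ph)
  for (i in seq_len(nr - 1)) {
    for (j in seq_len(nth)) {
      f[[length(f) + 1]] <- c(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1))
      f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j))
    }
  }
  for (j in seq_len(nth)) {
    f[[length(f) + 1]] <- c(top, idx(1, j + 1), idx(1, j))
    f[[length(f) + 1]] <- c(bot, idx(nr, j), idx(nr, j + 1))
  }
  v <- sweep(v, 2, center, "+")
  out <- trimesh(v, do.call(rbind, f), clean = FALSE)
  if (mesh_volume(out) < 0)
    out <- trimesh(out$vertices, out$faces[, c(1, 3, 2)], clean = FALSE)
  out
}

#' Closest points on a mesh
#'
#' For each query point, the closest point on the mesh surface, the
#' distance and the face it lies on (uniform-grid accelerated).
#' @param mesh a [trimesh()].
#' @param points n x 3 matrix.
#' @param max_dist search cap (mm): points farther than this report
#'   `distance = max_dist` and `face = 0`. A finite cap speeds up
#'   banded level-set evaluations considerably.
#' @return list with `distance`, `point` (n x 3), `face`.
#' @export
mesh_closest <- function(mesh, points, max_dist = Inf) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  mesh_closest_cpp(mesh$vertices, mesh$faces, as.matrix(points), max_dist)
}

#' Laplacian (Taubin) smoothing
#'
#' Volume-preserving lambda/mu smoothing; used optionally after surface
#' extraction.
#' @param mesh a [trimesh()].
#' @param iterations smoothing passes.
#' @param lambda,mu Taubin parameters.
#' @export
taubin_smooth <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  v <- mesh$vertices
  nv <- nrow(v)
  deg <- tabulate(e[, 1], nbins = nv)
  step <- function(v, w) {
    nb <- rowsum(v[e[, 2], , drop = FALSE], e[, 1], reorder = TRUE)
    lap <- nb / pmax(deg, 1) - v[as.integer(rownames(nb)), , drop = FALSE]
    out <- v
    out[as.integer(rownames(nb)), ] <-
      v[as.integer(rownames(nb)), ] + w * lap
    out
  }
  for (i in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  trimesh(v, mesh$faces, mesh$regions, clean = FALSE)
}
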