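# Q3DCT engine: mirror / shaft-align the contralateral template, fit the
# fragment's rigid transform by trimmed ICP, and decompose it into the
# six deformity parameters (x, y, z translations; zeta sagittal, theta
# coronal, phi axial rotations).

.deg2rad <- function(a) a * pi / 180
.rad2deg <- function(a) a * 180 / pi

.rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
.rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
.rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Euler rotation of the deformity convention
#'
#' Intrinsic z-x-y sequence: axial `phi` about z, then coronal `theta`
#' about x, then sagittal `zeta` about y, i.e.
#' `R = Rz(phi) %*% Rx(theta) %*% Ry(zeta)`. Angles in degrees.
#' @param zeta,theta,phi rotations in degrees.
#' @export
euler_zxy <- function(zeta, theta, phi) {
  .rot_z(.deg2rad(phi)) %*% .rot_x(.deg2rad(theta)) %*%
    .rot_y(.deg2rad(zeta))
}

#' @rdname euler_zxy
#' @param R 3 x 3 rotation matrix.
#' @return `euler_from_rotation` returns a list with `zeta`, `theta`,
#'   `phi` (degrees, in (-180, 180]) and a `gimbal` flag set near
#'   theta = +/-90 deg, where the reported convention fixes `phi = 0`.
#' @export
euler_from_rotation <- function(R) {
  s_theta <- max(-1, min(1, R[3, 2]))
  theta <- asin(s_theta)
  gimbal <- abs(abs(.rad2deg(theta)) - 90) < 0.1
  if (!gimbal) {
    zeta <- atan2(-R[3, 1], R[3, 3])
    phi <- atan2(-R[1, 2], R[2, 2])
  } else {
    phi <- 0
    zeta <- atan2(R[1, 3], R[1, 1])
  }
  list(zeta = .rad2deg(zeta), theta = .rad2deg(theta),
       phi = .rad2deg(phi), gimbal = gimbal)
}

#' Build the rigid transform of a six-parameter deformity
#'
#' Rotation about `center` by the intrinsic z-x-y Euler angles, followed
#' by translation along the anatomical frame axes. This is the exact
#' inverse-path of [decompose_transform()], and the convention used by
#' the phantom generator when implanting deformities.
#'
#' @param dx,dy,dz translations (mm) along the frame's x
#'   (anterior-posterior), y (lateral-medial) and z (caudal-cranial)
#'   axes.
#' @param zeta,theta,phi sagittal / coronal / axial rotations (degrees).
#' @param center rotation centre (mm, world coordinates).
#' @param frame an [anatomical_frame()].
#' @export
deformity_transform <- function(dx = 0, dy = 0, dz = 0, zeta = 0,
                                theta = 0, phi = 0, center = c(0, 0, 0),
                                frame = anatomical_frame()) {
  A <- .frame_basis(frame)
  Rw <- A %*% euler_zxy(zeta, theta, phi) %*% t(A)
  tw <- as.numeric(A %*% c(dx, dy, dz))
  center <- as.numeric(center)
  rigid_transform(Rw, center + tw - as.numeric(Rw %*% center))
}

#' Decompose a rigid transform into the six deformity parameters
#'
#' Translations are the displacement of `center` projected on the frame
#' axes; the rotation is decomposed as intrinsic z-x-y (axial phi, then
#' coronal theta, then sagittal zeta). Recomposition through
#' [deformity_transform()] reproduces the transform to machine
#' precision away from gimbal lock.
#'
#' @param T a [rigid_transform()].
#' @param frame an [anatomical_frame()].
#' @param center rotation centre; the reported translations depend on
#'   it (default: the frame origin).
#' @param context `"pre"` or `"planned_vs_postop"`.
#' @return object of class `"deformity_report"`.
#' @export
decompose_transform <- function(T, frame = anatomical_frame(),
                                center = NULL, context = "pre") {
  center <- as.numeric(center %||% frame$origin)
  A <- .frame_basis(frame)
  Rf <- t(A) %*% T$rotation %*% A
  ang <- euler_from_rotation(Rf)
  disp <- as.numeric(apply_transform(T, center)) - center
  tf <- as.numeric(t(A) %*% disp)
  structure(list(dx = tf[1], dy = tf[2], dz = tf[3],
                 zeta = ang$zeta, theta = ang$theta, phi = ang$phi,
                 gimbal = ang$gimbal, center = center,
                 side = frame$side, context = context),
            class = "deformity_report")
}

.dir_label <- function(value, pos, neg) {
  if (abs(value) < 1e-9) "" else if (value > 0) pos else neg
}

#' @export
print.deformity_report <- function(x, ...) {
  lat <- if (x$side == "right") c("medial", "lateral")
         else c("lateral", "medial")
  cat(sprintf("Deformity report (%s)\n", x$context))
  cat(sprintf("  x (anterior-posterior): %7.2f mm %s\n", abs(x$dx),
              .dir_label(x$dx, "posterior", "anterior")))
  cat(sprintf("  y (medial-lateral):     %7.2f mm %s\n", abs(x$dy),
              .dir_label(x$dy, lat[1], lat[2])))
  cat(sprintf("  z (cranial-caudal):     %7.2f mm %s\n", abs(x$dz),
              .dir_label(x$dz, "cranial", "caudal")))
  cat(sprintf("  zeta  (sagittal):       %7.2f deg\n", x$zeta))
  cat(sprintf("  theta (coronal):        %7.2f deg\n", x$theta))
  cat(sprintf("  phi   (axial):          %7.2f deg\n", x$phi))
  if (isTRUE(x$gimbal))
    cat("  [gimbal proximity: phi fixed to 0 by convention]\n")
  invisible(x)
}

#' @export
coef.deformity_report <- function(object, ...) {
  c(dx = object$dx, dy = object$dy, dz = object$dz,
    zeta = object$zeta, theta = object$theta, phi = object$phi)
}

#' @export
as.data.frame.deformity_report <- function(x, ...) {
  data.frame(parameter = c("dx", "dy", "dz", "zeta", "theta", "phi"),
             value = as.numeric(coef(x)),
             unit = c("mm", "mm", "mm", "deg", "deg", "deg"),
             context = x$context)
}

#' @export
plot.deformity_report <- function(x, ...) {
  v <- coef(x)
  graphics::barplot(abs(v), names.arg = names(v),
                    ylab = "magnitude (mm / deg)",
                    main = sprintf("Deformity (%s)", x$context), ...)
  invisible(x)
}

# ---- ICP internals -------------------------------------------------------

.subsample_rows <- function(m, nmax) {
  n <- nrow(m)
  if (n <= nmax) return(m)
  m[unique(round(seq(1, n, length.out = nmax))), , drop = FALSE]
}

.rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.kabsch <- function(src, dst) {
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

# faces of an open patch lying within `margin` mm of its boundary;
# correspondences landing there are clamped (no true counterpart) and
# are rejected during partial-overlap registration
.boundary_faces <- function(mesh, margin = 1.0) {
  oe <- open_edges(mesh)
  if (nrow(oe) == 0) return(integer())
  bv <- unique(as.vector(oe))
  fc <- face_centers(mesh)
  bp <- mesh$vertices[bv, , drop = FALSE]
  # distance from each face centre to the nearest boundary vertex
  idx <- integer()
  for (start in seq(1, nrow(fc), by = 20000)) {
    sl <- start:min(start + 19999, nrow(fc))
    dmin <- rep(Inf, length(sl))
    for (bstart in seq(1, nrow(bp), by = 2000)) {
      bs <- bstart:min(bstart + 1999, nrow(bp))
      dd <- sqrt(outer(rowSums(fc[sl, , drop = FALSE]^2), rep(1, length(bs))) -
                   2 * fc[sl, , drop = FALSE] %*% t(bp[bs, , drop = FALSE]) +
                   outer(rep(1, length(sl)), rowSums(bp[bs, , drop = FALSE]^2)))
      dmin <- pmin(dmin, apply(dd, 1, min))
    }
    idx <- c(idx, sl[dmin < margin])
  }
  idx
}

# one ICP run; method "point" (trimmed point-to-point) or "plane"
# (point-to-plane, untrimmed unless trim < 1)
.icp <- function(src, target, init, method = c("point", "plane"),
                 trim = 1.0, max_iter = 100, tol = 1e-6,
                 exclude_faces = NULL, grid = NULL) {
  method <- match.arg(method)
  tn <- face_normals(target)
  excl <- if (length(exclude_faces))
    seq_len(nrow(target$faces)) %in% exclude_faces else NULL
  if (is.null(grid))
    grid <- mesh_grid_build_cpp(target$vertices, target$faces)
  T <- init
  rms <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- apply_transform(T, src)
    cl <- mesh_grid_query_cpp(grid, cur)
    d <- cl$distance
    # trimmed inliers with a noise-floor guard: the cut never reaches
    # below 3x the median residual, so on outlier-free surfaces the
    # trim is inactive (a plain quantile cut on spatially correlated
    # surface noise drags the fit along its sloppiest rotation mode)
    keep <- if (trim < 1) {
      d <= max(stats::quantile(d, trim), 5 * stats::median(d))
    } else {
      rep(TRUE, length(d))
    }
    if (!is.null(excl)) keep <- keep & !excl[cl$face]
    p <- cur[keep, , drop = FALSE]
    q <- cl$point[keep, , drop = FALSE]
    if (method == "point") {
      Td <- .kabsch(p, q)
    } else {
      n <- tn[cl$face[keep], , drop = FALSE]
      r <- rowSums((p - q) * n)
      cxn <- .cross_rows(p, n)
      A <- cbind(cxn, n)
      AtA <- crossprod(A)
      Atr <- crossprod(A, r)
      x <- tryCatch(solve(AtA + 1e-12 * diag(6), -Atr),
                    error = function(e) rep(0, 6))
      Td <- rigid_transform(.rodrigues(x[1:3]), x[4:6])
    }
    T <- rt_compose(Td, T)
    rms <- sqrt(mean(rowSums((apply_transform(Td, p) - q)^2)))
    step_t <- sqrt(sum(Td$translation^2))
    step_r <- acos(min(1, max(-1, (sum(diag(Td$rotation)) - 1) / 2)))
    if (step_t < tol && step_r < tol) {
      converged <- TRUE
      break
    }
  }
  list(transform = T, rms = rms, converged = converged, iterations = it)
}

.pca_inits <- function(src, dst_pts) {
  cs <- colMeans(src)
  cd <- colMeans(dst_pts)
  es <- eigen(stats::cov(src), symmetric = TRUE)$vectors
  ed <- eigen(stats::cov(dst_pts), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(ed) < 0) ed[, 3] <- -ed[, 3]
  inits <- list(rigid_transform(diag(3), cd - cs))
  for (s1 in c(1, -1)) {
    for (s2 in c(1, -1)) {
      S <- diag(c(s1, s2, s1 * s2))
      R <- ed %*% S %*% t(es)
      inits[[length(inits) + 1]] <-
        rigid_transform(R, cd - as.numeric(R %*% cs))
    }
  }
  inits
}

#' Align two bones on the shaft
#'
#' Point-to-plane ICP restricted to the moving mesh's shaft region
#' (centroid initialization with a PCA fallback, fixed iteration cap,
#' deterministic). Used to seat the mirrored contralateral template on
#' the affected bone.
#'
#' @param moving,fixed [trimesh()] objects; `moving` carries the shaft
#'   region label.
#' @param shaft_region region label on `moving` (default `"shaft"`); if
#'   absent, all faces below 40 percent of the proximal-distal extent
#'   are used.
#' @param max_iter,tol iteration cap and convergence threshold (mm /
#'   radians).
#' @param max_points vertex subsample cap.
#' @return a [rigid_transform()] (moving to fixed) with attributes
#'   `rms`, `converged`, `n_points`.
#' @export
align_shaft <- function(moving, fixed, shaft_region = "shaft",
                        max_iter = 100, tol = 1e-6, max_points = 4000) {
  stopifnot(nrow(moving$vertices) > 0, nrow(fixed$vertices) > 0)
  fidx <- if (!is.null(moving$regions) &&
              any(moving$regions == shaft_region)) {
    region_faces(moving, shaft_region)
  } else {
    default_shaft_faces(moving)
  }
  patch <- submesh(moving, fidx)
  src <- .subsample_rows(patch$vertices, max_points)
  grid <- mesh_grid_build_cpp(fixed$vertices, fixed$faces)
  init <- rigid_transform(diag(3),
                          colMeans(fixed$vertices) -
                            colMeans(moving$vertices))
  # coarse-to-fine: converge on a 1000-point subsample, refine with all
  coarse <- .icp(.subsample_rows(src, 1000), fixed, init,
                 method = "plane", max_iter = max_iter, tol = tol,
                 grid = grid)
  fit <- .icp(src, fixed, coarse$transform, method = "plane",
              max_iter = 30, tol = tol, grid = grid)
  if (fit$rms > 5) {
    # badly seated: retry across PCA axis-sign candidates
    cands <- .pca_inits(src, .subsample_rows(fixed$vertices, max_points))
    fits <- lapply(cands, function(i0)
      .icp(src, fixed, i0, method = "plane", max_iter = 15, tol = tol,
           grid = grid))
    best <- fits[[which.min(vapply(fits, `[[`, 0, "rms"))]]
    fit <- .icp(src, fixed, best$transform, method = "plane",
                max_iter = max_iter, tol = tol, grid = grid)
  }
  out <- fit$transform
  attr(out, "rms") <- fit$rms
  attr(out, "converged") <- fit$converged
  attr(out, "n_points") <- nrow(src)
  if (!fit$converged)
    attr(out, "flag") <- "non_converged"
  out
}

#' Default shaft region: faces below 40 percent of the z extent
#' @param mesh a [trimesh()].
#' @return integer face indices.
#' @export
default_shaft_faces <- function(mesh) {
  fc <- face_centers(mesh)
  zr <- range(mesh$vertices[, 3])
  which(fc[, 3] < zr[1] + 0.4 * diff(zr))
}

#' Fit the rigid transform between two fragment surfaces
#'
#' Trimmed (90 percent inlier) point-to-point ICP, robust to a missing
#' defect or mismatched cut edges; initialization tries the centroid
#' shift and the four sign-consistent PCA axis alignments, keeping the
#' best. Deterministic.
#'
#' @param fragment_current,fragment_target [trimesh()] fragment
#'   surfaces of the same bone region.
#' @param trim inlier fraction for trimming.
#' @param max_iter,tol iteration cap and convergence threshold.
#' @param max_points vertex subsample cap.
#' @return a [rigid_transform()] mapping current onto target, with
#'   attributes `rms`, `converged`, `overlap` (fraction of points within
#'   1 mm after fit) and `flag = "low_confidence"` when overlap < 0.5.
#' @export
fit_fragment_transform <- function(fragment_current, fragment_target,
                                   trim = 0.9, max_iter = 100,
                                   tol = 1e-6, max_points = 4000) {
  src <- .subsample_rows(fragment_current$vertices, max_points)
  grid <- mesh_grid_build_cpp(fragment_target$vertices,
                              fragment_target$faces)
  src1 <- .subsample_rows(src, 1000)
  cands <- .pca_inits(src, .subsample_rows(fragment_target$vertices,
                                           max_points))
  probes <- lapply(cands, function(i0)
    .icp(src1, fragment_target, i0, method = "point", trim = trim,
         max_iter = 10, tol = tol, grid = grid))
  best <- probes[[which.min(vapply(probes, `[[`, 0, "rms"))]]
  coarse <- .icp(src1, fragment_target, best$transform,
                 method = "point", trim = trim, max_iter = max_iter,
                 tol = tol, grid = grid)
  fit <- .icp(src, fragment_target, coarse$transform, method = "point",
              trim = trim, max_iter = 30, tol = tol, grid = grid)
  out <- fit$transform
  final <- mesh_grid_query_cpp(grid, apply_transform(out, src))
  overlap <- mean(final$distance < 1.0)
  attr(out, "rms") <- fit$rms
  attr(out, "converged") <- fit$converged
  attr(out, "overlap") <- overlap
  if (overlap < 0.5) attr(out, "flag") <- "low_confidence"
  out
}

#' Quantify a malunion against the mirrored contralateral bone
#'
#' The Q3DCT pipeline: mirror the contralateral bone, align it on the
#' shaft of the affected bone, fit the fragment's rigid displacement
#' from its anatomical (template) position, and decompose it into three
#' translations and three rotations. The rotation centre is the
#' centroid of the template fragment patch.
#'
#' @param affected affected bone mesh with `fragment` (and ideally
#'   `shaft`) region labels.
#' @param contralateral intact contralateral bone mesh with matching
#'   region labels.
#' @param frame an [anatomical_frame()].
#' @param fragment_region,shaft_region region labels.
#' @param mirror_plane [plane()] used for mirroring; default is the
#'   mid-sagittal plane through the contralateral centroid (any valid
#'   choice differs only by a rigid motion, which the shaft alignment
#'   absorbs).
#' @param max_points ICP subsample cap.
#' @return a [deformity_report()] with context `"pre"`; attributes
#'   carry the shaft and fragment ICP residuals and transforms.
#' @export
quantify_malunion <- function(affected, contralateral,
                              frame = anatomical_frame(),
                              fragment_region = "fragment",
                              shaft_region = "shaft",
                              mirror_plane = NULL, max_points = 4000) {
  mp <- mirror_plane %||% plane(colMeans(contralateral$vertices),
                                frame$y_axis)
  tmpl <- mirror_mesh(contralateral, mp)
  Ts <- align_shaft(tmpl, affected, shaft_region,
                    max_points = max_points)
  tmpl <- transform_mesh(tmpl, Ts)
  frag_cur <- submesh(affected, fragment_region)
  frag_tgt <- submesh(tmpl, fragment_region)
  Tfit <- fit_fragment_transform(frag_cur, frag_tgt,
                                 max_points = max_points)
  Tdef <- rt_inverse(Tfit)
  center <- mesh_centroid(frag_tgt)
  rep <- decompose_transform(Tdef, frame, center, context = "pre")
  attr(rep, "shaft_rms") <- attr(Ts, "rms")
  attr(rep, "fragment_rms") <- attr(Tfit, "rms")
  attr(rep, "overlap") <- attr(Tfit, "overlap")
  attr(rep, "shaft_transform") <- Ts
  attr(rep, "fragment_transform") <- Tfit
  attr(rep, "flags") <- c(attr(Ts, "flag"), attr(Tfit, "flag"))
  rep
}

#' Assess the achieved fragment position against the plan
#'
#' Shaft-aligns the postoperative model onto the planned model, fits the
#' fragment's residual transform and decomposes it: the report is the
#' displacement of the achieved fragment from its planned pose.
#'
#' @param postop postoperative bone mesh with region labels.
#' @param planned planned bone model with matching labels.
#' @inheritParams quantify_malunion
#' @return a [deformity_report()] with context `"planned_vs_postop"`.
#' @export
assess_postop <- function(postop, planned, frame = anatomical_frame(),
                          fragment_region = "fragment",
                          shaft_region = "shaft", max_points = 4000) {
  Ts <- align_shaft(postop, planned, shaft_region,
                    max_points = max_points)
  postop <- transform_mesh(postop, Ts)
  frag_cur <- submesh(postop, fragment_region)
  frag_tgt <- submesh(planned, fragment_region)
  Tfit <- fit_fragment_transform(frag_cur, frag_tgt,
                                 max_points = max_points)
  Tres <- rt_inverse(Tfit)
  center <- mesh_centroid(frag_tgt)
  rep <- decompose_transform(Tres, frame, center,
                             context = "planned_vs_postop")
  attr(rep, "shaft_rms") <- attr(Ts, "rms")
  attr(rep, "fragment_rms") <- attr(Tfit, "rms")
  attr(rep, "flags") <- c(attr(Ts, "flag"), attr(Tfit, "flag"))
  rep
}
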