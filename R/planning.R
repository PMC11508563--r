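# Curved-osteotomy planning: the cut is an ordered set of depth-
# controlled drill trajectories along the old fracture line; drilling
# depth is measured to the far cortex minus a posterior safety margin.

#' Fracture trace (polyline on the bone surface)
#'
#' @param points n x 3 matrix of ordered points (mm), n >= 2,
#'   consecutive points distinct.
#' @param closed is the polyline a closed loop.
#' @export
fracture_trace <- function(points, closed = FALSE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  seg <- diff(points)
  if (any(sqrt(rowSums(seg^2)) < 1e-12))
    stop("consecutive trace points must be distinct")
  structure(list(points = points, closed = isTRUE(closed)),
            class = "fracture_trace")
}

#' @export
print.fracture_trace <- function(x, ...) {
  cat(sprintf("<fracture_trace: %d points, %s, length %.1f mm>\n",
              nrow(x$points), if (x$closed) "closed" else "open",
              trace_length(x)))
  invisible(x)
}

#' Arc length of a trace
#' @param trace a [fracture_trace()].
#' @export
trace_length <- function(trace) {
  p <- trace$points
  if (trace$closed) p <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Resample a trace at uniform arc-length spacing
#'
#' Endpoints of open traces are preserved; resampled points lie on the
#' original polyline.
#' @param trace a [fracture_trace()].
#' @param spacing target spacing (mm), > 0.
#' @export
resample_trace <- function(trace, spacing) {
  stopifnot(spacing > 0)
  p <- trace$points
  if (trace$closed) p <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (!trace$closed && spacing >= L) {
    warning("spacing exceeds trace length; returning endpoints only")
    return(fracture_trace(p[c(1, nrow(p)), ], closed = FALSE))
  }
  if (trace$closed) {
    n <- max(3L, as.integer(ceiling(L / spacing)))
    ts <- seq(0, L, length.out = n + 1)[seq_len(n)]
  } else {
    n <- max(2L, as.integer(round(L / spacing)) + 1L)
    ts <- seq(0, L, length.out = n)
  }
  out <- t(vapply(ts, function(tt) {
    i <- max(1L, min(length(seg), findInterval(tt, s,
                                               rightmost.closed = TRUE)))
    w <- if (seg[i] > 0) (tt - s[i]) / seg[i] else 0
    (1 - w) * p[i, ] + w * p[i + 1, ]
  }, numeric(3)))
  fracture_trace(out, closed = trace$closed)
}

#' Drill trajectory
#'
#' @param entry entry point on the bone surface (mm).
#' @param direction unit vector pointing into the bone.
#' @param depth planned in-bone drilling distance (mm), > 0 (may be
#'   `NA` until [compute_depth()] assigns it).
#' @param diameter drill diameter (mm, default 1.8).
#' @export
drill_trajectory <- function(entry, direction, depth = NA_real_,
                             diameter = 1.8) {
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  structure(list(entry = as.numeric(entry), direction = d,
                 depth = depth, diameter = diameter),
            class = "drill_trajectory")
}

#' Plan drill trajectories along the fracture trace
#'
#' One trajectory per resampled trace point. Each drill direction is the
#' approach vector orthogonalized against the local trace tangent (so
#' adjacent drill segments rule a smooth surface), and each entry is
#' snapped to the bone surface along that direction. Trace points whose
#' ray misses the bone are dropped with a warning.
#'
#' @param bone watertight bone [trimesh()].
#' @param trace a [fracture_trace()] on the bone surface.
#' @param approach unit vector pointing into the bone.
#' @param spacing trajectory spacing along the trace (mm, default 2.5
#'   centre-to-centre).
#' @param diameter drill diameter (mm, default 1.8).
#' @return list of [drill_trajectory()] objects (depths unset).
#' @export
plan_trajectories <- function(bone, trace, approach, spacing = 2.5,
                              diameter = 1.8) {
  rs <- resample_trace(trace, spacing)
  p <- rs$points
  n <- nrow(p)
  a <- as.numeric(approach)
  a <- a / sqrt(sum(a^2))
  trajs <- list()
  for (i in seq_len(n)) {
    ip <- if (rs$closed) ((i - 2) %% n) + 1 else max(1, i - 1)
    inx <- if (rs$closed) (i %% n) + 1 else min(n, i + 1)
    tang <- p[inx, ] - p[ip, ]
    tang <- tang / sqrt(sum(tang^2))
    d <- a - sum(a * tang) * tang
    if (sqrt(sum(d^2)) < 1e-6) {
      warning("approach parallel to trace tangent at point ", i,
              "; point dropped")
      next
    }
    d <- d / sqrt(sum(d^2))
    hits <- ray_intersect(bone, p[i, ] - 10 * d, d)
    if (nrow(hits) < 2) {
      warning("ray misses the bone at trace point ", i, "; point dropped")
      next
    }
    entry <- p[i, ] - 10 * d + hits$distance[1] * d
    trajs[[length(trajs) + 1]] <-
      drill_trajectory(entry, d, diameter = diameter)
  }
  trajs
}

#' Depth-controlled drilling distance for one trajectory
#'
#' Distance from the entry to the far cortex exit along the drill
#' direction, minus the posterior safety margin (so the drill tip stays
#' clear of posterior neurovascular structures), clamped to at least
#' 1 mm and never beyond the exit.
#'
#' @param bone watertight bone [trimesh()].
#' @param traj a [drill_trajectory()].
#' @param posterior_margin safety margin (mm, default 2).
#' @return depth in mm; attribute `flag = "too_shallow"` when the
#'   in-bone path is shorter than `posterior_margin + 1` mm.
#' @export
compute_depth <- function(bone, traj, posterior_margin = 2.0) {
  hits <- ray_intersect(bone, traj$entry - 1e-3 * traj$direction,
                        traj$direction)
  if (nrow(hits) < 2) stop("trajectory does not enter the bone")
  chord <- hits$distance[2] - hits$distance[1]
  depth <- max(chord - posterior_margin, 1)
  depth <- min(depth, chord)
  if (chord < posterior_margin + 1) attr(depth, "flag") <- "too_shallow"
  depth
}

#' Osteotomy plan container
#'
#' @param trajectories ordered list of [drill_trajectory()] with depths
#'   assigned.
#' @param surface ruled cut surface [trimesh()] (optional).
#' @param posterior_margin safety margin used (mm).
#' @export
osteotomy_plan <- function(trajectories, surface = NULL,
                           posterior_margin = 2.0) {
  structure(list(trajectories = trajectories, surface = surface,
                 posterior_margin = posterior_margin),
            class = "osteotomy_plan")
}

#' @export
print.osteotomy_plan <- function(x, ...) {
  dep <- vapply(x$trajectories, `[[`, 0, "depth")
  cat(sprintf("<osteotomy_plan: %d trajectories, depths %.1f-%.1f mm, margin %.1f mm>\n",
              length(x$trajectories), min(dep), max(dep),
              x$posterior_margin))
  invisible(x)
}

#' Plan a curved osteotomy end-to-end
#'
#' Convenience wrapper: resample the trace, plan trajectories, compute
#' depths and triangulate the ruled cut surface.
#' @inheritParams plan_trajectories
#' @inheritParams compute_depth
#' @export
plan_osteotomy <- function(bone, trace, approach, spacing = 2.5,
                           diameter = 1.8, posterior_margin = 2.0) {
  trajs <- plan_trajectories(bone, trace, approach, spacing, diameter)
  trajs <- lapply(trajs, function(tr) {
    dep <- compute_depth(bone, tr, posterior_margin)
    tr$depth <- as.numeric(dep)
    tr$flag <- attr(dep, "flag")
    tr
  })
  shallow <- vapply(trajs, function(tr) identical(tr$flag,
                                                  "too_shallow"), TRUE)
  if (any(shallow)) {
    warning(sum(shallow), " trajectory(ies) dropped: in-bone path ",
            "shorter than margin + 1 mm")
    trajs <- trajs[!shallow]
  }
  surf <- build_osteotomy_surface(trajs)
  osteotomy_plan(trajs, surf, posterior_margin)
}

# min distance between 3D segments p1+s*(p2-p1), q1+t*(q2-q1)
.seg_seg_dist <- function(p1, p2, q1, q2) {
  u <- p2 - p1; v <- q2 - q1; w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * cc - b * b
  if (D < 1e-14) {
    s <- 0
    t <- if (cc > 1e-14) e / cc else 0
  } else {
    s <- (b * e - cc * d) / D
    t <- (a * e - b * d) / D
  }
  s <- min(1, max(0, s))
  t <- if (cc > 1e-14) min(1, max(0, (e + s * b) / cc)) else 0
  s <- if (a > 1e-14) min(1, max(0, (b * t - d) / a)) else 0
  list(d = sqrt(sum((p1 + s * u - q1 - t * v)^2)), s = s, t = t)
}

#' Ruled cut surface through the drill segments
#'
#' Triangulates the strip between consecutive drill segments (entry to
#' tip). Crossing segments (a self-intersecting cut) are rejected.
#' @param trajs list of [drill_trajectory()] with depths set.
#' @return an open [trimesh()] sheet; attribute `area` is its area.
#' @export
build_osteotomy_surface <- function(trajs) {
  n <- length(trajs)
  if (n < 2) stop("need at least two trajectories")
  ent <- t(vapply(trajs, `[[`, numeric(3), "entry"))
  tip <- ent + t(vapply(trajs, function(t) t$depth * t$direction,
                        numeric(3)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ss <- .seg_seg_dist(ent[i, ], tip[i, ], ent[j, ], tip[j, ])
      # touching at shared endpoints (e.g. a fan apex) is legitimate;
      # only interior crossings make the ruled sheet self-intersect
      interior <- (ss$s > 0.01 && ss$s < 0.99) ||
        (ss$t > 0.01 && ss$t < 0.99)
      if (ss$d < 1e-9 && interior)
        stop("crossing drill segments ", i, " and ", j,
             ": cut surface would self-intersect")
    }
  }
  v <- rbind(ent, tip)
  f <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
    rbind(c(i, i + 1, n + i + 1), c(i, n + i + 1, n + i))
  }))
  out <- trimesh(v, f, clean = FALSE)
  attr(out, "area") <- mesh_area(out)
  out
}

#' Planned reduction of the osteotomized fragment
#'
#' The rigid transform bringing the fragment to its anatomical position,
#' fitted against the mirrored-template fragment (delegates to
#' [fit_fragment_transform()]).
#' @param fragment current fragment surface.
#' @param template_fragment anatomical target surface (from the mirrored
#'   contralateral template).
#' @return a [rigid_transform()]; attribute `planned_model` holds the
#'   fragment moved to its planned position.
#' @export
plan_reduction <- function(fragment, template_fragment) {
  T <- fit_fragment_transform(fragment, template_fragment)
  attr(T, "planned_model") <- transform_mesh(fragment, T)
  T
}

#' Serialize / deserialize an osteotomy plan as JSON
#' @param plan an [osteotomy_plan()].
#' @param path JSON file path.
#' @export
write_plan <- function(plan, path) {
  obj <- list(
    posterior_margin = plan$posterior_margin,
    trajectories = lapply(plan$trajectories, function(t) {
      list(entry = t$entry, direction = t$direction, depth = t$depth,
           diameter = t$diameter)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trajs <- lapply(seq_len(nrow(obj$trajectories)), function(i) {
    r <- obj$trajectories[i, ]
    drill_trajectory(unlist(r$entry), unlist(r$direction), r$depth,
                     r$diameter)
  })
  osteotomy_plan(trajs, NULL, obj$posterior_margin)
}
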