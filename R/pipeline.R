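# End-to-end pipeline: segment -> quantify -> plan -> guides ->
# (optionally) assess, with a provenance manifest. The function surface
# is the primary interface; inst/cli/panflute.R wraps it for the shell.

#' Pipeline configuration
#'
#' @param fixture phantom fixture name (see [phantom_fixture()]), or
#'   `NULL` when meshes are supplied via `affected`/`contralateral`.
#' @param affected,contralateral STL paths (with `.regions.json`
#'   sidecars) used when no fixture is named.
#' @param out_dir artifact directory.
#' @param use_ct run the CT route (voxelize, threshold, grow, surface)
#'   instead of using the phantom meshes directly.
#' @param ct_spacing simulated CT voxel spacing (mm).
#' @param hu_min bone threshold (HU).
#' @param trace_spacing drill-trajectory spacing (mm).
#' @param posterior_margin drilling safety margin (mm).
#' @param drill_working_length usable drill length (mm).
#' @param clearance,thickness guide fit gap and shell thickness (mm).
#' @param guide_resolution guide level-set resolution (mm).
#' @param do_guides build the three guide solids.
#' @param seed RNG seed recorded in the manifest.
#' @export
pipeline_config <- function(fixture = "paper_case", affected = NULL,
                            contralateral = NULL,
                            out_dir = tempfile("panflute_run_"),
                            use_ct = FALSE, ct_spacing = 0.5,
                            hu_min = 226, trace_spacing = 2.5,
                            posterior_margin = 2.0,
                            drill_working_length = 60,
                            clearance = 0.2, thickness = 3,
                            guide_resolution = 0.2, do_guides = TRUE,
                            seed = 42L) {
  structure(as.list(environment()), class = "run_config")
}

#' Segment the largest bone from a CT volume
#'
#' Threshold at the bone window, grow the component under the seed (by
#' default the largest component's first voxel) and extract its surface.
#' @param vol a [ct_volume()].
#' @param hu_min bone threshold (HU, inclusive).
#' @param seed optional voxel index (1-based) for region growing.
#' @param method `"iso"` places the surface at the cortical half-maximum
#'   iso-level of the HU field restricted to the grown component (the
#'   standard sub-voxel bone-surface localization, unbiased with respect
#'   to surface orientation when the volume carries partial-volume
#'   information); `"binary"` extracts the 0.5 iso-surface of the
#'   thresholded mask.
#' @param iso_hu HU level for the `"iso"` route; `NULL` picks the
#'   half-maximum between the cortical plateau (median HU of the mask
#'   boundary shell) and the adjacent background.
#' @param smooth_iterations Taubin smoothing passes applied to the
#'   extracted surface.
#' @export
segment_bone <- function(vol, hu_min = 226, seed = NULL,
                         method = c("iso", "binary"), iso_hu = NULL,
                         smooth_iterations = 0) {
  method <- match.arg(method)
  mask <- threshold_bone(vol, hu_min)
  if (is.null(seed)) {
    comp <- array(cc26_cpp(as.integer(mask$labels != 0L),
                           dim(mask$labels)), dim(mask$labels))
    sizes <- tabulate(comp[comp > 0])
    seed <- arrayInd(which(comp == which.max(sizes))[1],
                     dim(mask$labels))[1, ]
  }
  grown <- region_grow(mask, seed)
  if (method == "binary")
    return(extract_surface(grown, 1L,
                           smooth_iterations = smooth_iterations))
  # iso route: keep HU values in a 2-voxel halo around the component so
  # the iso-surface can interpolate into the background
  d <- dim(grown$labels)
  gi <- as.integer(grown$labels)
  halo <- array(dilate26_cpp(gi, d, 2L), d)
  if (is.null(iso_hu)) {
    # cortical plateau: interior ring one voxel inside the mask surface;
    # background: ring one voxel outside
    ring_in <- array(erode26_cpp(gi, d, 1L), d) == 1L &
      array(erode26_cpp(gi, d, 3L), d) == 0L
    ring_out <- array(dilate26_cpp(gi, d, 3L), d) == 1L &
      halo == 0L
    fg <- stats::median(vol$voxels[ring_in])
    bg <- stats::median(vol$voxels[ring_out])
    iso_hu <- (fg + bg) / 2
  }
  field <- vol$voxels
  lo <- min(field)
  field[halo == 0L] <- lo
  # fill the component interior so only the outer cortical surface is
  # extracted (trabecular HU may fall below the half-maximum level)
  interior <- array(erode26_cpp(gi, d, 1L), d) == 1L
  field[interior] <- pmax(field[interior], iso_hu + 1)
  fp <- array(1, d + 2L)
  fp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
    (iso_hu - field) / abs(iso_hu - lo)
  g <- list(origin = grown$origin - grown$spacing,
            spacing = grown$spacing, dims = d + 2L)
  out <- .surface_from_field(as.numeric(fp), g, iso = 0)
  if (smooth_iterations > 0) out <- taubin_smooth(out, smooth_iterations)
  out
}

# open working portion of the fracture trace: the anterior-facing upper
# branch of the closed loop, ordered caudal to cranial (drilling runs
# anterior to posterior, protecting the posterior structures)
.planning_trace <- function(case, z_range = c(103, 118)) {
  p <- case$trace$points
  cl <- mesh_closest(case$intact, p)
  nrm <- face_normals(case$intact)[cl$face, , drop = FALSE]
  keep <- nrm[, 1] < -0.2 & p[, 3] > z_range[1] & p[, 3] < z_range[2]
  q <- p[keep, , drop = FALSE]
  q <- q[order(q[, 3]), , drop = FALSE]
  # thin near-duplicate heights so the polyline ascends cleanly
  dz <- c(TRUE, diff(q[, 3]) > 0.3)
  fracture_trace(q[dz, , drop = FALSE], closed = FALSE)
}

# default K-wire set: three slightly divergent wires entering roughly
# perpendicular to the in-situ plate near its proximal half, so the
# same wires reference the cutting guide (which covers the plate), the
# intermediate guide and the reposition guide (which envelops the new
# plate in the same position)
.default_kwires <- function(bone, entries, plate = NULL) {
  ent <- matrix(NA_real_, 0, 3)
  dirs <- matrix(NA_real_, 0, 3)
  if (!is.null(plate)) {
    n <- nrow(plate$centerline)
    idx <- unique(pmax(1L, round(c(0.55, 0.75, 0.95) * n)))
    tilts <- rbind(c(0, 0, 0.08), c(0, 0, -0.06), c(0.06, 0, 0))
    for (k in seq_along(idx)) {
      i <- idx[k]
      into <- -plate$normals[i, ] + tilts[k, ]
      into <- into / sqrt(sum(into^2))
      o <- plate$centerline[i, ] - 40 * into
      hits <- ray_intersect(bone, o, into)
      if (nrow(hits) == 0) next
      ent <- rbind(ent, o + hits$distance[1] * into)
      dirs <- rbind(dirs, into)
    }
    return(kwire_set(ent, dirs))
  }
  # no plate: anterior wires bracketing the footprint, each verified to
  # meet an anterior-facing surface (oblique entries make no channel)
  ctr <- colMeans(entries)
  offs <- rbind(c(0, -4, -12), c(0, 6, -18), c(0, 1, -25))
  fn <- face_normals(bone)
  for (i in seq_len(nrow(offs))) {
    for (dy in c(0, 4, 8, 12)) {
      tgt <- ctr + offs[i, ] + c(0, dy, 0)
      hits <- ray_intersect(bone, c(-80, tgt[2], tgt[3]), c(1, 0, 0))
      if (nrow(hits) == 0) next
      if (fn[hits$face[1], 1] > -0.5) next
      ent <- rbind(ent, c(-80 + hits$distance[1], tgt[2], tgt[3]))
      dirs <- rbind(dirs, c(1, 0, 0))
      break
    }
  }
  kwire_set(ent, dirs)
}

#' Select a guide footprint region on the bone
#'
#' Faces near the drill entries, a lateral-anterior connector and an
#' anterior-shaft strip distal to the tuberosity (the paper-style
#' extensions); labelled `"footprint"` on the returned mesh.
#' @param bone bone [trimesh()].
#' @param entries n x 3 drill entry points.
#' @param radius patch radius around the entries (mm).
#' @export
select_footprint <- function(bone, entries, radius = 9) {
  fc <- face_centers(bone)
  de <- rep(Inf, nrow(fc))
  for (i in seq_len(nrow(entries))) {
    de <- pmin(de, sqrt((fc[, 1] - entries[i, 1])^2 +
                          (fc[, 2] - entries[i, 2])^2 +
                          (fc[, 3] - entries[i, 3])^2))
  }
  zr <- range(entries[, 3])
  near <- de < radius
  connector <- fc[, 1] < 0 & fc[, 2] < -8 &
    fc[, 3] > zr[1] - 18 & fc[, 3] < zr[2] + 2
  sel <- which(near | connector)
  set_region(bone, sel, "footprint")
}

#' Run the full planning pipeline
#'
#' Executes segmentation (optional), malunion quantification, osteotomy
#' planning, guide generation and, when the fixture provides it,
#' postoperative assessment; writes artifacts and a JSON manifest with
#' the configuration, per-stage reports and file checksums.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest list (invisibly); `status` attribute is 0 on
#'   success.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg[setdiff(names(cfg), "")],
                   stages = list())
  status <- 0
  files <- character()
  tryCatch({
    if (!is.null(cfg$fixture)) {
      case <- phantom_fixture(cfg$fixture)
      affected <- case$affected
      contralateral <- case$contralateral
      mirror_plane <- case$mirror_plane
    } else {
      affected <- read_stl(cfg$affected)
      contralateral <- read_stl(cfg$contralateral)
      case <- NULL
      mirror_plane <- NULL
    }
    if (cfg$use_ct && !is.null(case)) {
      va <- voxelize_ct(case, cfg$ct_spacing, "affected")
      vc <- voxelize_ct(case, cfg$ct_spacing, "contralateral")
      affected <- label_against_truth(segment_bone(va, cfg$hu_min), case)
      contralateral <- label_template(segment_bone(vc, cfg$hu_min), case)
    }
    pre <- quantify_malunion(affected, contralateral,
                             mirror_plane = mirror_plane)
    manifest$stages$quantify <- list(
      report = as.list(coef(pre)),
      shaft_rms = attr(pre, "shaft_rms"),
      fragment_rms = attr(pre, "fragment_rms"))

    if (!is.null(case)) {
      trace <- .planning_trace(case)
      plan <- plan_osteotomy(affected, trace, approach = c(1, 0, 0),
                             spacing = cfg$trace_spacing,
                             posterior_margin = cfg$posterior_margin)
      pf <- file.path(cfg$out_dir, "plan.json")
      write_plan(plan, pf)
      files <- c(files, pf)
      manifest$stages$plan <- list(
        n_trajectories = length(plan$trajectories),
        depths = vapply(plan$trajectories, `[[`, 0, "depth"),
        posterior_margin = plan$posterior_margin)

      frag_cur <- submesh(affected, "fragment")
      mp <- mirror_plane %||% plane(colMeans(contralateral$vertices),
                                    c(0, 1, 0))
      tmpl <- mirror_mesh(contralateral, mp)
      Ts <- align_shaft(tmpl, affected)
      tmpl <- transform_mesh(tmpl, Ts)
      Tred <- plan_reduction(frag_cur, submesh(tmpl, "fragment"))
      manifest$stages$reduction <- list(
        translation = Tred$translation,
        rms = attr(Tred, "rms"))

      if (isTRUE(cfg$do_guides)) {
        ent <- t(vapply(plan$trajectories, `[[`, numeric(3), "entry"))
        bonefp <- select_footprint(affected, ent)
        plate_old <- fit_plate(affected, role = "in_situ")
        kw <- .default_kwires(affected, ent, plate_old)
        cut <- design_cutting_guide(
          bonefp, plan, plate = plate_old, kwires = kw,
          drill_working_length = cfg$drill_working_length,
          clearance = cfg$clearance, thickness = cfg$thickness,
          resolution = cfg$guide_resolution)
        plate_new <- fit_plate(case$intact, role = "new")
        dist_holes <- plate_new$holes[plate_new$holes$set == "distal", ]
        shaft_fp <- select_footprint(
          affected,
          rbind(as.matrix(dist_holes[, c("px", "py", "pz")]),
                kw$entries),
          radius = 12)
        inter <- design_intermediate_guide(
          shaft_fp, plate_new, kw, clearance = cfg$clearance,
          thickness = cfg$thickness,
          resolution = cfg$guide_resolution)
        repos <- design_reposition_guide(
          plate_new, case$intact, kw, clearance = cfg$clearance,
          resolution = cfg$guide_resolution)
        gman <- export_guides(list(cut, inter, repos),
                              file.path(cfg$out_dir, "guides"))
        manifest$stages$guides <- gman
        files <- c(files, list.files(file.path(cfg$out_dir, "guides"),
                                     full.names = TRUE))
      }
    }
    if (!is.null(case$postop)) {
      post <- assess_postop(case$postop, case$planned)
      manifest$stages$assess <- list(report = as.list(coef(post)))
    }
  }, error = function(e) {
    status <<- 1
    manifest$stages$FAILED <<- conditionMessage(e)
  })
  manifest$files <- lapply(files, function(f)
    list(file = f, md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir,
                                 if (status == 0) "manifest.json"
                                 else "manifest.FAILED.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  attr(manifest, "status") <- status
  invisible(manifest)
}
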