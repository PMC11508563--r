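# CT segmentation following the clinical recipe: Hounsfield threshold
# (>= 226 by default), region growing, mask splitting and surface
# extraction. Voxel indexing is 1-based at the R API; a voxel's world
# coordinate is its centre; the volume extent is half-open.

#' CT volume container
#'
#' @param voxels 3D numeric array of Hounsfield units.
#' @param spacing length-3 voxel spacing (mm/voxel), strictly positive.
#' @param origin world coordinate (mm) of the centre of voxel (1,1,1).
#' @return object of class `"ct_volume"`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3, length(spacing) == 3,
            all(spacing > 0), all(is.finite(voxels)))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume: %d x %d x %d voxels, spacing (%g, %g, %g) mm, HU range [%g, %g]>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Label mask on a CT grid
#' @param labels 3D integer array (0 = background).
#' @param spacing,origin grid geometry, as in [ct_volume()].
#' @export
label_mask <- function(labels, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_mask: %d x %d x %d voxels, labels: %s>\n",
              d[1], d[2], d[3],
              paste(setdiff(sort(unique(as.vector(x$labels))), 0L),
                    collapse = ", ")))
  invisible(x)
}

#' Threshold a CT volume at the bone window
#'
#' Voxels with HU at or above `hu_min` (inclusive, default 226) are
#' labelled 1. Metal voxels (HU >= `metal_hu`) are excluded by default
#' with a warning, since in-situ hardware corrupts bone segmentation; no
#' artifact correction is attempted.
#'
#' @param vol a [ct_volume()].
#' @param hu_min bone threshold in HU (inclusive).
#' @param exclude_metal drop voxels at or above `metal_hu`.
#' @param metal_hu metal threshold in HU.
#' @return a [label_mask()] with labels 0/1.
#' @export
threshold_bone <- function(vol, hu_min = 226, exclude_metal = TRUE,
                           metal_hu = 3000) {
  m <- vol$voxels >= hu_min
  if (exclude_metal) {
    metal <- vol$voxels >= metal_hu
    if (any(metal)) {
      warning(sprintf("excluding %d metal voxels (HU >= %g) from the bone mask",
                      sum(metal), metal_hu))
      m <- m & !metal
    }
  }
  label_mask(array(as.integer(m), dim(vol$voxels)), vol$spacing, vol$origin)
}

#' Region growing from a seed voxel
#'
#' Returns the 26-connected foreground component containing the seed.
#' @param mask a [label_mask()].
#' @param seed length-3 integer voxel index (1-based).
#' @export
region_grow <- function(mask, seed) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 3)
  d <- dim(mask$labels)
  if (any(seed < 1L) || any(seed > d)) stop("seed outside the volume")
  if (mask$labels[seed[1], seed[2], seed[3]] == 0L)
    stop("seed voxel is background")
  out <- flood26_cpp(as.integer(mask$labels != 0L), d, seed - 1L)
  label_mask(array(out, d), mask$spacing, mask$origin)
}

#' Split a foreground mask into seeded components
#'
#' Each foreground voxel receives the label of the seed of its connected
#' component. Components containing several seeds (bones touching via a
#' thin bridge) are separated by erosion, seeded re-labelling and
#' constrained re-growth; bridge voxels whose assignment is ambiguous go
#' to the nearest seed label.
#'
#' @param mask a [label_mask()] (foreground = nonzero).
#' @param seeds matrix / list of 1-based voxel indices, one row per seed.
#' @param labels integer label per seed (defaults to 1, 2, ...).
#' @param erosion_radius erosion steps used to break thin bridges.
#' @export
split_mask <- function(mask, seeds, labels = NULL,
                       erosion_radius = 1) {
  if (is.list(seeds) && !is.data.frame(seeds))
    seeds <- do.call(rbind, seeds)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  ns <- nrow(seeds)
  if (ns < 1) stop("need at least one seed")
  labels <- as.integer(labels %||% seq_len(ns))
  d <- dim(mask$labels)
  fg <- as.integer(mask$labels != 0L)
  for (s in seq_len(ns)) {
    if (fg[seeds[s, 1] + d[1] * (seeds[s, 2] - 1) +
           d[1] * d[2] * (seeds[s, 3] - 1)] == 0L)
      stop("seed ", s, " lies on background")
  }
  comp <- array(cc26_cpp(fg, d), d)
  seed_comp <- comp[seeds]
  out <- array(0L, d)
  for (cid in unique(seed_comp)) {
    in_comp <- which(seed_comp == cid)
    sub <- as.integer(comp == cid)
    if (length(in_comp) == 1) {
      out[comp == cid] <- labels[in_comp]
      next
    }
    ero <- erode26_cpp(sub, d, as.integer(erosion_radius))
    ecc <- array(cc26_cpp(ero, d), d)
    se <- ecc[seeds[in_comp, , drop = FALSE]]
    if (anyDuplicated(se[se > 0]) || any(se == 0)) {
      # fall back: nearest eroded component, or give up if still joined
      if (all(se == se[1]) && se[1] > 0) {
        warning("seeds ", paste(in_comp, collapse = ", "),
                " remain in one inseparable component")
        out[comp == cid] <- labels[in_comp[1]]
        next
      }
      if (any(se == 0)) {
        ev <- which(ero == 1L)
        ecoord <- arrayInd(ev, d)
        for (k in which(se == 0)) {
          dd <- colSums((t(ecoord) - as.numeric(seeds[in_comp[k], ]))^2)
          se[k] <- ecc[ev[which.min(dd)]]
        }
      }
    }
    lab <- array(0L, d)
    for (k in seq_along(in_comp)) lab[ecc == se[k]] <- labels[in_comp[k]]
    # constrained multi-source growth back into the eroded band
    remaining <- sub == 1L & lab == 0L
    while (any(remaining)) {
      grew <- FALSE
      for (k in seq_along(in_comp)) {
        cur <- as.integer(lab == labels[in_comp[k]])
        dil <- array(dilate26_cpp(cur, d, 1L), d)
        add <- dil == 1L & remaining
        if (any(add)) {
          lab[add] <- labels[in_comp[k]]
          remaining <- remaining & !add
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    out[lab != 0L] <- lab[lab != 0L]
  }
  label_mask(out, mask$spacing, mask$origin)
}

#' Extract a surface mesh from a label mask
#'
#' Watertight iso-surface at the 0.5 level of the binary indicator of
#' `label`, with vertices in world millimetres. Optional Taubin
#' smoothing (off by default).
#'
#' @param mask a [label_mask()].
#' @param label which label to surface.
#' @param smooth_iterations Taubin smoothing passes (0 = off).
#' @export
extract_surface <- function(mask, label = 1L, smooth_iterations = 0) {
  m <- mask$labels == label
  if (!any(m)) stop("label ", label, " not present in mask")
  d <- dim(m)
  # pad with background so the surface closes at the volume boundary
  fp <- array(1, d + 2L)
  fp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- 1 - m
  g <- list(origin = mask$origin - mask$spacing,
            spacing = mask$spacing, dims = d + 2L)
  out <- .surface_from_field(as.numeric(fp), g, iso = 0.5)
  if (smooth_iterations > 0) out <- taubin_smooth(out, smooth_iterations)
  out
}

#' Rasterize a solid mesh onto a voxel grid
#'
#' Inside/outside classification by ray parity per voxel column.
#' @param mesh watertight [trimesh()].
#' @param spacing voxel spacing (mm) - scalar or length 3.
#' @param origin optional grid origin; defaults to the mesh bounding box
#'   padded by two voxels.
#' @param dims optional grid dimensions.
#' @return a [label_mask()] with labels 0/1.
#' @export
voxelize_mesh <- function(mesh, spacing, origin = NULL, dims = NULL) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (is.null(origin) || is.null(dims)) {
    bb <- .mesh_bbox(mesh)
    origin <- bb$lo - 2 * spacing
    dims <- as.integer(ceiling((bb$hi - origin) / spacing)) + 3L
  }
  m <- voxelize_cpp(mesh$vertices, mesh$faces, as.integer(dims),
                    spacing, origin)
  label_mask(array(as.integer(m), dims), spacing, origin)
}

# ---- volume I/O ----------------------------------------------------------

#' Read / write CT volumes and label masks
#'
#' NIfTI (.nii/.nii.gz) via RNifti and MetaImage (.mhd/.mha,
#' uncompressed) are supported.
#' @param path file path; format chosen by extension.
#' @param vol a [ct_volume()] or [label_mask()].
#' @export
read_ct_volume <- function(path) {
  if (grepl("\\.(mhd|mha)$", path)) return(.read_metaimage(path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  sp <- RNifti::pixdim(img)[1:3]
  ct_volume(arr, sp, origin = c(0, 0, 0))
}

#' @rdname read_ct_volume
#' @export
write_ct_volume <- function(vol, path) {
  arr <- if (inherits(vol, "label_mask")) vol$labels else vol$voxels
  if (grepl("\\.(mhd|mha)$", path)) {
    .write_metaimage(arr, vol$spacing, vol$origin, path)
  } else {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

.write_metaimage <- function(arr, spacing, origin, path) {
  storage.mode(arr) <- "double"
  mha <- grepl("\\.mha$", path)
  rawfile <- if (mha) "LOCAL" else sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", dim(arr)[1], dim(arr)[2],
                   dim(arr)[3]),
           sprintf("ElementSpacing = %g %g %g", spacing[1], spacing[2],
                   spacing[3]),
           sprintf("Offset = %g %g %g", origin[1], origin[2], origin[3]),
           "ElementType = MET_DOUBLE",
           sprintf("ElementDataFile = %s", rawfile))
  if (mha) {
    con <- file(path, "wb")
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
    close(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), rawfile), "wb")
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
    close(con)
  }
  invisible(path)
}

.read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- character()
    repeat {
      ch <- readBin(con, "raw", 1)
      if (length(ch) == 0 || ch == charToRaw("\n")) break
      line <- c(line, rawToChar(ch))
    }
    line <- paste(line, collapse = "")
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line) || length(ch) == 0) break
  }
  get <- function(k) {
    ln <- grep(paste0("^", k, " *="), hdr, value = TRUE)
    trimws(sub(".*=", "", ln[1]))
  }
  dims <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  off <- as.numeric(strsplit(get("Offset"), " +")[[1]])
  dfile <- get("ElementDataFile")
  n <- prod(dims)
  if (identical(dfile, "LOCAL")) {
    vals <- readBin(con, "numeric", n, size = 8, endian = "little")
  } else {
    con2 <- file(file.path(dirname(path), dfile), "rb")
    vals <- readBin(con2, "numeric", n, size = 8, endian = "little")
    close(con2)
  }
  ct_volume(array(vals, dims), sp, off)
}
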