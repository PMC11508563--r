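# STL input/output (binary and ASCII), units mm. Region labels survive a
# round trip through an optional JSON sidecar (label -> face indices),
# since STL itself carries no attributes.

#' Write a mesh to STL
#'
#' @param mesh a [trimesh()].
#' @param path output path.
#' @param ascii write ASCII STL instead of binary.
#' @param sidecar if `TRUE` and the mesh has region labels, write
#'   `<path>.regions.json` mapping each label to its face indices.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE, sidecar = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid panflute", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      for (m in 1:3) {
        p <- v[f[i, m], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid panflute", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "panflute binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    tri <- matrix(0, nrow = nrow(f), ncol = 12)
    tri[, 1:3] <- n
    tri[, 4:6] <- v[f[, 1], , drop = FALSE]
    tri[, 7:9] <- v[f[, 2], , drop = FALSE]
    tri[, 10:12] <- v[f[, 3], , drop = FALSE]
    # interleave the 2-byte attribute count by writing per-facet records
    raw_f <- writeBin(as.numeric(t(tri)), raw(), size = 4,
                      endian = "little")
    rec <- matrix(raw_f, nrow = 48)
    out <- raw(nrow(f) * 50)
    idx <- rep(seq_len(nrow(f)) - 1, each = 48) * 50 +
      rep(seq_len(48), times = nrow(f))
    out[idx] <- as.raw(rec)
    writeBin(out, con)
  }
  if (sidecar && !is.null(mesh$regions)) {
    labs <- unique(mesh$regions[nzchar(mesh$regions)])
    side <- lapply(labs, function(L) which(mesh$regions == L))
    names(side) <- labs
    jsonlite::write_json(side, paste0(path, ".regions.json"))
  }
  invisible(path)
}

#' Read an STL file
#'
#' Binary or ASCII is auto-detected; duplicated corner vertices are
#' welded by exact coordinate match. A `<path>.regions.json` sidecar, if
#' present, restores per-face region labels.
#' @param path STL file.
#' @return a [trimesh()].
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  probe <- readBin(con, "raw", 512)
  close(con)
  is_ascii <- grepl("^solid", rawToChar(probe[1:80])) &&
    grepl("facet", rawToChar(probe), fixed = TRUE)
  if (is_ascii) {
    txt <- readLines(path)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(s) {
      as.numeric(s[2:4])
    }))
    corners <- nums
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    body <- readBin(con, "raw", nf * 50)
    keep <- rep(c(rep(TRUE, 48), FALSE, FALSE), nf)
    vals <- readBin(body[keep], "numeric", nf * 12, size = 4,
                    endian = "little")
    tri <- matrix(vals, ncol = 12, byrow = TRUE)
    corners <- rbind(tri[, 4:6], tri[, 7:9], tri[, 10:12])
    ord <- as.vector(t(matrix(seq_len(3 * nf), ncol = 3)))
    corners <- corners[ord, , drop = FALSE]
  }
  key <- paste(corners[, 1], corners[, 2], corners[, 3])
  uid <- !duplicated(key)
  verts <- corners[uid, , drop = FALSE]
  vmap <- match(key, key[uid])
  faces <- matrix(vmap, ncol = 3, byrow = TRUE)
  regions <- NULL
  sidecar <- paste0(path, ".regions.json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    regions <- rep("", nrow(faces))
    for (L in names(side)) regions[side[[L]]] <- L
  }
  trimesh(verts, faces, regions, clean = FALSE)
}
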