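#' Triangle surface mesh
#'
#' Lightweight container for a triangulated surface: an `n x 3` vertex
#' matrix (mm) and an `m x 3` integer face matrix of 1-based vertex
#' indices, counter-clockwise when seen from outside.
#'
#' @param vertices Numeric `n x 3` matrix.
#' @param faces Integer `m x 3` matrix of vertex indices.
#' @return Object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (ncol(faces) != 3) stop("faces must be m x 3")
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Per-face areas of a triangle mesh
#' @param mesh A `trimesh`.
#' @return Numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Total surface area
#' @inheritParams face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed volume of a closed mesh (signed, divergence theorem)
#' @inheritParams face_areas
#' @return Volume in mm^3; positive for outward-oriented closed surfaces.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# Directed edge table: one row per half-edge (face traversal order)
half_edges <- function(mesh) {
  f <- mesh$faces
  cbind(from = as.vector(t(f)),
        to   = as.vector(t(f[, c(2, 3, 1), drop = FALSE])))
}

#' Boundary edges of a mesh
#' @inheritParams face_areas
#' @return 2-column matrix of vertex index pairs on the boundary
#'   (edges used by exactly one face), in face traversal direction.
#' @export
boundary_edges <- function(mesh) {
  he <- half_edges(mesh)
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  he[key %in% names(which(table(key) == 1)), , drop = FALSE]
}

#' Check that a mesh bounds a solid (closed, consistently oriented)
#'
#' Every directed half-edge must be matched by its reverse: the surface
#' then has empty boundary and a well-defined enclosed volume.  Multiple
#' closed components are allowed, including exactly coincident walls of
#' touching shells (as produced by the panel extruder), which after
#' vertex welding appear as edges shared by two face pairs.
#'
#' @inheritParams face_areas
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  if (!nrow(mesh$faces)) return(FALSE)
  he <- half_edges(mesh)
  fwd <- paste(he[, 1], he[, 2])
  rev <- paste(he[, 2], he[, 1])
  tf <- table(fwd)
  tr <- table(rev)
  keys <- union(names(tf), names(tr))
  cf <- as.integer(tf[keys]); cf[is.na(cf)] <- 0L
  cr <- as.integer(tr[keys]); cr[is.na(cr)] <- 0L
  all(cf == cr)
}

#' Connected components of a mesh
#' @inheritParams face_areas
#' @return Integer vector: component id per vertex.
#' @export
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (k in seq_len(nrow(f))) {
    a <- find(f[k, 1]); b <- find(f[k, 2]); c_ <- find(f[k, 3])
    parent[b] <- a; parent[find(c_)] <- a
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

# Merge vertices closer than tol; returns mesh plus the old->new index map
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  map <- match(key, key)            # first occurrence
  keep <- sort(unique(map))
  newid <- match(map, keep)
  f <- matrix(newid[mesh$faces], ncol = 3)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  m <- trimesh(v[keep, , drop = FALSE], f[!degen, , drop = FALSE])
  attr(m, "vertex_map") <- newid
  m
}

#' Merge several meshes into one (as separate components)
#' @param ... `trimesh` objects.
#' @export
mesh_union_components <- function(...) {
  ms <- list(...)
  vs <- lapply(ms, `[[`, "vertices")
  off <- cumsum(c(0, vapply(vs, nrow, integer(1))))
  fs <- Map(function(m, o) m$faces + o, ms, off[seq_along(ms)])
  trimesh(do.call(rbind, vs), do.call(rbind, fs))
}

# Rigid transforms ----------------------------------------------------------

transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0), scale = 1) {
  mesh$vertices <- sweep(mesh$vertices %*% t(R) * scale, 2, -t)
  mesh
}

# STL / OFF input-output -----------------------------------------------------

#' Read an STL file (binary or ASCII)
#'
#' @param path File path.
#' @param weld Merge coincident vertices (default TRUE).
#' @return A [trimesh].
#' @export
read_stl <- function(path, weld = TRUE) {
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80)
  close(con)
  size <- file.info(path)$size
  is_ascii <- FALSE
  txt5 <- rawToChar(header[1:5])
  if (identical(tolower(txt5), "solid")) {
    # might still be binary; check the size arithmetic
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (is.na(ntri) || size != 84 + 50 * as.numeric(ntri)) is_ascii <- TRUE
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
    v <- do.call(rbind, nums)
    if (nrow(v) %% 3 != 0) stop("malformed ASCII STL: vertex count not multiple of 3")
    f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  } else {
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    dat <- readBin(con, "raw", 50 * ntri)
    close(con)
    m <- matrix(dat, nrow = 50)
    tri <- vapply(seq_len(ntri), function(i) {
      readBin(m[1:48, i], "numeric", 12, size = 4, endian = "little")
    }, numeric(12))
    v <- matrix(NA_real_, 3 * ntri, 3)
    for (k in 1:3) v[seq(k, by = 3, length.out = ntri), ] <- t(tri[3 * k + 1:3, , drop = FALSE])
    f <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  }
  m <- trimesh(v, f)
  if (weld) m <- weld_vertices(m)
  m
}

#' Write a mesh as STL
#'
#' @param mesh A `trimesh` (or `solid_panel`, whose mesh is taken).
#' @param path Output path.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  if (inherits(mesh, "solid_panel")) mesh <- mesh$mesh
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-300)
  nrm <- cbind(nx / nn, ny / nn, nz / nn)
  if (mode == "binary") {
    con <- file(path, "wb")
    writeBin(rep(as.raw(0), 80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    block <- rbind(t(nrm), t(a), t(b), t(c_))  # 12 floats per triangle
    for (i in seq_len(nrow(f))) {
      writeBin(block[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
    close(con)
  } else {
    con <- file(path, "w")
    writeLines("solid capgen", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      writeLines(sprintf("      vertex %.9g %.9g %.9g", c(a[i, 1], b[i, 1], c_[i, 1]),
                         c(a[i, 2], b[i, 2], c_[i, 2]), c(a[i, 3], b[i, 3], c_[i, 3])), con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid capgen", con)
    close(con)
  }
  invisible(path)
}

#' Read an OFF mesh file
#' @param path File path.
#' @return A [trimesh].
#' @export
read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!grepl("^OFF", lines[1])) stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vt <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (x[1] != 3) stop("only triangular OFF faces supported")
    x[2:4] + 1L
  }))
  trimesh(vt, fc)
}

#' Write a mesh as OFF
#' @inheritParams write_stl
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  close(con)
  invisible(path)
}

#' Closest points on a mesh surface
#'
#' @param mesh A `trimesh`.
#' @param points `k x 3` matrix of query points.
#' @return data.frame with columns x, y, z (closest surface point), face,
#'   dist, b1..b3 (barycentrics) and nearest_vertex.
#' @export
nearest_on_mesh <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  r <- cpp_nearest_on_mesh(mesh$vertices, mesh$faces, points)
  data.frame(x = r[, 1], y = r[, 2], z = r[, 3], face = as.integer(r[, 4]),
             dist = r[, 5], b1 = r[, 6], b2 = r[, 7], b3 = r[, 8],
             nearest_vertex = as.integer(r[, 9]))
}
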