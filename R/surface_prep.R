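# Embedding labeled surface points as mesh vertices, and cutting the
# head surface into left / mid / right panel surfaces.

#' Embed labeled surface points as mesh vertices
#'
#' Each point is projected to its closest surface point and inserted as
#' an exact mesh vertex: interior-of-triangle insertion splits one face
#' into three, on-edge insertion splits the two incident faces, and a
#' point coincident with an existing vertex reuses it.  Total surface
#' area is unchanged to float tolerance.
#'
#' @param head A [head_mesh] or [trimesh].
#' @param points k x 3 matrix of points within `max_dist` of the surface.
#' @param labels Character vector of k labels.
#' @param max_dist Maximum allowed point-to-surface distance (mm).
#' @param snap_tol Distance below which a point reuses an existing
#'   vertex / lands on an edge (mm).
#' @return The input object with points embedded; the vertex ids are in
#'   `attr(, "embedded")` (named integer vector).  For a `head_mesh` the
#'   mesh field is replaced.
#' @export
embed_points <- function(head, points, labels = NULL, max_dist = 0.5,
                         snap_tol = 0.1) {
  is_head <- inherits(head, "head_mesh")
  mesh <- if (is_head) head$mesh else head
  points <- matrix(as.numeric(points), ncol = 3)
  if (is.null(labels)) labels <- paste0("pt", seq_len(nrow(points)))
  ids <- setNames(integer(nrow(points)), labels)
  for (k in seq_len(nrow(points))) {
    nr <- nearest_on_mesh(mesh, points[k, , drop = FALSE])
    if (nr$dist > max_dist)
      stop(sprintf("point '%s' is %.3f mm from the surface (max %.3f)",
                   labels[k], nr$dist, max_dist))
    p <- c(nr$x, nr$y, nr$z)
    tri <- mesh$faces[nr$face, ]
    vtx <- mesh$vertices[tri, , drop = FALSE]
    dv <- sqrt(rowSums(sweep(vtx, 2, p)^2))
    if (min(dv) < snap_tol) {            # coincident with existing vertex
      ids[k] <- tri[which.min(dv)]
      next
    }
    # distance to each edge of the host triangle
    eidx <- rbind(c(1, 2), c(2, 3), c(3, 1))
    de <- apply(eidx, 1, function(e) {
      a <- vtx[e[1], ]; b <- vtx[e[2], ]
      t <- sum((p - a) * (b - a)) / max(sum((b - a)^2), 1e-300)
      t <- min(max(t, 0), 1)
      vnorm(a + t * (b - a) - p)
    })
    newv <- rbind(mesh$vertices, p)
    vid <- nrow(newv)
    if (min(de) < snap_tol) {            # on an edge: split both incident faces
      e <- tri[eidx[which.min(de), ]]
      fidx <- which(apply(mesh$faces, 1, function(f) all(e %in% f)))
      newf <- mesh$faces[-fidx, , drop = FALSE]
      for (fi in fidx) {
        f <- mesh$faces[fi, ]
        # replace edge e with two faces through vid, preserving orientation
        pos <- which(f %in% e)
        other <- setdiff(seq_len(3), pos)
        # f = (a, b, c) cyclic; edge e occupies two slots
        for (rot in 0:2) {
          fr <- f[(0:2 + rot) %% 3 + 1]
          if (all(fr[1:2] %in% e)) {
            newf <- rbind(newf, c(fr[1], vid, fr[3]), c(vid, fr[2], fr[3]))
            break
          }
        }
      }
      mesh <- trimesh(newv, newf)
    } else {                              # interior: 1 face -> 3
      f <- mesh$faces[nr$face, ]
      newf <- rbind(mesh$faces[-nr$face, , drop = FALSE],
                    c(f[1], f[2], vid), c(f[2], f[3], vid), c(f[3], f[1], vid))
      mesh <- trimesh(newv, newf)
    }
    ids[k] <- vid
  }
  if (is_head) {
    head$mesh <- mesh
    attr(head, "embedded") <- ids
    head
  } else {
    attr(mesh, "embedded") <- ids
    mesh
  }
}

#' Embed a landmark set into the head mesh
#'
#' Convenience wrapper around [embed_points()] that records the vertex
#' id of every landmark in the landmark set.
#'
#' @param head A [head_mesh].
#' @param landmarks A `landmark_set`.
#' @return list(head, landmarks) with `landmarks$positions$vertex` filled.
#' @export
embed_landmarks <- function(head, landmarks) {
  df <- landmarks$positions
  head2 <- embed_points(head, as.matrix(df[, c("x", "y", "z")]), df$label)
  ids <- attr(head2, "embedded")
  landmarks$positions$vertex <- as.integer(ids[df$label])
  landmarks$positions[, c("x", "y", "z")] <-
    head2$mesh$vertices[landmarks$positions$vertex, ]
  list(head = head2, landmarks = landmarks)
}

# Cut a mesh by a plane, keeping the side where <x,n> >= off.
# Returns list(mesh, provenance, markers) where provenance[i] is the
# original vertex id or NA for vertices created on the cut.
mesh_cut_plane <- function(mesh, normal, offset, markers = integer(0),
                           provenance = NULL, keep = c("above", "below")) {
  keep <- match.arg(keep)
  v <- mesh$vertices
  d <- as.vector(v %*% normal) - offset
  if (keep == "below") d <- -d
  eps <- 1e-9 * max(abs(d), 1)
  d[abs(d) < eps] <- 0
  f <- mesh$faces
  if (is.null(provenance)) provenance <- seq_len(nrow(v))
  newv <- v
  newprov <- provenance
  cutflag <- rep(FALSE, nrow(v))
  edge_cache <- new.env(hash = TRUE)
  cut_point <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    t <- d[a] / (d[a] - d[b])
    p <- (1 - t) * v[a, ] + t * v[b, ]
    newv <<- rbind(newv, p)
    newprov <<- c(newprov, NA_integer_)
    cutflag <<- c(cutflag, TRUE)
    id <- nrow(newv)
    edge_cache[[key]] <- id
    id
  }
  out_faces <- vector("list", nrow(f))
  for (k in seq_len(nrow(f))) {
    tri <- f[k, ]
    dd <- d[tri]
    if (all(dd >= 0)) { out_faces[[k]] <- matrix(tri, 1); next }
    if (all(dd <= 0)) next
    # Sutherland-Hodgman clip of the triangle against the halfspace
    poly <- integer(0)
    for (i in 1:3) {
      a <- tri[i]; b <- tri[i %% 3 + 1]
      if (d[a] >= 0) poly <- c(poly, a)
      if ((d[a] > 0 && d[b] < 0) || (d[a] < 0 && d[b] > 0))
        poly <- c(poly, cut_point(a, b))
    }
    if (length(poly) >= 3) {
      out_faces[[k]] <- do.call(rbind, lapply(2:(length(poly) - 1), function(i)
        c(poly[1], poly[i], poly[i + 1])))
    }
  }
  faces2 <- do.call(rbind, out_faces)
  used <- sort(unique(as.vector(faces2)))
  remap <- match(seq_len(nrow(newv)), used)
  m2 <- trimesh(newv[used, , drop = FALSE],
                matrix(remap[faces2], ncol = 3))
  mk <- remap[markers]
  names(mk) <- names(markers)
  list(mesh = m2, provenance = newprov[used], cut_new = cutflag[used],
       markers = mk)
}

#' Panel surface: a cut piece of the scalp with provenance
#'
#' @param mesh Submesh ([trimesh]).
#' @param provenance Original head-mesh vertex id per vertex (NA = created
#'   by a cut).
#' @param markers Named vertex ids (landmarks and optodes present on this
#'   panel).
#' @param boundary data.frame of boundary edges with a `loop` label
#'   (axial / sagittal-left / sagittal-right / other).
#' @param role Panel role: `"left"`, `"mid"` or `"right"`.
#' @return Object of class `panel_surface`.
#' @export
panel_surface <- function(mesh, provenance, markers, boundary, role) {
  structure(list(mesh = mesh, provenance = provenance, markers = markers,
                 boundary = boundary, role = role), class = "panel_surface")
}

#' @export
print.panel_surface <- function(x, ...) {
  cat(sprintf("<panel_surface:%s> %d vertices, %d faces, %d markers\n",
              x$role, nrow(x$mesh$vertices), nrow(x$mesh$faces),
              length(x$markers)))
  invisible(x)
}

label_boundary <- function(mesh, planes, tol = 1e-6) {
  be <- boundary_edges(mesh)
  if (!nrow(be)) return(data.frame(from = integer(), to = integer(), loop = character()))
  lab <- rep("other", nrow(be))
  v <- mesh$vertices
  for (nm in names(planes)) {
    pl <- planes[[nm]]
    d1 <- abs(as.vector(v[be[, 1], , drop = FALSE] %*% pl$normal) - pl$offset)
    d2 <- abs(as.vector(v[be[, 2], , drop = FALSE] %*% pl$normal) - pl$offset)
    on_plane <- d1 < tol & d2 < tol & lab == "other"
    lab[on_plane] <- nm
  }
  data.frame(from = be[, 1], to = be[, 2], loop = lab)
}

#' Cut the head surface into left, mid and right panel surfaces
#'
#' The axial cut plane passes through Iz and the point `axial_offset` mm
#' superior of Nz (normal in the Y-Z plane); everything below is
#' discarded.  Two sagittal planes X = +/- x0 bound the mid panel, with
#' x0 chosen so the coronal arc LPA-Cz-RPA between the planes equals
#' `mid_fraction` of its total length (`"arc"` interpretation; the
#' `"chord"` alternative measures the straight-line LPA-RPA distance).
#'
#' @param head A [head_mesh] with landmarks embedded (see
#'   [embed_landmarks()]).
#' @param landmarks The embedded `landmark_set`.
#' @param optode_vertices Named integer vector of registered optode
#'   vertex ids (these must survive the axial cut; an error names any
#'   optode that falls below it).
#' @param axial_offset mm above Nz for the axial cut (default 15).
#' @param mid_fraction Fraction of the coronal LPA-RPA distance spanned
#'   by the mid panel (default 3/7).
#' @param mid_measure `"arc"` (default) or `"chord"`.
#' @return list of three [panel_surface] objects: `left`, `mid`, `right`,
#'   with attribute `x0` (sagittal plane offset, mm) and `planes`.
#' @export
cut_panels <- function(head, landmarks, optode_vertices = integer(0),
                       axial_offset = 15, mid_fraction = 3 / 7,
                       mid_measure = c("arc", "chord")) {
  mid_measure <- match.arg(mid_measure)
  mesh <- head$mesh
  fid <- head$fiducials
  Cz <- landmark_positions(landmarks, "Cz")[1, ]
  # axial plane through Iz and Nz + offset, lateral orientation
  p1 <- fid["Iz", ]; p2 <- fid["Nz", ] + c(0, 0, axial_offset)
  nrm <- cross3(c(1, 0, 0), p2 - p1)
  nrm <- normalize(nrm)
  if (nrm[3] < 0) nrm <- -nrm             # "above" = +Z side
  axial <- list(normal = nrm, offset = sum(nrm * p1))
  # sagittal offset x0 from the coronal arc
  pl_cor <- plane_from_points(fid["LPA", ], fid["RPA", ], Cz)
  if (mid_measure == "arc") {
    half <- mid_fraction / 2
    pts <- arc_fraction_points(mesh, fid["LPA", ], fid["RPA", ], pl_cor,
                               c(0.5 - half, 0.5 + half))
    x0 <- mean(abs(pts[, 1]))
  } else {
    x0 <- mid_fraction / 2 * vnorm(fid["RPA", ] - fid["LPA", ])
  }
  sag_l <- list(normal = c(1, 0, 0), offset = -x0)
  sag_r <- list(normal = c(1, 0, 0), offset = x0)
  markers0 <- c(setNames(landmarks$positions$vertex, landmarks$positions$label),
                optode_vertices)
  # check optodes survive the axial cut
  if (length(optode_vertices)) {
    dz <- as.vector(mesh$vertices[optode_vertices, , drop = FALSE] %*% axial$normal) - axial$offset
    if (any(dz < 0))
      stop("registered optode(s) below the axial cut: ",
           paste(names(optode_vertices)[dz < 0], collapse = ", "))
  }
  top <- mesh_cut_plane(mesh, axial$normal, axial$offset, markers0)
  make_panel <- function(cut, role) {
    planes <- list(axial = axial, "sagittal-left" = sag_l, "sagittal-right" = sag_r)
    bl <- label_boundary(cut$mesh, planes)
    mk <- cut$markers[!is.na(cut$markers)]
    panel_surface(cut$mesh, cut$provenance, mk, bl, role)
  }
  left <- mesh_cut_plane(top$mesh, sag_l$normal, sag_l$offset,
                         top$markers[!is.na(top$markers)],
                         provenance = top$provenance, keep = "below")
  right <- mesh_cut_plane(top$mesh, sag_r$normal, sag_r$offset,
                          top$markers[!is.na(top$markers)],
                          provenance = top$provenance, keep = "above")
  midtmp <- mesh_cut_plane(top$mesh, sag_l$normal, sag_l$offset,
                           top$markers[!is.na(top$markers)],
                           provenance = top$provenance, keep = "above")
  mid <- mesh_cut_plane(midtmp$mesh, sag_r$normal, sag_r$offset,
                        midtmp$markers[!is.na(midtmp$markers)],
                        provenance = midtmp$provenance, keep = "below")
  out <- list(left = make_panel(left, "left"),
              mid = make_panel(mid, "mid"),
              right = make_panel(right, "right"))
  attr(out, "x0") <- x0
  attr(out, "planes") <- list(axial = axial, "sagittal-left" = sag_l,
                              "sagittal-right" = sag_r)
  attr(out, "discarded_area") <- mesh_area(mesh) - mesh_area(top$mesh)
  out
}
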