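# 2D panel design: outlines traced from flattened cut lines, hexagonal
# lattice fill, seams and welding tabs, mid-panel halving.

#' Printable 2D panel design
#'
#' @param role One of `"left"`, `"right"`, `"mid-front"`, `"mid-back"`.
#' @param outline Closed 2D polygon (k x 2, mm), counter-clockwise.
#' @param outline_labels Character per outline edge (vertex i -> i+1):
#'   which cut/template it came from.
#' @param grommets data.frame: `x`, `y`, `rotation`, `grommet`, `name`.
#' @param seams Named list; each seam holds `poly` (2D polyline) and `s`
#'   (shared arc-length parameter along the 3D cut, identical across the
#'   two panels of the seam).
#' @return Object of class `panel_design`.
#' @export
panel_design_2d <- function(role, outline, outline_labels, grommets = NULL,
                            seams = list()) {
  if (is.null(grommets))
    grommets <- data.frame(x = numeric(), y = numeric(), rotation = numeric(),
                           grommet = character(), name = character())
  structure(list(role = role, outline = outline,
                 outline_labels = outline_labels, grommets = grommets,
                 seams = seams, lattice = NULL, tabs = NULL),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("<panel_design:%s> outline %d pts, %d grommets, %s lattice, %d tabs\n",
              x$role, nrow(x$outline), nrow(x$grommets),
              if (is.null(x$lattice)) "no" else sprintf("%d-beam", nrow(x$lattice$edges)),
              if (is.null(x$tabs)) 0L else nrow(x$tabs)))
  invisible(x)
}

# Ordered boundary loop of a flat mesh: vertex ids, 2D coords and the
# per-edge cut labels carried from the panel surface.
flat_outline <- function(flat) {
  be <- boundary_edges(list(vertices = cbind(flat$xy, flat$z), faces = flat$faces))
  lab_df <- flat$boundary
  key <- paste(pmin(lab_df$from, lab_df$to), pmax(lab_df$from, lab_df$to))
  labmap <- setNames(lab_df$loop, key)
  nxt <- setNames(be[, 2], be[, 1])
  elab <- setNames(labmap[paste(pmin(be[, 1], be[, 2]), pmax(be[, 1], be[, 2]))],
                   be[, 1])
  start <- be[1, 1]
  ids <- integer(0); labs <- character(0)
  cur <- start
  repeat {
    ids <- c(ids, cur)
    labs <- c(labs, elab[[as.character(cur)]])
    cur <- nxt[[as.character(cur)]]
    if (is.null(cur) || cur == start) break
    if (length(ids) > nrow(be) + 1) stop("open or non-manifold boundary loop")
  }
  xy <- flat$xy[ids, , drop = FALSE]
  if (polygon_area(xy) < 0) {         # force counter-clockwise
    ids <- rev(ids); xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    labs <- rev(c(labs[-1], labs[1]))
  }
  list(ids = ids, xy = xy, labels = labs)
}

# Rotate (and possibly reflect) the flat mesh into a canonical frame
# using flattened landmark positions: +y toward the top of the panel
# (sagittal cut for sides, nothing to do for mid), +x toward the front
# (nasion side).  Returns the flat mesh with xy replaced.
canonicalize_flat <- function(flat) {
  mk <- flat$markers
  get2 <- function(lbl) {
    i <- mk[[lbl]]
    if (is.null(i) || is.na(i)) NULL else flat$xy[i, ]
  }
  pick <- function(cands) {
    for (l in cands) { p <- get2(l); if (!is.null(p)) return(p) }
    NULL
  }
  if (flat$role == "mid") {
    front <- pick(c("Fpz", "AFpz", "AFz", "Fz"))
    back <- pick(c("Oz", "POOz", "POz", "Pz"))
    left <- pick(c("C3", "C1", "C3h"))
    right <- pick(c("C4", "C2", "C4h"))
    if (is.null(front) || is.null(back)) return(flat)
    u <- normalize2(front - back)            # +y toward front
    Rm <- rbind(c(u[2], -u[1]), c(u[1], u[2]))  # maps u -> (0,1)
    xy <- flat$xy %*% t(Rm)
    if (!is.null(left) && !is.null(right)) {
      l2 <- Rm %*% left; r2 <- Rm %*% right
      if (l2[1] > r2[1]) xy[, 1] <- -xy[, 1]   # +x toward the right ear
    }
    flat$xy <- xy
  } else {
    side <- if (flat$role == "left") "7" else "8"
    front <- pick(paste0(c("F", "AF", "FT", "Fp"), side))
    back <- pick(paste0(c("P", "PO", "TP", "O"), c(side, side, side, sub("7", "1", sub("8", "2", side)))))
    low <- pick(paste0(c("T", "FT", "TP"), side))
    high <- pick(paste0(c("C", "FC", "CP"), if (side == "7") "5" else "6"))
    if (is.null(front) || is.null(back)) return(flat)
    u <- normalize2(front - back)            # +x toward front
    Rm <- rbind(c(u[1], u[2]), c(-u[2], u[1]))  # maps u -> (1,0)
    xy <- flat$xy %*% t(Rm)
    if (!is.null(low) && !is.null(high)) {
      l2 <- Rm %*% low; h2 <- Rm %*% high
      if (h2[2] < l2[2]) xy[, 2] <- -xy[, 2]   # +y toward the top of the head
    }
    flat$xy <- xy
  }
  flat
}

normalize2 <- function(v) v / sqrt(sum(v^2))

# 2D image of the slice of the flat mesh's 3D parent by a plane: used to
# cut the mid panel at the coronal line through Cz.  Interpolates along
# mesh edges so the 2D and 3D polylines correspond exactly.
flat_slice_2d <- function(flat, normal, offset) {
  V3 <- flat$panel_vertices_3d
  d <- as.vector(V3 %*% normal) - offset
  scale <- max(abs(d), 1)
  d[abs(d) < 1e-12 * scale] <- 1e-12 * scale
  f <- flat$faces
  segs <- list(); keys <- list()
  for (k in seq_len(nrow(f))) {
    tri <- f[k, ]
    if (!(min(d[tri]) < 0 && max(d[tri]) > 0)) next
    pts2 <- matrix(NA_real_, 0, 2); kk <- character(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- tri[e[1]]; b <- tri[e[2]]
      if (sign(d[a]) != sign(d[b])) {
        t <- d[a] / (d[a] - d[b])
        pts2 <- rbind(pts2, (1 - t) * flat$xy[a, ] + t * flat$xy[b, ])
        kk <- c(kk, paste(min(a, b), max(a, b)))
      }
    }
    segs[[length(segs) + 1]] <- pts2
    keys[[length(keys) + 1]] <- kk
  }
  if (!length(segs)) stop("halving plane does not cross the panel")
  # chain by edge key into one open polyline
  nseg <- length(segs)
  used <- rep(FALSE, nseg)
  k1 <- vapply(keys, `[`, "", 1); k2 <- vapply(keys, `[`, "", 2)
  allk <- c(k1, k2); segof <- rep(seq_len(nseg), 2); endof <- rep(1:2, each = nseg)
  lut <- split(seq_along(allk), allk)
  # find an endpoint key that appears once (boundary end)
  cnt <- table(allk)
  start_key <- names(cnt)[cnt == 1][1]
  inc <- lut[[start_key]][1]
  cur <- segof[inc]; ein <- endof[inc]
  used[cur] <- TRUE
  pts <- if (ein == 1) rbind(segs[[cur]][1, ], segs[[cur]][2, ]) else
    rbind(segs[[cur]][2, ], segs[[cur]][1, ])
  repeat {
    lastk <- if (ein == 1) k2[cur] else k1[cur]
    nxt <- NULL
    for (ci in lut[[lastk]]) {
      s <- segof[ci]
      if (!used[s]) { nxt <- ci; break }
    }
    if (is.null(nxt)) break
    cur <- segof[nxt]; ein <- endof[nxt]
    used[cur] <- TRUE
    pts <- rbind(pts, if (ein == 1) segs[[cur]][2, ] else segs[[cur]][1, ])
  }
  pts
}

#' Split the flattened mid panel into front and back outlines
#'
#' The halving line is the flattened image of the coronal plane through
#' Cz (normal along the anterior axis).  Grommets are assigned to the
#' half containing them; a grommet exactly on the line goes to the front
#' half and is flagged.
#'
#' @param flat_mid A canonicalized `flat_mesh` of the mid panel.
#' @param grommets Optional data.frame of grommet placements in the mid
#'   panel (columns x, y, rotation, grommet, name).
#' @return List of two [panel_design_2d] objects `front` and `back`,
#'   each carrying the halving polyline as seam `"midline"` plus the
#'   sagittal seams.
#' @export
build_mid_outlines <- function(flat_mid, grommets = NULL) {
  ol <- flat_outline(flat_mid)
  czv <- flat_mid$markers[["Cz"]]
  if (is.null(czv) || is.na(czv)) stop("mid panel has no embedded Cz landmark")
  cz3 <- flat_mid$panel_vertices_3d[czv, ]
  cutline <- flat_slice_2d(flat_mid, c(0, 1, 0), cz3[2])
  if (cutline[1, 1] > cutline[nrow(cutline), 1])
    cutline <- cutline[rev(seq_len(nrow(cutline))), , drop = FALSE]
  p1 <- cutline[1, ]; p2 <- cutline[nrow(cutline), ]
  # insert the two cut endpoints into the outline polygon
  poly <- ol$xy
  for (p in list(p1, p2)) {
    nn <- nrow(poly)
    a <- poly; b <- poly[c(2:nn, 1), , drop = FALSE]
    ab <- b - a
    t <- rowSums(sweep(-a, 2, p, `+`) * ab) / pmax(rowSums(ab^2), 1e-300)
    t <- pmin(pmax(t, 0), 1)
    proj <- a + ab * t
    i <- which.min(rowSums(sweep(proj, 2, p)^2))
    poly <- rbind(poly[seq_len(i), , drop = FALSE], p,
                  if (i < nn) poly[(i + 1):nn, , drop = FALSE])
  }
  poly <- close_clean(poly)
  nn <- nrow(poly)
  i1 <- which.min(rowSums(sweep(poly, 2, p1)^2))
  i2 <- which.min(rowSums(sweep(poly, 2, p2)^2))
  walk <- function(from, to) if (from <= to) from:to else c(from:nn, 1:to)
  mk_half <- function(seg) {
    starts_at_p1 <- sum((seg[1, ] - p1)^2) < sum((seg[1, ] - p2)^2)
    # seg runs p1..p2 (or p2..p1); close back along the cutline
    cl <- if (starts_at_p1) cutline[rev(seq_len(nrow(cutline))), , drop = FALSE] else cutline
    close_clean(rbind(seg, cl[-1, , drop = FALSE]))
  }
  segA <- poly[walk(i1, i2), , drop = FALSE]
  segB <- poly[walk(i2, i1), , drop = FALSE]
  polyA <- mk_half(segA)
  polyB <- mk_half(segB)
  a_is_front <- mean(segA[, 2]) > mean(segB[, 2])
  poly_front <- if (a_is_front) polyA else polyB
  poly_back <- if (a_is_front) polyB else polyA
  if (polygon_area(poly_front) < 0)
    poly_front <- poly_front[rev(seq_len(nrow(poly_front))), , drop = FALSE]
  if (polygon_area(poly_back) < 0)
    poly_back <- poly_back[rev(seq_len(nrow(poly_back))), , drop = FALSE]
  seam_mid <- list(poly = cutline, s = polyline_lengths(cutline))
  sag <- panel_seam_records(flat_mid, ol)
  seams <- c(list(midline = seam_mid), sag)
  gro <- grommets
  gf <- gb <- NULL
  if (!is.null(gro) && nrow(gro)) {
    online <- vapply(seq_len(nrow(gro)), function(i)
      arc_position(cbind(cutline, 0), c(gro$x[i], gro$y[i], 0), closed = FALSE)$dist < 1e-6,
      logical(1))
    inf <- points_in_polygon(as.matrix(gro[, c("x", "y")]), poly_front)
    gro$on_midline <- online
    gf <- gro[inf | online, , drop = FALSE]     # tie-break: front
    gb <- gro[!(inf | online), , drop = FALSE]
  }
  front <- panel_design_2d("mid-front", poly_front,
                           classify_outline_edges(poly_front, seams), gf, seams)
  back <- panel_design_2d("mid-back", poly_back,
                          classify_outline_edges(poly_back, seams), gb, seams)
  list(front = front, back = back)
}

close_clean <- function(poly, tol = 1e-9) {
  keep <- c(TRUE, sqrt(rowSums(diff(poly)^2)) > tol)
  poly <- poly[keep, , drop = FALSE]
  if (nrow(poly) > 1 && sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2)) < tol)
    poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}

# label every outline edge by the seam polyline it lies on ("axial" if none)
classify_outline_edges <- function(poly, seams, tol = 1e-6) {
  n <- nrow(poly)
  mid <- (poly + poly[c(2:n, 1), , drop = FALSE]) / 2
  labs <- rep("axial", n)
  for (nm in names(seams)) {
    sp3 <- cbind(seams[[nm]]$poly, 0)
    for (i in which(labs == "axial")) {
      if (arc_position(sp3, c(mid[i, ], 0), closed = FALSE)$dist < tol)
        labs[i] <- nm
    }
  }
  labs
}

# Seam records for the sagittal boundaries of a flat panel: the 2D
# boundary portion labeled sagittal-left/right plus the shared arc
# parameter computed from the 3D cut-line coordinates (identical across
# the two panels sharing the cut).
panel_seam_records <- function(flat, ol) {
  out <- list()
  for (nm in c("sagittal-left", "sagittal-right")) {
    sel <- which(ol$labels == nm)
    if (!length(sel)) next
    # contiguous run (a boundary label occupies one run on the loop)
    ids <- ol$ids
    n <- length(ids)
    runs <- split(sel, cumsum(c(1, diff(sel) != 1)))
    # merge wrap-around
    if (length(runs) > 1 && sel[1] == 1 && sel[length(sel)] == n) {
      runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
      runs[[length(runs)]] <- NULL
    }
    run <- runs[[which.max(lengths(runs))]]
    vidx <- c(run, run[length(run)] %% n + 1)   # edge i spans vertex i..i+1
    pts2 <- ol$xy[ifelse(vidx > n, vidx - n, vidx), , drop = FALSE]
    ids3 <- ol$ids[ifelse(vidx > n, vidx - n, vidx)]
    p3 <- flat$panel_vertices_3d[ids3, , drop = FALSE]
    # shared parameter: 3D arc length from the anterior (max y) end
    if (p3[1, 2] < p3[nrow(p3), 2]) {
      pts2 <- pts2[rev(seq_len(nrow(pts2))), , drop = FALSE]
      p3 <- p3[rev(seq_len(nrow(p3))), , drop = FALSE]
    }
    out[[nm]] <- list(poly = pts2, s = polyline_lengths(p3))
  }
  out
}

#' Build the side-panel outline: flattened sagittal cut + lower template
#'
#' The sagittal cutting line after flattening forms the upper outline;
#' the lower outline (under the chin, around the ear, above the neck) is
#' a parametric template curve, laterally stretched so its endpoints
#' meet the outmost points of the upper outline.
#'
#' @param flat_side Canonicalized `flat_mesh` of a side panel.
#' @param template data.frame with columns `frac` (0..1 along the chord
#'   between the upper outline's endpoints) and `drop` (mm below the
#'   chord); default [side_template()].
#' @param grommets Optional grommet placement data.frame.
#' @return A [panel_design_2d] with the sagittal seam recorded.
#' @export
build_side_outline <- function(flat_side, template = side_template(),
                               grommets = NULL) {
  ol <- flat_outline(flat_side)
  nm <- if (flat_side$role == "left") "sagittal-left" else "sagittal-right"
  seams <- panel_seam_records(flat_side, ol)
  if (is.null(seams[[nm]])) stop("side panel has no labeled sagittal boundary")
  upper <- seams[[nm]]$poly
  # upper runs front -> back along +x in the canonical frame; outline
  # traversal wants it in loop order; template spans its endpoints
  e1 <- upper[1, ]; e2 <- upper[nrow(upper), ]
  chord <- e2 - e1
  width <- sqrt(sum(chord^2))
  if (width < 10) stop("degenerate flat side panel: sagittal outline too short")
  u <- chord / width
  v <- c(-u[2], u[1])
  # "down" = away from the panel interior (the mesh lies above the chord)
  ctr <- colMeans(flat_side$xy)
  if (sum((ctr - e1) * v) > 0) v <- -v
  tcurve <- catmull_rom(cbind(template$frac, template$drop), n_out = 80)
  low <- t(vapply(seq_len(nrow(tcurve)), function(i)
    e1 + tcurve[i, 1] * width * u + tcurve[i, 2] * v, numeric(2)))
  poly <- close_clean(rbind(upper, low[rev(seq_len(nrow(low))), , drop = FALSE][-1, , drop = FALSE]))
  labs <- c(rep(nm, nrow(upper) - 1), rep("template", nrow(poly) - nrow(upper) + 1))
  if (polygon_area(poly) < 0) {
    poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
    labs <- rev(labs)
  }
  if (!polygon_is_simple(poly))
    stop("side outline self-intersects; adjust the template")
  panel_design_2d(flat_side$role, poly, labs, grommets, seams[nm])
}

#' Default lower-outline template for side panels
#'
#' Control points in normalized lateral coordinates (`frac` 0 = front
#' endpoint of the upper outline, 1 = back endpoint) and mm of drop
#' below the endpoint chord: a chin dip at the front, clearance around
#' the ear, and a neck rise at the back.  The published cap uses a
#' hand-optimized curve; this one is a configurable stand-in with the
#' same structure.
#'
#' @return data.frame with columns `frac` and `drop`.
#' @export
side_template <- function() {
  data.frame(
    frac = c(0, 0.06, 0.16, 0.30, 0.45, 0.60, 0.75, 0.88, 0.96, 1),
    drop = c(0, 18, 38, 52, 58, 56, 46, 28, 10, 0))
}

# Centripetal Catmull-Rom through control points, endpoint-clamped
catmull_rom <- function(pts, n_out = 64) {
  p <- rbind(pts[1, ], pts, pts[nrow(pts), ])
  out <- list()
  nseg <- nrow(p) - 3
  per <- max(2, ceiling(n_out / nseg))
  for (i in seq_len(nseg)) {
    P0 <- p[i, ]; P1 <- p[i + 1, ]; P2 <- p[i + 2, ]; P3 <- p[i + 3, ]
    t <- seq(0, 1, length.out = per + 1)[-(per + 1)]
    m1 <- (P2 - P0) / 2; m2 <- (P3 - P1) / 2
    h00 <- 2 * t^3 - 3 * t^2 + 1; h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2; h11 <- t^3 - t^2
    out[[i]] <- cbind(h00 * P1[1] + h10 * m1[1] + h01 * P2[1] + h11 * m2[1],
                      h00 * P1[2] + h10 * m1[2] + h01 * P2[2] + h11 * m2[2])
  }
  rbind(do.call(rbind, out), pts[nrow(pts), ])
}

#' Fill a panel outline with a hexagonal lattice
#'
#' A regular hexagonal grid (pointy-top, edge length `edge`) is clipped
#' to the outline; beams crossing the boundary are trimmed at the
#' crossing and connected to the outline ring, which itself becomes part
#' of the lattice.  Interior beams have length exactly `edge`.
#'
#' @param design A [panel_design_2d] (or a bare polygon for testing).
#' @param edge Hexagon edge length, mm (default 10).
#' @param width Beam width, mm (default 0.85).
#' @param min_stub Trimmed beams shorter than this are dropped (mm).
#' @return The design with `$lattice`: `nodes` (m x 2), `edges` (e x 2),
#'   `width` (per edge), `kind` (`"hex"`/`"outline"`).  For a bare
#'   polygon input the lattice list itself is returned.
#' @export
hex_fill <- function(design, edge = 10, width = 0.85, min_stub = 1) {
  bare <- !inherits(design, "panel_design")
  outline <- if (bare) design else design$outline
  if (abs(polygon_area(outline)) < (3 * sqrt(3) / 2) * edge^2)
    stop("outline smaller than one hexagon: degenerate lattice")
  bb <- apply(outline, 2, range)
  a <- edge
  dx <- sqrt(3) * a       # horizontal center spacing (pointy-top)
  dy <- 1.5 * a
  qmin <- floor((bb[1, 1] - 2 * a) / dx) - 2
  qmax <- ceiling((bb[2, 1] + 2 * a) / dx) + 2
  rmin <- floor((bb[1, 2] - 2 * a) / dy) - 2
  rmax <- ceiling((bb[2, 2] + 2 * a) / dy) + 2
  vkey <- new.env(hash = TRUE)
  nodes <- list()
  getnode <- function(x, y) {
    k <- paste(round(x * 1e6), round(y * 1e6))
    id <- vkey[[k]]
    if (is.null(id)) {
      nodes[[length(nodes) + 1]] <<- c(x, y)
      id <- length(nodes)
      vkey[[k]] <- id
    }
    id
  }
  eseen <- new.env(hash = TRUE)
  e_from <- integer(0); e_to <- integer(0)
  ang <- pi / 6 + (0:5) * pi / 3
  hx <- a * cos(ang); hy <- a * sin(ang)
  for (r in rmin:rmax) {
    cy <- r * dy
    xoff <- if (r %% 2 == 0) 0 else dx / 2
    for (q in qmin:qmax) {
      cx <- q * dx + xoff
      vid <- vapply(1:6, function(k) getnode(cx + hx[k], cy + hy[k]), integer(1))
      for (k in 1:6) {
        i <- vid[k]; j <- vid[k %% 6 + 1]
        ek <- paste(min(i, j), max(i, j))
        if (is.null(eseen[[ek]])) {
          eseen[[ek]] <- TRUE
          e_from <- c(e_from, i); e_to <- c(e_to, j)
        }
      }
    }
  }
  nodemat <- do.call(rbind, nodes)
  inside <- points_in_polygon(nodemat, outline)
  keep_e <- list()
  cross_nodes <- list()     # crossing points to insert on the outline ring
  new_nodes <- nodemat
  add_node <- function(p) {
    new_nodes <<- rbind(new_nodes, p)
    nrow(new_nodes)
  }
  for (k in seq_along(e_from)) {
    i <- e_from[k]; j <- e_to[k]
    pi_ <- nodemat[i, ]; pj <- nodemat[j, ]
    if (inside[i] && inside[j]) {
      # both inside; make sure the segment does not exit (convexity dips)
      ts <- segment_polygon_crossings(pi_, pj, outline)
      ts <- ts[ts > 1e-9 & ts < 1 - 1e-9]
      if (!length(ts)) keep_e[[length(keep_e) + 1]] <- c(i, j, "hex")
    } else if (inside[i] || inside[j]) {
      if (inside[j]) { tmp <- i; i <- j; j <- tmp; pi_ <- nodemat[i, ]; pj <- nodemat[j, ] }
      ts <- segment_polygon_crossings(pi_, pj, outline)
      ts <- ts[ts > 1e-9]
      if (!length(ts)) next
      t0 <- ts[1]
      pc <- pi_ + t0 * (pj - pi_)
      if (sqrt(sum((pc - pi_)^2)) < min_stub) next
      cid <- add_node(pc)
      cross_nodes[[length(cross_nodes) + 1]] <- cid
      keep_e[[length(keep_e) + 1]] <- c(i, cid, "hex")
    }
  }
  # outline ring: polygon vertices + crossing nodes + any lattice node
  # that falls exactly on the boundary (hex edges collinear with the
  # outline then duplicate ring segments and are deduplicated below),
  # chained in arc order
  ring_ids <- vapply(seq_len(nrow(outline)), function(i) add_node(outline[i, ]), integer(1))
  op <- rbind(outline, outline[1, , drop = FALSE])
  cl <- polyline_lengths(op)
  ring_s <- cl[seq_len(nrow(outline))]
  used_nodes <- sort(unique(unlist(lapply(keep_e, function(e) as.integer(e[1:2])))))
  used_nodes <- used_nodes[used_nodes <= nrow(nodemat)]
  on_bnd <- used_nodes[vapply(used_nodes, function(i)
    arc_position(cbind(op, 0), c(nodemat[i, ], 0), closed = FALSE)$dist < 1e-6,
    logical(1))]
  cross_ids <- c(unlist(cross_nodes), on_bnd)
  cross_s <- vapply(cross_ids, function(cid) {
    arc_position(cbind(op, 0), c(new_nodes[cid, ], 0), closed = FALSE)$s
  }, numeric(1))
  allr <- c(ring_ids, cross_ids)
  alls <- c(ring_s, cross_s)
  ordr <- order(alls, allr)
  seq_ring <- allr[ordr]
  for (k in seq_along(seq_ring)) {
    i <- seq_ring[k]; j <- seq_ring[k %% length(seq_ring) + 1]
    if (i != j) keep_e[[length(keep_e) + 1]] <- c(i, j, "outline")
  }
  em <- do.call(rbind, keep_e)
  edges <- cbind(as.integer(em[, 1]), as.integer(em[, 2]))
  kind <- em[, 3]
  g <- weld_graph_nodes(new_nodes, edges, rep(width, nrow(edges)), kind,
                        tol = 0.3)
  lattice <- list(nodes = g$nodes, edges = g$edges, width = g$width,
                  kind = g$kind, hex_edge = edge)
  if (bare) return(lattice)
  design$lattice <- lattice
  design
}

#' Generate welding tabs along a shared seam of two panels
#'
#' Lattice beams ending on the seam are paired across the two panels by
#' their shared seam-arc position; each pair is repositioned to the
#' midpoint position and both beams are extended past the seam by the
#' partner's beam length so the printed tabs overlap for ultrasonic
#' welding.  Unequal counts are resolved by two-to-one merging; a
#' grommet within one hex edge of the seam extends the overlapping tab
#' to the next lattice node.
#'
#' @param panelA,panelB [panel_design_2d] objects that both carry seam
#'   `seam_name` (same arc parameterization, from the shared 3D cut).
#' @param seam_name Name of the seam in both designs' `$seams`.
#' @param tab_width Printed tab width, mm (default 2).
#' @param reach Search distance toward the seam, mm (default one hex
#'   edge, 10).
#' @return list(panelA, panelB) with `$tabs` data.frames appended
#'   (columns: pair id, base/tip coordinates, width, merged, near_grommet)
#'   and an `unpaired` attribute listing seam edges with no counterpart.
#' @export
generate_weld_tabs <- function(panelA, panelB, seam_name, tab_width = 2,
                               reach = 10) {
  sa <- seam_tab_candidates(panelA, seam_name)
  sb <- seam_tab_candidates(panelB, seam_name)
  # restrict to the seam window both panels actually cover (a side panel
  # faces the two mid halves across the same sagittal seam)
  if (nrow(sa) && nrow(sb)) {
    lo <- max(min(sa$s), min(sb$s)) - reach
    hi <- min(max(sa$s), max(sb$s)) + reach
    sa <- sa[sa$s >= lo & sa$s <= hi, , drop = FALSE]
    sb <- sb[sb$s >= lo & sb$s <= hi, , drop = FALSE]
  }
  if (!nrow(sa) || !nrow(sb)) {
    attr(panelA, "unpaired") <- nrow(sa)
    attr(panelB, "unpaired") <- nrow(sb)
    return(list(panelA = panelA, panelB = panelB))
  }
  swap <- nrow(sb) > nrow(sa)
  pa <- panelA; pb <- panelB
  if (swap) { tmp <- sa; sa <- sb; sb <- tmp; pa <- panelB; pb <- panelA }
  # pair each (larger-side) edge with its closest partner by seam arc;
  # candidates with no counterpart within 2 x reach stay unpaired (the
  # printed cap is still assemblable there)
  j <- vapply(sa$s, function(s) which.min(abs(sb$s - s)), integer(1))
  dist_s <- abs(sb$s[j] - sa$s)
  ok_pair <- dist_s <= reach
  unpairedA <- sum(!ok_pair)
  groups <- split(seq_len(nrow(sa))[ok_pair], j[ok_pair])
  tabsA <- list(); tabsB <- list()
  unpairedB <- setdiff(seq_len(nrow(sb)), as.integer(names(groups)))
  pid <- 0
  for (gb in names(groups)) {
    ga <- groups[[gb]]
    bi <- as.integer(gb)
    if (length(ga) > 2) ga <- ga[order(abs(sa$s[ga] - sb$s[bi]))][1:2]
    pid <- pid + 1
    id <- sprintf("%s[%s|%s]:%d", seam_name, pa$role, pb$role, pid)
    s_star <- (mean(sa$s[ga]) + sb$s[bi]) / 2
    merged <- length(ga) > 1
    # a merged pair joins the same partner tab but lands at two slightly
    # separated seam points so the two beams do not collapse onto one
    # junction node
    offs <- if (merged) seq(-0.75, 0.75, length.out = length(ga)) else 0
    rowsA <- list()
    for (gi in seq_along(ga)) {
      ai <- ga[gi]
      rowsA[[gi]] <- make_tab(pa, seam_name, sa[ai, ], s_star + offs[gi],
                              ext = sb$len[bi], id = id, merged = merged,
                              tab_width = tab_width, reach = reach)
    }
    rowB <- make_tab(pb, seam_name, sb[bi, ], s_star, ext = max(sa$len[ga]),
                     id = id, merged = merged, tab_width = tab_width,
                     reach = reach)
    rowsA <- rowsA[!vapply(rowsA, is.null, logical(1))]
    if (!length(rowsA) || is.null(rowB)) { unpairedA <- unpairedA + 1; next }
    tabsA <- c(tabsA, rowsA)
    tabsB[[length(tabsB) + 1]] <- rowB
  }
  A <- panelA; B <- panelB
  ta <- do.call(rbind, tabsA); tb <- do.call(rbind, tabsB)
  if (swap) { tmp <- ta; ta <- tb; tb <- tmp }
  A$tabs <- rbind(A$tabs, ta)
  B$tabs <- rbind(B$tabs, tb)
  if (swap) {
    attr(A, "unpaired") <- length(unpairedB)
    attr(B, "unpaired") <- unpairedA
  } else {
    attr(A, "unpaired") <- unpairedA
    attr(B, "unpaired") <- length(unpairedB)
  }
  if (unpairedA + length(unpairedB) > 0)
    warning(sprintf("seam %s: %d tab candidate(s) without a counterpart within 2x reach",
                    seam_name, unpairedA + length(unpairedB)))
  list(panelA = A, panelB = B)
}

# Lattice edges with exactly one endpoint on the named seam polyline.
seam_tab_candidates <- function(design, seam_name, tol = 1e-6) {
  seam <- design$seams[[seam_name]]
  if (is.null(seam)) stop("panel '", design$role, "' does not carry seam ", seam_name)
  lat <- design$lattice
  if (is.null(lat)) stop("hex_fill must run before tab generation")
  sp3 <- cbind(seam$poly, 0)
  on_seam <- vapply(seq_len(nrow(lat$nodes)), function(i) {
    arc_position(sp3, c(lat$nodes[i, ], 0), closed = FALSE)$dist < tol
  }, logical(1))
  off_seam <- vapply(seq_len(nrow(lat$nodes)), function(i) {
    arc_position(sp3, c(lat$nodes[i, ], 0), closed = FALSE)$dist > 0.5
  }, logical(1))
  rows <- list()
  tabbed <- if (is.null(design$tabs)) integer(0) else design$tabs$edge
  for (k in seq_len(nrow(lat$edges))) {
    if (lat$kind[k] != "hex") next
    if (k %in% tabbed) next
    i <- lat$edges[k, 1]; j <- lat$edges[k, 2]
    if (!xor(on_seam[i], on_seam[j])) next
    if (on_seam[j]) { tmp <- i; i <- j; j <- tmp }
    if (!off_seam[j]) next                     # edge lies along the seam
    ap <- arc_position(sp3, c(lat$nodes[i, ], 0), closed = FALSE)
    # must be directed toward the seam, not parallel to it
    sL <- polyline_lengths(seam$poly)
    p_a <- polyline_point_at(seam$poly, max(ap$s - 1, 0))[1, ]
    p_b <- polyline_point_at(seam$poly, min(ap$s + 1, sL[length(sL)]))[1, ]
    tangent <- normalize2(p_b - p_a)
    edir <- normalize2(lat$nodes[j, ] - lat$nodes[i, ])
    if (abs(sum(tangent * edir)) > 0.95) next
    # arc position in the shared parameterization
    elen <- sqrt(sum((lat$nodes[i, ] - lat$nodes[j, ])^2))
    if (elen < 3) next                         # trimming stub, not a beam
    s_shared <- seam_s_at(seam, ap$s)
    rows[[length(rows) + 1]] <- data.frame(
      edge = k, seam_node = i, free_node = j, s = s_shared,
      len = elen)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

# convert a 2D arc position along seam$poly into the shared parameter s
seam_s_at <- function(seam, s2d) {
  cl <- polyline_lengths(seam$poly)
  stats::approx(cl, seam$s, xout = min(max(s2d, 0), cl[length(cl)]))$y
}

# inverse: 2D point on this panel's seam at shared parameter s
seam_point_at <- function(seam, s) {
  cl <- polyline_lengths(seam$poly)
  s2d <- stats::approx(seam$s, cl, xout = min(max(s, min(seam$s)), max(seam$s)))$y
  polyline_point_at(seam$poly, s2d)[1, ]
}

make_tab <- function(design, seam_name, cand, s_star, ext, id, merged,
                     tab_width, reach) {
  seam <- design$seams[[seam_name]]
  lat <- design$lattice
  base <- lat$nodes[cand$free_node, ]
  new_seam_pt <- seam_point_at(seam, s_star)
  dirv <- new_seam_pt - base
  L <- sqrt(sum(dirv^2))
  dirv <- dirv / max(L, 1e-12)
  # refuse tabs that would slant more than 60 degrees away from the
  # beam they replace (they would run along the seam and overlap
  # neighbouring beams); the original beam is kept instead
  dir0 <- lat$nodes[cand$seam_node, ] - base
  dir0 <- dir0 / max(sqrt(sum(dir0^2)), 1e-12)
  if (sum(dirv * dir0) < cos(pi / 3)) return(NULL)
  near_grommet <- FALSE
  if (nrow(design$grommets)) {
    dg <- vapply(seq_len(nrow(design$grommets)), function(i) {
      arc_position(cbind(seam$poly, 0),
                   c(design$grommets$x[i], design$grommets$y[i], 0),
                   closed = FALSE)$dist
    }, numeric(1))
    if (any(dg <= lat$hex_edge)) {
      gi <- which(dg <= lat$hex_edge)
      dstar <- sqrt((design$grommets$x[gi] - new_seam_pt[1])^2 +
                    (design$grommets$y[gi] - new_seam_pt[2])^2)
      if (any(dstar <= lat$hex_edge)) {
        near_grommet <- TRUE
        ext <- ext + lat$hex_edge   # extend to the next lattice node
      }
    }
  }
  tip <- new_seam_pt + dirv * ext
  data.frame(pair_id = id, base_x = base[1], base_y = base[2],
             seam_x = new_seam_pt[1], seam_y = new_seam_pt[2],
             tip_x = tip[1], tip_y = tip[2], width = tab_width,
             merged = merged, near_grommet = near_grommet,
             edge = cand$edge, stringsAsFactors = FALSE)
}

#' Render a panel design as SVG (visual QA)
#'
#' @param design A [panel_design_2d] with lattice (and tabs).
#' @param path Output `.svg` path.
#' @return `path`, invisibly.
#' @export
panel_design_svg <- function(design, path) {
  bb <- apply(design$outline, 2, range)
  pad <- 10
  w <- diff(bb[, 1]) + 2 * pad; h <- diff(bb[, 2]) + 2 * pad
  tx <- function(x) x - bb[1, 1] + pad
  ty <- function(y) bb[2, 2] - y + pad
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.1f %.1f">', w, h, w, h))
  pts <- paste(sprintf("%.2f,%.2f", tx(design$outline[, 1]), ty(design$outline[, 2])), collapse = " ")
  lines <- c(lines, sprintf('<polygon points="%s" fill="none" stroke="black" stroke-width="0.85"/>', pts))
  if (!is.null(design$lattice)) {
    lat <- design$lattice
    for (k in seq_len(nrow(lat$edges))) {
      p <- lat$nodes[lat$edges[k, 1], ]; q <- lat$nodes[lat$edges[k, 2], ]
      lines <- c(lines, sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="black" stroke-width="%.2f"/>',
                                tx(p[1]), ty(p[2]), tx(q[1]), ty(q[2]), lat$width[k]))
    }
  }
  if (!is.null(design$tabs) && nrow(design$tabs)) {
    t <- design$tabs
    lines <- c(lines, sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="red" stroke-width="%.2f"/>',
                              tx(t$base_x), ty(t$base_y), tx(t$tip_x), ty(t$tip_y), t$width))
  }
  if (nrow(design$grommets)) {
    g <- design$grommets
    lines <- c(lines, sprintf('<circle cx="%.2f" cy="%.2f" r="5" fill="none" stroke="blue" stroke-width="0.5"/>',
                              tx(g$x), ty(g$y)))
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}


# Weld graph nodes closer than tol (first occurrence wins), dropping
# collapsed and duplicated edges.  Beams are at least ~1 mm apart
# everywhere a weld below 0.5 mm could apply, so geometry moves by less
# than the beam width.
weld_graph_nodes <- function(nodes, edges, width, kind, tol = 0.3) {
  n <- nrow(nodes)
  map <- seq_len(n)
  ordx <- order(nodes[, 1])
  for (a in seq_len(n - 1)) {
    i <- ordx[a]
    if (map[i] != i) next
    b <- a + 1
    while (b <= n && nodes[ordx[b], 1] - nodes[i, 1] <= tol) {
      j <- ordx[b]
      if (map[j] == j && j != i &&
          sum((nodes[i, ] - nodes[j, ])^2) <= tol^2) {
        map[max(i, j)] <- min(i, j)
      }
      b <- b + 1
    }
  }
  # path-compress
  for (i in seq_len(n)) {
    while (map[map[i]] != map[i]) map[i] <- map[map[i]]
  }
  keep <- sort(unique(map))
  remap <- match(map, keep)
  nodes2 <- nodes[keep, , drop = FALSE]
  e2 <- matrix(remap[edges], ncol = 2)
  ok <- e2[, 1] != e2[, 2]
  e2 <- e2[ok, , drop = FALSE]; width <- width[ok]; kind <- kind[ok]
  dup <- duplicated(paste(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2])))
  e2 <- e2[!dup, , drop = FALSE]; width <- width[!dup]; kind <- kind[!dup]
  used <- sort(unique(as.vector(e2)))
  remap2 <- match(seq_len(nrow(nodes2)), used)
  list(nodes = nodes2[used, , drop = FALSE],
       edges = matrix(remap2[e2], ncol = 2), width = width, kind = kind)
}
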