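# Extruding 2D panel designs into watertight printable solids.
#
# A panel design is a graph of straight beams (lattice, outline ring,
# welding tabs) with per-beam widths.  The union of the beam strokes is
# built exactly: each beam contributes a quad bounded by its two side
# lines, trimmed at every node by miter/bevel joins against the angular
# neighbours; the left-over wedge at each node is a small "join" polygon.
# These polygons tile the stroked region without overlap, so caps
# (z = 0 and z = thickness) triangulate exactly and walls are emitted
# along every polygon edge not shared by two polygons.  Volume is exact:
# sum(polygon areas) * thickness.

#' Solid panel: extruded design plus merged features
#'
#' @param mesh Watertight [trimesh] (possibly several closed components).
#' @param design The [panel_design_2d] it was extruded from.
#' @param thickness Extrusion thickness (mm).
#' @param manifest data.frame of merged features.
#' @return Object of class `solid_panel`.
#' @export
solid_panel <- function(mesh, design, thickness, manifest = NULL) {
  if (is.null(manifest))
    manifest <- data.frame(feature = character(), id = character(),
                           x = numeric(), y = numeric(), rotation = numeric())
  structure(list(mesh = mesh, design = design, thickness = thickness,
                 manifest = manifest), class = "solid_panel")
}

#' @export
print.solid_panel <- function(x, ...) {
  cat(sprintf("<solid_panel:%s> %d triangles, volume %.0f mm^3, %d features\n",
              x$design$role, nrow(x$mesh$faces), mesh_volume(x$mesh),
              nrow(x$manifest)))
  invisible(x)
}

# -- 2D stroked-graph machinery ---------------------------------------------

# Fold welding tabs into the lattice graph: each tab replaces its
# trimmed lattice edge by a wider beam from its base node to its
# extended tip.  Idempotent (tabs are cleared afterwards).
bake_tabs <- function(design) {
  if (is.null(design$tabs) || !nrow(design$tabs)) return(design)
  lat <- design$lattice
  nodes <- lat$nodes; edges <- lat$edges; widths <- lat$width; kind <- lat$kind
  drop_e <- rep(FALSE, nrow(edges))
  drop_e[design$tabs$edge] <- TRUE
  append_edge <- function(a, b, w, kd) {
    edges <<- rbind(edges, c(a, b))
    widths <<- c(widths, w)
    kind <<- c(kind, kd)
    drop_e <<- c(drop_e, FALSE)
  }
  # insert a point as a node on the outline ring, splitting the segment
  # that contains it (tab beams must meet the ring at a node, never
  # cross it mid-segment)
  ring_insert <- function(p) {
    d2n <- (nodes[, 1] - p[1])^2 + (nodes[, 2] - p[2])^2
    if (min(d2n) < 0.25) return(which.min(d2n))   # snap within 0.5 mm
    best <- NULL; bestd <- Inf
    for (k in which(kind == "outline" & !drop_e)) {
      a <- nodes[edges[k, 1], ]; b <- nodes[edges[k, 2], ]
      ab <- b - a
      t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
      t <- min(max(t, 0), 1)
      d2 <- sum((a + t * ab - p)^2)
      if (d2 < bestd) { bestd <- d2; best <- k }
    }
    nodes <<- rbind(nodes, p)
    pid <- nrow(nodes)
    if (!is.null(best) && bestd < 1e-4) {
      a <- edges[best, 1]; b <- edges[best, 2]
      drop_e[best] <<- TRUE
      append_edge(a, pid, widths[best], "outline")
      append_edge(pid, b, widths[best], "outline")
    }
    pid
  }
  for (k in seq_len(nrow(design$tabs))) {
    tb <- design$tabs[k, ]
    base_id <- which.min((nodes[, 1] - tb$base_x)^2 + (nodes[, 2] - tb$base_y)^2)
    seam_id <- ring_insert(c(tb$seam_x, tb$seam_y))
    nodes <- rbind(nodes, c(tb$tip_x, tb$tip_y))
    tip_id <- nrow(nodes)
    append_edge(base_id, seam_id, tb$width, "tab")
    append_edge(seam_id, tip_id, tb$width, "tab")
  }
  edges <- edges[!drop_e, , drop = FALSE]
  widths <- widths[!drop_e]
  kind <- kind[!drop_e]
  g <- weld_graph_nodes(nodes, edges, widths, kind, tol = 0.8)
  design$lattice <- list(nodes = g$nodes, edges = g$edges, width = g$width,
                         kind = g$kind, hex_edge = lat$hex_edge)
  design$tabs_baked <- design$tabs
  design$tabs <- NULL
  design
}

# Connected components of a beam graph (per node, edge-induced)
graph_components <- function(lat) {
  n <- nrow(lat$nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(lat$edges)))
    parent[find(lat$edges[k, 1])] <- find(lat$edges[k, 2])
  vapply(seq_len(n), find, integer(1))
}

# Remove tiny disconnected fragments (clipped slivers around a punched
# hole); errors remain the caller's job via graph_connected().
drop_minor_components <- function(lat, max_minor = 0.02) {
  comp <- graph_components(lat)
  len <- sqrt(rowSums((lat$nodes[lat$edges[, 1], , drop = FALSE] -
                       lat$nodes[lat$edges[, 2], , drop = FALSE])^2))
  ecomp <- comp[lat$edges[, 1]]
  tot <- rowsum(len, ecomp)
  main <- as.integer(rownames(tot))[which.max(tot[, 1])]
  minor <- as.integer(rownames(tot))[tot[, 1] < max_minor * sum(tot)]
  minor <- setdiff(minor, main)
  keep <- !(ecomp %in% minor)
  lat$edges <- lat$edges[keep, , drop = FALSE]
  lat$width <- lat$width[keep]
  lat$kind <- lat$kind[keep]
  lat
}

# Is the beam graph one connected component?  (Nodes without edges are
# ignored; isolated tab tips etc. count through their beams.)
graph_connected <- function(lat) {
  n <- nrow(lat$nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(lat$edges)))
    parent[find(lat$edges[k, 1])] <- find(lat$edges[k, 2])
  used <- unique(as.vector(lat$edges))
  length(unique(vapply(used, find, integer(1)))) == 1
}

# Full beam graph of a design (tabs folded in).  Two beams leaving one
# node within ~4 degrees of each other would overlap along their whole
# length and degenerate the miter construction; the lower-priority one
# is dropped (tab < hex < outline; ties: the shorter).
design_graph <- function(design) {
  design <- bake_tabs(design)
  lat <- design$lattice
  if (is.null(lat)) stop("design has no lattice; run hex_fill() first")
  nodes <- lat$nodes
  edges <- lat$edges
  widths <- lat$width
  kind <- lat$kind
  len <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                       nodes[edges[, 2], , drop = FALSE])^2))
  ok <- len > 1          # sub-millimeter stubs degenerate the joins
  edges <- edges[ok, , drop = FALSE]; widths <- widths[ok]
  kind <- kind[ok]; len <- len[ok]
  prio <- c(tab = 1, hex = 2, ring = 2, holder = 2, outline = 3)[kind]
  prio[is.na(prio)] <- 2
  for (pass in 1:3) {
    drop <- rep(FALSE, nrow(edges))
    inc <- vector("list", nrow(nodes))
    for (e in seq_len(nrow(edges))) {
      if (drop[e]) next
      inc[[edges[e, 1]]] <- c(inc[[edges[e, 1]]], e)
      inc[[edges[e, 2]]] <- c(inc[[edges[e, 2]]], e)
    }
    for (v in seq_len(nrow(nodes))) {
      ie <- inc[[v]]
      if (length(ie) < 2) next
      other <- ifelse(edges[ie, 1] == v, edges[ie, 2], edges[ie, 1])
      dd <- nodes[other, , drop = FALSE] - matrix(nodes[v, ], length(ie), 2, byrow = TRUE)
      ang <- atan2(dd[, 2], dd[, 1])
      for (a in seq_along(ie)) {
        for (b in seq_along(ie)) {
          if (a >= b || drop[ie[a]] || drop[ie[b]]) next
          gap <- abs(ang[a] - ang[b])
          gap <- min(gap, 2 * pi - gap)
          if (gap < 0.07) {
            pick <- if (prio[ie[a]] != prio[ie[b]]) {
              if (prio[ie[a]] < prio[ie[b]]) ie[a] else ie[b]
            } else if (len[ie[a]] <= len[ie[b]]) ie[a] else ie[b]
            drop[pick] <- TRUE
          }
        }
      }
    }
    if (!any(drop)) break
    edges <- edges[!drop, , drop = FALSE]
    widths <- widths[!drop]; kind <- kind[!drop]
    len <- len[!drop]; prio <- prio[!drop]
  }
  list(nodes = nodes, edges = edges, widths = widths)
}

# Exact union of beam strokes as non-overlapping polygons.
# Returns list(points = pool of 2D points, polys = list of integer id
# vectors, ccw).
stroke_graph_polygons <- function(graph, miter_limit_factor = 4) {
  nodes <- graph$nodes; edges <- graph$edges; widths <- graph$widths
  ne <- nrow(edges)
  pool <- new.env(hash = TRUE)
  pts <- list()
  # corner points are pooled PER NODE: the only legitimate coincidences
  # (beam-end chords shared with the node join polygon) happen at one
  # node; pooling globally would weld coincidental contacts of nearly
  # parallel beams into non-manifold edges
  pid <- function(v, p) {
    k <- paste(v, round(p[1] * 1e7), round(p[2] * 1e7))
    id <- pool[[k]]
    if (is.null(id)) {
      pts[[length(pts) + 1]] <<- p
      id <- length(pts)
      pool[[k]] <- id
    }
    id
  }
  # incidence: for each node, the incident (edge, other-node) sorted ccw
  inc <- vector("list", nrow(nodes))
  for (e in seq_len(ne)) {
    inc[[edges[e, 1]]] <- c(inc[[edges[e, 1]]], e)
    inc[[edges[e, 2]]] <- c(inc[[edges[e, 2]]], e)
  }
  # corner ids per (edge, node, flank): flank 1 = cw, 2 = ccw
  Ccw <- matrix(NA_integer_, ne, 2)    # [edge, which end (1 = at edges[,1])]
  Cccw <- matrix(NA_integer_, ne, 2)
  node_polys <- list()
  for (v in seq_len(nrow(nodes))) {
    ie <- inc[[v]]
    if (is.null(ie)) next
    pv <- nodes[v, ]
    other <- ifelse(edges[ie, 1] == v, edges[ie, 2], edges[ie, 1])
    dirs <- nodes[other, , drop = FALSE] - matrix(pv, length(ie), 2, byrow = TRUE)
    dl <- sqrt(rowSums(dirs^2))
    dirs <- dirs / dl
    angs <- atan2(dirs[, 2], dirs[, 1])
    ord <- order(angs, ie)
    ie <- ie[ord]; dirs <- dirs[ord, , drop = FALSE]; dl <- dl[ord]
    d <- length(ie)
    # for each ccw-consecutive pair (e_i, e_next), compute join corners
    cor_ccw_of <- vector("list", d)  # ccw-flank corner point(s) of edge i
    cor_cw_of <- vector("list", d)
    for (i in seq_len(d)) {
      jn <- i %% d + 1
      ei <- ie[i]; ej <- ie[jn]
      di <- dirs[i, ]; dj <- dirs[jn, ]
      wi <- widths[ei] / 2; wj <- widths[ej] / 2
      ni <- c(-di[2], di[1])      # ccw-side normal of e_i
      nj <- c(dj[2], -dj[1])      # cw-side normal of e_j
      P <- pv + wi * ni
      Q <- pv + wj * nj
      use_bevel <- TRUE
      if (!(d == 1 && i == jn)) {
        den <- di[1] * (-dj[2]) - di[2] * (-dj[1])
        if (abs(den) > 1e-12) {
          rhs <- Q - P
          t <- (rhs[1] * (-dj[2]) - rhs[2] * (-dj[1])) / den
          s <- (di[1] * rhs[2] - di[2] * rhs[1]) / den
          lim_i <- min(miter_limit_factor * wi * 2, dl[i] * 0.45)
          lim_j <- min(miter_limit_factor * wj * 2, dl[jn] * 0.45)
          # joins between beams of different widths can need a slightly
          # negative parameter on the wider side (the narrow beam
          # emerges from within the wide stroke)
          neg <- 2 * abs(wi - wj)   # zero for equal widths
          if (t >= -neg - 1e-9 && s >= -neg - 1e-9 && t <= lim_i && s <= lim_j) {
            M <- P + t * di
            cor_ccw_of[[i]] <- c(cor_ccw_of[[i]], pid(v, M))
            cor_cw_of[[jn]] <- c(pid(v, M), cor_cw_of[[jn]])
            use_bevel <- FALSE
          }
        }
      }
      if (use_bevel) {
        # bevel caps retract by the partner's half width so a beam
        # meeting its neighbour at a shallow angle butts against it
        # instead of plunging through (which would double-count volume);
        # a free end (d == 1) keeps its exact flat cap
        ri <- if (d == 1) 0 else min(wj, dl[i] * 0.45)
        rj <- if (d == 1) 0 else min(wi, dl[jn] * 0.45)
        cor_ccw_of[[i]] <- c(cor_ccw_of[[i]], pid(v, P + ri * di))
        cor_cw_of[[jn]] <- c(pid(v, Q + rj * dj), cor_cw_of[[jn]])
      }
    }
    # store beam-end corners and build the node join polygon
    ring <- integer(0)
    for (i in seq_len(d)) {
      e <- ie[i]
      endk <- if (edges[e, 1] == v) 1L else 2L
      Ccw[e, endk] <- cor_cw_of[[i]][1]
      Cccw[e, endk] <- cor_ccw_of[[i]][1]
      ring <- c(ring, cor_cw_of[[i]][1], cor_ccw_of[[i]][1])
    }
    ring <- ring[!duplicated(ring)]
    if (length(ring) >= 3) {
      node_polys[[length(node_polys) + 1]] <- list(ids = ring, center = pv)
    }
  }
  beam_polys <- vector("list", ne)
  for (e in seq_len(ne)) {
    quad <- c(Ccw[e, 1], Cccw[e, 2], Ccw[e, 2], Cccw[e, 1])
    quad <- quad[!duplicated(quad)]
    if (length(quad) >= 3) beam_polys[[e]] <- list(ids = quad, center = NULL)
  }
  polys <- c(beam_polys[!vapply(beam_polys, is.null, logical(1))], node_polys)
  P <- do.call(rbind, pts)
  # enforce ccw orientation, drop degenerate
  out <- list()
  for (pg in polys) {
    a <- polygon_area(P[pg$ids, , drop = FALSE])
    if (abs(a) < 1e-12) next
    if (a < 0) pg$ids <- rev(pg$ids)
    out[[length(out) + 1]] <- pg
  }
  list(points = P, polys = out)
}

# Extrude the union polygons into a solid between z = 0 and z = t.
# Each polygon becomes its own closed prism (caps + all walls), so the
# result is watertight by construction: neighbouring prisms touch along
# exactly coincident internal walls, which slicers treat as a plain
# union of solids.  The total volume is the exact tiling sum,
# sum(polygon areas) * thickness.
extrude_polygons <- function(pp, thickness) {
  P <- pp$points
  Vs <- list(); tris <- list()
  off <- 0L
  for (pg in pp$polys) {
    ids <- pg$ids
    m <- length(ids)
    ctr <- if (is.null(pg$center)) colMeans(P[ids, , drop = FALSE]) else pg$center
    # local vertices: 1..m bottom ring, m+1..2m top ring, 2m+1 bottom
    # center, 2m+2 top center
    Vs[[length(Vs) + 1]] <- rbind(cbind(P[ids, , drop = FALSE], 0),
                                  cbind(P[ids, , drop = FALSE], thickness),
                                  c(ctr, 0), c(ctr, thickness))
    cb <- off + 2L * m + 1L; ct <- cb + 1L
    for (i in seq_len(m)) {
      j <- i %% m + 1
      tris[[length(tris) + 1]] <- c(ct, off + m + i, off + m + j)   # top cap
      tris[[length(tris) + 1]] <- c(cb, off + j, off + i)           # bottom cap
      tris[[length(tris) + 1]] <- c(off + i, off + j, off + m + j)  # wall
      tris[[length(tris) + 1]] <- c(off + i, off + m + j, off + m + i)
    }
    off <- off + 2L * m + 2L
  }
  trimesh(do.call(rbind, Vs), do.call(rbind, tris))
}

#' Extrude a panel design into a printable solid
#'
#' Every beam, outline segment and welding tab is rendered as a
#' rectangular-section prism (its design width, height = `thickness`)
#' and the exact union is extruded into one watertight solid occupying
#' `0 <= Z <= thickness`.
#'
#' @param design A [panel_design_2d] with lattice (and optionally tabs).
#' @param thickness Extrusion thickness in mm (default 0.9).
#' @return A [solid_panel].
#' @export
extrude_panel <- function(design, thickness = 0.9) {
  if (thickness <= 0) stop("thickness must be positive")
  design <- bake_tabs(design)
  g <- design_graph(design)
  pp <- stroke_graph_polygons(g)
  mesh <- extrude_polygons(pp, thickness)
  if (!is_watertight(mesh))
    stop("extrusion produced a non-watertight solid (degenerate joins)")
  sp <- solid_panel(mesh, design, thickness)
  attr(sp, "flat_area") <- sum(vapply(pp$polys, function(pg)
    polygon_area(pp$points[pg$ids, , drop = FALSE]), numeric(1)))
  sp
}

#' Generate a default annular grommet solid
#'
#' Watertight ring used when no vendor grommet library is available;
#' local origin at the ring center on its base plane.
#'
#' @param inner_diameter,outer_diameter Ring diameters, mm
#'   (0 < inner < outer).
#' @param height Ring height, mm.
#' @param segments Tessellation (default 48).
#' @return A [trimesh].
#' @export
make_default_grommet <- function(inner_diameter = 12, outer_diameter = 18,
                                 height = 6, segments = 48) {
  ri <- inner_diameter / 2; ro <- outer_diameter / 2
  if (ri <= 0 || ro <= ri) stop("need 0 < inner_diameter < outer_diameter")
  th <- seq(0, 2 * pi, length.out = segments + 1)[-(segments + 1)]
  ci <- cbind(ri * cos(th), ri * sin(th))
  co <- cbind(ro * cos(th), ro * sin(th))
  V <- rbind(cbind(co, 0), cbind(ci, 0), cbind(co, height), cbind(ci, height))
  n <- segments
  io0 <- 0L; ii0 <- n; io1 <- 2L * n; ii1 <- 3L * n
  f <- list()
  for (k in seq_len(n)) {
    k2 <- k %% n + 1
    # outer wall (outward)
    f[[length(f) + 1]] <- c(io0 + k, io0 + k2, io1 + k2)
    f[[length(f) + 1]] <- c(io0 + k, io1 + k2, io1 + k)
    # inner wall (faces the hole)
    f[[length(f) + 1]] <- c(ii0 + k2, ii0 + k, ii1 + k)
    f[[length(f) + 1]] <- c(ii0 + k2, ii1 + k, ii1 + k2)
    # top annulus (up)
    f[[length(f) + 1]] <- c(io1 + k, io1 + k2, ii1 + k2)
    f[[length(f) + 1]] <- c(io1 + k, ii1 + k2, ii1 + k)
    # bottom annulus (down)
    f[[length(f) + 1]] <- c(io0 + k2, io0 + k, ii0 + k)
    f[[length(f) + 1]] <- c(io0 + k2, ii0 + k, ii0 + k2)
  }
  trimesh(V, do.call(rbind, f))
}

#' Grommet library directory
#'
#' Directory layout: one folder per grommet identifier (the `"#name"`
#' token), each containing `grommet.stl`.  Loaded solids are cached.
#'
#' @param dir Library directory path.
#' @return Object of class `grommet_library`.
#' @export
grommet_library <- function(dir) {
  structure(list(dir = dir, cache = new.env()), class = "grommet_library")
}

#' Create a grommet library with the default generated grommet
#' @param dir Directory to create.
#' @param ids Character vector of grommet ids to populate (`"#..."`).
#' @return A [grommet_library].
#' @export
make_default_grommet_library <- function(dir, ids = "#default") {
  for (id in ids) {
    d <- file.path(dir, id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_stl(make_default_grommet(), file.path(d, "grommet.stl"))
  }
  grommet_library(dir)
}

load_grommet <- function(library, id) {
  hit <- library$cache[[id]]
  if (!is.null(hit)) return(hit)
  path <- file.path(library$dir, id, "grommet.stl")
  if (!file.exists(path))
    stop(errorCondition(sprintf("grommet id '%s' not found in library %s", id, library$dir),
                        grommet_id = id,
                        class = c("capgen_library_error", "error", "condition")))
  m <- read_stl(path)
  if (!is_watertight(m))
    warning(sprintf("grommet '%s' is not watertight", id))
  library$cache[[id]] <- m
  m
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Merge grommet solids onto a panel at their 2D design coordinates
#'
#' Each grommet is rotated about +Z by its placement rotation, translated
#' so its base plane sits flush on the panel's top surface
#' (Z = thickness), and added to the solid (as a touching closed
#' component).  The manifest records every placement.
#'
#' @param solid A [solid_panel].
#' @param placements data.frame with `x`, `y`, `rotation`, `grommet`
#'   (id), `name`; defaults to the design's grommets.
#' @param library A [grommet_library].
#' @return Updated [solid_panel].
#' @export
place_grommets <- function(solid, placements = NULL, library) {
  if (is.null(placements)) placements <- solid$design$grommets
  if (!nrow(placements)) return(solid)
  mesh <- solid$mesh
  man <- solid$manifest
  for (k in seq_len(nrow(placements))) {
    pl <- placements[k, ]
    g <- load_grommet(library, pl$grommet)
    gv <- g$vertices %*% t(rot_z(pl$rotation))
    gv <- sweep(gv, 2, c(pl$x, pl$y, solid$thickness), `+`)
    mesh <- mesh_union_components(mesh, trimesh(gv, g$faces))
    man <- rbind(man, data.frame(feature = "grommet", id = pl$grommet,
                                 x = pl$x, y = pl$y, rotation = pl$rotation))
  }
  solid$mesh <- mesh
  solid$manifest <- man
  solid
}

# stadium (discorectangle) polygon: length L along unit axis u, width w,
# centered at c
stadium_polygon <- function(center, axis, length, width, n_arc = 16) {
  u <- axis / sqrt(sum(axis^2))
  v <- c(-u[2], u[1])
  r <- width / 2
  h <- (length - width) / 2   # half-length of the straight section
  if (h < 0) stop("stadium length must exceed width")
  a1 <- center + h * u
  a2 <- center - h * u
  base_ang <- atan2(u[2], u[1])
  th1 <- base_ang - pi / 2 + seq(0, pi, length.out = n_arc)
  th2 <- base_ang + pi / 2 + seq(0, pi, length.out = n_arc)
  rbind(t(vapply(th1, function(a) a1 + r * c(cos(a), sin(a)), numeric(2))),
        t(vapply(th2, function(a) a2 + r * c(cos(a), sin(a)), numeric(2))))
}

#' Stamp a slanted ear slit out of a side panel
#'
#' A stadium-shaped hole, slanted backward by `slant_deg`, centered
#' `offset_up` mm up from the flattened pre-auricular (LPA/RPA) point,
#' is cut out of the lattice; a reinforcing outline ring is placed
#' around it and every cut beam is reconnected to the ring.  The panel
#' is re-extruded, so it stays watertight and connected.
#'
#' @param solid A [solid_panel] of a side panel.
#' @param ear_point 2D point: the flattened LPA/RPA (or its closest
#'   boundary proxy).
#' @param offset_up mm above `ear_point` for the slit center (default 15).
#' @param slit_length,slit_width Stadium dimensions, mm.
#' @param slant_deg Backward slant of the slit axis (default 20).
#' @return Updated [solid_panel].
#' @export
add_ear_slit <- function(solid, ear_point, offset_up = 15, slit_length = 40,
                         slit_width = 14, slant_deg = 20) {
  design <- solid$design
  if (!design$role %in% c("left", "right"))
    stop("ear slits only apply to side panels")
  center <- c(ear_point[1], ear_point[2] + offset_up)
  a <- slant_deg * pi / 180
  axis <- c(-sin(a), cos(a))            # backward slant: top leans to -x
  poly <- stadium_polygon(center, axis, slit_length, slit_width)
  design2 <- punch_hole(bake_tabs(design), poly)
  design2$lattice <- drop_minor_components(design2$lattice, max_minor = 0.02)
  if (!graph_connected(design2$lattice))
    stop("ear slit severs the panel into multiple components")
  solid2 <- extrude_panel(design2, solid$thickness)
  solid2$manifest <- rbind(solid$manifest,
                           data.frame(feature = "ear-slit", id = "stadium",
                                      x = center[1], y = center[2],
                                      rotation = slant_deg))
  attr(solid2, "hole_area") <- abs(polygon_area(poly))
  solid2
}

# Remove the part of the lattice inside `poly` and add `poly` itself as
# a reinforcing ring of beams; cut beams are reconnected at the ring.
punch_hole <- function(design, poly, ring_width = NULL) {
  lat <- design$lattice
  if (is.null(ring_width)) ring_width <- max(lat$width)
  nodes <- lat$nodes; edges <- lat$edges; widths <- lat$width; kind <- lat$kind
  inside <- points_in_polygon(nodes, poly, tol = 1e-9)
  new_edges <- list(); new_w <- numeric(0); new_k <- character(0)
  ring_pts <- list()
  add_node <- function(p) { nodes <<- rbind(nodes, p); nrow(nodes) }
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    if (inside[i] && inside[j]) next
    if (!inside[i] && !inside[j]) {
      ts <- segment_polygon_crossings(nodes[i, ], nodes[j, ], poly)
      ts <- ts[ts > 1e-9 & ts < 1 - 1e-9]
      if (length(ts) >= 2) {
        # passes through the hole: keep the two outside stubs
        p1 <- nodes[i, ] + ts[1] * (nodes[j, ] - nodes[i, ])
        p2 <- nodes[i, ] + ts[length(ts)] * (nodes[j, ] - nodes[i, ])
        id1 <- add_node(p1); id2 <- add_node(p2)
        ring_pts <- c(ring_pts, id1, id2)
        new_edges <- c(new_edges, list(c(i, id1)), list(c(id2, j)))
        new_w <- c(new_w, widths[k], widths[k]); new_k <- c(new_k, kind[k], kind[k])
      } else {
        new_edges <- c(new_edges, list(c(i, j)))
        new_w <- c(new_w, widths[k]); new_k <- c(new_k, kind[k])
      }
    } else {
      if (inside[i]) { tmp <- i; i <- j; j <- tmp }
      ts <- segment_polygon_crossings(nodes[i, ], nodes[j, ], poly)
      ts <- ts[ts > 1e-9 & ts < 1 - 1e-9]
      if (!length(ts)) next
      pc <- nodes[i, ] + ts[1] * (nodes[j, ] - nodes[i, ])
      if (sqrt(sum((pc - nodes[i, ])^2)) < 0.8) next   # drop tiny stub
      idc <- add_node(pc)
      ring_pts <- c(ring_pts, idc)
      new_edges <- c(new_edges, list(c(i, idc)))
      new_w <- c(new_w, widths[k]); new_k <- c(new_k, kind[k])
    }
  }
  # reinforcing ring: polygon vertices + reconnection points in arc order
  ring_ids <- vapply(seq_len(nrow(poly)), function(i) add_node(poly[i, ]), integer(1))
  op <- rbind(poly, poly[1, , drop = FALSE])
  ring_s <- polyline_lengths(op)[seq_len(nrow(poly))]
  cross_s <- vapply(unlist(ring_pts), function(id)
    arc_position(cbind(op, 0), c(nodes[id, ], 0), closed = FALSE)$s, numeric(1))
  allr <- c(ring_ids, unlist(ring_pts))
  alls <- c(ring_s, cross_s)
  ordr <- order(alls, allr)
  seqr <- allr[ordr]
  for (k in seq_along(seqr)) {
    i <- seqr[k]; j <- seqr[k %% length(seqr) + 1]
    if (i == j) next
    new_edges <- c(new_edges, list(c(i, j)))
    new_w <- c(new_w, ring_width); new_k <- c(new_k, "ring")
  }
  em <- do.call(rbind, new_edges)
  # weld coincident nodes
  key <- paste(round(nodes[, 1] * 1e7), round(nodes[, 2] * 1e7))
  first <- match(key, key)
  keepn <- sort(unique(first))
  remap <- match(first, keepn)
  nodes2 <- nodes[keepn, , drop = FALSE]
  em2 <- matrix(remap[em], ncol = 2)
  ok <- em2[, 1] != em2[, 2]
  em2 <- em2[ok, , drop = FALSE]; new_w <- new_w[ok]; new_k <- new_k[ok]
  dup <- duplicated(paste(pmin(em2[, 1], em2[, 2]), pmax(em2[, 1], em2[, 2])))
  em2 <- em2[!dup, , drop = FALSE]; new_w <- new_w[!dup]; new_k <- new_k[!dup]
  used <- sort(unique(as.vector(em2)))
  remap2 <- match(seq_len(nrow(nodes2)), used)
  design$lattice <- list(nodes = nodes2[used, , drop = FALSE],
                         edges = matrix(remap2[em2], ncol = 2),
                         width = new_w, kind = new_k, hex_edge = lat$hex_edge)
  # grommets inside the hole would be floating; refuse
  if (nrow(design$grommets)) {
    gin <- points_in_polygon(as.matrix(design$grommets[, c("x", "y")]), poly)
    if (any(gin)) stop("hole would swallow grommet(s): ",
                       paste(design$grommets$name[gin], collapse = ", "))
  }
  design
}

#' Add chin/neck strap holders to a side panel
#'
#' Slotted-loop holders (a rectangular ring of beams with an open slot)
#' are attached at configured positions along the panel's lower template
#' outline: by default one anterior (chin strap) and one posterior
#' (neck strap) of the ear.
#'
#' @param solid A [solid_panel] of a side panel.
#' @param fractions Positions as fractions of the template outline arc
#'   (0 = front end, 1 = back end).
#' @param loop_w,loop_h Outer dimensions of the holder loop (mm).
#' @param beam_w Holder beam width (mm).
#' @return Updated [solid_panel].
#' @export
add_strap_holders <- function(solid, fractions = c(0.12, 0.88),
                              loop_w = 18, loop_h = 12, beam_w = 2.5) {
  design <- solid$design
  if (!design$role %in% c("left", "right"))
    stop("strap holders only apply to side panels")
  tmpl_edges <- which(design$outline_labels == "template")
  if (!length(tmpl_edges)) stop("panel outline has no template portion for strap holders")
  n <- nrow(design$outline)
  # template polyline in outline order
  runs <- split(tmpl_edges, cumsum(c(1, diff(tmpl_edges) != 1)))
  run <- runs[[which.max(lengths(runs))]]
  vidx <- c(run, run[length(run)] %% n + 1)
  vidx <- ifelse(vidx > n, vidx - n, vidx)
  tp <- design$outline[vidx, , drop = FALSE]
  L <- polyline_lengths(tp)
  total <- L[length(L)]
  lat <- design$lattice
  nodes <- lat$nodes; edges <- lat$edges; widths <- lat$width; kind <- lat$kind
  man <- solid$manifest
  for (fr in fractions) {
    if (fr < 0 || fr > 1) stop("strap holder position outside panel outline")
    p <- polyline_point_at(tp, fr * total)[1, ]
    # local frame: outward = away from the outline interior
    p2 <- polyline_point_at(tp, min(fr * total + 1, total))[1, ]
    tangent <- normalize2(p2 - p)
    outward <- c(tangent[2], -tangent[1])
    ctr <- colMeans(design$outline)
    if (sum((p - ctr) * outward) < 0) outward <- -outward
    cen <- p + outward * (loop_h / 2 + 1)
    ux <- tangent; uy <- outward
    corners <- rbind(cen - ux * loop_w / 2 - uy * loop_h / 2,
                     cen + ux * loop_w / 2 - uy * loop_h / 2,
                     cen + ux * loop_w / 2 + uy * loop_h / 2,
                     cen - ux * loop_w / 2 + uy * loop_h / 2)
    base <- nrow(nodes)
    nodes <- rbind(nodes, corners)
    ring <- cbind(base + 1:4, base + c(2, 3, 4, 1))
    edges <- rbind(edges, ring)
    widths <- c(widths, rep(beam_w, 4)); kind <- c(kind, rep("holder", 4))
    # connect holder to the nearest outline-ring lattice node
    d2 <- rowSums(sweep(nodes[seq_len(base), , drop = FALSE], 2, p)^2)
    near <- which.min(d2)
    att <- base + which.min(rowSums(sweep(corners, 2, nodes[near, ])^2))
    edges <- rbind(edges, c(near, att))
    widths <- c(widths, beam_w); kind <- c(kind, "holder")
    man <- rbind(man, data.frame(feature = "strap-holder", id = "loop",
                                 x = cen[1], y = cen[2], rotation = 0))
  }
  design$lattice <- list(nodes = nodes, edges = edges, width = widths,
                         kind = kind, hex_edge = lat$hex_edge)
  solid2 <- extrude_panel(design, solid$thickness)
  solid2$manifest <- man
  solid2
}

#' Validate a solid panel
#'
#' @param solid A [solid_panel] (or [trimesh]).
#' @param thickness Expected Z extent of the base lattice (optional).
#' @return Named logical vector of checks.
#' @export
validate_solid <- function(solid, thickness = NULL) {
  mesh <- if (inherits(solid, "solid_panel")) solid$mesh else solid
  checks <- c(watertight = is_watertight(mesh),
              positive_volume = mesh_volume(mesh) > 0)
  if (!is.null(thickness)) {
    zr <- range(mesh$vertices[, 3])
    checks <- c(checks, z_extent = isTRUE(all.equal(zr[1], 0)) &&
                  mesh$vertices[, 3][which.max(mesh$vertices[, 3])] >= thickness - 1e-9)
  }
  checks
}
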