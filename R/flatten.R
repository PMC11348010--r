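# Flattening curved panel surfaces to the plane by iterative gravity +
# spring relaxation.  Edges of the 3D mesh act as springs with rest
# length equal to their 3D length; a normalized gravity step (largest
# displacement 0.1 mm) pulls vertices toward Z = 0; probe-node vertices
# keep their three distances to the closest 10-5 vertices fixed.

mesh_edges_unique <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Flatten a panel surface to 2D
#'
#' @param panel A [panel_surface] (connected, oriented).
#' @param gravity_step Maximum gravity displacement per iteration (mm).
#' @param z_tol Convergence: all |Z| at or below this (mm).
#' @param spring_cap Maximum spring displacement per substep (mm).
#' @param damping Spring force damping factor.
#' @param substeps Spring substeps per gravity step.
#' @param max_iters Outer iteration bound.
#' @param area_tol Warn if the flat/3D area ratio deviates more than this.
#' @param spring_mode `"hybrid"` (default) applies full 3D spring forces
#'   while the gravity descent makes progress, then switches to planar
#'   (X-Y only) forces so the Z criterion is reached; `"planar"` and
#'   `"3d"` force either behaviour throughout.
#' @param polish_iters,polish_tol After Z convergence, continue in-plane
#'   spring relaxation (Z frozen) until the largest spring displacement
#'   falls below `polish_tol` mm or `polish_iters` steps.
#' @return Object of class `flat_mesh`: 2D vertices (`xy`, with the
#'   residual `z` kept separately), faces, provenance to panel vertices
#'   (identity), markers, per-edge rest lengths, probe couplings, and
#'   convergence diagnostics.
#' @export
flatten_panel <- function(panel, gravity_step = 0.1, z_tol = 0.1,
                          spring_cap = 0.1, damping = 0.5, substeps = 8,
                          max_iters = 50000, area_tol = 0.05,
                          spring_mode = c("hybrid", "planar", "3d"),
                          polish_iters = 50000, polish_tol = 1e-4) {
  spring_mode <- match.arg(spring_mode)
  mode_code <- c("3d" = 0L, planar = 1L, hybrid = 2L)[[spring_mode]]
  mesh <- panel$mesh
  V <- mesh$vertices
  E <- mesh_edges_unique(mesh$faces)
  rest <- sqrt(rowSums((V[E[, 1], , drop = FALSE] - V[E[, 2], , drop = FALSE])^2))
  if (any(rest <= 0)) stop("degenerate zero-length edge in panel mesh")
  # probe-node / 10-5 couplings: three closest landmark vertices in 3D
  mk <- panel$markers
  probe_ids <- mk[grepl("^optode:", names(mk))]
  lmk_ids <- mk[!grepl("^optode:", names(mk))]
  cp_node <- integer(0); cp_partner <- matrix(0L, 0, 3); cp_dist <- matrix(0, 0, 3)
  if (length(probe_ids) && length(lmk_ids) >= 3) {
    lmk_ids <- sort(unname(lmk_ids))      # ties broken by vertex index
    for (pv in probe_ids) {
      # an anchored optode embedded at its landmark IS a 10-5 vertex:
      # the flattening carries it exactly, no coupling needed (and a
      # zero-distance partner would make trilateration degenerate)
      if (pv %in% lmk_ids) next
      cand <- setdiff(lmk_ids, pv)        # an anchored optode shares its
      d <- sqrt(rowSums(sweep(V[cand, , drop = FALSE], 2, V[pv, ])^2))
      keep <- d > 1e-9                    # landmark vertex: not a partner
      cand <- cand[keep]; d <- d[keep]
      if (length(cand) < 3) next
      ordc <- order(d, cand)
      # closest three, skipping picks that leave the partner triangle
      # nearly collinear (trilateration is ill-posed along a 10-5 chain)
      near <- cand[ordc[1:2]]
      for (ci in ordc[-(1:2)]) {
        tri <- rbind(V[near[1], ], V[near[2], ], V[cand[ci], ])
        alt <- 2 * sqrt(sum(cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])^2)) / 2 /
          max(vnorm(tri[2, ] - tri[1, ]), vnorm(tri[3, ] - tri[1, ]), vnorm(tri[3, ] - tri[2, ]))
        if (alt >= 3) { near <- c(near, cand[ci]); break }
      }
      if (length(near) < 3) near <- cand[ordc[1:3]]
      cp_node <- c(cp_node, pv)
      cp_partner <- rbind(cp_partner, near)
      cp_dist <- rbind(cp_dist, sqrt(rowSums(sweep(V[near, , drop = FALSE], 2, V[pv, ])^2)))
    }
  }
  # initial pose.  Default: area-weighted best-fit plane -> X-Y, centroid
  # at origin, dome side up.  The mid panel is a band over the top of the
  # head whose front and back ends drop almost vertically to the axial
  # cut; pressing that band straight down folds the ends over themselves,
  # so it gets a cylindrical-unroll pose about the ear-to-ear (X) axis
  # instead (the band is nearly developable about that axis).
  fa <- face_areas(mesh)
  w <- numeric(nrow(V))
  for (c_ in 1:3) {
    agg <- rowsum(fa / 3, mesh$faces[, c_])
    ii <- as.integer(rownames(agg))
    w[ii] <- w[ii] + agg[, 1]
  }
  if (identical(panel$role, "mid")) {
    rho <- sqrt(V[, 2]^2 + V[, 3]^2)
    theta <- atan2(V[, 3], V[, 2])
    Rbar <- sum(rho * w) / sum(w)
    V0 <- cbind(V[, 1], -Rbar * (theta - pi / 2), rho - Rbar)
    V0 <- sweep(V0, 2, colSums(V0 * w) / sum(w))
  } else {
    ctr <- colSums(V * w) / sum(w)
    Vc <- sweep(V, 2, ctr)
    C <- t(Vc * w) %*% Vc
    ev <- eigen(C, symmetric = TRUE)
    nrml <- ev$vectors[, 3]
    R <- rotation_between(nrml, c(0, 0, 1))
    V0 <- Vc %*% t(R)
    if (max(V0[, 3]) < -min(V0[, 3])) {
      V0[, 2] <- -V0[, 2]; V0[, 3] <- -V0[, 3]   # rotate pi about X: dome up
    }
  }
  area3 <- face_areas(mesh)
  sliver0 <- face_min_altitude(mesh) < 0.1
  frest <- ifelse(sliver0, 0, area3)
  # couplings join the relaxation as stiff springs (weight 10); they are
  # re-imposed exactly by trilateration once the panel is flat
  Ek <- E; restk <- rest; ewk <- rep(1, nrow(E))
  if (length(cp_node)) {
    cpe <- cbind(rep(cp_node, each = 3), as.vector(t(cp_partner)))
    Ek <- rbind(E, cpe)
    restk <- c(rest, as.vector(t(cp_dist)))
    ewk <- c(ewk, rep(10, nrow(cpe)))
  }
  res <- cpp_flatten_relax(V0, Ek, restk, ewk, mesh$faces, frest, cp_node,
                           cp_partner, cp_dist,
                           gravity_step, spring_cap, damping,
                           as.integer(substeps), z_tol, as.integer(max_iters),
                           mode_code, as.integer(polish_iters), polish_tol)
  if (!res$converged) {
    stop(errorCondition(
      sprintf("flattening did not converge in %d iterations (max |Z| = %.4f mm)",
              max_iters, tail(res$maxz_history, 1)),
      history = res$maxz_history,
      class = c("capgen_convergence_error", "error", "condition")))
  }
  Vf <- res$vertices
  iterations <- res$iterations
  # A "material" flip is a triangle inverted w.r.t. the majority
  # orientation whose 2D overlap is not negligible.  Faces that are
  # slivers in 3D (cut/embed artefacts, altitude < 0.1 mm) or that are
  # squeezed near-degenerate in 2D (overlap area < 0.05 mm^2) are
  # tolerated: their overlap is below print resolution.
  material_flips <- function(Vf) {
    fl <- flipped_faces(Vf, mesh$faces)
    # overlap depth = 2D altitude of the inverted triangle; below 0.1 mm
    # it is a hairline fold under print resolution (same threshold as
    # the 3D sliver rule)
    a2d <- abs(signed_areas_2d(Vf, mesh$faces))
    f <- mesh$faces
    e1 <- sqrt((Vf[f[, 2], 1] - Vf[f[, 1], 1])^2 + (Vf[f[, 2], 2] - Vf[f[, 1], 2])^2)
    e2 <- sqrt((Vf[f[, 3], 1] - Vf[f[, 2], 1])^2 + (Vf[f[, 3], 2] - Vf[f[, 2], 2])^2)
    e3 <- sqrt((Vf[f[, 1], 1] - Vf[f[, 3], 1])^2 + (Vf[f[, 1], 2] - Vf[f[, 3], 2])^2)
    alt2d <- 2 * a2d / pmax(e1, e2, e3, 1e-12)
    fl & !sliver0 & alt2d > 0.1
  }
  flipped <- material_flips(Vf)
  if (any(flipped)) {
    # local repair: Laplacian untangling of the folded region (flipped
    # faces plus their one-ring), then re-relax in-plane
    nbr <- split(c(E[, 2], E[, 1]), c(E[, 1], E[, 2]))
    for (round in 1:5) {
      for (u in 1:200) {
        seed <- unique(as.vector(mesh$faces[flipped, , drop = FALSE]))
        bad <- unique(c(seed, unlist(nbr[as.character(seed)])))
        for (vid in bad) {
          nb <- nbr[[as.character(vid)]]
          Vf[vid, 1:2] <- colMeans(Vf[nb, 1:2, drop = FALSE])
        }
        flipped <- material_flips(Vf)
        if (!any(flipped)) break
      }
      res <- cpp_flatten_relax(Vf, Ek, restk, ewk, mesh$faces, frest,
                               cp_node, cp_partner, cp_dist,
                               gravity_step / 2, spring_cap / 2, damping,
                               as.integer(substeps), z_tol,
                               as.integer(max_iters), 1L,
                               as.integer(polish_iters), polish_tol)
      Vf <- res$vertices
      flipped <- material_flips(Vf)
      if (!any(flipped)) break
    }
    if (any(flipped))
      stop(sprintf("flattening produced %d flipped triangle(s); refusing to emit a self-intersecting panel",
                   sum(flipped)))
  }
  a3 <- mesh_area(mesh)
  a2 <- flat_area(Vf, mesh$faces)
  if (abs(a2 - a3) / a3 > area_tol)
    warning(sprintf("flattened area deviates %.1f%% from 3D panel area",
                    100 * abs(a2 - a3) / a3))
  structure(list(
    xy = Vf[, 1:2, drop = FALSE], z = Vf[, 3], faces = mesh$faces,
    provenance = panel$provenance, markers = mk, boundary = panel$boundary,
    role = panel$role, edges = E, rest_lengths = rest,
    couplings = list(node = cp_node, partner = cp_partner, dist = cp_dist),
    panel_vertices_3d = V,
    iterations = iterations, maxz = max(abs(Vf[, 3])),
    max_gravity_disp = res$max_gravity_disp,
    maxz_history = res$maxz_history,
    area_3d = a3, area_2d = a2), class = "flat_mesh")
}

face_min_altitude <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- row_norms(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  e2 <- row_norms(v[f[, 3], , drop = FALSE] - v[f[, 2], , drop = FALSE])
  e3 <- row_norms(v[f[, 1], , drop = FALSE] - v[f[, 3], , drop = FALSE])
  2 * face_areas(mesh) / pmax(e1, e2, e3)
}

signed_areas_2d <- function(V, faces) {
  x <- V[, 1]; y <- V[, 2]
  a <- faces[, 1]; b <- faces[, 2]; c_ <- faces[, 3]
  ((x[b] - x[a]) * (y[c_] - y[a]) - (x[c_] - x[a]) * (y[b] - y[a])) / 2
}

flipped_faces <- function(V, faces) {
  s <- signed_areas_2d(V, faces)
  if (sum(sign(s)) >= 0) s < 0 else s > 0
}

flat_area <- function(V, faces) {
  x <- V[, 1]; y <- V[, 2]
  a <- faces[, 1]; b <- faces[, 2]; c_ <- faces[, 3]
  sum(abs((x[b] - x[a]) * (y[c_] - y[a]) - (x[c_] - x[a]) * (y[b] - y[a]))) / 2
}

#' @export
print.flat_mesh <- function(x, ...) {
  cat(sprintf("<flat_mesh:%s> %d vertices, %d iterations, max|Z| %.3f mm, area ratio %.3f\n",
              x$role, nrow(x$xy), x$iterations, x$maxz, x$area_2d / x$area_3d))
  invisible(x)
}

#' Distortion metrics of a flattened panel
#'
#' @param flat A `flat_mesh` from [flatten_panel()].
#' @param pair_radius Pairs of 10-5 vertices closer than this in 3D count
#'   as adjacent for the landmark-distance metric (mm).
#' @return List with per-edge strain statistics, area ratio, adjacent
#'   10-5 pair distance errors, and probe coupling residuals (mm).
#' @export
distortion_report <- function(flat, pair_radius = 35) {
  E <- flat$edges
  V3 <- flat$panel_vertices_3d
  xy <- flat$xy
  len2 <- sqrt(rowSums((xy[E[, 1], , drop = FALSE] - xy[E[, 2], , drop = FALSE])^2))
  strain <- abs(len2 / flat$rest_lengths - 1)
  # micro-edges from cutting/embedding dominate relative strain without
  # carrying any printable geometry; exclude them from the statistics
  strain <- strain[flat$rest_lengths >= 0.5]
  mk <- flat$markers
  lmk <- mk[!grepl("^optode:", names(mk))]
  pair_err <- numeric(0)
  if (length(lmk) >= 2) {
    ids <- unname(lmk)
    d3 <- as.matrix(dist(V3[ids, , drop = FALSE]))
    d2 <- as.matrix(dist(xy[ids, , drop = FALSE]))
    sel <- upper.tri(d3) & d3 > 1e-9 & d3 <= pair_radius
    pair_err <- abs(d2[sel] - d3[sel]) / d3[sel]
  }
  cp <- flat$couplings
  coupling_resid <- numeric(0)
  if (length(cp$node)) {
    coupling_resid <- vapply(seq_along(cp$node), function(i) {
      p <- xy[cp$node[i], ]
      q <- xy[cp$partner[i, ], , drop = FALSE]
      max(abs(sqrt(rowSums(sweep(q, 2, p)^2)) - cp$dist[i, ]))
    }, numeric(1))
  }
  list(edge_strain_mean = mean(strain), edge_strain_max = max(strain),
       area_ratio = flat$area_2d / flat$area_3d,
       landmark_pair_err_mean = if (length(pair_err)) mean(pair_err) else NA_real_,
       landmark_pair_err_max = if (length(pair_err)) max(pair_err) else NA_real_,
       coupling_resid_max = if (length(coupling_resid)) max(coupling_resid) else 0,
       coupling_resid = coupling_resid,
       maxz = flat$maxz, iterations = flat$iterations)
}
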