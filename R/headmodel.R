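#' Head mesh with fiducials
#'
#' A scalp surface [trimesh] in mm together with the four fiducials.
#' Coordinate convention: +X toward RPA, +Y toward Nz (anterior),
#' +Z superior; the Iz-Cz-Nz midline lies in the X = 0 plane.
#'
#' @param mesh A [trimesh].
#' @param fiducials Named list/matrix with entries `Nz`, `Iz`, `LPA`,
#'   `RPA`: either vertex indices or length-3 points lying on the surface.
#' @return Object of class `head_mesh` with fields `mesh` and
#'   `fiducials` (a 4 x 3 matrix with rownames).
#' @export
head_mesh <- function(mesh, fiducials) {
  need <- c("Nz", "Iz", "LPA", "RPA")
  if (!all(need %in% names(fiducials)))
    stop("fiducials must contain Nz, Iz, LPA, RPA")
  fid <- matrix(NA_real_, 4, 3, dimnames = list(need, c("x", "y", "z")))
  for (nm in need) {
    v <- fiducials[[nm]]
    fid[nm, ] <- if (length(v) == 1) mesh$vertices[v, ] else as.numeric(v)
  }
  structure(list(mesh = mesh, fiducials = fid), class = "head_mesh")
}

#' @export
print.head_mesh <- function(x, ...) {
  cat(sprintf("<head_mesh> %d vertices, %d faces, HC %.1f cm\n",
              nrow(x$mesh$vertices), nrow(x$mesh$faces),
              head_circumference(x) / 10))
  invisible(x)
}

#' Generate a synthetic head surface
#'
#' Builds an upper superellipsoid hull with a short vertical skirt below
#' the fiducial plane, scaled so that the horizontal circumference
#' measured through Nz-LPA-Iz-RPA equals `circumference_cm`.  This is the
#' package's stand-in for an atlas scalp surface; any user STL/OFF scalp
#' can be used instead.
#'
#' @param circumference_cm Target head circumference in cm (e.g. 56).
#' @param axis_ratios Length-3 positive scalars: relative semi-axes along
#'   X (ear-to-ear), Y (nasion-inion) and Z (height).  Default
#'   `c(1, 1.25, 1.1)` approximates an adult head (heads are longer
#'   front-to-back than wide, and roughly as tall above the ears as wide).
#' @param refinement Integer >= 2; azimuthal resolution is
#'   `16 * 2^(refinement - 1)` vertices.
#' @param exponent Superellipse exponent of the horizontal cross-section
#'   (2 = ellipse, larger = boxier).
#' @param skirt_mm Depth of the vertical skirt below the fiducial plane.
#' @return A [head_mesh] with fiducials on the +/-Y and +/-X extremes of
#'   the measuring plane.
#' @export
synthetic_head <- function(circumference_cm = 56,
                           axis_ratios = c(1, 1.25, 1.1),
                           refinement = 3, exponent = 2,
                           skirt_mm = 25) {
  if (circumference_cm <= 0) stop("circumference must be positive")
  if (any(axis_ratios <= 0)) stop("axis_ratios must be positive")
  if (refinement < 2) stop("refinement must be >= 2")
  ntheta <- as.integer(16 * 2^(refinement - 1))
  nphi <- ntheta %/% 4
  nskirt <- 3L
  p <- exponent
  theta <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  cs <- sign(cos(theta)) * abs(cos(theta))^(2 / p)
  sn <- sign(sin(theta)) * abs(sin(theta))^(2 / p)
  # unit cross-section perimeter -> scale so measured HC == requested
  per <- sum(sqrt(diff(c(axis_ratios[1] * cs, axis_ratios[1] * cs[1]))^2 +
                  diff(c(axis_ratios[2] * sn, axis_ratios[2] * sn[1]))^2))
  s <- circumference_cm * 10 / per
  A <- s * axis_ratios[1]; B <- s * axis_ratios[2]; C <- s * axis_ratios[3]
  verts <- matrix(NA_real_, 0, 3)
  # rings from equator (j = 0) up to just below the pole
  phis <- seq(0, pi / 2, length.out = nphi + 1)
  for (j in seq_len(nphi + 1) - 1) {
    phi <- phis[j + 1]
    if (j == nphi) next  # pole handled as a single vertex
    r <- cos(phi)
    verts <- rbind(verts, cbind(A * r * cs, B * r * sn, C * sin(phi)))
  }
  pole <- c(0, 0, C)
  verts <- rbind(verts, pole)
  pole_id <- nrow(verts)
  # skirt rings below the equator (same cross-section, vertical wall)
  for (k in seq_len(nskirt)) {
    z <- -skirt_mm * k / nskirt
    verts <- rbind(verts, cbind(A * cs, B * sn, z))
  }
  ring_id <- function(j) (j * ntheta) + seq_len(ntheta)  # j = 0 .. nphi-1
  skirt_id <- function(k) pole_id + (k - 1) * ntheta + seq_len(ntheta)
  faces <- matrix(NA_integer_, 0, 3)
  quad_strip <- function(lo, hi) {
    # lo below hi; outward CCW orientation
    i2 <- c(2:ntheta, 1)
    rbind(cbind(lo, lo[i2], hi[i2]), cbind(lo, hi[i2], hi))
  }
  for (j in seq_len(nphi - 1)) {
    faces <- rbind(faces, quad_strip(ring_id(j - 1), ring_id(j)))
  }
  top <- ring_id(nphi - 1)
  i2 <- c(2:ntheta, 1)
  faces <- rbind(faces, cbind(top, top[i2], pole_id))
  faces <- rbind(faces, quad_strip(skirt_id(1), ring_id(0)))
  if (nskirt > 1) {
    for (k in seq_len(nskirt - 1)) {
      faces <- rbind(faces, quad_strip(skirt_id(k + 1), skirt_id(k)))
    }
  }
  mesh <- trimesh(verts, faces)
  # ensure outward orientation (positive radial component of normals)
  fa <- mesh$faces
  va <- mesh$vertices[fa[, 1], ]; vb <- mesh$vertices[fa[, 2], ]; vc <- mesh$vertices[fa[, 3], ]
  nrm <- cbind((vb[, 2] - va[, 2]) * (vc[, 3] - va[, 3]) - (vb[, 3] - va[, 3]) * (vc[, 2] - va[, 2]),
               (vb[, 3] - va[, 3]) * (vc[, 1] - va[, 1]) - (vb[, 1] - va[, 1]) * (vc[, 3] - va[, 3]),
               (vb[, 1] - va[, 1]) * (vc[, 2] - va[, 2]) - (vb[, 2] - va[, 2]) * (vc[, 1] - va[, 1]))
  ctr <- (va + vb + vc) / 3
  ctr[, 3] <- pmax(ctr[, 3], 0)  # radial test w.r.t. upper hull
  if (sum(rowSums(nrm * ctr)) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  q <- ntheta / 4
  fid <- list(RPA = 1L, Nz = as.integer(q + 1), LPA = as.integer(2 * q + 1),
              Iz = as.integer(3 * q + 1))
  head_mesh(mesh, fid)
}

# Best-fit measuring plane through the four fiducials (normal ~ +Z)
fiducial_plane <- function(head) {
  fid <- head$fiducials
  ctr <- colMeans(fid)
  sv <- svd(sweep(fid, 2, ctr))
  n <- sv$v[, 3]
  if (n[3] < 0) n <- -n
  list(normal = n, offset = sum(n * ctr))
}

#' Head circumference through the fiducial plane
#'
#' Length of the plane-surface intersection loop through (close to)
#' Nz-LPA-Iz-RPA.  The plane is nudged 1e-3 mm below the fiducial plane
#' so mesh vertices that lie exactly on it do not degenerate the slice.
#'
#' @param head A [head_mesh].
#' @return Circumference in mm.
#' @export
head_circumference <- function(head) {
  pl <- fiducial_plane(head)
  loops <- slice_mesh(head$mesh, pl$normal, pl$offset - 1e-3)
  if (!length(loops)) stop("cannot measure head circumference: fiducial plane misses the mesh")
  loop <- slice_loop_near(loops, head$fiducials)
  loop_length(loop)
}

#' Scale a head linearly to a target circumference
#'
#' All vertex coordinates (and fiducials/landmark positions) are
#' multiplied by `target_cm / current` about the origin.  Only
#' circumference-based scaling is implemented; nasion-inion or
#' ear-to-ear based scaling are recognised but unimplemented options.
#'
#' @param head A [head_mesh].
#' @param target_cm Target head circumference in cm.
#' @param landmarks Optional landmark set (see [compute_10_5_landmarks()])
#'   to scale along.
#' @param mode Only `"HC"` is implemented.
#' @return The scaled head, or `list(head, landmarks)` if landmarks given.
#' @export
scale_head <- function(head, target_cm, landmarks = NULL, mode = c("HC", "IzNz", "LPARPA")) {
  mode <- match.arg(mode)
  if (mode != "HC") stop("only circumference (HC) scaling is implemented")
  if (target_cm <= 0) stop("target circumference must be positive")
  cur <- head_circumference(head)
  s <- target_cm * 10 / cur
  head$mesh$vertices <- head$mesh$vertices * s
  head$fiducials <- head$fiducials * s
  if (is.null(landmarks)) return(head)
  landmarks$positions[, c("x", "y", "z")] <- landmarks$positions[, c("x", "y", "z")] * s
  list(head = head, landmarks = landmarks)
}

# ---------------------------------------------------------------------------
# 10-5 landmark construction by iterative arc subdivision on plane slices.

midline_labels <- c("Nz", "NFpz", "Fpz", "AFpz", "AFz", "AFFz", "Fz", "FFCz",
                    "FCz", "FCCz", "Cz", "CCPz", "CPz", "CPPz", "Pz", "PPOz",
                    "POz", "POOz", "Oz", "OIz", "Iz")
coronal_labels <- c("LPA", "T9h", "T7", "T7h", "C5", "C5h", "C3", "C3h", "C1",
                    "C1h", "Cz", "C2h", "C2", "C4h", "C4", "C6h", "C6", "T8h",
                    "T8", "T10h", "RPA")

# points at fractions of the arc a -> b through the branch passing `via`
arc_fraction_points <- function(mesh, a, b, plane, fractions) {
  loops <- slice_mesh(mesh, plane$normal, plane$offset)
  loop <- slice_loop_near(loops, rbind(a, b))
  closed <- isTRUE(attr(loop, "closed"))
  pa <- arc_position(loop, a, closed = closed)
  pb <- arc_position(loop, b, closed = closed)
  if (!closed) {
    arc <- arc_open_between(loop, min(pa$s, pb$s), max(pa$s, pb$s))
    if (pb$s < pa$s) arc <- arc[rev(seq_len(nrow(arc))), , drop = FALSE]
    return(polyline_point_at(arc, fractions * loop_length_open(arc)))
  }
  arc1 <- arc_between(loop, pa$s, pb$s, forward = TRUE)
  arc2 <- arc_between(loop, pa$s, pb$s, forward = FALSE)
  z1 <- max(arc1[, 3]); z2 <- max(arc2[, 3])
  arc <- if (z1 >= z2) arc1 else arc2
  # arc runs from a to b regardless of walking direction
  if (vnorm(arc[1, ] - pa$point) > vnorm(arc[nrow(arc), ] - pa$point))
    arc <- arc[rev(seq_len(nrow(arc))), , drop = FALSE]
  L <- loop_length_open(arc)
  polyline_point_at(arc, fractions * L)
}

arc_open_between <- function(loop, s1, s2) {
  cl <- polyline_lengths(loop)
  inner <- cl[cl > s1 + 1e-12 & cl < s2 - 1e-12]
  polyline_point_at(loop, sort(unique(c(s1, inner, s2))))
}

# full-loop fractional points, measured from `origin` walking toward `towards`
ring_fraction_points <- function(mesh, plane, origin, towards, fractions) {
  loops <- slice_mesh(mesh, plane$normal, plane$offset)
  loop <- slice_loop_near(loops, rbind(origin, towards))
  if (!isTRUE(attr(loop, "closed"))) stop("ring slice is not a closed loop")
  total <- loop_length(loop)
  po <- arc_position(loop, origin, closed = TRUE)
  pt <- arc_position(loop, towards, closed = TRUE)
  dfwd <- (pt$s - po$s) %% total
  fwd <- dfwd < total / 2     # is `towards` reached sooner walking forward?
  ss <- if (fwd) po$s + fractions * total else po$s - fractions * total
  loop_point_at(loop, ss %% total)
}

#' Construct EEG 10-5 landmarks on a scalp mesh
#'
#' Implements the standard iterative arc-subdivision construction on
#' plane slices: Cz is found by alternating midpoint iteration of the
#' midline (Nz-Cz-Iz) and coronal (LPA-Cz-RPA) arcs; both principal arcs
#' are then subdivided at 5% increments; a circumferential ring through
#' Fpz-T7-Oz-T8 and intermediate coronal chains (AF, F, FC, CP, P, PO)
#' complete the grid.  A lower ring through Nz and Iz provides the
#' near-midline reference points NFp1/2(h) and I1/2(h).
#'
#' @param head A [head_mesh] with all four fiducials.
#' @param cz_tol Convergence tolerance for the Cz fixed-point iteration (mm).
#' @return Object of class `landmark_set`: a list with `positions`
#'   (data.frame label/x/y/z/vertex; `vertex` is NA until the landmarks
#'   are embedded with [embed_points()]).
#' @export
compute_10_5_landmarks <- function(head, cz_tol = 0.1) {
  mesh <- head$mesh
  fid <- head$fiducials
  Nz <- fid["Nz", ]; Iz <- fid["Iz", ]; LPA <- fid["LPA", ]; RPA <- fid["RPA", ]
  if (min(dist(fid)) < 1e-6) stop("invalid fiducials: coincident points")
  # seed Cz: topmost vertex
  top <- mesh$vertices[which.max(mesh$vertices[, 3]), ]
  Cz <- top
  for (it in 1:50) {
    pl_mid <- plane_from_points(Nz, Iz, Cz)
    m1 <- arc_fraction_points(mesh, Nz, Iz, pl_mid, 0.5)[1, ]
    pl_cor <- plane_from_points(LPA, RPA, m1)
    m2 <- arc_fraction_points(mesh, LPA, RPA, pl_cor, 0.5)[1, ]
    if (vnorm(m2 - Cz) < cz_tol) { Cz <- m2; break }
    Cz <- m2
  }
  fr5 <- seq(0, 1, by = 0.05)
  pl_mid <- plane_from_points(Nz, Iz, Cz)
  pl_cor <- plane_from_points(LPA, RPA, Cz)
  mid_pts <- arc_fraction_points(mesh, Nz, Iz, pl_mid, fr5)
  cor_pts <- arc_fraction_points(mesh, LPA, RPA, pl_cor, fr5)
  pos <- list()
  add <- function(labels, pts) {
    for (i in seq_along(labels)) {
      if (!labels[i] %in% names(pos)) pos[[labels[i]]] <<- pts[i, ]
    }
  }
  add(midline_labels, mid_pts)
  add(coronal_labels, cor_pts)
  get <- function(l) pos[[l]]
  # circumferential ring through Fpz, T7, Oz (and ~T8)
  pl_ring <- plane_from_points(get("Fpz"), get("T7"), get("Oz"))
  ringL <- ring_fraction_points(mesh, pl_ring, get("Fpz"), get("T7"),
                                seq(0.05, 0.45, by = 0.05))
  ringR <- ring_fraction_points(mesh, pl_ring, get("Fpz"), get("T8"),
                                seq(0.05, 0.45, by = 0.05))
  add(c("Fp1", "AF7", "F7", "FT7", "T7r", "TP7", "P7", "PO7", "O1"), ringL)
  add(c("Fp2", "AF8", "F8", "FT8", "T8r", "TP8", "P8", "PO8", "O2"), ringR)
  pos[["T7r"]] <- NULL; pos[["T8r"]] <- NULL  # authoritative T7/T8 from coronal arc
  # lower ring through Nz and Iz: NFp and I reference points
  pl0 <- fiducial_plane(head)
  pl0$offset <- pl0$offset - 1e-3
  r0L <- ring_fraction_points(mesh, pl0, Nz, LPA, c(0.05, 0.10))
  r0R <- ring_fraction_points(mesh, pl0, Nz, RPA, c(0.05, 0.10))
  add(c("NFp1h", "NFp1"), r0L)
  add(c("NFp2h", "NFp2"), r0R)
  i0L <- ring_fraction_points(mesh, pl0, Iz, LPA, c(0.05, 0.10))
  i0R <- ring_fraction_points(mesh, pl0, Iz, RPA, c(0.05, 0.10))
  add(c("I1h", "I1"), i0L)
  add(c("I2h", "I2"), i0R)
  # intermediate coronal chains: left end on the 10% ring, apex on midline
  chains <- list(
    AF = c("AF7", "AFz", "AF8"), F = c("F7", "Fz", "F8"),
    FC = c("FT7", "FCz", "FT8"), CP = c("TP7", "CPz", "TP8"),
    P = c("P7", "Pz", "P8"), PO = c("PO7", "POz", "PO8"))
  for (nm in names(chains)) {
    ends <- chains[[nm]]
    pl <- plane_from_points(get(ends[1]), get(ends[2]), get(ends[3]))
    fr <- seq(0, 1, by = 1 / 16)
    pts <- arc_fraction_points(mesh, get(ends[1]), get(ends[3]), pl, fr)
    inner <- chain_labels(nm, ends)
    add(inner, pts)
  }
  df <- data.frame(label = names(pos),
                   do.call(rbind, pos),
                   vertex = NA_integer_, row.names = NULL)
  colnames(df)[2:4] <- c("x", "y", "z")
  structure(list(positions = df), class = "landmark_set")
}

# systematic 10-5 names along an intermediate coronal chain, left to right,
# at sixteenth-arc spacing (h-points between the tenth-arc positions)
chain_labels <- function(level, ends) {
  main <- c(ends[1], paste0(level, c(5, 3, 1)), ends[2],
            paste0(level, c(2, 4, 6)), ends[3])
  out <- character(17)
  out[seq(1, 17, by = 2)] <- main
  for (i in seq(2, 16, by = 2)) out[i] <- paste0(main[(i + 2) %/% 2], "h")
  out
}

#' Look up landmark positions by label
#' @param landmarks A `landmark_set`.
#' @param labels Character vector of 10-5 labels.
#' @return Matrix of positions (one row per label).
#' @export
landmark_positions <- function(landmarks, labels) {
  df <- landmarks$positions
  i <- match(labels, df$label)
  if (anyNA(i)) stop("unknown landmark label(s): ",
                     paste(labels[is.na(i)], collapse = ", "))
  m <- as.matrix(df[i, c("x", "y", "z")])
  rownames(m) <- labels
  m
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d labeled positions (%s...)\n",
              nrow(x$positions), paste(head(x$positions$label, 6), collapse = ", ")))
  invisible(x)
}
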