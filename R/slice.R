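# Plane-surface slicing: the geometric primitive behind arc-length
# measurement, head-circumference measurement and 10-5 landmark
# construction.  A slice of a triangle mesh by a plane is a set of
# polylines; on a closed-over region of the scalp it is a single loop.

# Intersect mesh with plane {x : <x,n> = off}.  Returns a list of
# polylines (k x 3 matrices) with attribute "closed".  Vertices exactly
# on the plane are nudged to the positive side so that every
# intersection point lies strictly inside a unique mesh edge.
slice_mesh <- function(mesh, normal, offset) {
  v <- mesh$vertices
  d <- as.vector(v %*% normal) - offset
  scale <- max(abs(d), 1)
  d[abs(d) < 1e-12 * scale] <- 1e-12 * scale
  f <- mesh$faces
  s1 <- d[f[, 1]]; s2 <- d[f[, 2]]; s3 <- d[f[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing)) return(list())
  fi <- which(crossing)
  nseg <- length(fi)
  seg_pt <- array(NA_real_, c(nseg, 2, 3))
  seg_key <- matrix(NA_character_, nseg, 2)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  for (k in seq_len(nseg)) {
    tri <- f[fi[k], ]
    j <- 0
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- tri[e[1]]; b <- tri[e[2]]
      if (sign(d[a]) != sign(d[b])) {
        t <- d[a] / (d[a] - d[b])
        j <- j + 1
        seg_pt[k, j, ] <- (1 - t) * v[a, ] + t * v[b, ]
        seg_key[k, j] <- edge_key(a, b)
      }
    }
  }
  # incidence lookup: edge key -> (segment, end) pairs
  inc_key <- c(seg_key[, 1], seg_key[, 2])
  inc_seg <- rep(seq_len(nseg), 2)
  inc_end <- rep(c(1L, 2L), each = nseg)
  lookup <- split(seq_along(inc_key), inc_key)
  used <- rep(FALSE, nseg)
  next_inc <- function(seg, endk) {
    for (ci in lookup[[seg_key[seg, endk]]]) {
      s <- inc_seg[ci]; e <- inc_end[ci]
      if (!(s == seg && e == endk)) return(c(s, e))
    }
    NULL
  }
  out <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    used[start] <- TRUE
    fwd <- list(seg_pt[start, 1, ], seg_pt[start, 2, ])
    closed <- FALSE
    cur <- c(start, 2L)
    repeat {
      nx <- next_inc(cur[1], cur[2])
      if (is.null(nx)) break
      if (nx[1] == start) { closed <- TRUE; break }
      if (used[nx[1]]) break
      used[nx[1]] <- TRUE
      far <- if (nx[2] == 1L) 2L else 1L
      fwd[[length(fwd) + 1]] <- seg_pt[nx[1], far, ]
      cur <- c(nx[1], far)
    }
    if (!closed) {
      cur <- c(start, 1L)
      repeat {
        nx <- next_inc(cur[1], cur[2])
        if (is.null(nx) || used[nx[1]]) break
        used[nx[1]] <- TRUE
        far <- if (nx[2] == 1L) 2L else 1L
        fwd <- c(list(seg_pt[nx[1], far, ]), fwd)
        cur <- c(nx[1], far)
      }
    }
    pl <- do.call(rbind, fwd)
    attr(pl, "closed") <- closed
    out[[length(out) + 1]] <- pl
  }
  out
}

# Pick the slice polyline closest to the given points
slice_loop_near <- function(loops, pts) {
  if (!length(loops)) stop("plane does not intersect the mesh")
  best <- 1; bestd <- Inf
  for (i in seq_along(loops)) {
    d <- 0
    for (k in seq_len(nrow(pts))) {
      d <- d + min(rowSums(sweep(loops[[i]], 2, pts[k, ])^2))
    }
    if (d < bestd) { bestd <- d; best <- i }
  }
  loops[[best]]
}

# Arc position (mm along polyline) of the projection of p onto the polyline
arc_position <- function(poly, p, closed = TRUE) {
  n <- nrow(poly)
  nseg <- if (closed) n else n - 1
  a <- poly[seq_len(nseg), , drop = FALSE]
  bidx <- if (closed) c(2:n, 1) else 2:n
  b <- poly[bidx, , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2, p, `+`)
  len2 <- pmax(rowSums(ab^2), 1e-300)
  t <- pmin(pmax(rowSums(ap * ab) / len2, 0), 1)
  proj <- a + ab * t
  d2 <- rowSums(sweep(proj, 2, p)^2)
  i <- which.min(d2)
  cl <- polyline_lengths(poly)
  s <- cl[i] + t[i] * sqrt(len2[i])
  list(s = s, dist = sqrt(d2[i]), point = proj[i, ])
}

# Total length of a polyline (closing segment included when closed)
loop_length <- function(poly) {
  L <- polyline_lengths(poly)
  L <- L[length(L)]
  if (isTRUE(attr(poly, "closed")))
    L <- L + vnorm(poly[1, ] - poly[nrow(poly), ])
  L
}

loop_length_open <- function(poly) {
  L <- polyline_lengths(poly)
  L[length(L)]
}

# Extract the sub-polyline of a closed loop from arc position s1 to s2,
# walking in the direction of increasing s (forward) or decreasing s.
arc_between <- function(loop, s1, s2, forward = TRUE) {
  total <- loop_length(loop)
  pts2 <- rbind(loop, loop, loop[1, , drop = FALSE])   # covers 0 .. 2*total
  cl2 <- polyline_lengths(pts2)
  if (!forward) { tmp <- s1; s1 <- s2; s2 <- tmp }
  s1 <- s1 %% total
  s2 <- s2 %% total
  if (s2 <= s1) s2 <- s2 + total
  inner <- cl2[cl2 > s1 + 1e-12 & cl2 < s2 - 1e-12]
  ss <- sort(unique(c(s1, inner, s2)))
  polyline_point_at(pts2, ss)
}

# Point at absolute arc position s along a closed loop
loop_point_at <- function(loop, s) {
  total <- loop_length(loop)
  pts <- rbind(loop, loop[1, , drop = FALSE])
  polyline_point_at(pts, s %% total)
}

#' Arc length between two surface points along a plane slice
#'
#' Slices the mesh with the plane and measures the length of the
#' intersection polyline between the projections of `a` and `b`.
#'
#' @param mesh A [trimesh] (or head mesh).
#' @param a,b Length-3 points on (or near) the surface.
#' @param plane A list with `normal`/`offset` (see [plane_from_points()])
#'   or a 3 x 3 matrix whose rows are three points defining the plane.
#' @param branch `"upper"` (default) picks the branch whose maximum Z is
#'   larger (the over-the-head path), `"shorter"` the shorter branch,
#'   `"full"` the whole loop length.
#' @param on_surface_tol Maximum allowed distance of `a`/`b` from the
#'   slice curve (mm).
#' @return Arc length in mm.
#' @export
arc_length <- function(mesh, a, b, plane, branch = c("upper", "shorter", "full"),
                       on_surface_tol = 2) {
  branch <- match.arg(branch)
  if (inherits(mesh, "head_mesh")) mesh <- mesh$mesh
  if (is.matrix(plane)) plane <- plane_from_points(plane[1, ], plane[2, ], plane[3, ])
  loops <- slice_mesh(mesh, plane$normal, plane$offset)
  if (!length(loops)) stop("plane does not intersect the mesh")
  loop <- slice_loop_near(loops, rbind(a, b))
  closed <- isTRUE(attr(loop, "closed"))
  if (branch == "full") return(loop_length(loop))
  pa <- arc_position(loop, a, closed = closed)
  pb <- arc_position(loop, b, closed = closed)
  if (pa$dist > on_surface_tol || pb$dist > on_surface_tol)
    stop(sprintf("point not on the slice curve (distances %.2f / %.2f mm)",
                 pa$dist, pb$dist))
  if (vnorm(a - b) < 1e-9) return(0)
  d_direct <- abs(pb$s - pa$s)
  if (!closed) return(d_direct)
  total <- loop_length(loop)
  d_other <- total - d_direct
  if (branch == "shorter") return(min(d_direct, d_other))
  arc1 <- arc_between(loop, pa$s, pb$s, forward = pb$s >= pa$s)
  arc2 <- arc_between(loop, pa$s, pb$s, forward = pb$s < pa$s)
  z1 <- max(arc1[, 3]); z2 <- max(arc2[, 3])
  if (abs(z1 - z2) < 1e-9) min(d_direct, d_other)
  else if (z1 > z2) loop_length_open(arc1) else loop_length_open(arc2)
}
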