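# Small 3D/2D vector helpers shared across the package.  Points are rows
# of numeric matrices; all lengths in millimeters.

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) stop("cannot normalize zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

row_norms <- function(m) sqrt(rowSums(m^2))

#' Define a plane from three points
#'
#' @param p1,p2,p3 Numeric length-3 points (mm), not collinear.
#' @return List with unit `normal` and scalar `offset` so that points `x`
#'   on the plane satisfy `sum(x * normal) == offset`.
#' @export
plane_from_points <- function(p1, p2, p3) {
  n <- cross3(p2 - p1, p3 - p1)
  if (vnorm(n) < 1e-9) stop("degenerate plane: points are collinear")
  n <- normalize(n)
  list(normal = n, offset = sum(n * p1))
}

# Rotation matrix mapping unit vector `from` onto unit vector `to`
rotation_between <- function(from, to) {
  from <- normalize(from); to <- normalize(to)
  v <- cross3(from, to)
  c_ <- sum(from * to)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # 180 degrees: rotate about any axis orthogonal to `from`
    ax <- normalize(cross3(from, if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / sum(v^2))
}

# Cumulative arc length along a polyline (rows of m)
polyline_lengths <- function(pts) {
  if (nrow(pts) < 2) return(0)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# Point at arc-length fraction t (0..1) along an open polyline
polyline_point_at <- function(pts, s) {
  cl <- polyline_lengths(pts)
  total <- cl[length(cl)]
  s <- pmin(pmax(s, 0), total)
  out <- matrix(NA_real_, length(s), ncol(pts))
  for (k in seq_along(s)) {
    i <- findInterval(s[k], cl, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(cl) - 1)
    w <- if (cl[i + 1] > cl[i]) (s[k] - cl[i]) / (cl[i + 1] - cl[i]) else 0
    out[k, ] <- (1 - w) * pts[i, ] + w * pts[i + 1, ]
  }
  out
}

# 2D helpers ---------------------------------------------------------------

rot90ccw <- function(v) c(-v[2], v[1])

#' Signed area of a closed 2D polygon (positive = counter-clockwise)
#' @param p n x 2 matrix, implicitly closed.
#' @export
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(seq_len(nrow(p))[-1], 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Test points against a closed polygon (even-odd rule)
#' @param pts n x 2 query points; `poly` m x 2 polygon.
#' @return logical vector, TRUE for inside (boundary counts as inside).
#' @export
points_in_polygon <- function(pts, poly, tol = 1e-9) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  nx <- px[c(2:n, 1)]; ny <- py[c(2:n, 1)]
  vapply(seq_len(nrow(pts)), function(k) {
    x <- pts[k, 1]; y <- pts[k, 2]
    # boundary test
    dx <- nx - px; dy <- ny - py
    tt <- ((x - px) * dx + (y - py) * dy) / pmax(dx^2 + dy^2, 1e-300)
    tt <- pmin(pmax(tt, 0), 1)
    d2 <- (px + tt * dx - x)^2 + (py + tt * dy - y)^2
    if (any(d2 < tol^2)) return(TRUE)
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((py[i] > y) != (py[j] > y)) {
        xi <- px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
        if (x < xi) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# Intersection parameters of segment p+t*(q-p), t in [0,1], with polygon
# boundary; returns sorted t values (possibly empty).
segment_polygon_crossings <- function(p, q, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  r <- q - p
  ts <- numeric(0)
  for (i in seq_len(n)) {
    s <- b[i, ] - a[i, ]
    den <- r[1] * s[2] - r[2] * s[1]
    if (abs(den) < 1e-14) next
    d <- a[i, ] - p
    t <- (d[1] * s[2] - d[2] * s[1]) / den
    u <- (d[1] * r[2] - d[2] * r[1]) / den
    if (t >= -1e-12 && t <= 1 + 1e-12 && u >= -1e-12 && u <= 1 + 1e-12) {
      ts <- c(ts, min(max(t, 0), 1))
    }
  }
  sort(unique(ts))
}

#' Is a closed polygon simple (no self-intersections)?
#' @param poly n x 2 matrix, implicitly closed.
#' @param tol Intersection parameter tolerance.
#' @return Logical scalar.  O(n^2) check, adjacent segments excluded.
#' @export
polygon_is_simple <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      p <- a[i, ]; r <- b[i, ] - p
      q <- a[j, ]; s <- b[j, ] - q
      den <- r[1] * s[2] - r[2] * s[1]
      if (abs(den) < 1e-14) next
      d <- q - p
      t <- (d[1] * s[2] - d[2] * s[1]) / den
      u <- (d[1] * r[2] - d[2] * r[1]) / den
      if (t > tol && t < 1 - tol && u > tol && u < 1 - tol) return(FALSE)
    }
  }
  TRUE
}
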