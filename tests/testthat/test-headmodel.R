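# Synthetic head generation, arc measurement, 10-5 landmark construction
# and head scaling, checked against closed forms on the sphere.

test_that("synthetic sphere head hits the requested circumference", {
  h <- sphere_head(3)
  expect_equal(head_circumference(h), 560, tolerance = 0.005)
  # every horizontal cross-section of the (1,1,1) head is a circle
  v <- h$mesh$vertices
  ring <- v[abs(v[, 3] - 20) < 15 & v[, 3] > 0, ]
  r_at <- sqrt(ring[, 1]^2 + ring[, 2]^2)
  z_group <- round(ring[, 3], 6)
  for (g in unique(z_group)) {
    expect_lt(diff(range(r_at[z_group == g])), 1e-9)
  }
})

test_that("axis ratios control the fiducial distances analytically", {
  h <- cached("head_ratio_13", synthetic_head(56, c(1, 1.3, 1), refinement = 2))
  fid <- h$fiducials
  ratio <- vnorm(fid["Nz", ] - fid["Iz", ]) / vnorm(fid["LPA", ] - fid["RPA", ])
  expect_equal(ratio, 1.3, tolerance = 0.01)
})

test_that("vertex count strictly increases with refinement; fiducials stay on the plane", {
  n <- vapply(2:4, function(k)
    nrow(synthetic_head(50, refinement = k)$mesh$vertices), numeric(1))
  expect_true(all(diff(n) > 0))
  h <- sphere_head(3)
  expect_lt(max(abs(h$fiducials[, 3])), 1e-9)
})

test_that("invalid parameters are rejected", {
  expect_error(synthetic_head(-1), "positive")
  expect_error(synthetic_head(56, c(1, -1, 1)), "positive")
  expect_error(synthetic_head(56, refinement = 1), "refinement")
})

test_that("arc_length recovers pi*r between antipodal points on the sphere", {
  h <- sphere_head(3)
  r <- sphere_radius(3)
  fid <- h$fiducials
  plane <- plane_from_points(fid["Nz", ], fid["Iz", ], c(0, 0, r))
  L <- arc_length(h, fid["Nz", ], fid["Iz", ], plane)
  expect_equal(L, pi * r, tolerance = 0.01)
  expect_equal(arc_length(h, fid["Nz", ], fid["Nz", ], plane), 0)
})

test_that("arc length error decreases monotonically with refinement", {
  errs <- vapply(2:4, function(k) {
    h <- synthetic_head(56, c(1, 1, 1), refinement = k)
    r <- head_circumference(h) / (2 * pi)
    fid <- h$fiducials
    plane <- plane_from_points(fid["Nz", ], fid["Iz", ], c(0, 0, r))
    # compare against the smooth-sphere value at this head's max radius
    r_true <- max(sqrt(rowSums(h$mesh$vertices^2)))
    abs(arc_length(h, fid["Nz", ], fid["Iz", ], plane) - pi * r_true) / (pi * r_true)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("Cz sits at the sphere pole and Fpz at 18 degrees from Nz", {
  lm <- sphere_landmarks(3)
  r <- sphere_radius(3)
  cz <- landmark_positions(lm, "Cz")[1, ]
  expect_lt(vnorm(cz - c(0, 0, max(sphere_head(3)$mesh$vertices[, 3]))), 0.5)
  fpz <- landmark_positions(lm, "Fpz")[1, ]
  expect_lt(abs(fpz[1]), 1e-6)                       # on the X = 0 midline
  expect_equal(unname(atan2(fpz[3], fpz[2]) * 180 / pi), 18, tolerance = 0.1)
})

test_that("landmark construction matches closed-form spherical angles to < 1%", {
  lm <- sphere_landmarks(3)
  r <- sphere_radius(3)
  arcq <- pi * r / 2                   # Nz -> Cz quarter arc
  # midline at 5% steps: polar angle from Nz = frac * 180 deg in X=0 plane
  for (probe in list(c("Fz", 0.30), c("Pz", 0.70), c("Oz", 0.90))) {
    p <- landmark_positions(lm, probe[1])[1, ]
    ang <- atan2(p[3], p[2])                          # elevation from +Y
    expected <- as.numeric(probe[2]) * pi
    expect_lt(abs(ang - expected) * r, 0.01 * pi * r) # < 1% of arc
  }
  # coronal chain: C3 at 30% from LPA
  c3 <- landmark_positions(lm, "C3")[1, ]
  ang <- atan2(c3[3], -c3[1])
  expect_lt(abs(ang - 0.3 * pi) * r, 0.01 * pi * r)
})

test_that("landmark positions are scale-equivariant", {
  h1 <- cached("scale_head_a", synthetic_head(50, refinement = 2))
  lm1 <- cached("scale_lm_a", compute_10_5_landmarks(h1))
  h2 <- h1
  h2$mesh$vertices <- h2$mesh$vertices * 1.2
  h2$fiducials <- h2$fiducials * 1.2
  lm2 <- compute_10_5_landmarks(h2)
  p1 <- landmark_positions(lm1, c("Cz", "C3", "Fpz", "PO4"))
  p2 <- landmark_positions(lm2, c("Cz", "C3", "Fpz", "PO4"))
  expect_equal(p2, p1 * 1.2, tolerance = 1e-6)
})

test_that("scale_head is linear and re-measures to the target", {
  h <- cached("scale_head_a", synthetic_head(50, refinement = 2))
  h2 <- scale_head(h, 58)
  expect_equal(h2$mesh$vertices, h$mesh$vertices * (580 / head_circumference(h)),
               tolerance = 1e-9)
  expect_equal(head_circumference(h2), 580, tolerance = 0.005 * 580)
  # identity
  cur <- head_circumference(h) / 10
  h3 <- scale_head(h, cur)
  expect_equal(h3$mesh$vertices, h$mesh$vertices, tolerance = 1e-9)
})

test_that("midline arc fractions are additive up to float", {
  lm <- sphere_landmarks(3)
  h <- sphere_head(3)
  fid <- h$fiducials
  cz <- landmark_positions(lm, "Cz")[1, ]
  plane <- plane_from_points(fid["Nz", ], fid["Iz", ], cz)
  full <- arc_length(h, fid["Nz", ], fid["Iz", ], plane)
  half1 <- arc_length(h, fid["Nz", ], cz, plane)
  half2 <- arc_length(h, cz, fid["Iz", ], plane)
  expect_equal(half1 + half2, full, tolerance = 1e-6)
})

test_that("degenerate fiducials are rejected", {
  h <- sphere_head(2)
  h$fiducials["Iz", ] <- h$fiducials["Nz", ]
  expect_error(compute_10_5_landmarks(h), "fiducial")
})
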