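# Point embedding and panel cutting.

test_that("interior point insertion splits 1 face into 3", {
  h <- sphere_head(2)
  mesh <- h$mesh
  f1 <- mesh$faces[10, ]
  centroid <- colMeans(mesh$vertices[f1, ])
  m2 <- embed_points(mesh, rbind(centroid), "pt", max_dist = 5)
  expect_equal(nrow(m2$vertices), nrow(mesh$vertices) + 1)
  expect_equal(nrow(m2$faces), nrow(mesh$faces) + 2)
  expect_equal(mesh_area(m2), mesh_area(mesh), tolerance = 1e-9)
})

test_that("a point at an existing vertex reuses it", {
  h <- sphere_head(2)
  mesh <- h$mesh
  m2 <- embed_points(mesh, mesh$vertices[7, , drop = FALSE], "v7")
  expect_equal(nrow(m2$vertices), nrow(mesh$vertices))
  expect_equal(attr(m2, "embedded")[["v7"]], 7L)
})

test_that("embedding 100 random surface points conserves total area to 1e-9", {
  h <- sphere_head(2)
  mesh <- h$mesh
  set.seed(11)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / row_norms(dirs)
  dirs[, 3] <- abs(dirs[, 3])            # upper hull only
  pts <- as.matrix(nearest_on_mesh(mesh, dirs * 200)[, c("x", "y", "z")])
  a0 <- mesh_area(mesh)
  m2 <- embed_points(mesh, pts, max_dist = 1)
  expect_equal(mesh_area(m2), a0, tolerance = 1e-9)
  expect_error(embed_points(mesh, rbind(c(0, 0, 500))), "from the surface")
})

test_that("sagittal cut offset matches the closed form x0 = r sin(3 pi / 14)", {
  el <- cached("sphere_embedded_3", embed_landmarks(sphere_head(3), sphere_landmarks(3)))
  pan <- cached("sphere_panels_3", cut_panels(el$head, el$landmarks))
  r <- sphere_radius(3)
  expect_equal(attr(pan, "x0"), r * sin(3 * pi / 14), tolerance = 0.01)
})

test_that("cutting conserves area and partitions by |X|", {
  el <- cached("sphere_embedded_3", embed_landmarks(sphere_head(3), sphere_landmarks(3)))
  pan <- cached("sphere_panels_3", cut_panels(el$head, el$landmarks))
  a_total <- mesh_area(el$head$mesh)
  a_panels <- sum(vapply(pan, function(p) mesh_area(p$mesh), numeric(1)))
  expect_equal(a_panels + attr(pan, "discarded_area"), a_total,
               tolerance = 1e-6 * a_total)
  x0 <- attr(pan, "x0")
  expect_true(all(abs(pan$mid$mesh$vertices[, 1]) <= x0 + 1e-6))
  expect_true(all(pan$left$mesh$vertices[, 1] <= -x0 + 1e-6))
  expect_true(all(pan$right$mesh$vertices[, 1] >= x0 - 1e-6))
})

test_that("boundary loops carry plane labels; cut vertices coincide across panels", {
  el <- cached("sphere_embedded_3", embed_landmarks(sphere_head(3), sphere_landmarks(3)))
  pan <- cached("sphere_panels_3", cut_panels(el$head, el$landmarks))
  expect_setequal(unique(pan$mid$boundary$loop),
                  c("axial", "sagittal-left", "sagittal-right"))
  # shared sagittal-left cut: same coordinates duplicated in left and mid
  get_cut <- function(p, lab) {
    b <- p$boundary[p$boundary$loop == lab, ]
    pts <- p$mesh$vertices[unique(c(b$from, b$to)), , drop = FALSE]
    pts[order(pts[, 2], pts[, 3]), ]
  }
  cl <- get_cut(pan$left, "sagittal-left")
  cm <- get_cut(pan$mid, "sagittal-left")
  expect_equal(nrow(cl), nrow(cm))
  expect_equal(cl, cm, tolerance = 1e-9)
})

test_that("provenance partitions original vertices across panels", {
  el <- cached("sphere_embedded_3", embed_landmarks(sphere_head(3), sphere_landmarks(3)))
  pan <- cached("sphere_panels_3", cut_panels(el$head, el$landmarks))
  provs <- lapply(pan, function(p) p$provenance[!is.na(p$provenance)])
  # strictly interior vertices belong to exactly one panel
  x0 <- attr(pan, "x0")
  planes <- attr(pan, "planes")
  v <- el$head$mesh$vertices
  above <- as.vector(v %*% planes$axial$normal) > planes$axial$offset + 1e-6
  interior_left <- which(v[, 1] < -x0 - 1e-6 & above)
  expect_true(all(interior_left %in% provs$left))
  expect_false(any(interior_left %in% provs$mid))
})

test_that("an optode below the axial cut raises a placement error naming it", {
  el <- cached("sphere_embedded_3", embed_landmarks(sphere_head(3), sphere_landmarks(3)))
  # the Iz-adjacent skirt region is below the cut; fake an optode there
  low <- which.min(el$head$mesh$vertices[, 3])
  ids <- c("optode:99" = low)
  expect_error(cut_panels(el$head, el$landmarks, ids), "optode:99")
})

test_that("sagittal cuts pass near the NFp/I reference points on the default head", {
  el2 <- cached("default_embedded_2", embed_landmarks(default_head(2), default_landmarks(2)))
  pan <- cached("default_panels_2", cut_panels(el2$head, el2$landmarks))
  x0 <- attr(pan, "x0")
  # mean edge length of the head mesh
  E <- capgen:::mesh_edges_unique(el2$head$mesh$faces)
  mel <- mean(row_norms(el2$head$mesh$vertices[E[, 1], ] - el2$head$mesh$vertices[E[, 2], ]))
  p <- landmark_positions(el2$landmarks, c("NFp1", "NFp2", "I1", "I2"))
  expect_true(all(abs(abs(p[, 1]) - x0) < mel))
})

test_that("chord interpretation of the mid fraction is available", {
  el <- cached("sphere_embedded_3", embed_landmarks(sphere_head(3), sphere_landmarks(3)))
  pan <- cut_panels(el$head, el$landmarks, mid_measure = "chord")
  r <- sphere_radius(3)
  expect_equal(attr(pan, "x0"), (3 / 7) * r, tolerance = 0.01)
})
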