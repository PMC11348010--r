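# Gravity + spring-relaxation flattening and its distortion metrics.

planar_panel <- function() {
  g <- expand.grid(x = seq(0, 50, by = 5), y = seq(0, 30, by = 5))
  V <- cbind(g$x, g$y, 0)
  nx <- 11
  idx <- function(i, j) (j - 1) * nx + i
  F <- matrix(NA_integer_, 0, 3)
  for (j in 1:6) for (i in 1:10) {
    F <- rbind(F, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  panel_surface(trimesh(V, F), seq_len(nrow(V)), integer(0),
                data.frame(from = integer(), to = integer(), loop = character()),
                "left")
}

test_that("an already-planar panel is returned undistorted", {
  fl <- flatten_panel(planar_panel())
  dr <- distortion_report(fl)
  expect_lt(dr$edge_strain_max, 1e-9)
  expect_equal(dr$area_ratio, 1, tolerance = 1e-12)
  expect_lt(fl$maxz, 0.1)
})

test_that("developable cylinder strip unrolls to a rectangle with < 0.5% strain", {
  fl <- cached("flat_cylinder", flatten_panel(cylinder_panel()))
  dr <- distortion_report(fl)
  expect_lt(dr$edge_strain_mean, 0.005)
  expect_lt(dr$edge_strain_max, 0.005)
  expect_lt(fl$maxz, 0.1 + 1e-12)
  # unrolls to r*phi x h
  expect_equal(diff(range(fl$xy[, 1])), 80 * 100 * pi / 180, tolerance = 0.01)
  expect_equal(diff(range(fl$xy[, 2])), 60, tolerance = 0.01)
})

test_that("spherical cap panel converges with area within 5%", {
  el <- cached("sphere_embedded_3", embed_landmarks(sphere_head(3), sphere_landmarks(3)))
  pan <- cached("sphere_panels_3", cut_panels(el$head, el$landmarks))
  fl <- cached("flat_sphere_left", flatten_panel(pan$left))
  dr <- distortion_report(fl)
  expect_lt(fl$maxz, 0.1 + 1e-12)
  expect_lt(abs(dr$area_ratio - 1), 0.05)
  # locality: adjacent 10-5 pair errors below the global mean strain
  expect_lt(dr$landmark_pair_err_mean, dr$edge_strain_mean)
})

test_that("gravity never displaces a vertex by more than 0.1 mm per step", {
  fl <- cached("flat_cylinder", flatten_panel(cylinder_panel()))
  expect_lte(fl$max_gravity_disp, 0.1 + 1e-12)
})

test_that("two runs with identical config are bit-identical", {
  p <- cylinder_panel(r = 60, h = 40, na = 21, nh = 13)
  f1 <- flatten_panel(p)
  f2 <- flatten_panel(p)
  expect_identical(f1$xy, f2$xy)
  expect_identical(f1$z, f2$z)
})

test_that("probe-node couplings hold their three 10-5 distances within 0.2 mm", {
  run <- default_cap_run()
  for (nm in names(run$intermediates$flats)) {
    dr <- distortion_report(run$intermediates$flats[[nm]])
    expect_lte(dr$coupling_resid_max, 0.2)
  }
})

test_that("coupling distances equal the 3D distances at construction, exactly", {
  run <- default_cap_run()
  fl <- run$intermediates$flats$mid
  cp <- fl$couplings
  expect_gt(length(cp$node), 0)   # the default probe has free optodes mid-panel
  V3 <- fl$panel_vertices_3d
  for (i in seq_along(cp$node)) {
    d3 <- row_norms(V3[cp$partner[i, ], , drop = FALSE] -
                    matrix(V3[cp$node[i], ], 3, 3, byrow = TRUE))
    expect_identical(unname(cp$dist[i, ]), unname(d3))
  }
})

test_that("non-convergence raises a structured error with the residual profile", {
  err <- tryCatch(flatten_panel(cylinder_panel(), max_iters = 5),
                  error = function(e) e)
  expect_s3_class(err, "capgen_convergence_error")
  expect_true(length(err$history) > 0)
})
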