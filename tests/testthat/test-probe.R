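# Probe design I/O, validation and spring-relaxation registration.

test_that("JSON probe round-trip is lossless", {
  p <- probe_16()
  path <- tempfile(fileext = ".json")
  write_probe_json(p, path)
  p2 <- read_probe_design(path, "json")
  expect_equal(p2$optodes$x, p$optodes$x)
  expect_equal(p2$optodes$kind, p$optodes$kind)
  expect_equal(p2$optodes$grommet, p$optodes$grommet)
  expect_equal(p2$springs$rest, p$springs$rest)
  expect_equal(p2$anchors$landmark, p$anchors$landmark)
})

test_that("SD MAT dialect: negative spring length reads as the flexible sentinel", {
  p <- probe_minimal()
  path <- tempfile(fileext = ".sd")
  write_probe_sd(p, path)
  p2 <- read_probe_design(path, "sd-mat")
  expect_equal(nrow(p2$optodes), nrow(p$optodes))
  expect_equal(sum(is.na(p2$springs$rest)), sum(is.na(p$springs$rest)))
  expect_equal(sort(p2$springs$rest[!is.na(p2$springs$rest)]),
               sort(p$springs$rest[!is.na(p$springs$rest)]))
  expect_setequal(p2$anchors$landmark, p$anchors$landmark)
  # a raw SD file with an explicit negative spring length
  sd <- list(SrcPos = matrix(c(0, 0, 100), 1), DetPos = matrix(c(30, 0, 100), 1),
             DummyPos = matrix(numeric(0), 0, 3),
             SpringList = matrix(c(1, 2, -1), 1),
             AnchorList = list(1, "Cz"))
  path2 <- tempfile(fileext = ".sd")
  write_mat(list(SD = sd), path2)
  p3 <- read_probe_design(path2)
  expect_true(is.na(p3$springs$rest[1]))
})

test_that("missing required SD fields give named format errors", {
  path <- tempfile(fileext = ".sd")
  write_mat(list(notSD = list(a = 1)), path)
  expect_error(read_probe_design(path), "SD")
  write_mat(list(SD = list(SrcPos = matrix(c(0, 0, 1), 1))), path)
  expect_error(read_probe_design(path), "AnchorList")
})

test_that("validate_probe reports dangling indices, unreachable parts, duplicates", {
  op <- data.frame(x = 1:5, y = 0, z = 0, kind = "dummy", grommet = "#d", rotation = 0)
  p <- probe_design(op, data.frame(i = 1, j = 99, rest = 10),
                    data.frame(optode = 1, landmark = "Cz"))
  rep1 <- validate_probe(p)
  expect_true("dangling-index" %in% rep1$code)
  # two disconnected clusters, one unanchored
  p2 <- probe_design(op, data.frame(i = c(1, 3), j = c(2, 4), rest = 10),
                     data.frame(optode = 1, landmark = "Cz"))
  rep2 <- validate_probe(p2)
  expect_true("unreachable-from-anchor" %in% rep2$code)
  # duplicate anchors
  p3 <- probe_design(op[1, ], NULL,
                     data.frame(optode = c(1, 1), landmark = c("Cz", "Pz")))
  expect_true("duplicate-anchor" %in% validate_probe(p3)$code)
  # valid probe: empty report
  expect_equal(nrow(validate_probe(probe_16(), sphere_landmarks(2))), 0)
})

test_that("single anchored dummy lands exactly on its landmark", {
  h <- sphere_head(3)
  lm <- sphere_landmarks(3)
  op <- data.frame(x = 10, y = 10, z = 120, kind = "dummy", grommet = "#d", rotation = 0)
  p <- probe_design(op, NULL, data.frame(optode = 1, landmark = "Cz"))
  X <- register_probe(p, h, lm)
  expect_identical(as.numeric(X[1, ]), as.numeric(landmark_positions(lm, "Cz")))
})

test_that("rigid 30 mm spring from an anchor ends 30 +/- 0.5 mm away, on the surface", {
  h <- sphere_head(3)
  lm <- sphere_landmarks(3)
  op <- data.frame(x = c(0, 30), y = c(0, 0), z = c(100, 100),
                   kind = "dummy", grommet = "#d", rotation = 0)
  p <- probe_design(op, data.frame(i = 1, j = 2, rest = 30),
                    data.frame(optode = 1, landmark = "Cz"))
  X <- register_probe(p, h, lm)
  expect_equal(vnorm(X[2, ] - X[1, ]), 30, tolerance = 0.5 / 30)
  d <- nearest_on_mesh(h$mesh, X[2, , drop = FALSE])$dist
  expect_lt(d, 0.1)
})

test_that("registration residual history decreases and result is permutation invariant", {
  h <- sphere_head(3)
  lm <- sphere_landmarks(3)
  p <- probe_minimal()
  X <- register_probe(p, h, lm)
  hist <- attr(X, "residual_history")
  # monotone decrease over outer iterations (allow float noise)
  expect_true(all(diff(hist) <= 1e-9))
  # permute optode order (relabel springs/anchors accordingly)
  perm <- c(3, 1, 2, 6, 4, 5)
  inv <- order(perm)
  p2 <- probe_design(p$optodes[perm, ],
                     transform(p$springs, i = inv[p$springs$i], j = inv[p$springs$j]),
                     transform(p$anchors, optode = inv[p$anchors$optode]))
  X2 <- register_probe(p2, h, lm)
  expect_equal(X2, X[perm, ], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("infeasible rigid constraints surface as residuals, not silent success", {
  h <- sphere_head(2)
  lm <- sphere_landmarks(2)
  r <- sphere_radius(2)
  # rest length far exceeding the head diameter cannot be satisfied
  op <- data.frame(x = c(0, 10), y = c(0, 0), z = c(100, 100),
                   kind = "dummy", grommet = "#d", rotation = 0)
  p <- probe_design(op, data.frame(i = 1, j = 2, rest = 4 * r),
                    data.frame(optode = 1, landmark = "Cz"))
  res <- tryCatch(register_probe(p, h, lm), error = function(e) e)
  if (inherits(res, "error")) {
    expect_s3_class(res, "capgen_convergence_error")
  } else {
    expect_gt(attr(res, "residual"), 1)
  }
})
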