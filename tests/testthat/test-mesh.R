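# Mesh container, validity checks and STL/OFF input-output.

unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * 10
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  trimesh(v, f)
}

test_that("mesh metrics and validity on a closed cube", {
  m <- unit_cube()
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), 1000)
  expect_equal(mesh_area(m), 600)
  expect_equal(nrow(boundary_edges(m)), 0)
  # open mesh: drop a face
  m2 <- trimesh(m$vertices, m$faces[-1, ])
  expect_false(is_watertight(m2))
  expect_equal(nrow(boundary_edges(m2)), 3)
})

test_that("STL round-trips preserve geometry; binary size follows the format", {
  m <- unit_cube()
  for (mode in c("binary", "ascii")) {
    path <- tempfile(fileext = ".stl")
    write_stl(m, path, mode = mode)
    m2 <- read_stl(path)
    expect_equal(nrow(m2$faces), nrow(m$faces))
    expect_equal(mesh_volume(m2), 1000, tolerance = 1e-9)
    expect_true(is_watertight(m2))
  }
  path <- tempfile(fileext = ".stl")
  write_stl(m, path, mode = "binary")
  expect_identical(file.info(path)$size, 84 + 50 * nrow(m$faces))
})

test_that("OFF round-trip is exact", {
  m <- unit_cube()
  path <- tempfile(fileext = ".off")
  write_off(m, path)
  m2 <- read_off(path)
  expect_equal(m2$vertices, m$vertices, ignore_attr = TRUE)
  expect_equal(m2$faces, m$faces, ignore_attr = TRUE)
})

test_that("nearest_on_mesh projects onto faces, edges and vertices", {
  m <- unit_cube()
  # above the top face center
  r <- nearest_on_mesh(m, rbind(c(5, 5, 20)))
  expect_equal(c(r$x, r$y, r$z), c(5, 5, 10))
  expect_equal(r$dist, 10)
  # outside a corner
  r2 <- nearest_on_mesh(m, rbind(c(-3, -4, -12)))
  expect_equal(c(r2$x, r2$y, r2$z), c(0, 0, 0))
  expect_equal(r2$dist, 13)
})
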