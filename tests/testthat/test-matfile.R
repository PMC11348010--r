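# Minimal MAT v5 reader/writer used for the .SD probe dialect.

test_that("MAT round-trip preserves matrices, strings, cells and structs", {
  vars <- list(A = matrix(seq(0.5, 3, by = 0.5), 2, 3),
               s = "hello world",
               cl = list(1.5, "x", c(1, 2, 3)),
               st = list(a = c(1, 2, 3), b = "lab", nest = list(z = 9)))
  path <- tempfile(fileext = ".mat")
  write_mat(vars, path)
  r <- read_mat(path)
  expect_equal(r$A, vars$A)
  expect_identical(r$s, vars$s)
  expect_equal(r$cl[[1]], 1.5)
  expect_identical(r$cl[[2]], "x")
  expect_equal(r$st$a, c(1, 2, 3))
  expect_identical(r$st$b, "lab")
  expect_equal(r$st$nest$z, 9)
})

test_that("reader rejects non-MAT input", {
  path <- tempfile()
  writeLines("not a mat file at all, padded to some length...", path)
  expect_error(read_mat(path), "MAT")
})
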