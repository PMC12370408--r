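test_that("a minimal well-formed 3ddose file parses", {
  f <- withr::local_tempfile(fileext = ".3ddose")
  writeLines(c("1 1 1", "0 1", "0 1", "0 1", "5.0", "0.01"), f)
  g <- read_3ddose(f)
  expect_equal(c(g$nx, g$ny, g$nz), c(1L, 1L, 1L))
  expect_equal(as.vector(g$dose), 5.0)
  expect_equal(as.vector(g$rel_unc), 0.01)
  expect_equal(voxel_centers(g, "x"), 0.5)
})

test_that("scientific notation and plain decimals both parse", {
  f <- withr::local_tempfile(fileext = ".3ddose")
  writeLines(c("2 1 1", "0 0.5 1.0", "0 1", "0 1",
               "5.0E-17 4.2e-17", "1.0E-2 0.02"), f)
  g <- read_3ddose(f)
  expect_equal(as.vector(g$dose), c(5.0e-17, 4.2e-17))
})

test_that("write/read round trip preserves a random grid", {
  g <- random_grid(5, 5, 5, seed = 11)
  f <- withr::local_tempfile(fileext = ".3ddose")
  write_3ddose(g, f)
  expect_true(grids_equal(read_3ddose(f), g))
})

test_that("malformed files raise distinct named parse errors", {
  write_case <- function(lines) {
    f <- tempfile(fileext = ".3ddose")
    writeLines(lines, f)
    f
  }
  expect_error(read_3ddose(write_case("2 2")), class = "tdeg_parse_header")
  expect_error(read_3ddose(write_case(c("0 1 1", "0 1", "0 1", "0 1"))),
               class = "tdeg_parse_header")
  expect_error(read_3ddose(write_case(c("1 1 1", "0 x", "0 1", "0 1",
                                        "5", "0.1"))),
               class = "tdeg_parse_numeric")
  # header says nx = 4 but only 4 x-boundaries follow (need 5)
  expect_error(read_3ddose(write_case(c("4 1 1", "0 1 2 3", "0 1", "0 1",
                                        paste(rep("1", 4), collapse = " "),
                                        paste(rep("0", 4), collapse = " ")))),
               class = "tdeg_parse_bounds_count")
  expect_error(read_3ddose(write_case(c("1 1 1", "1 0", "0 1", "0 1",
                                        "5", "0.1"))),
               class = "tdeg_parse_bounds_monotone")
  expect_error(read_3ddose(write_case(c("2 2 1", "0 1 2", "0 1 2", "0 1",
                                        "5 4 3"))),
               class = "tdeg_parse_dose_count")
  expect_error(read_3ddose(write_case(c("2 1 1", "0 1 2", "0 1", "0 1",
                                        "5 4", "0.1"))),
               class = "tdeg_parse_unc_count")
  expect_error(read_3ddose(write_case(c("1 1 1", "0 1", "0 1", "0 1",
                                        "5", "0.1 0.1"))),
               class = "tdeg_parse_trailing")
  expect_error(read_3ddose(write_case(c("1 1 1", "0 1", "0 1", "0 1",
                                        "-5", "0.1"))),
               class = "tdeg_parse_value_range")
})

test_that("the grid constructor enforces its invariants", {
  expect_error(dose_grid(c(0, 1), c(0, 1), c(0, 1), -1),
               class = "tdeg_invalid_grid")
  expect_error(dose_grid(c(0, 1), c(0, 1), c(0, 1), 1, rel_unc = 2),
               class = "tdeg_invalid_grid")
  expect_error(dose_grid(c(0, 1, 1), c(0, 1), c(0, 1), c(1, 2)),
               class = "tdeg_invalid_grid")
  expect_error(write_3ddose(list(), tempfile()))
})

test_that("extract_plane picks the nearest layer, ties toward smaller", {
  g <- dose_grid(0:5, 0:5, 0:5,
                 array(seq_len(125), dim = c(5, 5, 5)))
  pl <- extract_plane(g, "transverse", 2.5)  # exactly layer 3 center
  expect_equal(pl$coordinate, 2.5)
  expect_equal(pl$dose, matrix(g$dose[, , 3], 5, 5))
  # midway between layer centers 1.5 and 2.5 -> smaller wins
  tie <- extract_plane(g, "transverse", 2.0)
  expect_equal(tie$coordinate, 1.5)
  expect_error(extract_plane(g, "transverse", 12),
               class = "tdeg_range")
})

test_that("plane extraction is deterministic", {
  g <- random_grid(6, 5, 4, seed = 3)
  mid <- mean(range(g$y_bounds))
  a <- extract_plane(g, "coronal", mid)
  b <- extract_plane(g, "coronal", mid)
  expect_identical(sum(a$dose), sum(b$dose))
  expect_identical(a, b)
})
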