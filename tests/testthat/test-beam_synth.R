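params <- beam_params()

test_that("identical seeds give identical fields; NC is the unit beam", {
  a <- generate_field("NC", 10, params, seed = 5)
  b <- generate_field("NC", 10, params, seed = 5)
  expect_identical(a$grid$dose, b$grid$dose)
  c <- generate_field("NC", 10, params, seed = 6)
  expect_false(identical(a$grid$dose, c$grid$dose))
  expect_equal(a$severity, 0)
  expect_equal(a$chamber_dose, 1)
})

test_that("noise-free central-axis dose equals the PDD law exactly", {
  for (fs in c(3, 10, 30)) {
    f <- generate_field("NC", fs, params, noise = 0)
    zc <- voxel_centers(f$grid, "z")
    cax <- extract_pdd(f)
    law <- dose_law(rep(0, length(zc)), rep(0, length(zc)), zc, fs, "NC",
                    params)
    expect_equal(cax$value, law / max(law) * 100, tolerance = 1e-9)
    expect_equal(cax$z_max, params$z_max)
  }
})

test_that("output deviations reproduce the calibration anchors", {
  nc <- generate_field("NC", 10, params, noise = 0)
  dev_of <- function(nm) output_deviation(
    beam_output(generate_field(nm, 10, params, noise = 0)), beam_output(nc))
  expect_equal(dev_of("D0.6"), -5.7, tolerance = 1e-8)
  expect_equal(dev_of("D0.7"), -15.4, tolerance = 1e-8)
  expect_equal(dev_of("D0.7W2.0"), -24.1, tolerance = 1e-8)
})

test_that("chamber response ratios: fixtures verbatim, model monotone", {
  expect_equal(rch_model("NC", params), 1)
  expect_equal(rch_model("D0.6", params, mode = "fixture"), 0.945)
  expect_equal(rch_model("WC", params, mode = "fixture"), 0.031)
  expect_equal(rch_model("Z3", params, mode = "fixture"), 0.430)
  expect_error(rch_model("D0.2W1.4", params, mode = "fixture"),
               class = "tdeg_unknown_scenario")
  # model mode: anchored at D0.6/D0.7, strictly decreasing with severity in
  # the tungsten regime
  expect_equal(rch_model("D0.6", params), 0.945, tolerance = 1e-9)
  expect_equal(rch_model("D0.7", params), 0.853, tolerance = 1e-9)
  depths <- seq(0.1, 0.889, by = 0.1)
  r <- vapply(depths, function(d)
    rch_model(degradation_scenario("s", d, 1.5), params), numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("nominal 30 cm beam is flat and peaks at z_max", {
  f <- generate_field("NC", 30, params, noise = 0)
  prof <- extract_profile(f, "diagonal", 10)
  expect_lt(flatness(prof), 3)
  pdd <- extract_pdd(f)
  expect_equal(pdd$z_max, params$z_max, tolerance = 0.26)  # one voxel
  expect_equal(sum(pdd$value == 100), 1)
})

test_that("grid spec and field size limits are enforced", {
  expect_error(generate_field("NC", 2, params), class = "tdeg_field_size")
  expect_error(generate_field("NC", 40, params), class = "tdeg_field_size")
  big <- list(x_bounds = seq(0, 200, 0.5), y_bounds = seq(0, 200, 0.5),
              z_bounds = seq(0, 30, 0.25))
  expect_error(generate_field("NC", 10, params, spec = big),
               class = "tdeg_grid_spec")
})

test_that("generated grids survive a 3ddose round trip", {
  f <- generate_field("D0.6", 30, params, seed = 9)
  path <- withr::local_tempfile(fileext = ".3ddose")
  write_3ddose(f$grid, path)
  expect_true(grids_equal(read_3ddose(path), f$grid))
})

test_that("plane pairs agree at the center and sag off-center", {
  flu <- matrix(1, 41, 41)
  nc <- generate_plane_pair("NC", flu, spacing = 0.5)
  expect_equal(nc$reference$dose, nc$test$dose, tolerance = 1e-12)
  pr <- generate_plane_pair("W1", flu, spacing = 0.5, field_size = 30)
  ic <- which.min(abs(pr$reference$pos1))
  expect_equal(pr$test$dose[ic, ic], pr$reference$dose[ic, ic])
  # flat fluence: relative dose ratio falls monotonically with distance
  ratio <- pr$test$dose[ic:(ic + 15), ic] / pr$reference$dose[ic:(ic + 15), ic]
  expect_true(all(diff(ratio) < 1e-12))
  expect_lt(ratio[16], 1)
  expect_error(generate_plane_pair("NC", matrix(0, 3, 3)),
               class = "tdeg_fluence")
})
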