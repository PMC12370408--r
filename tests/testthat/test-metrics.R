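params <- beam_params()

test_that("PDD20,10 matches analytic values on constructed curves", {
  z <- seq(0, 25, by = 0.5)
  cv <- pdd_curve(z, exp(-0.05 * z), field_size = 10)
  expect_equal(pdd_ratio_20_10(cv), exp(-0.5), tolerance = 1e-12)
  flat <- pdd_curve(z, rep(1, length(z)), field_size = 10)
  expect_equal(pdd_ratio_20_10(flat), 1)
  short <- pdd_curve(seq(0, 15, 0.5), exp(-0.05 * seq(0, 15, 0.5)))
  expect_error(pdd_ratio_20_10(short), class = "tdeg_range")
})

test_that("profiles of simple planes behave as defined", {
  # flat plane of ones: OAF identically 1 on any axis
  g <- dose_grid(seq(-5.5, 5.5), seq(-5.5, 5.5), c(9, 10, 11),
                 array(1, dim = c(11, 11, 2)))
  for (ax in c("x", "y", "diagonal")) {
    pr <- extract_profile(g, ax, 10)
    expect_true(all(abs(pr$value - 1) < 1e-12))
  }
  # linear field 1 + 0.01 x: OAF equals it exactly (CAX value 1)
  xs <- seq(-5.5, 5.5)
  d <- array(rep(1 + 0.01 * (xs[-1] - 0.5), times = 11 * 2),
             dim = c(11, 11, 2))
  gl <- dose_grid(xs, xs, c(9, 10, 11), d)
  pr <- extract_profile(gl, "x", 10)
  expect_equal(pr$value, 1 + 0.01 * pr$position, tolerance = 1e-12)
})

test_that("profile curves demand a central-axis sample", {
  expect_error(profile_curve(c(1, 2, 3), c(1, 1, 1)),
               class = "tdeg_invalid_curve")
  expect_error(extract_profile(random_grid(4, 4, 4, seed = 1), "x", 1e3),
               class = "tdeg_range")
})

test_that("Savitzky-Golay smoothing reproduces quadratics and cuts noise", {
  pos <- seq(-10, 10, by = 0.1)
  quad <- profile_curve(pos, 2 + 0.3 * pos - 0.05 * pos^2, "x", 10, 20)
  sm <- smooth_profile(quad)
  expect_equal(sm$value, quad$value, tolerance = 1e-9)
  expect_identical(sm$position, quad$position)
  const <- profile_curve(pos, rep(3, length(pos)), "x", 10, 20)
  expect_equal(smooth_profile(const)$value, const$value, tolerance = 1e-12)
  expect_error(smooth_profile(profile_curve(-2:2, rep(1, 5), "x")),
               class = "tdeg_too_few_samples")
  # 1% noise on a smooth profile: RMS residual reduced at least 2x
  set.seed(31)
  truth <- dose_law(pos / sqrt(2), pos / sqrt(2), 10, 30, "NC", params)
  noisy <- profile_curve(pos, truth * (1 + 0.01 * rnorm(length(pos))),
                         "diagonal", 10, 30)
  sm <- smooth_profile(noisy)
  expect_lt(sqrt(mean((sm$value - truth)^2)),
            sqrt(mean((noisy$value - truth)^2)) / 2)
})

test_that("deviation_max obeys its defining formula and tie rules", {
  pos <- seq(-12, 12, by = 0.5)
  base <- profile_curve(pos, rep(1, length(pos)), "x", depth = 0,
                        field_size = 20, normalized = TRUE)
  expect_s3_class(base, "profile_curve")
  same <- deviation_max(base, base, 0.8)
  expect_equal(same$negative$max_pct, 0)
  expect_equal(same$positive$max_pct, 0)
  # one in-region bump of +3% on the positive side only
  v <- rep(1, length(pos)); v[pos == 5] <- 1.03
  test <- profile_curve(pos, v, "x", depth = 0, field_size = 20,
                        normalized = TRUE)
  dm <- deviation_max(test, base, 0.8)
  expect_equal(dm$positive$max_pct, 3.0, tolerance = 1e-12)
  expect_equal(dm$positive$signed_pct, 3.0, tolerance = 1e-12)
  expect_equal(dm$positive$at, 5)
  expect_equal(dm$negative$max_pct, 0)
  # invariance under common rescaling of both curves
  sc_t <- test; sc_t$value <- sc_t$value * 7.3
  sc_b <- base; sc_b$value <- sc_b$value * 7.3
  expect_equal(deviation_max(sc_t, sc_b, 0.8)$positive$max_pct, 3.0,
               tolerance = 1e-12)
  # mismatched metadata refuses
  other <- profile_curve(pos, v, "diagonal", depth = 0, field_size = 20)
  expect_error(deviation_max(other, base, 0.8), class = "tdeg_mismatch")
})

test_that("the 0.95 region deviation dominates the 0.8 region", {
  nc <- generate_field("NC", 30, params, noise = 0)
  w1 <- generate_field("W1", 30, params, noise = 0)
  tp <- extract_profile(w1, "diagonal", 10)
  bp <- extract_profile(nc, "diagonal", 10)
  expect_gte(deviation_max(tp, bp, 0.95)$positive$max_pct,
             deviation_max(tp, bp, 0.8)$positive$max_pct)
})

test_that("flatness follows (M - m)/(M + m) and is scale invariant", {
  pos <- seq(-12, 12, by = 0.5)
  const <- profile_curve(pos, rep(2, length(pos)), "x", depth = 0,
                         field_size = 20)
  expect_equal(flatness(const), 0)
  v <- rep(1, length(pos)); v[pos == 2] <- 1.05; v[pos == -3] <- 0.95
  cv <- profile_curve(pos, v, "x", depth = 0, field_size = 20)
  expect_equal(flatness(cv), 5.0, tolerance = 1e-12)
  cv2 <- cv; cv2$value <- cv2$value * 42
  expect_equal(flatness(cv2), flatness(cv), tolerance = 1e-12)
  narrow <- profile_curve(seq(-3, 3), rep(1, 7), "x", depth = 0,
                          field_size = 20)
  expect_error(flatness(narrow), class = "tdeg_range")
})

test_that("beam output is linear and reproducible", {
  f <- generate_field("NC", 10, params, seed = 2)
  o <- beam_output(f)
  doubled <- f$grid
  doubled$dose <- doubled$dose * 2
  expect_equal(beam_output(doubled), 2 * o, tolerance = 1e-12)
  expect_identical(beam_output(generate_field("NC", 10, params, seed = 2)), o)
  shallow <- dose_grid(c(-1, 0, 1), c(-1, 0, 1), c(0, 1, 2),
                       array(1, dim = c(2, 2, 2)))
  expect_error(beam_output(shallow), class = "tdeg_range")
})

test_that("resampling preserves curve values at original lattice points", {
  pos <- seq(-10, 10, by = 1)
  cv <- profile_curve(pos, 1 + 0.02 * abs(pos), "x", 10, 20)
  rs <- resample_curve(cv, 0.1)
  expect_equal(min(diff(rs$position)), 0.1, tolerance = 1e-12)
  keep <- rs$position %in% pos
  expect_equal(rs$value[keep], cv$value[match(rs$position[keep], pos)],
               tolerance = 1e-12)
})
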