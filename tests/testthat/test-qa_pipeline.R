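params <- beam_params()

small_lib <- scenario_library(list(
  degradation_scenario("NC", 0, 0),
  degradation_scenario("D0.5", 0.5, 1),
  degradation_scenario("D0.7", 0.7, 1)))

test_that("an NC-only sweep is a single all-zero unflagged row", {
  lib <- scenario_library(list(degradation_scenario("NC", 0, 0)))
  sw <- run_sweep(lib, fields = 10, params = params, seed = 3,
                  z_extent = 22)
  expect_equal(nrow(sw$summary), 1)
  expect_equal(sw$summary$output_dev_pct, 0)
  expect_equal(sw$summary$dev_diag_095_pct, 0)
  expect_equal(sw$summary$pdd2010_dev_pct, 0)
  expect_false(any(sw$summary$flagged))
})

test_that("sweeps are deterministic under a fixed seed", {
  a <- run_sweep(small_lib, fields = 10, params = params, seed = 11,
                 z_extent = 22)
  b <- run_sweep(small_lib, fields = 10, params = params, seed = 11,
                 z_extent = 22)
  expect_identical(a$summary, b$summary)
  expect_identical(a$deviations, b$deviations)
})

test_that("raising thresholds never increases the number of flags", {
  sw <- run_sweep(small_lib, fields = c(10, 30), params = params, seed = 4,
                  z_extent = 22)
  set.seed(99)
  for (i in 1:200) {
    base <- detection_rules(daily_output = runif(1, 0.5, 8),
                            weekly_output = runif(1, 0.5, 12),
                            diagonal_dev = runif(1, 0.5, 8),
                            any_profile_dev = runif(1, 0.2, 5))
    raised <- detection_rules(daily_output = base$daily_output + runif(1, 0, 5),
                              weekly_output = base$weekly_output + runif(1, 0, 5),
                              diagonal_dev = base$diagonal_dev + runif(1, 0, 5),
                              any_profile_dev = base$any_profile_dev + runif(1, 0, 5))
    f0 <- apply_rules(sw, base)
    f1 <- apply_rules(sw, raised)
    for (cl in names(f0)) expect_lte(sum(f1[[cl]]), sum(f0[[cl]]))
  }
})

test_that("friedman statistic follows the rank formula", {
  # all treatments identical in every block: statistic 0, p = 1
  m <- matrix(5, nrow = 4, ncol = 3)
  r <- friedman_test(m)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # k = 2 with one treatment always larger: statistic = n
  for (n in c(4, 6, 9)) {
    m2 <- cbind(a = seq_len(n), b = seq_len(n) + 1)
    expect_equal(friedman_test(m2)$statistic, n, tolerance = 1e-12)
  }
  expect_error(friedman_test(matrix(1, 3, 1)), class = "tdeg_friedman")
  expect_error(friedman_test(matrix(1, 1, 3)), class = "tdeg_friedman")
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "tdeg_friedman")
})

test_that("friedman agrees with the reference implementation", {
  set.seed(17)
  m <- matrix(rnorm(8 * 4), nrow = 8, ncol = 4)
  ours <- friedman_test(m)
  ref <- stats::friedman.test(m)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("asymptotic friedman p is close to the exact permutation p", {
  set.seed(23)
  m <- matrix(rnorm(4 * 3, sd = 0.5) + rep(c(0, 2, 4), each = 4), 4, 3)
  obs <- friedman_test(m)$statistic
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  idx <- expand.grid(1:6, 1:6, 1:6, 1:6)
  stats_all <- apply(idx, 1, function(ii) {
    mm <- m
    for (b in 1:4) mm[b, ] <- m[b, perms[[ii[b]]]]
    friedman_test(mm)$statistic
  })
  p_exact <- mean(stats_all >= obs - 1e-9)
  p_asym <- friedman_test(m)$p.value
  expect_lt(abs(p_exact - p_asym), 0.05)
})

test_that("factor comparison runs one test per varied factor", {
  sw <- run_sweep(small_lib, fields = c(10, 30), params = params, seed = 4,
                  z_extent = 22, wedge = TRUE)
  out <- compare_deviation_factors(sw, "D0.7")
  expect_true(all(c("axis", "region", "depth", "wedge") %in% names(out)))
  for (r in out) expect_s3_class(r, "friedman_test")
  # the wider 0.95 region dominates the 0.8 region per block, so the
  # region factor must come out significant
  expect_lt(out$region$p.value, 0.05)
})

test_that("reports are tidy and byte-identical on rerun", {
  sw <- run_sweep(builtin_library(), fields = 10, params = params,
                  seed = 5, z_extent = 22)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_report(sw, d1)
  f2 <- write_report(sw, d2)
  expect_true(all(file.exists(f1)))
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
  got <- read.csv(f1[1])
  expect_equal(sort(unique(got$scenario)), sort(names(builtin_library())))
  expect_equal(nrow(got), 12)
})
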