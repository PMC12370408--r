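# Beam-quality and profile metrics: PDD extraction and the PDD20,10
# quality index, off-axis profiles and their off-axis factors (OAF),
# Savitzky-Golay smoothing, maximum profile deviation from baseline, the
# (M - m)/(M + m) flatness, and the central-axis beam output at 10 cm
# depth.  Field-size regions (0.8 / 0.95 field size) are divergence-scaled
# to the evaluation depth by (SSD + z)/SSD, because field size is defined
# at the SSD plane.

# ---- curve containers -----------------------------------------------------

#' Construct a percentage depth dose curve
#'
#' @param depth Depths along the central axis, cm (strictly increasing).
#' @param value Dose values; normalized to 100 at the maximum (ties broken
#'   at the shallowest depth) unless already so.
#' @param field_size Field size at the SSD plane, cm.
#' @param ssd Source-to-surface distance, cm.
#' @param max_raw Pre-normalization maximum dose (kept for absolute work).
#' @return An object of class `pdd_curve`.
#' @export
pdd_curve <- function(depth, value, field_size = NA_real_, ssd = 100,
                      max_raw = max(value)) {
  stopifnot(length(depth) == length(value), !anyNA(value), all(value >= 0))
  if (any(diff(depth) <= 0))
    tdeg_error("invalid_curve", "depths must be strictly increasing")
  imax <- which(value == max(value))[1]
  val <- value / value[imax] * 100
  structure(list(depth = as.numeric(depth), value = val,
                 field_size = field_size, ssd = ssd,
                 max_raw = max_raw, z_max = depth[imax]),
            class = "pdd_curve")
}

#' Construct an off-axis profile curve
#'
#' @param position Signed distances from the central axis, cm, strictly
#'   increasing; a sample within half a voxel of 0 must be present.
#' @param value Dose or off-axis factor values.
#' @param axis `"x"`, `"y"` or `"diagonal"`.
#' @param depth Evaluation depth, cm.
#' @param field_size Field size at the SSD plane, cm.
#' @param ssd Source-to-surface distance, cm.
#' @param normalized Values are OAF (central-axis value 1).
#' @return An object of class `profile_curve`.
#' @export
profile_curve <- function(position, value, axis = c("x", "y", "diagonal"),
                          depth = NA_real_, field_size = NA_real_,
                          ssd = 100, normalized = FALSE) {
  axis <- match.arg(axis)
  stopifnot(length(position) == length(value), !anyNA(value))
  if (any(diff(position) <= 0))
    tdeg_error("invalid_curve", "positions must be strictly increasing")
  step <- min(diff(position))
  if (min(abs(position)) > step / 2 + 1e-9)
    tdeg_error("invalid_curve", "no central-axis sample (position 0) present")
  structure(list(position = as.numeric(position), value = as.numeric(value),
                 axis = axis, depth = depth, field_size = field_size,
                 ssd = ssd, normalized = normalized),
            class = "profile_curve")
}

#' @export
print.pdd_curve <- function(x, ...) {
  cat(sprintf("<pdd_curve> %d depths [%g, %g] cm, field %g cm, z_max %.2f cm\n",
              length(x$depth), min(x$depth), max(x$depth), x$field_size,
              x$z_max))
  invisible(x)
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("<profile_curve> %s axis at %g cm depth, field %g cm, %d points%s\n",
              x$axis, x$depth, x$field_size, length(x$position),
              if (x$normalized) " (OAF)" else ""))
  invisible(x)
}

#' @export
plot.profile_curve <- function(x, ...) {
  plot(x$position, x$value, type = "l",
       xlab = sprintf("%s position (cm)", x$axis),
       ylab = if (x$normalized) "OAF" else "dose", ...)
  invisible(x)
}

#' @export
plot.pdd_curve <- function(x, ...) {
  plot(x$depth, x$value, type = "l", xlab = "depth (cm)", ylab = "PDD (%)",
       ...)
  invisible(x)
}

# ---- interpolation helpers ------------------------------------------------

# Trilinear sample of a dose grid at arbitrary points (voxel-center basis).
sample_grid <- function(grid, x, y, z) {
  xc <- voxel_centers(grid, "x")
  yc <- voxel_centers(grid, "y")
  zc <- voxel_centers(grid, "z")
  ix <- locate(xc, x); iy <- locate(yc, y); iz <- locate(zc, z)
  fx <- frac(xc, x, ix); fy <- frac(yc, y, iy); fz <- frac(zc, z, iz)
  at <- function(i, j, k)
    grid$dose[cbind(i, j, k)]
  d00 <- at(ix, iy, iz) * (1 - fx) + at(ix + 1, iy, iz) * fx
  d10 <- at(ix, iy + 1, iz) * (1 - fx) + at(ix + 1, iy + 1, iz) * fx
  d01 <- at(ix, iy, iz + 1) * (1 - fx) + at(ix + 1, iy, iz + 1) * fx
  d11 <- at(ix, iy + 1, iz + 1) * (1 - fx) + at(ix + 1, iy + 1, iz + 1) * fx
  (d00 * (1 - fy) + d10 * fy) * (1 - fz) +
    (d01 * (1 - fy) + d11 * fy) * fz
}

# Index of the left neighbor center, clamped so i and i+1 are valid.
locate <- function(cen, q) {
  i <- findInterval(q, cen)
  pmin(pmax(i, 1L), length(cen) - 1L)
}

frac <- function(cen, q, i) {
  f <- (q - cen[i]) / (cen[i + 1] - cen[i])
  pmin(pmax(f, 0), 1)
}

in_extent <- function(cen, q) q >= cen[1] & q <= cen[length(cen)]

# ---- extraction -----------------------------------------------------------

#' Extract the central-axis percentage depth dose
#'
#' Dose is bilinearly interpolated to (x, y) = (0, 0) at every depth layer
#' (exact when a voxel-center column sits on the central axis) and
#' normalized to 100 at the maximum.
#'
#' @param grid A [dose_grid()] or [generate_field()] result.
#' @param field_size Field-size metadata, cm (taken from a `sim_field`
#'   automatically).
#' @param ssd Source-to-surface distance, cm.
#' @return A [pdd_curve()].
#' @export
extract_pdd <- function(grid, field_size = NA_real_, ssd = 100) {
  if (inherits(grid, "sim_field")) {
    if (is.na(field_size)) field_size <- grid$field_size
    grid <- grid$grid
  }
  xc <- voxel_centers(grid, "x"); yc <- voxel_centers(grid, "y")
  if (!in_extent(xc, 0) || !in_extent(yc, 0))
    tdeg_error("range", "central axis (0, 0) outside the grid")
  zc <- voxel_centers(grid, "z")
  v <- sample_grid(grid, rep(0, length(zc)), rep(0, length(zc)), zc)
  pdd_curve(zc, v, field_size = field_size, ssd = ssd, max_raw = max(v))
}

#' PDD20,10 beam-quality index
#'
#' Ratio of the percentage depth dose at 20 cm to that at 10 cm depth
#' (each linearly interpolated in depth), conventionally taken on a 10 cm
#' field at 100 cm SSD.
#'
#' @param curve A [pdd_curve()] spanning at least 20 cm depth.
#' @return Dimensionless ratio.
#' @export
pdd_ratio_20_10 <- function(curve) {
  stopifnot(inherits(curve, "pdd_curve"))
  if (min(curve$depth) > 10 || max(curve$depth) < 20)
    tdeg_error("range", "PDD curve must span 10-20 cm depth (has [%g, %g])",
               min(curve$depth), max(curve$depth))
  v <- approx(curve$depth, curve$value, xout = c(10, 20))$y
  v[2] / v[1]
}

#' Extract an off-axis profile
#'
#' Samples the dose at evenly spaced signed distances from the central
#' axis in the plane at `depth` (trilinear interpolation).  `x` and `y`
#' profiles step at the in-plane voxel pitch so samples coincide with
#' voxel-center columns; the diagonal profile walks the x = y lattice
#' diagonal, its positions being signed Euclidean distances from the
#' central axis.
#'
#' @param grid A [dose_grid()] or [generate_field()] result.
#' @param axis `"x"`, `"y"` or `"diagonal"`.
#' @param depth Evaluation depth, cm (within the grid).
#' @param field_size Field-size metadata, cm.
#' @param ssd Source-to-surface distance, cm.
#' @param normalize Divide by the central-axis value (OAF).
#' @return A [profile_curve()].
#' @export
extract_profile <- function(grid, axis = c("x", "y", "diagonal"), depth,
                            field_size = NA_real_, ssd = 100,
                            normalize = TRUE) {
  axis <- match.arg(axis)
  if (inherits(grid, "sim_field")) {
    if (is.na(field_size)) field_size <- grid$field_size
    grid <- grid$grid
  }
  zc <- voxel_centers(grid, "z")
  if (!in_extent(zc, depth))
    tdeg_error("range", "depth %g cm outside grid depths [%g, %g]",
               depth, min(zc), max(zc))
  xc <- voxel_centers(grid, "x"); yc <- voxel_centers(grid, "y")
  pitch <- min(min(diff(xc)), min(diff(yc)))
  if (axis == "diagonal") {
    kmax <- floor(min(max(xc), max(yc), -min(xc), -min(yc)) / pitch)
    k <- seq(-kmax, kmax)
    px <- k * pitch; py <- k * pitch
    pos <- sign(k) * sqrt(px^2 + py^2)
  } else {
    cen <- if (axis == "x") xc else yc
    half <- floor(min(max(cen), -min(cen)) / pitch)
    pos <- seq(-half, half) * pitch
    px <- if (axis == "x") pos else rep(0, length(pos))
    py <- if (axis == "y") pos else rep(0, length(pos))
  }
  v <- sample_grid(grid, px, py, rep(depth, length(px)))
  if (normalize) {
    cax <- v[which.min(abs(pos))]
    if (cax <= 0)
      tdeg_error("range", "central-axis value is zero; cannot normalize")
    v <- v / cax
  }
  profile_curve(pos, v, axis = axis, depth = depth, field_size = field_size,
                ssd = ssd, normalized = normalize)
}

#' Central-axis beam output at depth
#'
#' Interpolated central-axis dose at 10 cm depth (beyond the electron
#' range, so free of electron contamination), in the grid's own dose
#' units.
#'
#' @param grid A [dose_grid()] or [generate_field()] result.
#' @param depth Evaluation depth, cm.
#' @return Numeric dose.
#' @export
beam_output <- function(grid, depth = 10) {
  if (inherits(grid, "sim_field")) grid <- grid$grid
  zc <- voxel_centers(grid, "z")
  if (!in_extent(zc, depth))
    tdeg_error("range", "depth %g cm outside grid depths [%g, %g]",
               depth, min(zc), max(zc))
  xc <- voxel_centers(grid, "x"); yc <- voxel_centers(grid, "y")
  if (!in_extent(xc, 0) || !in_extent(yc, 0))
    tdeg_error("range", "central axis (0, 0) outside the grid")
  sample_grid(grid, 0, 0, depth)
}

# ---- smoothing and resampling --------------------------------------------

#' Savitzky-Golay smoothing of a curve
#'
#' Second-order Savitzky-Golay filter with an adaptive window: the
#' smallest odd integer at least 5 percent of the sample count, floored at
#' 7.  Endpoints are handled by the off-center polynomial fits of the
#' first/last window.  Positions are unchanged; quadratic signals pass
#' through exactly.
#'
#' @param curve A [profile_curve()] or [pdd_curve()] with at least 7
#'   samples.
#' @param order Polynomial order.
#' @return A curve of the same class with smoothed values.
#' @export
smooth_profile <- function(curve, order = 2) {
  n <- length(curve$value)
  if (n < 7)
    tdeg_error("too_few_samples", "need >= 7 samples to smooth (have %d)", n)
  win <- ceiling(0.05 * n)               # adaptive: 5% of the sample count
  if (win %% 2L == 0L) win <- win + 1L   # smallest odd integer above it
  win <- max(win, 7L)
  win <- min(win, if (n %% 2L == 1L) n else n - 1L)
  curve$value <- as.numeric(signal::sgolayfilt(curve$value, p = order,
                                               n = win))
  curve
}

#' Normalize a profile to its central-axis value
#'
#' Divides by the value interpolated at position 0 (off-axis factor
#' convention).  Normalizing after smoothing keeps central-axis noise out
#' of every point of the OAF curve.
#'
#' @param curve A [profile_curve()].
#' @return The curve with `normalized = TRUE`.
#' @export
normalize_profile <- function(curve) {
  stopifnot(inherits(curve, "profile_curve"))
  cax <- approx(curve$position, curve$value, xout = 0)$y
  if (is.na(cax) || cax <= 0)
    tdeg_error("range", "central-axis value is zero; cannot normalize")
  curve$value <- curve$value / cax
  curve$normalized <- TRUE
  curve
}

#' Resample a curve to a finer uniform step
#'
#' Linear interpolation onto a uniform lattice (default 1 mm), mirroring
#' the convention of interpolating scan data to 1 mm before metric
#' evaluation.  No extrapolation: the lattice stays inside the curve
#' range.
#'
#' @param curve A [profile_curve()] or [pdd_curve()].
#' @param step Target step, cm.
#' @return A curve of the same class.
#' @export
resample_curve <- function(curve, step = 0.1) {
  ax <- if (inherits(curve, "pdd_curve")) "depth" else "position"
  p <- curve[[ax]]
  grid <- seq(ceiling(min(p) / step) * step, floor(max(p) / step) * step,
              by = step)
  curve[[ax]] <- grid
  curve$value <- approx(p, curve$value, xout = grid)$y
  curve
}

# ---- deviation and flatness ----------------------------------------------

region_limit <- function(region_fraction, field_size, depth, ssd) {
  region_fraction * (field_size / 2) * (ssd + depth) / ssd
}

#' Maximum profile deviation from baseline
#'
#' For each side of the profile (negative and positive positions), over
#' the central `region_fraction` of the (divergence-scaled) field size,
#' computes `max |TP - BP| / BP * 100` with the test profile interpolated
#' onto the baseline positions.  The magnitude is reported together with
#' the signed value of the extreme deviation; ties go to the point nearest
#' the central axis.
#'
#' @param test,baseline [profile_curve()]s on the same axis, depth and
#'   field size, OAF-normalized.
#' @param region_fraction Central region as a fraction of field size
#'   (conventionally 0.8 or 0.95).
#' @return An object of class `deviation_report`: list with `negative` and
#'   `positive` entries (`max_pct`, `signed_pct`, `at`), plus the region
#'   and curve metadata.
#' @export
deviation_max <- function(test, baseline, region_fraction = 0.95) {
  stopifnot(inherits(test, "profile_curve"), inherits(baseline, "profile_curve"))
  if (!identical(test$axis, baseline$axis) ||
      !isTRUE(all.equal(test$field_size, baseline$field_size)) ||
      !isTRUE(all.equal(test$depth, baseline$depth)))
    tdeg_error("mismatch", "test and baseline profiles differ in axis, depth or field size")
  lim <- region_limit(region_fraction, baseline$field_size, baseline$depth,
                      baseline$ssd)
  tp <- approx(test$position, test$value, xout = baseline$position)$y
  side <- function(keep) {
    pos <- baseline$position[keep]
    bp <- baseline$value[keep]
    tpv <- tp[keep]
    ok <- !is.na(tpv)
    pos <- pos[ok]; bp <- bp[ok]; tpv <- tpv[ok]
    if (!length(pos))
      tdeg_error("range", "no profile samples in the %g field-size region",
                 region_fraction)
    if (any(bp <= 0))
      tdeg_error("range", "baseline profile is zero inside the region")
    dev <- (tpv - bp) / bp * 100
    o <- order(abs(pos))
    dev <- dev[o]; pos <- pos[o]
    i <- which(abs(dev) >= max(abs(dev)) - 1e-12)[1]  # tie: nearest CAX
    list(max_pct = abs(dev[i]), signed_pct = dev[i], at = pos[i])
  }
  structure(list(
    negative = side(baseline$position < 0 & baseline$position >= -lim),
    positive = side(baseline$position > 0 & baseline$position <= lim),
    region_fraction = region_fraction, axis = baseline$axis,
    depth = baseline$depth, field_size = baseline$field_size),
    class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report> %s axis, %g cm depth, field %g cm, region %.2f FS\n",
              x$axis, x$depth, x$field_size, x$region_fraction))
  cat(sprintf("  negative side: %.3f%% (signed %+.3f%% at %.2f cm)\n",
              x$negative$max_pct, x$negative$signed_pct, x$negative$at))
  cat(sprintf("  positive side: %.3f%% (signed %+.3f%% at %.2f cm)\n",
              x$positive$max_pct, x$positive$signed_pct, x$positive$at))
  invisible(x)
}

#' Profile flatness
#'
#' `(M - m) / (M + m) * 100` with M and m the maximum and minimum values
#' over the central `region_fraction` (default 0.8) of the
#' divergence-scaled field size.
#'
#' @param curve A [profile_curve()] covering the region.
#' @param region_fraction Central region as a fraction of field size.
#' @return Flatness in percent.
#' @export
flatness <- function(curve, region_fraction = 0.8) {
  stopifnot(inherits(curve, "profile_curve"))
  lim <- region_limit(region_fraction, curve$field_size, curve$depth,
                      curve$ssd)
  keep <- abs(curve$position) <= lim
  if (!any(keep))
    tdeg_error("range", "profile does not cover the central %.2f field size",
               region_fraction)
  if (min(curve$position) > -lim || max(curve$position) < lim)
    tdeg_error("range", "profile does not span the central %.2f field size",
               region_fraction)
  M <- max(curve$value[keep]); m <- min(curve$value[keep])
  (M - m) / (M + m) * 100
}
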