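# Synthetic water-phantom fields.  generate_field() samples the analytic
# dose law onto a rectilinear voxel grid, optionally adds seeded
# multiplicative Monte Carlo-like noise, and attaches the monitor-chamber
# dose so the absolute-dose correction chain can be exercised end to end.

#' Default voxel grid specification for a field size
#'
#' Lateral voxel centers are placed on a symmetric 1 cm lattice that
#' includes the central axis and extends past the divergence-scaled field
#' edge; depth centers sit on a 0.25 cm lattice so the reference depths
#' (z_max 1.5 cm, 5, 10 and 20 cm) are sampled exactly.
#'
#' @param field_size Square field side at the SSD plane, cm.
#' @param lateral_pitch In-plane voxel pitch, cm.
#' @param z_pitch Depth pitch, cm.
#' @param z_extent Maximum depth covered, cm.
#' @param margin Lateral margin beyond the half field size, cm.
#' @return List with `x_bounds`, `y_bounds`, `z_bounds`.
#' @export
grid_spec <- function(field_size, lateral_pitch = 1, z_pitch = 0.25,
                      z_extent = 30, margin = 5) {
  half <- ceiling(field_size / 2 * 1.1 + margin)
  xc <- seq(-half, half, by = lateral_pitch)
  zc <- seq(z_pitch, z_extent, by = z_pitch)
  list(x_bounds = centers_to_bounds(xc),
       y_bounds = centers_to_bounds(xc),
       z_bounds = centers_to_bounds(zc))
}

centers_to_bounds <- function(centers) {
  n <- length(centers)
  if (n == 1L) return(centers + c(-0.5, 0.5))
  mids <- (centers[-1] + centers[-n]) / 2
  c(centers[1] - (centers[2] - centers[1]) / 2, mids,
    centers[n] + (centers[n] - centers[n - 1]) / 2)
}

#' Generate a synthetic water-phantom field
#'
#' Evaluates the analytic dose law of [dose_law()] at every voxel center of
#' `spec`, applies multiplicative Gaussian noise (truncated at five sigma,
#' seeded) and fills the uncertainty grid with the noise level, emulating a
#' Monte Carlo water-phantom run at that type A uncertainty.
#'
#' @param scenario Scenario name or [degradation_scenario()].
#' @param field_size Square field side at the SSD plane, in 3--30 cm.
#' @param params A [beam_params()].
#' @param spec Grid specification from [grid_spec()] (or any list of three
#'   boundary vectors); at most 1e6 voxels.
#' @param wedge Simulate the 30-degree physical wedge field.
#' @param noise Fractional per-voxel noise sigma; defaults to
#'   `params$noise`.  Use 0 for a noise-free field.
#' @param seed Integer seed for the noise (the global RNG state is
#'   restored on exit).  Identical seeds give identical fields.
#' @return An object of class `sim_field`: list with the `dose_grid`
#'   (`$grid`), `field_size`, `scenario`, `wedge`, `chamber_dose` (arbitrary
#'   units, `1 / R_ch`) and `severity`.
#' @export
generate_field <- function(scenario, field_size, params = beam_params(),
                           spec = grid_spec(field_size), wedge = FALSE,
                           noise = params$noise, seed = NULL) {
  if (field_size < 3 || field_size > 30)
    tdeg_error("field_size", "field_size %g cm outside the modeled 3-30 cm range",
               field_size)
  s <- resolve_scenario(scenario)
  nx <- length(spec$x_bounds) - 1L
  ny <- length(spec$y_bounds) - 1L
  nz <- length(spec$z_bounds) - 1L
  if (nx < 1L || ny < 1L || nz < 1L || nx * ny * nz > 1e6)
    tdeg_error("grid_spec", "grid spec resolves to %g voxels (need 1..1e6)",
               nx * ny * nz)
  xc <- midpoints(spec$x_bounds)
  yc <- midpoints(spec$y_bounds)
  zc <- midpoints(spec$z_bounds)
  pts <- expand_points(xc, yc, zc)
  d <- dose_law(pts$x, pts$y, pts$z, field_size, s, params, wedge = wedge)
  if (noise > 0) {
    restore <- local_seed(seed)
    on.exit(restore())
    eps <- pmin(pmax(rnorm(length(d)), -5), 5)
    d <- d * (1 + noise * eps)
    d <- pmax(d, 0)
  }
  grid <- dose_grid(spec$x_bounds, spec$y_bounds, spec$z_bounds, d,
                    array(noise, dim = c(nx, ny, nz)))
  structure(list(grid = grid, field_size = field_size, scenario = s,
                 wedge = wedge,
                 chamber_dose = 1 / rch_model(s, params),
                 severity = model_severity(s, params),
                 params = params, noise = noise, seed = seed),
            class = "sim_field")
}

midpoints <- function(b) (b[-1] + b[-length(b)]) / 2

expand_points <- function(xc, yc, zc) {
  nx <- length(xc); ny <- length(yc); nz <- length(zc)
  list(x = rep(xc, times = ny * nz),
       y = rep(rep(yc, each = nx), times = nz),
       z = rep(zc, each = nx * ny))
}

# Seed the RNG locally, restoring (or clearing) the global state on exit.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(seed)) set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE) &&
          !is.null(seed))
        rm(".Random.seed", envir = globalenv())
    } else if (!is.null(seed)) {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' @export
print.sim_field <- function(x, ...) {
  cat(sprintf("<sim_field> %s, %g cm %s field (severity %.4g, noise %.3g)\n",
              x$scenario$name, x$field_size,
              if (x$wedge) "30-deg wedge" else "open", x$severity, x$noise))
  print(x$grid)
  invisible(x)
}

#' Generate a reference/test planar dose pair
#'
#' Convolves a plan-like fluence map with a small Gaussian dose kernel to
#' build the nominal-condition reference plane, then applies the degraded
#' beam's off-axis response to build the test plane.  The test plane is
#' rescaled so the two agree exactly at the plane center, emulating the
#' daily output recalibration that keeps machine output at baseline even as
#' the target degrades: what remains of the degradation is a relative sag
#' that grows away from the center.
#'
#' @param scenario Scenario name or [degradation_scenario()].
#' @param fluence Non-negative 2-D matrix, the plan-like fluence map.
#' @param spacing Fluence/plane pixel spacing, cm.
#' @param field_size Field-size context for the sag law (sets the radius
#'   scale), cm.
#' @param depth Depth of the plane, cm.
#' @param params A [beam_params()].
#' @param kernel_sigma Gaussian dose-kernel sigma, cm.
#' @param noise Fractional per-pixel noise sigma (0 = noise-free planes).
#' @param seed Integer seed for the noise.
#' @return List with `reference` and `test` [dose_plane()] objects.
#' @export
generate_plane_pair <- function(scenario, fluence, spacing = 0.5,
                                field_size = 30, depth = 10,
                                params = beam_params(), kernel_sigma = 0.4,
                                noise = 0, seed = NULL) {
  fluence <- as.matrix(fluence)
  if (length(fluence) == 0L || all(fluence == 0))
    tdeg_error("fluence", "fluence map is empty")
  if (any(fluence < 0))
    tdeg_error("fluence", "fluence map must be non-negative")
  s <- resolve_scenario(scenario)
  ref <- gauss_blur(fluence, kernel_sigma / spacing)
  n1 <- nrow(ref); n2 <- ncol(ref)
  p1 <- (seq_len(n1) - (n1 + 1) / 2) * spacing
  p2 <- (seq_len(n2) - (n2 + 1) / 2) * spacing
  r <- sqrt(outer(p1^2, p2^2, `+`))
  rf <- (field_size / 2) * (params$ssd + depth) / params$ssd
  sev <- model_severity(s, params)
  h0f <- params$h0 * (field_size / 30)
  ht <- h0f * (1 - params$k_horn * if (sev > 0) sev^params$gamma_horn else 0)
  # off-axis response of degraded vs nominal beam, normalized at the center
  sag <- (1 + ht * (r / rf)^params$p) / (1 + h0f * (r / rf)^params$p)
  tst <- ref * sag / sag[which.min(abs(p1)), which.min(abs(p2))]
  if (noise > 0) {
    restore <- local_seed(seed)
    on.exit(restore())
    tst <- pmax(tst * (1 + noise * pmin(pmax(rnorm(length(tst)), -5), 5)), 0)
  }
  list(reference = dose_plane(p1, p2, ref, "coronal", coordinate = depth,
                              axes = c("x", "y")),
       test = dose_plane(p1, p2, tst, "coronal", coordinate = depth,
                         axes = c("x", "y")))
}

# Separable Gaussian blur with reflected edges; sigma in pixels.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    idx <- seq_len(n)
    out <- numeric(n)
    for (j in seq_along(k)) {
      sh <- idx + (j - half - 1L)
      sh <- pmin(pmax(sh, 1L), n)  # clamp at edges
      out <- out + k[j] * v[sh]
    }
    out
  }
  m <- apply(m, 2, blur1)
  t(apply(t(m), 2, blur1))
}
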