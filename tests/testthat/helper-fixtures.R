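# Fixtures are built in code: random grids, a brute-force gamma oracle and
# small curve constructors shared across test files.

random_grid <- function(nx = 5, ny = 5, nz = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bounds <- function(n) cumsum(c(runif(1, -10, 0), runif(n, 0.1, 2)))
  dose_grid(bounds(nx), bounds(ny), bounds(nz),
            array(runif(nx * ny * nz, 0, 10), dim = c(nx, ny, nz)),
            array(runif(nx * ny * nz, 0, 0.05), dim = c(nx, ny, nz)))
}

grids_equal <- function(a, b, tol = 1e-6) {
  isTRUE(all.equal(a$x_bounds, b$x_bounds, tolerance = tol)) &&
    isTRUE(all.equal(a$y_bounds, b$y_bounds, tolerance = tol)) &&
    isTRUE(all.equal(a$z_bounds, b$z_bounds, tolerance = tol)) &&
    isTRUE(all.equal(a$dose, b$dose, tolerance = tol)) &&
    isTRUE(all.equal(a$rel_unc, b$rel_unc, tolerance = 1e-3))
}

# Random dose plane on a regular lattice: band-limited (smoothed white
# noise), so gradients are dose-distribution-like rather than pixel noise.
random_plane <- function(n = 20, spacing = 0.3, seed = NULL,
                         smooth_passes = 40) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(n * n, 0.2, 1), n, n)
  for (i in seq_len(smooth_passes)) {
    m <- (m + cbind(m[, 1], m[, -n]) + cbind(m[, -1], m[, n]) +
            rbind(m[1, ], m[-n, ]) + rbind(m[-1, ], m[n, ])) / 5
  }
  m <- m / max(m)
  pos <- (seq_len(n) - (n + 1) / 2) * spacing
  dose_plane(pos, pos, m, "transverse", coordinate = 0, axes = c("x", "y"))
}

# Exhaustive-search gamma oracle: same definition as gamma_map but a much
# finer search lattice (step = dta/50), evaluated point by point.
gamma_oracle <- function(reference, test, criteria, fine = 1 / 50) {
  dn <- max(reference$dose)
  dta_cm <- criteria$dta / 10
  step <- fine * dta_cm
  rad <- criteria$radius_frac * dta_cm
  off <- seq(-rad, rad, by = step)
  og <- expand.grid(dx = off, dy = off)
  og <- og[og$dx^2 + og$dy^2 <= rad^2 + 1e-12, ]
  dd_abs <- criteria$dd / 100 * dn
  dr2 <- (og$dx^2 + og$dy^2) / dta_cm^2
  n1 <- length(reference$pos1); n2 <- length(reference$pos2)
  gam <- matrix(NA_real_, n1, n2)
  bil <- function(qx, qy) {
    p1 <- test$pos1; p2 <- test$pos2
    ok <- qx >= p1[1] & qx <= p1[length(p1)] &
      qy >= p2[1] & qy <= p2[length(p2)]
    out <- rep(NA_real_, length(qx))
    if (!any(ok)) return(out)
    i <- pmin(pmax(findInterval(qx[ok], p1), 1L), length(p1) - 1L)
    j <- pmin(pmax(findInterval(qy[ok], p2), 1L), length(p2) - 1L)
    fx <- pmin(pmax((qx[ok] - p1[i]) / (p1[i + 1] - p1[i]), 0), 1)
    fy <- pmin(pmax((qy[ok] - p2[j]) / (p2[j + 1] - p2[j]), 0), 1)
    d <- test$dose
    out[ok] <- d[cbind(i, j)] * (1 - fx) * (1 - fy) +
      d[cbind(i + 1L, j)] * fx * (1 - fy) +
      d[cbind(i, j + 1L)] * (1 - fx) * fy +
      d[cbind(i + 1L, j + 1L)] * fx * fy
    out
  }
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    dr <- reference$dose[i, j]
    if (dr < criteria$cutoff / 100 * dn) next
    dt <- bil(reference$pos1[i] + og$dx, reference$pos2[j] + og$dy)
    g2 <- ((dt - dr) / dd_abs)^2 + dr2
    gam[i, j] <- sqrt(min(g2, na.rm = TRUE))
  }
  gam
}
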