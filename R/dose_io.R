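# DOSXYZnrc `3ddose` dose grids: the exchange format between every stage of
# the pipeline.  Layout: header `nx ny nz`; three boundary records (n + 1
# coordinates each, cm); nx*ny*nz dose values with x varying fastest, then y,
# then z; the same count of fractional (type A) uncertainties.

#' Construct a rectilinear 3-D dose grid
#'
#' A `dose_grid` holds the payload of a DOSXYZnrc `3ddose` file: voxel
#' boundary coordinates along each axis (cm), a 3-D dose array (dose per
#' incident particle, or any linearly rescaled unit) and a matching array of
#' fractional type A uncertainties.  Voxel centers are boundary midpoints;
#' all downstream sampling works on centers.
#'
#' @param x_bounds,y_bounds,z_bounds Strictly increasing numeric vectors of
#'   voxel boundary coordinates in cm (length `n + 1` for `n` voxels).
#' @param dose Numeric array of non-negative dose values, dim `c(nx, ny, nz)`
#'   (a vector in x-fastest order is accepted and reshaped).
#' @param rel_unc Array of fractional uncertainties in `[0, 1]`, same shape
#'   as `dose`.  Defaults to zero.
#' @return An object of class `dose_grid`.
#' @seealso [read_3ddose()], [write_3ddose()], [extract_plane()]
#' @export
dose_grid <- function(x_bounds, y_bounds, z_bounds, dose, rel_unc = NULL) {
  nx <- length(x_bounds) - 1L
  ny <- length(y_bounds) - 1L
  nz <- length(z_bounds) - 1L
  if (nx < 1L || ny < 1L || nz < 1L)
    tdeg_error("invalid_grid", "each axis needs at least one voxel (two boundaries)")
  for (ax in list(x = x_bounds, y = y_bounds, z = z_bounds)) {
    if (anyNA(ax) || any(diff(ax) <= 0))
      tdeg_error("invalid_grid", "voxel boundaries must be strictly increasing")
  }
  dose <- as_grid_array(dose, nx, ny, nz, "dose")
  if (is.null(rel_unc)) rel_unc <- array(0, dim = c(nx, ny, nz))
  rel_unc <- as_grid_array(rel_unc, nx, ny, nz, "rel_unc")
  if (anyNA(dose) || any(dose < 0))
    tdeg_error("invalid_grid", "dose values must be finite and >= 0")
  if (anyNA(rel_unc) || any(rel_unc < 0 | rel_unc > 1))
    tdeg_error("invalid_grid", "rel_unc values must lie in [0, 1]")
  structure(
    list(nx = nx, ny = ny, nz = nz,
         x_bounds = as.numeric(x_bounds),
         y_bounds = as.numeric(y_bounds),
         z_bounds = as.numeric(z_bounds),
         dose = dose, rel_unc = rel_unc),
    class = "dose_grid")
}

as_grid_array <- function(v, nx, ny, nz, what) {
  if (is.null(dim(v))) {
    if (length(v) != nx * ny * nz)
      tdeg_error("invalid_grid", "%s has %d values, expected %d", what,
                 length(v), nx * ny * nz)
    v <- array(as.numeric(v), dim = c(nx, ny, nz))
  } else if (!identical(as.integer(dim(v)), as.integer(c(nx, ny, nz)))) {
    tdeg_error("invalid_grid", "%s has shape (%s), expected (%d, %d, %d)",
               what, paste(dim(v), collapse = ", "), nx, ny, nz)
  }
  storage.mode(v) <- "double"
  v
}

#' Voxel-center coordinates of a dose grid
#'
#' @param grid A [dose_grid()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Numeric vector of midpoints of the voxel boundaries.
#' @export
voxel_centers <- function(grid, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  b <- grid[[paste0(axis, "_bounds")]]
  (b[-1] + b[-length(b)]) / 2
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels\n", x$nx, x$ny, x$nz))
  cat(sprintf("  x: [%g, %g] cm  y: [%g, %g] cm  z: [%g, %g] cm\n",
              min(x$x_bounds), max(x$x_bounds), min(x$y_bounds),
              max(x$y_bounds), min(x$z_bounds), max(x$z_bounds)))
  cat(sprintf("  dose: [%.4g, %.4g]  median rel. unc.: %.3g\n",
              min(x$dose), max(x$dose), stats::median(x$rel_unc)))
  invisible(x)
}

#' Read a DOSXYZnrc `3ddose` file
#'
#' Parses the standard `3ddose` layout: a header line of voxel counts,
#' three line-delimited boundary records, then the dose record (x varying
#' fastest, then y, then z) and the relative-uncertainty record, each
#' whitespace-delimited and free to wrap across lines.  Plain decimals and
#' scientific notation are both accepted.  Malformed files raise classed
#' parse errors (`tdeg_parse_*`) naming the offending record.
#'
#' @param path Path to a `3ddose` text file.
#' @return A [dose_grid()].
#' @examples
#' f <- tempfile(fileext = ".3ddose")
#' writeLines(c("1 1 1", "0 1", "0 1", "0 1", "5.0", "0.01"), f)
#' read_3ddose(f)
#' @export
read_3ddose <- function(path) {
  if (!file.exists(path))
    parse_error("file", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 4L)
    parse_error("header", "file has %d non-blank record(s); need header, 3 boundary records, dose and uncertainty",
                length(lines))
  toks_of <- function(line) strsplit(trimws(line), "\\s+")[[1]]
  num_of <- function(tok, rec) {
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v))
      parse_error("numeric", "%s record: non-numeric token '%s'",
                  rec, tok[which(is.na(v))[1]])
    v
  }
  htok <- toks_of(lines[1])
  if (length(htok) != 3L)
    parse_error("header", "header record: expected 3 voxel counts, found %d token(s)",
                length(htok))
  n <- suppressWarnings(as.integer(htok))
  if (anyNA(n) || any(n < 1L))
    parse_error("header", "header record: voxel counts must be positive integers (got '%s')",
                paste(htok, collapse = " "))
  # the three boundary records are line-delimited (the DOSXYZnrc layout)
  bounds <- list()
  for (i in 1:3) {
    axn <- c("x", "y", "z")[i]
    rec <- paste0(axn, "-boundary")
    b <- num_of(toks_of(lines[1L + i]), rec)
    if (length(b) != n[i] + 1L)
      parse_error("bounds_count", "%s record: expected %d boundaries, found %d",
                  rec, n[i] + 1L, length(b))
    if (any(diff(b) <= 0))
      parse_error("bounds_monotone",
                  "%s-boundary record: coordinates are not strictly increasing", axn)
    bounds[[axn]] <- b
  }
  rest <- unlist(lapply(lines[-(1:4)], toks_of), use.names = FALSE)
  vals <- num_of(rest, "dose/uncertainty")
  nvox <- prod(n)
  if (length(vals) < nvox)
    parse_error("dose_count", "dose record: expected %d values, found %d",
                nvox, length(vals))
  dose <- vals[seq_len(nvox)]
  vals <- vals[-seq_len(nvox)]
  if (length(vals) < nvox)
    parse_error("unc_count", "uncertainty record: expected %d values, found %d",
                nvox, length(vals))
  runc <- vals[seq_len(nvox)]
  if (length(vals) > nvox)
    parse_error("trailing", "%d unexpected trailing value(s) after the uncertainty record",
                length(vals) - nvox)
  if (any(dose < 0))
    parse_error("value_range", "dose record: negative dose value at position %d",
                which(dose < 0)[1])
  if (any(runc < 0 | runc > 1))
    parse_error("value_range", "uncertainty record: value outside [0, 1] at position %d",
                which(runc < 0 | runc > 1)[1])
  dose_grid(bounds$x, bounds$y, bounds$z, dose, runc)
}

#' Write a dose grid as a `3ddose` file
#'
#' Emits the exact layout [read_3ddose()] accepts; numbers carry 7
#' significant digits so a read/write round trip preserves the grid to
#' better than 1e-6 relative.
#'
#' @param grid A valid [dose_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_3ddose <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  # 9 significant digits: a text round trip stays within 1e-6 relative;
  # boundary records are single lines (the layout read_3ddose expects)
  fmt <- function(v) paste(sprintf("%.9g", v), collapse = " ")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d %d", grid$nx, grid$ny, grid$nz), con)
  writeLines(fmt(grid$x_bounds), con)
  writeLines(fmt(grid$y_bounds), con)
  writeLines(fmt(grid$z_bounds), con)
  writeLines(chunked(sprintf("%.8e", as.vector(grid$dose)), 6L), con)
  writeLines(chunked(sprintf("%.4e", as.vector(grid$rel_unc)), 8L), con)
  invisible(path)
}

chunked <- function(strs, per_line) {
  idx <- ceiling(seq_along(strs) / per_line)
  vapply(split(strs, idx), paste, character(1), collapse = " ")
}

#' Construct a planar dose distribution
#'
#' @param pos1,pos2 Strictly increasing in-plane voxel-center coordinates, cm.
#' @param dose Matrix of non-negative doses, dim `c(length(pos1), length(pos2))`.
#' @param orientation `"coronal"`, `"transverse"` or `"sagittal"`.
#' @param coordinate Fixed third coordinate actually sampled, cm.
#' @param axes Character pair naming the in-plane axes.
#' @return An object of class `dose_plane`.
#' @export
dose_plane <- function(pos1, pos2, dose,
                       orientation = c("coronal", "transverse", "sagittal"),
                       coordinate = 0, axes = NULL) {
  orientation <- match.arg(orientation)
  if (any(diff(pos1) <= 0) || any(diff(pos2) <= 0))
    tdeg_error("invalid_plane", "plane positions must be strictly increasing")
  dose <- as.matrix(dose)
  if (!identical(dim(dose), c(length(pos1), length(pos2))))
    tdeg_error("invalid_plane", "dose matrix is %d x %d, expected %d x %d",
               nrow(dose), ncol(dose), length(pos1), length(pos2))
  if (anyNA(dose) || any(dose < 0))
    tdeg_error("invalid_plane", "plane dose must be finite and >= 0")
  if (is.null(axes))
    axes <- switch(orientation, transverse = c("x", "y"),
                   coronal = c("x", "z"), sagittal = c("y", "z"))
  structure(list(pos1 = as.numeric(pos1), pos2 = as.numeric(pos2),
                 dose = dose, orientation = orientation,
                 coordinate = coordinate, axes = axes),
            class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("<dose_plane> %s (%s-%s) at %s = %g cm, %d x %d points\n",
              x$orientation, x$axes[1], x$axes[2],
              setdiff(c("x", "y", "z"), x$axes)[1], x$coordinate,
              length(x$pos1), length(x$pos2)))
  invisible(x)
}

#' Extract a planar slice from a dose grid
#'
#' Samples the voxel layer whose center is nearest the requested coordinate
#' (ties broken toward the smaller coordinate).  The returned plane records
#' the coordinate actually used.
#'
#' @param grid A [dose_grid()].
#' @param orientation `"coronal"` (fixed y), `"transverse"` (fixed z) or
#'   `"sagittal"` (fixed x).
#' @param coordinate Requested coordinate along the fixed axis, cm; must lie
#'   within the grid extent.
#' @return A [dose_plane()].
#' @export
extract_plane <- function(grid,
                          orientation = c("coronal", "transverse", "sagittal"),
                          coordinate = 0) {
  stopifnot(inherits(grid, "dose_grid"))
  orientation <- match.arg(orientation)
  ax <- switch(orientation, coronal = "y", transverse = "z", sagittal = "x")
  b <- grid[[paste0(ax, "_bounds")]]
  if (coordinate < min(b) || coordinate > max(b))
    tdeg_error("range", "coordinate %g cm outside grid extent [%g, %g] on %s",
               coordinate, min(b), max(b), ax)
  cen <- voxel_centers(grid, ax)
  d <- abs(cen - coordinate)
  layer <- which(d == min(d))[1]  # centers ascending: first match = smaller
  sl <- switch(ax,
               x = grid$dose[layer, , , drop = FALSE],
               y = grid$dose[, layer, , drop = FALSE],
               z = grid$dose[, , layer, drop = FALSE])
  sl <- matrix(sl, nrow = dim(sl)[c(x = 2L, y = 1L, z = 1L)[ax]],
               ncol = dim(sl)[c(x = 3L, y = 3L, z = 2L)[ax]])
  axes <- switch(orientation, transverse = c("x", "y"),
                 coronal = c("x", "z"), sagittal = c("y", "z"))
  dose_plane(voxel_centers(grid, axes[1]), voxel_centers(grid, axes[2]),
             sl, orientation, coordinate = cen[layer], axes = axes)
}
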