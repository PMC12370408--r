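# Target geometry and degradation scenarios.  A degraded photon target is
# modeled as a cylindrical vacuum zone burned into the tungsten button (and,
# for severe cases, into the copper base beneath it), described by a hole
# depth and width in mm.

#' Photon-target layer geometry
#'
#' Default thicknesses match the C-series tungsten-on-copper target: a
#' 0.889 mm tungsten button on a 1.575 mm copper base.
#'
#' @param tungsten_thickness Tungsten layer thickness, mm.
#' @param copper_thickness Copper base thickness, mm.
#' @return An object of class `target_geometry`.
#' @export
target_geometry <- function(tungsten_thickness = 0.889,
                            copper_thickness = 1.575) {
  stopifnot(tungsten_thickness > 0, copper_thickness > 0)
  structure(list(tungsten_thickness = tungsten_thickness,
                 copper_thickness = copper_thickness),
            class = "target_geometry")
}

#' Define a target degradation scenario
#'
#' @param name Scenario label, e.g. `"D0.6W2.0"`.
#' @param depth Hole depth, mm (0 for the nominal condition).
#' @param width Hole (cylinder) diameter, mm; must be positive whenever
#'   `depth > 0`.
#' @param geometry A [target_geometry()]; the hole may not exceed the total
#'   target thickness.
#' @return An object of class `degradation_scenario`.
#' @export
degradation_scenario <- function(name, depth, width,
                                 geometry = target_geometry()) {
  if (depth < 0 || width < 0)
    tdeg_error("invalid_scenario", "depth and width must be >= 0")
  if (depth > 0 && width <= 0)
    tdeg_error("invalid_scenario", "a degraded scenario (depth > 0) needs width > 0")
  total <- geometry$tungsten_thickness + geometry$copper_thickness
  if (depth > total)
    tdeg_error("invalid_scenario", "depth %.3f mm exceeds total target thickness %.3f mm",
               depth, total)
  structure(list(name = as.character(name), depth = depth, width = width),
            class = "degradation_scenario")
}

#' @export
print.degradation_scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: depth %.3f mm, width %.1f mm\n",
              x$name, x$depth, x$width))
  invisible(x)
}

#' Build a scenario library
#'
#' @param scenarios List of [degradation_scenario()] objects; names must be
#'   unique and the nominal condition `"NC"` must appear exactly once.
#' @return An object of class `scenario_library` (a named list).
#' @export
scenario_library <- function(scenarios) {
  nms <- vapply(scenarios, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    tdeg_error("invalid_library", "duplicate scenario names: %s",
               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (sum(nms == "NC") != 1L)
    tdeg_error("invalid_library", "library must contain the nominal condition NC exactly once")
  structure(setNames(scenarios, nms), class = "scenario_library")
}

#' @export
print.scenario_library <- function(x, ...) {
  cat(sprintf("<scenario_library> %d scenarios\n", length(x)))
  df <- data.frame(name = names(x),
                   depth_mm = vapply(x, `[[`, numeric(1), "depth"),
                   width_mm = vapply(x, `[[`, numeric(1), "width"),
                   row.names = NULL)
  print(df)
  invisible(x)
}

#' The built-in degradation scenario library
#'
#' The twelve named conditions used throughout the analysis: the nominal
#' target NC; progressively deeper 1 mm-wide holes (D0.1--D0.7) plus the
#' widened D0.6W2.0; full tungsten burn-through at 1 and 2 mm width (W1,
#' W2); burn-through plus 1 mm of copper (WC); and full two-layer
#' degradation at 2 and 3 mm width (Z2, Z3).
#'
#' @param geometry A [target_geometry()].
#' @return A [scenario_library()] with 12 entries.
#' @export
builtin_library <- function(geometry = target_geometry()) {
  tw <- geometry$tungsten_thickness
  rows <- list(
    c("NC", 0, 0),
    c("D0.1", 0.1, 1.0),
    c("D0.3", 0.3, 1.0),
    c("D0.5", 0.5, 1.0),
    c("D0.6", 0.6, 1.0),
    c("D0.6W2.0", 0.6, 2.0),
    c("D0.7", 0.7, 1.0),
    c("W1", tw, 1.0),
    c("W2", tw, 2.0),
    c("WC", tw + 1.0, 2.0),
    c("Z2", tw + 1.575, 2.0),
    c("Z3", tw + 1.575, 3.0)
  )
  scenario_library(lapply(rows, function(r)
    degradation_scenario(r[1], as.numeric(r[2]), as.numeric(r[3]), geometry)))
}

#' Fine depth/width sweep of scenarios
#'
#' Generates a grid of scenarios in 0.2 mm increments (the resolution used
#' to localize realistic degradation), named `D<depth>W<width>`.
#'
#' @param depths,widths Numeric vectors in mm.
#' @param geometry A [target_geometry()].
#' @param include_nc Prepend the nominal condition.
#' @return A [scenario_library()].
#' @export
sweep_library <- function(depths = seq(0.1, 0.7, by = 0.2),
                          widths = seq(1.0, 2.0, by = 0.2),
                          geometry = target_geometry(), include_nc = TRUE) {
  sc <- list()
  if (include_nc) sc <- list(degradation_scenario("NC", 0, 0, geometry))
  for (d in depths) for (w in widths)
    sc <- c(sc, list(degradation_scenario(sprintf("D%.1fW%.1f", d, w), d, w,
                                          geometry)))
  scenario_library(sc)
}

resolve_scenario <- function(scenario, library = builtin_library()) {
  if (inherits(scenario, "degradation_scenario")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1L) {
    if (scenario %in% names(library)) return(library[[scenario]])
    # names of the fine-sweep form D<depth>[W<width>] resolve directly
    m <- regmatches(scenario,
                    regexec("^D([0-9]*\\.?[0-9]+)(W([0-9]*\\.?[0-9]+))?$",
                            scenario))[[1]]
    if (length(m)) {
      w <- if (nzchar(m[4])) as.numeric(m[4]) else 1.0
      return(degradation_scenario(scenario, as.numeric(m[2]), w))
    }
    tdeg_error("unknown_scenario", "unknown scenario '%s'", scenario)
  }
  tdeg_error("unknown_scenario", "scenario must be a name or a degradation_scenario")
}

#' Dimensionless degradation severity
#'
#' Collapses a (depth, width) scenario onto a single non-negative scalar,
#' `(depth / tungsten_thickness)^a * (width / w0)^b`, zero for the nominal
#' condition.  With `a > b > 0` the scalar rises much faster with hole depth
#' than with width, mirroring the observed output response.  The defaults
#' (`a = 3`, `b = 0.5`, `w0 = 1` mm) give `severity = 1` for full tungsten
#' burn-through at 1 mm width.
#'
#' @param scenario A [degradation_scenario()] (or a name in `library`).
#' @param geometry A [target_geometry()].
#' @param a Depth exponent (> 0).
#' @param b Width exponent (> 0).
#' @param w0 Width scale, mm.
#' @param library Library used to resolve scenario names.
#' @return Non-negative numeric severity.
#' @export
severity <- function(scenario, geometry = target_geometry(),
                     a = 3, b = 0.5, w0 = 1, library = builtin_library()) {
  s <- resolve_scenario(scenario, library)
  stopifnot(a > 0, b > 0, w0 > 0)
  if (s$depth < 0 || s$width < 0)
    tdeg_error("invalid_scenario", "negative depth or width")
  if (s$depth == 0) return(0)
  (s$depth / geometry$tungsten_thickness)^a * (s$width / w0)^b
}

#' Read scenarios from a JSON or YAML configuration file
#'
#' The file holds a list of flat records with fields `name`, `depth_mm`,
#' `width_mm` (either a top-level array or under a `scenarios` key).  The
#' nominal condition NC is added if absent.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param geometry A [target_geometry()].
#' @return A [scenario_library()].
#' @export
read_scenarios <- function(path, geometry = target_geometry()) {
  if (!file.exists(path))
    tdeg_error("config", "config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$scenarios)) cfg <- cfg$scenarios
  sc <- lapply(cfg, function(r) {
    if (is.null(r$name) || is.null(r$depth_mm) || is.null(r$width_mm))
      tdeg_error("config", "each scenario record needs name, depth_mm, width_mm")
    degradation_scenario(r$name, r$depth_mm, r$width_mm, geometry)
  })
  if (!"NC" %in% vapply(sc, `[[`, character(1), "name"))
    sc <- c(list(degradation_scenario("NC", 0, 0, geometry)), sc)
  scenario_library(sc)
}
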