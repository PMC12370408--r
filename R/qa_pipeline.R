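# Orchestration: scenario sweeps over generated (or supplied) fields,
# degradation-detection rules, the Friedman comparison of deviation
# factors, and tidy CSV reporting.

#' Degradation detection rules
#'
#' Thresholds on the sweep metrics that flag a degrading target: sudden
#' output changes beyond the daily (3%) and weekly (6%) safety levels; a
#' diagonal profile deviation above 3% in the 0.95 field-size region for
#' large (>= 30 cm) fields; and a 1% any-profile action level for routine
#' checks.
#'
#' @param daily_output Daily output-change threshold, percent.
#' @param weekly_output Weekly output-change threshold, percent.
#' @param diagonal_dev Large-field diagonal 0.95-region threshold, percent.
#' @param any_profile_dev Any-field, any-axis action level, percent.
#' @param diagonal_min_field Minimum field size for the diagonal rule, cm.
#' @return An object of class `detection_rules`.
#' @export
detection_rules <- function(daily_output = 3, weekly_output = 6,
                            diagonal_dev = 3, any_profile_dev = 1,
                            diagonal_min_field = 30) {
  stopifnot(daily_output > 0, weekly_output > 0, diagonal_dev > 0,
            any_profile_dev > 0)
  structure(list(daily_output = daily_output, weekly_output = weekly_output,
                 diagonal_dev = diagonal_dev,
                 any_profile_dev = any_profile_dev,
                 diagonal_min_field = diagonal_min_field),
            class = "detection_rules")
}

#' Run a degradation sweep
#'
#' Generates nominal and degraded fields for every scenario in the
#' library, computes all QA metrics against the nominal-condition
#' baseline (output deviation at 10 cm depth, PDD20,10 deviation, maximum
#' profile deviations in the 0.8/0.95 regions along the diagonal and x
#' axes at 5 and 10 cm depth, flatness, ROF and wedge-factor deviations)
#' and applies the detection rules.  Deterministic under a fixed seed.
#'
#' Profiles are resampled to 1 mm and Savitzky-Golay smoothed before the
#' deviation and flatness metrics, matching water-phantom scan practice.
#'
#' @param library A [scenario_library()] containing NC.
#' @param fields Field sizes to sweep, cm.
#' @param params A [beam_params()].
#' @param rules A [detection_rules()].
#' @param noise Per-voxel noise sigma (default from `params`).
#' @param seed Integer seed; every generated field derives its noise
#'   stream from it.
#' @param depths Profile evaluation depths, cm.
#' @param axes Profile axes to evaluate.
#' @param wedge Also sweep 30-degree wedge fields (adds wedge-field
#'   deviations and wedge factors).
#' @param z_extent Depth extent of generated grids, cm (>= 20 needed for
#'   PDD20,10).
#' @return An object of class `sweep_result`: `$summary` (one row per
#'   scenario x field with metrics and flags) and `$deviations` (long
#'   table of maximum profile deviations per axis/depth/region/wedge).
#' @export
run_sweep <- function(library = builtin_library(), fields = c(10, 20, 30),
                      params = beam_params(), rules = detection_rules(),
                      noise = params$noise, seed = 1L,
                      depths = c(5, 10), axes = c("diagonal", "x"),
                      wedge = FALSE, z_extent = 30) {
  if (!"NC" %in% names(library))
    tdeg_error("missing_nc", "scenario library must contain the nominal condition NC")
  factors <- correction_factors(
    r_ch = c(setNames(
      vapply(library, function(s) rch_model(s, params), numeric(1)),
      names(library))))
  scen_names <- names(library)
  summary_rows <- list()
  dev_rows <- list()
  seed_of <- function(i, f, w) {
    (seed * 97L + i * 1009L + round(f) * 13L + w) %% .Machine$integer.max
  }
  # generate all fields once (NC first so baselines exist)
  fields_by <- list()
  for (i in seq_along(scen_names)) {
    nm <- scen_names[i]
    for (f in fields) {
      spec <- grid_spec(f, z_extent = z_extent)
      fields_by[[key_of(nm, f, FALSE)]] <-
        generate_field(library[[nm]], f, params, spec = spec, wedge = FALSE,
                       noise = noise, seed = seed_of(i, f, 0L))
      if (wedge)
        fields_by[[key_of(nm, f, TRUE)]] <-
          generate_field(library[[nm]], f, params, spec = spec, wedge = TRUE,
                         noise = noise, seed = seed_of(i, f, 1L))
    }
  }
  prep_profile <- function(fld, axis, depth) {
    pr <- extract_profile(fld, axis = axis, depth = depth, normalize = FALSE)
    normalize_profile(smooth_profile(resample_curve(pr, 0.1)))
  }
  ref10_out <- if (10 %in% fields)
    beam_output(fields_by[[key_of("NC", 10, FALSE)]]) else NA_real_
  for (nm in scen_names) {
    for (f in fields) {
      fld <- fields_by[[key_of(nm, f, FALSE)]]
      base <- fields_by[[key_of("NC", f, FALSE)]]
      self_baseline <- nm == "NC"
      out <- beam_output(fld)
      out_dev <- output_deviation(out, beam_output(base))
      prep_pdd <- function(ff)
        pdd_ratio_20_10(smooth_profile(resample_curve(extract_pdd(ff), 0.1)))
      pdd <- prep_pdd(fld)
      pdd_base <- prep_pdd(base)
      devs <- list()
      for (ax in axes) for (dp in depths) for (wg in
        c(FALSE, if (wedge) TRUE)) {
        tfld <- fields_by[[key_of(nm, f, wg)]]
        bfld <- fields_by[[key_of("NC", f, wg)]]
        tp <- prep_profile(tfld, ax, dp)
        bp <- if (self_baseline && !wg) tp else prep_profile(bfld, ax, dp)
        if (self_baseline && wg) bp <- tp
        for (rg in c(0.8, 0.95)) {
          dm <- deviation_max(tp, bp, region_fraction = rg)
          dev_rows[[length(dev_rows) + 1L]] <- data.frame(
            scenario = nm, field = f, axis = ax, depth = dp,
            wedge = wg, region = rg,
            dev_pct = max(dm$negative$max_pct, dm$positive$max_pct))
        }
      }
      diag10 <- prep_profile(fld, "diagonal", 10)
      diag10_b <- if (self_baseline) diag10 else prep_profile(base, "diagonal", 10)
      dm95 <- deviation_max(diag10, diag10_b, 0.95)
      dm80 <- deviation_max(diag10, diag10_b, 0.8)
      flat <- flatness(diag10, 0.8)
      have_rof <- 10 %in% fields &&
        format(f, trim = TRUE) %in% names(factors$f_backscatter)
      rof_val <- if (have_rof)
        rof(out, beam_output(fields_by[[key_of(nm, 10, FALSE)]]), f, factors)
      else NA_real_
      rof_base <- if (have_rof) rof(beam_output(base), ref10_out, f, factors)
      else NA_real_
      wf_dev <- NA_real_
      if (wedge) {
        zc <- params$z_max
        wf_val <- wedge_factor(
          beam_output(fields_by[[key_of(nm, f, TRUE)]], depth = zc),
          beam_output(fld, depth = zc))
        wf_base <- wedge_factor(
          beam_output(fields_by[[key_of("NC", f, TRUE)]], depth = zc),
          beam_output(base, depth = zc))
        wf_dev <- if (self_baseline) 0 else output_deviation(wf_val, wf_base)
      }
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        scenario = nm, field = f,
        severity = model_severity(library[[nm]], params),
        output_dev_pct = if (self_baseline) 0 else out_dev,
        pdd2010 = pdd,
        pdd2010_dev_pct = if (self_baseline) 0 else
          output_deviation(pdd, pdd_base),
        dev_diag_095_pct = max(dm95$negative$max_pct, dm95$positive$max_pct),
        dev_diag_08_pct = max(dm80$negative$max_pct, dm80$positive$max_pct),
        flatness_pct = flat,
        rof = rof_val,
        rof_dev_pct = if (self_baseline) 0 else if (have_rof)
          output_deviation(rof_val, rof_base) else NA_real_,
        wf_dev_pct = wf_dev)
    }
  }
  summary <- do.call(rbind, summary_rows)
  deviations <- do.call(rbind, dev_rows)
  res <- structure(list(summary = summary, deviations = deviations,
                        rules = rules, fields = fields, seed = seed,
                        noise = noise),
                   class = "sweep_result")
  res$summary <- cbind(summary, apply_rules(res, rules))
  res
}

key_of <- function(nm, f, wedge) sprintf("%s|%g|%d", nm, f, as.integer(wedge))

#' Apply detection rules to a sweep
#'
#' Evaluates each threshold against the sweep metrics and returns one
#' logical flag column per rule.  Raising any threshold can only clear
#' flags, never add them.
#'
#' @param sweep A [run_sweep()] result.
#' @param rules A [detection_rules()].
#' @return Data frame of logical columns `flag_output_daily`,
#'   `flag_output_weekly`, `flag_diagonal`, `flag_action`, and `flagged`
#'   (any of them), aligned with `sweep$summary` rows.
#' @export
apply_rules <- function(sweep, rules = detection_rules()) {
  s <- sweep$summary[c("scenario", "field", "output_dev_pct",
                       "dev_diag_095_pct")]
  max_dev <- tapply(sweep$deviations$dev_pct,
                    list(sweep$deviations$scenario, sweep$deviations$field),
                    max)
  any_dev <- mapply(function(nm, f) max_dev[nm, as.character(f)],
                    s$scenario, s$field)
  out <- data.frame(
    flag_output_daily = abs(s$output_dev_pct) > rules$daily_output,
    flag_output_weekly = abs(s$output_dev_pct) > rules$weekly_output,
    flag_diagonal = s$field >= rules$diagonal_min_field &
      s$dev_diag_095_pct > rules$diagonal_dev,
    flag_action = any_dev > rules$any_profile_dev)
  out$flagged <- out$flag_output_daily | out$flag_output_weekly |
    out$flag_diagonal | out$flag_action
  rownames(out) <- NULL
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d scenarios x %d fields (noise %.3g, seed %s)\n",
              length(unique(x$summary$scenario)), length(x$fields),
              x$noise, format(x$seed)))
  cols <- c("scenario", "field", "output_dev_pct", "pdd2010_dev_pct",
            "dev_diag_095_pct", "flagged")
  print(x$summary[cols], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Friedman rank test
#'
#' Nonparametric repeated-measures comparison of k treatments over n
#' blocks: values are ranked within each block (mean ranks on ties) and
#' the statistic \deqn{\chi^2_F = \frac{12 n}{k(k+1)} \sum_j \bar R_j^2 -
#' 3 n (k+1)} is referred to the chi-squared distribution with k - 1
#' degrees of freedom.
#'
#' @param blocks Numeric matrix, one row per block, one column per
#'   treatment (no missing cells, k >= 2, n >= 2).
#' @return List of class `friedman_test` with `statistic`, `df`,
#'   `p.value`.
#' @export
friedman_test <- function(blocks) {
  blocks <- as.matrix(blocks)
  n <- nrow(blocks); k <- ncol(blocks)
  if (k < 2L)
    tdeg_error("friedman", "need at least 2 treatments (columns)")
  if (n < 2L)
    tdeg_error("friedman", "need at least 2 blocks (rows)")
  if (anyNA(blocks))
    tdeg_error("friedman", "missing cells are not supported")
  ranks <- t(apply(blocks, 1, rank))
  rj <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  structure(list(statistic = stat, df = k - 1L,
                 p.value = pchisq(stat, k - 1L, lower.tail = FALSE),
                 n_blocks = n, n_treatments = k),
            class = "friedman_test")
}

#' @export
print.friedman_test <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4g, df = %d, p-value = %.4g (%d blocks x %d treatments)\n",
              x$statistic, x$df, x$p.value, x$n_blocks, x$n_treatments))
  invisible(x)
}

#' Friedman comparison of deviation factors
#'
#' Runs one Friedman test per factor of interest (axis, region, depth,
#' and open/wedge if present) on the long deviation table of a sweep for
#' one scenario, blocking on all remaining factor combinations.
#'
#' @param sweep A [run_sweep()] result.
#' @param scenario Scenario whose deviations are compared.
#' @return Named list of `friedman_test` results.
#' @export
compare_deviation_factors <- function(sweep, scenario = "W1") {
  d <- sweep$deviations[sweep$deviations$scenario == scenario, ]
  if (!nrow(d))
    tdeg_error("friedman", "no deviations for scenario '%s'", scenario)
  one <- function(factor_col) {
    lv <- sort(unique(d[[factor_col]]))
    if (length(lv) < 2L) return(NULL)
    others <- setdiff(c("field", "axis", "depth", "region", "wedge"),
                      factor_col)
    blk <- interaction(d[others], drop = TRUE)
    m <- tapply(d$dev_pct, list(blk, d[[factor_col]]), mean)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 2L) return(NULL)
    friedman_test(m)
  }
  out <- list(axis = one("axis"), region = one("region"),
              depth = one("depth"), wedge = one("wedge"))
  out[!vapply(out, is.null, logical(1))]
}

#' Write a sweep report
#'
#' Writes the tidy metric summary (with flags) and the long deviation
#' table as CSV files; reruns on identical input are byte-identical.
#'
#' @param sweep A [run_sweep()] result.
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(sweep, dir) {
  stopifnot(inherits(sweep, "sweep_result"), nrow(sweep$summary) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- file.path(dir, c("sweep_summary.csv", "sweep_deviations.csv"))
  write.csv(sweep$summary, fs[1], row.names = FALSE)
  write.csv(sweep$deviations, fs[2], row.names = FALSE)
  invisible(fs)
}
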