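# 2-D gamma-index comparison of dose planes (global normalization).  For
# every reference point above the low-dose cutoff,
#   gamma = min over nearby test positions of
#           sqrt( (dD / (dd% * D_norm))^2 + (dr / dta)^2 )
# with the test dose bilinearly interpolated on a sub-voxel search lattice.

#' Gamma-analysis criteria
#'
#' @param dd Dose-difference criterion, percent of the normalization dose.
#' @param dta Distance-to-agreement criterion, mm.
#' @param cutoff Low-dose cutoff, percent of the normalization dose;
#'   reference points below it are not evaluated.
#' @param step_frac Interpolation step of the search lattice, as a
#'   fraction of the DTA.
#' @param radius_frac Maximum search radius, in multiples of the DTA.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dd = 3, dta = 2, cutoff = 10,
                           step_frac = 0.1, radius_frac = 2) {
  stopifnot(dd > 0, dta > 0, cutoff >= 0, cutoff < 100,
            step_frac > 0, radius_frac >= 1)
  structure(list(dd = dd, dta = dta, cutoff = cutoff,
                 step_frac = step_frac, radius_frac = radius_frac),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm, %g%% cutoff (step %g DTA, radius %g DTA)\n",
              x$dd, x$dta, x$cutoff, x$step_frac, x$radius_frac))
  invisible(x)
}

# Bilinear interpolation on a plane; NA outside its extent.
interp_plane <- function(plane, qx, qy) {
  p1 <- plane$pos1; p2 <- plane$pos2
  out <- rep(NA_real_, length(qx))
  ok <- qx >= p1[1] & qx <= p1[length(p1)] &
    qy >= p2[1] & qy <= p2[length(p2)]
  if (!any(ok)) return(out)
  i <- locate(p1, qx[ok]); j <- locate(p2, qy[ok])
  fx <- frac(p1, qx[ok], i); fy <- frac(p2, qy[ok], j)
  d <- plane$dose
  v <- d[cbind(i, j)] * (1 - fx) * (1 - fy) +
    d[cbind(i + 1L, j)] * fx * (1 - fy) +
    d[cbind(i, j + 1L)] * (1 - fx) * fy +
    d[cbind(i + 1L, j + 1L)] * fx * fy
  out[ok] <- v
  out
}

#' 2-D gamma-index map and pass rate
#'
#' Computes the global-normalization gamma index of `test` against
#' `reference` at every reference point above the low-dose cutoff,
#' searching test positions within `radius_frac * dta` of each point on a
#' lattice of step `step_frac * dta` (bilinear dose interpolation).  A
#' point passes when gamma <= 1.
#'
#' @param reference,test [dose_plane()]s; they must overlap spatially and
#'   the reference maximum must be positive.
#' @param criteria A [gamma_criteria()].
#' @return An object of class `gamma_result`: the gamma map (NA below
#'   cutoff), evaluated/passing counts, `pass_rate` in percent, and the
#'   criteria.
#' @export
gamma_map <- function(reference, test, criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "dose_plane"), inherits(test, "dose_plane"))
  dnorm_ <- max(reference$dose)
  if (dnorm_ <= 0)
    tdeg_error("range", "reference plane has zero maximum dose")
  if (min(test$pos1) > max(reference$pos1) ||
      max(test$pos1) < min(reference$pos1) ||
      min(test$pos2) > max(reference$pos2) ||
      max(test$pos2) < min(reference$pos2))
    tdeg_error("range", "reference and test planes do not overlap")
  dta_cm <- criteria$dta / 10
  step <- criteria$step_frac * dta_cm
  rad <- criteria$radius_frac * dta_cm
  off <- seq(-rad, rad, by = step)
  og <- expand.grid(dx = off, dy = off)
  keep <- og$dx^2 + og$dy^2 <= rad^2 + 1e-12
  og <- og[keep, ]
  dr2 <- (og$dx^2 + og$dy^2) / dta_cm^2
  n1 <- length(reference$pos1); n2 <- length(reference$pos2)
  px <- rep(reference$pos1, times = n2)
  py <- rep(reference$pos2, each = n1)
  dref <- as.vector(reference$dose)
  eval_pt <- dref >= criteria$cutoff / 100 * dnorm_
  gam <- rep(NA_real_, n1 * n2)
  idx <- which(eval_pt)
  dd_abs <- criteria$dd / 100 * dnorm_
  # loop over search offsets (few hundred), vectorized over all points
  g2 <- rep(Inf, length(idx))
  for (k in seq_len(nrow(og))) {
    dt <- interp_plane(test, px[idx] + og$dx[k], py[idx] + og$dy[k])
    cand <- ((dt - dref[idx]) / dd_abs)^2 + dr2[k]
    upd <- !is.na(cand) & cand < g2
    g2[upd] <- cand[upd]
  }
  gam[idx] <- sqrt(g2)
  gmat <- matrix(gam, n1, n2)
  n_eval <- length(idx)
  n_pass <- sum(gam[idx] <= 1 + 1e-12, na.rm = TRUE)
  structure(list(gamma = gmat, pos1 = reference$pos1, pos2 = reference$pos2,
                 n_evaluated = n_eval, n_pass = n_pass,
                 pass_rate = if (n_eval > 0) 100 * n_pass / n_eval else NA_real_,
                 criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: pass rate %.1f%% (%d / %d points)\n",
              x$criteria$dd, x$criteria$dta, x$pass_rate, x$n_pass,
              x$n_evaluated))
  invisible(x)
}

#' @export
plot.gamma_result <- function(x, ...) {
  image(x$pos1, x$pos2, x$gamma, xlab = "x (cm)", ylab = "y (cm)",
        main = sprintf("gamma %g%%/%g mm", x$criteria$dd, x$criteria$dta),
        ...)
  invisible(x)
}

#' Gamma and pass flags along a central line
#'
#' Extracts the gamma values along the central line of the map in the
#' stated direction (the row/column nearest zero on the other axis),
#' summarizing where failures sit relative to the center.
#'
#' @param result A [gamma_result()].
#' @param axis `"x"` (vary pos1 at pos2 nearest 0) or `"y"`.
#' @return Data frame with `position`, `gamma`, `pass`.
#' @export
pass_rate_profile <- function(result, axis = c("x", "y")) {
  stopifnot(inherits(result, "gamma_result"))
  axis <- match.arg(axis)
  if (axis == "x") {
    j <- which.min(abs(result$pos2))
    data.frame(position = result$pos1, gamma = result$gamma[, j],
               pass = !is.na(result$gamma[, j]) & result$gamma[, j] <= 1 + 1e-12)
  } else {
    i <- which.min(abs(result$pos1))
    data.frame(position = result$pos2, gamma = result$gamma[i, ],
               pass = !is.na(result$gamma[i, ]) & result$gamma[i, ] <= 1 + 1e-12)
  }
}
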