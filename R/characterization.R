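# Sensor performance metrics derived from the forward model (sensitivity,
# linear range) and from calibration statistics (resolution, LOD/LOQ,
# quantification of unknowns).

#' Default decade concentration grid
#'
#' The mantissa-{1, 2.5, 5} decade grid spanning `lo` to `hi`, the working
#' grid for sensitivity curves.
#'
#' @param lo,hi Grid limits \[M\], defaults 1e-8 and 1e-5.
#' @return Ascending concentrations \[M\].
#' @export
default_concentration_grid <- function(lo = 1e-8, hi = 1e-5) {
  dec <- 10^(floor(log10(lo)):ceiling(log10(hi)))
  g <- sort(unique(as.vector(outer(c(1, 2.5, 5), dec))))
  g[g >= lo * (1 - 1e-12) & g <= hi * (1 + 1e-12)]
}

#' Model-predicted sensitivity curve
#'
#' Evaluates the forward model (Langmuir occupancy, exponential approach over
#' the accumulation time, moles-to-current conversion) over a concentration
#' grid at a fixed accumulation time.
#'
#' @param t_acc Accumulation time \[s\].
#' @param params A [kinetic_params()] object.
#' @param config An [electrochem_config()] object.
#' @param grid Ascending positive concentrations \[M\];
#'   default [default_concentration_grid()].
#' @return An object of class `sensitivity_curve`: a data.frame with columns
#'   `concentration`, `bound`, `ipa`, and attribute `t_acc`.
#' @export
sensitivity_curve <- function(t_acc, params, config,
                              grid = default_concentration_grid()) {
  .check_params(params, need_rates = TRUE)
  .check_config(config)
  if (length(grid) == 0) stop("'grid' must be non-empty", call. = FALSE)
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    stop("'grid' must be strictly positive and ascending [M]", call. = FALSE)
  }
  bound <- adsorption_at_time(grid, t_acc, params)
  structure(
    data.frame(concentration = grid, bound = bound,
               ipa = bound_to_current(bound, config)),
    class = c("sensitivity_curve", "data.frame"), t_acc = t_acc)
}

#' Algorithmic linear range of a sensitivity curve
#'
#' Finds the widest contiguous grid window (at least 3 points) whose ordinary
#' least-squares line leaves every member point within `tolerance` relative
#' deviation of its observed value. Ties on width are broken toward the
#' window with the lower low end. This is an algorithmic stand-in for the
#' visual judgement traditionally used; the tolerance is exposed.
#'
#' @param curve A [sensitivity_curve()] (or data.frame with `concentration`
#'   and `ipa`) with at least 4 grid points.
#' @param tolerance Maximum relative deviation from the window's OLS line
#'   (default 0.10).
#' @return A list with `found` (logical), `low`, `high` \[M\], and the
#'   member indices. `found = FALSE` (not an error) when no window of >= 3
#'   points satisfies the tolerance.
#' @export
linear_range <- function(curve, tolerance = 0.10) {
  if (!all(c("concentration", "ipa") %in% names(curve))) {
    stop("'curve' must have 'concentration' and 'ipa' columns", call. = FALSE)
  }
  n <- nrow(curve)
  if (n < 4) stop("linear_range requires at least 4 grid points", call. = FALSE)
  x <- curve$concentration
  y <- curve$ipa
  best <- NULL
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      idx <- i:j
      fit <- stats::lm.fit(cbind(1, x[idx]), y[idx])
      pred <- cbind(1, x[idx]) %*% fit$coefficients
      dev <- abs(pred - y[idx]) / pmax(abs(y[idx]), .Machine$double.xmin)
      if (all(dev <= tolerance)) {
        w <- j - i
        if (is.null(best) || w > best$w || (w == best$w && i < best$i)) {
          best <- list(w = w, i = i, j = j)
        }
      }
    }
  }
  if (is.null(best)) {
    return(list(found = FALSE, low = NA_real_, high = NA_real_,
                indices = integer(0)))
  }
  list(found = TRUE, low = x[best$i], high = x[best$j],
       indices = best$i:best$j)
}

#' Sensitivity (calibration slope) over a concentration window
#'
#' Ordinary least-squares slope (with intercept) of predicted or measured
#' peak current against concentration, restricted to grid points inside the
#' window (inclusive).
#'
#' @param curve A [sensitivity_curve()] or data.frame with `concentration`
#'   and `ipa`.
#' @param range Numeric length-2 `c(low, high)` \[M\], or the result of
#'   [linear_range()].
#' @param intercept Include an intercept in the regression? Default `TRUE`.
#' @return Sensitivity \[A/M\].
#' @export
sensitivity <- function(curve, range, intercept = TRUE) {
  if (is.list(range) && !is.null(range$low)) range <- c(range$low, range$high)
  lo <- range[1] * (1 - 1e-9)
  hi <- range[2] * (1 + 1e-9)
  idx <- curve$concentration >= lo & curve$concentration <= hi
  if (sum(idx) < 2) {
    stop("sensitivity requires at least 2 grid points inside the range",
         call. = FALSE)
  }
  x <- curve$concentration[idx]
  y <- curve$ipa[idx]
  if (intercept) {
    unname(stats::lm.fit(cbind(1, x), y)$coefficients[2])
  } else {
    sum(x * y) / sum(x * x)
  }
}

#' Resolution, limit of detection and limit of quantification
#'
#' Standard blank-noise figures of merit: resolution `3*sigma` \[A\],
#' `LOD = 3*sigma / S` and `LOQ = 10*sigma / S` \[M\], where `sigma` is the
#' standard deviation of the signal at the lowest (blank-like) concentration
#' and `S` the calibration sensitivity.
#'
#' @param sigma_blank Standard deviation of the blank/lowest-concentration
#'   signal \[A\].
#' @param sensitivity Calibration sensitivity \[A/M\].
#' @return A list with `resolution_3sigma` \[A\], `lod` \[M\], `loq` \[M\].
#' @examples
#' lod_loq(501e-9 / 3, 17.8)  # LOD 28.1 nM, LOQ 93.8 nM
#' @export
lod_loq <- function(sigma_blank, sensitivity) {
  if (!is.finite(sigma_blank) || sigma_blank <= 0) {
    stop("'sigma_blank' must be strictly positive [A]", call. = FALSE)
  }
  if (!is.finite(sensitivity) || sensitivity <= 0) {
    stop("'sensitivity' must be strictly positive [A/M]", call. = FALSE)
  }
  list(resolution_3sigma = 3 * sigma_blank,
       lod = 3 * sigma_blank / sensitivity,
       loq = 10 * sigma_blank / sensitivity)
}

#' Linear calibration for quantifying unknown samples
#'
#' Ordinary least-squares line through calibration pairs; the returned object
#' quantifies an unknown peak current as `(Ipa - intercept) / slope`.
#'
#' @param concentration Calibration concentrations \[M\] (>= 2 distinct).
#' @param ipa Calibration peak currents \[A\].
#' @return An object of class `linear_calibration` with `slope` \[A/M\] and
#'   `intercept` \[A\].
#' @export
calibrate_linear <- function(concentration, ipa) {
  if (length(concentration) != length(ipa)) {
    stop("'concentration' and 'ipa' must have equal length", call. = FALSE)
  }
  if (length(unique(concentration)) < 2) {
    stop("calibration requires at least 2 distinct concentrations",
         call. = FALSE)
  }
  co <- stats::lm.fit(cbind(1, concentration), ipa)$coefficients
  structure(list(slope = unname(co[2]), intercept = unname(co[1])),
            class = "linear_calibration")
}

#' Quantify an unknown sample against a linear calibration
#'
#' @param calibration A [calibrate_linear()] result.
#' @param ipa Measured peak current(s) \[A\].
#' @return Concentration(s) \[M\].
#' @export
quantify <- function(calibration, ipa) {
  stopifnot(inherits(calibration, "linear_calibration"))
  (ipa - calibration$intercept) / calibration$slope
}

#' Full model-based performance report
#'
#' Combines a model-predicted sensitivity curve, its algorithmic linear
#' range, the sensitivity over that range, and blank-noise LOD/LOQ into one
#' report.
#'
#' @param t_acc Accumulation time \[s\].
#' @param params A [kinetic_params()] object.
#' @param config An [electrochem_config()] object.
#' @param sigma_blank Blank signal standard deviation \[A\], or `NULL` to
#'   omit LOD/LOQ.
#' @param grid Concentration grid \[M\].
#' @param tolerance Linear-range tolerance.
#' @return A list of class `performance_report`.
#' @export
performance_report <- function(t_acc, params, config, sigma_blank = NULL,
                               grid = default_concentration_grid(),
                               tolerance = 0.10) {
  curve <- sensitivity_curve(t_acc, params, config, grid)
  rng <- linear_range(curve, tolerance)
  S <- if (rng$found) sensitivity(curve, rng) else NA_real_
  out <- list(t_acc = t_acc, sensitivity = S,
              linear_range = c(rng$low, rng$high),
              resolution_3sigma = NA_real_, lod = NA_real_, loq = NA_real_,
              curve = curve)
  if (!is.null(sigma_blank) && rng$found) {
    ll <- lod_loq(sigma_blank, S)
    out$resolution_3sigma <- ll$resolution_3sigma
    out$lod <- ll$lod
    out$loq <- ll$loq
  }
  structure(out, class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Sensor performance at t_acc = %g s\n", x$t_acc))
  cat(sprintf("  sensitivity : %.4g A/M\n", x$sensitivity))
  cat(sprintf("  linear range: %.3g - %.3g M\n",
              x$linear_range[1], x$linear_range[2]))
  if (is.finite(x$lod)) {
    cat(sprintf("  resolution  : %.4g A (3 sigma)\n", x$resolution_3sigma))
    cat(sprintf("  LOD / LOQ   : %.4g / %.4g M\n", x$lod, x$loq))
  }
  invisible(x)
}
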