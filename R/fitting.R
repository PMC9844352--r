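# Nonlinear least-squares estimation of binding parameters from calibration
# data: (K_D, ELD_tot) from an equilibrium isotherm, (k_on, k_off) from a
# fixed-concentration time course.

#' Tidy calibration measurement table
#'
#' Container for calibration data consumed by the fitters. In `isotherm` mode
#' `x` is concentration \[M\] and measurements were taken at equilibrium
#' (long accumulation, fresh electrode per point). In `timecourse` mode `x`
#' is accumulation time \[s\] at a fixed applied concentration `fixed_C`.
#' `y` is either peak current \[A\] or adsorbed moles \[mol\], flagged by
#' `y_unit`. Rows are sorted by `x` on construction.
#'
#' @param x Concentration \[M\] (isotherm) or accumulation time \[s\]
#'   (timecourse).
#' @param y Peak current \[A\] or bound analyte \[mol\].
#' @param mode One of `"isotherm"`, `"timecourse"`.
#' @param y_unit One of `"A"`, `"mol"`.
#' @param fixed_C Applied concentration \[M\]; required for timecourse mode.
#' @param replicate_id Optional grouping label per row.
#' @return A `data.frame` of class `measurement_table` with columns
#'   `x`, `y`, `replicate_id`.
#' @export
measurement_table <- function(x, y, mode = c("isotherm", "timecourse"),
                              y_unit = c("A", "mol"), fixed_C = NULL,
                              replicate_id = NULL) {
  mode <- match.arg(mode)
  y_unit <- match.arg(y_unit)
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("'x' and 'y' must be finite", call. = FALSE)
  }
  if (mode == "isotherm" && any(x <= 0)) {
    stop("isotherm concentrations must be strictly positive [M]",
         call. = FALSE)
  }
  if (mode == "timecourse") {
    if (any(x < 0)) {
      stop("accumulation times must be nonnegative [s]", call. = FALSE)
    }
    if (is.null(fixed_C) || !is.finite(fixed_C) || fixed_C <= 0) {
      stop("timecourse mode requires a strictly positive 'fixed_C' [M]",
           call. = FALSE)
    }
  }
  if (any(y < 0)) stop("'y' must be nonnegative", call. = FALSE)
  if (is.null(replicate_id)) replicate_id <- rep(NA_character_, length(x))
  ord <- order(x)
  out <- data.frame(x = x[ord], y = y[ord],
                    replicate_id = as.character(replicate_id)[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("measurement_table", "data.frame"),
            mode = mode, y_unit = y_unit, fixed_C = fixed_C)
}

#' Read a calibration CSV into a measurement table
#'
#' Expects columns `concentration_M` (isotherm) or `t_acc_s` (timecourse),
#' one of `ipa_A` / `bound_mol`, and optionally `replicate_id`. Lines
#' starting with `#` are treated as metadata and ignored; a
#' `# fixed_C_M = <value>` line supplies the applied concentration for
#' timecourse data (overridden by the `fixed_C` argument).
#'
#' @param path CSV file path.
#' @param fixed_C Applied concentration \[M\] for timecourse files.
#' @return A [measurement_table()].
#' @export
read_measurement_csv <- function(path, fixed_C = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  meta_lines <- grep("^#", readLines(path), value = TRUE)
  if (is.null(fixed_C)) {
    m <- regmatches(meta_lines,
                    regexec("fixed_C_M\\s*=\\s*([0-9.eE+-]+)", meta_lines))
    hit <- vapply(m, length, 1L) == 2L
    if (any(hit)) fixed_C <- as.numeric(m[[which(hit)[1]]][2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  if ("concentration_M" %in% names(df)) {
    mode <- "isotherm"; x <- df$concentration_M
  } else if ("t_acc_s" %in% names(df)) {
    mode <- "timecourse"; x <- df$t_acc_s
  } else {
    stop("CSV must contain a 'concentration_M' or 't_acc_s' column",
         call. = FALSE)
  }
  if ("ipa_A" %in% names(df)) {
    y_unit <- "A"; y <- df$ipa_A
  } else if ("bound_mol" %in% names(df)) {
    y_unit <- "mol"; y <- df$bound_mol
  } else {
    stop("CSV must contain an 'ipa_A' or 'bound_mol' column", call. = FALSE)
  }
  measurement_table(x, y, mode = mode, y_unit = y_unit, fixed_C = fixed_C,
                    replicate_id = df$replicate_id)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` of a prediction against observations.
#'
#' @param observed Observed values (length >= 2, nonzero variance).
#' @param predicted Predictions of equal length.
#' @return Dimensionless R^2 (at most 1; can be negative for poor fits).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) {
    stop("R^2 requires at least 2 observations", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R^2 is undefined: observed values have zero variance",
         call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

# Assemble the common fit-result container.
.fit_result <- function(estimates, units, observed, predicted, converged,
                        constraint_note, std_errors = NULL) {
  structure(
    list(estimates = estimates, units = units,
         std_errors = std_errors,
         r_squared = r_squared(observed, predicted),
         residuals = observed - predicted,
         fitted = predicted,
         converged = converged,
         constraint_note = constraint_note),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Nonlinear least-squares fit\n")
  for (nm in names(x$estimates)) {
    se <- if (!is.null(x$std_errors) && nm %in% names(x$std_errors)) {
      sprintf(" (SE %.3g)", x$std_errors[[nm]])
    } else ""
    cat(sprintf("  %-8s: %.6g %s%s\n", nm, x$estimates[[nm]],
                x$units[[nm]], se))
  }
  cat(sprintf("  R^2     : %.4f\n", x$r_squared))
  cat(sprintf("  converged: %s\n", x$converged))
  if (nzchar(x$constraint_note)) cat("  note: ", x$constraint_note, "\n")
  invisible(x)
}

# y on the bound (mol) scale regardless of input unit.
.as_bound <- function(data, config) {
  if (attr(data, "y_unit") == "A") current_to_bound(data$y, config) else data$y
}

#' Fit the equilibrium Langmuir isotherm
#'
#' Estimates `K_D` and `ELD_tot` by unweighted least squares of the Langmuir
#' isotherm `bound = C * ELD_tot / (K_D + C)` on the bound (mol) scale.
#' Current measurements are first converted to moles via the configured
#' moles-to-amperes factor (gain-corrected). Replicates enter as individual
#' points.
#'
#' @param data A [measurement_table()] in isotherm mode with at least 4
#'   distinct concentrations.
#' @param config An [electrochem_config()] used for the current-to-bound
#'   conversion.
#' @return A `fit_result` with estimates `K_D` \[M\] and `ELD_tot` \[mol\],
#'   Jacobian-based standard errors, residuals and R^2 on the bound scale.
#' @export
fit_isotherm <- function(data, config) {
  if (!inherits(data, "measurement_table") || attr(data, "mode") != "isotherm") {
    stop("'data' must be a measurement_table in isotherm mode", call. = FALSE)
  }
  .check_config(config)
  if (length(unique(data$x)) < 4) {
    stop("isotherm fitting requires at least 4 distinct concentrations",
         call. = FALSE)
  }
  C <- data$x
  b <- .as_bound(data, config)
  # Rescale the response to O(1): mol-scale sums of squares (~1e-22) defeat
  # the optimiser's absolute convergence tests.
  s <- max(b)
  if (s <= 0) stop("all responses are zero; nothing to fit", call. = FALSE)
  bs <- b / s
  df <- data.frame(C = C, bs = bs)
  start <- list(K_D = stats::median(C), E = 1.05)
  fit <- tryCatch(
    stats::nls(bs ~ C * E / (K_D + C), data = df, start = start,
               algorithm = "port", lower = c(K_D = 1e-30, E = 1e-30),
               control = stats::nls.control(maxiter = 1000, tol = 1e-12,
                                            warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # Fall back to direct SSE minimisation on log-parameters.
    sse <- function(p) sum((bs - C * exp(p[2]) / (exp(p[1]) + C))^2)
    opt <- stats::optim(log(unlist(start)), sse, method = "Nelder-Mead",
                        control = list(maxit = 10000, reltol = 1e-12))
    est <- exp(opt$par)
    pred <- C * est[2] / (est[1] + C)
    return(.fit_result(
      estimates = list(K_D = unname(est[1]), ELD_tot = unname(est[2]) * s),
      units = list(K_D = "M", ELD_tot = "mol"),
      observed = b, predicted = pred * s,
      converged = opt$convergence == 0,
      constraint_note = "direct-search fallback; no standard errors"))
  }
  co <- stats::coef(fit)
  est <- list(K_D = unname(co["K_D"]), ELD_tot = unname(co["E"]) * s)
  se <- tryCatch({
    ses <- summary(fit)$coefficients[, "Std. Error"]
    list(K_D = unname(ses["K_D"]), ELD_tot = unname(ses["E"]) * s)
  }, error = function(e) NULL)
  pred <- stats::predict(fit) * s
  .fit_result(
    estimates = est, units = list(K_D = "M", ELD_tot = "mol"),
    observed = b, predicted = pred,
    converged = fit$convInfo$isConv,
    constraint_note = "", std_errors = se)
}

#' Fit adsorption kinetics from a fixed-concentration time course
#'
#' Fits the exponential-approach model
#' `bound(t) = eq_bound * (1 - exp(-lambda * t))`, `lambda = C*k_on + k_off`,
#' to a time course at a single applied concentration. The equilibrium level
#' `eq_bound` is supplied externally (typically the averaged equilibrium
#' measurement at that concentration), matching experimental practice.
#'
#' A single-concentration time course identifies only the lumped rate
#' `lambda`, so the default `"constrained"` mode imposes
#' `k_off = K_D * k_on` (one free rate) using the supplied `K_D`.
#' `"lumped"` mode reports `lambda` alone with an identifiability caveat.
#' `"unconstrained"` mode is refused for single-concentration data.
#'
#' @param data A [measurement_table()] in timecourse mode.
#' @param eq_bound Equilibrium bound level at `fixed_C` \[mol\].
#' @param K_D Dissociation constant \[M\]; required for constrained mode.
#' @param config An [electrochem_config()] for unit conversion.
#' @param mode `"constrained"` (default), `"lumped"`, or `"unconstrained"`.
#' @return A `fit_result`. Constrained mode estimates `k_on` \[M^-1 s^-1\]
#'   and `k_off` \[s^-1\] (with `k_off/k_on = K_D` exactly by construction);
#'   lumped mode estimates `lambda` \[s^-1\].
#' @export
fit_kinetics <- function(data, eq_bound, K_D = NULL, config,
                         mode = c("constrained", "lumped", "unconstrained")) {
  mode <- match.arg(mode)
  if (!inherits(data, "measurement_table") ||
      attr(data, "mode") != "timecourse") {
    stop("'data' must be a measurement_table in timecourse mode",
         call. = FALSE)
  }
  .check_config(config)
  if (!is.finite(eq_bound) || eq_bound <= 0) {
    stop("'eq_bound' must be strictly positive [mol]", call. = FALSE)
  }
  C <- attr(data, "fixed_C")
  if (mode == "unconstrained") {
    stop(paste("both rates are not identifiable from a single-concentration",
               "time course; use mode = 'constrained' (with K_D) or 'lumped'"),
         call. = FALSE)
  }
  if (mode == "constrained" && (is.null(K_D) || !is.finite(K_D) || K_D <= 0)) {
    stop("constrained mode requires a strictly positive K_D [M]",
         call. = FALSE)
  }
  t <- data$x
  b <- .as_bound(data, config)

  # Log-linearised start: -log(1 - b/eq)/t averaged over interior points.
  frac <- pmin(pmax(b / eq_bound, 1e-12), 1 - 1e-12)
  ok <- t > 0 & frac < 0.999
  lam0 <- if (any(ok)) stats::median(-log(1 - frac[ok]) / t[ok]) else 1e-4
  lam0 <- max(lam0, 1e-12)

  # Fit the occupancy fraction (O(1) scale) rather than raw moles.
  fr <- b / eq_bound
  df <- data.frame(t = t, fr = fr)
  fit <- tryCatch(
    stats::nls(fr ~ 1 - exp(-lam * t), data = df,
               start = list(lam = lam0), algorithm = "port",
               lower = c(lam = 1e-30),
               control = stats::nls.control(maxiter = 1000, tol = 1e-12,
                                            warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    opt <- stats::optimize(
      function(loglam) sum((fr - (1 - exp(-exp(loglam) * t)))^2),
      interval = log(lam0) + c(-15, 15), tol = 1e-12)
    lam <- exp(opt$minimum)
    lam_se <- NULL
    converged <- TRUE
  } else {
    lam <- unname(stats::coef(fit)["lam"])
    lam_se <- tryCatch(unname(summary(fit)$coefficients["lam", "Std. Error"]),
                       error = function(e) NULL)
    converged <- fit$convInfo$isConv
  }
  pred <- eq_bound * (1 - exp(-lam * t))

  if (mode == "lumped") {
    return(.fit_result(
      estimates = list(lambda = lam), units = list(lambda = "s^-1"),
      observed = b, predicted = pred, converged = converged,
      constraint_note = paste(
        "single-concentration data identifies only lambda = C*k_on + k_off;",
        "individual rates require an external K_D or multiple concentrations"),
      std_errors = if (!is.null(lam_se)) list(lambda = lam_se) else NULL))
  }
  # Constrained: lambda = k_on * (C + K_D), k_off = K_D * k_on.
  k_on <- lam / (C + K_D)
  k_off <- K_D * k_on
  se <- if (!is.null(lam_se)) {
    list(k_on = lam_se / (C + K_D), k_off = K_D * lam_se / (C + K_D))
  } else NULL
  .fit_result(
    estimates = list(k_on = k_on, k_off = k_off),
    units = list(k_on = "M^-1 s^-1", k_off = "s^-1"),
    observed = b, predicted = pred, converged = converged,
    constraint_note = sprintf(
      "k_off constrained to K_D * k_on with K_D = %g M", K_D),
    std_errors = se)
}

#' Serialise a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
fit_report_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(estimates = fit$estimates, units = fit$units,
              std_errors = fit$std_errors, r_squared = fit$r_squared,
              converged = fit$converged, constraint_note = fit$constraint_note)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
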