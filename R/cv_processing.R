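# Raw cyclic-voltammogram processing: zero-phase low-pass smoothing, linear
# baseline subtraction, and anodic peak extraction.

#' Cyclic voltammogram trace container
#'
#' A sampled potential/current sweep with its sampling rate and scan rate.
#'
#' @param potential Sampled potential \[V\].
#' @param current Sampled current \[A\], same length.
#' @param sampling_rate Sampling frequency \[Hz\].
#' @param scan_rate Potential scan rate \[V/s\].
#' @param sweep_window Length-2 `c(E_low, E_high)` \[V\]; defaults to the
#'   data range.
#' @param meta Optional named list of metadata (e.g. generator ground truth).
#' @return An object of class `cv_trace`.
#' @export
cv_trace <- function(potential, current, sampling_rate, scan_rate,
                     sweep_window = range(potential), meta = list()) {
  if (length(potential) != length(current)) {
    stop("'potential' and 'current' must have equal length", call. = FALSE)
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("'sampling_rate' must be strictly positive [Hz]", call. = FALSE)
  }
  if (!is.finite(scan_rate) || scan_rate <= 0) {
    stop("'scan_rate' must be strictly positive [V/s]", call. = FALSE)
  }
  eps <- 1e-9
  if (any(potential < sweep_window[1] - eps | potential > sweep_window[2] + eps)) {
    stop("potentials fall outside the sweep window", call. = FALSE)
  }
  structure(
    list(potential = potential, current = current,
         sampling_rate = sampling_rate, scan_rate = scan_rate,
         sweep_window = sweep_window, meta = meta),
    class = "cv_trace")
}

#' @export
print.cv_trace <- function(x, ...) {
  cat(sprintf("CV trace: %d samples, %g-%g V, fs = %g Hz, scan %g V/s\n",
              length(x$potential), x$sweep_window[1], x$sweep_window[2],
              x$sampling_rate, x$scan_rate))
  invisible(x)
}

# One biquad pass: y[k] = b0 x[k] + b1 x[k-1] + b2 x[k-2] - a1 y[k-1] - a2 y[k-2]
.biquad <- function(x, b, a) {
  n <- length(x)
  xp <- c(0, 0, x)
  v <- b[1] * xp[3:(n + 2)] + b[2] * xp[2:(n + 1)] + b[3] * xp[1:n]
  as.numeric(stats::filter(v, -a, method = "recursive"))
}

# Second-order Butterworth low-pass coefficients via the bilinear transform.
.butter2 <- function(fc, fs) {
  K <- tan(pi * fc / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  list(b = c(K^2, 2 * K^2, K^2) * norm,
       a = c(2 * (K^2 - 1), 1 - sqrt(2) * K + K^2) * norm)
}

#' Zero-phase low-pass smoothing of a CV trace
#'
#' Forward-backward (zero-phase) pass of a second-order Butterworth low-pass
#' over the current channel, with odd-reflection padding at both ends to
#' suppress edge transients. The per-pass corner is pre-adjusted so the
#' combined two-pass response has half power at `cutoff`; DC is preserved
#' exactly and attenuation is monotone above the cutoff.
#'
#' @param trace A [cv_trace()].
#' @param cutoff Cutoff frequency \[Hz\], default 3; must be below Nyquist.
#' @return The trace with smoothed current.
#' @export
lowpass_smooth <- function(trace, cutoff = 3) {
  stopifnot(inherits(trace, "cv_trace"))
  fs <- trace$sampling_rate
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    stop(sprintf("'cutoff' must lie in (0, Nyquist = %g Hz)", fs / 2),
         call. = FALSE)
  }
  # Half-power of the two-pass cascade at `cutoff`:
  # |H|^4 = 1/(1+(f/fc')^4)^2 = 1/2  =>  fc' = cutoff / (sqrt(2)-1)^(1/4).
  co <- .butter2(cutoff / (sqrt(2) - 1)^0.25, fs)
  x <- trace$current
  n <- length(x)
  npad <- min(n - 1, ceiling(3 * fs / cutoff))
  if (npad < 1) stop("trace too short to filter", call. = FALSE)
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- .biquad(xp, co$b, co$a)
  y <- rev(.biquad(rev(y), co$b, co$a))
  trace$current <- y[(npad + 1):(npad + n)]
  trace
}

#' Baseline-corrected anodic peak extraction
#'
#' Processes the ascending-potential (anodic) segment only. An ordinary
#' least-squares line is fitted to the current over the pre-peak baseline
#' window, extrapolated across the peak window, and subtracted; the anodic
#' peak current `ipa` is the maximum of the corrected current and `epa` the
#' potential at that maximum (ties broken toward the lowest potential).
#'
#' @param trace A [cv_trace()].
#' @param baseline_window Length-2 potential window \[V\] for the background
#'   regression, default `c(0.10, 0.25)`.
#' @param peak_window Length-2 potential window \[V\] searched for the peak,
#'   default `c(0.25, 0.45)`.
#' @return An object of class `peak_result` with `ipa` \[A\], `epa` \[V\],
#'   `baseline` (slope, intercept), `no_peak` and `boundary_peak` flags, and
#'   the windows used. When the corrected maximum is not positive the result
#'   has `no_peak = TRUE` and `ipa`/`epa` are `NA`.
#' @export
extract_peak <- function(trace, baseline_window = c(0.10, 0.25),
                         peak_window = c(0.25, 0.45)) {
  stopifnot(inherits(trace, "cv_trace"))
  sw <- trace$sweep_window
  for (w in list(baseline_window, peak_window)) {
    if (w[1] >= w[2] || w[1] < sw[1] - 1e-9 || w[2] > sw[2] + 1e-9) {
      stop("windows must be ordered and lie inside the sweep window",
           call. = FALSE)
    }
  }
  if (baseline_window[2] > peak_window[1] + 1e-12) {
    stop("baseline and peak windows must not overlap", call. = FALSE)
  }
  # Anodic segment: samples up to the first potential maximum.
  apex <- which.max(trace$potential)
  E <- trace$potential[1:apex]
  I <- trace$current[1:apex]

  bidx <- which(E >= baseline_window[1] & E <= baseline_window[2])
  pidx <- which(E >= peak_window[1] & E <= peak_window[2])
  if (length(bidx) < 10) {
    stop("baseline window must contain at least 10 anodic samples",
         call. = FALSE)
  }
  if (length(pidx) < 10) {
    stop("peak window must contain at least 10 anodic samples", call. = FALSE)
  }
  co <- stats::lm.fit(cbind(1, E[bidx]), I[bidx])$coefficients
  corrected <- I[pidx] - (co[1] + co[2] * E[pidx])
  # Ties toward the lowest potential: first index within the ascending sweep.
  k <- which.max(corrected)
  ipa <- corrected[k]
  res <- list(ipa = NA_real_, epa = NA_real_,
              baseline = c(slope = unname(co[2]), intercept = unname(co[1])),
              baseline_window = baseline_window, peak_window = peak_window,
              no_peak = FALSE, boundary_peak = FALSE)
  if (ipa <= 0) {
    res$no_peak <- TRUE
    class(res) <- "peak_result"
    return(res)
  }
  res$ipa <- ipa
  res$epa <- E[pidx][k]
  if (k == 1 || k == length(pidx)) res$boundary_peak <- TRUE
  class(res) <- "peak_result"
  res
}

#' @export
print.peak_result <- function(x, ...) {
  if (x$no_peak) {
    cat("No anodic peak above baseline\n")
  } else {
    cat(sprintf("Anodic peak: Ipa = %.4g A at Epa = %.4g V%s\n", x$ipa, x$epa,
                if (x$boundary_peak) " (at window edge)" else ""))
  }
  invisible(x)
}

#' Read / write CV trace CSV
#'
#' Native dialect: `#`-prefixed `key = value` metadata lines (requiring
#' `sampling_rate_Hz` and `scan_rate_V_per_s`; any other keys are kept as
#' trace metadata), a `potential_V,current_A` header, then two numeric
#' columns. Round trip is lossless for channels and metadata.
#'
#' @param path CSV file path.
#' @return [read_trace()]: a [cv_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.+)\\s*$", ln))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  for (key in c("sampling_rate_Hz", "scan_rate_V_per_s")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("trace file is missing required metadata key '%s'", key),
           call. = FALSE)
    }
  }
  body <- which(!is_meta & nzchar(trimws(lines)))
  if (length(body) == 0) stop("trace file contains no data", call. = FALSE)
  start <- body[1]
  if (grepl("potential", lines[start], ignore.case = TRUE)) {
    body <- body[-1]
  }
  pot <- numeric(length(body))
  cur <- numeric(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(lines[body[i]], ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2 || any(is.na(vals))) {
      stop(sprintf("malformed trace row at line %d: '%s'", body[i],
                   lines[body[i]]), call. = FALSE)
    }
    pot[i] <- vals[1]
    cur[i] <- vals[2]
  }
  extra <- meta[setdiff(names(meta), c("sampling_rate_Hz", "scan_rate_V_per_s"))]
  cv_trace(pot, cur, sampling_rate = meta$sampling_rate_Hz,
           scan_rate = meta$scan_rate_V_per_s, meta = extra)
}

#' @rdname read_trace
#' @param trace A [cv_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cv_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_Hz = %.15g", trace$sampling_rate), con)
  writeLines(sprintf("# scan_rate_V_per_s = %.15g", trace$scan_rate), con)
  for (nm in names(trace$meta)) {
    v <- trace$meta[[nm]]
    writeLines(sprintf("# %s = %s", nm,
                       if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)),
               con)
  }
  writeLines("potential_V,current_A", con)
  writeLines(sprintf("%.15g,%.15g", trace$potential, trace$current), con)
  invisible(path)
}
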