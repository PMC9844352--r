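# Shared key = value configuration file, parsed identically by library and
# CLI. Keys carry explicit SI units in their names to prevent nM/uM mix-ups.

#' Read a run configuration file
#'
#' Plain-text `key = value` format (one per line, `#` comments allowed).
#' Recognised keys: `n`, `scan_rate_V_per_s`, `temperature_K`, `gain`,
#' `K_D_M`, `k_on_per_M_s`, `k_off_per_s`, `ELD_tot_mol`. Unknown keys raise
#' an error so typos cannot silently change units.
#'
#' @param path Configuration file path.
#' @return A list with elements `params` ([kinetic_params()], when binding
#'   keys are present) and `config` ([electrochem_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(\\S+)$", ln))[[1]]
    if (length(m) != 3) {
      stop(sprintf("malformed config line: '%s' (expected key = value)", ln),
           call. = FALSE)
    }
    kv[[m[2]]] <- as.numeric(m[3])
  }
  known <- c("n", "scan_rate_V_per_s", "temperature_K", "gain",
             "K_D_M", "k_on_per_M_s", "k_off_per_s", "ELD_tot_mol")
  bad <- setdiff(names(kv), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown config key(s): %s (known: %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(kv$scan_rate_V_per_s)) {
    stop("config must set 'scan_rate_V_per_s'", call. = FALSE)
  }
  config <- electrochem_config(
    n = if (is.null(kv$n)) 2L else kv$n,
    scan_rate = kv$scan_rate_V_per_s,
    temperature = if (is.null(kv$temperature_K)) 298.15 else kv$temperature_K,
    gain = if (is.null(kv$gain)) 1.0 else kv$gain)
  params <- NULL
  if (!is.null(kv$ELD_tot_mol)) {
    params <- kinetic_params(
      K_D = if (is.null(kv$K_D_M)) NA_real_ else kv$K_D_M,
      k_on = if (is.null(kv$k_on_per_M_s)) NA_real_ else kv$k_on_per_M_s,
      k_off = if (is.null(kv$k_off_per_s)) NA_real_ else kv$k_off_per_s,
      ELD_tot = kv$ELD_tot_mol)
  }
  list(params = params, config = config)
}

#' Write a run configuration file
#'
#' @param params A [kinetic_params()] or `NULL`.
#' @param config An [electrochem_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(params, config, path) {
  .check_config(config)
  lines <- c(
    sprintf("n = %d", config$n),
    sprintf("scan_rate_V_per_s = %.15g", config$scan_rate),
    sprintf("temperature_K = %.15g", config$temperature),
    sprintf("gain = %.15g", config$gain))
  if (!is.null(params)) {
    lines <- c(lines,
      if (!is.na(params$K_D)) sprintf("K_D_M = %.15g", params$K_D),
      if (!is.na(params$k_on)) sprintf("k_on_per_M_s = %.15g", params$k_on),
      if (!is.na(params$k_off)) sprintf("k_off_per_s = %.15g", params$k_off),
      sprintf("ELD_tot_mol = %.15g", params$ELD_tot))
  }
  writeLines(lines, path)
  invisible(path)
}
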