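# Flat key=value configuration files and deterministic CSV output.
#
# Config format: one `key = value` per line, `#` comments, blank lines
# ignored. Values are numbers or comma-separated number lists. Unknown keys
# are rejected by name. Temperature may be given either as `temperature`
# (Kelvin) or `temperature_c` (Celsius, converted once at the boundary).

.config_keys <- c(
  "dic", "reference_ph", "ph", "ph_min", "ph_max", "ph_step",
  "vmax_over_d", "k", "temperature", "temperature_c", "salinity"
)

abort_config <- function(msg) {
  rlang::abort(msg, class = c("diatomccm_config_error", "diatomccm_error"))
}

parse_config_value <- function(raw, key) {
  parts <- trimws(strsplit(raw, ",", fixed = TRUE)[[1L]])
  val <- suppressWarnings(as.numeric(parts))
  if (length(val) == 0L || any(is.na(val))) {
    abort_config(sprintf(
      "Config key `%s` has a non-numeric value: '%s'.", key, raw
    ))
  }
  val
}

#' Read a scan configuration from a flat key=value file
#'
#' Parses a plain-text configuration (one `key = value` per line, `#`
#' comments) into a validated [scan_config()]. Recognized keys: `dic`,
#' `reference_ph`, `ph` (comma-separated grid) or `ph_min`/`ph_max`/
#' `ph_step`, `vmax_over_d` (comma-separated), `k`, `temperature` (Kelvin)
#' or `temperature_c` (Celsius), `salinity`. Any key left out takes the
#' package default; an empty file yields the default configuration. Unknown
#' keys, non-numeric values and out-of-range values raise an error naming
#' the offending key.
#'
#' @param path Path to the configuration file.
#' @return A `ccm_config`.
#' @seealso [write_ccm_config()] for the inverse; the pair round-trips.
#' @export
read_ccm_config <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("Config file not found: '%s'.", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  kv <- list()
  for (line in lines) {
    if (!grepl("=", line, fixed = TRUE)) {
      abort_config(sprintf("Config line is not `key = value`: '%s'.", line))
    }
    key <- trimws(sub("=.*$", "", line))
    raw <- trimws(sub("^[^=]*=", "", line))
    if (!key %in% .config_keys) {
      abort_config(sprintf(
        "Unknown config key `%s` (known keys: %s).",
        key, paste(.config_keys, collapse = ", ")
      ))
    }
    if (key %in% names(kv)) {
      abort_config(sprintf("Duplicate config key `%s`.", key))
    }
    kv[[key]] <- parse_config_value(raw, key)
  }

  if ("temperature" %in% names(kv) && "temperature_c" %in% names(kv)) {
    abort_config("Give `temperature` (K) or `temperature_c` (C), not both.")
  }
  if ("temperature_c" %in% names(kv)) {
    kv$temperature <- kv$temperature_c + 273.15
    kv$temperature_c <- NULL
  }
  if ("ph" %in% names(kv) &&
      any(c("ph_min", "ph_max", "ph_step") %in% names(kv))) {
    abort_config("Give `ph` or `ph_min`/`ph_max`/`ph_step`, not both.")
  }
  if (any(c("ph_min", "ph_max", "ph_step") %in% names(kv))) {
    need <- c("ph_min", "ph_max", "ph_step")
    if (!all(need %in% names(kv))) {
      abort_config("`ph_min`, `ph_max` and `ph_step` must be given together.")
    }
    kv$ph <- seq(kv$ph_min, kv$ph_max, by = kv$ph_step)
    kv[c("ph_min", "ph_max", "ph_step")] <- NULL
  }

  scalar_keys <- c("dic", "reference_ph", "k", "temperature", "salinity")
  for (key in intersect(scalar_keys, names(kv))) {
    if (length(kv[[key]]) != 1L) {
      abort_config(sprintf("Config key `%s` must be a single number.", key))
    }
  }

  args <- kv[intersect(names(kv), names(formals(scan_config)))]
  rlang::try_fetch(
    do.call(scan_config, args),
    diatomccm_error = function(cnd) {
      abort_config(sprintf("Invalid config value: %s", rlang::cnd_message(cnd)))
    }
  )
}

#' Write a scan configuration as a flat key=value file
#'
#' Writes every field (defaults included, so the file is a complete record)
#' with full numeric precision; [read_ccm_config()] recovers an identical
#' configuration.
#'
#' @param config A `ccm_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccm_config <- function(config, path) {
  if (!inherits(config, "ccm_config")) {
    abort_invalid("`config` must be a `ccm_config` from scan_config().")
  }
  num <- function(x) paste(sprintf("%.17g", x), collapse = ", ")
  lines <- c(
    "# middle-space CCM scan configuration (all values recorded)",
    sprintf("dic = %s", num(config$dic)),
    sprintf("reference_ph = %s", num(config$reference_ph)),
    sprintf("ph = %s", num(config$ph)),
    sprintf("vmax_over_d = %s", num(config$vmax_over_d)),
    sprintf("k = %s", num(config$k)),
    sprintf("temperature = %s", num(config$temperature)),
    sprintf("salinity = %s", num(config$salinity))
  )
  writeLines(lines, path)
  invisible(path)
}

# Format a data frame as RFC-4180 CSV lines with numbers at 10 significant
# digits, so identical configs give byte-identical files on any platform.
format_csv_lines <- function(df) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) {
      out <- sprintf("%.10g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      as.character(col)
    }
  })
  c(
    paste(names(df), collapse = ","),
    do.call(paste, c(cols, sep = ","))
  )
}

config_as_list <- function(config) {
  list(
    dic = config$dic,
    reference_ph = config$reference_ph,
    ph = config$ph,
    vmax_over_d = config$vmax_over_d,
    k = config$k,
    temperature = config$temperature,
    salinity = config$salinity
  )
}

#' Write the scan tables as CSV files with a provenance sidecar
#'
#' Writes the three canonical tables ([figure_tables()]) as
#' `<prefix>_middle_co2.csv`, `<prefix>_plastid_co2.csv`,
#' `<prefix>_fold_change.csv`, optionally the combined long table
#' `<prefix>_scan.csv`, and a JSON sidecar `<prefix>_provenance.json`
#' recording every configuration value (defaults included) and the package
#' version. Numbers are written at 10 significant digits so output is
#' byte-stable across platforms.
#'
#' @param scan A `ccm_scan` from [run_scan()].
#' @param dir Output directory, created if needed.
#' @param prefix File-name prefix.
#' @param combined Also write the combined long-format table?
#' @return Named character vector of the files written, invisibly.
#' @export
write_scan_tables <- function(scan, dir = ".", prefix = "scan",
                              combined = FALSE) {
  if (!inherits(scan, "ccm_scan")) {
    abort_invalid("`scan` must be a `ccm_scan` from run_scan().")
  }
  config <- attr(scan, "config")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  tabs <- figure_tables(scan)
  paths <- c(
    middle_co2 = file.path(dir, paste0(prefix, "_middle_co2.csv")),
    plastid_co2 = file.path(dir, paste0(prefix, "_plastid_co2.csv")),
    fold_change = file.path(dir, paste0(prefix, "_fold_change.csv"))
  )
  for (name in names(paths)) {
    writeLines(format_csv_lines(tabs[[name]]), paths[[name]])
  }
  if (combined) {
    paths <- c(paths, scan = file.path(dir, paste0(prefix, "_scan.csv")))
    writeLines(format_csv_lines(tibble::as_tibble(scan)), paths[["scan"]])
  }

  provenance <- list(
    package = "diatomccm",
    version = as.character(utils::packageVersion("diatomccm")),
    config = config_as_list(config),
    files = as.list(basename(paths))
  )
  prov_path <- file.path(dir, paste0(prefix, "_provenance.json"))
  jsonlite::write_json(provenance, prov_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, provenance = prov_path)
  invisible(paths)
}
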