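## Delimited-text formats shared by all tools.
##   spectrum: optional '# key=value' metadata lines, header y_keV_um,d_y
##   series:   long format depth_mm,y_keV_um,d_y
##   profile:  depth_mm,physical_dose_Gy[,z_star_Gy,alpha_Gy-1,rbe,
##             rbe_weighted_dose_Gy]
## Numbers are written with 17 significant digits so write-then-read is
## value-identical well past 12 significant digits.

fmt_num <- function(x) sprintf("%.17g", x)

detect_sep <- function(header) if (grepl("\t", header, fixed = TRUE)) "\t" else ","

read_delim_body <- function(path, required) {
  if (!file.exists(path))
    stop_mkm("file_not_found", sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2L)
    stop_mkm("parse_error", sprintf("'%s': no data rows", path))
  sep <- detect_sep(body[1])
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_mkm("missing_column", sprintf("'%s': missing column(s) %s", path,
                                       paste(missing_cols, collapse = ", ")))
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(key)]] <- if (is.na(num)) trimws(val) else num
    }
  }
  list(df = df, meta = meta, sep = sep)
}

#' Read and write lineal-energy spectrum files
#'
#' Spectrum files are comma- or tab-delimited text with a header line
#' `y_keV_um,d_y`, one row per grid point, and optional `#`-prefixed
#' `key=value` metadata lines (e.g. `# depth_mm=102`). Values round-trip
#' identically to at least 12 significant digits; the stored density is
#' written as-is (no renormalization on either side).
#'
#' @param path file path.
#' @return `read_spectrum()`: a [lineal_spectrum()] (not renormalized).
#' @export
read_spectrum <- function(path) {
  parsed <- read_delim_body(path, c("y_keV_um", "d_y"))
  df <- parsed$df
  bad <- which(diff(df$y_keV_um) <= 0)
  if (length(bad))
    stop_mkm("unsorted_grid", sprintf(
      "'%s': y grid not strictly increasing at data row %d", path, bad[1] + 1L))
  lineal_spectrum(df$y_keV_um, df$d_y, metadata = parsed$meta,
                  normalize = FALSE)
}

#' @rdname read_spectrum
#' @param spec a [lineal_spectrum()].
#' @param sep field separator, `","` or `"\t"`.
#' @export
write_spectrum <- function(spec, path, sep = ",") {
  spec <- as_lineal_spectrum(spec)
  con <- file(path, "w"); on.exit(close(con))
  for (key in names(spec$metadata)) {
    val <- spec$metadata[[key]]
    writeLines(sprintf("# %s=%s", key,
                       if (is.numeric(val)) fmt_num(val) else as.character(val)),
               con)
  }
  writeLines(paste("y_keV_um", "d_y", sep = sep), con)
  writeLines(paste(fmt_num(spec$y), fmt_num(spec$d), sep = sep), con)
  invisible(path)
}

#' Read and write spectrum-series files
#'
#' Long-format delimited text with columns `depth_mm,y_keV_um,d_y`; one
#' block of rows per depth. Depths must be grouped and increasing; each
#' block must carry a strictly increasing y grid.
#'
#' @param path file path.
#' @return `read_series()`: a [spectrum_series()] (densities not
#'   renormalized).
#' @export
read_series <- function(path) {
  parsed <- read_delim_body(path, c("depth_mm", "y_keV_um", "d_y"))
  df <- parsed$df
  depths <- unique(df$depth_mm)
  spectra <- lapply(depths, function(dd) {
    block <- df[df$depth_mm == dd, ]
    bad <- which(diff(block$y_keV_um) <= 0)
    if (length(bad))
      stop_mkm("unsorted_grid", sprintf(
        "'%s': y grid not increasing within depth %g (row %d of block)",
        path, dd, bad[1] + 1L))
    lineal_spectrum(block$y_keV_um, block$d_y,
                    metadata = list(depth_mm = dd), normalize = FALSE)
  })
  spectrum_series(depths, spectra)
}

#' @rdname read_series
#' @param series a [spectrum_series()].
#' @param sep field separator.
#' @export
write_series <- function(series, path, sep = ",") {
  if (!inherits(series, "spectrum_series"))
    stop_mkm("type_error", "expected a 'spectrum_series' object")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("depth_mm", "y_keV_um", "d_y", sep = sep), con)
  for (i in seq_along(series$depths)) {
    sp <- series$spectra[[i]]
    writeLines(paste(fmt_num(rep(series$depths[i], length(sp$y))),
                     fmt_num(sp$y), fmt_num(sp$d), sep = sep), con)
  }
  invisible(path)
}

## column names as written on disk vs stored internally
.profile_cols <- c(depth_mm = "depth_mm",
                   physical_dose_Gy = "physical_dose_Gy",
                   z_star_Gy = "z_star_Gy",
                   `alpha_Gy-1` = "alpha_Gy.1",
                   rbe = "rbe",
                   rbe_weighted_dose_Gy = "rbe_weighted_dose_Gy")

#' Read and write depth-profile files
#'
#' Delimited text with columns `depth_mm,physical_dose_Gy` and, when the
#' profile has been through [mkm_rbe()], the derived columns
#' `z_star_Gy,alpha_Gy-1,rbe,rbe_weighted_dose_Gy`. Derived columns are
#' written only when present.
#'
#' @param path file path.
#' @return `read_profile()`: a data frame with the internal column names
#'   (`alpha_Gy.1` for the on-disk `alpha_Gy-1`).
#' @export
read_profile <- function(path) {
  parsed <- read_delim_body(path, c("depth_mm", "physical_dose_Gy"))
  df <- parsed$df
  known <- names(.profile_cols)
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    stop_mkm("unknown_column", sprintf("'%s': unknown column(s) %s", path,
                                       paste(unknown, collapse = ", ")))
  names(df) <- .profile_cols[names(df)]
  if (any(diff(df$depth_mm) <= 0))
    stop_mkm("unsorted_grid", sprintf(
      "'%s': depth_mm not strictly increasing at data row %d", path,
      which(diff(df$depth_mm) <= 0)[1] + 1L))
  df
}

#' @rdname read_profile
#' @param profile an `"mkm_profile"` or a data frame with at least
#'   `depth_mm` and `physical_dose_Gy`.
#' @param sep field separator.
#' @export
write_profile <- function(profile, path, sep = ",") {
  df <- if (inherits(profile, "mkm_profile")) profile$data else profile
  disk <- names(.profile_cols)[match(names(df), .profile_cols)]
  if (anyNA(disk))
    stop_mkm("unknown_column", "profile contains columns outside the format")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(disk, collapse = sep), con)
  rows <- do.call(paste, c(lapply(df, fmt_num), sep = sep))
  writeLines(rows, con)
  invisible(path)
}

.config_keys <- c("schema_version", "mkm_params", "reference", "endpoint",
                  "normalization", "beam", "window_mm")

#' Read a run configuration
#'
#' Configurations are JSON or YAML with blocks `mkm_params` (a preset name
#' `"SET_A"`/`"SET_B"` or explicit values), `reference` (preset `"X200KVP"`
#' or explicit `alpha_x`/`beta_x`), `endpoint` (`survival`), `normalization`
#' (`mode`, `target_dose`, `on`), `beam` (arguments of [beam_config()]) and
#' `window_mm`. Unknown top-level keys are rejected.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with resolved components `params`, `reference`,
#'   `survival`, `window_mm`, `normalization`, `beam` plus the raw input.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_mkm("file_not_found", sprintf("config '%s' does not exist", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  resolve_run_config(raw)
}

resolve_run_config <- function(raw) {
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop_mkm("unknown_key", sprintf("unknown config key(s): %s",
                                    paste(unknown, collapse = ", ")))
  params <- if (is.null(raw$mkm_params)) mkm_preset("SET_B")
    else if (is.character(raw$mkm_params)) mkm_preset(raw$mkm_params)
    else do.call(mkm_params, as.list(raw$mkm_params))
  reference <- if (is.null(raw$reference)) reference_radiation()
    else if (is.character(raw$reference)) reference_preset(raw$reference)
    else do.call(reference_radiation, as.list(raw$reference))
  survival <- if (is.null(raw$endpoint$survival)) 0.1 else raw$endpoint$survival
  check_survival_fraction(survival)
  beam <- if (is.null(raw$beam)) NULL else do.call(beam_config, as.list(raw$beam))
  list(params = params, reference = reference, survival = survival,
       window_mm = if (is.null(raw$window_mm)) 1.5 else raw$window_mm,
       normalization = raw$normalization, beam = beam, raw = raw)
}
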