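#' Read a quench titration series from a delimited text file
#'
#' Expects a header row naming two numeric columns (concentration then
#' intensity); additional columns are ignored. Lines of the form
#' `# key: value` before the header carry metadata (`temperature_K`,
#' `protein_conc_M`, `label`); explicit arguments override them. The
#' delimiter is comma by default and tab is auto-detected. Rows are sorted
#' by concentration on ingest.
#'
#' @param path Path to the CSV/TSV file.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @param conc_unit Unit of the concentration column: `"M"`, `"mM"` or
#'   `"uM"`; values are converted to mol/L internally.
#' @param temperature_K,protein_conc_M,label Optional metadata overriding
#'   any `# key: value` header lines.
#' @return A [titration_series()].
#' @export
read_titration <- function(path, delim = NULL, conc_unit = c("M", "mM", "uM"),
                           temperature_K = NULL, protein_conc_M = NULL,
                           label = NULL) {
  conc_unit <- match.arg(conc_unit)
  parsed <- read_delim_table(path, delim, n_numeric = 2L)
  meta <- parsed$meta
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6)[[conc_unit]]
  conc <- parsed$data[[1L]] * scale
  inten <- parsed$data[[2L]]
  ord <- order(conc)
  titration_series(
    ligand_conc_M = conc[ord], intensity = inten[ord],
    temperature_K = temperature_K %||% meta$temperature_K %||% 298,
    protein_conc_M = protein_conc_M %||% meta$protein_conc_M %||% 5e-6,
    label = label %||% meta$label %||% basename(path)
  )
}

#' Write a titration series as CSV
#'
#' Emits `# key: value` metadata lines followed by a two-column CSV
#' (`ligand_conc_M,intensity`) at full double precision, in the dialect
#' [read_titration()] reads back.
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  write_delim_table(
    path,
    meta = list(temperature_K = series$temperature_K,
                protein_conc_M = series$protein_conc_M,
                label = series$label),
    data = data.frame(ligand_conc_M = series$ligand_conc_M,
                      intensity = series$intensity)
  )
}

#' Read a chemical-denaturation profile from a delimited text file
#'
#' Same dialect as [read_titration()]: optional `# key: value` metadata
#' lines, then a header naming two numeric columns (denaturant
#' concentration in mol/L, then signal).
#'
#' @inheritParams read_titration
#' @return An [unfolding_profile()].
#' @export
read_unfolding <- function(path, delim = NULL, temperature_K = NULL,
                           label = NULL) {
  parsed <- read_delim_table(path, delim, n_numeric = 2L)
  meta <- parsed$meta
  denat <- parsed$data[[1L]]
  sig <- parsed$data[[2L]]
  ord <- order(denat)
  unfolding_profile(denat[ord], sig[ord],
                    temperature_K = temperature_K %||% meta$temperature_K %||% 298,
                    label = label %||% meta$label %||% basename(path))
}

#' @rdname write_titration
#' @param profile An [unfolding_profile()].
#' @export
write_unfolding <- function(profile, path) {
  stopifnot(inherits(profile, "unfolding_profile"))
  write_delim_table(
    path,
    meta = list(temperature_K = profile$temperature_K, label = profile$label),
    data = data.frame(denaturant_M = profile$denaturant_M,
                      signal = profile$signal)
  )
}

#' Read a spectrum (wavelength vs signal) from a delimited text file
#'
#' @inheritParams read_titration
#' @param signal_kind Kind of signal stored in the second column.
#' @return A [new_spectrum()].
#' @export
read_spectrum <- function(path, signal_kind = c("fluorescence", "cd_millideg",
                                                "scattering",
                                                "mre_deg_cm2_dmol"),
                          delim = NULL, label = NULL) {
  signal_kind <- match.arg(signal_kind)
  parsed <- read_delim_table(path, delim, n_numeric = 2L)
  wl <- parsed$data[[1L]]
  sig <- parsed$data[[2L]]
  ord <- order(wl)
  new_spectrum(wl[ord], sig[ord], signal_kind,
               label = label %||% parsed$meta$label %||% basename(path))
}

#' @rdname write_titration
#' @param spectrum A [new_spectrum()] object.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "specbind_spectrum"))
  write_delim_table(
    path,
    meta = list(signal_kind = spectrum$signal_kind, label = spectrum$label),
    data = data.frame(wavelength_nm = spectrum$wavelength_nm,
                      signal = spectrum$signal)
  )
}

#' Write an analysis result record as structured JSON
#'
#' Serializes any specbind result object (quench, binding, thermodynamic,
#' kinetic, transition or comparison fits, and the data containers) to a
#' JSON file carrying every field, with units embedded in the field names,
#' plus provenance (object class, package version, and any label/seed the
#' object carries). Numbers are emitted at full double precision so a
#' write/read round trip is an identity to within float formatting.
#'
#' @param record A specbind result or data object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_result()]
#' @export
write_result <- function(record, path) {
  cls <- class(record)[1L]
  if (!is.list(record) || cls == "list")
    stop_specbind("record must be one of the package result types",
                  "specbind_validation_error")
  if (!nzchar(path))
    stop_specbind("empty output path", "specbind_io_error")
  payload <- list(
    type = cls,
    package = "specbind",
    package_version = as.character(utils::packageVersion("specbind")),
    fields = strip_fits(unclass(record))
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_specbind(sprintf("cannot write '%s': %s", path,
                          conditionMessage(ok)), "specbind_io_error")
  invisible(path)
}

#' Read back a result record written by [write_result()]
#'
#' @param path Path to a JSON result file.
#' @return The reconstructed object, with its original class restored.
#' @export
read_result <- function(path) {
  if (!file.exists(path))
    stop_specbind(sprintf("no such file: '%s'", path), "specbind_io_error")
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- payload$fields
  structure(out, class = payload$type)
}

# ---- internal helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# Drop heavyweight model objects before serialization, and turn named
# atomic vectors into named lists so JSON keeps their names.
strip_fits <- function(x) {
  if (inherits(x, "lm")) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_fits)
    x[!vapply(x, is.null, logical(1L))]
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)
  } else x
}

read_delim_table <- function(path, delim, n_numeric) {
  if (!file.exists(path))
    stop_specbind(sprintf("no such file: '%s'", path), "specbind_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_meta <- grepl("^\\s*#", lines)
  meta <- parse_meta(lines[is_meta])
  body <- lines[!is_meta]
  if (length(body) < 2L)
    stop_specbind("file has no data rows below the header",
                  "specbind_format_error")
  if (is.null(delim))
    delim <- if (grepl("\t", body[1L])) "\t" else ","
  tab <- utils::read.table(text = body, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < n_numeric)
    stop_specbind(sprintf("expected at least %d columns, found %d",
                          n_numeric, ncol(tab)), "specbind_format_error")
  for (j in seq_len(n_numeric)) {
    col <- suppressWarnings(as.numeric(tab[[j]]))
    if (anyNA(col)) {
      bad <- which(is.na(col))[1L]
      stop_specbind(sprintf("non-numeric value in column '%s', data row %d",
                            names(tab)[j], bad), "specbind_format_error")
    }
    tab[[j]] <- col
  }
  list(meta = meta, data = tab)
}

parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      val <- trimws(m[3L])
      num <- suppressWarnings(as.numeric(val))
      out[[m[2L]]] <- if (!is.na(num)) num else val
    }
  }
  out
}

write_delim_table <- function(path, meta, data) {
  if (!nzchar(path))
    stop_specbind("empty output path", "specbind_io_error")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_specbind(sprintf("cannot open '%s' for writing", path),
                  "specbind_io_error"))
  on.exit(close(con))
  for (key in names(meta)) {
    val <- meta[[key]]
    if (is.numeric(val)) val <- format(val, digits = 15)
    if (nzchar(val)) writeLines(sprintf("# %s: %s", key, val), con)
  }
  writeLines(paste(names(data), collapse = ","), con)
  rows <- do.call(paste, c(lapply(data, function(col)
    vapply(col, function(v) format(v, digits = 15), character(1L))),
    sep = ","))
  writeLines(rows, con)
  invisible(path)
}
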