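# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA sequences, two-column peak lists, kinetic time courses with key=value
# metadata headers, and TSV/JSON result exports.

#' Read protein sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` that returns plain
#' character sequences named by accession. UniProt-style description lines
#' (`db|ACCESSION|NAME ...`) are parsed for the accession; otherwise the first
#' whitespace-delimited token is used.
#'
#' @param path FASTA file (single- or multi-record).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(names(set), parse_accession, character(1),
                        USE.NAMES = FALSE)
  seqs
}

parse_accession <- function(desc) {
  first <- strsplit(desc, "\\s+")[[1]][1]
  parts <- strsplit(first, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2L && nzchar(parts[2])) parts[2] else first
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a peak list from a two-column table
#'
#' Accepts TSV or CSV with columns m/z and intensity; a header line is
#' detected and skipped automatically.
#'
#' @param path File path.
#' @param condition,sample Optional metadata labels attached to the result.
#' @return A [peak_list].
#' @export
read_peak_list <- function(path, condition = NA_character_,
                           sample = NA_character_) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  header <- is.na(suppressWarnings(as.numeric(strsplit(first, sep)[[1]][1])))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("peak list must have two columns: mz, intensity")
  peak_list(df[[1]], df[[2]], condition = condition, sample = sample)
}

#' Write a peak list as TSV
#'
#' @param peaks A [peak_list].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks)[, c("mz", "intensity")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write neutral-mass estimates
#'
#' Serializes deconvolution output as TSV (one row per estimate, charge
#' support as a comma-separated range) or JSON.
#'
#' @param estimates Result of [deconvolute].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_estimates <- function(estimates, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  flat <- data.frame(
    mass = estimates$mass,
    mass_sd = estimates$mass_sd,
    n_charges = estimates$n_charges,
    z_support = vapply(estimates$z_support, paste, character(1),
                       collapse = ","),
    total_intensity = estimates$total_intensity,
    stringsAsFactors = FALSE
  )
  if (format == "tsv") {
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a kinetic time course from CSV
#'
#' Expects columns `time_min` and `signal`; leading comment lines of the form
#' `# key=value` (e.g. `# enzyme_nM=1.2`) are parsed into curve metadata.
#'
#' @param path CSV file path.
#' @return A [progress_curve].
#' @export
read_progress_curve <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("time_min", "signal") %in% names(df)))
    stop("time course must have columns time_min, signal")
  progress_curve(
    time_min = df$time_min, signal = df$signal,
    enzyme_nM = as.numeric(meta$enzyme_nM %||% NA),
    substrate = meta$substrate %||% NA_character_,
    substrate_conc0 = as.numeric(meta$substrate_uM %||% NA),
    signal_unit = meta$signal_unit %||% "uM"
  )
}

#' Write a kinetic time course as CSV
#'
#' Metadata is emitted as `# key=value` comment lines, readable by
#' [read_progress_curve].
#'
#' @param curve A [progress_curve].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_progress_curve <- function(curve, path) {
  meta <- attributes(curve)
  hdr <- c(
    sprintf("# enzyme_nM=%g", meta$enzyme_nM),
    if (!is.na(meta$substrate)) sprintf("# substrate=%s", meta$substrate),
    if (!is.na(meta$substrate_conc0))
      sprintf("# substrate_uM=%g", meta$substrate_conc0),
    sprintf("# signal_unit=%s", meta$signal_unit)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(time_min = curve$time_min,
                              signal = curve$signal),
                   con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
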