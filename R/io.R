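#' Single-lead ECG record container
#'
#' @param samples Numeric sample vector (raw ADC counts or physical units).
#' @param fs Sampling frequency in Hz.
#' @param source_bits Source bit resolution per sample (8..32).
#' @param units Unit label (informational).
#' @param record_id,lead Identification labels (informational).
#' @return An object of class `scyf_record`.
#' @export
ecg_record <- function(samples, fs, source_bits = 16L, units = "adu",
                       record_id = "", lead = "") {
  check_numeric_vector(samples, "samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    scyf_stop("`fs` must be a positive sampling frequency", "scyf_config_error")
  source_bits <- as.integer(source_bits)
  if (source_bits < 8L || source_bits > 32L)
    scyf_stop("`source_bits` must be in 8..32", "scyf_invalid_input")
  structure(list(samples = samples, fs = as.numeric(fs),
                 source_bits = source_bits, units = units,
                 record_id = record_id, lead = lead),
            class = "scyf_record")
}

#' @export
print.scyf_record <- function(x, ...) {
  cat(sprintf("<scyf_record> %s%s: %d samples @ %g Hz, %d-bit, units '%s'\n",
              x$record_id, if (nzchar(x$lead)) paste0("/", x$lead) else "",
              length(x$samples), x$fs, x$source_bits, x$units))
  invisible(x)
}

#' Read / write ECG samples as CSV
#'
#' The CSV dialect is one sample per line with an optional single header
#' line and a decimal point. CSV carries no metadata, so `fs` (and usually
#' `source_bits`) must be supplied. Values are written with 17 significant
#' digits so that doubles round-trip exactly.
#'
#' @param path File path.
#' @param fs Sampling frequency in Hz (required for CSV input).
#' @param source_bits Source resolution, bits per sample.
#' @param column Column to read when the file has several.
#' @param ... Passed on to [ecg_record()].
#' @return `read_ecg_csv`: a `scyf_record`.
#' @export
read_ecg_csv <- function(path, fs = NULL, source_bits = 16L, column = 1L, ...) {
  if (is.null(fs))
    scyf_stop("CSV input requires an explicit `fs`", "scyf_config_error")
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][column])))
  df <- utils::read.csv(path, header = has_header)
  vals <- df[[column]]
  if (!is.numeric(vals))
    scyf_stop("selected CSV column is not numeric", "scyf_invalid_input")
  ecg_record(as.numeric(vals), fs = fs, source_bits = source_bits,
             record_id = basename(path), ...)
}

#' @param record A `scyf_record` or bare numeric vector.
#' @return `write_ecg_csv`: `path`, invisibly.
#' @rdname read_ecg_csv
#' @export
write_ecg_csv <- function(record, path) {
  samples <- if (inherits(record, "scyf_record")) record$samples else record
  check_numeric_vector(samples, "record")
  writeLines(sprintf("%.17g", samples), path)
  invisible(path)
}

#' Read a WFDB (PhysioNet) record
#'
#' Minimal reader for the text `.hea` header plus a format-16 (little-endian
#' 16-bit integer, interleaved leads) `.dat` signal file. Samples are
#' returned as raw ADC counts, unmodified; sampling frequency and ADC
#' resolution come from the header. Other WFDB storage formats are
#' rejected.
#'
#' @param path Record path, with or without the `.hea` extension.
#' @param lead Lead selector: 1-based index or signal description string.
#' @return A `scyf_record` for the selected lead.
#' @export
read_wfdb <- function(path, lead = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea))
    scyf_stop(sprintf("WFDB header not found: %s", hea), "scyf_invalid_input")
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- sub("/.*", "", rec[1])
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  if (is.na(nsig) || nsig < 1L || length(lines) < 1L + nsig)
    scyf_stop("malformed WFDB header", "scyf_invalid_input")
  sig <- lapply(lines[1L + seq_len(nsig)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  files <- vapply(sig, `[`, "", 1L)
  formats <- vapply(sig, `[`, "", 2L)
  adcres <- vapply(sig, function(f) {
    if (length(f) >= 4) as.integer(f[4]) else 12L
  }, integer(1))
  descs <- vapply(sig, function(f) {
    if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
  }, character(1))
  if (is.character(lead)) {
    idx <- match(lead, descs)
    if (is.na(idx)) scyf_stop(sprintf("unknown lead '%s'", lead), "scyf_lookup_error")
  } else {
    idx <- as.integer(lead)
    if (idx < 1L || idx > nsig)
      scyf_stop(sprintf("lead index %d out of 1..%d", idx, nsig), "scyf_lookup_error")
  }
  if (any(sub("x.*", "", formats) != "16"))
    scyf_stop("only WFDB storage format 16 is supported", "scyf_invalid_input")
  dat <- file.path(dirname(hea), files[idx])
  if (!file.exists(dat))
    scyf_stop(sprintf("WFDB signal file not found: %s", dat), "scyf_invalid_input")
  vals <- readBin(dat, "integer", n = file.size(dat) %/% 2L, size = 2L,
                  endian = "little", signed = TRUE)
  m <- length(vals) %/% nsig
  if (!is.na(nsamp)) m <- min(m, nsamp)
  samples <- vals[seq.int(idx, by = nsig, length.out = m)]
  ecg_record(as.numeric(samples), fs = fs,
             source_bits = max(8L, min(32L, adcres[idx])),
             record_id = record_name,
             lead = if (nzchar(descs[idx])) descs[idx] else as.character(idx))
}
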