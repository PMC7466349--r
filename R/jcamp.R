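# Minimal JCAMP-DX 1D reader/writer. FIDs and complex spectra are stored as
# two NTUPLES pages (real, imaginary) of AFFN "x y" pairs; acquisition
# parameters, provenance and the processing log travel in $-prefixed
# private header labels, and the dialect is recorded in the header.

JCAMP_DIALECT <- "NTUPLES-AFFN-XYPAIRS"
LOG_SEP <- " || "

jcamp_header <- function(title, data_type, params, provenance, proc_log) {
  c(sprintf("##TITLE= %s", title),
    "##JCAMP-DX= 5.01",
    sprintf("##DATA TYPE= %s", data_type),
    "##DATA CLASS= NTUPLES",
    "##ORIGIN= arsqnmr",
    "##OWNER= arsqnmr",
    "##NUM DIM= 1",
    sprintf("##.OBSERVE FREQUENCY= %.6g", params$spectrometer_freq),
    sprintf("##$SWEEPWIDTH= %.10g", params$sweep_width),
    sprintf("##$TDPOINTS= %d", params$td_points),
    sprintf("##$ACQUISITIONTIME= %.10g", params$acquisition_time),
    sprintf("##$RELAXATIONDELAY= %.10g", params$relaxation_delay),
    sprintf("##$NSCANS= %d", params$n_scans),
    sprintf("##$LINEBROADENINGDEFAULT= %.10g", params$line_broadening_default),
    sprintf("##$TEMPERATURE= %.10g", params$temperature),
    sprintf("##$PULSEANGLE= %.10g", params$pulse_angle),
    sprintf("##$REFPPM= %.10g", params$ref_ppm),
    sprintf("##$DIALECT= %s", JCAMP_DIALECT),
    sprintf("##$PROVENANCE= %s", provenance),
    sprintf("##$PROCESSINGLOG= %s", paste(proc_log, collapse = LOG_SEP)))
}

jcamp_page <- function(n, var, x, y) {
  c(sprintf("##PAGE= %d (%s)", n, var),
    "##DATA TABLE= (XY..XY)",
    sprintf("%.10e %.10e", x, y))
}

#' Write a FID or spectrum as JCAMP-DX
#'
#' 1D NTUPLES dialect with two pages (real and imaginary trace) in AFFN
#' form; acquisition parameters and the processing log are serialized into
#' the header so that a read-back object is fully reconstructed.
#'
#' @param x an `ars_fid` or `ars_spectrum`.
#' @param path output path.
#' @param title TITLE header field.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(x, path, title = "arsqnmr simulated data") {
  if (inherits(x, "ars_fid")) {
    n <- length(x$data)
    t <- (seq_len(n) - 1) / x$params$sweep_width
    lines <- c(jcamp_header(title, "NMR FID", x$params, x$provenance,
                            x$processing_log),
               "##NTUPLES= NMR FID",
               "##VAR_NAME= TIME, REAL, IMAG",
               jcamp_page(1, "REAL", t, Re(x$data)),
               jcamp_page(2, "IMAG", t, Im(x$data)),
               "##END NTUPLES= NMR FID",
               "##END=")
  } else if (inherits(x, "ars_spectrum")) {
    lines <- c(jcamp_header(title, "NMR SPECTRUM", x$params, "",
                            x$processing_log),
               "##NTUPLES= NMR SPECTRUM",
               "##VAR_NAME= PPM, REAL, IMAG",
               jcamp_page(1, "REAL", x$ppm, x$real),
               jcamp_page(2, "IMAG", x$ppm, x$imag),
               "##END NTUPLES= NMR SPECTRUM",
               "##END=")
  } else stop("invalid_object: write_jcamp handles ars_fid and ars_spectrum")
  writeLines(lines, path)
  invisible(path)
}

#' Read a 1D JCAMP-DX file written by [write_jcamp()]
#'
#' Reconstructs the `ars_fid` or `ars_spectrum`, including acquisition
#' parameters and the processing log. Only one-dimensional data are
#' supported; a multi-dimensional file raises a parse error naming the
#' offending dimension count.
#'
#' @param path file path.
#' @return an `ars_fid` or `ars_spectrum`.
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) stop(sprintf("file_not_found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_label <- startsWith(lines, "##")
  labels <- list()
  for (ln in lines[is_label]) {
    m <- regmatches(ln, regexec("^##([^=]*)=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) labels[[trimws(m[2])]] <- trimws(m[3])
  }
  if (is.null(labels[["DATA TYPE"]]))
    stop("jcamp_parse_error: missing ##DATA TYPE= label")
  ndim <- labels[["NUM DIM"]]
  if (!is.null(ndim) && as.numeric(ndim) != 1)
    stop(sprintf("unsupported_dimension: %s-dimensional data (only 1D supported)",
                 ndim))
  need <- c("$SWEEPWIDTH", "$TDPOINTS", "$RELAXATIONDELAY", "$NSCANS",
            ".OBSERVE FREQUENCY")
  miss <- need[!need %in% names(labels)]
  if (length(miss) > 0)
    stop(sprintf("jcamp_parse_error: missing header label(s): %s",
                 paste(miss, collapse = ", ")))
  params <- acq_params(
    spectrometer_freq = as.numeric(labels[[".OBSERVE FREQUENCY"]]),
    sweep_width = as.numeric(labels[["$SWEEPWIDTH"]]),
    td_points = as.integer(labels[["$TDPOINTS"]]),
    relaxation_delay = as.numeric(labels[["$RELAXATIONDELAY"]]),
    n_scans = as.integer(labels[["$NSCANS"]]),
    line_broadening_default = as.numeric(labels[["$LINEBROADENINGDEFAULT"]] %||% 0.3),
    temperature = as.numeric(labels[["$TEMPERATURE"]] %||% 298),
    pulse_angle = as.numeric(labels[["$PULSEANGLE"]] %||% 90),
    ref_ppm = as.numeric(labels[["$REFPPM"]] %||% 6.5))
  proc_log <- labels[["$PROCESSINGLOG"]] %||% ""
  proc_log <- if (nzchar(proc_log)) strsplit(proc_log, LOG_SEP, fixed = TRUE)[[1]]
              else character()
  page_starts <- grep("^##PAGE=", lines)
  if (length(page_starts) != 2)
    stop(sprintf("jcamp_parse_error: expected 2 data pages, found %d",
                 length(page_starts)))
  read_page <- function(start) {
    end <- min(c(page_starts[page_starts > start] - 1L,
                 grep("^##END", lines)[1] - 1L))
    block <- lines[(start + 1L):end]
    block <- block[!startsWith(block, "##") & nzchar(trimws(block))]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) != 2)
    if (length(bad) > 0)
      stop(sprintf("jcamp_parse_error: malformed data line %d: '%s'",
                   start + bad[1], block[bad[1]]))
    x <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1)))
    y <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
    if (anyNA(x) || anyNA(y)) {
      bad <- which(is.na(x) | is.na(y))[1]
      stop(sprintf("jcamp_parse_error: non-numeric value at data line %d: '%s'",
                   start + bad, block[bad]))
    }
    list(x = x, y = y)
  }
  p1 <- read_page(page_starts[1])
  p2 <- read_page(page_starts[2])
  if (length(p1$y) != length(p2$y))
    stop("jcamp_parse_error: real and imaginary pages differ in length")
  dtype <- toupper(labels[["DATA TYPE"]])
  if (grepl("FID", dtype)) {
    new_fid(complex(real = p1$y, imaginary = p2$y), params,
            provenance = labels[["$PROVENANCE"]] %||% "", log = proc_log)
  } else {
    structure(list(real = p1$y, imag = p2$y, ppm = p1$x, params = params,
                   processing_log = proc_log),
              class = "ars_spectrum")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
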