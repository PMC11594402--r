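# Signal and event file I/O.  CSV (header `index,value`) is the canonical
# interchange; raw little-endian int16 with a JSON sidecar supports
# acquisition dumps.  Lines starting with '#' are provenance comments.

#' Read a single-channel signal file
#'
#' Two formats are supported.  CSV: optional leading `#` comment lines, a
#' mandatory `index,value` header, then one sample per row; malformed rows
#' are reported with their line number.  Raw: little-endian 16-bit signed
#' integers with a JSON sidecar `<stem>.json` holding `sample_rate` (Hz) and
#' `scale` (signal units per count); values are returned as `count * scale`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.csv` is CSV, anything else raw),
#'   `"csv"`, or `"raw"`.
#' @return numeric vector of samples in signal units.  Raw files carry
#'   `sample_rate` and `scale` attributes.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_signal(c(1.5, -2), f)
#' read_signal(f)
#' @export
read_signal <- function(path, format = c("auto", "csv", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("signal file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "raw"
  if (format == "csv") read_signal_csv(path) else read_signal_raw(path)
}

read_signal_csv <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data in ", path)
  if (trimws(lines[1]) != "index,value")
    stop(path, ": line ", lineno[1],
         ": expected header 'index,value', got '", lines[1], "'")
  body <- lines[-1]
  if (!length(body)) return(numeric(0))
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(path, ": line ", lineno[-1][bad[1]], ": malformed row '",
         body[bad[1]], "'")
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop(path, ": line ", lineno[-1][bad[1]],
         ": value is not a finite number: '", body[bad[1]], "'")
  vals
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_signal_raw <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("raw signal ", path, " is missing its JSON sidecar ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$sample_rate) || is.null(meta$scale))
    stop(sc, ": sidecar must provide 'sample_rate' and 'scale'")
  n <- file.size(path) %/% 2L
  counts <- readBin(path, what = "integer", n = n, size = 2L,
                    signed = TRUE, endian = "little")
  structure(counts * meta$scale,
            sample_rate = meta$sample_rate, scale = meta$scale)
}

#' Write a single-channel signal file
#'
#' @param x numeric samples.
#' @param path output path.
#' @param format `"csv"` or `"raw"` (little-endian int16 plus JSON sidecar).
#' @param sample_rate sampling rate recorded in the raw sidecar (Hz).
#' @param scale signal units per integer count for raw output; by default
#'   chosen so the largest magnitude maps to 32000 counts.
#' @param comment optional character vector written as leading `#` lines
#'   (CSV only), used by the CLI to embed the run configuration.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = c("csv", "raw"),
                         sample_rate = 30000, scale = NULL, comment = NULL) {
  format <- match.arg(format)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  if (format == "csv") {
    lines <- c(if (length(comment)) paste0("# ", comment),
               "index,value",
               paste(seq_along(x) - 1L, format(x, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                     sep = ","))
    writeLines(lines, path)
  } else {
    if (is.null(scale))
      scale <- if (max(abs(x)) == 0) 1 else max(abs(x)) / 32000
    counts <- as.integer(round(x / scale))
    counts <- pmax(pmin(counts, 32767L), -32768L)
    writeBin(counts, path, size = 2L, endian = "little")
    jsonlite::write_json(list(sample_rate = sample_rate, scale = scale),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read and write spike-event tables
#'
#' Events are exchanged as CSV with header `index,peak,threshold` and
#' optional leading `#` comment lines.
#'
#' @param events a `spike_events` data.frame (see [detect_crossings()]).
#' @param path file path.
#' @param comment optional `#` comment lines.
#' @return `write_events()` returns `path` invisibly; `read_events()` a
#'   `spike_events` data.frame.
#' @export
write_events <- function(events, path, comment = NULL) {
  stopifnot(is.data.frame(events),
            all(c("index", "peak", "threshold") %in% names(events)))
  lines <- c(if (length(comment)) paste0("# ", comment),
             "index,peak,threshold",
             sprintf("%d,%.17g,%.17g", as.integer(events$index),
                     events$peak, events$threshold))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines) || trimws(lines[1]) != "index,peak,threshold")
    stop(path, ": expected header 'index,peak,threshold'")
  if (length(lines) == 1L)
    ev <- data.frame(index = integer(0), peak = numeric(0),
                     threshold = numeric(0))
  else {
    m <- do.call(rbind, strsplit(lines[-1], ",", fixed = TRUE))
    ev <- data.frame(index = as.integer(m[, 1]), peak = as.numeric(m[, 2]),
                     threshold = as.numeric(m[, 3]))
  }
  structure(ev, class = c("spike_events", "data.frame"))
}
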