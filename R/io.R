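#' Read timestamps from a one-per-line text file
#'
#' One decimal number (seconds) per non-comment line; `'#'` starts a comment
#' and blank lines are ignored. Output is sorted; duplicates are allowed.
#' An unparsable line raises an error naming the line number.
#'
#' @param path Path to the file.
#' @param units `"s"` (default) or `"ms"`; millisecond input is converted to
#'   seconds on ingest.
#' @return Sorted numeric vector of times in seconds.
#' @export
read_timestamps <- function(path, units = c("s", "ms")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("timestamp file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", lines))
  keep <- which(nzchar(stripped))
  vals <- suppressWarnings(as.numeric(stripped[keep]))
  if (anyNA(vals)) {
    bad <- keep[which(is.na(vals))[1]]
    stop("unparsable timestamp at line ", bad, " of ", path, ": '",
         lines[bad], "'")
  }
  if (length(vals) == 0) warning("no timestamps in ", path)
  if (units == "ms") vals <- vals / 1000
  sort(vals)
}

#' Write timestamps as one-per-line text
#'
#' Seconds at 9 decimal places (nanosecond resolution), one per line.
#'
#' @param times Numeric vector of times (s).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timestamps <- function(times, path) {
  writeLines(sprintf("%.9f", as.numeric(times)), path)
  invisible(path)
}

#' Write a JSON result report
#'
#' Every report carries a schema version, the resolved configuration and the
#' seed alongside the numeric payload, so a run can be reproduced from its
#' own output (reproducibility manifest).
#'
#' @param payload A serializable result (list, data frame, summary object).
#' @param path Output path.
#' @param seed The seed the run used (or `NULL`).
#' @param config The resolved configuration (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_report <- function(payload, path, seed = NULL, config = NULL) {
  if (inherits(payload, "delay_summary")) payload <- unclass(payload)
  if (is.data.frame(payload)) {
    payload <- as.list(payload)
  }
  report <- list(schema_version = "1.0",
                 seed = seed,
                 config = config,
                 payload = payload)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Persist a calibration table as JSON
#'
#' @param table A `calibration_table` from [calibrate_frequencies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  obj <- list(schema_version = "1.0",
              target_level = attr(table, "target_level"),
              backend = attr(table, "backend"),
              created = attr(table, "created"),
              entries = as.data.frame(table))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calibration table from JSON
#'
#' @param path Path written by [write_calibration_table()].
#' @return A `calibration_table`.
#' @export
read_calibration_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as.data.frame(obj$entries)
  attr(out, "target_level") <- obj$target_level
  attr(out, "backend") <- obj$backend
  attr(out, "created") <- obj$created
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' Samples are clamped to [-1, 1] (clipping is reported with a warning) and
#' quantized to signed 16-bit integers at full scale 32767.
#'
#' @param waveform A `waveform` (list of `samples`, `sample_rate`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path) {
  stopifnot(inherits(waveform, "waveform"))
  s <- waveform$samples
  if (any(abs(s) > 1)) {
    warning(sum(abs(s) > 1), " samples clipped to full scale on WAV export")
    s <- pmin(pmax(s, -1), 1)
  }
  pcm <- as.integer(round(s * 32767))
  sr <- as.integer(waveform$sample_rate)
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")         # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(2L * sr, con, size = 4, endian = "little")     # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal reader for files produced by [write_wav()] (PCM, mono, 16-bit);
#' walks the RIFF chunks to locate `fmt ` and `data`.
#'
#' @param path Path to the WAV file.
#' @return A `waveform` with samples rescaled to [-1, 1].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1) stop("only PCM mono WAV is supported")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      bits <- readBin(con, "integer", n = 2, size = 2, endian = "little")[2]
      if (bits != 16) stop("only 16-bit WAV is supported")
    } else if (id == "data") {
      samples <- readBin(con, "integer", n = size / 2, size = 2,
                         signed = TRUE, endian = "little")
    } else {
      seek(con, size, origin = "current")
    }
    if (!is.null(sample_rate) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  new_waveform(samples / 32767, sample_rate)
}
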