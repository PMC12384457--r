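#' Minimal GDF-style recording reader
#'
#' Reads the subset of the GDF 2.x binary layout that cue-based
#' motor-imagery pipelines need: the fixed header (sampling geometry,
#' channel count, record count), per-channel headers (labels, physical and
#' digital ranges, samples per record, sample type), the sample records
#' (int16 or float32, little-endian, converted to physical units), and the
#' trailing event table (mode 1 or 3). It is a native subset implementation,
#' not a full biosig reader; files produced by [write_gdf()] round-trip
#' exactly, and the supported fields are the ones the epoching pipeline
#' consumes.
#'
#' @param path Path to the recording.
#' @return A `raw_recording`: list with `signal` (channels x samples matrix,
#'   physical units), `fs` (Hz), `events` (data frame with 0-based `sample`
#'   and integer `code`), `channel_names`.
#' @export
read_gdf <- function(path) {
  if (!file.exists(path)) stop(sprintf("GDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!startsWith(magic, "GDF"))
    stop(sprintf("not a GDF file (magic '%s'): %s", trimws(magic), path))
  seek(con, 184L)
  head_blocks <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                         endian = "little")
  seek(con, 236L)
  n_rec <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, 244L)
  dur <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  seek(con, 252L)
  ns <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                endian = "little")
  if (ns < 1L || n_rec < 0L || head_blocks < ns + 1L)
    stop(sprintf("corrupt GDF header in %s", path))
  rec_dur <- dur[1L] / dur[2L]

  seek(con, 256L)
  labels <- vapply(seq_len(ns), function(i)
    trimws(rawToChar(readBin(con, "raw", 16L))), character(1L))
  physdim <- vapply(seq_len(ns), function(i)
    trimws(rawToChar(readBin(con, "raw", 6L))), character(1L))
  physmin <- readBin(con, "double", ns, size = 8L, endian = "little")
  physmax <- readBin(con, "double", ns, size = 8L, endian = "little")
  digmin <- readBin(con, "double", ns, size = 8L, endian = "little")
  digmax <- readBin(con, "double", ns, size = 8L, endian = "little")
  spr <- readBin(con, "integer", ns, size = 4L, endian = "little")
  gdftyp <- readBin(con, "integer", ns, size = 4L, endian = "little")
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[1L] / rec_dur
  scale <- (physmax - physmin) / (digmax - digmin)
  offset <- physmin - digmin * scale

  seek(con, 256L * (1L + ns))
  n_samp <- n_rec * spr[1L]
  signal <- matrix(0, ns, n_samp)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      vals <- switch(as.character(gdftyp[ch]),
        "3" = readBin(con, "integer", spr[ch], size = 2L, signed = TRUE,
                      endian = "little"),
        "16" = readBin(con, "double", spr[ch], size = 4L, endian = "little"),
        stop(sprintf("unsupported GDF sample type %d", gdftyp[ch])))
      if (length(vals) < spr[ch])
        stop(sprintf("truncated GDF data records in %s", path))
      signal[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        vals * scale[ch] + offset[ch]
    }
  }

  events <- data.frame(sample = integer(0), code = integer(0))
  mode_raw <- readBin(con, "raw", 1L)
  if (length(mode_raw) == 1L) {
    mode <- as.integer(mode_raw)
    nev <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    readBin(con, "double", 1L, size = 4L, endian = "little")  # event fs
    pos <- readBin(con, "integer", nev, size = 4L, endian = "little")
    typ <- readBin(con, "integer", nev, size = 2L, signed = FALSE,
                   endian = "little")
    if (length(pos) < nev || length(typ) < nev)
      stop(sprintf("truncated GDF event table in %s", path))
    events <- data.frame(sample = pos - 1L, code = typ)  # file is 1-based
    if (mode == 3L) {
      readBin(con, "integer", nev, size = 2L, signed = FALSE, endian = "little")
      readBin(con, "integer", nev, size = 4L, endian = "little")
    }
  }
  if (any(events$sample < 0L) || any(events$sample >= n_samp))
    stop(sprintf("GDF event outside the recording in %s", path))

  structure(list(signal = signal, fs = fs, events = events,
                 channel_names = labels, physdim = physdim),
            class = "raw_recording")
}

#' Write a recording in the minimal GDF-style layout
#'
#' Counterpart of [read_gdf()]; stores samples as float32 with identity
#' digital scaling. Used to build test fixtures and to materialise synthetic
#' recordings in an interchange format.
#'
#' @param rec A `raw_recording` (or list with `signal`, `fs`, `events`,
#'   `channel_names`).
#' @param path Output path.
#' @param record_s Duration of one data record in seconds; the signal length
#'   must be a whole number of records.
#' @return `path`, invisibly.
#' @export
write_gdf <- function(rec, path, record_s = 1) {
  signal <- as.matrix(rec$signal)
  ns <- nrow(signal)
  fs <- rec$fs
  spr <- as.integer(round(fs * record_s))
  if (ncol(signal) %% spr != 0L)
    stop("signal length must be a whole number of records")
  n_rec <- ncol(signal) %/% spr
  labels <- rec$channel_names %||% paste0("ch", seq_len(ns))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  pad_to <- function(at) {
    cur <- seek(con)
    if (at < cur) stop("internal header overflow")
    writeBin(raw(at - cur), con)
  }
  writeBin(charToRaw(sprintf("%-8s", "GDF 2.20")), con)
  pad_to(184L)
  writeBin(as.integer(1L + ns), con, size = 2L, endian = "little")
  pad_to(236L)
  writeBin(as.integer(n_rec), con, size = 4L, endian = "little")
  pad_to(244L)
  # record duration as a rational number (numerator seconds, denominator 1)
  den <- 1000000L
  writeBin(as.integer(round(record_s * den)), con, size = 4L, endian = "little")
  writeBin(den, con, size = 4L, endian = "little")
  writeBin(as.integer(ns), con, size = 2L, endian = "little")
  pad_to(256L)

  for (lab in labels)
    writeBin(charToRaw(formatC(substr(lab, 1L, 16L), width = -16L)), con)
  for (i in seq_len(ns)) writeBin(charToRaw(sprintf("%-6s", "uV")), con)
  rng <- apply(signal, 1L, range)
  physmin <- rng[1L, ] - 1; physmax <- rng[2L, ] + 1
  writeBin(physmin, con, size = 8L, endian = "little")
  writeBin(physmax, con, size = 8L, endian = "little")
  writeBin(physmin, con, size = 8L, endian = "little")  # digital = physical
  writeBin(physmax, con, size = 8L, endian = "little")
  writeBin(rep(spr, ns), con, size = 4L, endian = "little")
  writeBin(rep(16L, ns), con, size = 4L, endian = "little")  # float32
  pad_to(256L * (1L + ns))

  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      writeBin(signal[ch, ((r - 1L) * spr + 1L):(r * spr)], con,
               size = 4L, endian = "little")
    }
  }

  ev <- rec$events
  if (is.null(ev)) ev <- data.frame(sample = integer(0), code = integer(0))
  writeBin(as.raw(1L), con)
  writeBin(as.integer(nrow(ev)), con, size = 4L, endian = "little")
  writeBin(fs, con, size = 4L, endian = "little")
  writeBin(as.integer(ev$sample + 1L), con, size = 4L, endian = "little")
  writeBin(as.integer(ev$code), con, size = 2L, endian = "little")
  invisible(path)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$events)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
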