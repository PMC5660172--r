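# Recording and event I/O: EDF (European Data Format) and a delimited-text
# fallback (TSV samples + key=value sidecar). EDF layout: 256-byte fixed
# header, 256 bytes per signal of field headers, then little-endian int16
# data records with per-signal physical/digital scaling.

edf_pad <- function(x, n) {
  x <- substr(as.character(x), 1L, n)
  sprintf(paste0("%-", n, "s"), x)
}

edf_num <- function(x, n) {
  s <- formatC(x, digits = n - 1L, width = 1, format = "g")
  if (nchar(s) > n) s <- substr(s, 1L, n)
  edf_pad(s, n)
}

#' Write a recording
#'
#' @param rec an [recording()].
#' @param path output file path.
#' @param format `"edf"` for European Data Format (16-bit), or
#'   `"delimited"` for a TSV of samples (one column per channel, header row
#'   of labels) plus a `<path>.meta` sidecar holding `fs` and `start_time`.
#' @return `path`, invisibly.
#' @details EDF stores whole one-second data records; a trailing partial
#'   second is dropped with a warning. Samples are quantized to the 16-bit
#'   digital range over each channel's observed physical range.
#' @export
write_recording <- function(rec, path, format = c("edf", "delimited")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "delimited") {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$labels
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(c(paste0("fs=", rec$fs), paste0("start_time=", rec$start_time)),
               paste0(path, ".meta"))
    return(invisible(path))
  }
  ns <- nrow(rec$data)
  spr <- as.integer(round(rec$fs))           # samples per 1 s record
  if (abs(spr - rec$fs) > 1e-9)
    stop_param("EDF writer requires an integer sampling rate")
  nrec <- ncol(rec$data) %/% spr
  if (nrec * spr < ncol(rec$data))
    warning("EDF: dropping trailing partial data record (",
            ncol(rec$data) - nrec * spr, " samples)")
  if (nrec < 1) stop_param("recording shorter than one EDF data record (1 s)")
  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-6
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("tauconn", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (ns + 1L), 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  sig <- paste0(
    paste(vapply(rec$labels, edf_pad, "", n = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", n = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", n = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  # recompute physical extrema as written (string round-trip) so scaling on
  # read matches scaling on write
  pmin_w <- as.numeric(vapply(pmin, edf_num, "", n = 8))
  pmax_w <- as.numeric(vapply(pmax, edf_num, "", n = 8))
  gain <- (pmax_w - pmin_w) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- as.integer(round((rec$data[s, idx] - pmin_w[s]) / gain[s]) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording
#'
#' @param path file path.
#' @param format `"edf"` or `"delimited"` (see [write_recording()]).
#' @return An [recording()] with channel count, labels and sampling rate taken
#'   from the file header and samples converted to microvolts.
#' @export
read_recording <- function(path, format = c("edf", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_param("cannot read recording: no such file '", path, "'")
  if (format == "delimited") {
    meta_path <- paste0(path, ".meta")
    if (!file.exists(meta_path))
      stop_param("missing sidecar metadata file '", meta_path, "'")
    kv <- strsplit(readLines(meta_path), "=", fixed = TRUE)
    meta <- stats::setNames(
      vapply(kv, function(p) p[2], ""), vapply(kv, function(p) p[1], ""))
    fs <- as.numeric(meta[["fs"]])
    st <- as.numeric(meta["start_time"] %||% "0")
    if (is.na(st)) st <- 0
    df <- utils::read.delim(path, check.names = FALSE)
    if (nrow(df) == 0) stop_param("empty recording file '", path, "'")
    return(recording(t(as.matrix(df)), fs = fs, labels = names(df),
                     start_time = st))
  }
  info <- file.info(path)
  if (is.na(info$size) || info$size < 256)
    stop_param("not a readable EDF file (too short): '", path, "'")
  con <- file(path, "rb")
  on.exit(close(con))
  rd_s <- function(n) {
    raw <- readChar(con, n, useBytes = TRUE)
    trimws(raw)
  }
  rd_s(8)                                    # version
  rd_s(80); rd_s(80); rd_s(8); rd_s(8)       # ids, date, time
  rd_s(8); rd_s(44)
  nrec <- as.integer(rd_s(8))
  recdur <- as.numeric(rd_s(8))
  ns <- as.integer(rd_s(4))
  if (is.na(ns) || ns < 1 || is.na(nrec))
    stop_param("malformed EDF header in '", path, "'")
  fld <- function(w) vapply(seq_len(ns), function(i) rd_s(w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1L)
    stop_param("EDF with heterogeneous per-signal sampling rates is not supported")
  fs <- spr[1] / recdur
  gain <- (pmax - pmin) / (dmax - dmin)
  data <- matrix(0, nrow = ns, ncol = nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) != spr[1])
        stop_param("truncated EDF data record in '", path, "'")
      idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
      data[s, idx] <- pmin[s] + (dig - dmin[s]) * gain[s]
    }
  }
  recording(data, fs = fs, labels = labels)
}

#' Read / write event tables
#'
#' Event files are TSV with columns `onset_s` and `code`.
#'
#' @param path file path.
#' @return [read_events()] returns an [event_list()].
#' @export
read_events <- function(path) {
  if (!file.exists(path))
    stop_param("cannot read events: no such file '", path, "'")
  df <- utils::read.delim(path)
  if (!all(c("onset_s", "code") %in% names(df)))
    stop_param("event file must have columns onset_s and code")
  event_list(df$onset_s, df$code)
}

#' @rdname read_events
#' @param events an [event_list()].
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
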