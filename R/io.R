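# Recording I/O: a plain-text dump format, a minimal EDF reader/writer,
# and CSV table output.  The dump format is the package's documented
# interchange format; EDF covers the common clinical container (16-bit,
# fixed-layout header — implemented directly since no R EDF parser is
# available as a dependency).

#' Write a recording as a plain-text dump
#'
#' Format: comment header (`# microstatr-dump v1`, `# sfreq:`,
#' `# channels:`, optional `# positions:` with `x y z` triplets separated
#' by `;`), then one tab-separated line per sample.  Values are printed
#' with 17 significant digits, so a write/read round trip is bit-identical.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_dump <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# microstatr-dump v1", con)
  writeLines(sprintf("# sfreq: %.17g", rec$sfreq), con)
  ch <- rownames(rec$data) %||% sprintf("E%03d", seq_len(nrow(rec$data)))
  writeLines(paste0("# channels: ", paste(ch, collapse = ",")), con)
  if (!is.null(rec$layout)) {
    pos <- apply(rec$layout$positions, 1L, function(p)
      paste(sprintf("%.17g", p), collapse = " "))
    writeLines(paste0("# positions: ", paste(pos, collapse = ";")), con)
  }
  # samples as rows, 17 significant digits (doubles round-trip exactly)
  writeLines(apply(rec$data, 2L, function(v)
    paste(sprintf("%.17g", v), collapse = "\t")), con)
  invisible(path)
}

#' Read a plain-text recording dump
#'
#' @param path file written by [write_recording_dump()].
#' @return an `eeg_recording` (with layout when positions were stored).
#' @export
read_recording_dump <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "# microstatr-dump v1") {
    stop_invalid("not a microstatr dump: ", path)
  }
  hdr <- grep("^#", lines)
  get_field <- function(name) {
    ln <- grep(paste0("^# ", name, ": "), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", name, ": "), "", ln[1L])
  }
  sfreq <- as.numeric(get_field("sfreq"))
  channels <- strsplit(get_field("channels"), ",", fixed = TRUE)[[1L]]
  body <- lines[-hdr]
  if (!length(body)) stop_invalid("truncated dump: no samples")
  mat <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  if (ncol(mat) != length(channels) || anyNA(mat)) {
    stop_invalid("truncated or corrupt dump: ", path)
  }
  data <- t(mat)
  rownames(data) <- channels
  layout <- NULL
  pos_field <- get_field("positions")
  if (!is.null(pos_field)) {
    pos <- do.call(rbind, lapply(strsplit(pos_field, ";", fixed = TRUE)[[1L]],
                                 function(s) as.numeric(strsplit(s, " ")[[1L]])))
    colnames(pos) <- c("x", "y", "z")
    layout <- structure(list(channel_names = channels, positions = pos),
                        class = "eeg_layout")
  }
  structure(list(data = data, sfreq = sfreq, layout = layout,
                 annotations = list()),
            class = "eeg_recording")
}

# --- minimal EDF ------------------------------------------------------

.pad <- function(s, width) {
  s <- substr(s, 1L, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write a recording to EDF
#'
#' Minimal EDF writer: continuous signals, common sampling rate, 16-bit
#' samples scaled channel-wise to the physical range, 1-second data
#' records; a trailing partial record is dropped.
#'
#' @param rec an `eeg_recording` (data in microvolts).
#' @param path output path.
#' @param record_s data-record duration in seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_s = 1) {
  ns <- nrow(rec$data)
  spr <- round(record_s * rec$sfreq)
  nr <- floor(ncol(rec$data) / spr)
  if (nr < 1L) stop_invalid("recording shorter than one EDF record")
  ch <- rownames(rec$data) %||% sprintf("E%03d", seq_len(ns))
  pmin_v <- apply(rec$data, 1L, min)
  pmax_v <- apply(rec$data, 1L, max)
  same <- pmax_v - pmin_v < 1e-12
  pmax_v[same] <- pmin_v[same] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wch <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wch(.pad("0", 8))
  wch(.pad("X X X X", 80))
  wch(.pad("Startdate 01-JAN-2000 X X microstatr", 80))
  wch(.pad("01.01.00", 8)); wch(.pad("00.00.00", 8))
  wch(.pad(as.character(256L + ns * 256L), 8))
  wch(.pad("", 44))
  wch(.pad(as.character(nr), 8))
  wch(.pad(sprintf("%g", record_s), 8))
  wch(.pad(as.character(ns), 4))
  for (s in ch) wch(.pad(s, 16))
  for (s in seq_len(ns)) wch(.pad("AgAgCl electrode", 80))
  for (s in seq_len(ns)) wch(.pad("uV", 8))
  for (v in pmin_v) wch(.pad(sprintf("%.8g", v), 8))
  for (v in pmax_v) wch(.pad(sprintf("%.8g", v), 8))
  for (s in seq_len(ns)) wch(.pad(as.character(dmin), 8))
  for (s in seq_len(ns)) wch(.pad(as.character(dmax), 8))
  for (s in seq_len(ns)) wch(.pad("", 80))
  for (s in seq_len(ns)) wch(.pad(as.character(spr), 8))
  for (s in seq_len(ns)) wch(.pad("", 32))

  scale <- (dmax - dmin) / (pmax_v - pmin_v)
  for (r in seq_len(nr)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((rec$data[s, cols] - pmin_v[s]) * scale[s] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Minimal EDF reader for continuous recordings with a common sampling
#' rate across signals.  Values are returned in the file's physical units
#' (expected microvolts).
#'
#' @param path EDF file path.
#' @return an `eeg_recording` (layout NULL; see [read_recording()]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rch <- function(n) readChar(con, n, useBytes = TRUE)
  rnum <- function(n) as.numeric(trimws(rch(n)))
  rch(8)                       # version
  rch(80); rch(80); rch(8); rch(8)
  header_bytes <- rnum(8)
  rch(44)
  nr <- rnum(8)
  record_s <- rnum(8)
  ns <- as.integer(rnum(4))
  if (is.na(ns) || ns < 1L) stop_invalid("corrupt EDF header")
  labels <- trimws(vapply(seq_len(ns), function(i) rch(16), character(1)))
  for (i in seq_len(ns)) rch(80)
  for (i in seq_len(ns)) rch(8)
  pmin_v <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  pmax_v <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  for (i in seq_len(ns)) rch(80)
  spr <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  for (i in seq_len(ns)) rch(32)
  if (length(unique(spr)) != 1L) {
    stop_invalid("EDF with mixed sampling rates not supported")
  }
  spr <- spr[1L]
  sfreq <- spr / record_s
  data <- matrix(NA_real_, ns, nr * spr)
  for (r in seq_len(nr)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr, size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr) stop_invalid("truncated EDF data: ", path)
      phys <- (dig - dmin[s]) / (dmax[s] - dmin[s]) * (pmax_v[s] - pmin_v[s]) +
        pmin_v[s]
      data[s, ((r - 1L) * spr + 1L):(r * spr)] <- phys
    }
  }
  rownames(data) <- labels
  structure(list(data = data, sfreq = sfreq, layout = NULL,
                 annotations = list()),
            class = "eeg_recording")
}

#' Read a recording from any supported container
#'
#' @param path file path.
#' @param format one of `"dump"`, `"edf"`; `"fif"` is not supported and
#'   errors informatively.
#' @param layout optional `eeg_layout`; when absent, a scalp-cap layout is
#'   built for channel names of the package's `E###` convention, otherwise
#'   the unmapped names are reported.
#' @return an `eeg_recording` with a layout attached.
#' @export
read_recording <- function(path, format = c("dump", "edf", "fif"),
                           layout = NULL) {
  format <- match.arg(format)
  rec <- switch(format,
                dump = read_recording_dump(path),
                edf = read_edf(path),
                fif = stop_invalid("FIF reading is not supported; ",
                                   "convert to EDF or the dump format"))
  if (is.null(rec$layout)) {
    ch <- rownames(rec$data)
    if (!is.null(layout)) {
      if (!identical(layout$channel_names, ch)) {
        stop_invalid("layout/channel name mismatch")
      }
      rec$layout <- layout
    } else if (all(grepl("^E\\d{3}$", ch))) {
      lay <- make_layout(length(ch))
      lay$channel_names <- ch
      rec$layout <- lay
    } else {
      stop_invalid("no layout for channels: ", paste(ch, collapse = ", "))
    }
  }
  rec
}

#' Write a results table as CSV
#'
#' UTF-8, `.` decimal separator, header row, missing values as empty
#' fields, stable column order.
#'
#' @param table nonempty data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  if (!nrow(table)) stop_invalid("refusing to write an empty table")
  utils::write.csv(table, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
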