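# File ingestion and export.  Two signal formats are supported: continuous
# EDF (16-bit, physical-dimension honoured and converted to muV) and a
# delimited text format with a one-line header.  Event markers travel as a
# two-column CSV (time_s, label).

edf_pad <- function(x, width) {
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

dim_to_uv <- function(dim) {
  d <- trimws(dim)
  # EDF files write the micro sign either as "u" or as UTF-8 mu
  if (d %in% c("uV", "µV", "μV", "")) return(1)
  if (d == "mV") return(1e3)
  if (d == "V") return(1e6)
  if (d == "nV") return(1e-3)
  warning("unrecognised physical dimension '", dim, "'; assuming uV")
  1
}

#' Read a continuous EDF recording
#'
#' Minimal reader for continuous (non-discontinuous) EDF/EDF+ files with
#' identical sampling rate on every signal.  Physical dimensions V, mV, uV
#' and nV are converted to muV.  EDF+ annotation signals are skipped (event
#' markers are read separately with [read_events_csv()]).
#'
#' @param path EDF file path.
#' @return an [recording()] object in muV.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr(8L)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  hdr(80L); hdr(80L)          # patient, recording id
  hdr(8L); hdr(8L)            # start date, time
  header_bytes <- as.integer(hdr(8L))
  hdr(44L)                    # reserved
  n_records <- as.integer(hdr(8L))
  record_dur <- as.numeric(hdr(8L))
  ns <- as.integer(hdr(4L))
  field <- function(width) vapply(seq_len(ns), function(i) hdr(width), "")
  labels <- field(16L)
  field(80L)                  # transducer
  dims <- field(8L)
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  field(80L)                  # prefiltering
  nsamp <- as.integer(field(8L))
  field(32L)                  # reserved
  stopifnot(header_bytes == 256L + 256L * ns)
  keep <- !grepl("^EDF Annotations", labels)
  if (length(unique(nsamp[keep])) != 1L)
    stop("EDF signals have differing sampling rates; not supported")
  fs <- nsamp[keep][1L] / record_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  total <- n_records * nsamp[keep][1L]
  out <- matrix(0, nrow = sum(keep), ncol = total)
  row_of <- cumsum(keep)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = nsamp[s], size = 2L, signed = TRUE,
                   endian = "little")
      if (!keep[s]) next
      phys <- (v - dig_min[s]) * scale[s] + phys_min[s]
      cols <- ((r - 1L) * nsamp[s] + 1L):(r * nsamp[s])
      out[row_of[s], cols] <- phys * dim_to_uv(dims[s])
    }
  }
  recording(out, fs = fs, channel_labels = labels[keep])
}

#' Write a recording as continuous EDF
#'
#' One data record per second (`fs` must be a whole number); samples are
#' quantised to 16 bits over each channel's observed range, physical
#' dimension "uV".  The recording is zero-padded to a whole number of
#' records.
#'
#' @param rec an [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  n_records <- ceiling(n / fs)
  x <- cbind(rec$samples, matrix(0, ns, n_records * fs - n))
  pmin_ <- apply(x, 1L, min); pmax_ <- apply(x, 1L, max)
  pad <- pmax(1e-6, (pmax_ - pmin_) * 0.005)
  pmin_ <- pmin_ - pad; pmax_ <- pmax_ + pad
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(v, width) writeBin(charToRaw(paste0(vapply(v, edf_pad, "", width = width),
                                                      collapse = "")), con)
  put("0", 8L)
  put("synthetic", 80L); put("gaborclean export", 80L)
  put("01.01.00", 8L); put("00.00.00", 8L)
  put(as.character(256L + 256L * ns), 8L)
  put("", 44L)
  put(as.character(n_records), 8L)
  put("1", 8L)
  put(as.character(ns), 4L)
  putn <- function(v, width) put(as.character(v), width)
  putn(rec$channel_labels, 16L)
  putn(rep("", ns), 80L)
  putn(rep("uV", ns), 8L)
  putn(formatC(pmin_, digits = 5, format = "g"), 8L)
  putn(formatC(pmax_, digits = 5, format = "g"), 8L)
  putn(rep(dmin, ns), 8L)
  putn(rep(dmax, ns), 8L)
  putn(rep("", ns), 80L)
  putn(rep(fs, ns), 8L)
  putn(rep("", ns), 32L)
  pmin_w <- as.numeric(formatC(pmin_, digits = 5, format = "g"))
  pmax_w <- as.numeric(formatC(pmax_, digits = 5, format = "g"))
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((x[s, cols] - pmin_w[s]) / (pmax_w[s] - pmin_w[s]) * (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(dmax, pmax(dmin, dig))), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from delimited text
#'
#' First line is a header `# fs=<Hz> channels=<lab1,lab2,...>`; the rest is
#' a numeric matrix, one time point per row, one channel per column, in muV.
#'
#' @param path file path.
#' @return an [recording()].
#' @export
read_recording_txt <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("fs=([0-9.]+)\\s+channels=(\\S+)", hdr))[[1L]]
  if (length(m) != 3L) stop("malformed header line in ", path,
                            " (expected '# fs=<Hz> channels=<a,b,...>')")
  fs <- as.numeric(m[2L])
  labels <- strsplit(m[3L], ",")[[1L]]
  x <- as.matrix(utils::read.table(path, skip = 1L))
  if (ncol(x) != length(labels)) stop("column count does not match channel labels")
  recording(t(x), fs = fs, channel_labels = labels)
}

#' Write a recording as delimited text
#' @param rec an [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_txt <- function(rec, path) {
  writeLines(sprintf("# fs=%g channels=%s", rec$fs,
                     paste(rec$channel_labels, collapse = ",")), path)
  utils::write.table(format(t(rec$samples), digits = 10, trim = TRUE, scientific = TRUE),
                     path, append = TRUE, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read event markers from a two-column CSV
#' @param path CSV with columns `time_s,label`.
#' @param label if given, keep only events with this label.
#' @return an [event_series()].
#' @export
read_events_csv <- function(path, label = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "label") %in% names(d)))
    stop("event CSV must have columns time_s,label")
  if (!is.null(label)) d <- d[d$label == label, , drop = FALSE]
  if (!nrow(d)) stop("no events", if (!is.null(label)) paste0(" with label '", label, "'"))
  event_series(sort(d$time_s), label = label %||% d$label[1L])
}

#' Write event markers to CSV
#' @param events an [event_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(data.frame(time_s = events$times, label = events$label),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
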