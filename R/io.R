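# full-precision numeric formatting: shortest representation that
# round-trips a double exactly
.fmt <- function(x) sprintf("%.17g", x)

#' Write a recording as a full-precision CSV matrix
#'
#' Samples as rows, channels as columns, header row = channel names.
#' Values are written with 17 significant digits so the round trip is
#' lossless. The sampling rate goes into a JSON sidecar `<path>.json`.
#'
#' @param rec An [eeg_recording].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$data)
  lines <- c(paste(rec$channel_names, collapse = ","),
             apply(m, 1, function(r) paste(.fmt(r), collapse = ",")))
  writeLines(lines, path)
  jsonlite::write_json(list(fs = rec$fs, n_channels = nrow(rec$data),
                            n_samples = ncol(rec$data)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a recording from CSV or EDF
#'
#' CSV matrices are samples x channels with a channel-name header row; the
#' sampling rate comes from the `<path>.json` sidecar or the `fs` argument.
#' Files ending in `.edf` are dispatched to [read_edf()].
#'
#' @param path Input path (`.csv` or `.edf`).
#' @param fs Sampling rate in Hz; overrides/replaces the sidecar for CSV.
#' @return An [eeg_recording].
#' @export
read_recording <- function(path, fs = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (any(!is.na(suppressWarnings(as.numeric(header)))))
    stop("malformed header (line 1): expected channel names, got numbers")
  nch <- length(header)
  vals <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(vals) != nch)
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, ": expected ", nch,
         " fields, got ", lengths(vals)[bad[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(vals))), nrow = nch)
  if (anyNA(m)) {
    badrow <- which(apply(m, 2, anyNA))[1]
    stop("non-numeric data at line ", badrow + 1L)
  }
  if (is.null(fs)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("sampling rate unknown: pass 'fs' or provide ", sidecar)
    fs <- jsonlite::read_json(sidecar)$fs
    if (is.null(fs) || !is.numeric(fs))
      stop("sampling rate missing or non-numeric in ", sidecar)
  }
  eeg_recording(m, fs, header)
}

#' Write an epoch set as CSV plus JSON sidecar
#'
#' One numeric container: rows are (epoch, sample) pairs in order, columns
#' are channels; the sidecar carries fs, epoch length and counts.
#'
#' @param ep An [eeg_epochs].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$epochs)
  m <- matrix(0, d[1] * d[3], d[2])
  for (e in seq_len(d[1]))
    m[((e - 1) * d[3] + 1):(e * d[3]), ] <- t(matrix(ep$epochs[e, , ], dim(ep$epochs)[2]))
  lines <- c(paste(ep$channel_names, collapse = ","),
             apply(m, 1, function(r) paste(.fmt(r), collapse = ",")))
  writeLines(lines, path)
  jsonlite::write_json(list(fs = ep$fs, n_epochs = d[1], n_channels = d[2],
                            epoch_length_s = ep$epoch_length_s),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return An [eeg_epochs].
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  rec <- read_recording(path, fs = meta$fs)
  len <- as.integer(round(meta$epoch_length_s * meta$fs))
  arr <- array(0, c(meta$n_epochs, nrow(rec$data), len))
  for (e in seq_len(meta$n_epochs))
    arr[e, , ] <- rec$data[, ((e - 1) * len + 1):(e * len)]
  eeg_epochs(arr, meta$fs, rec$channel_names)
}

#' Write template maps as CSV (channels x k, labelled columns)
#' @param ts An [ms_templates].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_templates <- function(ts, path) {
  stopifnot(inherits(ts, "ms_templates"))
  m <- t(ts$maps)
  lines <- c(paste(ts$class_labels, collapse = ","),
             apply(m, 1, function(r) paste(.fmt(r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a backfitted label sequence as tidy CSV (epoch, sample, class)
#' @param ls An `ms_labels` from [backfit()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(ls, path) {
  stopifnot(inherits(ls, "ms_labels"))
  d <- dim(ls$labels)
  df <- data.frame(epoch = rep(seq_len(d[1]), each = d[2]),
                   sample = rep(seq_len(d[2]), times = d[1]),
                   class = ls$class_labels[as.vector(t(ls$labels))])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write or read a lead field as CSV (channels x voxels, voxel-id header)
#' @param lf An `ms_leadfield`.
#' @param path CSV path.
#' @return `path` (write) or an `ms_leadfield` (read).
#' @export
write_leadfield <- function(lf, path) {
  stopifnot(inherits(lf, "ms_leadfield"))
  lines <- c(paste(lf$voxel_ids, collapse = ","),
             apply(lf$matrix, 1, function(r) paste(.fmt(r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  vals <- strsplit(lines[-1], ",", fixed = TRUE)
  m <- t(matrix(as.numeric(unlist(vals)), nrow = length(ids)))
  if (anyNA(m)) stop("non-numeric lead field data in ", path)
  structure(list(matrix = m, voxel_ids = ids,
                 channel_names = paste0("Ch", seq_len(nrow(m)))),
            class = "ms_leadfield")
}

# ---------------------------------------------------------------------------
# Minimal EDF (European Data Format) support: continuous 16-bit recordings,
# one fixed-duration data record per second. Sufficient for ingesting and
# exporting plain resting EEG; no annotations, no EDF+.

.edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording as a minimal EDF file
#'
#' Continuous EDF with 1-s data records and 16-bit samples; the physical
#' range is set symmetrically per channel from the data. The sampling rate
#' must be an integer and the duration is truncated to whole seconds.
#'
#' @param rec An [eeg_recording]; `fs` must be an integer.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer fs")
  fs <- as.integer(round(fs))
  nrec <- ncol(rec$data) %/% fs
  if (nrec < 1) stop("recording shorter than one EDF data record (1 s)")
  nch <- nrow(rec$data)
  x <- rec$data[, seq_len(nrec * fs), drop = FALSE]
  pmax_ <- pmax(apply(abs(x), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(.edf_pad(s, width), con, width,
                                     eos = NULL)
  wr("0", 8); wr("synthetic subject", 80); wr("eegmicrostates export", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (1L + nch)), 8); wr("", 44)
  wr(as.character(nrec), 8); wr("1", 8); wr(as.character(nch), 4)
  for (ch in rec$channel_names) wr(ch, 16)
  for (i in seq_len(nch)) wr("AgAgCl electrode", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(sprintf("%.6g", -pmax_[i]), 8)
  for (i in seq_len(nch)) wr(sprintf("%.6g", pmax_[i]), 8)
  for (i in seq_len(nch)) wr("-32768", 8)
  for (i in seq_len(nch)) wr("32767", 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(as.character(fs), 8)
  for (i in seq_len(nch)) wr("", 32)
  scale <- pmax_ / 32767
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    dig <- round(x[, idx, drop = FALSE] / scale)
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a minimal EDF file
#'
#' Supports continuous EDF with identical sampling rate across signals.
#'
#' @param path EDF path.
#' @return An [eeg_recording] in physical units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  if (ver != "0") stop("unsupported EDF version field: '", ver, "'")
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (anyNA(c(nrec, dur, nch))) stop("malformed EDF header in ", path)
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / dur
  x <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    raw <- readBin(con, integer(), n = nch * spr[1], size = 2,
                   endian = "little")
    blk <- matrix(raw, nrow = spr[1])  # samples x channels
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    x[, idx] <- t(blk)
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  x <- x * gain + (pmin_ - dmin * gain)
  eeg_recording(x, fs, labels)
}

#' Write the tidy per-subject parameter table
#'
#' Columns: subject, group, class, mmd_ms, rtt, gev, occurrence -- the
#' direct input to the group statistics stage.
#'
#' @param params Data frame as produced by the pipeline.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
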