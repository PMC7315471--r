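#' Multichannel EEG recording
#'
#' Lightweight container for a continuous multichannel EEG recording:
#' a channels x samples numeric matrix (microvolts), a sampling rate,
#' and channel names.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Optional character vector of channel names; defaults
#'   to `"Ch1"`, `"Ch2"`, ...
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_names`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(8 * 100), 8), fs = 100)
#' rec
#' @export
eeg_recording <- function(data, fs, channel_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data))
    stop("recording data must be a numeric matrix without NA values")
  if (nrow(data) < 8)
    stop("a recording needs at least 8 channels (got ", nrow(data), ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  if (is.null(channel_names))
    channel_names <- paste0("Ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must equal the number of channels")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Set of fixed-length EEG epochs
#'
#' @param epochs 3-D numeric array, n_epochs x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional channel names.
#' @return An object of class `eeg_epochs` with elements `epochs`, `fs`,
#'   `epoch_length_s`, `channel_names`.
#' @export
eeg_epochs <- function(epochs, fs, channel_names = NULL) {
  if (length(dim(epochs)) != 3L)
    stop("'epochs' must be a 3-D array: epochs x channels x samples")
  if (anyNA(epochs)) stop("epochs contain NA values")
  if (is.null(channel_names))
    channel_names <- paste0("Ch", seq_len(dim(epochs)[2]))
  structure(list(epochs = epochs, fs = fs,
                 epoch_length_s = dim(epochs)[3] / fs,
                 channel_names = channel_names),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Microstate template set
#'
#' A set of k topographic maps, each zero-mean across channels and unit
#' L2 norm, with class labels and a level tag (individual or group).
#'
#' @param maps Numeric matrix, k x channels.
#' @param class_labels Character labels, typically subset of A--D.
#' @param level `"individual"` or `"group"`.
#' @return An object of class `ms_templates`.
#' @export
ms_templates <- function(maps, class_labels = NULL,
                         level = c("individual", "group")) {
  maps <- as.matrix(maps)
  level <- match.arg(level)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("template map with zero variance")
  maps <- maps / nrm
  if (is.null(class_labels))
    class_labels <- if (nrow(maps) <= 26) LETTERS[seq_len(nrow(maps))]
                    else paste0("T", seq_len(nrow(maps)))
  rownames(maps) <- class_labels
  structure(list(maps = maps, class_labels = class_labels, level = level),
            class = "ms_templates")
}

#' @export
print.ms_templates <- function(x, ...) {
  cat(sprintf("<ms_templates> %d maps (%s) x %d channels, level = %s\n",
              nrow(x$maps), paste(x$class_labels, collapse = ","),
              ncol(x$maps), x$level))
  invisible(x)
}

#' Plot microstate templates as channel profiles
#'
#' @param x An `ms_templates` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ms_templates <- function(x, ...) {
  graphics::matplot(t(x$maps), type = "l", lty = 1,
                    xlab = "channel", ylab = "normalized potential", ...)
  graphics::legend("topright", legend = x$class_labels, lty = 1,
                   col = seq_len(nrow(x$maps)), bty = "n")
  invisible(x)
}
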