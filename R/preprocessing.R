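#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward
#' ([signal::filtfilt()]) to every channel, giving zero phase distortion of
#' the topographies. The pass band defaults to 2--20 Hz, the band used for
#' resting microstate analysis. The channel means (DC) are removed. The
#' default design order 3 attenuates 50 Hz mains to below 0.2 percent
#' while keeping pass-band edge ringing (which blurs microstate
#' transitions) smaller than steeper designs.
#'
#' @param rec An [eeg_recording].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth design order.
#' @return A filtered [eeg_recording] of the same shape.
#' @export
bandpass <- function(rec, low = 2, high = 20, order = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= rec$fs / 2)
    stop("'high' must be below the Nyquist frequency ", rec$fs / 2, " Hz")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  x <- rec$data - rowMeans(rec$data)
  out <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  eeg_recording(out, rec$fs, rec$channel_names)
}

#' Downsample a recording with anti-alias filtering
#'
#' Decimates each channel by an integer factor after a zero-phase
#' anti-aliasing low-pass (order-8 Chebyshev type I at 0.8 of the new
#' Nyquist frequency, applied forward-backward). The target rate must
#' divide the current rate.
#'
#' @param rec An [eeg_recording].
#' @param target_fs Target sampling rate in Hz (default 250).
#' @return An [eeg_recording] at `target_fs`.
#' @export
downsample <- function(rec, target_fs = 250) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs) stop("target_fs exceeds the sampling rate")
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("target_fs must divide the sampling rate (", rec$fs, " Hz)")
  q <- as.integer(round(q))
  aa <- signal::cheby1(8, 0.05, 0.8 / q)
  keep <- seq(1, ncol(rec$data), by = q)
  out <- t(apply(rec$data, 1, function(ch)
    signal::filtfilt(aa, ch)[keep]))
  eeg_recording(out, target_fs, rec$channel_names)
}

#' Cut consecutive epochs and keep the first n artifact-free ones
#'
#' Splits the recording into consecutive non-overlapping windows of
#' `epoch_s` seconds from the start, drops windows failing the optional
#' rejection predicate, and keeps exactly the first `n_epochs` survivors
#' in temporal order.
#'
#' @param rec An [eeg_recording].
#' @param epoch_s Epoch length in seconds (default 2).
#' @param n_epochs Number of surviving epochs to keep (default 20).
#' @param reject Optional predicate `function(epoch_matrix)` returning
#'   `TRUE` for epochs to discard (an artifact-screening hook).
#' @param subject Optional subject id used in error messages.
#' @return An [eeg_epochs] object with `n_epochs` epochs.
#' @export
epoch_and_select <- function(rec, epoch_s = 2, n_epochs = 20, reject = NULL,
                             subject = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- as.integer(round(epoch_s * rec$fs))
  n_avail <- ncol(rec$data) %/% len
  keep <- integer(0)
  for (e in seq_len(n_avail)) {
    idx <- ((e - 1L) * len + 1L):(e * len)
    ep <- rec$data[, idx, drop = FALSE]
    if (!is.null(reject) && isTRUE(reject(ep))) next
    keep <- c(keep, e)
    if (length(keep) == n_epochs) break
  }
  if (length(keep) < n_epochs)
    stop("only ", length(keep), " artifact-free epochs available, need ",
         n_epochs, if (!is.null(subject)) paste0(" (subject ", subject, ")"))
  arr <- array(0, c(n_epochs, nrow(rec$data), len))
  for (i in seq_along(keep)) {
    idx <- ((keep[i] - 1L) * len + 1L):(keep[i] * len)
    arr[i, , ] <- rec$data[, idx]
  }
  eeg_epochs(arr, rec$fs, rec$channel_names)
}

#' Re-reference epochs to the average reference
#'
#' Subtracts the instantaneous mean over channels from every time sample.
#' Idempotent.
#'
#' @param ep An [eeg_epochs] object.
#' @return The re-referenced [eeg_epochs].
#' @export
average_reference <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$epochs)
  if (d[2] < 2) stop("average reference needs at least 2 channels")
  arr <- ep$epochs
  for (e in seq_len(d[1])) {
    m <- matrix(arr[e, , ], d[2])
    arr[e, , ] <- m - rep(colMeans(m), each = d[2])
  }
  eeg_epochs(arr, ep$fs, ep$channel_names)
}

#' Full signal-conditioning chain for one recording
#'
#' Band-pass (2--20 Hz), downsample to 250 Hz, cut 2-s epochs keeping the
#' first 20 artifact-free ones, and apply the average reference -- the
#' standard conditioning chain ahead of microstate analysis.
#'
#' @param rec An [eeg_recording].
#' @inheritParams bandpass
#' @inheritParams downsample
#' @inheritParams epoch_and_select
#' @return An analysis-ready [eeg_epochs] object.
#' @export
preprocess <- function(rec, low = 2, high = 20, target_fs = 250,
                       epoch_s = 2, n_epochs = 20, reject = NULL,
                       subject = NULL) {
  rec <- bandpass(rec, low, high)
  rec <- downsample(rec, target_fs)
  ep <- epoch_and_select(rec, epoch_s, n_epochs, reject, subject)
  average_reference(ep)
}
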