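#' Construct an EEG epoch object
#'
#' A light container for one artifact-free multichannel EEG segment: a
#' channels-by-samples matrix of potentials (uV), a sampling rate, and the
#' montage giving channel names/positions. Rows must follow the montage
#' channel order.
#'
#' @param data Numeric matrix, channels x samples (uV). Row names, if
#'   present, must match the montage channel names.
#' @param sfreq Sampling rate in Hz.
#' @param montage Montage tibble (see [montage_1020()]).
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, sfreq, montage = montage_1020()) {
  validate_montage(montage)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!all(is.finite(data))) stop("epoch data must be finite", call. = FALSE)
  if (nrow(data) != nrow(montage)) {
    stop("epoch has ", nrow(data), " channels but montage has ", nrow(montage),
         call. = FALSE)
  }
  if (ncol(data) < 3) stop("epoch must have at least 3 samples", call. = FALSE)
  if (!is.null(rownames(data)) && !identical(rownames(data), montage$channel)) {
    stop("epoch channel order does not match montage", call. = FALSE)
  }
  rownames(data) <- montage$channel
  structure(list(data = data, sfreq = sfreq, montage = montage),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  invisible(x)
}

#' @export
dim.eeg_epoch <- function(x) dim(x$data)

check_band <- function(low_hz, high_hz, sfreq) {
  nyq <- sfreq / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("invalid band: need 0 < low < high < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Zero-phase 4th-order Butterworth band-pass applied to a channels x samples
# matrix. The forward-backward (filtfilt) cascade has transfer function
# |H(f)|^2 with zero phase; that gain is applied directly in the frequency
# domain (all channels at once via mvfft), with mirror padding to suppress
# circular-convolution edge effects.
bandpass_matrix <- function(data, low_hz, high_hz, sfreq, order = 4) {
  n <- ncol(data)
  pad <- min(n - 1L, 256L)
  left <- data[, seq(pad + 1L, 2L), drop = FALSE]
  right <- data[, seq(n - 1L, n - pad), drop = FALSE]
  x <- cbind(left, data, right)
  big_n <- ncol(x)
  f <- pmin(seq_len(big_n) - 1L, big_n - (seq_len(big_n) - 1L)) * sfreq / big_n
  u <- ifelse(f > 0, (f^2 - low_hz * high_hz) / (f * (high_hz - low_hz)), Inf)
  gain <- 1 / (1 + u^(2 * order))
  X <- stats::mvfft(t(x))
  y <- Re(stats::mvfft(X * gain, inverse = TRUE)) / big_n
  t(y)[, pad + seq_len(n), drop = FALSE]
}

#' Zero-phase band-pass filter an epoch
#'
#' Applies a 4th-order Butterworth band-pass with zero phase, channel-wise,
#' so the timing of topographic features is preserved. The zero-phase
#' response (the squared Butterworth magnitude, identical in transfer
#' function to running the filter forward and backward) is applied in the
#' frequency domain with mirror padding. The default 2-20 Hz band is the
#' standard microstate analysis band for eyes-closed resting EEG.
#'
#' @param epoch An [eeg_epoch()].
#' @param low_hz,high_hz Band edges in Hz; require
#'   `0 < low_hz < high_hz < sfreq/2`.
#' @return The filtered `eeg_epoch`.
#' @export
bandpass_filter <- function(epoch, low_hz = 2, high_hz = 20) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  check_band(low_hz, high_hz, epoch$sfreq)
  epoch$data <- bandpass_matrix(epoch$data, low_hz, high_hz, epoch$sfreq)
  rownames(epoch$data) <- epoch$montage$channel
  epoch
}

#' Re-reference an epoch to the common average
#'
#' Subtracts, at every sample, the mean over channels from each channel, so
#' each momentary topography has zero channel mean. Idempotent, and invariant
#' to any reference offset common to all channels.
#'
#' @param epoch An [eeg_epoch()].
#' @return The re-referenced `eeg_epoch`.
#' @export
average_reference <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  epoch$data <- sweep(epoch$data, 2, colMeans(epoch$data))
  epoch
}

#' Global field power of an epoch
#'
#' GFP(t) is the spatial standard deviation of the momentary topography: the
#' root mean square over channels of the average-referenced potentials at
#' sample t. It quantifies overall potential variance across the electrode
#' set; its peaks are the moments of maximal topographic signal-to-noise and
#' are the only samples entering clustering.
#'
#' The per-sample channel mean is subtracted before the RMS, so the result is
#' identical whether or not the epoch was already average-referenced, and is
#' invariant to a global sign flip of the data.
#'
#' @param epoch An [eeg_epoch()].
#' @return A numeric vector of length `n_samples` (class `ms_gfp`, with the
#'   sampling rate in attribute `sfreq`).
#' @export
compute_gfp <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  centred <- sweep(epoch$data, 2, colMeans(epoch$data))
  g <- sqrt(colMeans(centred^2))
  structure(g, class = "ms_gfp", sfreq = epoch$sfreq)
}

#' Find interior local maxima of a GFP series
#'
#' Returns the (1-based) sample indices of strict interior local maxima.
#' A plateau of equal values strictly above both neighbours yields a single
#' index at its centre (the left-of-centre sample when the plateau has even
#' length). Endpoints are never returned.
#'
#' @param gfp Numeric vector (typically from [compute_gfp()]).
#' @return Strictly increasing integer vector of peak indices in
#'   `2:(length(gfp) - 1)`.
#' @export
find_gfp_peaks <- function(gfp) {
  g <- as.numeric(gfp)
  n <- length(g)
  if (n < 3) stop("GFP series must have at least 3 samples", call. = FALSE)
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  if (m < 3) return(integer(0))
  keep <- which(seq_len(m) > 1L & seq_len(m) < m &
                  r$values > c(-Inf, r$values)[seq_len(m)] &
                  r$values > c(r$values[-1], -Inf))
  if (!length(keep)) return(integer(0))
  # centre of each plateau, left-biased on even lengths
  as.integer(starts[keep] + (r$lengths[keep] - 1L) %/% 2L)
}
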