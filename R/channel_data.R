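#' Multichannel time-series container
#'
#' A light container for [channels x samples] data in SI units (tesla for
#' magnetometer rows, tesla/meter for gradiometer rows) with its sampling
#' rate and optional bad-channel mask.
#'
#' @param data numeric matrix [channels x samples].
#' @param sfreq sampling rate in Hz.
#' @param bad_channels integer indices of bad channels.
#' @return object of class `channel_data`.
#' @export
channel_data <- function(data, sfreq, bad_channels = integer()) {
  stopifnot(is.matrix(data), sfreq > 0)
  structure(list(data = data, sfreq = sfreq,
                 bad_channels = as.integer(bad_channels)),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  cat(sprintf("<channel_data> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  invisible(x)
}
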