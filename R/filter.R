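#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth low-pass, the conventional
#' smoother for 100 Hz optical motion capture before differentiation. The
#' series is odd-reflection padded at both ends before filtering so that
#' constant and slowly varying signals pass through without edge transients.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param fs sampling rate (Hz).
#' @param cutoff_hz cutoff frequency (Hz); must be below the Nyquist rate.
#' @param order Butterworth order of the underlying filter.
#' @return Filtered series, same shape as `x`.
#' @examples
#' lowpass_filter(rep(3, 100), fs = 100)          # DC passes unchanged
#' @export
lowpass_filter <- function(x, fs, cutoff_hz = 6, order = 4) {
  if (cutoff_hz >= fs / 2)
    hr_stop("`cutoff_hz` must be below the Nyquist frequency fs/2",
            "headreach_invalid_argument")
  if (cutoff_hz <= 0 || order < 1)
    hr_stop("`cutoff_hz` must be positive and `order` >= 1",
            "headreach_invalid_argument")
  bf <- signal::butter(order, cutoff_hz / (fs / 2))
  filt1 <- function(v) {
    n <- length(v)
    if (n < 3) return(v)
    # remove the endpoint-to-endpoint line so the padded series starts and
    # ends at zero (kills start-up transients; constants pass exactly)
    line <- v[1] + (v[n] - v[1]) * (seq_len(n) - 1) / (n - 1)
    r <- v - line
    pad <- min(n - 1, max(3 * order, round(10 * fs / cutoff_hz)))
    head_pad <- -r[seq(pad + 1, 2)]
    tail_pad <- -r[seq(n - 1, n - pad)]
    out <- signal::filtfilt(bf, c(head_pad, r, tail_pad))
    out[pad + seq_len(n)] + line
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}
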