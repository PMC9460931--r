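#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order Butterworth applied forward and backward (zero phase, so
#' event timing is preserved), with odd-reflection padding at both ends to
#' suppress edge transients. The default 20 Hz cutoff is the one used for
#' angular-velocity conditioning in the thrust index; event detection uses
#' a 10 Hz copy of the acceleration channels.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate in Hz; must exceed `2 * cutoff`.
#' @param cutoff Cutoff frequency in Hz (default 20).
#' @param order Filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, rate, cutoff = 20, order = 4L) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (rate <= 2 * cutoff) {
    stop(sprintf("sampling rate (%g Hz) must exceed twice the cutoff (%g Hz)",
                 rate, cutoff), call. = FALSE)
  }
  n <- length(x)
  # reflection long enough for the filter's start-up transient (pole radius
  # grows as the cutoff drops, so the pad scales with rate/cutoff)
  padlen <- max(3L * (2L * order + 1L), ceiling(9 * rate / cutoff))
  if (n <= 3L * (2L * order + 1L)) {
    stop(sprintf("signal too short for zero-phase filtering: length %d, minimum %d",
                 n, 3L * (2L * order + 1L) + 1L), call. = FALSE)
  }
  padlen <- min(padlen, n - 1L)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # odd (point-symmetric) extension keeps level and slope continuous at the edges
  left <- 2 * x[1L] - x[seq(padlen + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  xp <- c(left, x, right)
  yp <- signal::filtfilt(bf, xp)
  yp[seq(padlen + 1L, padlen + n)]
}
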