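# single IIR pass with steady-state initialization at the first sample, so
# a constant input passes through exactly (DC gain 1 to float precision).
bw_pass <- function(b, a, x) {
  nb <- length(b)
  x0 <- x[1]
  xp <- c(rep(x0, nb - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  y <- stats::filter(v, -a[-1], method = "recursive",
                     init = rep(x0, length(a) - 1L))
  as.numeric(y)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (dual pass) Butterworth low-pass of a sampled angle
#' curve. Each pass uses an order-`order` design whose cutoff is pre-warped
#' by `(sqrt(2) - 1)^(-1/(2 * order))` so the effective -3 dB point of the
#' double pass sits at `cutoff`. Padding controls the boundary: odd
#' reflection (default) for generic curves, or wrap-around (`"periodic"`)
#' for curves covering exactly one gait cycle, where heel strike to heel
#' strike is periodic by construction. DC gain is exactly 1 and the output
#' has the length of the input.
#'
#' @param x numeric curve (e.g. degrees per frame).
#' @param cutoff effective low-pass cutoff in Hz (default 6).
#' @param rate sampling rate in Hz; must exceed `2 * cutoff`.
#' @param order Butterworth order of each pass.
#' @param prewarp compensate the cutoff for the double pass (default TRUE).
#' @param boundary `"reflect"` or `"periodic"` padding.
#' @return filtered curve, same length as `x`.
#' @export
#' @examples
#' butterworth_lowpass(rep(3.2, 120))[1:5]
butterworth_lowpass <- function(x, cutoff = 6, rate = 100, order = 4,
                                prewarp = TRUE,
                                boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  check_number(cutoff, "cutoff", min = 1e-6)
  check_number(rate, "rate", min = 1e-6)
  if (rate <= 2 * cutoff) {
    fk_stop("`rate` must exceed twice the cutoff", "footkin_signal_error")
  }
  if (!all(is.finite(x))) {
    fk_stop("curve contains non-finite values", "footkin_signal_error")
  }
  fc <- if (prewarp) cutoff / (sqrt(2) - 1)^(1 / (2 * order)) else cutoff
  if (fc >= rate / 2) {
    fk_stop("pre-warped cutoff reaches the Nyquist rate",
            "footkin_signal_error")
  }
  bf <- signal::butter(order, 2 * fc / rate, type = "low")
  padlen <- 6L * (2L * order + 1L)
  n <- length(x)
  if (n <= padlen) {
    fk_stop(sprintf("curve too short to filter (need > %d samples)", padlen),
            "footkin_signal_error")
  }
  xp <- switch(boundary,
    reflect = c(2 * x[1] - x[(padlen + 1):2], x,
                2 * x[n] - x[(n - 1):(n - padlen)]),
    periodic = c(x[(n - padlen + 1):n], x, x[1:padlen])
  )
  y <- bw_pass(bf$b, bf$a, xp)
  y <- rev(bw_pass(bf$b, bf$a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Analytic dual-pass Butterworth magnitude response
#'
#' Squared analog Butterworth magnitude at frequency `f` for the dual-pass
#' (zero-phase) filter of [butterworth_lowpass()]: the independent
#' reference for filter-contract checks.
#'
#' @param f frequency in Hz.
#' @param cutoff effective cutoff in Hz.
#' @param order per-pass order.
#' @return gain of the double pass at `f` (1 at DC).
#' @export
butterworth_gain <- function(f, cutoff = 6, order = 4) {
  fc <- cutoff / (sqrt(2) - 1)^(1 / (2 * order))
  1 / (1 + (f / fc)^(2 * order))
}
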