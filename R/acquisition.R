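#' Acquisition parameters for a TCSPC FLIM measurement
#'
#' Bundles the timing geometry of a time-correlated single photon counting
#' acquisition: laser repetition rate, number of time channels, channel width
#' and image shape. The angular frequency used by the phasor transform,
#' \eqn{\omega = 2\pi f \cdot h}, is derived from the repetition rate `f` and
#' the harmonic index `h`.
#'
#' @param rep_rate Laser repetition frequency in Hz.
#' @param n_channels Number of time channels per excitation period.
#' @param channel_width Width of one time channel in seconds.
#' @param image_shape Integer vector `c(rows, cols)` of the image in pixels.
#' @param harmonic Phasor harmonic index (default 1, the laser fundamental).
#'
#' @return An object of class `acquisition_params` with fields `rep_rate`,
#'   `n_channels`, `channel_width`, `image_shape`, `harmonic`, `period`
#'   (`1/rep_rate`, seconds) and `omega` (rad/s).
#'
#' @details The time window `n_channels * channel_width` must equal the laser
#' period `1/rep_rate` to within one channel width. Acquisition systems often
#' print a window that is a few channels longer than the period; channels past
#' the period sample the decay folded modulo the period.
#'
#' @examples
#' acq <- acquisition_params(80.08e6, 783, 16e-12, c(512, 512))
#' acq$omega
#' @export
acquisition_params <- function(rep_rate, n_channels, channel_width,
                               image_shape = c(1L, 1L), harmonic = 1L) {
  stopifnot(is.numeric(rep_rate), length(rep_rate) == 1L, is.finite(rep_rate),
            rep_rate > 0)
  n_channels <- as.integer(n_channels)
  stopifnot(n_channels >= 1L, is.numeric(channel_width),
            is.finite(channel_width), channel_width > 0)
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1L))
  harmonic <- as.integer(harmonic)
  stopifnot(harmonic >= 1L)
  period <- 1 / rep_rate
  window <- n_channels * channel_width
  if (abs(window - period) > channel_width && window < period) {
    stop("acquisition window (", signif(window * 1e9, 6),
         " ns) is more than one channel short of the laser period (",
         signif(period * 1e9, 6), " ns)")
  }
  structure(
    list(rep_rate = rep_rate, n_channels = n_channels,
         channel_width = channel_width, image_shape = image_shape,
         harmonic = harmonic, period = period,
         omega = 2 * pi * rep_rate * harmonic),
    class = "acquisition_params")
}

#' Preset acquisition geometries
#'
#' `"paper"` is the acquisition used throughout the reference data set:
#' 512 x 512 pixels, 783 time channels of 16 ps at an 80.08 MHz repetition
#' rate (12.528 ns window). `"desk"` is the same timing at 128 x 128 pixels
#' for desk-scale runs, and `"exact"` is a 625 x 20 ps geometry whose window
#' equals the laser period of an 80 MHz laser exactly (useful for
#' discretization studies).
#'
#' @param name One of `"paper"`, `"desk"`, `"exact"`.
#' @param image_shape Optional override of the image shape.
#' @return An [acquisition_params()] object.
#' @export
acq_preset <- function(name = c("paper", "desk", "exact"), image_shape = NULL) {
  name <- match.arg(name)
  acq <- switch(name,
    paper = acquisition_params(80.08e6, 783L, 16e-12, c(512L, 512L)),
    desk  = acquisition_params(80.08e6, 783L, 16e-12, c(128L, 128L)),
    exact = acquisition_params(80e6, 625L, 20e-12, c(128L, 128L)))
  if (!is.null(image_shape)) {
    acq$image_shape <- as.integer(image_shape)
    stopifnot(length(acq$image_shape) == 2L, all(acq$image_shape >= 1L))
  }
  acq
}

#' Channel center times of an acquisition
#'
#' @param acq An [acquisition_params()] object.
#' @return Numeric vector of length `acq$n_channels`, the bin-center times in
#'   seconds, starting at half a channel width.
#' @export
channel_times <- function(acq) {
  (seq_len(acq$n_channels) - 0.5) * acq$channel_width
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "TCSPC acquisition: %d x %d px, %d channels x %.3g ps, %.4g MHz (window %.4g ns)\n",
    x$image_shape[1], x$image_shape[2], x$n_channels, x$channel_width * 1e12,
    x$rep_rate / 1e6, x$n_channels * x$channel_width * 1e9))
  invisible(x)
}

#' Bi-exponential decay model parameters
#'
#' Describes the fluorescence decay of one (possibly mixed) species as
#' \eqn{I(t) = A [p_1 e^{-t/\tau_1} + (1 - p_1) e^{-t/\tau_2}] + b}, with
#' `a1_frac` \eqn{= p_1 = a_1/(a_1+a_2)} the amplitude fraction of the short
#' component, `amplitude` \eqn{A} an overall scale and `background_rate` a
#' uniform per-channel background added to the expected intensity.
#'
#' @param tau1 Short lifetime, seconds. `0 < tau1 <= tau2`.
#' @param tau2 Long lifetime, seconds. A mono-exponential decay is expressed
#'   with `a1_frac = 1` (then `tau2` is ignored and defaults to `tau1`).
#' @param a1_frac Amplitude fraction of the short component in `[0, 1]`.
#' @param background_rate Uniform background, expressed as expected background
#'   counts per channel per unit decay amplitude (dimensionless); default 0.
#' @param amplitude Overall decay amplitude scale (default 1); `amplitude = 0`
#'   gives a pure-background (flat) signal.
#' @return An object of class `decay_model`.
#' @examples
#' decay_model(tau1 = 0.085e-9, tau2 = 2.096e-9, a1_frac = 0.9843)
#' @export
decay_model <- function(tau1, tau2 = tau1, a1_frac = 1,
                        background_rate = 0, amplitude = 1) {
  stopifnot(is.numeric(tau1), is.finite(tau1), tau1 > 0,
            is.numeric(tau2), is.finite(tau2),
            is.numeric(a1_frac), is.finite(a1_frac),
            a1_frac >= 0, a1_frac <= 1,
            is.numeric(background_rate), is.finite(background_rate),
            background_rate >= 0,
            is.numeric(amplitude), is.finite(amplitude), amplitude >= 0)
  if (a1_frac < 1 && tau2 < tau1)
    stop("tau2 must be >= tau1 (components are ordered)")
  structure(
    list(tau1 = tau1, tau2 = tau2, a1_frac = a1_frac,
         background_rate = background_rate, amplitude = amplitude),
    class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf(
    "decay model: tau1 = %.4g ns (a1 = %.2f%%), tau2 = %.4g ns, bg = %.3g, A = %.3g\n",
    x$tau1 * 1e9, 100 * x$a1_frac, x$tau2 * 1e9, x$background_rate,
    x$amplitude))
  invisible(x)
}

#' Instrument response function model
#'
#' The measured decay is the true decay convolved with the instrument response
#' function (IRF). Two shapes are supported: an ideal `"delta"` pulse at
#' `center`, and a `"gaussian"` pulse of given full width at half maximum.
#'
#' @param shape `"delta"` or `"gaussian"`.
#' @param center Pulse position within the window, seconds.
#' @param fwhm Full width at half maximum, seconds (ignored for `"delta"`).
#' @return An object of class `irf_model` with an additional `sigma` field
#'   (`fwhm / (2 sqrt(2 log 2))`).
#' @examples
#' irf_model("gaussian", center = 1.25e-9, fwhm = 150e-12)
#' @export
irf_model <- function(shape = c("gaussian", "delta"), center = 0,
                      fwhm = 150e-12) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(center), is.finite(center), center >= 0,
            is.numeric(fwhm), is.finite(fwhm), fwhm >= 0)
  if (shape == "delta") fwhm <- 0
  structure(
    list(shape = shape, center = center, fwhm = fwhm,
         sigma = fwhm / (2 * sqrt(2 * log(2)))),
    class = "irf_model")
}

#' Default IRF for the preset acquisition
#'
#' Gaussian, 150 ps FWHM (typical for hybrid-detector TCSPC), centered at 10%
#' of the acquisition window.
#'
#' @param acq An [acquisition_params()] object.
#' @return An [irf_model()].
#' @export
default_irf <- function(acq) {
  irf_model("gaussian", center = 0.1 * acq$n_channels * acq$channel_width,
            fwhm = 150e-12)
}

#' @export
print.irf_model <- function(x, ...) {
  cat(sprintf("IRF: %s, center %.4g ns, FWHM %.4g ps\n",
              x$shape, x$center * 1e9, x$fwhm * 1e12))
  invisible(x)
}
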