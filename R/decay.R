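# Forward model: periodic (wrap-around) convolution of exponential decays
# with the IRF, evaluated at channel centers.

# Scaled complementary error function, stable for large |x|.
erfcx <- function(x) {
  out <- numeric(length(x))
  lo <- x < 5
  # exp(x^2) * erfc(x); erfc(x) = 2 * pnorm(-x * sqrt(2))
  out[lo] <- exp(x[lo]^2) * 2 * stats::pnorm(-x[lo] * sqrt(2))
  if (any(!lo)) {
    xi <- x[!lo]
    # asymptotic series, relative error < 1e-10 for x >= 5
    x2 <- 1 / (2 * xi^2)
    out[!lo] <- (1 - x2 * (1 - 3 * x2 * (1 - 5 * x2))) / (xi * sqrt(pi))
  }
  out
}

# One-sided exponential decay exp(-(u - t0)/tau) (u >= t0) convolved with a
# unit-area Gaussian of width sigma centered at 0, evaluated at u.
conv_exp_gauss <- function(u, tau, t0, sigma) {
  du <- u - t0
  b <- (sigma / tau - du / sigma) / sqrt(2)
  h <- numeric(length(u))
  far <- b < -4            # erfc saturates at 2: pure exponential regime
  if (any(far))
    h[far] <- exp(sigma^2 / (2 * tau^2) - du[far] / tau)
  if (any(!far))
    h[!far] <- 0.5 * exp(-du[!far]^2 / (2 * sigma^2)) * erfcx(b[!far])
  h
}

# Periodic single-exponential response at times t (within one period),
# folded at `period`; IRF delta or Gaussian at irf$center. Channels whose
# center lies beyond the period are outside the sync range of a TCSPC unit
# and record no decay signal (the stated 783 x 16 ps window slightly exceeds
# the 80.08 MHz period; its trailing channels are dark).
periodic_component <- function(t, tau, irf, period) {
  in_range <- t < period
  if (!all(in_range)) {
    out <- numeric(length(t))
    out[in_range] <- periodic_component(t[in_range], tau, irf, period)
    return(out)
  }
  q <- exp(-period / tau)
  if (irf$shape == "delta") {
    dt <- (t - irf$center) %% period
    exp(-dt / tau) / (1 - q)
  } else {
    sigma <- irf$sigma
    if (sigma <= 0) return(periodic_component(t, tau, irf_model("delta", irf$center), period))
    if (irf$center + 6 * sigma >= period)
      stop("IRF center too close to the end of the period for the periodic fold")
    # within-period pulse plus the geometric tail of all earlier pulses:
    # for k >= 1, t + k*period - center >> sigma, so the convolution is in
    # its pure exponential regime and the sum over k is geometric.
    h0 <- conv_exp_gauss(t, tau, irf$center, sigma)
    tail <- exp(sigma^2 / (2 * tau^2)) *
      exp(-(t + period - irf$center) / tau) / (1 - q)
    h0 + tail
  }
}

#' Expected TCSPC decay histogram (noiseless forward model)
#'
#' Evaluates the periodic convolution of a bi-exponential decay with the IRF
#' at the channel centers of an acquisition, plus a uniform background:
#' \deqn{\mu_k = A [p_1 D_{\tau_1}(t_k) + (1-p_1) D_{\tau_2}(t_k)] + b}
#' where \eqn{D_\tau} is the single-exponential response folded at the laser
#' period (wrap-around handles incomplete decay of long lifetimes within one
#' period).
#'
#' @param model A [decay_model()].
#' @param irf An [irf_model()].
#' @param acq An [acquisition_params()].
#' @return Numeric vector of length `acq$n_channels`: per-channel expected
#'   intensity (unnormalized).
#' @examples
#' acq <- acq_preset("paper")
#' mu <- expected_decay(decay_model(2e-9), irf_model("delta"), acq)
#' @export
expected_decay <- function(model, irf, acq) {
  stopifnot(inherits(model, "decay_model"), inherits(irf, "irf_model"),
            inherits(acq, "acquisition_params"))
  t <- channel_times(acq)
  mu <- rep(model$background_rate, acq$n_channels)
  if (model$amplitude > 0) {
    d <- model$a1_frac *
      periodic_component(t, model$tau1, irf, acq$period)
    if (model$a1_frac < 1)
      d <- d + (1 - model$a1_frac) *
        periodic_component(t, model$tau2, irf, acq$period)
    mu <- mu + model$amplitude * d
  }
  mu
}

#' Closed-form phasor of a mono-exponential decay
#'
#' For a single-exponential decay of lifetime \eqn{\tau} at angular frequency
#' \eqn{\omega}, the phasor is \eqn{g = 1/(1+(\omega\tau)^2)},
#' \eqn{s = \omega\tau/(1+(\omega\tau)^2)}; it lies exactly on the universal
#' semicircle \eqn{(g - 1/2)^2 + s^2 = 1/4}.
#'
#' @param tau Lifetime in seconds (vectorized), `tau >= 0`.
#' @param acq An [acquisition_params()] (supplies \eqn{\omega}).
#' @return A list with numeric fields `g` and `s`.
#' @examples
#' mono_exp_phasor(1e-9, acq_preset("paper"))
#' @export
mono_exp_phasor <- function(tau, acq) {
  stopifnot(all(tau >= 0))
  wt <- acq$omega * tau
  list(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

# Analytic phasor of a bi-exponential model (intensity-fraction weighting);
# used for ground-truth tables.
model_phasor <- function(model, acq) {
  a1 <- model$a1_frac
  a2 <- 1 - a1
  i1 <- a1 * model$tau1
  i2 <- a2 * model$tau2
  f1 <- if (i1 + i2 > 0) i1 / (i1 + i2) else 1
  p1 <- mono_exp_phasor(model$tau1, acq)
  p2 <- mono_exp_phasor(model$tau2, acq)
  list(g = f1 * p1$g + (1 - f1) * p2$g,
       s = f1 * p1$s + (1 - f1) * p2$s)
}
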