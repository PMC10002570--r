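# Shared desk-scale fixtures. Everything is generated in code; no files.

paper_acq <- function(shape = c(8L, 8L)) acq_preset("paper", image_shape = shape)

exact_acq <- function(shape = c(8L, 8L)) acq_preset("exact", image_shape = shape)

# binned timing geometry used by the fitting stage (391 x 32 ps)
binned_acq <- function() acquisition_params(80.08e6, 391L, 32e-12, c(1L, 1L))

std_irf <- function() irf_model("gaussian", center = 1.2528e-9, fwhm = 150e-12)

# brute-force multi-period fold of a delta-IRF decay, the independent oracle
# for the wrap-around of expected_decay
brute_force_periodic <- function(t, tau, period, center = 0, n_periods = 60) {
  out <- numeric(length(t))
  for (k in 0:(n_periods - 1)) {
    tt <- ((t - center) %% period) + k * period
    out <- out + exp(-tt / tau)
  }
  ifelse(t < period, out, 0)
}
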