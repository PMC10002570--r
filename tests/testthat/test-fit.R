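# Bi-exponential reconvolution fitting: derived quantities on published
# inputs, parameter recovery on simulations, QC behavior, IRF estimation.

test_that("derived_lifetimes reproduces the published worked example", {
  # native DHICA: tau1 = 0.085 ns, a1 = 98.43%, tau2 = 2.096 ns
  d <- derived_lifetimes(0.085e-9, 2.096e-9, 98.43, 1.57)
  expect_equal(d$tau_av_amp * 1e9, 0.117, tolerance = 0.01)
  expect_equal(d$tau_av_int * 1e9, 0.649, tolerance = 0.01)
  expect_equal(d$a1_pct, 98.43)
  expect_equal(d$a1_pct + d$a2_pct, 100)
})

test_that("derived_lifetimes limits and errors", {
  d <- derived_lifetimes(1.3e-9, 2e-9, 5, 0)   # a2 = 0: mono-exponential
  expect_equal(d$tau_av_amp, 1.3e-9)
  expect_equal(d$tau_av_int, 1.3e-9)
  expect_error(derived_lifetimes(1e-9, 2e-9, 0, 0), "positive")
  expect_error(derived_lifetimes(1e-9, 2e-9, -1, 2), "non-negative")
})

test_that("amplitude- vs intensity-weighting inequality holds (property)", {
  set.seed(11)
  for (i in 1:200) {
    tau1 <- runif(1, 0.02, 1) * 1e-9
    tau2 <- tau1 + runif(1, 0, 5e-9)
    a1 <- runif(1, 0, 100); a2 <- runif(1, 0, 100)
    d <- derived_lifetimes(tau1, tau2, a1, a2)
    expect_lte(d$tau_av_amp, d$tau_av_int * (1 + 1e-12))
  }
})

test_that("estimate_irf recovers a pure Gaussian pulse within one channel", {
  acq <- paper_acq()
  sigma <- 150e-12 / (2 * sqrt(2 * log(2)))
  pulse <- round(1e6 * dnorm(channel_times(acq), 1.25e-9, sigma) *
                   acq$channel_width)
  est <- estimate_irf(pulse, acq)
  expect_lt(abs(est$center - 1.25e-9), acq$channel_width)
  expect_lt(abs(est$fwhm - 150e-12), acq$channel_width)
})

test_that("estimate_irf recovers the IRF width from a decay within 20%", {
  acq <- paper_acq()
  irf <- std_irf()
  h <- simulate_decay_histogram(decay_model(0.3e-9, 2e-9, 0.9), irf, acq,
                                1e6, seed = 3)
  est <- estimate_irf(h, acq)
  expect_lt(abs(est$fwhm - 150e-12) / 150e-12, 0.2)
  expect_lt(abs(est$center - irf$center), 3 * acq$channel_width)
})

test_that("estimate_irf rejects flat or empty histograms", {
  acq <- paper_acq()
  expect_error(estimate_irf(rep(0, acq$n_channels), acq), "explicit IRF")
  expect_error(estimate_irf(rep(7, acq$n_channels), acq), "explicit IRF")
})

test_that("fit_pixel_decay recovers a two-component decay (delta IRF)", {
  acq <- binned_acq()
  truth <- decay_model(0.10e-9, 2.0e-9, 0.95)
  irf <- irf_model("delta", center = 1.2e-9)
  set.seed(101)
  res <- sapply(1:40, function(i) {
    h <- simulate_decay_histogram(truth, irf, acq, 5e4)
    fr <- fit_pixel_decay(h, irf, acq)
    c(fr$tau1, fr$tau2, fr$a1_pct, fr$chi2red, fr$tau_av_amp <= fr$tau_av_int,
      fr$tau1 <= fr$tau2)
  })
  expect_lt(abs(median(res[1, ]) / 0.10e-9 - 1), 0.15)
  expect_lt(abs(median(res[2, ]) / 2.0e-9 - 1), 0.10)
  expect_lt(abs(median(res[3, ]) - 95), 2)
  # chi-squared calibration on correctly specified simulations
  expect_lt(median(res[4, ]), 2)
  expect_gt(mean(res[4, ] < 2), 0.95)
  # ordering and weighting invariants on every fit
  expect_true(all(res[5, ] == 1))
  expect_true(all(res[6, ] == 1))
})

test_that("mono-exponential input comes back mono (a2% < 2)", {
  acq <- binned_acq()
  irf <- std_irf()
  set.seed(55)
  for (i in 1:5) {
    h <- simulate_decay_histogram(decay_model(4e-9), irf, acq, 1e4)
    fr <- fit_pixel_decay(h, irf, acq)
    expect_lt(fr$a2_pct, 2)
    expect_equal(fr$tau_av_amp, fr$tau_av_int, tolerance = 1e-9)
  }
})

test_that("low-intensity pixels fail QC without fitting", {
  acq <- binned_acq()
  fr <- fit_pixel_decay(rep(0, acq$n_channels), std_irf(), acq)
  expect_false(fr$qc_pass)
  expect_identical(fr$code, "low_intensity")
  expect_true(is.na(fr$tau1))
  expect_identical(fr$total_counts, 0)
})

test_that("fit_image: uniform phantom gives spatially flat maps", {
  acq <- paper_acq(c(24L, 24L))
  truth <- melanin_preset("pheo_native")$model
  irf <- std_irf()
  img <- render_phantom(uniform_layout(acq, truth, 25), irf, acq, seed = 31)
  frm <- fit_image(img, irf, binning = binning_policy(20L, 2L),
                   stride = 6L)
  for (p in c("tau1", "tau2", "a1_pct", "tau_av_amp")) {
    v <- frm$maps[[p]]$values
    v <- v[is.finite(v)]
    expect_gt(length(v), 10)
    expect_lt(sd(v) / mean(v), 0.05)
  }
  # median recovery against the generating model
  expect_lt(abs(median(frm$maps$tau1$values, na.rm = TRUE) / truth$tau1 - 1),
            0.15)
  expect_lt(abs(median(frm$maps$tau2$values, na.rm = TRUE) / truth$tau2 - 1),
            0.10)
})

test_that("a dark phantom fails QC on intensity nearly everywhere", {
  acq <- paper_acq(c(24L, 24L))
  fx <- make_fixture_set("dark_powder", seed = 4, acq = acq,
                         photons_per_pixel = 25)
  frm <- fit_image(fx$images$dark_powder, fx$irf,
                   binning = binning_policy(20L, 2L), stride = 6L)
  qc <- frm$qc_pass[!is.na(frm$qc_pass)]
  expect_gte(mean(!qc), 0.99)
})
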