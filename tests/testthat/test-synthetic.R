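# Synthetic TCSPC generator: forward model correctness (wrap-around, IRF
# convolution), Poisson sampling, phantom structure, preset registry.

test_that("expected_decay matches the brute-force multi-period fold (delta IRF)", {
  acq <- paper_acq()
  t <- channel_times(acq)
  for (tau in c(0.1e-9, 2e-9, 5e-9)) {
    mu <- expected_decay(decay_model(tau), irf_model("delta"), acq)
    bf <- brute_force_periodic(t, tau, acq$period)
    sel <- bf > 0
    expect_lt(max(abs(mu[sel] - bf[sel]) / bf[sel]), 1e-6)
  }
})

test_that("expected_decay Gaussian-IRF convolution matches adaptive quadrature", {
  acq <- paper_acq()
  irf <- std_irf()
  t <- channel_times(acq)
  tau <- 0.5e-9
  mu <- expected_decay(decay_model(tau), irf, acq)
  # independent oracle: quadrature of the convolution integral, with the
  # multi-period fold summed explicitly
  for (ch in c(60, 79, 85, 200, 700)) {
    tot <- 0
    for (k in 0:59) {
      u <- t[ch] + k * acq$period
      fn <- function(x) dnorm(x, irf$center, irf$sigma) * exp(-(u - x) / tau)
      tot <- tot + stats::integrate(fn, irf$center - 10 * irf$sigma,
                                    min(u, irf$center + 10 * irf$sigma),
                                    rel.tol = 1e-12)$value
    }
    expect_equal(mu[ch], tot, tolerance = 1e-9)
  }
})

test_that("pure background gives a flat histogram; zero amplitude allowed", {
  acq <- paper_acq()
  mu <- expected_decay(decay_model(1e-9, background_rate = 1, amplitude = 0),
                       irf_model("delta"), acq)
  expect_true(all(mu == 1))
})

test_that("preset acquisition matches the published geometry", {
  acq <- acq_preset("paper")
  expect_identical(acq$n_channels, 783L)
  expect_equal(acq$channel_width, 16e-12)
  expect_equal(acq$n_channels * acq$channel_width, 12.528e-9)
  expect_equal(acq$rep_rate, 80.08e6)
  expect_identical(acq$image_shape, c(512L, 512L))
  expect_equal(acq$omega, 2 * pi * 80.08e6)
})

test_that("invalid model/acquisition parameters are rejected", {
  expect_error(decay_model(-1e-9), "tau1")
  expect_error(decay_model(2e-9, 1e-9, a1_frac = 0.5), "ordered")
  expect_error(decay_model(1e-9, a1_frac = 2))
  expect_error(acquisition_params(80e6, 100L, 16e-12), "short of the laser")
  expect_error(simulate_decay_histogram(decay_model(1e-9), irf_model("delta"),
                                        paper_acq(), -5), ">= 0")
})

test_that("simulate_decay_histogram: empty draw, determinism, budget", {
  acq <- paper_acq()
  m <- decay_model(1e-9)
  irf <- irf_model("delta")
  expect_identical(simulate_decay_histogram(m, irf, acq, 0),
                   integer(acq$n_channels))
  h1 <- simulate_decay_histogram(m, irf, acq, 1e4, seed = 99)
  h2 <- simulate_decay_histogram(m, irf, acq, 1e4, seed = 99)
  expect_identical(h1, h2)
  expect_false(identical(h1, simulate_decay_histogram(m, irf, acq, 1e4,
                                                      seed = 100)))
  # expected total is the budget; Poisson fluctuation ~ sqrt(budget)
  totals <- vapply(1:20, function(s)
    sum(simulate_decay_histogram(m, irf, acq, 1e4, seed = s)), 0)
  expect_true(all(abs(totals - 1e4) < 5 * sqrt(1e4)))
})

test_that("simulated mono-exponential phasor is close to the closed form", {
  acq <- paper_acq()
  h <- simulate_decay_histogram(decay_model(1e-9), irf_model("delta"), acq,
                                1e6, seed = 7)
  p <- compute_phasor(h, acq)
  m <- mono_exp_phasor(1e-9, acq)
  expect_lt(abs(p$g - m$g), 0.005)
  expect_lt(abs(p$s - m$s), 0.005)
})

test_that("render_phantom: homogeneity, sum conservation, determinism", {
  acq <- paper_acq(c(24L, 24L))
  m <- decay_model(0.5e-9, 2e-9, 0.9)
  img <- render_phantom(uniform_layout(acq, m, 400), std_irf(), acq, seed = 5)
  totals <- apply(img$counts, c(1, 2), sum)
  # pixel totals are Poisson about the budget: 99% within 5 sqrt(expected)
  frac_ok <- mean(abs(totals - 400) < 5 * sqrt(400))
  expect_gte(frac_ok, 0.99)
  img2 <- render_phantom(uniform_layout(acq, m, 400), std_irf(), acq, seed = 5)
  expect_identical(img$counts, img2$counts)
})

test_that("aggregates are brighter and shorter-lived than the matrix", {
  acq <- paper_acq(c(32L, 32L))
  base <- decay_model(0.118e-9, 1.924e-9, 0.9178)
  agg <- decay_model(0.08e-9, 1.5e-9, 0.95)
  layout <- uniform_layout(acq, base, 200, aggregates = list(
    list(center = c(10, 10), radius = 4, intensity = 3, model = agg)))
  img <- render_phantom(layout, std_irf(), acq, seed = 8)
  totals <- apply(img$counts, c(1, 2), sum)
  inside <- melflim:::disk_mask(c(32L, 32L), c(10, 10), 4)
  expect_gt(mean(totals[inside]), 2 * mean(totals[!inside]))
  # pooled decays: aggregate pixels fit to a shorter amplitude-weighted
  # lifetime than matrix pixels
  acqp <- acq; acqp$image_shape <- c(1L, 1L)
  pool <- function(mask) {
    apply(img$counts, 3, function(sl) sum(sl[mask]))
  }
  fa <- fit_pixel_decay(pool(inside), std_irf(), acqp)
  fm <- fit_pixel_decay(pool(!inside), std_irf(), acqp)
  expect_lt(fa$tau_av_amp, fm$tau_av_amp)
})

test_that("overlapping aggregates are applied last-wins with a message", {
  acq <- paper_acq(c(16L, 16L))
  m <- decay_model(1e-9)
  layout <- uniform_layout(acq, m, 50, aggregates = list(
    list(center = c(8, 8), radius = 3, intensity = 2, model = m),
    list(center = c(9, 9), radius = 3, intensity = 2, model = m)))
  expect_message(render_phantom(layout, irf_model("delta"), acq, seed = 1),
                 "overlapping")
})

test_that("two species separate in the phasor plane at the stated budget", {
  acq <- paper_acq(c(20L, 40L))
  mA <- melanin_preset("dhica_native")$model
  mB <- melanin_preset("dhica_uva7")$model
  mask <- matrix(FALSE, 20, 40)
  maskA <- mask; maskA[, 1:20] <- TRUE
  maskB <- mask; maskB[, 21:40] <- TRUE
  layout <- phantom_layout(list(
    list(mask = maskA, model = mA, photons = 100),
    list(mask = maskB, model = mB, photons = 100)))
  img <- render_phantom(layout, std_irf(), acq, seed = 12)
  pm <- phasor_image(img, spatial_bin = 10)  # ~1e4 photons per binned pixel
  gA <- pm$g[, 5:16]; gB <- pm$g[, 25:36]   # interiors of each half
  sA <- pm$s[, 5:16]; sB <- pm$s[, 25:36]
  sep <- sqrt((mean(gA) - mean(gB))^2 + (mean(sA) - mean(sB))^2)
  spread <- max(sd(gA), sd(gB), sd(sA), sd(sB))
  expect_gt(sep, 3 * spread)
})

test_that("fixture truth tables apply the closed-form definitions", {
  fx <- make_fixture_set(c("dhica_native", "fluorescein", "dark_powder"),
                         seed = 3, acq = paper_acq(c(16L, 16L)),
                         photons_per_pixel = 25)
  tr <- fx$truth
  row <- tr[tr$preset == "dhica_native", ]
  m <- melanin_preset("dhica_native")$model
  a1 <- m$a1_frac; a2 <- 1 - a1
  expect_equal(row$tau_av_amp, (a1 * m$tau1 + a2 * m$tau2))
  expect_equal(row$tau_av_int,
               (a1 * m$tau1^2 + a2 * m$tau2^2) / (a1 * m$tau1 + a2 * m$tau2))
  # fluorescein is mono-exponential with configurable reference lifetime
  fl <- melanin_preset("fluorescein", fluorescein_tau = 3.6e-9)
  expect_equal(fl$model$a1_frac, 1)
  expect_equal(fl$model$tau1, 3.6e-9)
  # dark powder: near-zero counts with an IRF-shaped residual
  dark <- fx$images$dark_powder
  bright <- fx$images$dhica_native
  expect_lt(sum(dark$counts), 0.05 * sum(bright$counts))
  expect_error(make_fixture_set("no_such_preset"), "unknown preset")
})

test_that("preset registry covers the reference table plus controls", {
  reg <- melanin_presets()
  ref <- melanin_reference_table()
  expect_true(all(ref$condition %in% names(reg)))
  expect_true(all(c("fluorescein", "dark_powder") %in% names(reg)))
  for (i in seq_len(nrow(ref))) {
    m <- reg[[ref$condition[i]]]$model
    expect_equal(m$tau1 * 1e9, ref$tau1_ns[i])
    expect_equal(m$tau2 * 1e9, ref$tau2_ns[i])
    expect_equal(100 * m$a1_frac, ref$a1_pct[i])
  }
})
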