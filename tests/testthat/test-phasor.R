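# Phasor analysis: transform correctness, semicircle geometry, calibration,
# mixture linearity, phase/modulation lifetimes, fUVA-Mel distances.

test_that("compute_phasor endpoints: delta decay and flat background", {
  acq <- paper_acq()
  h <- rep(0, acq$n_channels); h[1] <- 1000
  p <- compute_phasor(h, acq)
  # the first channel center sits at half a channel width, omega*cw/2 ~ 0.004
  expect_equal(p$g, 1, tolerance = 0.01)
  expect_lt(abs(p$s), 0.01)
  pf <- compute_phasor(rep(10, acq$n_channels), acq)
  expect_lt(abs(pf$g), 0.01)
  expect_lt(abs(pf$s), 0.01)
  # on an exact-period geometry the orthogonality is near machine precision
  acqe <- exact_acq()
  pfe <- compute_phasor(rep(10, acqe$n_channels), acqe)
  expect_lt(abs(pfe$g), 1e-10)
  expect_lt(abs(pfe$s), 1e-10)
  expect_error(compute_phasor(rep(0, acq$n_channels), acq), "zero-count")
})

test_that("noiseless mono-exponential phasor matches the closed form", {
  # exact-period geometry: discretization-limited agreement < 1e-4 once the
  # lifetime spans at least ~10 channels; below that (85 ps over 20 ps
  # channels) the center-sampling residual grows to ~2e-4
  acqe <- exact_acq()
  for (tau in c(0.2e-9, 0.5e-9, 1e-9, 2e-9, 4e-9)) {
    mu <- expected_decay(decay_model(tau), irf_model("delta"), acqe)
    p <- compute_phasor(mu, acqe)
    m <- mono_exp_phasor(tau, acqe)
    expect_lt(abs(p$g - m$g), 1e-4)
    expect_lt(abs(p$s - m$s), 1e-4)
  }
  mu <- expected_decay(decay_model(0.085e-9), irf_model("delta"), acqe)
  p <- compute_phasor(mu, acqe)
  m <- mono_exp_phasor(0.085e-9, acqe)
  expect_lt(abs(p$s - m$s), 1e-3)
  # published geometry (window exceeds the period by ~2.5 channels): < 1e-3
  acq <- paper_acq()
  for (tau in c(0.085e-9, 1e-9, 4e-9)) {
    mu <- expected_decay(decay_model(tau), irf_model("delta"), acq)
    p <- compute_phasor(mu, acq)
    m <- mono_exp_phasor(tau, acq)
    expect_lt(abs(p$g - m$g), 1e-3)
    expect_lt(abs(p$s - m$s), 1e-3)
  }
})

test_that("mono_exp_phasor lies on the universal semicircle (machine precision)", {
  acq <- paper_acq()
  taus <- c(0, 10^seq(-12, -7, length.out = 50))
  p <- mono_exp_phasor(taus, acq)
  expect_true(all(abs((p$g - 0.5)^2 + p$s^2 - 0.25) < 1e-12))
  expect_equal(unlist(mono_exp_phasor(0, acq)), c(g = 1, s = 0))
  far <- mono_exp_phasor(1e-3, acq)   # tau -> Inf limit
  expect_lt(abs(far$g), 1e-6)
  expect_lt(abs(far$s), 1e-3)
  apex <- mono_exp_phasor(1 / acq$omega, acq)
  expect_equal(apex$g, 0.5)
  expect_equal(apex$s, 0.5)
})

test_that("phasor_lifetimes matches the published worked example", {
  acq <- paper_acq()
  # native DHICA published phasor means (g = 0.888, s = 0.084)
  lt <- phasor_lifetimes(0.888, 0.084, acq)
  expect_equal(lt$tau_phi * 1e9, 0.190, tolerance = 0.02)
  expect_equal(lt$tau_m * 1e9, 1.000, tolerance = 0.02)
})

test_that("phase and modulation lifetimes agree only on the semicircle", {
  acq <- paper_acq()
  p <- mono_exp_phasor(1e-9, acq)
  lt <- phasor_lifetimes(p$g, p$s, acq)
  expect_equal(lt$tau_phi, 1e-9, tolerance = 1e-12)
  expect_equal(lt$tau_m, 1e-9, tolerance = 1e-12)
  # strict two-component mixtures: tau_phi < tau_m
  set.seed(21)
  for (i in 1:100) {
    t1 <- runif(1, 0.02, 1) * 1e-9
    t2 <- t1 * runif(1, 1.5, 20)
    f <- runif(1, 0.05, 0.95)
    p1 <- mono_exp_phasor(t1, acq); p2 <- mono_exp_phasor(t2, acq)
    lt <- phasor_lifetimes(f * p1$g + (1 - f) * p2$g,
                           f * p1$s + (1 - f) * p2$s, acq)
    expect_lt(lt$tau_phi, lt$tau_m)
  }
  # unphysical coordinates are flagged, not clamped
  bad <- phasor_lifetimes(c(-0.1, 0.9), c(0.2, 0.9), acq)
  expect_true(all(bad$flagged))
  expect_true(all(is.na(bad$tau_phi)))
})

test_that("phasor linearity: mixtures recover intensity fractions (1e-3)", {
  acq <- exact_acq()
  irf <- irf_model("delta")
  unit <- function(tau) {
    mu <- expected_decay(decay_model(tau), irf, acq)
    mu / sum(mu)
  }
  set.seed(31)
  for (i in 1:20) {
    tA <- runif(1, 0.05, 0.8) * 1e-9
    tB <- tA * runif(1, 2, 15)
    fA <- runif(1, 0.05, 0.95)
    mixed <- fA * unit(tA) + (1 - fA) * unit(tB)
    pm <- compute_phasor(mixed, acq)
    fr <- two_species_fractions(pm, compute_phasor(unit(tA), acq),
                                compute_phasor(unit(tB), acq))
    expect_lt(abs(fr$f_a - fA), 1e-3)
    expect_lt(fr$residual, 1e-6)
  }
  # the published two-species example: 0.7 / 0.3 intensity fractions
  mixed <- 0.7 * unit(0.2e-9) + 0.3 * unit(2.4e-9)
  fr <- two_species_fractions(compute_phasor(mixed, acq),
                              compute_phasor(unit(0.2e-9), acq),
                              compute_phasor(unit(2.4e-9), acq))
  expect_equal(fr$f_a, 0.7, tolerance = 1e-3)
  expect_equal(fr$f_b, 0.3, tolerance = 1e-3)
})

test_that("two_species_fractions endpoints and degenerate input", {
  A <- list(g = 0.9, s = 0.1); B <- list(g = 0.4, s = 0.45)
  expect_equal(two_species_fractions(A, A, B)$f_a, 1)
  expect_equal(two_species_fractions(B, A, B)$f_b, 1)
  mid <- list(g = 0.65, s = 0.275)
  fr <- two_species_fractions(mid, A, B)
  expect_equal(fr$f_a, 0.5)
  expect_equal(fr$f_b, 0.5)
  expect_error(two_species_fractions(mid, A, A), "coincident")
})

test_that("calibration: identity, injected distortion, end-to-end", {
  acq <- paper_acq(c(16L, 16L))
  # 1. reference measured exactly at theory -> identity correction
  th <- mono_exp_phasor(4e-9, acq)
  fake <- structure(list(g = matrix(th$g, 2, 2), s = matrix(th$s, 2, 2),
                         intensity = matrix(1, 2, 2),
                         valid = matrix(TRUE, 2, 2), acq = acq,
                         harmonic = 1L, spatial_bin = 1L,
                         calibration = NULL), class = "phasor_map")
  cal <- calibrate(fake, fake, 4e-9)
  expect_equal(cal$record$phase_correction, 0, tolerance = 1e-12)
  expect_equal(cal$record$modulation_correction, 1, tolerance = 1e-12)

  # 2. known synthetic distortion: rotation +0.2 rad, modulation x0.9
  rot <- 0.2; k <- 0.9
  gd <- k * (th$g * cos(rot) - th$s * sin(rot))
  sd_ <- k * (th$g * sin(rot) + th$s * cos(rot))
  fake2 <- fake; fake2$g[] <- gd; fake2$s[] <- sd_
  cal2 <- calibrate(fake2, fake2, 4e-9)
  expect_equal(cal2$record$phase_correction, -rot, tolerance = 0.01 * rot)
  expect_equal(cal2$record$modulation_correction, 1 / k,
               tolerance = 0.01 / k)

  # 3. end-to-end: calibrate with a simulated fluorescein frame, then a
  # simulated 2 ns mono-exponential must land on the semicircle within 0.01
  irf <- std_irf()
  ref_img <- render_phantom(uniform_layout(acq, decay_model(4e-9), 200),
                            irf, acq, seed = 41)
  rec <- calibrate(phasor_image(ref_img, 10), phasor_image(ref_img, 10),
                   4e-9)$record
  img2 <- render_phantom(uniform_layout(acq, decay_model(2e-9), 200),
                         irf, acq, seed = 42)
  m2 <- apply_calibration(phasor_image(img2, 10), rec)
  ctr <- reference_centroid(m2)
  expect_lt(abs(sqrt((ctr$g - 0.5)^2 + ctr$s^2) - 0.5), 0.01)
  th2 <- mono_exp_phasor(2e-9, acq)
  expect_lt(sqrt((ctr$g - th2$g)^2 + (ctr$s - th2$s)^2), 0.01)
  expect_error(calibrate(fake, list(g = 0, s = 0), 4e-9), "origin")
})

test_that("reference_centroid: single pixel, cloud, empty mask", {
  acq <- paper_acq(c(10L, 10L))
  set.seed(51)
  pmap <- structure(list(g = matrix(rnorm(100, 0.7, 0.01), 10),
                         s = matrix(rnorm(100, 0.2, 0.01), 10),
                         intensity = matrix(1, 10, 10),
                         valid = matrix(TRUE, 10, 10), acq = acq,
                         harmonic = 1L, spatial_bin = 1L, calibration = NULL),
                    class = "phasor_map")
  one <- matrix(FALSE, 10, 10); one[3, 4] <- TRUE
  c1 <- reference_centroid(pmap, one)
  expect_equal(c1$g, pmap$g[3, 4])
  expect_equal(c1$s, pmap$s[3, 4])
  call_ <- reference_centroid(pmap)
  expect_lt(abs(call_$g - 0.7), 5 * 0.01 / 10)
  expect_lt(abs(call_$s - 0.2), 5 * 0.01 / 10)
  expect_error(reference_centroid(pmap, matrix(FALSE, 10, 10)), "no valid")
})

test_that("fUVA-Mel reproduces the published distances from printed centroids", {
  ref <- melanin_reference_table()
  ctr <- function(cond) {
    r <- ref[ref$condition == cond, ]
    list(g = r$g, s = r$s)
  }
  dist2 <- function(a, b) sqrt((a$g - b$g)^2 + (a$s - b$s)^2)
  # DHICA: native (0.888, 0.084) vs 1-day (0.677, 0.222) and 7-day (0.589, 0.304)
  expect_equal(dist2(ctr("dhica_native"), ctr("dhica_uva1")), 0.252,
               tolerance = 0.01)
  expect_equal(dist2(ctr("dhica_native"), ctr("dhica_uva7")), 0.371,
               tolerance = 0.01)
  expect_equal(dist2(ctr("eupheo_native"), ctr("eupheo_uva7")), 0.288,
               tolerance = 0.01)
  expect_equal(dist2(ctr("dopa_native"), ctr("dopa_uva1")), 0.186,
               tolerance = 0.01)
})

test_that("fraction_modified: zero at centroid, Jensen, rotation covariance", {
  acq <- paper_acq(c(12L, 12L))
  set.seed(61)
  pmap <- structure(list(g = matrix(rnorm(144, 0.6, 0.02), 12),
                         s = matrix(rnorm(144, 0.3, 0.02), 12),
                         intensity = matrix(1, 12, 12),
                         valid = matrix(TRUE, 12, 12), acq = acq,
                         harmonic = 1L, spatial_bin = 1L, calibration = NULL),
                    class = "phasor_map")
  own <- reference_centroid(pmap)
  fm0 <- fraction_modified(pmap, own)
  expect_equal(fm0$centroid_distance, 0, tolerance = 1e-12)
  # pixel exactly at the centroid has distance zero
  pin <- pmap; pin$g[] <- own$g; pin$s[] <- own$s
  expect_true(all(fraction_modified(pin, own)$map$values == 0))
  # Jensen: mean pixel distance >= centroid distance
  far <- list(g = 0.9, s = 0.1)
  fm <- fraction_modified(pmap, far)
  expect_gte(fm$mean_pixel_distance, fm$centroid_distance)
  # a pure rotation applied to both map and centroid preserves distances
  rec <- structure(list(reference_name = "r", tau_ref = 4e-9,
                        phase_correction = 0.3, modulation_correction = 1),
                   class = "calibration_record")
  rmap <- apply_calibration(pmap, rec)
  rfar <- list(g = cos(0.3) * far$g - sin(0.3) * far$s,
               s = sin(0.3) * far$g + cos(0.3) * far$s)
  fm_r <- fraction_modified(rmap, rfar)
  expect_equal(fm_r$map$values, fm$map$values, tolerance = 1e-12)
  expect_error(fraction_modified(pmap, list(g = NULL, s = NULL)),
               "missing reference centroid")
})
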