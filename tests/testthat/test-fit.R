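acq <- dmi_acq()
pr <- dmi_priors()

test_that("a noiseless Gaussian resonance is recovered essentially exactly", {
  prl <- dmi_priors("lactate")
  fid <- synthesize_fid(c(lactate = 1.3), prl, acq, fwhm_hz = 25)
  fit <- fit_resonances(fid, prl, acq)
  truth_area <- expected_area(1.3, "lactate", pr, acq)
  expect_true(fit$converged)
  expect_equal(fit$coefficients$area, truth_area, tolerance = 1e-6)
  f_true <- ppm_to_hz(1.3 - acq$reference_ppm, acq$carrier_mhz)
  expect_lt(abs(fit$coefficients$freq_hz - f_true), 0.01)
  expect_equal(fit$coefficients$fwhm_hz, 25, tolerance = 1e-4)
  expect_lt(fit$rss / sum(Mod(fid)^2), 1e-10)
})

test_that("two overlapping resonances agree with a grid-search oracle", {
  pr2 <- dmi_priors(c("water", "glucose"))
  a_true <- c(water = 3, glucose = 1.2)
  set.seed(14)
  tt <- (seq_len(acq$n_points) - 1) / acq$spectral_width
  f_true <- ppm_to_hz(pr2$ppm - acq$reference_ppm, acq$carrier_mhz)
  gam <- (pi * 30)^2 / (4 * log(2))
  clean <- a_true[1] * exp(2i * pi * f_true[1] * tt - gam * tt^2) +
    a_true[2] * exp(2i * pi * f_true[2] * tt - gam * tt^2)
  noise_sd <- max(Mod(clean)) / 20 / sqrt(2)  # peak SNR ~ 20
  fid <- clean + complex(real = rnorm(length(tt), 0, noise_sd),
                         imaginary = rnorm(length(tt), 0, noise_sd))
  fit <- fit_resonances(fid, pr2, acq)
  expect_equal(fit$coefficients$area, unname(a_true),
               tolerance = 0.05)
  # exhaustive coarse grid over (A1, A2, width), frequencies at priors
  grid <- expand.grid(a1 = seq(2, 4, 0.1), a2 = seq(0.6, 1.8, 0.05),
                      w = seq(20, 40, 2.5))
  rss <- mapply(function(a1, a2, w) {
    g <- (pi * w)^2 / (4 * log(2))
    mdl <- a1 * exp(2i * pi * f_true[1] * tt - g * tt^2) +
      a2 * exp(2i * pi * f_true[2] * tt - g * tt^2)
    sum(Mod(fid - mdl)^2)
  }, grid$a1, grid$a2, grid$w)
  best <- grid[which.min(rss), ]
  expect_equal(fit$coefficients$area[1], best$a1, tolerance = 0.05)
  expect_equal(fit$coefficients$area[2], best$a2, tolerance = 0.05)
  # the optimizer does at least as well as the oracle grid
  expect_lte(fit$rss, min(rss) + 1e-9)
})

test_that("fitted areas are exactly linear in the data scale", {
  fid <- synthesize_fid(c(water = 8, glucose = 1, glx = 0.7,
                          lactate = 1.1), pr, acq, noise_sd = 0.3,
                        seed = 21)
  f1 <- fit_resonances(fid, pr, acq)
  f2 <- fit_resonances(2 * fid, pr, acq)
  expect_equal(f2$coefficients$area, 2 * f1$coefficients$area,
               tolerance = 1e-8)
  expect_equal(f2$coefficients$freq_hz, f1$coefficients$freq_hz,
               tolerance = 1e-8)
  expect_equal(f2$coefficients$fwhm_hz, f1$coefficients$fwhm_hz,
               tolerance = 1e-8)
})

test_that("degenerate and adversarial inputs are handled", {
  z <- fit_resonances(rep(0 + 0i, acq$n_points), pr, acq)
  expect_true(z$converged)
  expect_equal(z$coefficients$area, rep(0, 4))
  expect_error(fit_resonances(1:10, pr, acq), "length")
  # accepts a spectrum object too
  fid <- synthesize_fid(c(water = 5), pr, acq)
  fsp <- fit_resonances(fid_to_spectrum(fid, acq), pr, acq)
  expect_equal(fsp$coefficients$area[1], expected_area(5, "water", pr, acq),
               tolerance = 1e-6)
})

test_that("areas are invariant to zero-order phase errors up to 45 deg", {
  fid <- synthesize_fid(c(water = 8, glucose = 1, glx = 0.7,
                          lactate = 1.1), pr, acq)
  ref <- fit_resonances(fid, pr, acq,
                        fit_config(share_phase = TRUE))$coefficients$area
  for (phi in c(-45, -20, 10, 30, 45)) {
    rot <- fit_resonances(fid * exp(1i * phi * pi / 180), pr, acq,
                          fit_config(share_phase = TRUE))
    expect_equal(rot$coefficients$area, ref, tolerance = 1e-5)
  }
})

test_that("accepted iterations never increase the objective", {
  fid <- synthesize_fid(c(water = 8, glucose = 1, glx = 0.7,
                          lactate = 1.1), pr, acq, noise_sd = 0.9,
                        seed = 8)
  fit <- fit_resonances(fid, pr, acq)
  expect_true(all(diff(fit$rss_trace) <= 1e-9 * fit$rss_trace[-1]))
})

test_that("well-determined areas carry small median bias, none negative", {
  conc <- c(water = 11.6, glucose = 1.0, glx = 0.8, lactate = 1.08)
  truth <- vapply(names(conc), function(m)
    expected_area(conc[[m]], m, pr, acq), numeric(1))
  set.seed(31)
  areas <- t(replicate(60, {
    fid <- synthesize_fid(conc, pr, acq, noise_sd = 0.7)
    fit_resonances(fid, pr, acq)$coefficients$area
  }))
  expect_true(all(areas >= 0))
  bias <- apply(areas, 2, median) / truth - 1
  # water, glucose, lactate: the strong resonances recover within 2%;
  # Glx, the weakest line at this noise level, is noisier (its bias is
  # exercised at full spec tolerance in the acceptance suite)
  expect_lt(abs(bias[1]), 0.02)
  expect_lt(abs(bias[2]), 0.03)
  expect_lt(abs(bias[4]), 0.03)
})

test_that("goodness of fit reports residual fraction and rising errors", {
  fid <- synthesize_fid(c(water = 8, lactate = 1.1), pr, acq)
  perfect <- fit_resonances(fid, dmi_priors(c("water", "lactate")),
                            acq)
  g <- goodness_of_fit(perfect)
  expect_lt(g$residual_fraction, 1e-10)
  expect_true(g$available)
  expect_true(all(g$se$se_area >= 0))
  # pure noise with (near) nothing to fit: residual fraction near 1
  set.seed(9)
  noise <- complex(real = rnorm(acq$n_points),
                   imaginary = rnorm(acq$n_points))
  gn <- goodness_of_fit(fit_resonances(noise, pr, acq))
  expect_gt(gn$residual_fraction, 0.8)
  expect_lte(gn$residual_fraction, 1)
  # area uncertainty grows monotonically as noise doubles (50 seeds)
  mean_se <- vapply(c(0.3, 0.6, 1.2), function(sdv) {
    ses <- vapply(1:50, function(s) {
      f <- fit_resonances(
        synthesize_fid(c(water = 8, lactate = 1.1), pr, acq,
                       noise_sd = sdv, seed = 1000 + s),
        dmi_priors(c("water", "lactate")), acq)
      goodness_of_fit(f)$se$se_area[2]
    }, numeric(1))
    mean(ses, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_se) > 0))
})
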