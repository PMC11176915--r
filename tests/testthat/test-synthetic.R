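acq <- dmi_acq()
pr <- dmi_priors()

test_that("uptake curves honor the stated initial rates and plateaus", {
  st <- subtype_params("glycolytic", lactate_rate = 0.12,
                       glx_rate = 0.08, lactate_plateau = 1.08,
                       glx_plateau = 0.80)
  tr <- simulate_timecourses(st, time_grid = seq(0, 65, 5))
  # tangent slope at t = 0 equals the stated rate (Richardson
  # extrapolation of the analytic curve's one-sided difference)
  slope0 <- function(f, h = 1e-4) 2 * f(h / 2) / (h / 2) - f(h) / h
  expect_equal(slope0(tr$curves$lactate), 0.12, tolerance = 1e-9)
  expect_equal(slope0(tr$curves$glx), 0.08, tolerance = 1e-9)
  # plateau approached from below, never exceeded
  expect_true(all(tr$conc$lactate <= 1.08))
  expect_true(all(diff(tr$conc$lactate) > 0))
  # glucose maximum at the grid point nearest 20 min
  expect_equal(tr$time_min[which.max(tr$conc$glucose)], 20)
  # slower-labeling tissue stays below a faster one everywhere (t > 0)
  slow <- simulate_timecourses(subtype_preset("tumor_free"),
                               seq(0, 65, 1))
  fast <- simulate_timecourses(subtype_preset("glycolytic"),
                               seq(0, 65, 1))
  tpos <- slow$time_min > 0
  expect_true(all(slow$conc$lactate[tpos] < fast$conc$lactate[tpos]))
  # degenerate request rejected
  expect_error(subtype_params("x", lactate_rate = 0.1, glx_rate = 0,
                              lactate_plateau = 0, glx_plateau = 1),
               "plateau 0")
  # concentrations are never negative for all presets
  for (p in c("glycolytic", "mitochondrial", "tumor_free", "u87",
              "at5"))
    expect_true(all(simulate_timecourses(subtype_preset(p))$conc >= 0))
})

test_that("FID synthesis is linear and seed-reproducible", {
  fid1 <- synthesize_fid(c(lactate = 1), pr, acq)
  fid2 <- synthesize_fid(c(lactate = 2), pr, acq)
  expect_equal(fid2, 2 * fid1, tolerance = 1e-14)
  # fitted area proportional to c * n * F
  fit1 <- fit_resonances(fid1, dmi_priors("lactate"), acq)
  expect_equal(fit1$coefficients$area,
               expected_area(1, "lactate", pr, acq), tolerance = 1e-6)
  # doubling one concentration doubles only that resonance's area
  mix1 <- c(water = 10, lactate = 1)
  mix2 <- c(water = 10, lactate = 2)
  f1 <- fit_resonances(synthesize_fid(mix1, pr, acq),
                       dmi_priors(c("water", "lactate")), acq)
  f2 <- fit_resonances(synthesize_fid(mix2, pr, acq),
                       dmi_priors(c("water", "lactate")), acq)
  expect_equal(f2$coefficients$area[2], 2 * f1$coefficients$area[2],
               tolerance = 1e-6)
  expect_equal(f2$coefficients$area[1], f1$coefficients$area[1],
               tolerance = 1e-6)
  # bit-reproducible under a fixed seed
  a <- synthesize_fid(c(water = 10), pr, acq, noise_sd = 1, seed = 11)
  b <- synthesize_fid(c(water = 10), pr, acq, noise_sd = 1, seed = 11)
  expect_identical(a, b)
  expect_error(synthesize_fid(c(water = -1), pr, acq), "negative")
  expect_error(synthesize_fid(c(unknown = 1), pr, acq), "no prior")
})

test_that("dynamic series has the right frame structure and baseline", {
  tr <- simulate_timecourses(subtype_preset("glycolytic"))
  ser <- simulate_dynamic_series(tr, acq, pr, noise_sd = 0.7,
                                 seed = 3)
  # post-injection frame count = ceil(65 / 5)
  expect_equal(sum(ser$start_time_min >= 0), ceiling(65 / 5))
  expect_equal(ncol(ser$fids), ceiling(65 / 5) + 1)
  # baseline frame holds water but no metabolites above 3x noise
  bfit <- fit_resonances(ser$fids[, 1], pr, acq)
  cf <- bfit$coefficients
  noise_area_scale <- 0.7  # same order as per-point noise sd
  expect_gt(cf$area[cf$resonance == "water"],
            0.8 * expected_area(9.984, "water", pr, acq))
  for (m in c("glucose", "glx", "lactate"))
    expect_lt(cf$area[cf$resonance == m], 3 * noise_area_scale)
  # seeded reproducibility of the whole series
  ser2 <- simulate_dynamic_series(tr, acq, pr, noise_sd = 0.7,
                                  seed = 3)
  expect_identical(ser$fids, ser2$fids)
})

test_that("cohort sampling is seeded and respects positivity", {
  co <- simulate_cohort(6, "glycolytic", seed = 5)
  co2 <- simulate_cohort(6, "glycolytic", seed = 5)
  expect_equal(vapply(co, `[[`, numeric(1), "lactate_plateau"),
               vapply(co2, `[[`, numeric(1), "lactate_plateau"))
  expect_true(all(vapply(co, `[[`, numeric(1), "lactate_plateau") > 0))
  expect_true(all(vapply(co, `[[`, numeric(1), "glx_plateau") > 0))
  # plateaus vary between animals; rates stay at the nominal preset
  expect_gt(sd(vapply(co, `[[`, numeric(1), "lactate_plateau")), 0)
  expect_equal(unique(vapply(co, `[[`, numeric(1), "lactate_rate")),
               0.12)
})

test_that("cohort plateau contrasts give > 0.8 power at n = 5-6", {
  # group differences detectable by the downstream statistics:
  # per-animal steady-window averages from drawn plateaus, lactate
  # glycolytic vs mitochondrial, paired with compare_groups
  set.seed(202)
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    g <- simulate_cohort(6, "glycolytic")
    m <- simulate_cohort(5, "mitochondrial")
    wavg <- function(an) {
      tc <- simulate_timecourses(an, seq(0, 65, 5))
      mean(tc$conc$lactate[tc$time_min >= 20 & tc$time_min < 65])
    }
    p <- compare_groups(list(
      glycolytic = vapply(g, wavg, numeric(1)),
      mitochondrial = vapply(m, wavg, numeric(1))))$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.8)
})
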