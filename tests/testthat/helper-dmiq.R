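# Shared fixtures and independent oracles used across test files.

# Independent saturation oracle: iterate the longitudinal Bloch
# recursion M+ = M cos(a) E1 + M0 (1 - E1) to its fixed point, take
# the transverse signal M sin(a), and normalize by the fully relaxed
# signal M0 sin(a).
bloch_saturation_oracle <- function(t1, tr, flip_deg, iters = 5000) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr / t1)
  m <- 1
  for (i in seq_len(iters)) m <- m * cos(a) * e1 + (1 - e1)
  (m * sin(a)) / sin(a)
}

# A minimal hand-built fit object for quantification arithmetic tests.
make_fit <- function(areas, priors, acq) {
  cf <- data.frame(resonance = priors$name, area = areas,
                   freq_hz = 0, ppm = priors$ppm, fwhm_hz = 20,
                   phase_deg = 0, stringsAsFactors = FALSE)
  structure(list(coefficients = cf, rss = 0,
                 fitted = complex(acq$n_points),
                 residuals = complex(acq$n_points), converged = TRUE,
                 iterations = 0L, rss_trace = numeric(0),
                 data = complex(acq$n_points), priors = priors,
                 acq = acq, config = fit_config()),
            class = "dmi_fit")
}

# A hand-built concentration time course (long format).
make_tc <- function(time_min, conc, metabolite = "lactate",
                    frame_duration = diff(time_min)[1]) {
  out <- data.frame(time_min = time_min, metabolite = metabolite,
                    mmol_per_l = conc, se = NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "frame_duration_min") <- frame_duration
  class(out) <- c("dmi_timecourse", "data.frame")
  out
}

# Expected noiseless fitted area for a metabolite at concentration c
# (generator calibration constant 1).
expected_area <- function(c, name, priors, acq) {
  p <- priors[priors$name == name, ]
  c * p$n_deuterons * saturation_factor(p$t1, acq$tr, acq$flip_angle)
}
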