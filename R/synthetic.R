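#' Metabolic subtype parameters for the synthetic generator
#'
#' Describes one tissue class by the kinetic parameters of its
#' 2H-labeled metabolite time courses after a [6,6'-2H2]glucose bolus:
#' initial production rates and plateau concentrations for lactate and
#' Glx, the glucose peak, and the natural-abundance HDO baseline.
#' Lactate and Glx follow saturating exponentials
#' `C(t) = plateau * (1 - exp(-k t))` with `k = rate / plateau`, so the
#' tangent slope at t = 0 equals the stated initial rate; glucose
#' follows a gamma-variate bolus peaking at `glucose_peak_time`.
#'
#' @param label One of `"glycolytic"`, `"mitochondrial"`,
#'   `"tumor_free"` (free-text labels allowed for custom tissue).
#' @param lactate_rate,glx_rate Initial production rates, mmol/L/min.
#' @param lactate_plateau,glx_plateau Plateau concentrations, mmol/L.
#' @param glucose_peak Peak labeled-glucose concentration, mmol/L.
#' @param glucose_peak_time Time of the glucose maximum, min.
#' @param hdo_baseline Natural-abundance HDO concentration, mmol/L
#'   (tissue-referred: 12.48 x 0.80 by default).
#' @param hdo_slope Slow linear HDO rise from metabolism, mmol/L/min.
#' @param sd Named list of between-animal SDs used by the cohort
#'   sampler (`lactate_plateau`, `glx_plateau`, `lactate_rate`,
#'   `glx_rate`).
#' @return A `dmi_subtype_params` object.
#' @seealso [subtype_preset()] for the built-in tumor models.
#' @export
subtype_params <- function(label, lactate_rate, glx_rate,
                           lactate_plateau, glx_plateau,
                           glucose_peak = 1.5, glucose_peak_time = 20,
                           hdo_baseline = 12.48 * 0.80,
                           hdo_slope = 0.04, sd = list()) {
  stopifnot(lactate_rate >= 0, glx_rate >= 0,
            lactate_plateau >= 0, glx_plateau >= 0,
            glucose_peak >= 0, glucose_peak_time > 0,
            hdo_baseline > 0, hdo_slope >= 0)
  if (lactate_plateau == 0 && lactate_rate > 0)
    stop("subtype_params: lactate plateau 0 with positive rate")
  if (glx_plateau == 0 && glx_rate > 0)
    stop("subtype_params: glx plateau 0 with positive rate")
  structure(list(label = label, lactate_rate = lactate_rate,
                 glx_rate = glx_rate, lactate_plateau = lactate_plateau,
                 glx_plateau = glx_plateau, glucose_peak = glucose_peak,
                 glucose_peak_time = glucose_peak_time,
                 hdo_baseline = hdo_baseline, hdo_slope = hdo_slope,
                 sd = sd),
            class = "dmi_subtype_params")
}

#' Built-in subtype presets
#'
#' Kinetic presets for the four orthotopic GBM models and tumor-free
#' brain. Initial rates and (where reported) plateau means/SDs follow
#' the in-vivo group values: glycolytic tumors (A11, U87) label lactate
#' fast (0.12 and 0.11 mmol/L/min) with plateaus near 1.1 mmol/L;
#' mitochondrial tumors (S2, AT5) label Glx fast (0.12-0.13 mmol/L/min)
#' with Glx plateaus near 1.2 mmol/L; tumor-free brain labels both
#' slowly. `"glycolytic"` and `"mitochondrial"` are aliases for the A11
#' and S2 presets.
#'
#' @param name Preset name: `"glycolytic"`, `"mitochondrial"`,
#'   `"tumor_free"`, `"a11"`, `"u87"`, `"s2"`, or `"at5"`.
#' @return A [subtype_params()] object.
#' @export
subtype_preset <- function(name = c("glycolytic", "mitochondrial",
                                    "tumor_free", "a11", "u87", "s2",
                                    "at5")) {
  name <- match.arg(name)
  switch(name,
    glycolytic = , a11 = subtype_params(
      "glycolytic", lactate_rate = 0.12, glx_rate = 0.08,
      lactate_plateau = 1.08, glx_plateau = 0.80,
      sd = list(lactate_plateau = 0.18, glx_plateau = 0.18,
                lactate_rate = 0.03, glx_rate = 0.02)),
    u87 = subtype_params(
      "glycolytic", lactate_rate = 0.11, glx_rate = 0.08,
      lactate_plateau = 1.16, glx_plateau = 0.80,
      sd = list(lactate_plateau = 0.19, glx_plateau = 0.18,
                lactate_rate = 0.03, glx_rate = 0.03)),
    mitochondrial = , s2 = subtype_params(
      "mitochondrial", lactate_rate = 0.08, glx_rate = 0.12,
      lactate_plateau = 0.73, glx_plateau = 1.21,
      sd = list(lactate_plateau = 0.14, glx_plateau = 0.27,
                lactate_rate = 0.01, glx_rate = 0.02)),
    at5 = subtype_params(
      "mitochondrial", lactate_rate = 0.08, glx_rate = 0.13,
      lactate_plateau = 0.83, glx_plateau = 1.25,
      sd = list(lactate_plateau = 0.10, glx_plateau = 0.15,
                lactate_rate = 0.02, glx_rate = 0.02)),
    tumor_free = subtype_params(
      "tumor_free", lactate_rate = 0.08, glx_rate = 0.09,
      lactate_plateau = 0.65, glx_plateau = 0.95,
      sd = list(lactate_plateau = 0.12, glx_plateau = 0.18,
                lactate_rate = 0.01, glx_rate = 0.02))
  )
}

## Analytic concentration curves (mmol/L vs minutes post-injection).
## Pre-injection (t < 0): only the HDO baseline is present.
truth_curves <- function(subtype) {
  stopifnot(inherits(subtype, "dmi_subtype_params"))
  sat_curve <- function(rate, plateau) {
    if (plateau == 0) return(function(t) rep(0, length(t)))
    k <- rate / plateau
    function(t) ifelse(t > 0, plateau * (1 - exp(-k * t)), 0)
  }
  tp <- subtype$glucose_peak_time
  alpha <- 2  # gamma-variate shape; rise over ~tp, gentle decline
  glucose <- function(t) {
    g <- ifelse(t > 0, (t / tp)^alpha * exp(alpha * (1 - t / tp)), 0)
    subtype$glucose_peak * g
  }
  hdo <- function(t)
    subtype$hdo_baseline + subtype$hdo_slope * pmax(t, 0)
  list(water = hdo, glucose = glucose,
       glx = sat_curve(subtype$glx_rate, subtype$glx_plateau),
       lactate = sat_curve(subtype$lactate_rate,
                           subtype$lactate_plateau))
}

#' Simulate noiseless ground-truth metabolite time courses
#'
#' Evaluates the analytic curves of a subtype on a time grid: a
#' gamma-variate glucose bolus peaking at `glucose_peak_time`,
#' saturating-exponential lactate and Glx uptake whose initial slopes
#' equal the preset rates, and a constant-plus-slow-rise HDO baseline.
#' Time 0 is the start of the glucose injection; negative times are
#' pre-injection.
#'
#' @param subtype A [subtype_params()] object.
#' @param time_grid Ascending times, min; default 0-65 at 1-min steps.
#' @param seed Optional integer recorded for provenance (the curves
#'   themselves are deterministic).
#' @return A `dmi_truth` object: the evaluated grid (`$conc`, one
#'   column per metabolite), the curve functions (`$curves`), and the
#'   subtype.
#' @export
simulate_timecourses <- function(subtype, time_grid = seq(0, 65, 1),
                                 seed = NULL) {
  stopifnot(inherits(subtype, "dmi_subtype_params"))
  if (is.unsorted(time_grid, strictly = TRUE))
    stop("simulate_timecourses: time grid must be strictly ascending")
  curves <- truth_curves(subtype)
  conc <- vapply(curves, function(f) f(time_grid),
                 numeric(length(time_grid)))
  structure(list(time_min = time_grid,
                 conc = as.data.frame(conc),
                 curves = curves, subtype = subtype, seed = seed),
            class = "dmi_truth")
}

#' @export
print.dmi_truth <- function(x, ...) {
  cat(sprintf("ground-truth time courses (%s): %d points, %.0f-%.0f min\n",
              x$subtype$label, length(x$time_min), min(x$time_min),
              max(x$time_min)))
  invisible(x)
}

## Mean of a curve over [t0, t1] by composite trapezoid (33 nodes —
## ample for these smooth curves).
frame_average <- function(f, t0, t1, n = 33) {
  tt <- seq(t0, t1, length.out = n)
  y <- f(tt)
  sum((y[-1] + y[-n]) / 2) * (tt[2] - tt[1]) / (t1 - t0)
}

## Default generator linewidths (Gaussian FWHM, Hz) per resonance.
default_fwhm <- function(names) {
  base <- c(water = 18, glucose = 22, glx = 25, lactate = 22)
  out <- base[names]
  out[is.na(out)] <- 20
  names(out) <- names
  out
}

#' Synthesize one complex FID from metabolite concentrations
#'
#' Forward model inverting the quantification chain: each resonance
#' contributes
#' `A * exp(2i pi f t) * exp(-(pi fwhm)^2 t^2 / (4 log 2))`
#' with amplitude `A = conc * n_deuterons * F(T1) * calibration`, where
#' `F` is [saturation_factor()] at the acquisition TR/flip and `f` is
#' the resonance offset from the carrier. The Gaussian time-domain
#' envelope yields a Gaussian spectral line of the stated FWHM.
#' Complex circular Gaussian noise of standard deviation `noise_sd`
#' (per real/imaginary point) is added when requested.
#'
#' @param conc Named concentrations, mmol/L; names must appear in
#'   `priors$name`.
#' @param priors A [dmi_priors()] table.
#' @param acq A [dmi_acq()] object.
#' @param noise_sd Time-domain noise SD (signal units).
#' @param seed Optional integer seed (bit-reproducible output).
#' @param fwhm_hz Named or scalar Gaussian FWHM per resonance, Hz.
#' @param calibration Arbitrary signal-scale constant (cancels in
#'   water-referenced quantification).
#' @return Complex FID of length `acq$n_points`.
#' @export
synthesize_fid <- function(conc, priors, acq, noise_sd = 0,
                           seed = NULL, fwhm_hz = NULL,
                           calibration = 1) {
  stopifnot(inherits(priors, "dmi_priors"), inherits(acq, "dmi_acq"))
  if (any(conc < 0)) stop("synthesize_fid: negative concentrations")
  miss <- setdiff(names(conc), priors$name)
  if (length(miss))
    stop("synthesize_fid: no prior for: ", paste(miss, collapse = ", "))
  if (is.null(fwhm_hz)) fwhm_hz <- default_fwhm(names(conc))
  if (length(fwhm_hz) == 1 && is.null(names(fwhm_hz)))
    fwhm_hz <- stats::setNames(rep(fwhm_hz, length(conc)), names(conc))
  if (!is.null(seed)) set.seed(seed)
  tt <- (seq_len(acq$n_points) - 1) / acq$spectral_width
  fid <- complex(real = numeric(acq$n_points),
                 imaginary = numeric(acq$n_points))
  for (m in names(conc)) {
    p <- priors[priors$name == m, ]
    amp <- conc[[m]] * p$n_deuterons *
      saturation_factor(p$t1, acq$tr, acq$flip_angle) * calibration
    f <- ppm_to_hz(p$ppm - acq$reference_ppm, acq$carrier_mhz)
    gam <- (pi * fwhm_hz[[m]])^2 / (4 * log(2))
    fid <- fid + amp * exp(2i * pi * f * tt - gam * tt^2)
  }
  if (noise_sd > 0)
    fid <- fid + complex(real = stats::rnorm(acq$n_points, 0, noise_sd),
                         imaginary = stats::rnorm(acq$n_points, 0,
                                                  noise_sd))
  fid
}

#' Simulate a dynamic single-voxel FID series
#'
#' One FID per frame, with per-frame concentrations equal to the time
#' average of the ground-truth curves over that frame. Baseline
#' (pre-injection) frames at negative times contain only the HDO
#' signal, as the curves are zero before injection.
#'
#' @param truth A `dmi_truth` from [simulate_timecourses()].
#' @param acq A [dmi_acq()] object (`frame_duration` sets the frame
#'   length).
#' @param priors A [dmi_priors()] table.
#' @param noise_sd Time-domain noise SD per frame; the pipeline preset
#'   (0.9) gives a fitted-lactate coefficient of variation of about
#'   15\% at a 1.1 mmol/L plateau, comparable to the between-animal
#'   spread of the in-vivo group data.
#' @param seed Optional integer seed.
#' @param total_min Post-injection coverage, min (default 65).
#' @param n_baseline Number of pre-injection baseline frames.
#' @return A `dmi_series`: complex FID matrix (`n_points` x frames),
#'   frame start times (min, injection at 0), and provenance.
#' @export
simulate_dynamic_series <- function(truth, acq, priors, noise_sd = 0,
                                    seed = NULL, total_min = 65,
                                    n_baseline = 1) {
  stopifnot(inherits(truth, "dmi_truth"), inherits(acq, "dmi_acq"))
  if (!is.null(seed)) set.seed(seed)
  fd <- acq$frame_duration / 60
  n_post <- ceiling(total_min / fd)
  starts <- c(-rev(seq_len(n_baseline)) * fd, (seq_len(n_post) - 1) * fd)
  fids <- matrix(0i, acq$n_points, length(starts))
  for (j in seq_along(starts)) {
    cj <- vapply(truth$curves, frame_average,
                 numeric(1), t0 = starts[j], t1 = starts[j] + fd)
    fids[, j] <- synthesize_fid(cj, priors, acq, noise_sd = noise_sd)
  }
  structure(list(fids = fids, start_time_min = starts,
                 frame_duration_min = fd, acq = acq, priors = priors,
                 noise_sd = noise_sd, seed = seed,
                 subtype = truth$subtype$label),
            class = "dmi_series")
}

#' @export
print.dmi_series <- function(x, ...) {
  cat(sprintf("dynamic 2H series: %d frames of %.0f min (%d points each)\n",
              ncol(x$fids), x$frame_duration_min, nrow(x$fids)))
  cat(sprintf("  frame starts %g to %g min; noise sd %g\n",
              min(x$start_time_min), max(x$start_time_min), x$noise_sd))
  invisible(x)
}

#' Two-region spatial phantom for CSI simulation
#'
#' A rectangular voxel grid holding a tumor region and surrounding
#' brain, each with its own subtype kinetics. The default geometry
#' matches a 9 x 9 x 3 matrix over a 27 x 27 x 27 mm field of view
#' (3 x 3 x 9 mm voxels), with a 2 x 2 x 1 tumor block beside the grid
#' center.
#'
#' @param matrix_size Integer length-3 grid size.
#' @param fov_mm Field of view per axis, mm.
#' @param tumor Subtype for tumor voxels ([subtype_params()] or preset
#'   name).
#' @param brain Subtype for brain voxels.
#' @param tumor_mask Optional logical array (grid-shaped); default a
#'   2 x 2 x 1 block.
#' @return A `dmi_phantom` object.
#' @export
csi_phantom <- function(matrix_size = c(9, 9, 3),
                        fov_mm = c(27, 27, 27),
                        tumor = "glycolytic", brain = "tumor_free",
                        tumor_mask = NULL) {
  stopifnot(length(matrix_size) == 3, all(matrix_size >= 1),
            length(fov_mm) == 3, all(fov_mm > 0))
  if (is.character(tumor)) tumor <- subtype_preset(tumor)
  if (is.character(brain)) brain <- subtype_preset(brain)
  if (is.null(tumor_mask)) {
    tumor_mask <- array(FALSE, matrix_size)
    cx <- pmax(1, floor(matrix_size[1] / 2))
    cy <- pmax(1, floor(matrix_size[2] / 2))
    cz <- pmax(1, ceiling(matrix_size[3] / 2))
    tumor_mask[cx:min(cx + 1, matrix_size[1]),
               cy:min(cy + 1, matrix_size[2]), cz] <- TRUE
  }
  stopifnot(identical(dim(tumor_mask), as.integer(matrix_size)),
            any(tumor_mask))
  structure(list(matrix_size = as.integer(matrix_size), fov_mm = fov_mm,
                 voxel_size_mm = fov_mm / matrix_size,
                 tumor_mask = tumor_mask, brain_mask = !tumor_mask,
                 tumor = tumor, brain = brain),
            class = "dmi_phantom")
}

## Centered 3-D spatial DFT pair (unitary). k-space and image grids
## both carry their origin at index floor(n/2)+1 per axis, so a uniform
## k-space reconstructs to a point at the central voxel.
shift3 <- function(a, inverse = FALSE) {
  d <- dim(a)
  idx <- lapply(d, function(n) {
    if (n == 1) return(1L)
    h <- if (inverse) floor(n / 2) else ceiling(n / 2)
    c((h + 1):n, seq_len(h))
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

dft3 <- function(a, inverse = FALSE) {
  n <- prod(dim(a))
  if (inverse)
    shift3(stats::fft(shift3(a, inverse = TRUE), inverse = TRUE)) / sqrt(n)
  else
    shift3(stats::fft(shift3(a, inverse = TRUE))) / sqrt(n)
}

## Apply the spatial DFT to the three leading modes of a 5-mode array.
spatial_dft5 <- function(arr, inverse = FALSE) {
  d <- dim(arr)
  out <- array(0i, d)
  for (f in seq_len(d[5])) for (p in seq_len(d[4]))
    out[, , , p, f] <- dft3(array(arr[, , , p, f], d[1:3]),
                            inverse = inverse)
  out
}

#' Simulate a dynamic 3-D CSI k-space dataset
#'
#' Builds per-voxel FIDs from the phantom's region kinetics (frame
#' averages, as in [simulate_dynamic_series()]), forward phase-encodes
#' each (FID point, frame) slice with a centered unitary 3-D DFT, and
#' adds complex Gaussian noise in k-space. The default frame structure
#' is one 10-min baseline frame plus six 10-min post-injection frames
#' (seven frames total).
#'
#' @param phantom A [csi_phantom()].
#' @param acq A [dmi_acq()] object (spectral settings).
#' @param priors A [dmi_priors()] table.
#' @param noise_sd k-space complex noise SD.
#' @param seed Optional integer seed.
#' @param n_frames Total frames including baseline.
#' @param frame_duration_min Frame length, min.
#' @param n_baseline Baseline frames before injection.
#' @return A `dmi_csi` with `domain = "kspace"`; the 5-mode complex
#'   array is `(kx, ky, kz, fid_point, frame)`.
#' @export
simulate_csi_dataset <- function(phantom, acq, priors, noise_sd = 0,
                                 seed = NULL, n_frames = 7,
                                 frame_duration_min = 10,
                                 n_baseline = 1) {
  stopifnot(inherits(phantom, "dmi_phantom"), inherits(acq, "dmi_acq"))
  if (!is.null(seed)) set.seed(seed)
  ms <- phantom$matrix_size
  starts <- (seq_len(n_frames) - 1 - n_baseline) * frame_duration_min
  curves <- list(tumor = truth_curves(phantom$tumor),
                 brain = truth_curves(phantom$brain))
  vox <- array(0i, c(ms, acq$n_points, n_frames))
  for (f in seq_len(n_frames)) {
    fid_reg <- lapply(curves, function(cv) {
      cj <- vapply(cv, frame_average, numeric(1),
                   t0 = starts[f], t1 = starts[f] + frame_duration_min)
      synthesize_fid(cj, priors, acq, noise_sd = 0)
    })
    for (p in seq_len(acq$n_points)) {
      slab <- array(0i, ms)
      slab[phantom$tumor_mask] <- fid_reg$tumor[p]
      slab[phantom$brain_mask] <- fid_reg$brain[p]
      vox[, , , p, f] <- slab
    }
  }
  ksp <- spatial_dft5(vox, inverse = FALSE)
  if (noise_sd > 0) {
    n <- length(ksp)
    ksp <- ksp + array(complex(real = stats::rnorm(n, 0, noise_sd),
                               imaginary = stats::rnorm(n, 0, noise_sd)),
                       dim(ksp))
  }
  structure(list(data = ksp, domain = "kspace",
                 geometry = list(fov_mm = phantom$fov_mm,
                                 matrix_size = ms,
                                 voxel_size_mm = phantom$voxel_size_mm,
                                 frame_start_min = starts,
                                 frame_duration_min = frame_duration_min),
                 acq = acq, priors = priors, phantom = phantom,
                 noise_sd = noise_sd, seed = seed),
            class = "dmi_csi")
}

#' @export
print.dmi_csi <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("dynamic CSI dataset (%s domain): %s matrix, %d points, %d frames\n",
              x$domain, paste(g$matrix_size, collapse = "x"),
              dim(x$data)[4], dim(x$data)[5]))
  cat(sprintf("  FOV %s mm -> voxels %s mm\n",
              paste(g$fov_mm, collapse = "x"),
              paste(format(g$voxel_size_mm, digits = 3), collapse = "x")))
  invisible(x)
}

#' Draw a synthetic cohort of animals from a subtype preset
#'
#' Samples per-animal plateau concentrations (and optionally rates)
#' from the preset's between-animal means and SDs, truncated at a small
#' positive floor. Each animal is returned as its own
#' [subtype_params()], ready for [simulate_timecourses()].
#'
#' @param n Number of animals.
#' @param preset A preset name or [subtype_params()] with `sd` entries.
#' @param seed Optional integer seed.
#' @param draw_rates If `TRUE`, rates are sampled too; otherwise all
#'   animals share the preset's nominal rates.
#' @return List of `n` `dmi_subtype_params`.
#' @export
simulate_cohort <- function(n, preset = "glycolytic", seed = NULL,
                            draw_rates = FALSE) {
  if (is.character(preset)) preset <- subtype_preset(preset)
  stopifnot(inherits(preset, "dmi_subtype_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(mean, sd_name) {
    s <- preset$sd[[sd_name]]
    if (is.null(s)) return(mean)
    max(stats::rnorm(1, mean, s), 0.05)
  }
  lapply(seq_len(n), function(i) {
    lp <- draw(preset$lactate_plateau, "lactate_plateau")
    gp <- draw(preset$glx_plateau, "glx_plateau")
    lr <- if (draw_rates) draw(preset$lactate_rate, "lactate_rate")
          else preset$lactate_rate
    gr <- if (draw_rates) draw(preset$glx_rate, "glx_rate")
          else preset$glx_rate
    subtype_params(preset$label,
                   lactate_rate = min(lr, 5 * lp), glx_rate = min(gr, 5 * gp),
                   lactate_plateau = lp, glx_plateau = gp,
                   glucose_peak = preset$glucose_peak,
                   glucose_peak_time = preset$glucose_peak_time,
                   hdo_baseline = preset$hdo_baseline,
                   hdo_slope = preset$hdo_slope)
  })
}

#' Export ground-truth curves as CSV
#'
#' Long format: `time_min, metabolite, mmol_per_l`.
#'
#' @param truth A `dmi_truth`.
#' @param file Output path.
#' @export
write_truth_csv <- function(truth, file) {
  stopifnot(inherits(truth, "dmi_truth"))
  long <- do.call(rbind, lapply(names(truth$conc), function(m)
    data.frame(time_min = truth$time_min, metabolite = m,
               mmol_per_l = truth$conc[[m]])))
  utils::write.csv(long, file, row.names = FALSE)
  invisible(file)
}
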