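#' Acquisition parameters for a 2H pulse-acquire experiment
#'
#' Bundles the scanner settings needed to interpret a deuterium FID:
#' the 2H carrier frequency, spectral width, number of complex points,
#' repetition time, nominal flip angle, and the ppm value the carrier is
#' anchored to (water, 4.7 ppm, by convention). Defaults are typical of
#' short-TR pulse-acquire 2H MRS at 7 T.
#'
#' @param carrier_mhz 2H Larmor frequency in MHz (about 45.7 at 7 T).
#' @param spectral_width Spectral width (sampling rate) in Hz.
#' @param n_points Number of complex time-domain points.
#' @param tr Repetition time in seconds.
#' @param flip_angle Nominal excitation flip angle in degrees.
#' @param n_averages Number of averaged excitations per stored FID.
#' @param frame_duration Duration of one dynamic frame in seconds.
#' @param reference_ppm Chemical shift (ppm) assigned to the carrier
#'   frequency; the water resonance by default.
#' @return An object of class `dmi_acq`.
#' @examples
#' acq <- dmi_acq()
#' acq$spectral_width / acq$n_points  # spectral resolution, Hz/point
#' @export
dmi_acq <- function(carrier_mhz = 45.7, spectral_width = 2003,
                    n_points = 256, tr = 0.140, flip_angle = 50,
                    n_averages = 2250, frame_duration = 300,
                    reference_ppm = 4.7) {
  stopifnot(
    is.numeric(carrier_mhz), carrier_mhz > 0,
    is.numeric(spectral_width), spectral_width > 0,
    n_points >= 2, n_points == as.integer(n_points),
    tr > 0, flip_angle > 0, flip_angle < 180,
    n_averages >= 1, frame_duration > 0
  )
  structure(list(
    carrier_mhz = carrier_mhz, spectral_width = spectral_width,
    n_points = as.integer(n_points), tr = tr, flip_angle = flip_angle,
    n_averages = n_averages, frame_duration = frame_duration,
    reference_ppm = reference_ppm
  ), class = "dmi_acq")
}

#' @export
print.dmi_acq <- function(x, ...) {
  cat("2H acquisition parameters\n")
  cat(sprintf("  carrier %.3f MHz, SW %.0f Hz, %d points\n",
              x$carrier_mhz, x$spectral_width, x$n_points))
  cat(sprintf("  TR %.0f ms, flip %.0f deg, %d averages, frame %.0f s\n",
              1e3 * x$tr, x$flip_angle, x$n_averages, x$frame_duration))
  cat(sprintf("  carrier anchored at %.2f ppm\n", x$reference_ppm))
  invisible(x)
}

#' Prior-knowledge resonance table for 2H brain spectra
#'
#' The four resonances observed after [6,6'-2H2]glucose infusion, with
#' the chemical shifts, longitudinal relaxation times, and deuteron
#' counts used for fitting and for absolute quantification:
#' water/HDO 4.7 ppm (T1 320 ms, 1 deuteron), glucose 3.72 ppm (64 ms,
#' 2 deuterons at the labeled 6,6' position), the combined
#' glutamate+glutamine (Glx) resonance 2.3 ppm (146 ms, 1 deuteron),
#' and lactate 1.3 ppm (297 ms, 2 deuterons). Glx is treated as a
#' single unresolved line. Fit constraints (shift tolerance, linewidth
#' bounds) are carried per resonance.
#'
#' @param names Optional character vector selecting a subset of
#'   resonances (in the table's order).
#' @param shift_tol Allowed deviation of each fitted center from its
#'   prior chemical shift, ppm.
#' @param lw_bounds Length-2 numeric, Gaussian FWHM bounds in Hz.
#' @return A `dmi_priors` data frame with one row per resonance.
#' @examples
#' dmi_priors()
#' dmi_priors(c("water", "lactate"))
#' @export
dmi_priors <- function(names = NULL, shift_tol = 0.1,
                       lw_bounds = c(5, 120)) {
  stopifnot(shift_tol > 0, length(lw_bounds) == 2,
            all(lw_bounds > 0), lw_bounds[1] < lw_bounds[2])
  tab <- data.frame(
    name = c("water", "glucose", "glx", "lactate"),
    ppm = c(4.7, 3.72, 2.3, 1.3),
    t1 = c(0.320, 0.064, 0.146, 0.297),
    n_deuterons = c(1L, 2L, 1L, 2L),
    shift_tol = shift_tol,
    lw_min = lw_bounds[1],
    lw_max = lw_bounds[2],
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    miss <- setdiff(names, tab$name)
    if (length(miss))
      stop("unknown resonance(s): ", paste(miss, collapse = ", "))
    tab <- tab[match(names, tab$name), , drop = FALSE]
    rownames(tab) <- NULL
  }
  class(tab) <- c("dmi_priors", "data.frame")
  tab
}

#' Build a custom resonance prior table
#'
#' @param name Character vector of resonance labels.
#' @param ppm Chemical shifts, ppm.
#' @param t1 Longitudinal relaxation times, s (must be > 0).
#' @param n_deuterons Deuterons contributing to each resonance.
#' @param shift_tol,lw_bounds Fit constraints as in [dmi_priors()].
#' @return A `dmi_priors` data frame.
#' @export
dmi_priors_custom <- function(name, ppm, t1, n_deuterons,
                              shift_tol = 0.1, lw_bounds = c(5, 120)) {
  stopifnot(length(name) == length(ppm), length(ppm) == length(t1),
            length(t1) == length(n_deuterons),
            all(t1 > 0), all(n_deuterons >= 1),
            all(lw_bounds > 0), lw_bounds[1] < lw_bounds[2])
  tab <- data.frame(name = as.character(name), ppm = ppm, t1 = t1,
                    n_deuterons = as.integer(n_deuterons),
                    shift_tol = shift_tol, lw_min = lw_bounds[1],
                    lw_max = lw_bounds[2], stringsAsFactors = FALSE)
  class(tab) <- c("dmi_priors", "data.frame")
  tab
}
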