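#' Convert a chemical-shift offset to a frequency offset
#'
#' One ppm corresponds to one millionth of the carrier frequency, so an
#' offset of `delta_ppm` at a carrier of `carrier_mhz` MHz is
#' `delta_ppm * carrier_mhz` Hz (sign-preserving).
#'
#' @param delta_ppm Chemical-shift offset(s), ppm.
#' @param carrier_mhz Carrier (Larmor) frequency, MHz.
#' @return Frequency offset(s) in Hz.
#' @examples
#' ppm_to_hz(4.7 - 1.3, 45.7)  # water-lactate separation at 7 T
#' @export
ppm_to_hz <- function(delta_ppm, carrier_mhz) {
  if (!all(is.finite(delta_ppm)) || !all(is.finite(carrier_mhz)))
    stop("ppm_to_hz: inputs must be finite")
  if (any(carrier_mhz <= 0)) stop("ppm_to_hz: carrier must be positive")
  delta_ppm * carrier_mhz
}

#' @rdname ppm_to_hz
#' @param delta_hz Frequency offset(s), Hz.
#' @export
hz_to_ppm <- function(delta_hz, carrier_mhz) {
  if (!all(is.finite(delta_hz)) || !all(is.finite(carrier_mhz)))
    stop("hz_to_ppm: inputs must be finite")
  if (any(carrier_mhz <= 0)) stop("hz_to_ppm: carrier must be positive")
  delta_hz / carrier_mhz
}

#' Steady-state saturation factor for short-TR pulse-acquire
#'
#' With repetition times comparable to T1, the longitudinal
#' magnetization does not recover fully between excitations and the
#' observed signal is attenuated. For an ideally spoiled pulse-acquire
#' sequence the steady-state signal, relative to the fully relaxed
#' signal at the same flip angle, is
#' \deqn{F = (1 - E_1) / (1 - \cos\alpha \, E_1), \quad
#'       E_1 = e^{-TR/T_1}.}
#' Dividing a fitted resonance integral by F (with that species' T1)
#' removes the saturation bias before concentrations are computed.
#'
#' @param t1 Longitudinal relaxation time, s.
#' @param tr Repetition time, s.
#' @param flip_angle Flip angle, degrees (0 < flip < 180).
#' @return Saturation factor in (0, 1]; decreasing in T1, increasing
#'   in TR.
#' @examples
#' saturation_factor(0.297, 0.140, 50)  # lactate at TR 140 ms, 50 deg
#' @export
saturation_factor <- function(t1, tr, flip_angle) {
  if (!all(is.finite(t1)) || !all(is.finite(tr)) ||
      !all(is.finite(flip_angle)))
    stop("saturation_factor: inputs must be finite")
  if (any(t1 <= 0)) stop("saturation_factor: t1 must be > 0")
  if (any(tr <= 0)) stop("saturation_factor: tr must be > 0")
  if (any(flip_angle <= 0) || any(flip_angle >= 180))
    stop("saturation_factor: flip_angle must be in (0, 180)")
  e1 <- exp(-tr / t1)
  (1 - e1) / (1 - cos(flip_angle * pi / 180) * e1)
}

## fftshift for a vector: move DC (index 1) to the center bin
## floor(n/2)+1, so an even-length axis runs -n/2 ... n/2-1.
fftshift_vec <- function(x) {
  n <- length(x)
  h <- ceiling(n / 2)
  c(x[(h + 1):n], x[seq_len(h)])
}

ifftshift_vec <- function(x) {
  n <- length(x)
  h <- floor(n / 2)
  c(x[(h + 1):n], x[seq_len(h)])
}

## Frequency axis after fftshift: ascending, DC at floor(n/2)+1.
shifted_freq_axis <- function(n, sw) {
  (seq_len(n) - 1 - floor(n / 2)) * sw / n
}

#' Fourier transform a FID into a spectrum
#'
#' Computes the unitary discrete Fourier transform of a complex FID and
#' attaches an ascending frequency/ppm axis with the carrier mapped to
#' `acq$reference_ppm` (water at 4.7 ppm by default). The unitary
#' scaling (1/sqrt(N)) makes the transform energy-preserving.
#'
#' @param fid Complex vector of length `acq$n_points`.
#' @param acq A [dmi_acq()] object.
#' @return A `dmi_spectrum`: list with `values` (complex), `hz` and
#'   `ppm` axes (ascending), the acquisition record, and the applied
#'   phase record (`phase0`, `phase1`, both 0 for a fresh transform).
#' @export
fid_to_spectrum <- function(fid, acq) {
  stopifnot(inherits(acq, "dmi_acq"))
  if (length(fid) != acq$n_points)
    stop("fid_to_spectrum: fid length (", length(fid),
         ") does not match acq$n_points (", acq$n_points, ")")
  n <- acq$n_points
  values <- fftshift_vec(stats::fft(as.complex(fid))) / sqrt(n)
  hz <- shifted_freq_axis(n, acq$spectral_width)
  structure(list(
    values = values, hz = hz,
    ppm = acq$reference_ppm + hz / acq$carrier_mhz,
    phase0 = 0, phase1 = 0, acq = acq
  ), class = "dmi_spectrum")
}

#' Inverse-transform a spectrum back to a FID
#'
#' Exact inverse of [fid_to_spectrum()] up to numerical round-off.
#'
#' @param spectrum A `dmi_spectrum`.
#' @return Complex FID vector.
#' @export
spectrum_to_fid <- function(spectrum) {
  stopifnot(inherits(spectrum, "dmi_spectrum"))
  n <- length(spectrum$values)
  stats::fft(ifftshift_vec(spectrum$values), inverse = TRUE) / sqrt(n)
}

#' Apply zero- and first-order phase correction
#'
#' Multiplies each spectral point by
#' `exp(i * (phi0 + phi1 * (ppm - pivot)) * pi/180)`. The magnitude
#' spectrum is unchanged; only the distribution between absorptive
#' (real) and dispersive (imaginary) parts rotates.
#'
#' @param spectrum A `dmi_spectrum`.
#' @param phi0 Zero-order phase, degrees.
#' @param phi1 First-order phase, degrees per ppm.
#' @param pivot Pivot chemical shift for the first-order term, ppm;
#'   defaults to the acquisition reference (water).
#' @return The phased `dmi_spectrum`, with the cumulative applied
#'   phases recorded in `phase0`/`phase1`.
#' @export
phase_correct <- function(spectrum, phi0, phi1 = 0, pivot = NULL) {
  stopifnot(inherits(spectrum, "dmi_spectrum"))
  if (!is.finite(phi0) || !is.finite(phi1))
    stop("phase_correct: phases must be finite")
  if (is.null(pivot)) pivot <- spectrum$acq$reference_ppm
  ang <- (phi0 + phi1 * (spectrum$ppm - pivot)) * pi / 180
  spectrum$values <- spectrum$values * exp(1i * ang)
  spectrum$phase0 <- spectrum$phase0 + phi0
  spectrum$phase1 <- spectrum$phase1 + phi1
  spectrum
}

#' Automatic zero/first-order phasing
#'
#' Deterministic coarse-to-fine grid search for the phase pair
#' minimizing the negative-real-part penalty of the phased spectrum
#' (the summed squared negative real values, normalized by the total
#' spectral energy), i.e. driving all lines toward upright
#' absorption. A vanishingly weighted integrated-real-part term
#' breaks ties across the penalty's flat valley, making the optimum
#' unique; both terms are invariant to the overall data scale. The
#' first-order pivot is the water resonance by default.
#'
#' One-sided FIDs carry dispersive tails whose interference shifts
#' individual peak phases by several degrees even in a perfectly
#' phased spectrum; the criterion therefore defines "well phased"
#' operationally (no negative lobes, maximal upright signal) rather
#' than recovering a nominal phase exactly.
#'
#' @param spectrum A `dmi_spectrum`.
#' @param pivot First-order pivot, ppm.
#' @param phi1_range Search range for the first-order term, deg/ppm.
#' @param n_refine Number of refinement passes.
#' @return The phased spectrum; chosen phases in `phase0`/`phase1`.
#' @export
auto_phase <- function(spectrum, pivot = NULL, phi1_range = c(-20, 20),
                       n_refine = 3) {
  stopifnot(inherits(spectrum, "dmi_spectrum"))
  if (is.null(pivot)) pivot <- spectrum$acq$reference_ppm
  pen <- phase_penalty(spectrum$values, spectrum$ppm, pivot)
  p0_grid <- seq(-180, 175, by = 5)
  p1_grid <- seq(phi1_range[1], phi1_range[2], by = 2)
  best <- c(0, 0); best_val <- Inf
  for (p0 in p0_grid) for (p1 in p1_grid) {
    v <- pen(p0, p1)
    if (v < best_val) { best_val <- v; best <- c(p0, p1) }
  }
  step0 <- 5; step1 <- 2
  for (r in seq_len(n_refine)) {
    step0 <- step0 / 5; step1 <- step1 / 5
    p0s <- best[1] + seq(-5, 5) * step0
    p1s <- best[2] + seq(-5, 5) * step1
    for (p0 in p0s) for (p1 in p1s) {
      v <- pen(p0, p1)
      if (v < best_val) { best_val <- v; best <- c(p0, p1) }
    }
  }
  phase_correct(spectrum, best[1], best[2], pivot = pivot)
}

## The auto-phasing objective: normalized negative-real-part penalty
## with a tiny integrated-real tie-breaker (scale-free).
phase_penalty <- function(values, ppm, pivot) {
  energy <- sum(Mod(values)^2)
  scale <- sqrt(energy * length(values))
  function(p0, p1) {
    ang <- (p0 + p1 * (ppm - pivot)) * pi / 180
    re <- Re(values * exp(1i * ang))
    sum(pmin(re, 0)^2) / energy - 1e-3 * sum(re) / scale
  }
}

#' @export
print.dmi_spectrum <- function(x, ...) {
  cat(sprintf("2H spectrum: %d points, %.2f to %.2f ppm\n",
              length(x$values), min(x$ppm), max(x$ppm)))
  cat(sprintf("  applied phases: %.2f deg, %.2f deg/ppm\n",
              x$phase0, x$phase1))
  invisible(x)
}

#' @export
plot.dmi_spectrum <- function(x, part = c("real", "magnitude"),
                              xlim = rev(range(x$ppm)), ...) {
  part <- match.arg(part)
  y <- if (part == "real") Re(x$values) else Mod(x$values)
  graphics::plot(x$ppm, y, type = "l", xlim = xlim,
                 xlab = "chemical shift (ppm)", ylab = part, ...)
  invisible(x)
}

#' Export a spectrum to CSV
#'
#' Writes columns `ppm`, `real`, `imag`.
#'
#' @param spectrum A `dmi_spectrum`.
#' @param file Output path.
#' @export
write_spectrum_csv <- function(spectrum, file) {
  stopifnot(inherits(spectrum, "dmi_spectrum"))
  utils::write.csv(data.frame(ppm = spectrum$ppm,
                              real = Re(spectrum$values),
                              imag = Im(spectrum$values)),
                   file, row.names = FALSE)
  invisible(file)
}
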