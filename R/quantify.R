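#' Quantification configuration
#'
#' Settings converting fitted resonance areas into absolute
#' concentrations. The internal reference is the natural-abundance HDO
#' signal in the pre-injection baseline spectrum: 12.48 mmol/L HDO in
#' pure water, scaled by a brain water content of 0.80, giving a
#' tissue-referred reference of 9.984 mmol/L. Both factors are exposed
#' because the literature states them separately. Deuteron counts
#' default to 2 for glucose (the 6,6' label), 2 for lactate (methyl
#' deuterons inherited from the label), 1 for the Glx resonance and 1
#' for HDO; no correction for deuterium label loss or exchange is
#' applied, and these counts are configurable.
#'
#' @param hdo_reference_mmol Natural-abundance HDO concentration in
#'   pure water, mmol/L.
#' @param water_fraction Tissue water content, dimensionless in (0,1].
#' @param water_deuterons Deuterons per HDO molecule contributing to
#'   the water resonance.
#' @param deuterons Named deuteron counts per metabolite.
#' @param apply_saturation Apply the T1 [saturation_factor()]
#'   correction (needs a T1 for every quantified species).
#' @return A `dmi_quant_config`.
#' @export
quant_config <- function(hdo_reference_mmol = 12.48,
                         water_fraction = 0.80, water_deuterons = 1,
                         deuterons = c(glucose = 2, lactate = 2,
                                       glx = 1),
                         apply_saturation = TRUE) {
  stopifnot(hdo_reference_mmol > 0, water_fraction > 0,
            water_fraction <= 1, water_deuterons >= 1,
            all(deuterons >= 1))
  structure(list(hdo_reference_mmol = hdo_reference_mmol,
                 water_fraction = water_fraction,
                 water_deuterons = water_deuterons,
                 deuterons = deuterons,
                 apply_saturation = isTRUE(apply_saturation)),
            class = "dmi_quant_config")
}

## Deuteron count for a metabolite: config first, then priors table.
deuteron_count <- function(name, priors, config) {
  if (name == "water") return(config$water_deuterons)
  if (!is.null(config$deuterons[[name]])) return(config$deuterons[[name]])
  p <- priors[priors$name == name, ]
  if (nrow(p)) return(p$n_deuterons)
  stop("no deuteron count for metabolite: ", name)
}

#' Convert fitted areas to absolute concentrations
#'
#' Water-referenced quantification: for metabolite m with fitted area
#' I_m,
#' \deqn{c_m = \frac{I_m / (n_m F_m)}{I_{w,base} / (n_w F_w)}
#'       \times C_{tissue},}
#' where n are deuteron counts, F the steady-state
#' [saturation_factor()] values at the acquisition TR and flip angle
#' (skipped when `apply_saturation = FALSE`), and
#' `C_tissue = hdo_reference_mmol * water_fraction`. The water
#' resonance itself is quantified against the same baseline area, so
#' post-injection HDO accumulation is reported on the same scale.
#'
#' @param fit A `dmi_fit`.
#' @param baseline_water_area Fitted water area of the pre-injection
#'   baseline spectrum (> 0).
#' @param config A [quant_config()].
#' @param se_area Optional per-resonance standard errors of the areas
#'   (same order as `coef(fit)`), propagated linearly.
#' @return Named numeric vector of concentrations (mmol/L), with the
#'   propagated standard errors in attribute `"se"` when provided.
#' @export
concentration_from_areas <- function(fit, baseline_water_area,
                                     config = quant_config(),
                                     se_area = NULL) {
  stopifnot(inherits(fit, "dmi_fit"),
            inherits(config, "dmi_quant_config"))
  if (!is.finite(baseline_water_area) || baseline_water_area <= 0)
    stop("concentration_from_areas: baseline water area must be > 0")
  cf <- fit$coefficients
  priors <- fit$priors
  acq <- fit$acq
  c_tissue <- config$hdo_reference_mmol * config$water_fraction
  sat <- function(name) {
    if (!config$apply_saturation) return(1)
    p <- priors[priors$name == name, ]
    if (!nrow(p) || !is.finite(p$t1))
      stop("concentration_from_areas: no T1 for '", name,
           "' with saturation correction enabled")
    saturation_factor(p$t1, acq$tr, acq$flip_angle)
  }
  f_w <- sat("water")
  denom <- baseline_water_area / (config$water_deuterons * f_w)
  conc <- vapply(seq_len(nrow(cf)), function(i) {
    nm <- cf$resonance[i]
    cf$area[i] / (deuteron_count(nm, priors, config) * sat(nm)) /
      denom * c_tissue
  }, numeric(1))
  names(conc) <- cf$resonance
  if (!is.null(se_area)) {
    se <- vapply(seq_len(nrow(cf)), function(i) {
      nm <- cf$resonance[i]
      se_area[i] / (deuteron_count(nm, priors, config) * sat(nm)) /
        denom * c_tissue
    }, numeric(1))
    names(se) <- cf$resonance
    attr(conc, "se") <- se
  }
  conc
}

#' Quantify a fitted dynamic series into concentration time courses
#'
#' Applies [concentration_from_areas()] frame by frame against the
#' baseline water area taken from the pre-injection frame(s): the
#' fitted water area of frame `baseline_index`, or the mean over the
#' first `n_baseline_avg` frames starting there. Fit standard errors
#' are propagated linearly.
#'
#' @param fits A `dmi_fit_series` from [fit_series()].
#' @param baseline_index Index of the (first) baseline frame; it must
#'   precede the injection (start time < 0... the first post-injection
#'   frame starts at 0).
#' @param n_baseline_avg Number of baseline frames to average.
#' @param config A [quant_config()].
#' @param compute_se Compute and propagate fit standard errors
#'   (slower; requires the Jacobian per frame).
#' @return A `dmi_timecourse`: long data frame with columns
#'   `time_min` (frame start), `metabolite`, `mmol_per_l`, `se`.
#' @export
quantify_series <- function(fits, baseline_index = 1,
                            n_baseline_avg = 1,
                            config = quant_config(),
                            compute_se = FALSE) {
  stopifnot(inherits(fits, "dmi_fit_series"))
  nf <- length(fits$fits)
  if (baseline_index < 1 || baseline_index > nf)
    stop("quantify_series: baseline index out of range")
  idx <- baseline_index:min(baseline_index + n_baseline_avg - 1, nf)
  if (any(fits$start_time_min[idx] >= 0))
    stop("quantify_series: baseline frame(s) must precede injection ",
         "(start time < 0)")
  w_area <- mean(vapply(idx, function(j) {
    cf <- fits$fits[[j]]$coefficients
    cf$area[cf$resonance == "water"]
  }, numeric(1)))
  if (!length(w_area) || w_area <= 0)
    stop("quantify_series: baseline water area is zero or missing")
  rows <- lapply(seq_len(nf), function(j) {
    f <- fits$fits[[j]]
    se_area <- if (compute_se) goodness_of_fit(f)$se$se_area else NULL
    conc <- concentration_from_areas(f, w_area, config,
                                     se_area = se_area)
    se <- attr(conc, "se")
    data.frame(time_min = fits$start_time_min[j],
               metabolite = names(conc), mmol_per_l = as.numeric(conc),
               se = if (is.null(se)) NA_real_ else as.numeric(se),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "frame_duration_min") <- fits$frame_duration_min
  attr(out, "baseline_water_area") <- w_area
  class(out) <- c("dmi_timecourse", "data.frame")
  out
}

#' @export
print.dmi_timecourse <- function(x, ...) {
  cat(sprintf("concentration time course: %d frames x %d metabolites\n",
              length(unique(x$time_min)),
              length(unique(x$metabolite))))
  print.data.frame(utils::head(x, 12), row.names = FALSE)
  if (nrow(x) > 12) cat("...\n")
  invisible(x)
}

#' @export
plot.dmi_timecourse <- function(x, metabolites = NULL, ...) {
  if (is.null(metabolites)) metabolites <- unique(x$metabolite)
  cols <- seq_along(metabolites)
  ylim <- range(x$mmol_per_l[x$metabolite %in% metabolites])
  graphics::plot(NA, xlim = range(x$time_min), ylim = ylim,
                 xlab = "time from injection (min)",
                 ylab = "concentration (mmol/L)", ...)
  for (i in seq_along(metabolites)) {
    d <- x[x$metabolite == metabolites[i], ]
    graphics::lines(d$time_min, d$mmol_per_l, col = cols[i], type = "b")
  }
  graphics::legend("topleft", metabolites, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Export a concentration time course as CSV
#'
#' @param tc A `dmi_timecourse`.
#' @param file Output path.
#' @export
write_timecourse_csv <- function(tc, file) {
  stopifnot(inherits(tc, "dmi_timecourse"))
  utils::write.csv(as.data.frame(tc), file, row.names = FALSE)
  invisible(file)
}
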