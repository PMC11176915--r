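#' Pipeline configuration
#'
#' Assembles the per-stage configurations into one object, optionally
#' overlaid from a YAML file whose sections mirror the stage configs
#' (`acquisition`, `quant`, `denoise_ranks`, `windows`, `subtype`,
#' `noise_sd`, `seed`). Defaults are the standard 2H acquisition
#' (2003 Hz / 256 points / TR 140 ms / flip 50), the four-resonance
#' prior table, HDO reference 12.48 mmol/L x 0.80 water fraction,
#' denoising ranks (6, 6, 3, 24, 5), rate window 0-20 min, averaging
#' window 20-65 min, and the calibrated subtype threshold 0.90 with
#' margin 0.02.
#'
#' @param file Optional YAML file; its entries override the defaults.
#' @param ... Named overrides applied after the file (e.g.
#'   `seed = 7`, `noise_sd = 0`).
#' @return A `dmi_pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- list(
    acquisition = list(),          # dmi_acq() overrides
    quant = list(),                # quant_config() overrides
    denoise_ranks = c(6, 6, 3, 24, 5),
    rate_window = c(0, 20),
    avg_window = c(20, 65),
    subtype_threshold = 0.90,
    subtype_margin = 0.02,
    noise_sd = 0.7,
    seed = 1L
  )
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    for (k in names(y)) cfg[[k]] <- y[[k]]
  }
  dots <- list(...)
  for (k in names(dots)) cfg[[k]] <- dots[[k]]
  cfg$acq <- do.call(dmi_acq, cfg$acquisition)
  cfg$priors <- dmi_priors()
  cfg$quant_cfg <- do.call(quant_config, cfg$quant)
  structure(cfg, class = "dmi_pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  keep <- setdiff(names(config), c("acq", "priors", "quant_cfg"))
  jsonlite::write_json(config[keep], tf, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

pipeline_log <- function(stage, ..., quiet = FALSE) {
  if (!quiet)
    message(sprintf("[dmiq:%s] %s", stage,
                    paste(sprintf("%s=%s", names(list(...)),
                                  unlist(list(...))),
                          collapse = " ")))
}

write_manifest <- function(out_dir, stage, config, extra = list()) {
  man <- c(list(stage = stage, package_version =
                  as.character(utils::packageVersion("dmiq")),
                seed = config$seed, config_hash = config_hash(config),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate a scenario to disk
#'
#' Scenarios: a subtype preset name (single-voxel dynamic series) or
#' `"csi_two_region"` (9 x 9 x 3 CSI phantom, glycolytic tumor in
#' tumor-free brain). Writes the dataset container, the ground-truth
#' curves as CSV, and a manifest recording seed, scenario and config
#' hash.
#'
#' @param scenario Scenario name.
#' @param out_dir Output directory (created).
#' @param config A [pipeline_config()].
#' @param quiet Suppress log lines.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(scenario, out_dir,
                         config = pipeline_config(), quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  pipeline_log("simulate", scenario = scenario, seed = config$seed,
               quiet = quiet)
  if (scenario == "csi_two_region") {
    ph <- csi_phantom(tumor = "glycolytic", brain = "tumor_free")
    csi <- simulate_csi_dataset(ph, config$acq, config$priors,
                                noise_sd = config$noise_sd,
                                seed = config$seed)
    write_csi(csi, file.path(out_dir, "csi"))
    tr <- simulate_timecourses(subtype_preset("glycolytic"))
    write_truth_csv(tr, file.path(out_dir, "truth_tumor.csv"))
    write_truth_csv(simulate_timecourses(subtype_preset("tumor_free")),
                    file.path(out_dir, "truth_brain.csv"))
    write_manifest(out_dir, "simulate", config,
                   list(scenario = scenario, kind = "csi"))
  } else {
    preset <- subtype_preset(scenario)
    tr <- simulate_timecourses(preset, seed = config$seed)
    series <- simulate_dynamic_series(tr, config$acq, config$priors,
                                      noise_sd = config$noise_sd,
                                      seed = config$seed)
    write_series(series, file.path(out_dir, "series"))
    write_truth_csv(tr, file.path(out_dir, "truth.csv"))
    write_manifest(out_dir, "simulate", config,
                   list(scenario = scenario, kind = "series",
                        preset_label = preset$label))
  }
  invisible(out_dir)
}

#' Fit and quantify a dynamic series container
#'
#' Reads a series container, fits every frame, quantifies against the
#' baseline water signal, and writes `fits.csv`,
#' `concentrations.csv`, `kinetics.csv` and a manifest.
#'
#' @param in_dir Directory holding a `series` container (or the
#'   container itself).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param quiet Suppress log lines.
#' @return The `dmi_timecourse`, invisibly.
#' @export
run_fit_quantify <- function(in_dir, out_dir,
                             config = pipeline_config(),
                             quiet = FALSE) {
  sdir <- if (file.exists(file.path(in_dir, "acquisition.json")))
    in_dir else file.path(in_dir, "series")
  series <- read_series(sdir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pipeline_log("fit_quantify", frames = ncol(series$fids),
               quiet = quiet)
  fits <- fit_series(series)
  n_fail <- sum(!vapply(fits$fits, function(f) f$converged,
                        logical(1)))
  if (n_fail > length(fits$fits) / 2)
    stop("run_fit_quantify: fit failed to converge on ", n_fail,
         " of ", length(fits$fits), " frames")
  tc <- quantify_series(fits, config = config$quant_cfg)
  export_fits_csv(fits, file.path(out_dir, "fits.csv"))
  write_timecourse_csv(tc, file.path(out_dir, "concentrations.csv"))
  ks <- kinetics_summary(tc, config$rate_window, config$avg_window)
  utils::write.csv(as.data.frame(ks), file.path(out_dir, "kinetics.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "fit_quantify", config,
                 list(n_frames = ncol(series$fids),
                      n_not_converged = n_fail))
  invisible(tc)
}

#' Reconstruct, denoise and map a CSI container
#'
#' Reads a k-space CSI container, reconstructs it, applies HOSVD
#' denoising at the configured ranks, computes metabolite maps over
#' the post-injection frames, and writes per-metabolite NIfTI volumes
#' plus `maps.csv` and a manifest.
#'
#' @param in_dir Directory holding a `csi` container (or the
#'   container itself).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param denoise Apply tensor denoising.
#' @param quiet Suppress log lines.
#' @return The `dmi_maps`, invisibly.
#' @export
run_csi <- function(in_dir, out_dir, config = pipeline_config(),
                    denoise = TRUE, quiet = FALSE) {
  cdir <- if (file.exists(file.path(in_dir, "geometry.json")))
    in_dir else file.path(in_dir, "csi")
  csi <- read_csi(cdir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vox <- csi_reconstruct(csi)
  ranks <- pmin(config$denoise_ranks, dim(vox$data))
  if (denoise) vox <- tensor_denoise(vox, ranks)
  pipeline_log("csi", matrix = paste(dim(csi$data)[1:3], collapse = "x"),
               denoise = denoise, quiet = quiet)
  maps <- metabolite_maps(vox, config$quant_cfg)
  for (m in names(maps$maps))
    write_map_nifti(maps, m, file.path(out_dir,
                                       paste0("map_", m, ".nii.gz")))
  d <- dim(vox$data)
  idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                     k = seq_len(d[3]))
  rows <- do.call(rbind, lapply(names(maps$maps), function(m)
    data.frame(idx, metabolite = m,
               mmol_per_l = as.vector(maps$maps[[m]]),
               converged = as.vector(maps$converged))))
  utils::write.csv(rows, file.path(out_dir, "maps.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "csi", config,
                 list(denoised = denoise,
                      ranks = if (denoise) ranks else NULL))
  invisible(maps)
}

#' Paired pre/post treatment-response report
#'
#' Reads two CSV tables (one row per animal, one column per
#' metabolite; matched rows), runs [response_analysis()], and writes a
#' JSON report with per-metabolite pre/post means, percent change and
#' paired-t results.
#'
#' @param pre_csv,post_csv Input CSV paths.
#' @param out_file Output JSON path.
#' @param quiet Suppress log lines.
#' @return The `dmi_response`, invisibly.
#' @export
run_respond <- function(pre_csv, post_csv, out_file, quiet = FALSE) {
  pre <- utils::read.csv(pre_csv)
  post <- utils::read.csv(post_csv)
  res <- response_analysis(pre, post)
  pipeline_log("respond", metabolites = nrow(res), n = res$n[1],
               quiet = quiet)
  out <- lapply(seq_len(nrow(res)), function(i) list(
    metabolite = res$metabolite[i], pre = res$pre_mean[i],
    post = res$post_mean[i], pct_change = res$pct_change[i],
    pct_change_display = round(res$pct_change[i]),
    t = res$t[i], p = res$p[i], n = res$n[i]))
  jsonlite::write_json(out, out_file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(res)
}
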