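## Plain-text on-disk containers. A dataset is a directory holding a
## JSON header (acquisition/geometry/priors/provenance) next to CSV
## payload tables of complex samples — the same logical schema as a
## hierarchical (group/attribute) container, in a text carrier.

acq_to_list <- function(acq) unclass(acq)

acq_from_list <- function(x) do.call(dmi_acq, x)

priors_to_list <- function(priors) as.data.frame(priors)

priors_from_list <- function(x) {
  tab <- as.data.frame(x, stringsAsFactors = FALSE)
  class(tab) <- c("dmi_priors", "data.frame")
  tab
}

#' Write a dynamic FID series container
#'
#' Creates directory `path` with `acquisition.json` (acquisition
#' parameters, resonance priors, frame times, provenance) and
#' `fids.csv` (`frame, start_time_min, point, re, im`).
#'
#' @param series A `dmi_series`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dmi_series"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(container = "dmi_series", version = 1L,
              acquisition = acq_to_list(series$acq),
              priors = priors_to_list(series$priors),
              start_time_min = series$start_time_min,
              frame_duration_min = series$frame_duration_min,
              noise_sd = series$noise_sd, seed = series$seed,
              subtype = series$subtype)
  jsonlite::write_json(hdr, file.path(path, "acquisition.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  nf <- ncol(series$fids); np <- nrow(series$fids)
  utils::write.csv(data.frame(
    frame = rep(seq_len(nf), each = np),
    start_time_min = rep(series$start_time_min, each = np),
    point = rep(seq_len(np), nf),
    re = as.vector(Re(series$fids)),
    im = as.vector(Im(series$fids))),
    file.path(path, "fids.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a dynamic FID series container
#'
#' @param path Directory written by [write_series()].
#' @return A `dmi_series`.
#' @export
read_series <- function(path) {
  hf <- file.path(path, "acquisition.json")
  if (!file.exists(hf))
    stop("read_series: container is missing 'acquisition.json' (",
         path, ")")
  df <- file.path(path, "fids.csv")
  if (!file.exists(df))
    stop("read_series: container is missing 'fids.csv' (", path, ")")
  hdr <- jsonlite::read_json(hf, simplifyVector = TRUE)
  d <- utils::read.csv(df)
  acq <- acq_from_list(hdr$acquisition)
  nf <- length(hdr$start_time_min)
  fids <- matrix(complex(real = d$re, imaginary = d$im),
                 acq$n_points, nf)
  structure(list(fids = fids, start_time_min = hdr$start_time_min,
                 frame_duration_min = hdr$frame_duration_min,
                 acq = acq, priors = priors_from_list(hdr$priors),
                 noise_sd = hdr$noise_sd, seed = hdr$seed,
                 subtype = hdr$subtype),
            class = "dmi_series")
}

#' Write a CSI dataset container
#'
#' Creates directory `path` with `geometry.json` (geometry, domain
#' tag, acquisition, priors, provenance) and `data.csv`
#' (`i, j, k, point, frame, re, im`; spatial indices 1-based with
#' voxel/encode (1,1,1) at the most negative corner).
#'
#' @param csi A `dmi_csi`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_csi <- function(csi, path) {
  stopifnot(inherits(csi, "dmi_csi"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(container = "dmi_csi", version = 1L, domain = csi$domain,
              geometry = csi$geometry,
              acquisition = acq_to_list(csi$acq),
              priors = priors_to_list(csi$priors),
              noise_sd = csi$noise_sd, seed = csi$seed)
  jsonlite::write_json(hdr, file.path(path, "geometry.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  d <- dim(csi$data)
  idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                     k = seq_len(d[3]), point = seq_len(d[4]),
                     frame = seq_len(d[5]))
  idx$re <- as.vector(Re(csi$data))
  idx$im <- as.vector(Im(csi$data))
  utils::write.csv(idx, file.path(path, "data.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a CSI dataset container
#'
#' @param path Directory written by [write_csi()].
#' @return A `dmi_csi`.
#' @export
read_csi <- function(path) {
  hf <- file.path(path, "geometry.json")
  if (!file.exists(hf))
    stop("read_csi: container is missing 'geometry.json' (", path, ")")
  df <- file.path(path, "data.csv")
  if (!file.exists(df))
    stop("read_csi: container is missing 'data.csv' (", path, ")")
  hdr <- jsonlite::read_json(hf, simplifyVector = TRUE)
  d <- utils::read.csv(df)
  g <- hdr$geometry
  ms <- as.integer(g$matrix_size)
  np <- max(d$point); nf <- max(d$frame)
  arr <- array(complex(real = d$re, imaginary = d$im),
               c(ms, np, nf))
  structure(list(data = arr, domain = hdr$domain,
                 geometry = list(fov_mm = g$fov_mm, matrix_size = ms,
                                 voxel_size_mm = g$voxel_size_mm,
                                 frame_start_min = g$frame_start_min,
                                 frame_duration_min =
                                   g$frame_duration_min),
                 acq = acq_from_list(hdr$acquisition),
                 priors = priors_from_list(hdr$priors),
                 noise_sd = hdr$noise_sd, seed = hdr$seed),
            class = "dmi_csi")
}
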