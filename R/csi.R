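#' Reconstruct phase-encoded CSI k-space into voxel spectra
#'
#' Inverse centered unitary 3-D discrete Fourier transform along the
#' three phase-encode modes, frame by frame and FID point by FID
#' point. The unitary scaling makes reconstruction energy-preserving
#' (Parseval), and k-space/image origins sit at the central index of
#' each axis, so a uniform k-space reconstructs to the central voxel.
#'
#' @param csi A `dmi_csi` with `domain = "kspace"`.
#' @return The `dmi_csi` in the voxel domain.
#' @export
csi_reconstruct <- function(csi) {
  stopifnot(inherits(csi, "dmi_csi"))
  if (csi$domain != "kspace")
    stop("csi_reconstruct: expected k-space data, got domain '",
         csi$domain, "'")
  csi$data <- spatial_dft5(csi$data, inverse = TRUE)
  csi$domain <- "voxel"
  csi
}

#' Forward phase-encode a voxel-domain CSI dataset
#'
#' Exact inverse of [csi_reconstruct()] (centered unitary 3-D DFT of
#' the spatial modes).
#'
#' @param csi A `dmi_csi` with `domain = "voxel"`.
#' @return The `dmi_csi` in k-space.
#' @export
csi_forward <- function(csi) {
  stopifnot(inherits(csi, "dmi_csi"))
  if (csi$domain != "voxel")
    stop("csi_forward: expected voxel-domain data, got domain '",
         csi$domain, "'")
  csi$data <- spatial_dft5(csi$data, inverse = FALSE)
  csi$domain <- "kspace"
  csi
}

## Mode-n unfolding: mode-n fibers as columns of a (d_n x prod(d_-n))
## matrix, remaining modes in ascending order.
unfold <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(x, perm), nrow = d[mode])
}

## Mode-n product with matrix U (r x d_n).
ttm <- function(x, u, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(seq_along(d), mode))
  m <- u %*% matrix(aperm(x, perm), nrow = d[mode])
  d_new <- d; d_new[mode] <- nrow(u)
  aperm(array(m, c(nrow(u), d_new[-mode])), order(perm))
}

#' Truncated higher-order SVD of a complex array
#'
#' Single-pass HOSVD: for each mode, the left singular vectors of the
#' mode unfolding are computed and truncated to the requested
#' multilinear rank; the core is formed by projecting onto all factor
#' bases and the array re-expanded. Optionally a few HOOI (alternating
#' least squares) refinement sweeps can follow.
#'
#' @param x Numeric or complex array with at least 2 modes.
#' @param ranks Integer vector, one rank per mode, each in
#'   `[1, dim]`.
#' @param hooi_sweeps Number of HOOI refinement sweeps (0 = plain
#'   truncated HOSVD, the default).
#' @return Array of the same shape; attributes `"energy_loss"`
#'   (squared Frobenius norm of the discarded part) and
#'   `"discarded_energy_bound"` (sum over modes of the discarded
#'   singular-value energies, an upper bound on the truncation error).
#' @export
hosvd_truncate <- function(x, ranks, hooi_sweeps = 0) {
  d <- dim(x)
  stopifnot(!is.null(d), length(ranks) == length(d))
  ranks <- as.integer(ranks)
  if (any(ranks < 1) || any(ranks > d))
    stop("hosvd_truncate: ranks must satisfy 1 <= rank <= mode size")
  factors <- vector("list", length(d))
  bound <- 0
  for (n in seq_along(d)) {
    s <- svd(unfold(x, n), nu = d[n], nv = 0)
    factors[[n]] <- s$u[, seq_len(ranks[n]), drop = FALSE]
    if (ranks[n] < length(s$d))
      bound <- bound + sum(s$d[(ranks[n] + 1):length(s$d)]^2)
  }
  for (sweep in seq_len(hooi_sweeps)) {
    for (n in seq_along(d)) {
      y <- x
      for (k in setdiff(seq_along(d), n))
        y <- ttm(y, Conj(t(factors[[k]])), k)
      s <- svd(unfold(y, n), nu = min(d[n], ranks[n]), nv = 0)
      factors[[n]] <- s$u[, seq_len(ranks[n]), drop = FALSE]
    }
  }
  core <- x
  for (n in seq_along(d)) core <- ttm(core, Conj(t(factors[[n]])), n)
  xhat <- core
  for (n in seq_along(d)) xhat <- ttm(xhat, factors[[n]], n)
  structure(xhat,
            energy_loss = sum(Mod(x - xhat)^2),
            discarded_energy_bound = bound)
}

#' Multilinear low-rank denoising of a dynamic CSI dataset
#'
#' Truncates the 5-mode array (x, y, z, FID point, frame) to the given
#' multilinear ranks by [hosvd_truncate()]. The default ranks
#' `c(6, 6, 3, 24, 5)` reduce a 9 x 9 x 3 x 256 x 7 dataset along
#' every compressible mode while retaining the spatial, spectral and
#' temporal structure of the metabolite signals; noise, which is full
#' rank, is largely discarded. Applied in the voxel domain after
#' reconstruction (the spatial modes are equivalent under the unitary
#' DFT).
#'
#' @param csi A `dmi_csi` (either domain; denoising the voxel domain
#'   is the package convention).
#' @param ranks Integer length-5 multilinear rank.
#' @param hooi_sweeps HOOI refinement sweeps (see
#'   [hosvd_truncate()]).
#' @return The denoised `dmi_csi`; truncation diagnostics in
#'   attributes `"energy_loss"` and `"discarded_energy_bound"` of the
#'   returned object's `$data`.
#' @export
tensor_denoise <- function(csi, ranks = c(6, 6, 3, 24, 5),
                           hooi_sweeps = 0) {
  stopifnot(inherits(csi, "dmi_csi"))
  csi$data <- hosvd_truncate(csi$data, ranks, hooi_sweeps)
  csi$denoise_ranks <- as.integer(ranks)
  csi
}

#' Extract a voxel (or voxel-mask sum) as a dynamic series
#'
#' Returns the per-frame FIDs of one voxel, or the complex sum over a
#' logical mask of voxels, as a `dmi_series` ready for [fit_series()]
#' and [quantify_series()].
#'
#' @param csi A voxel-domain `dmi_csi`.
#' @param index Integer length-3 voxel index (1-based), or `NULL` when
#'   `mask` is given.
#' @param mask Logical array of the spatial grid shape.
#' @return A `dmi_series`.
#' @export
extract_voxel <- function(csi, index = NULL, mask = NULL) {
  stopifnot(inherits(csi, "dmi_csi"))
  if (csi$domain != "voxel")
    stop("extract_voxel: reconstruct to the voxel domain first")
  d <- dim(csi$data)
  if (is.null(mask)) {
    stopifnot(length(index) == 3)
    if (any(index < 1) || any(index > d[1:3]))
      stop("extract_voxel: voxel index out of grid")
    fids <- csi$data[index[1], index[2], index[3], , ]
  } else {
    stopifnot(identical(dim(mask), d[1:3]))
    fids <- apply(csi$data, c(4, 5), function(v) sum(v[mask]))
  }
  fids <- matrix(as.complex(fids), d[4], d[5])
  g <- csi$geometry
  structure(list(fids = fids, start_time_min = g$frame_start_min,
                 frame_duration_min = g$frame_duration_min,
                 acq = csi$acq, priors = csi$priors,
                 noise_sd = csi$noise_sd, seed = csi$seed,
                 provenance = list(voxel = index,
                                   voxel_size_mm = g$voxel_size_mm)),
            class = "dmi_series")
}

#' Fit and quantify every voxel into metabolite concentration maps
#'
#' Per voxel: the baseline frame is fitted to obtain the water
#' reference area; the post-injection frames inside `window` (frame
#' start times, minutes from injection) are summed, fitted, and the
#' areas (divided by the number of summed frames, so they represent a
#' frame average) converted to concentrations with
#' [concentration_from_areas()]. Voxels whose fits fail are marked
#' missing (`NA`), not fatal; all-zero voxels quantify to zero.
#'
#' @param csi A voxel-domain `dmi_csi`.
#' @param config A [quant_config()].
#' @param window Length-2 window of frame start times, min; default
#'   all post-injection frames.
#' @param baseline_index Baseline frame index.
#' @param fit_cfg A [fit_config()].
#' @return A `dmi_maps`: list with `maps` (named list of 3-D arrays,
#'   mmol/L), `converged` (logical array), geometry, and the summed
#'   window used.
#' @export
metabolite_maps <- function(csi, config = quant_config(),
                            window = c(0, Inf), baseline_index = 1,
                            fit_cfg = fit_config()) {
  stopifnot(inherits(csi, "dmi_csi"))
  if (csi$domain != "voxel")
    stop("metabolite_maps: reconstruct to the voxel domain first")
  d <- dim(csi$data)
  g <- csi$geometry
  in_win <- g$frame_start_min >= window[1] &
    g$frame_start_min < window[2] & g$frame_start_min >= 0
  if (!any(in_win)) stop("metabolite_maps: empty frame window")
  n_sum <- sum(in_win)
  mets <- csi$priors$name
  maps <- lapply(mets, function(m) array(NA_real_, d[1:3]))
  names(maps) <- mets
  converged <- array(FALSE, d[1:3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (k in seq_len(d[3])) {
      base_fid <- csi$data[i, j, k, , baseline_index]
      sum_fid <- rowSums(matrix(csi$data[i, j, k, , in_win],
                                nrow = d[4]))
      if (all(Mod(base_fid) == 0) && all(Mod(sum_fid) == 0)) {
        for (m in mets) maps[[m]][i, j, k] <- 0
        converged[i, j, k] <- TRUE
        next
      }
      res <- tryCatch({
        bfit <- fit_resonances(base_fid, csi$priors, csi$acq, fit_cfg)
        w_area <- bfit$coefficients$area[
          bfit$coefficients$resonance == "water"]
        sfit <- fit_resonances(sum_fid, csi$priors, csi$acq, fit_cfg)
        sfit$coefficients$area <- sfit$coefficients$area / n_sum
        conc <- concentration_from_areas(sfit, w_area, config)
        list(conc = conc, ok = bfit$converged && sfit$converged)
      }, error = function(e) NULL)
      if (is.null(res)) next
      for (m in mets) maps[[m]][i, j, k] <- res$conc[[m]]
      converged[i, j, k] <- res$ok
    }
  structure(list(maps = maps, converged = converged, geometry = g,
                 window = window, n_summed_frames = n_sum),
            class = "dmi_maps")
}

#' @export
print.dmi_maps <- function(x, ...) {
  cat(sprintf("metabolite maps (%s grid, %d summed frames):\n",
              paste(x$geometry$matrix_size, collapse = "x"),
              x$n_summed_frames))
  for (m in names(x$maps))
    cat(sprintf("  %-8s mean %.3f mmol/L (max %.3f)\n", m,
                mean(x$maps[[m]], na.rm = TRUE),
                max(x$maps[[m]], na.rm = TRUE)))
  invisible(x)
}

#' Write a concentration map as a NIfTI volume
#'
#' Axis order (x, y, z) with voxel (1,1,1) at the most negative corner
#' of the field of view; voxel dimensions from the CSI geometry are
#' stored in the NIfTI header.
#'
#' @param maps A `dmi_maps`.
#' @param metabolite Which map to write.
#' @param file Output path (`.nii` / `.nii.gz`).
#' @export
write_map_nifti <- function(maps, metabolite, file) {
  stopifnot(inherits(maps, "dmi_maps"),
            metabolite %in% names(maps$maps))
  arr <- maps$maps[[metabolite]]
  arr[is.na(arr)] <- 0
  vs <- maps$geometry$voxel_size_mm
  img <- RNifti::asNifti(arr, pixdim = vs)
  RNifti::writeNifti(img, file)
  invisible(file)
}
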