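pr <- dmi_priors()
acq128 <- dmi_acq(n_points = 128)

small_csi <- function(tumor = "glycolytic", noise_sd = 0, seed = NULL,
                      n_frames = 5) {
  ph <- csi_phantom(matrix_size = c(5, 5, 1), fov_mm = c(27, 27, 9),
                    tumor = tumor)
  simulate_csi_dataset(ph, acq128, pr, noise_sd = noise_sd,
                       seed = seed, n_frames = n_frames,
                       frame_duration_min = 10)
}

test_that("spatial encode/reconstruct is a unitary inverse pair", {
  set.seed(2)
  csi <- small_csi(noise_sd = 0.4, seed = 2)
  vox <- csi_reconstruct(csi)
  # energy preserved (Parseval)
  expect_equal(sum(Mod(vox$data)^2), sum(Mod(csi$data)^2),
               tolerance = 1e-10)
  # round trip
  back <- csi_forward(vox)
  expect_equal(back$data, csi$data, tolerance = 1e-8)
  expect_error(csi_reconstruct(vox), "k-space")
  expect_error(csi_forward(csi), "voxel")
  # noiseless phantom reconstructs the regional FIDs exactly
  clean <- csi_reconstruct(small_csi(noise_sd = 0))
  ph <- clean$phantom
  tu <- which(ph$tumor_mask, arr.ind = TRUE)[1, ]
  truth <- synthesize_fid(vapply(
    dmiq:::truth_curves(ph$tumor), dmiq:::frame_average, numeric(1),
    t0 = 30, t1 = 40), pr, acq128)
  got <- clean$data[tu[1], tu[2], tu[3], , 5]
  expect_equal(got, truth, tolerance = 1e-8)
})

test_that("uniform k-space reconstructs to the single central voxel", {
  arr <- array(0i, c(5, 5, 3, 4, 1))
  arr[, , , , ] <- 1 + 0i
  csi <- structure(list(
    data = arr, domain = "kspace",
    geometry = list(fov_mm = c(27, 27, 27), matrix_size = c(5, 5, 3),
                    voxel_size_mm = c(5.4, 5.4, 9),
                    frame_start_min = 0, frame_duration_min = 10),
    acq = dmi_acq(n_points = 4), priors = pr), class = "dmi_csi")
  vox <- csi_reconstruct(csi)
  mag <- Mod(vox$data[, , , 1, 1])
  pk <- which(mag == max(mag), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(3, 3, 2))
  expect_lt(sum(mag > 1e-9), 2)
})

test_that("HOSVD truncation matches brute-force unfolding SVD oracles", {
  set.seed(5)
  x <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  # full ranks: identity
  expect_equal(hosvd_truncate(x, c(4, 5, 6)), x, tolerance = 1e-10,
               ignore_attr = TRUE)
  # mode-1 truncation vs an independent brute-force projector
  r <- 2
  xr <- hosvd_truncate(x, c(r, 5, 6))
  u <- svd(matrix(aperm(x, c(1, 2, 3)), nrow = 4))$u[, 1:r]
  oracle <- array((u %*% t(u)) %*% matrix(x, nrow = 4), dim(x))
  expect_equal(xr, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  # exactly low-multilinear-rank tensor is reproduced
  set.seed(6)
  core <- array(rnorm(2 * 2 * 1 * 3 * 2), c(2, 2, 1, 3, 2))
  fac <- list(matrix(rnorm(12), 6, 2), matrix(rnorm(10), 5, 2),
              matrix(rnorm(4), 4, 1), matrix(rnorm(21), 7, 3),
              matrix(rnorm(6), 3, 2))
  y <- core
  for (n in 1:5) y <- dmiq:::ttm(y, fac[[n]], n)
  yr <- hosvd_truncate(y, c(2, 2, 1, 3, 2))
  expect_equal(yr, y, tolerance = 1e-8, ignore_attr = TRUE)
  # truncation error bounded by the discarded singular energies
  xr2 <- hosvd_truncate(x, c(2, 3, 4))
  expect_lte(attr(xr2, "energy_loss"),
             attr(xr2, "discarded_energy_bound") + 1e-12)
  # complex input round trip at full rank
  z <- array(complex(real = rnorm(24), imaginary = rnorm(24)),
             c(2, 3, 4))
  expect_equal(hosvd_truncate(z, c(2, 3, 4)), z, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(hosvd_truncate(x, c(5, 5, 6)), "rank")
})

test_that("voxel extraction is linear and feeds the fit chain exactly", {
  vox <- csi_reconstruct(small_csi(noise_sd = 0))
  ph <- vox$phantom
  tu <- which(ph$tumor_mask, arr.ind = TRUE)
  s1 <- extract_voxel(vox, index = tu[1, ])
  m1 <- array(FALSE, dim(ph$tumor_mask)); m1[t(tu[1, , drop = TRUE])] <- TRUE
  s1m <- extract_voxel(vox, mask = m1)
  expect_equal(s1m$fids, s1$fids, tolerance = 1e-12)
  # disjoint-mask additivity
  m2 <- array(FALSE, dim(ph$tumor_mask)); m2[t(tu[2, , drop = TRUE])] <- TRUE
  s2 <- extract_voxel(vox, mask = m2)
  s12 <- extract_voxel(vox, mask = m1 | m2)
  expect_equal(s12$fids, s1$fids + s2$fids, tolerance = 1e-12)
  expect_error(extract_voxel(vox, index = c(9, 9, 9)), "out of grid")
  # end-to-end: noiseless tumor voxel recovers the region truth < 1%
  tc <- quantify_series(fit_series(s1))
  cv <- dmiq:::truth_curves(ph$tumor)
  for (m in c("glucose", "glx", "lactate")) {
    est <- tc$mmol_per_l[tc$metabolite == m]
    tru <- vapply(s1$start_time_min, function(t0)
      dmiq:::frame_average(cv[[m]], t0, t0 + 10), numeric(1))
    nz <- tru > 1e-6
    expect_lt(max(abs(est[nz] - tru[nz]) / tru[nz]), 0.01)
  }
})

test_that("metabolite maps separate tumor subtypes from brain", {
  for (subtype in c("glycolytic", "mitochondrial")) {
    vox <- csi_reconstruct(small_csi(tumor = subtype))
    maps <- metabolite_maps(vox)
    ph <- vox$phantom
    lac_t <- mean(maps$maps$lactate[ph$tumor_mask])
    lac_b <- mean(maps$maps$lactate[ph$brain_mask])
    glx_t <- mean(maps$maps$glx[ph$tumor_mask])
    glx_b <- mean(maps$maps$glx[ph$brain_mask])
    if (subtype == "glycolytic") {
      expect_gt(lac_t, lac_b)
    } else {
      expect_gt(glx_t, glx_b)
      expect_lt(abs(lac_t - lac_b), 0.25)  # lactate comparable to brain
    }
    expect_true(all(maps$converged))
  }
  # all-zero data quantifies to all-zero maps, flagged converged
  z <- csi_reconstruct(small_csi(noise_sd = 0))
  z$data[] <- 0i
  mz <- metabolite_maps(z)
  for (m in names(mz$maps)) expect_true(all(mz$maps[[m]] == 0))
  expect_true(all(mz$converged))
})

test_that("tensor denoising moves data toward truth and shrinks errors", {
  ranks <- c(3, 3, 1, 12, 3)
  clean <- csi_reconstruct(small_csi(noise_sd = 0))
  ph <- clean$phantom
  tu <- which(ph$tumor_mask, arr.ind = TRUE)
  lactate_se <- function(csi, v) {
    post <- csi$geometry$frame_start_min >= 0
    fid <- rowSums(matrix(csi$data[v[1], v[2], v[3], , post],
                          nrow = dim(csi$data)[4]))
    goodness_of_fit(fit_resonances(fid, pr, acq128))$se$se_area[4]
  }
  closer <- 0; se_better <- 0; se_total <- 0
  for (s in 1:20) {
    noisy <- csi_reconstruct(small_csi(noise_sd = 0.5,
                                       seed = 400 + s))
    den <- tensor_denoise(noisy, ranks)
    d_before <- sum(Mod(noisy$data - clean$data)^2)
    d_after <- sum(Mod(den$data - clean$data)^2)
    if (d_after <= d_before) closer <- closer + 1
    v <- tu[1 + (s %% nrow(tu)), ]
    se_n <- lactate_se(noisy, v)
    se_d <- lactate_se(den, v)
    if (!is.na(se_n) && !is.na(se_d)) {
      se_total <- se_total + 1
      if (se_d < se_n) se_better <- se_better + 1
    }
  }
  expect_equal(closer, 20)
  expect_gte(se_better / se_total, 0.9)
})
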