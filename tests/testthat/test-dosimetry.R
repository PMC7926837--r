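test_that("local deposition matches the hand unit-conversion oracle", {
  # 1 Bq.h/mL = 3600 decays/mL; 147.9 keV = 2.36938e-14 J;
  # 1 mL tissue = 1e-3 kg  =>  D = 3600 * 2.36938e-14 / 1e-3 Gy
  oracle <- 3600 * 147.9e3 * 1.602176634e-19 / 1e-3
  expect_equal(oracle, 8.529e-8, tolerance = 1e-4)
  for (vox in c(1.0, 1.95, 4.0)) {   # independent of voxel size
    tia <- structure(list(values = array(1, c(4, 4, 4)),
                          voxel_size_mm = rep(vox, 3), cycle_id = "c",
                          scheme = "given"), class = "tia_map")
    d <- dose_local_deposition(tia)
    expect_equal(d$values[1], oracle, tolerance = 1e-12)
  }
})

test_that("local deposition is linear and zero-preserving", {
  tia <- structure(list(values = array(stats::runif(64), c(4, 4, 4)),
                        voxel_size_mm = rep(1.95, 3), cycle_id = "c",
                        scheme = "given"), class = "tia_map")
  d1 <- dose_local_deposition(tia)
  tia2 <- tia; tia2$values <- 2 * tia$values
  expect_equal(dose_local_deposition(tia2)$values, 2 * d1$values)
  tia0 <- tia; tia0$values[] <- 0
  expect_true(all(dose_local_deposition(tia0)$values == 0))
  tneg <- tia; tneg$values[1] <- -1
  expect_error(dose_local_deposition(tneg), "negative")
})

test_that("delta-kernel convolution reproduces local deposition exactly", {
  ph <- build_phantom(sphere_spec(radius_mm = 8, fwhm = 4))
  tia <- tia_map_voxelwise(ph, "monoexp_global")
  d_local <- dose_local_deposition(tia)
  d_kern <- dose_kernel_convolution(tia, delta_kernel(tia$voxel_size_mm))
  rel <- max(abs(d_kern$values - d_local$values)) / max(d_local$values)
  expect_lt(rel, 1e-12)
})

test_that("uniform medium under periodic padding reaches equilibrium dose", {
  tia <- structure(list(values = array(100, c(12, 12, 12)),
                        voxel_size_mm = rep(1.95, 3), cycle_id = "c",
                        scheme = "given"), class = "tia_map")
  shape <- array(exp(-(outer(outer((-2:2)^2, (-2:2)^2, `+`),
                             (-2:2)^2, `+`)) / 4), c(5, 5, 5))
  kern <- normalized_kernel(shape, 1.95)
  d <- dose_kernel_convolution(tia, kern, periodic = TRUE)
  d_local <- dose_local_deposition(tia)
  expect_equal(d$values, d_local$values, tolerance = 1e-9)
})

test_that("kernel convolution spreads a point source but conserves energy", {
  kc <- lu177_constants()
  vals <- array(0, c(21, 21, 21)); vals[11, 11, 11] <- 1000
  tia <- structure(list(values = vals, voxel_size_mm = rep(1.95, 3),
                        cycle_id = "c", scheme = "given"),
                   class = "tia_map")
  shape <- array(1, c(3, 3, 3))
  kern <- normalized_kernel(shape, 1.95)
  d <- dose_kernel_convolution(tia, kern)
  expect_equal(sum(d$values > 0), 27L)
  mass_kg <- voxel_volume_ml(1.95) * 1e-3
  energy <- sum(d$values) * mass_kg
  decays <- 1000 * 3600 * voxel_volume_ml(1.95)
  expect_lt(abs(energy - decays * kc$delta_np_J) / (decays * kc$delta_np_J),
            1e-6)
})

test_that("kernel constructors validate shape and round-trip through CSV", {
  expect_error(dose_kernel(array(1, c(2, 3, 3)), 1.95), "odd")
  bad <- array(1, c(3, 3, 3)); bad[2, 2, 2] <- 0
  expect_error(dose_kernel(bad, 1.95), "centre")
  kern <- normalized_kernel(array(stats::runif(27) + 0.1, c(3, 3, 3)), 1.95)
  f <- tempfile(fileext = ".csv")
  write_dose_kernel(kern, f)
  kern2 <- read_dose_kernel(f)
  expect_equal(kern2$values, kern$values, tolerance = 1e-15)
  expect_equal(kern2$voxel_size_mm, kern$voxel_size_mm)
  # mismatched voxel size is rejected at convolution time
  tia <- structure(list(values = array(1, c(4, 4, 4)),
                        voxel_size_mm = rep(1.0, 3), cycle_id = "c",
                        scheme = "given"), class = "tia_map")
  expect_error(dose_kernel_convolution(tia, kern), "voxel size")
})

test_that("volume-ratio compensation follows its defining arithmetic", {
  expect_equal(eq1_pve_correct(3, 5, 5), 3)          # identity
  expect_equal(eq1_pve_correct(2, 4, 2), 4)          # direct arithmetic
  expect_error(eq1_pve_correct(2, 4, 0), "> 0")
  expect_warning(d <- eq1_pve_correct(2, 1, 2), "smaller")
  expect_equal(d, 1)
})

test_that("compensation pulls a blurred small sphere toward truth", {
  fwhm <- 10; sig <- fwhm / 2.3548
  sp <- phantom_spec(list(
    region_spec("les", "lesion", c(62.4, 62.4, 62.4), 3, 5e4,
                log(2) / 25)),
    psf_fwhm_mm = fwhm, seed = 3L)
  ph <- build_phantom(sp)
  tia <- tia_map_voxelwise(ph, "monoexp_global")
  dose <- dose_local_deposition(tia)
  truth <- ph$truth$mean_dose_Gy
  uncorrected <- mean(dose$values[ph$masks$les$mask])
  voi <- oracle_sphere_mask(c(64L, 64L, 64L), 1.95, rep(62.4, 3),
                            3 + 3.5 * sig)
  corrected <- eq1_pve_correct(mean(dose$values[voi]),
                               sum(voi) * voxel_volume_ml(1.95),
                               ph$masks$les$ct_volume_ml)
  expect_lt(abs(corrected - truth), abs(uncorrected - truth))
  expect_lt(abs(corrected - truth) / truth, 0.05)
})

test_that("MIRD self-dose matches its oracle and the voxel route", {
  # 1e12 decays, 147.9 keV/decay, 0.15 kg -> 0.158 Gy
  expect_equal(mird_self_dose(1e12, 0.15), 0.15796, tolerance = 1e-4)
  expect_equal(mird_self_dose(1e12, 0.075), 2 * mird_self_dose(1e12, 0.15))
  expect_error(mird_self_dose(1e12, 0), "> 0")

  # uniform unblurred organ: organ-level and voxel-level doses agree
  ph <- build_phantom(sphere_spec(radius_mm = 10, A0 = 3000,
                                  lambda = log(2) / 40, fwhm = 0,
                                  kind = "organ"))
  tia <- tia_map_regional(ph, ph$masks)
  dose <- dose_local_deposition(tia)
  mask <- ph$masks$s
  decays <- sum(tia$values[mask$mask]) * 3600 * voxel_volume_ml(1.95)
  mird <- mird_self_dose(decays, mask_volume_ml(mask) * 1e-3)
  expect_equal(mird, mean(dose$values[mask$mask]), tolerance = 1e-6)
})

test_that("dose normalisation by injected activity is a pure ratio", {
  expect_equal(dose_per_injected(38.33, 7395), 5.183, tolerance = 1e-3)
  expect_equal(dose_per_injected(1, 1000), 1)
  expect_equal(dose_per_injected(10, 2000), dose_per_injected(10, 1000) / 2)
})

test_that("organ dose report assembles consistent per-region rows", {
  ph <- build_phantom(sphere_spec(radius_mm = 8, A0 = 2000,
                                  lambda = log(2) / 30, fwhm = 0))
  tia <- tia_map_regional(ph, ph$masks)
  rep <- organ_dose_report(tia, ph$masks, injected_activity_MBq = 7395)
  expect_s3_class(rep, "organ_dose_report")
  expect_equal(rep$dose_Gy_per_GBq, rep$dose_Gy / 7.395)
  # small region with known CT volume: corrected = mean * voi/ct
  expect_equal(rep$corrected_dose_Gy,
               rep$mean_dose_Gy * rep$voi_volume_ml / rep$ct_volume_ml)
  # unblurred uniform region: dose equals ground truth
  expect_equal(rep$mean_dose_Gy, ph$truth$mean_dose_Gy, tolerance = 1e-9)
})

test_that("voxelwise and regional TIA agree on uniform-kinetics phantoms", {
  ph <- build_phantom(sphere_spec(radius_mm = 8, fwhm = 6))
  vox <- tia_map_voxelwise(ph, "monoexp_global")
  reg <- tia_map_regional(ph, ph$masks, scheme = "monoexp_global")
  mask <- ph$masks$s$mask
  # same total decays attributed to the region's own voxels
  expect_equal(mean(vox$values[mask]) /
                 mean(ph$maps[[1]]$values[mask] /
                        exp(-log(2) / 24 * 4) / (log(2) / 24)),
               1, tolerance = 1e-6)
  expect_equal(reg$values[mask][1],
               time_integrated_activity(extract_tac(ph, ph$masks$s),
                                        "monoexp_global"))
})
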