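whole_grid_roi <- function(grid) {
  roi_set(scalar_volume(array(1, grid$shape), grid, "dimensionless"),
          c(everything = 1L))
}

test_that("SUV is 1 for a uniform no-excretion distribution", {
  g <- voxel_grid(c(10, 10, 10), c(4, 4, 4))
  a0_mbq <- 9.88
  v_total_ml <- prod(g$shape) * voxel_volume_ml(g)
  meta <- study_meta(a0_mbq, subject_mass_kg = v_total_ml / 1000)  # 1 g/mL
  for (t in c(4, 24, 73)) {
    conc <- a0_mbq * 1e6 * decay_factor(zr89, t) / v_total_ml
    fr <- scalar_volume(array(conc, g$shape), g, "Bq/mL", timestamp = t)
    expect_equal(suv(fr, whole_grid_roi(g), "everything", meta, zr89), 1)
  }
})

test_that("SUV reduces to f * m / V for a fractional uptake ROI", {
  g <- voxel_grid(c(10, 10, 10), c(4, 4, 4))
  labels <- array(0, g$shape); labels[1:5, , ] <- 1
  rois <- roi_set(scalar_volume(labels, g, "dimensionless"), c(organ = 1L))
  f <- 0.23; mass_kg <- 11; a0_mbq <- 10; t <- 24
  v_ml <- sum(labels == 1) * voxel_volume_ml(g)
  conc <- a0_mbq * 1e6 * f * decay_factor(zr89, t) / v_ml
  vals <- array(0, g$shape); vals[labels == 1] <- conc
  fr <- scalar_volume(vals, g, "Bq/mL", timestamp = t)
  meta <- study_meta(a0_mbq, mass_kg)
  expect_equal(suv(fr, rois, "organ", meta, zr89),
               f * mass_kg * 1000 / v_ml, tolerance = 1e-12)
  # linear in subject mass
  meta2 <- study_meta(a0_mbq, 2 * mass_kg)
  expect_equal(suv(fr, rois, "organ", meta2, zr89),
               2 * suv(fr, rois, "organ", meta, zr89))
  # guards
  fr$timestamp <- NULL
  expect_error(suv(fr, rois, "organ", meta, zr89), "timestamp")
})

test_that("mass-weighted whole-body SUV is 1 for every frame of a sealed phantom", {
  cfg <- small_phantom_config()
  # seal the phantom: no biological clearance anywhere, density 1 everywhere
  cfg$organs <- lapply(cfg$organs, function(o) {
    o$pk$k_bio <- 0; o$density <- 1; o
  })
  cfg$body$pk$k_bio <- 0; cfg$body$density <- 1
  cfg$air_density <- 1e-9
  st <- build_phantom(cfg)
  ts <- roi_timeseries(st, zr89)
  vvox_ml <- voxel_volume_ml(st$grid)
  for (t in unique(ts$time_h)) {
    sl <- ts[ts$time_h == t, ]
    wb_suv <- sum(sl$suv * sl$n_voxels) / (st$meta$subject_mass_kg * 1000 /
                                           vvox_ml)
    expect_equal(wb_suv, 1, tolerance = 1e-6)
  }
})

test_that("whole-body recovery passes a faithful scan and flags a biased one", {
  st <- build_phantom(small_phantom_config())
  qc <- whole_body_recovery(st$frames[[1]], st$meta, zr89)
  expect_equal(qc$ratio, 1, tolerance = 1e-9)
  expect_true(qc$pass)

  biased <- st$frames[[1]]
  biased$values <- biased$values * 1.2
  qc2 <- whole_body_recovery(biased, st$meta, zr89)
  expect_false(qc2$pass)
  expect_equal(qc2$ratio, 1.2, tolerance = 1e-9)
  expect_warning(whole_body_recovery(st$frames[[1]], st$meta, zr89,
                                     excreted_fraction = 0.05),
                 "biased low")
})

test_that("default noisy phantom passes whole-body QC across seeds", {
  st <- build_phantom()
  for (s in c(1, 7, 20)) {
    noisy <- add_imaging_noise(st, seed = s)
    expect_true(whole_body_recovery(noisy$frames[[1]], noisy$meta, zr89)$pass)
  }
})

test_that("dose coefficients match the closed-form single-organ oracle within 1%", {
  cfg <- small_phantom_config()
  # retention-only kinetics: fast uptake, no biological clearance
  f <- 0.3; k_up <- 10
  cfg$organs <- list(organ_spec("organ", 2L,
                                list(type = "ellipsoid",
                                     center = c(96, 96, 170),
                                     radii = c(45, 40, 50)), 1.0,
                                pk_params(f, k_up, 0,
                                          c(urinary = 0, hepatobiliary = 1))))
  cfg$body$pk <- pk_params(1 - f, k_up, 0, c(urinary = 1, hepatobiliary = 0))
  st <- build_phantom(cfg)
  res <- study_dose_coefficients(st, zr89, lu177, method = "local")
  co <- res$coefficients
  n <- co$n_voxels[co$roi == "organ"]
  v_ml <- n * voxel_volume_ml(st$grid)
  k_gy <- charged_energy_per_decay(lu177) * 1000 * 3600  # Gy/h per Bq/mL, rho 1
  lam <- lu177$decay_constant
  oracle <- k_gy * 1e9 * f / v_ml * (1 / lam - 1 / (k_up + lam))
  expect_equal(co$gy_per_gbq[co$roi == "organ"], oracle, tolerance = 0.01)
})

test_that("dose coefficients are stable under voxel-resolution refinement", {
  c8 <- small_phantom_config()
  c4 <- small_phantom_config(grid = voxel_grid(c(48, 48, 80), c(4, 4, 4)))
  r8 <- study_dose_coefficients(build_phantom(c8), zr89, lu177,
                                method = "local")$coefficients
  r4 <- study_dose_coefficients(build_phantom(c4), zr89, lu177,
                                method = "local")$coefficients
  # holds for organs large against the voxel; thin structures (the 12 mm
  # spine cylinder at 8 mm spacing) are partial-volume limited
  for (roi in c("liver", "body")) {
    expect_equal(r8$gy_per_gbq[r8$roi == roi], r4$gy_per_gbq[r4$roi == roi],
                 tolerance = 0.02)
  }
})

test_that("dose coefficient table demands normalization provenance", {
  st <- build_phantom(small_phantom_config())
  maps <- lapply(st$frames, function(fr) {
    th <- substitute_isotope(fr, zr89, lu177)
    dose_rate_local(th, st$density, lu177)
  })
  dose <- integrate_dose(maps, lu177)
  expect_error(dose_coefficients(dose, st$labels), "normalization")
  dose$normalization <- "per_GBq"
  tab <- dose_coefficients(dose, st$labels)
  expect_true(all(tab$gy_per_gbq >= 0))
  expect_setequal(tab$roi, names(st$labels$names))
})

test_that("empty ROIs are rejected by name", {
  st <- build_phantom(small_phantom_config())
  res <- study_dose_coefficients(st, zr89, lu177, method = "local")
  rois <- st$labels
  rois$names <- c(rois$names, ghost = 99L)  # label absent from the volume
  expect_error(dose_coefficients(res$dose, rois, roi_names = "ghost"),
               "ghost")
})
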