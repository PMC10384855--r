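test_that("grid geometry: voxel volume and validation", {
  g <- voxel_grid(c(10, 10, 10), c(4, 4, 4))
  expect_equal(voxel_volume_ml(g), 0.064)
  expect_error(voxel_grid(c(0, 1, 1), c(1, 1, 1)), ">= 1")
  expect_error(voxel_grid(c(2, 2, 2), c(1, -1, 1)), "> 0")
})

test_that("scalar volumes enforce units, shape and non-negativity", {
  g <- voxel_grid(c(2, 2, 2), c(1, 1, 1))
  expect_error(scalar_volume(array(1, c(2, 2, 3)), g, "Gy"), "shape")
  bad <- array(1, c(2, 2, 2)); bad[1, 2, 1] <- -1
  expect_error(scalar_volume(bad, g, "Bq/mL"), "negative value")
  expect_error(scalar_volume(array(1, c(2, 2, 2)), g, "furlongs"))
  lab <- scalar_volume(array(-1, c(2, 2, 2)), g, "dimensionless")
  expect_s3_class(lab, "scalar_volume")  # dimensionless may be signed
})

test_that("NIfTI round trip preserves values to float32 and grid exactly", {
  v <- seeded_volume(42, shape = c(6, 7, 8), spacing = c(2, 3, 4))
  path <- file.path(tempdir(), "rt.nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(r$values, v$values, tolerance = 1e-6)
  expect_equal(r$grid$spacing, v$grid$spacing)
  expect_identical(r$grid$shape, v$grid$shape)
  expect_equal(r$units, "Bq/mL")
  expect_equal(r$timestamp, 2)
  expect_equal(r$nuclide, "Zr-89")
})

test_that("write rejects negative voxels naming the index; read demands sidecar", {
  g <- voxel_grid(c(3, 3, 3), c(1, 1, 1))
  vals <- array(1, c(3, 3, 3)); vals[2, 2, 2] <- 5
  v <- scalar_volume(vals, g, "Gy")
  v$values[14] <- -0.5  # mutate past the constructor
  expect_error(write_volume(v, tempfile(fileext = ".nii.gz")), "14")

  ok <- scalar_volume(array(1, c(3, 3, 3)), g, "Gy")
  p <- file.path(tempdir(), "nosc.nii.gz")
  write_volume(ok, p)
  file.remove(sidecar_path <- paste0(p, ".json"))
  expect_error(read_volume(p), "sidecar")
  expect_s3_class(read_volume(p, units = "Gy"), "scalar_volume")
})

test_that("label maps round trip as integers", {
  g <- voxel_grid(c(4, 4, 4), c(4, 4, 4))
  set.seed(1)
  lab <- scalar_volume(array(as.numeric(sample(0:3, 64, TRUE)), c(4, 4, 4)), g,
                       "dimensionless")
  p <- file.path(tempdir(), "lab.nii.gz")
  write_volume(lab, p)
  r <- read_volume(p)
  expect_identical(r$values, lab$values)
})

test_that("resampling to the same grid is the identity", {
  v <- seeded_volume(7)
  expect_identical(resample_to_reference(v, v$grid, "trilinear"), v)
})

test_that("nearest-neighbour resampling introduces no new labels", {
  g <- voxel_grid(c(12, 12, 12), c(4, 4, 4))
  set.seed(3)
  lab <- scalar_volume(array(sample(c(0, 2, 5), prod(g$shape), TRUE), g$shape),
                       g, "dimensionless")
  ref <- voxel_grid(c(7, 7, 7), c(7, 7, 7), origin = c(1, 1, 1))
  out <- resample_to_reference(lab, ref, "nearest")
  expect_true(all(unique(as.vector(out$values)) %in%
                  unique(as.vector(lab$values))))
  expect_error(resample_to_reference(lab, ref, "trilinear"), "nearest")
})

test_that("trilinear downsampling keeps a uniform field uniform in the interior", {
  g <- voxel_grid(c(16, 16, 16), c(4, 4, 4))
  v <- scalar_volume(array(1, g$shape), g, "Bq/mL", timestamp = 1)
  ref <- voxel_grid(c(8, 8, 8), c(8, 8, 8))
  out <- resample_to_reference(v, ref, "trilinear")
  interior <- out$values[2:7, 2:7, 2:7]
  expect_equal(as.vector(interior), rep(1, length(interior)))
})

test_that("trilinear resampling conserves total activity for interior-supported fields", {
  g <- voxel_grid(c(16, 16, 16), c(4, 4, 4))
  vals <- array(0, g$shape)
  set.seed(5)
  vals[5:12, 5:12, 5:12] <- runif(512)
  vals <- voxdose:::gaussian_blur_3d(vals, c(1, 1, 1))
  v <- scalar_volume(vals, g, "Bq/mL", timestamp = 1)
  ref <- voxel_grid(c(8, 8, 8), c(8, 8, 8))
  out <- resample_to_reference(v, ref, "trilinear")
  tot_in <- sum(v$values) * voxel_volume_ml(g)
  tot_out <- sum(out$values) * voxel_volume_ml(ref)
  expect_equal(tot_out, tot_in, tolerance = 0.01)
})

test_that("study manifests round trip and validate frame ordering", {
  st <- build_phantom(small_phantom_config())
  dir <- file.path(tempdir(), "study_rt")
  manifest <- write_study(st, dir)
  rt <- read_manifest(manifest)
  expect_equal(rt$meta$injected_activity_mbq, st$meta$injected_activity_mbq)
  expect_equal(rt$meta$subject_mass_kg, st$meta$subject_mass_kg, tolerance = 1e-6)
  expect_equal(length(rt$frames), length(st$frames))
  expect_equal(vapply(rt$frames, `[[`, numeric(1), "timestamp"),
               vapply(st$frames, `[[`, numeric(1), "timestamp"))
  expect_equal(rt$frames[[2]]$values, st$frames[[2]]$values, tolerance = 1e-6)
  expect_equal(sort(names(rt$labels$names)), sort(names(st$labels$names)))

  # corrupt the frame ordering
  m <- jsonlite::fromJSON(manifest, simplifyVector = FALSE)
  m$frames[[2]]$time_h <- m$frames[[1]]$time_h
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(m, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_manifest(bad), "strictly increasing.*1 and 2")

  m$frames[[2]]$time_h <- 24
  m$injected_activity_mbq <- NULL
  jsonlite::write_json(m, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_manifest(bad), "injected_activity")
})

test_that("default phantom manifest lists four frames at the canonical schedule", {
  cfg <- default_phantom_config()
  expect_equal(cfg$scan_times_h, c(4, 24, 48, 73))
  st <- build_phantom(small_phantom_config())
  dir <- file.path(tempdir(), "study_sched")
  m <- jsonlite::fromJSON(write_study(st, dir))
  expect_equal(vapply(m$frames$time_h, identity, numeric(1)), c(4, 24, 48, 73))
})

test_that("pipeline stages refuse unit-mismatched volumes", {
  act <- uniform_volume(1, units = "Bq/mL", timestamp = 1)
  den <- water_density()
  expect_error(dose_rate_local(den, den, lu177), "Bq/mL")
  expect_error(dose_rate_local(act, act, lu177), "g/cm")
  expect_error(integrate_dose(list(act), lu177), "Gy/h")
  expect_error(suv(den, NULL, "x", NULL, zr89), "Bq/mL")
  dose_like <- uniform_volume(1, units = "Gy/h", timestamp = 1)
  expect_error(substitute_isotope(dose_like, zr89, lu177), "Bq/mL")
})
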