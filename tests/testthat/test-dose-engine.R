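test_that("local deposition matches the hand unit-conversion oracle", {
  act <- uniform_volume(1e6)   # 1 MBq/mL
  den <- water_density()
  m <- dose_rate_local(act, den, lu177)
  # 2.3696e-14 J/decay * 1e6 Bq/mL in water: 2.370e-5 Gy/s = 0.08531 Gy/h
  expect_equal(m$values[1], 0.08530629, tolerance = 1e-6)
  expect_true(all(m$values == m$values[1]))
  expect_identical(m$method, "local")
})

test_that("local deposition is linear in activity and inverse in density", {
  act <- seeded_volume(21, shape = c(6, 6, 6))
  den <- water_density(shape = c(6, 6, 6))
  m1 <- dose_rate_local(act, den, lu177)
  act2 <- scalar_volume(act$values * 2, act$grid, "Bq/mL", timestamp = 1)
  expect_equal(dose_rate_local(act2, den, lu177)$values, 2 * m1$values)
  den2 <- scalar_volume(den$values / 2, den$grid, "g/cm^3")
  expect_equal(dose_rate_local(act, den2, lu177)$values, 2 * m1$values)
  expect_equal(dose_rate_local(scalar_volume(act$values * 0, act$grid, "Bq/mL",
                                             timestamp = 1),
                               den, lu177)$values, array(0, c(6, 6, 6)))
})

test_that("dose engines reject inconsistent geometry and density", {
  act <- uniform_volume(1)
  den_bad <- water_density(shape = c(4, 4, 4))
  expect_error(dose_rate_local(act, den_bad, lu177), "different grids")
  den0 <- water_density()
  den0$values[1, 1, 1] <- 0
  expect_error(dose_rate_local(act, den0, lu177), "zero density")
})

test_that("kernel method reduces to local deposition for photon-free nuclides", {
  act <- seeded_volume(4, shape = c(8, 8, 8))
  den <- water_density()
  k <- photon_kernel(lu_charged_only, c(4, 4, 4), truncation_cm = 10)
  out <- dose_rate_kernel(act, den, lu_charged_only, k)
  loc <- dose_rate_local(act, den, lu_charged_only)
  expect_equal(out$values, loc$values)
  expect_equal(out$escape_fraction, 0)
  expect_error(dose_rate_kernel(act, den, lu177, k), "built for")
})

test_that("kernel energy balance: deposited + escaped equals emitted within 1%", {
  k <- lu_kernel_4mm()
  # kernel discretization: total tabulated energy vs analytic within-truncation
  lines <- data.frame(e = c(208.4, 112.9), y = c(0.104, 0.062))
  within_j <- sum(vapply(seq_len(nrow(lines)), function(i) {
    mu <- water_mass_attenuation(lines$e[i])
    lines$y[i] * lines$e[i] * 1.602176634e-16 * (1 - exp(-mu * 30))
  }, numeric(1)))
  expect_equal(sum(k$energy_kernel_j), within_j, tolerance = 0.01)
  expect_equal(sum(k$energy_kernel_j) + k$beyond_truncation_j,
               k$total_photon_energy_j, tolerance = 0.01)

  # on a finite grid: in-grid deposition + reported escape = emission
  act <- uniform_volume(1e6, shape = c(12, 12, 12), timestamp = 1)
  den <- water_density(shape = c(12, 12, 12))
  out <- dose_rate_kernel(act, den, lu177, k)
  vvox <- voxel_volume_ml(act$grid)
  emitted <- sum(act$values * vvox * 3600) * k$total_photon_energy_j
  deposited <- sum((out$values - dose_rate_local(act, den, lu177)$values) *
                   voxdose:::voxel_mass_kg(den))
  expect_equal(deposited / emitted + out$escape_fraction, 1, tolerance = 0.01)
})

test_that("point-source photon dose falls monotonically following the kernel shape", {
  g <- voxel_grid(c(25, 25, 25), c(4, 4, 4))
  vals <- array(0, g$shape); vals[13, 13, 13] <- 1e6
  act <- scalar_volume(vals, g, "Bq/mL", timestamp = 1)
  den <- water_density(shape = c(25, 25, 25))
  out <- dose_rate_kernel(act, den, lu177, lu_kernel_4mm())
  photon <- out$values - dose_rate_local(act, den, lu177)$values
  idx <- as.matrix(expand.grid(1:25, 1:25, 1:25))
  r <- sqrt(rowSums(sweep(idx, 2, c(13, 13, 13))^2)) * 4
  shell <- cut(r, breaks = seq(2, 46, by = 4))
  means <- tapply(photon[idx], shell, mean)
  expect_true(all(diff(as.numeric(means)) < 0))
})

test_that("MC equals local deposition bitwise when the nuclide has no photons", {
  act <- seeded_volume(13, shape = c(6, 6, 6))
  den <- water_density(shape = c(6, 6, 6))
  loc <- dose_rate_local(act, den, lu_charged_only)
  for (s in c(1, 99)) {
    mc <- dose_rate_mc(act, den, lu_charged_only, n_decays_per_voxel = 50,
                       seed = s)
    expect_identical(mc$values, loc$values)
    expect_true(all(mc$relative_uncertainty == 0))
  }
})

test_that("MC is exactly linear in activity under a fixed seed", {
  act <- uniform_volume(5e5, shape = c(6, 6, 6))
  den <- water_density(shape = c(6, 6, 6))
  m1 <- dose_rate_mc(act, den, lu177, n_decays_per_voxel = 500, seed = 17)
  act2 <- scalar_volume(act$values * 2, act$grid, "Bq/mL", timestamp = 1)
  m2 <- dose_rate_mc(act2, den, lu177, n_decays_per_voxel = 500, seed = 17)
  expect_equal(m2$values, 2 * m1$values, tolerance = 1e-12)
})

test_that("MC energy balance: deposited + escaped equals simulated emission", {
  act <- uniform_volume(1e6, shape = c(8, 8, 8))
  den <- water_density(shape = c(8, 8, 8))
  vvox <- voxel_volume_ml(act$grid)
  decays_h <- as.numeric(act$values * vvox * 3600)
  set.seed(31)
  res <- voxdose:::mc_photon_transport(
    decays_h, as.numeric(den$values), act$grid$shape, act$grid$spacing / 10,
    c(208.4, 112.9) * 1.602176634e-16, c(0.104, 0.062),
    water_mass_attenuation(c(208.4, 112.9)), 2000L, 0)
  expect_equal(sum(res$photon_j_h) + res$escaped_j_h, res$emitted_j_h,
               tolerance = 1e-9)
  # simulated emission is within a few sigma of the analytic expectation
  analytic <- sum(decays_h) * sum(c(0.104, 0.062) * c(208.4, 112.9) *
                                  1.602176634e-16)
  expect_equal(res$emitted_j_h, analytic, tolerance = 0.02)
})

test_that("MC uncertainty follows the 1/sqrt(N) law", {
  act <- uniform_volume(1e6)
  den <- water_density()
  ratios <- vapply(1:3, function(s) {
    a <- dose_rate_mc(act, den, lu177, n_decays_per_voxel = 1000, seed = s)
    b <- dose_rate_mc(act, den, lu177, n_decays_per_voxel = 4000,
                      seed = s + 100)
    mean(b$relative_uncertainty) / mean(a$relative_uncertainty)
  }, numeric(1))
  expect_true(all(abs(ratios - 0.5) < 0.05))
})
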