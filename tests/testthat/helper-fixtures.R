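# shared fixtures: nuclides, small grids/volumes, reduced phantom configs

nucs <- default_nuclides()
zr89 <- nucs[["Zr-89"]]
lu177 <- nucs[["Lu-177"]]

uniform_volume <- function(value, shape = c(8, 8, 8), spacing = c(4, 4, 4),
                           units = "Bq/mL", timestamp = 1, nuclide = NULL) {
  g <- voxel_grid(shape, spacing)
  scalar_volume(array(value, g$shape), g, units, timestamp = timestamp,
                nuclide = nuclide)
}

water_density <- function(shape = c(8, 8, 8), spacing = c(4, 4, 4), rho = 1) {
  g <- voxel_grid(shape, spacing)
  scalar_volume(array(rho, g$shape), g, "g/cm^3")
}

seeded_volume <- function(seed, shape = c(6, 7, 8), spacing = c(4, 4, 4),
                          units = "Bq/mL", timestamp = 2) {
  set.seed(seed)
  g <- voxel_grid(shape, spacing)
  scalar_volume(array(runif(prod(shape)), shape), g, units,
                timestamp = timestamp, nuclide = "Zr-89")
}

# charged-only Lu-177 analogue (no photon lines)
lu_charged_only <- nuclide("Lu-177-charged", 159.53,
                           list(emission_line("charged", 147.9, 1)))

# a small two-organ phantom config that builds in well under a second
small_phantom_config <- function(grid = voxel_grid(c(24, 24, 40), c(8, 8, 8))) {
  cfg <- default_phantom_config(grid = grid)
  cfg$organs <- list(
    organ_spec("liver", 2L,
               list(type = "ellipsoid", center = c(96, 96, 170),
                    radii = c(45, 40, 50)), 1.04,
               pk_params(0.35, 0.15, 0.004, c(urinary = 0, hepatobiliary = 1))),
    organ_spec("marrow_spine", 8L,
               list(type = "cylinder", center = c(96, 40, 160), radius = 12,
                    half_length = 60, axis = 3L), 1.03,
               pk_params(0.03, 0.04, 0.001,
                         c(urinary = 0.5, hepatobiliary = 0.5))))
  cfg$body <- organ_spec("body", 12L,
                         list(type = "ellipsoid", center = c(96, 96, 160),
                              radii = c(85, 80, 150)), 1.04,
                         pk_params(1 - 0.35 - 0.03, 3, 0.05,
                                   c(urinary = 0.6, hepatobiliary = 0.4)))
  cfg$marrow_shell <- NULL
  cfg
}

# shared Lu-177 photon kernel at 4 mm, built once per test run
lu_kernel_4mm <- local({
  cache <- NULL
  function(truncation_cm = 30) {
    if (is.null(cache) || cache$truncation_cm != truncation_cm)
      cache <<- photon_kernel(lu177, c(4, 4, 4), truncation_cm = truncation_cm)
    cache
  }
})
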