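#' Compartmental pharmacokinetic parameters for one organ
#'
#' Each organ receives a fraction `uptake_fraction` of the injected activity
#' from the blood with uptake rate `k_up` (1/h) and clears it biologically at
#' `k_bio` (1/h) towards excretion, split between the urinary and
#' hepatobiliary routes.  The resident biological content (fraction of
#' injected, decay-corrected) follows the closed form
#' \deqn{b(t) = f \frac{k_{up}}{k_{up}-k_{bio}}
#'   \left(e^{-k_{bio} t} - e^{-k_{up} t}\right).}
#' The balance `in-transit + resident + excreted = f` holds exactly at all
#' times; activity still in transit (blood) is held by the remainder-of-body
#' compartment.
#'
#' @param uptake_fraction Fraction of injected activity routed to the organ,
#'   in \[0, 1\].
#' @param k_up Uptake rate, 1/h; must exceed `k_bio`.
#' @param k_bio Biological clearance rate, 1/h, >= 0.
#' @param route_split Named numeric `c(urinary = , hepatobiliary = )` summing
#'   to 1.
#' @return Object of class `pk_params`.
#' @export
pk_params <- function(uptake_fraction, k_up, k_bio,
                      route_split = c(urinary = 0.5, hepatobiliary = 0.5)) {
  if (uptake_fraction < 0 || uptake_fraction > 1)
    stop("uptake_fraction must be in [0, 1]")
  if (k_bio < 0) stop("k_bio must be >= 0")
  if (k_up <= k_bio)
    stop("k_up must exceed k_bio (k_up = k_bio degenerates the closed form)")
  rs <- route_split[c("urinary", "hepatobiliary")]
  if (anyNA(rs) || abs(sum(rs) - 1) > 1e-9)
    stop("route_split must name urinary and hepatobiliary fractions summing to 1")
  structure(list(uptake_fraction = uptake_fraction, k_up = k_up, k_bio = k_bio,
                 route_split = rs),
            class = "pk_params")
}

# closed-form compartment solutions (fractions of injected, decay-corrected)
pk_resident  <- function(pk, t)
  pk$uptake_fraction * pk$k_up / (pk$k_up - pk$k_bio) *
    (exp(-pk$k_bio * t) - exp(-pk$k_up * t))
pk_in_transit <- function(pk, t) pk$uptake_fraction * exp(-pk$k_up * t)
pk_excreted   <- function(pk, t)
  pk$uptake_fraction - pk_in_transit(pk, t) - pk_resident(pk, t)

#' Geometric organ specification for the synthetic phantom
#'
#' @param name Organ name (becomes the ROI name).
#' @param label Positive integer ROI label, unique across organs.
#' @param shape List describing a primitive: `list(type = "ellipsoid",
#'   center = mm, radii = mm)`, `list(type = "cylinder", center, radius,
#'   half_length, axis)` (axis 1:3) or `list(type = "box", center,
#'   half_widths)`.
#' @param density Mass density in g/cm^3 (> 0).
#' @param pk A [pk_params()].
#' @return Object of class `organ_spec`.
#' @export
organ_spec <- function(name, label, shape, density, pk) {
  stopifnot(is.character(name), label == round(label), label > 0,
            inherits(pk, "pk_params"))
  if (density <= 0) stop("density must be > 0 g/cm^3")
  if (!shape$type %in% c("ellipsoid", "cylinder", "box"))
    stop("unknown shape type '", shape$type, "'")
  structure(list(name = name, label = as.integer(label), shape = shape,
                 density = density, pk = pk),
            class = "organ_spec")
}

# logical mask of a primitive on a grid, optionally grown by `margin` mm
rasterize_shape <- function(shape, grid, margin = 0) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + (seq_len(grid$shape[k]) - 1) * grid$spacing[k])
  d <- function(k) ax[[k]] - shape$center[k]
  if (shape$type == "ellipsoid") {
    r <- shape$radii + margin
    q <- outer(outer((d(1) / r[1])^2, (d(2) / r[2])^2, `+`), (d(3) / r[3])^2, `+`)
    q <= 1
  } else if (shape$type == "cylinder") {
    axis <- shape$axis %||% 3L
    perp <- setdiff(1:3, axis)
    r <- shape$radius + margin
    h <- shape$half_length + margin
    radial <- Reduce(`+`, lapply(perp, function(k) {
      a <- array(0, grid$shape)
      sweep(a, k, (d(k) / r)^2, `+`)
    }))
    gate <- sweep(array(TRUE, grid$shape), axis, abs(d(axis)) <= h, `&`)
    radial <= 1 & gate
  } else { # box
    hw <- shape$half_widths + margin
    Reduce(`&`, lapply(1:3, function(k) {
      sweep(array(TRUE, grid$shape), k, abs(d(k)) <= hw[k], `&`)
    }))
  }
}

#' Default synthetic canine phantom configuration
#'
#' A desk-scale voxelized beagle: a soft-tissue body ellipsoid holding heart,
#' liver, spleen, adrenals, kidneys, spinal and shoulder marrow (with a
#' cortical-bone density shell) and, for male subjects, testes.  Default PK
#' parameters emulate the qualitative kinetics of an Zr-89-labeled IgG
#' antibody study: liver uptake dominates, adrenals next, marrow accumulates
#' over time (osteophilic catabolites), the heart (blood pool) clears
#' quickly, and biological excretion (urinary + hepatobiliary) is mostly over
#' within ~73 h, after which physical decay dominates.  Scan schedule
#' defaults to 4/24/48/73 h and injected activity to 9.88 MBq.
#'
#' @param sex `"female"` (no testes) or `"male"`.
#' @param scan_times_h Frame acquisition times, hours post injection.
#' @param injected_activity_mbq Injected activity at time zero, MBq.
#' @param grid A [voxel_grid()]; default 64 x 64 x 128 voxels at 4 mm.
#' @param subject_id Identifier stored in the study metadata.
#' @return A phantom configuration list accepted by [build_phantom()].
#' @export
default_phantom_config <- function(sex = c("female", "male"),
                                   scan_times_h = c(4, 24, 48, 73),
                                   injected_activity_mbq = 9.88,
                                   grid = voxel_grid(c(64, 64, 128), c(4, 4, 4)),
                                   subject_id = NULL) {
  sex <- match.arg(sex)
  ell <- function(center, radii) list(type = "ellipsoid", center = center,
                                      radii = radii)
  organs <- list(
    organ_spec("heart", 1L, ell(c(126, 126, 140), c(28, 25, 27)), 1.04,
               pk_params(0.05, 3, 0.05, c(urinary = 0.7, hepatobiliary = 0.3))),
    organ_spec("liver", 2L, ell(c(126, 126, 215), c(42, 40, 42)), 1.04,
               pk_params(0.35, 0.15, 0.004, c(urinary = 0, hepatobiliary = 1))),
    organ_spec("spleen", 3L, ell(c(56, 126, 215), c(18, 15, 25)), 1.04,
               pk_params(0.01, 0.1, 0.01, c(urinary = 0.5, hepatobiliary = 0.5))),
    organ_spec("adrenal_left", 4L, ell(c(72, 150, 240), c(8, 6, 10)), 1.04,
               pk_params(0.0013, 0.1, 0.002, c(urinary = 0.5, hepatobiliary = 0.5))),
    organ_spec("adrenal_right", 5L, ell(c(180, 150, 240), c(8, 6, 10)), 1.04,
               pk_params(0.0013, 0.1, 0.002, c(urinary = 0.5, hepatobiliary = 0.5))),
    organ_spec("kidney_left", 6L, ell(c(75, 174, 268), c(18, 15, 22)), 1.04,
               pk_params(0.012, 0.5, 0.015, c(urinary = 1, hepatobiliary = 0))),
    organ_spec("kidney_right", 7L, ell(c(177, 174, 268), c(18, 15, 22)), 1.04,
               pk_params(0.012, 0.5, 0.015, c(urinary = 1, hepatobiliary = 0))),
    organ_spec("marrow_spine", 8L,
               list(type = "cylinder", center = c(126, 58, 254), radius = 9,
                    half_length = 100, axis = 3L), 1.03,
               pk_params(0.03, 0.04, 0.001, c(urinary = 0.5, hepatobiliary = 0.5))),
    organ_spec("marrow_left_shoulder", 9L, ell(c(56, 96, 140), c(12, 12, 18)), 1.03,
               pk_params(0.007, 0.04, 0.001, c(urinary = 0.5, hepatobiliary = 0.5))),
    organ_spec("marrow_right_shoulder", 10L, ell(c(196, 96, 140), c(12, 12, 18)), 1.03,
               pk_params(0.007, 0.04, 0.001, c(urinary = 0.5, hepatobiliary = 0.5))))
  if (sex == "male") {
    organs <- c(organs, list(
      organ_spec("testes", 11L, ell(c(126, 168, 430), c(12, 10, 12)), 1.04,
                 pk_params(0.001, 0.05, 0.002, c(urinary = 1, hepatobiliary = 0)))))
  }
  f_used <- sum(vapply(organs, function(o) o$pk$uptake_fraction, numeric(1)))
  body <- organ_spec("body", 12L, ell(c(126, 126, 254), c(112, 100, 245)), 1.04,
                     pk_params(1 - f_used, 3, 0.05,
                               c(urinary = 0.6, hepatobiliary = 0.4)))
  list(grid = grid, sex = sex, scan_times_h = scan_times_h,
       injected_activity_mbq = injected_activity_mbq,
       subject_id = subject_id %||% paste0("phantom-", toupper(substr(sex, 1, 1))),
       organs = organs, body = body,
       marrow_shell = list(organs = c("marrow_spine", "marrow_left_shoulder",
                                      "marrow_right_shoulder"),
                           margin_mm = 8, density = 1.4),
       void_time_h = 5,
       air_density = 0.0012,
       imaging_nuclide = "Zr-89")
}

#' Build a synthetic phantom study
#'
#' Rasterizes the configured organs onto the voxel grid, evaluates the
#' compartmental closed forms at the scan times and emits a noiseless time
#' series of imaging-nuclide activity-concentration volumes.  The measured
#' concentration of organ o at time t is
#' `injected * b_o(t) * exp(-lambda_img * t)` distributed uniformly over the
#' organ's voxels; activity still in blood transit is held by the
#' remainder-of-body compartment, so whole-body decay-corrected activity plus
#' cumulative excreted activity equals the injected activity exactly.
#' Construction is fully deterministic; `seed` is recorded in the metadata and
#' seeds downstream noise.
#'
#' @param config Configuration from [default_phantom_config()] (possibly
#'   modified).
#' @param seed Integer recorded with the study.
#' @param nuclides Named list of [nuclide()]s providing the imaging nuclide.
#' @return Object of class `phantom_study` with elements `grid`, `density`,
#'   `labels` ([roi_set()]), `frames` (list of [scalar_volume()]), `meta`
#'   ([study_meta()]), `organs` and `seed`.
#' @export
build_phantom <- function(config = default_phantom_config(), seed = 1L,
                          nuclides = default_nuclides()) {
  grid <- config$grid
  img_nuc <- nuclides[[config$imaging_nuclide]]
  if (is.null(img_nuc)) stop("unknown imaging nuclide ", config$imaging_nuclide)
  times <- config$scan_times_h
  if (length(times) < 1 || any(diff(times) <= 0) || any(times < 0))
    stop("scan times must be non-negative and strictly increasing")

  body_mask <- rasterize_shape(config$body$shape, grid)
  organ_masks <- lapply(config$organs, function(o) rasterize_shape(o$shape, grid))
  names(organ_masks) <- vapply(config$organs, `[[`, character(1), "name")

  count <- Reduce(`+`, lapply(organ_masks, function(m) m * 1L))
  if (any(count > 1)) {
    stop("overlapping organ labels at ", sum(count > 1), " voxel(s)")
  }
  outside <- vapply(seq_along(organ_masks),
                    function(i) any(organ_masks[[i]] & !body_mask), logical(1))
  if (any(outside))
    stop("organ(s) extend outside the body: ",
         paste(names(organ_masks)[outside], collapse = ", "))
  if (any(vapply(organ_masks, sum, numeric(1)) == 0))
    stop("organ rasterized to zero voxels")

  labels <- array(0L, grid$shape)
  for (i in seq_along(config$organs))
    labels[organ_masks[[i]]] <- config$organs[[i]]$label
  body_rem <- body_mask & count == 0
  labels[body_rem] <- config$body$label

  # air outside the body, as a CT-derived density map would have
  density <- array(config$air_density %||% 0.0012, grid$shape)
  density[body_rem] <- config$body$density
  for (i in seq_along(config$organs))
    density[organ_masks[[i]]] <- config$organs[[i]]$density
  if (!is.null(config$marrow_shell)) {
    sh <- config$marrow_shell
    shell <- array(FALSE, grid$shape)
    for (nm in sh$organs) {
      o <- config$organs[[which(names(organ_masks) == nm)]]
      shell <- shell | (rasterize_shape(o$shape, grid, margin = sh$margin_mm) &
                        !organ_masks[[nm]])
    }
    shell <- shell & body_rem
    density[shell] <- sh$density
  }

  vvox <- voxel_volume_ml(grid)
  a0_bq <- config$injected_activity_mbq * 1e6
  void_h <- config$void_time_h %||% 0
  all_organs <- c(config$organs, list(config$body))
  f_total <- sum(vapply(all_organs, function(o) o$pk$uptake_fraction, numeric(1)))
  if (f_total > 1 + 1e-9) stop("uptake fractions sum to ", f_total, " > 1")

  frames <- lapply(times, function(t) {
    vals <- array(0, grid$shape)
    decay <- exp(-img_nuc$decay_constant * t)
    # blood in transit for every compartment resides spatially in the body
    transit <- sum(vapply(all_organs, function(o) pk_in_transit(o$pk, t),
                          numeric(1)))
    for (i in seq_along(config$organs)) {
      o <- config$organs[[i]]
      frac <- pk_resident(o$pk, t)
      vals[organ_masks[[i]]] <- a0_bq * frac * decay /
        (sum(organ_masks[[i]]) * vvox)
    }
    # before the first voiding, biologically cleared activity is still inside
    # the subject (bladder/gut content), held spatially by the body remainder
    retained_exc <- if (t < void_h)
      sum(vapply(all_organs, function(o) pk_excreted(o$pk, t), numeric(1)))
    else 0
    body_frac <- pk_resident(config$body$pk, t) + transit + retained_exc
    vals[body_rem] <- a0_bq * body_frac * decay / (sum(body_rem) * vvox)
    scalar_volume(vals, grid, "Bq/mL", timestamp = t, nuclide = img_nuc$name)
  })

  mass_kg <- sum(density) * vvox / 1000  # g/cm^3 * mL -> g, /1000 -> kg
  meta <- study_meta(config$injected_activity_mbq, mass_kg,
                     subject_id = config$subject_id)
  rois <- roi_set(scalar_volume(labels * 1, grid, "dimensionless"),
                  stats::setNames(vapply(all_organs, `[[`, integer(1), "label"),
                                  vapply(all_organs, `[[`, character(1), "name")))
  structure(list(grid = grid, density = scalar_volume(density, grid, "g/cm^3"),
                 labels = rois, frames = frames, meta = meta,
                 organs = all_organs, imaging_nuclide = img_nuc$name,
                 void_time_h = void_h, seed = as.integer(seed)),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("<phantom_study %s> %d frames at %s h, %.3g MBq into %.3g kg\n",
              x$meta$subject_id, length(x$frames),
              paste(vapply(x$frames, `[[`, numeric(1), "timestamp"),
                    collapse = "/"),
              x$meta$injected_activity_mbq, x$meta$subject_mass_kg))
  invisible(x)
}

# separable gaussian blur with zero padding; kernel normalized to sum 1 so
# interior mass is conserved and boundary mass is truncated
gaussian_blur_3d <- function(values, sigma_vox) {
  out <- values
  for (k in 1:3) {
    s <- sigma_vox[k]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    w <- w / sum(w)
    n <- dim(out)[k]
    acc <- array(0, dim(out))
    for (j in -r:r) {
      src <- seq_len(n) + j
      ok <- src >= 1 & src <= n
      idx_dst <- which(ok); idx_src <- src[ok]
      if (k == 1) acc[idx_dst, , ] <- acc[idx_dst, , ] + w[j + r + 1] * out[idx_src, , ]
      if (k == 2) acc[, idx_dst, ] <- acc[, idx_dst, ] + w[j + r + 1] * out[, idx_src, ]
      if (k == 3) acc[, , idx_dst] <- acc[, , idx_dst] + w[j + r + 1] * out[, , idx_src]
    }
    out <- acc
  }
  out
}

#' Add PET-like blur and noise to a phantom study
#'
#' Emulates reconstructed-image degradation: an isotropic Gaussian
#' point-spread blur (sigma in mm) followed by multiplicative Gaussian voxel
#' noise with coefficient of variation `noise_cv`; negative values are
#' clipped to zero.  Reconstruction itself is not simulated.  Reproducible
#' given `seed`.
#'
#' @param study A `phantom_study` from [build_phantom()].
#' @param psf_sigma Gaussian PSF sigma in mm (>= 0). Default 4 mm.
#' @param noise_cv Multiplicative noise coefficient of variation (>= 0).
#'   Default 0.03.
#' @param seed Integer RNG seed.
#' @return The study with degraded frames.
#' @export
add_imaging_noise <- function(study, psf_sigma = 4, noise_cv = 0.03, seed = 1L) {
  stopifnot(inherits(study, "phantom_study"))
  if (psf_sigma < 0 || noise_cv < 0)
    stop("psf_sigma and noise_cv must be >= 0")
  if (psf_sigma == 0 && noise_cv == 0) return(study)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  sig_vox <- psf_sigma / study$grid$spacing
  study$frames <- lapply(study$frames, function(fr) {
    v <- fr$values
    if (psf_sigma > 0) v <- gaussian_blur_3d(v, sig_vox)
    if (noise_cv > 0) {
      v <- v * (1 + noise_cv * stats::rnorm(length(v)))
      v[v < 0] <- 0
    }
    scalar_volume(v, fr$grid, fr$units, timestamp = fr$timestamp,
                  nuclide = fr$nuclide)
  })
  study$noise <- list(psf_sigma = psf_sigma, noise_cv = noise_cv, seed = seed)
  study
}

#' Cumulative excretion curves of a phantom study
#'
#' Evaluates the closed-form cumulative urinary and hepatobiliary excreted
#' fractions of injected (decay-corrected) activity that have left the
#' subject.  Before the first voiding time cleared activity is still held in
#' the body (so the curves are zero there); both curves are monotone
#' non-decreasing and their sum approaches the total biologically cleared
#' fraction at late times.
#'
#' @param study A `phantom_study` built by [build_phantom()].
#' @param times_h Evaluation times in hours.
#' @return `data.frame` with columns `time_h`, `urinary`, `hepatobiliary`.
#' @export
excretion_curves <- function(study, times_h = seq(0, 168, by = 1)) {
  stopifnot(inherits(study, "phantom_study"))
  if (is.null(study$organs))
    stop("study has no PK record (not built by build_phantom)")
  ur <- hb <- numeric(length(times_h))
  for (o in study$organs) {
    e <- pk_excreted(o$pk, times_h)
    ur <- ur + e * o$pk$route_split[["urinary"]]
    hb <- hb + e * o$pk$route_split[["hepatobiliary"]]
  }
  gate <- as.numeric(times_h >= (study$void_time_h %||% 0))
  data.frame(time_h = times_h, urinary = ur * gate, hepatobiliary = hb * gate)
}
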