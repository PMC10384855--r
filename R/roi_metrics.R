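#' Standardized uptake value of an ROI
#'
#' Body-weight SUV of the mean ROI activity concentration at the frame time,
#' decay-corrected with the imaging nuclide:
#' \deqn{SUV = \frac{\bar C_{ROI}}
#'   {A_{inj} e^{-\lambda T_n} / m_{subject}}}
#' with concentration in Bq/mL, injected activity in Bq and subject mass in
#' grams; dimensionless under the 1 g/mL tissue-density convention.
#'
#' @param frame [scalar_volume()] in Bq/mL with a timestamp.
#' @param rois A [roi_set()] on the same grid.
#' @param name ROI name.
#' @param meta [study_meta()].
#' @param imaging [nuclide()] whose decay constant corrects to scan time.
#' @return SUV (single number).
#' @export
suv <- function(frame, rois, name, meta, imaging) {
  assert_units(frame, "Bq/mL")
  stopifnot(inherits(rois, "roi_set"), inherits(meta, "study_meta"),
            inherits(imaging, "nuclide"))
  if (is.null(frame$timestamp)) stop("frame has no timestamp")
  if (!same_grid(frame$grid, rois$label_volume$grid))
    stop("frame and ROI label map are on different grids")
  mask <- roi_mask(rois, name)
  if (!any(mask)) stop("ROI '", name, "' is empty")
  mean_conc <- mean(frame$values[mask])
  a0_bq <- meta$injected_activity_mbq * 1e6
  if (a0_bq <= 0) stop("injected activity must be > 0")
  mass_g <- meta$subject_mass_kg * 1000
  mean_conc / (a0_bq * decay_factor(imaging, frame$timestamp) / mass_g)
}

#' ROI time series of concentration and SUV
#'
#' @param study A `phantom_study` (or [read_manifest()] result).
#' @param imaging [nuclide()] tagging the frames.
#' @param roi_names ROIs to tabulate (default: all named ROIs).
#' @return `data.frame` with columns `roi`, `time_h`, `mean_bq_ml`, `suv`,
#'   `n_voxels`.
#' @export
roi_timeseries <- function(study, imaging, roi_names = names(study$labels$names)) {
  stopifnot(inherits(study, "phantom_study"))
  rows <- list()
  for (nm in roi_names) {
    mask <- roi_mask(study$labels, nm)
    for (fr in study$frames) {
      rows[[length(rows) + 1]] <- data.frame(
        roi = nm, time_h = fr$timestamp,
        mean_bq_ml = mean(fr$values[mask]),
        suv = suv(fr, study$labels, nm, study$meta, imaging),
        n_voxels = sum(mask))
    }
  }
  do.call(rbind, rows)
}

#' Whole-body activity recovery QC
#'
#' Compares the decay-corrected whole-body activity of the earliest frame
#' (before any excretion) with the injected activity.  The scan passes when
#' the ratio is within `tolerance` of unity (the scanner-calibration
#' consistency criterion, nominally +/-10%).
#'
#' @param frame Earliest [scalar_volume()] frame, Bq/mL with timestamp.
#' @param meta [study_meta()].
#' @param imaging [nuclide()].
#' @param tolerance Acceptable |ratio - 1| (default 0.10).
#' @param excreted_fraction Cumulative excreted fraction at the frame time, if
#'   known; a warning is issued if materially nonzero.
#' @return List with `ratio`, `pass`, `tolerance`.
#' @export
whole_body_recovery <- function(frame, meta, imaging, tolerance = 0.10,
                                excreted_fraction = 0) {
  assert_units(frame, "Bq/mL")
  stopifnot(inherits(meta, "study_meta"), inherits(imaging, "nuclide"))
  if (is.null(frame$timestamp)) stop("frame has no timestamp")
  if (excreted_fraction > 0.01)
    warning("excreted fraction at first frame is ",
            signif(excreted_fraction, 3),
            "; whole-body recovery against injected activity is biased low")
  wb_bq <- sum(frame$values) * voxel_volume_ml(frame$grid)
  ratio <- wb_bq / decay_factor(imaging, frame$timestamp) /
    (meta$injected_activity_mbq * 1e6)
  list(ratio = ratio, pass = abs(ratio - 1) <= tolerance,
       tolerance = tolerance)
}

#' Per-ROI dose coefficients from a unit-activity dose map
#'
#' Given a dose map computed from frames normalized to 1 GBq of administered
#' therapy activity (see [study_dose_coefficients()]), the mean ROI dose in
#' Gy numerically equals the dose coefficient in Gy/GBq.
#'
#' @param dose A `dose_map` whose provenance records the 1 GBq normalization
#'   (`normalization == "per_GBq"`).
#' @param rois [roi_set()] on the dose grid.
#' @param roi_names ROIs to report (default all).
#' @return `data.frame` with columns `roi`, `gy_per_gbq`, `n_voxels`.
#' @export
dose_coefficients <- function(dose, rois, roi_names = names(rois$names)) {
  assert_units(dose, "Gy")
  if (is.null(dose$normalization) || dose$normalization != "per_GBq")
    stop("dose map lacks the 1 GBq normalization provenance; ",
         "use study_dose_coefficients() or set normalization explicitly")
  if (!same_grid(dose$grid, rois$label_volume$grid))
    stop("dose map and ROI label map are on different grids")
  rows <- lapply(roi_names, function(nm) {
    mask <- roi_mask(rois, nm)
    if (!any(mask)) stop("ROI '", nm, "' has no voxels")
    data.frame(roi = nm, gy_per_gbq = mean(dose$values[mask]),
               n_voxels = sum(mask))
  })
  do.call(rbind, rows)
}

#' End-to-end dose coefficients for a study
#'
#' Runs the dosimetry chain on a study: substitute each imaging frame to the
#' therapy nuclide, rescale the decay-corrected distribution so the
#' administered therapy activity is 1 GBq (factor
#' \eqn{10^9 / A_{inj,Bq}} applied per voxel), compute per-frame dose-rate
#' maps with the chosen engine, integrate over time, and reduce to per-ROI
#' Gy/GBq coefficients.
#'
#' @param study A `phantom_study`.
#' @param imaging,therapy [nuclide()] objects.
#' @param method `"local"`, `"kernel"` or `"mc"`.
#' @param tail,head Passed to [integrate_dose()].
#' @param ... Further arguments to the dose engine (`kernel`,
#'   `n_decays_per_voxel`, `seed`, `threshold`).
#' @return List with `coefficients` (data.frame), `dose` (the normalized
#'   `dose_map`) and `dose_rate_maps`.
#' @export
study_dose_coefficients <- function(study, imaging, therapy,
                                    method = c("local", "kernel", "mc"),
                                    tail = "physical_decay",
                                    head = "constant_backfill", ...) {
  method <- match.arg(method)
  stopifnot(inherits(study, "phantom_study"))
  scale <- 1e9 / (study$meta$injected_activity_mbq * 1e6)
  engine <- switch(method, local = dose_rate_local,
                   kernel = dose_rate_kernel, mc = dose_rate_mc)
  maps <- lapply(study$frames, function(fr) {
    th <- substitute_isotope(fr, imaging, therapy)
    th$values <- th$values * scale
    engine(th, study$density, therapy, ...)
  })
  dose <- integrate_dose(maps, therapy, tail = tail, head = head)
  dose$normalization <- "per_GBq"
  list(coefficients = dose_coefficients(dose, study$labels),
       dose = dose, dose_rate_maps = maps)
}
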