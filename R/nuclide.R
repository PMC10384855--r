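#' Radionuclide physical data
#'
#' A `nuclide` bundles the physical half-life, a summarized emission spectrum
#' (mean-energy charged lines and principal photon lines) and an optional
#' point-source gamma dose-rate constant.  The decay constant is derived as
#' \eqn{\lambda = \ln 2 / t_{1/2}} and is the quantity used by all decay
#' arithmetic in the package.
#'
#' @param name Identifier, e.g. `"Lu-177"`.
#' @param half_life_h Physical half-life in hours (> 0).
#' @param emissions List of [emission_line()] objects.
#' @param gamma_dose_rate_constant Optional point-source dose-rate constant in
#'   uSv m^2 MBq^-1 h^-1, used only by [external_dose_rate()].
#' @return An object of class `nuclide`.
#' @seealso [default_nuclides()] for the shipped Zr-89 / Lu-177 data.
#' @export
nuclide <- function(name, half_life_h, emissions = list(),
                    gamma_dose_rate_constant = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L || half_life_h <= 0)
    stop("half_life_h must be a single positive number, got ", half_life_h)
  for (e in emissions) {
    if (!inherits(e, "emission_line"))
      stop("emissions must be a list of emission_line objects")
  }
  if (!is.null(gamma_dose_rate_constant) &&
      (!is.numeric(gamma_dose_rate_constant) || gamma_dose_rate_constant <= 0))
    stop("gamma_dose_rate_constant must be positive or NULL")
  structure(
    list(name = name,
         half_life_h = half_life_h,
         decay_constant = log(2) / half_life_h,
         emissions = emissions,
         gamma_dose_rate_constant = gamma_dose_rate_constant),
    class = "nuclide")
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide %s> half-life %.4g h (lambda %.6g /h), %d emission line(s)\n",
              x$name, x$half_life_h, x$decay_constant, length(x$emissions)))
  invisible(x)
}

#' Emission line of a summarized decay spectrum
#'
#' @param kind `"charged"` (beta mean-energy line, conversion/Auger electrons)
#'   or `"photon"` (gamma/X line).
#' @param mean_energy_kev Mean energy per emission in keV (> 0).
#' @param yield Emissions per decay, in (0, 1].
#' @return An object of class `emission_line`.
#' @export
emission_line <- function(kind = c("charged", "photon"), mean_energy_kev, yield) {
  kind <- match.arg(kind)
  if (!is.numeric(mean_energy_kev) || mean_energy_kev <= 0)
    stop("mean_energy_kev must be > 0, got ", mean_energy_kev)
  if (!is.numeric(yield) || yield <= 0 || yield > 1)
    stop("yield must be in (0, 1], got ", yield)
  structure(list(kind = kind, mean_energy_kev = mean_energy_kev, yield = yield),
            class = "emission_line")
}

#' Load nuclide definitions from a constants file
#'
#' Reads a JSON file with entries `name`, `half_life_h`, `emissions`
#' (`kind`/`mean_energy_kev`/`yield`) and optional `gamma_dose_rate_constant`.
#' `default_nuclides()` loads the file shipped with the package, which defines
#' Zr-89 (78.41 h) and Lu-177 (159.53 h).
#'
#' @param path Path to a JSON nuclide constants file.
#' @return Named list of [nuclide()] objects.
#' @export
load_nuclides <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (n in spec$nuclides) {
    ems <- lapply(n$emissions, function(e)
      emission_line(e$kind, e$mean_energy_kev, e$yield))
    out[[n$name]] <- nuclide(n$name, n$half_life_h, ems,
                             gamma_dose_rate_constant = n$gamma_dose_rate_constant)
  }
  out
}

#' @rdname load_nuclides
#' @export
default_nuclides <- function() {
  load_nuclides(system.file("extdata", "nuclides.json", package = "voxdose",
                            mustWork = TRUE))
}

#' Total charged-particle energy per decay, in joules
#'
#' Sum over charged emission lines of energy times yield; the energy assumed
#' locally deposited by the local-deposition dose model.
#'
#' @param nuclide A [nuclide()].
#' @return Energy in J per decay.
#' @export
charged_energy_per_decay <- function(nuclide) {
  stopifnot(inherits(nuclide, "nuclide"))
  kev <- sum(vapply(nuclide$emissions, function(e)
    if (e$kind == "charged") e$mean_energy_kev * e$yield else 0, numeric(1)))
  kev * .KEV_TO_J
}

# photon lines as a data.frame (energy_kev, yield); zero rows if none
photon_lines <- function(nuclide) {
  stopifnot(inherits(nuclide, "nuclide"))
  ph <- Filter(function(e) e$kind == "photon", nuclide$emissions)
  data.frame(energy_kev = vapply(ph, `[[`, numeric(1), "mean_energy_kev"),
             yield = vapply(ph, `[[`, numeric(1), "yield"))
}

#' Physical decay factor
#'
#' Fraction of activity remaining after `elapsed_h` hours:
#' \eqn{e^{-\lambda t}}.  Multiplying a time-zero activity by it gives the
#' activity at `elapsed_h`; dividing decay-corrects back to time zero.
#'
#' @param nuclide A [nuclide()].
#' @param elapsed_h Elapsed time in hours, >= 0 (vectorized).
#' @return Decay factor(s) in (0, 1].
#' @export
decay_factor <- function(nuclide, elapsed_h) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (any(elapsed_h < 0))
    stop("elapsed time must be >= 0 h, got ", min(elapsed_h))
  exp(-nuclide$decay_constant * elapsed_h)
}

#' Substitute the imaging radionuclide for the therapeutic one
#'
#' Per-voxel decay correction from the imaging label to the therapeutic label:
#' the measured concentration is corrected back to injection time with the
#' imaging decay constant and re-decayed with the therapeutic one,
#' \eqn{A_{th}(t) = A_{img}(t)\, e^{+\lambda_{img} t}\, e^{-\lambda_{th} t}}.
#' The biological distribution (decay-corrected fraction per mL) is preserved
#' exactly; only the physical-decay weighting changes.
#'
#' @param measured [scalar_volume()] of activity concentration (Bq/mL) with a
#'   timestamp (hours post injection) and a nuclide tag equal to
#'   `imaging$name`.
#' @param imaging,therapy [nuclide()] objects for the measured and target
#'   labels.
#' @return A [scalar_volume()] on the same grid and timestamp, tagged with the
#'   therapy nuclide.
#' @export
substitute_isotope <- function(measured, imaging, therapy) {
  stopifnot(inherits(measured, "scalar_volume"),
            inherits(imaging, "nuclide"), inherits(therapy, "nuclide"))
  assert_units(measured, "Bq/mL")
  if (is.null(measured$timestamp))
    stop("measured volume has no timestamp (hours post injection)")
  if (is.null(measured$nuclide) || measured$nuclide != imaging$name)
    stop("measured volume is tagged '", measured$nuclide %||% "<none>",
         "', expected imaging nuclide '", imaging$name, "'")
  t <- measured$timestamp
  ratio <- exp((imaging$decay_constant - therapy$decay_constant) * t)
  out <- measured
  out$values <- measured$values * ratio
  out$nuclide <- therapy$name
  out
}

#' Radiolabeling yield from an iTLC strip
#'
#' Instant thin-layer chromatography yield: the labeled antibody stays at the
#' origin (bottom half of the strip) while free chelated activity runs with
#' the solvent front (top half).  Yield is the bottom fraction of total
#' counts, in percent.
#'
#' @param cpm_bottom,cpm_top Counts per minute in the bottom and top strip
#'   halves (both >= 0, not both zero).
#' @return Yield in percent.
#' @export
radiolabeling_yield <- function(cpm_bottom, cpm_top) {
  if (cpm_bottom < 0 || cpm_top < 0)
    stop("counts must be >= 0")
  if (cpm_bottom + cpm_top == 0)
    stop("both counts are zero: yield undefined")
  100 * cpm_bottom / (cpm_bottom + cpm_top)
}

#' Point-source external dose-rate estimate
#'
#' Screening estimate \eqn{\Gamma A / d^2} with the nuclide's gamma dose-rate
#' constant.  This is an upper-bound point-source estimate: self-attenuation
#' and geometry of the subject are ignored.
#'
#' @param activity_mbq Activity in MBq (>= 0).
#' @param nuclide A [nuclide()] with a `gamma_dose_rate_constant`.
#' @param distance_m Distance in metres (> 0).
#' @return Dose rate in uSv/h.
#' @export
external_dose_rate <- function(activity_mbq, nuclide, distance_m) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (is.null(nuclide$gamma_dose_rate_constant))
    stop("nuclide '", nuclide$name, "' has no gamma_dose_rate_constant")
  if (any(distance_m <= 0))
    stop("distance must be > 0 m, got ", min(distance_m))
  if (any(activity_mbq < 0))
    stop("activity must be >= 0 MBq")
  nuclide$gamma_dose_rate_constant * activity_mbq / distance_m^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
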