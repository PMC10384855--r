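#' Voxel grid geometry
#'
#' Defines the lattice a volume lives on.  Voxel indices are 0-based and the
#' world coordinate of a voxel centre is `origin + index * spacing`
#' (millimetres).
#'
#' @param shape Integer vector of length 3, voxels per axis (>= 1).
#' @param spacing Numeric length 3, voxel spacing in mm per axis (> 0).
#' @param origin Numeric length 3, world position of voxel (0,0,0) centre, mm.
#' @return Object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid shape must be >= 1 per axis")
  if (any(spacing <= 0)) stop("grid spacing must be > 0 mm")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s @ %s mm, origin %s>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ",")))
  invisible(x)
}

#' Voxel volume of a grid, in millilitres
#'
#' @param grid A [voxel_grid()].
#' @return Voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing) / 1000
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing))) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(b$spacing)))
}

.VOL_UNITS <- c("Bq/mL", "g/cm^3", "Gy/h", "Gy", "dimensionless")

#' A unit-tagged 3-D scalar field on a voxel grid
#'
#' The basic container of the pipeline: activity concentration, density, dose
#' rate or dose, with mandatory units and optional acquisition timestamp
#' (hours post injection) and nuclide tag.
#'
#' @param values 3-D numeric array matching `grid$shape`.
#' @param grid A [voxel_grid()].
#' @param units One of `"Bq/mL"`, `"g/cm^3"`, `"Gy/h"`, `"Gy"`,
#'   `"dimensionless"`.
#' @param timestamp Hours post injection, or NULL.
#' @param nuclide Nuclide name tag, or NULL.
#' @return Object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, units, timestamp = NULL, nuclide = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  units <- match.arg(units, .VOL_UNITS)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("values shape (", paste(dim(values), collapse = "x"),
         ") does not match grid shape (", paste(grid$shape, collapse = "x"), ")")
  if (units != "dimensionless" && any(values < 0, na.rm = TRUE)) {
    idx <- which(values < 0)[1]
    stop("negative value at linear voxel index ", idx,
         " not allowed for units ", units)
  }
  structure(list(values = values, grid = grid, units = units,
                 timestamp = timestamp, nuclide = nuclide),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume %s [%s]%s%s> range [%.4g, %.4g]\n",
              paste(x$grid$shape, collapse = "x"), x$units,
              if (!is.null(x$timestamp)) sprintf(" @ %g h", x$timestamp) else "",
              if (!is.null(x$nuclide)) paste0(" ", x$nuclide) else "",
              min(x$values), max(x$values)))
  invisible(x)
}

assert_units <- function(vol, units) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (vol$units != units)
    stop("expected a volume in ", units, ", got ", vol$units)
  invisible(vol)
}

#' Region-of-interest label map
#'
#' An integer label volume (0 = background) plus a label-to-name mapping.
#' Every named label must occur in the volume.
#'
#' @param label_volume [scalar_volume()] with `dimensionless` units holding
#'   non-negative integer labels.
#' @param names Named integer vector mapping ROI name -> label.
#' @return Object of class `roi_set`.
#' @export
roi_set <- function(label_volume, names) {
  assert_units(label_volume, "dimensionless")
  lv <- label_volume$values
  if (any(lv != round(lv)) || any(lv < 0))
    stop("label volume must contain non-negative integers")
  if (is.null(base::names(names)) || any(base::names(names) == ""))
    stop("names must be a fully named integer vector (name -> label)")
  if (anyDuplicated(names)) stop("ROI labels must be unique")
  if (any(names == 0)) stop("label 0 is reserved for background")
  present <- unique(as.vector(lv))
  missing <- setdiff(names, present)
  if (length(missing))
    stop("labels absent from volume: ",
         paste(base::names(names)[names %in% missing], collapse = ", "))
  labels <- stats::setNames(as.integer(names), base::names(names))
  structure(list(label_volume = label_volume, names = labels),
            class = "roi_set")
}

roi_mask <- function(rois, name) {
  if (!name %in% names(rois$names))
    stop("unknown ROI '", name, "'")
  rois$label_volume$values == rois$names[[name]]
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> ", length(x$names), " ROIs: ",
      paste(names(x$names), collapse = ", "), "\n", sep = "")
  invisible(x)
}
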