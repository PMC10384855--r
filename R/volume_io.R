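#' Read and write voxel volumes as NIfTI with a JSON sidecar
#'
#' Volumes are stored as NIfTI (`.nii` / `.nii.gz`) with spacing in the NIfTI
#' `pixdim`, and a JSON sidecar (`<path>.json`) carrying what NIfTI cannot:
#' units, acquisition timestamp, nuclide tag and the grid origin.  Continuous
#' fields are written as float32 (the round-trip contract is float32
#' precision), label maps as int16.
#'
#' @param vol A [scalar_volume()].
#' @param path Output/input NIfTI path.
#' @return `read_volume` returns a [scalar_volume()]; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (vol$units != "dimensionless" && any(vol$values < 0)) {
    idx <- which(vol$values < 0)[1]
    stop("refusing to write negative value at linear voxel index ", idx)
  }
  integer_field <- vol$units == "dimensionless" && all(vol$values == round(vol$values))
  img <- RNifti::asNifti(vol$values)
  RNifti::`pixdim<-`(img, vol$grid$spacing) -> img
  RNifti::writeNifti(img, path,
                     datatype = if (integer_field) "int16" else "float")
  sidecar <- list(units = vol$units,
                  origin_mm = vol$grid$origin,
                  spacing_mm = vol$grid$spacing,
                  timestamp_h = vol$timestamp,
                  nuclide = vol$nuclide)
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_volume
#' @param units Fallback units when no sidecar exists.  Activity volumes
#'   (`Bq/mL`) always require a sidecar (the timestamp lives there).
#' @export
read_volume <- function(path, units = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected 3-D data in ", path, ", got ", length(dim(img)), "-D")
  sc <- NULL
  if (file.exists(sidecar_path(path))) {
    sc <- jsonlite::fromJSON(sidecar_path(path))
  } else if (is.null(units)) {
    stop("no sidecar ", sidecar_path(path), " and no fallback units given")
  }
  units <- sc$units %||% units
  if (identical(units, "Bq/mL") && is.null(sc$timestamp_h) && is.null(sc))
    stop("activity volume requires a sidecar with a timestamp")
  spacing <- sc$spacing_mm %||% RNifti::pixdim(img)
  grid <- voxel_grid(dim(img), spacing, origin = sc$origin_mm %||% c(0, 0, 0))
  vals <- array(as.numeric(img), dim = dim(img))
  scalar_volume(vals, grid, units,
                timestamp = sc$timestamp_h, nuclide = sc$nuclide)
}

#' Resample a volume onto a reference grid
#'
#' Registration between time points is assumed rigid-identity (shared world
#' frame); resampling handles grid mismatch only.  `trilinear` interpolates
#' values at the reference voxel centres (outside the source support the value
#' is 0); `nearest` takes the nearest source voxel and is mandatory for label
#' volumes, which it cannot corrupt with new label values.
#'
#' @param vol Source [scalar_volume()].
#' @param ref Target [voxel_grid()].
#' @param mode `"trilinear"` or `"nearest"`.
#' @return A [scalar_volume()] on `ref`.
#' @export
resample_to_reference <- function(vol, ref, mode = c("trilinear", "nearest")) {
  stopifnot(inherits(vol, "scalar_volume"), inherits(ref, "voxel_grid"))
  mode <- match.arg(mode)
  is_labels <- vol$units == "dimensionless" && all(vol$values == round(vol$values))
  if (is_labels && mode == "trilinear")
    stop("label volumes must be resampled with mode = 'nearest'")
  if (same_grid(vol$grid, ref)) return(vol)

  # continuous source index of each reference voxel centre (0-based)
  ax <- lapply(1:3, function(k) {
    w <- ref$origin[k] + (seq_len(ref$shape[k]) - 1) * ref$spacing[k]
    (w - vol$grid$origin[k]) / vol$grid$spacing[k]
  })
  sx <- vol$grid$shape
  if (mode == "nearest") {
    idx <- lapply(1:3, function(k) {
      i <- round(ax[[k]]) + 1
      i[i < 1 | i > sx[k]] <- NA_integer_
      i
    })
    G <- as.matrix(expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]]))
    vals <- rep(0, nrow(G))
    ok <- stats::complete.cases(G)
    vals[ok] <- vol$values[G[ok, , drop = FALSE]]
  } else {
    fl <- lapply(ax, floor)
    fr <- Map(`-`, ax, fl)
    G0 <- as.matrix(expand.grid(i = fl[[1]], j = fl[[2]], k = fl[[3]]))
    W  <- as.matrix(expand.grid(i = fr[[1]], j = fr[[2]], k = fr[[3]]))
    vals <- rep(0, nrow(G0))
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      I <- cbind(G0[, 1] + di, G0[, 2] + dj, G0[, 3] + dk) + 1
      w <- (if (di) W[, 1] else 1 - W[, 1]) *
           (if (dj) W[, 2] else 1 - W[, 2]) *
           (if (dk) W[, 3] else 1 - W[, 3])
      ok <- I[, 1] >= 1 & I[, 1] <= sx[1] & I[, 2] >= 1 & I[, 2] <= sx[2] &
            I[, 3] >= 1 & I[, 3] <= sx[3] & w > 0
      if (any(ok)) vals[ok] <- vals[ok] + w[ok] * vol$values[I[ok, , drop = FALSE]]
    }
  }
  out <- array(vals, dim = ref$shape)
  if (is_labels) out <- round(out)
  scalar_volume(out, ref, vol$units, timestamp = vol$timestamp,
                nuclide = vol$nuclide)
}

#' Read and write a study manifest
#'
#' The manifest is a JSON file tying a study together: subject metadata
#' (injected activity in MBq at injection time, subject mass in kg), paths to
#' the density and label volumes and an ordered list of activity frames
#' (path, acquisition time in hours post injection, nuclide).  Paths are
#' stored relative to the manifest.
#'
#' @param study A `phantom_study` (see [build_phantom()]).
#' @param dir Output directory; created if needed.
#' @return `write_study` writes all volumes plus `manifest.json` and returns
#'   the manifest path; `read_manifest` returns a `phantom_study`-shaped list
#'   with frames, density, labels and meta.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(study$density, file.path(dir, "density.nii.gz"))
  write_volume(study$labels$label_volume, file.path(dir, "labels.nii.gz"))
  frames <- list()
  for (i in seq_along(study$frames)) {
    fn <- sprintf("frame_%02d.nii.gz", i)
    write_volume(study$frames[[i]], file.path(dir, fn))
    frames[[i]] <- list(path = fn, time_h = study$frames[[i]]$timestamp,
                        nuclide = study$frames[[i]]$nuclide)
  }
  manifest <- list(
    subject_id = study$meta$subject_id,
    injected_activity_mbq = study$meta$injected_activity_mbq,
    subject_mass_kg = study$meta$subject_mass_kg,
    injection_time_h = 0,
    density = "density.nii.gz",
    labels = "labels.nii.gz",
    roi_names = as.list(study$labels$names),
    frames = frames)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_study
#' @param path Path to a `manifest.json`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("injected_activity_mbq", "subject_mass_kg"))
    if (is.null(m[[field]]) || m[[field]] <= 0)
      stop("manifest missing or non-positive ", field)
  times <- vapply(m$frames, `[[`, numeric(1), "time_h")
  if (any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0)[1]
    stop("frame times must be strictly increasing; frames ", i, " and ", i + 1,
         " have times ", times[i], " and ", times[i + 1], " h")
  }
  dir <- dirname(path)
  density <- read_volume(file.path(dir, m$density), units = "g/cm^3")
  labels <- read_volume(file.path(dir, m$labels), units = "dimensionless")
  rois <- roi_set(labels, unlist(m$roi_names))
  frames <- lapply(m$frames, function(f) {
    v <- read_volume(file.path(dir, f$path))
    v$timestamp <- v$timestamp %||% f$time_h
    v$nuclide <- v$nuclide %||% f$nuclide
    v
  })
  meta <- study_meta(injected_activity_mbq = m$injected_activity_mbq,
                     subject_mass_kg = m$subject_mass_kg,
                     subject_id = m$subject_id %||% "subject")
  structure(list(grid = density$grid, density = density, labels = rois,
                 frames = frames, meta = meta, excretion = NULL),
            class = "phantom_study")
}

#' Study-level subject metadata
#'
#' @param injected_activity_mbq Injected activity at injection time, MBq (> 0).
#' @param subject_mass_kg Subject mass, kg (> 0).
#' @param subject_id Identifier.
#' @return Object of class `study_meta`.  Injection time is the time origin
#'   (0 h) for all decay arithmetic.
#' @export
study_meta <- function(injected_activity_mbq, subject_mass_kg,
                       subject_id = "subject") {
  if (injected_activity_mbq <= 0) stop("injected activity must be > 0 MBq")
  if (subject_mass_kg <= 0) stop("subject mass must be > 0 kg")
  structure(list(injected_activity_mbq = injected_activity_mbq,
                 subject_mass_kg = subject_mass_kg,
                 injection_time_h = 0,
                 subject_id = subject_id),
            class = "study_meta")
}
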