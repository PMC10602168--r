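#' A 3D image volume with physical voxel spacing
#'
#' The basic spatial container of the package: a 3D scalar lattice together
#' with its voxel spacing in mm and, for dynamic series, the acquisition time
#' in minutes after the end of tracer infusion. Physical coordinates are
#' voxel-centre positions, `(index - 1) * spacing`, in the volume's own frame;
#' volumes in one analysis are assumed co-registered.
#'
#' @param values A numeric (or, for masks, logical) 3D array with finite
#'   values.
#' @param spacing Voxel spacing in mm along each axis, length 3, strictly
#'   positive.
#' @param time_min Acquisition time in minutes after the end of infusion
#'   (`NA` for volumes without a timepoint, e.g. diffusion-weighted ones).
#' @param kind One of `"concentration"`, `"t1_signal"`, `"dw_signal"`,
#'   `"scalar_map"`, `"mask"`.
#'
#' @return An object of class `image_volume`: a list with elements `values`,
#'   `spacing`, `time_min` and `kind`.
#' @export
#' @examples
#' v <- image_volume(array(0, c(4, 4, 4)), spacing = c(0.125, 0.125, 0.167))
#' dim(v$values)
image_volume <- function(values, spacing, time_min = NA_real_,
                         kind = c("concentration", "t1_signal", "dw_signal",
                                  "scalar_map", "mask")) {
  kind <- match.arg(kind)
  if (!(is.array(values) && length(dim(values)) == 3)) {
    abort_input("`values` must be a 3D array")
  }
  if (!all(is.finite(values) | (kind == "mask" & !is.na(values)))) {
    abort_input("`values` must be finite everywhere")
  }
  spacing <- as_len3(spacing, "spacing")
  if (any(spacing <= 0)) abort_input("`spacing` must be strictly positive")
  if (!is.na(time_min) && (!is.numeric(time_min) || length(time_min) != 1)) {
    abort_input("`time_min` must be a single number or NA")
  }
  structure(
    list(values = values, spacing = spacing,
         time_min = as.numeric(time_min), kind = kind),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume> %s  %s voxels  spacing %s mm  t = %s min\n",
    x$kind, paste(dim(x$values), collapse = "x"),
    paste(signif(x$spacing, 4), collapse = "x"),
    ifelse(is.na(x$time_min), "NA", format(x$time_min))
  ))
  invisible(x)
}

# Accept either an image_volume or a bare 3D array wherever a volume is
# expected; returns the values array.
volume_values <- function(x, what = "volume") {
  if (inherits(x, "image_volume")) return(x$values)
  if (is.array(x) && length(dim(x)) == 3) return(x)
  abort_input(sprintf("`%s` must be an image_volume or a 3D array", what))
}

# As above for masks: coerces numeric {0,1} arrays to logical.
mask_values <- function(x, what = "mask") {
  v <- volume_values(x, what)
  if (is.logical(v)) return(v)
  if (all(v %in% c(0, 1))) return(v > 0.5)
  abort_input(sprintf("`%s` must be logical or contain only 0/1", what))
}

#' Read a NIfTI volume from disk
#'
#' Reads a NIfTI-1 file into an [image_volume], taking the voxel spacing from
#' the header `pixdim` field and attaching the supplied acquisition time.
#' Acquisition times are not parsed from headers: volumetric formats carry no
#' reliable post-infusion delay field, so timepoints travel in a sidecar
#' manifest (see [read_series_manifest()]).
#'
#' @param path Path to a NIfTI file.
#' @param time_min Minutes after the end of infusion for this volume.
#' @param kind Passed to [image_volume()].
#' @return An [image_volume].
#' @export
load_volume <- function(path, time_min = NA_real_, kind = "t1_signal") {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) {
    abort_input(sprintf("expected a 3D volume, got %d dimensions: %s",
                        length(d), path))
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    abort_input(sprintf("non-positive voxel spacing in header: %s", path))
  }
  image_volume(array(as.numeric(img), d), spacing = sp,
               time_min = time_min, kind = kind)
}

#' Write an image volume as NIfTI-1
#'
#' @param vol An [image_volume] (or 3D array plus `spacing`).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Required when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "image_volume")) {
    values <- vol$values
    spacing <- vol$spacing
  } else {
    values <- volume_values(vol)
    if (is.null(spacing)) abort_input("`spacing` is required for bare arrays")
    spacing <- as_len3(spacing, "spacing")
  }
  img <- RNifti::asNifti(array(as.numeric(values), dim(values)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a binary region-of-interest mask
#'
#' Reads a NIfTI mask with values in \{0, 1\} and checks its geometry against
#' a reference volume when one is given.
#'
#' @param path Path to a NIfTI mask.
#' @param reference Optional [image_volume] whose shape and spacing the mask
#'   must match.
#' @return A logical 3D array.
#' @export
load_mask <- function(path, reference = NULL) {
  vol <- load_volume(path, kind = "mask")
  m <- mask_values(vol$values, what = path)
  if (!is.null(reference)) {
    ref <- reference
    if (!identical(dim(m), dim(ref$values))) {
      abort_input(sprintf("mask shape does not match reference: %s", path))
    }
    if (max(abs(vol$spacing - ref$spacing)) > 1e-6) {
      abort_input(sprintf("mask spacing does not match reference: %s", path))
    }
  }
  m
}

#' Assemble co-registered volumes into a timepoint series
#'
#' Orders volumes by acquisition time and enforces the series contract:
#' at least two members, strictly increasing `time_min`, identical shape and
#' spacing throughout.
#'
#' @param volumes A list of [image_volume]s.
#' @return A `volume_series`: the sorted list with class attached.
#' @export
#' @examples
#' a <- image_volume(array(0, c(4, 4, 4)), c(1, 1, 1), time_min = 24)
#' b <- image_volume(array(0, c(4, 4, 4)), c(1, 1, 1), time_min = 4.5)
#' s <- assemble_series(list(a, b))
#' series_times(s)
assemble_series <- function(volumes) {
  if (!is.list(volumes) || !all(vapply(volumes, inherits, TRUE, "image_volume"))) {
    abort_input("`volumes` must be a list of image_volume objects")
  }
  if (length(volumes) < 2) {
    abort_input("a series needs at least 2 volumes")
  }
  times <- vapply(volumes, function(v) v$time_min, 0)
  if (anyNA(times)) abort_input("every volume in a series needs a time_min")
  if (anyDuplicated(times)) abort_input("duplicate timepoints in series")
  volumes <- volumes[order(times)]
  shp <- dim(volumes[[1]]$values)
  sp <- volumes[[1]]$spacing
  for (v in volumes[-1]) {
    if (!identical(dim(v$values), shp)) {
      abort_input("all volumes in a series must share the same shape")
    }
    if (max(abs(v$spacing - sp)) > 1e-6) {
      abort_input("all volumes in a series must share the same spacing")
    }
  }
  structure(list(volumes = volumes, spacing = sp, shape = shp),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series> %d volumes at t = %s min, %s voxels\n",
              length(x$volumes),
              paste(series_times(x), collapse = ", "),
              paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Acquisition times of a series
#' @param series A `volume_series`.
#' @return Numeric vector of timepoints in minutes, ascending.
#' @export
series_times <- function(series) {
  vapply(series$volumes, function(v) v$time_min, 0)
}

#' Read a timepoint-series manifest
#'
#' The manifest is a CSV with columns `path,time_min`; paths are resolved
#' relative to the manifest's directory. All volumes must be co-registered
#' 3D NIfTI files on a common grid.
#'
#' @param path Path to the manifest CSV.
#' @return A `volume_series`.
#' @export
read_series_manifest <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("path", "time_min") %in% names(tab))) {
    abort_input("series manifest needs columns `path` and `time_min`")
  }
  base <- dirname(normalizePath(path))
  vols <- purrr::map2(tab$path, tab$time_min, function(p, t) {
    full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    load_volume(full, time_min = t)
  })
  assemble_series(vols)
}
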