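#' Otsu's threshold over a 256-bin histogram
#'
#' Classical global thresholding: the input range is split into `n_bins`
#' equal-width bins and the cut between consecutive bins that maximises the
#' between-class variance is returned. Class statistics are accumulated from
#' the exact values falling in each bin (not bin midpoints), so the result
#' agrees exactly with an exhaustive search over the same candidate cuts.
#' Ties are broken toward the lower threshold.
#'
#' @param values A numeric vector with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (a bin edge); voxels with intensity strictly above
#'   it form the high class.
#' @export
#' @examples
#' otsu_threshold(c(rep(0, 50), rep(10, 50)))
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values) || any(!is.finite(values))) {
    abort_input("`values` must be finite and have length >= 2")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) {
    abort_input("degenerate input: all values are equal")
  }
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(pmax(floor((values - rng[1]) / width) + 1L, 1L), n_bins)
  cnt <- tabulate(bin, n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(values, bin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  n <- length(values)
  w0 <- cumsum(cnt)[1:(n_bins - 1)]
  s0 <- cumsum(sums)[1:(n_bins - 1)]
  stot <- sum(sums)
  w1 <- n - w0
  between <- rep(-Inf, n_bins - 1)
  ok <- w0 > 0 & w1 > 0
  # between-class variance up to the constant factor 1/n^2
  between[ok] <- ((s0 * n - stot * w0)^2 / (w0 * w1))[ok]
  k <- which.max(between)  # first maximum = lowest threshold on ties
  rng[1] + k * width
}

#' Segment tracer-containing tissue inside a manual ROI
#'
#' Splits the intensities inside the ROI into two classes with
#' [otsu_threshold()]; the higher-intensity class is the tissue containing
#' tracer. Optionally keeps only the largest 26-connected component, which
#' guards against noise-fragmented masks.
#'
#' @param volume An [image_volume] (or 3D array) of signal intensities.
#' @param roi Logical array (or 0/1 volume) of the same shape; must be
#'   non-empty.
#' @param largest_component If `TRUE`, restrict the mask to its largest
#'   26-connected component.
#' @return A logical mask array, a subset of `roi`.
#' @export
segment_tracer <- function(volume, roi, largest_component = FALSE) {
  vals <- volume_values(volume)
  roi <- mask_values(roi, "roi")
  if (!identical(dim(vals), dim(roi))) {
    abort_input("`roi` shape must match the volume shape")
  }
  if (!any(roi)) abort_input("`roi` is empty")
  thr <- otsu_threshold(vals[roi])
  mask <- roi & (vals > thr)
  if (largest_component && any(mask)) {
    mask <- largest_connected_component(mask)
  }
  mask
}

#' Largest 26-connected component of a mask
#'
#' @param mask Logical 3D array.
#' @return Logical array keeping only the largest component (ties broken by
#'   first-encountered component in array order).
#' @export
largest_connected_component <- function(mask) {
  mask <- mask_values(mask, "mask")
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(mask)
  lab <- integer(length(idx))
  names(lab) <- NULL
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)  # voxel linear index -> rank in idx
  ijk <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  cur_label <- 0L
  for (start in seq_along(idx)) {
    if (lab[start] != 0L) next
    cur_label <- cur_label + 1L
    queue <- start
    lab[start] <- cur_label
    while (length(queue)) {
      q <- ijk[queue, , drop = FALSE]
      nxt <- integer(0)
      for (r in seq_len(nrow(offs))) {
        nb <- sweep(q, 2, offs[r, ], `+`)
        keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(keep)) next
        nb <- nb[keep, , drop = FALSE]
        lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
        p <- pos[lin]
        p <- p[p > 0]
        p <- p[lab[p] == 0L]
        if (length(p)) {
          lab[p] <- cur_label
          nxt <- c(nxt, p)
        }
      }
      queue <- unique(nxt)
    }
  }
  sizes <- tabulate(lab, cur_label)
  best <- which.max(sizes)
  out <- array(FALSE, d)
  out[idx[lab == best]] <- TRUE
  out
}

#' Extract the boundary surface of a tracer mask
#'
#' The surface is the set of mask voxels with at least one face-adjacent
#' (6-connectivity) neighbour outside the mask or beyond the lattice edge --
#' equivalently the mask minus its 6-connectivity erosion. Voxel centres are
#' returned in physical mm.
#'
#' @param mask Logical 3D array; must be non-empty.
#' @param spacing Voxel spacing in mm (length 3).
#' @param time_min Timepoint tag for the surface.
#' @return A `tracer_surface`: a tibble with columns `x_mm`, `y_mm`, `z_mm`,
#'   attributes `time_min` and `n_points`.
#' @export
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
#' nrow(extract_boundary(m, c(1, 1, 1)))  # 26: all but the cube centre
extract_boundary <- function(mask, spacing, time_min = NA_real_) {
  mask <- mask_values(mask, "mask")
  spacing <- as_len3(spacing, "spacing")
  if (!any(mask)) abort_input("`mask` is empty")
  surf <- mask & !erode6(mask)
  ijk <- which(surf, arr.ind = TRUE)
  pts <- ijk_to_mm(ijk, spacing)
  out <- tibble::tibble(x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3])
  tracer_surface(out, time_min = time_min)
}

#' Construct a tracer surface from points
#'
#' @param points A data frame with columns `x_mm`, `y_mm`, `z_mm`.
#' @param time_min Timepoint in minutes.
#' @return A `tracer_surface` tibble.
#' @export
tracer_surface <- function(points, time_min = NA_real_) {
  points <- tibble::as_tibble(points)
  if (!all(c("x_mm", "y_mm", "z_mm") %in% names(points)) ||
      nrow(points) < 1) {
    abort_input("a surface needs >= 1 point with columns x_mm, y_mm, z_mm")
  }
  structure(points, time_min = as.numeric(time_min),
            n_points = nrow(points),
            class = c("tracer_surface", class(points)))
}

surface_points <- function(surface) {
  as.matrix(surface[, c("x_mm", "y_mm", "z_mm")])
}
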