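#' Nearest-point travel distances between two tracer surfaces
#'
#' For every point of the earlier surface, the Euclidean distance in mm to
#' the closest point of the later surface -- the distance the tracer front
#' travelled at that point between the two scans. Distances are computed in
#' physical coordinates, so anisotropic voxels are handled correctly.
#'
#' @param earlier,later `tracer_surface` objects (or data frames with
#'   `x_mm`, `y_mm`, `z_mm`), both non-empty and in the same physical frame.
#' @return A numeric vector of distances, one per point of `earlier`.
#' @export
#' @examples
#' s1 <- tracer_surface(data.frame(x_mm = 0, y_mm = 0, z_mm = 0))
#' s2 <- tracer_surface(data.frame(x_mm = c(1, 5), y_mm = 0, z_mm = 0))
#' nearest_distances(s1, s2)  # 1
nearest_distances <- function(earlier, later) {
  A <- surface_points(tracer_surface(earlier, attr(earlier, "time_min") %||% NA))
  B <- surface_points(tracer_surface(later, attr(later, "time_min") %||% NA))
  if (nrow(A) == 0 || nrow(B) == 0) abort_input("surfaces must be non-empty")
  out <- numeric(nrow(A))
  chunk <- 256L
  for (start in seq(1L, nrow(A), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(A))
    Ak <- A[rows, , drop = FALSE]
    # explicit coordinate differences keep exact zeros exact
    d2 <- outer(Ak[, 1], B[, 1], `-`)^2 +
      outer(Ak[, 2], B[, 2], `-`)^2 +
      outer(Ak[, 3], B[, 3], `-`)^2
    out[rows] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Per-point pseudo-ADC from travel distances
#'
#' Applies the mean-squared-displacement relation `ADC* = dist^2 / (2 d t)`
#' with dimensionality `d` (3 for volumetric data) and elapsed time `t` in
#' ms, turning each front travel distance into a diffusivity-like value in
#' mm^2/ms.
#'
#' @param distances Travel distances in mm.
#' @param dt_ms Elapsed time between the two surfaces in ms; positive.
#' @param d_dim Dimensionality (default 3).
#' @return Per-point ADC* values in mm^2/ms.
#' @export
#' @examples
#' pointwise_adcstar(0.3, dt_ms = 19.5 * 6e4)  # 1.282e-8 mm^2/ms
pointwise_adcstar <- function(distances, dt_ms, d_dim = 3L) {
  if (!is.numeric(dt_ms) || length(dt_ms) != 1 || dt_ms <= 0) {
    abort_input("`dt_ms` must be a single positive number")
  }
  if (d_dim < 1) abort_input("`d_dim` must be >= 1")
  if (any(distances < 0)) abort_input("distances must be >= 0")
  distances^2 / (2 * d_dim * dt_ms)
}

#' ADC* for one consecutive surface pair
#'
#' Computes nearest-point distances from the earlier to the later surface
#' and converts them to per-point ADC* values.
#'
#' @inheritParams nearest_distances
#' @param dt_ms Elapsed time in ms; taken from the surfaces' `time_min` tags
#'   when omitted.
#' @param d_dim Dimensionality, default 3.
#' @return A `surface_pair` tibble with columns `distance_mm` and `adcstar`,
#'   and attributes `dt_ms` and `d_dim`.
#' @export
surface_pair_adcstar <- function(earlier, later, dt_ms = NULL, d_dim = 3L) {
  if (is.null(dt_ms)) {
    t1 <- attr(earlier, "time_min")
    t2 <- attr(later, "time_min")
    if (is.null(t1) || is.null(t2) || is.na(t1) || is.na(t2)) {
      abort_input("surfaces carry no timepoints; supply `dt_ms`")
    }
    dt_ms <- (t2 - t1) * MIN_TO_MS
  }
  d <- nearest_distances(earlier, later)
  out <- tibble::tibble(distance_mm = d,
                        adcstar = pointwise_adcstar(d, dt_ms, d_dim))
  structure(out, dt_ms = dt_ms, d_dim = d_dim,
            class = c("surface_pair", class(out)))
}

#' Region-level diffusivity estimate
#'
#' The common result container of the two estimation routes: a one-row
#' tibble tagged with the region, the method (`"surface_adcstar"`,
#' `"dti_water"` or `"dti_scaled"`), the estimate in mm^2/ms, its standard
#' error and the number of contributing samples.
#'
#' @param region Region name.
#' @param value Estimate in mm^2/ms; must be `>= 0`.
#' @param se Standard error in mm^2/ms; `>= 0`.
#' @param method Estimation route.
#' @param n Number of contributing samples.
#' @return A `diffusivity_estimate` tibble with one row.
#' @export
diffusivity_estimate <- function(region, value, se, method, n) {
  if (value < 0 || se < 0) abort_input("value and se must be >= 0")
  out <- tibble::tibble(region = region, value = value, se = se,
                        method = method, n = as.integer(n))
  class(out) <- c("diffusivity_estimate", class(out))
  out
}

#' Pseudo-ADC of a tracer region from a timepoint series
#'
#' The full surface-propagation estimator: each timepoint of the series is
#' segmented inside its ROI with Otsu's threshold, the tracer boundary is
#' extracted, per-point ADC* values are computed for every consecutive
#' surface pair, and all per-point values are pooled into a mean with its
#' standard error (sample SD over the square root of the pooled point
#' count). A per-pair breakdown is attached as the `"pairs"` attribute.
#'
#' For a spreading tracer the surface sizes are expected to grow over time
#' (N1 < N2 < N3); when they do not, a warning is issued rather than an
#' error, since limited contrast-to-noise can break the expectation on real
#' data.
#'
#' @param series A `volume_series` of contrast-enhanced volumes.
#' @param rois A single logical ROI array reused at every timepoint, or a
#'   list of one ROI per timepoint.
#' @param region Region name for the report.
#' @param largest_component Passed to [segment_tracer()].
#' @param d_dim Dimensionality for the ADC* formula (default 3).
#' @return A [diffusivity_estimate()] with `method = "surface_adcstar"`;
#'   attribute `"pairs"` holds the per-pair summary tibble, attribute
#'   `"surfaces"` the extracted surfaces.
#' @export
region_adcstar <- function(series, rois, region = "roi",
                           largest_component = FALSE, d_dim = 3L) {
  stopifnot(inherits(series, "volume_series"))
  vols <- series$volumes
  nt <- length(vols)
  if (!is.list(rois) || is.array(rois)) rois <- rep(list(rois), nt)
  if (length(rois) != nt) {
    abort_input("`rois` must be one mask or one mask per timepoint")
  }
  surfaces <- vector("list", nt)
  for (i in seq_len(nt)) {
    mask <- tryCatch(
      segment_tracer(vols[[i]], rois[[i]], largest_component),
      error = function(e) {
        abort_input(sprintf("segmentation failed at t = %g min: %s",
                            vols[[i]]$time_min, conditionMessage(e)))
      })
    if (!any(mask)) {
      abort_input(sprintf("empty tracer mask at t = %g min", vols[[i]]$time_min))
    }
    surfaces[[i]] <- extract_boundary(mask, series$spacing,
                                      time_min = vols[[i]]$time_min)
  }
  ns <- vapply(surfaces, nrow, 0L)
  if (is.unsorted(ns, strictly = TRUE)) {
    warning("surface sizes do not grow strictly over time (N1 < N2 < ... ",
            "expected for a spreading tracer): ",
            paste(ns, collapse = ", "), call. = FALSE)
  }
  pooled <- numeric(0)
  pair_rows <- vector("list", nt - 1)
  for (i in seq_len(nt - 1)) {
    pr <- surface_pair_adcstar(surfaces[[i]], surfaces[[i + 1]], d_dim = d_dim)
    pooled <- c(pooled, pr$adcstar)
    pair_rows[[i]] <- tibble::tibble(
      t_from = vols[[i]]$time_min, t_to = vols[[i + 1]]$time_min,
      n = nrow(pr), mean_distance_mm = mean(pr$distance_mm),
      mean_adcstar = mean(pr$adcstar))
  }
  n <- length(pooled)
  se <- if (n > 1) stats::sd(pooled) / sqrt(n) else 0
  est <- diffusivity_estimate(region, mean(pooled), se,
                              method = "surface_adcstar", n = n)
  attr(est, "pairs") <- dplyr::bind_rows(pair_rows)
  attr(est, "surfaces") <- surfaces
  est
}
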