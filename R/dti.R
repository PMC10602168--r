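#' A voxelwise symmetric tensor field
#'
#' Lightweight container for the six unique components of a symmetric
#' diffusion tensor per voxel, in mm^2/ms, plus voxel spacing. Used both for
#' phantom ground truth and as the core of a fitted [fit_tensor()] map.
#'
#' @param comps A list of six 3D arrays named `xx`, `yy`, `zz`, `xy`, `xz`,
#'   `yz`, all of identical shape.
#' @param spacing Voxel spacing in mm.
#' @return A `tensor_field`.
#' @export
tensor_field <- function(comps, spacing) {
  need <- c("xx", "yy", "zz", "xy", "xz", "yz")
  if (!is.list(comps) || !all(need %in% names(comps))) {
    abort_input("`comps` must be a list with arrays xx, yy, zz, xy, xz, yz")
  }
  d <- dim(comps$xx)
  for (nm in need) {
    if (!identical(dim(comps[[nm]]), d)) {
      abort_input("tensor component arrays must share one shape")
    }
  }
  structure(list(comps = comps[need], spacing = as_len3(spacing, "spacing")),
            class = "tensor_field")
}

#' Default 6-direction gradient scheme
#'
#' The classical six-direction set on the face diagonals of the unit cube,
#' normalised to unit length: (1,1,0), (1,-1,0), (0,1,1), (0,1,-1), (1,0,1),
#' (-1,0,1), each divided by sqrt(2).
#'
#' @return A 6 x 3 matrix of unit vectors.
#' @export
default_directions <- function() {
  g <- rbind(c(1, 1, 0), c(1, -1, 0), c(0, 1, 1),
             c(0, 1, -1), c(1, 0, 1), c(-1, 0, 1))
  g / sqrt(2)
}

# design row per direction: signal exponent is -b * (g' D g) =
# -b * [gx^2, gy^2, gz^2, 2gxgy, 2gxgz, 2gygz] . [Dxx,Dyy,Dzz,Dxy,Dxz,Dyz]
tensor_design <- function(directions) {
  cbind(directions[, 1]^2, directions[, 2]^2, directions[, 3]^2,
        2 * directions[, 1] * directions[, 2],
        2 * directions[, 1] * directions[, 3],
        2 * directions[, 2] * directions[, 3])
}

check_directions <- function(directions) {
  if (!is.matrix(directions) || ncol(directions) != 3) {
    abort_input("`directions` must be a matrix with 3 columns")
  }
  if (nrow(directions) < 6) {
    abort_input("at least 6 gradient directions are required")
  }
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms - 1) > 1e-6)) {
    abort_input("every gradient direction must have unit norm (tol 1e-6)")
  }
  if (qr(tensor_design(directions))$rank < 6) {
    abort_input("gradient directions do not span a full-rank tensor design")
  }
  invisible(directions)
}

#' A diffusion-weighted acquisition
#'
#' One unweighted (b = 0) volume plus one diffusion-weighted volume per
#' gradient direction, with the common b-value in s/mm^2. All volumes must
#' share shape and spacing; the direction set must be unit-norm and span a
#' full-rank tensor design.
#'
#' @param s0_volume The unweighted [image_volume].
#' @param b_value Diffusion weighting in s/mm^2.
#' @param directions Matrix of unit gradient directions, one row per DW
#'   volume.
#' @param dw_volumes List of diffusion-weighted [image_volume]s, one per
#'   direction.
#' @return A `dwi_acquisition`.
#' @export
dwi_acquisition <- function(s0_volume, b_value, directions, dw_volumes) {
  stopifnot(inherits(s0_volume, "image_volume"))
  if (b_value <= 0) abort_input("b_value must be positive")
  directions <- as.matrix(directions)
  check_directions(directions)
  if (length(dw_volumes) != nrow(directions)) {
    abort_input("need exactly one DW volume per gradient direction")
  }
  shp <- dim(s0_volume$values)
  for (v in dw_volumes) {
    stopifnot(inherits(v, "image_volume"))
    if (!identical(dim(v$values), shp)) {
      abort_input("all DWI volumes must share the S0 volume's shape")
    }
    if (max(abs(v$spacing - s0_volume$spacing)) > 1e-6) {
      abort_input("all DWI volumes must share the S0 volume's spacing")
    }
  }
  structure(list(s0_volume = s0_volume, b_value = b_value,
                 directions = directions, dw_volumes = dw_volumes),
            class = "dwi_acquisition")
}

#' Read a DWI manifest
#'
#' CSV with columns `path,bval,gx,gy,gz`; the row with `bval = 0` names the
#' unweighted volume (its gradient entries are ignored). Paths resolve
#' relative to the manifest.
#'
#' @param path Manifest CSV path.
#' @return A [dwi_acquisition()].
#' @export
read_dwi_manifest <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("path", "bval", "gx", "gy", "gz")
  if (!all(need %in% names(tab))) {
    abort_input("DWI manifest needs columns path,bval,gx,gy,gz")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  b0 <- which(tab$bval == 0)
  if (length(b0) < 1) abort_input("DWI manifest must name one b = 0 volume")
  dw <- which(tab$bval > 0)
  bvals <- unique(tab$bval[dw])
  if (length(bvals) != 1) {
    abort_input("all weighted rows must share a single b-value")
  }
  s0 <- load_volume(resolve(tab$path[b0[1]]), kind = "dw_signal")
  vols <- lapply(tab$path[dw], function(p) {
    load_volume(resolve(p), kind = "dw_signal")
  })
  dwi_acquisition(s0, bvals, as.matrix(tab[dw, c("gx", "gy", "gz")]), vols)
}

#' Fit the diffusion tensor voxelwise
#'
#' Ordinary log-linear least squares: per voxel the system
#' `ln(S_g / S0) = -b g' D g` is solved for the six tensor components, the
#' tensor is eigendecomposed with eigenvalues sorted descending, and the
#' scalar maps FA, ADC, axial and radial diffusivity are filled. Voxels with
#' non-positive S0 or DW signal are excluded via the validity mask, as are
#' voxels where an eigenvalue had to be clamped to zero for the scalar maps.
#'
#' @param dwi A [dwi_acquisition()].
#' @param mask Optional logical array restricting the fit (e.g. an ROI);
#'   saves time on large volumes.
#' @return A `tensor_map`: a `tensor_field` plus arrays `l1 >= l2 >= l3`
#'   (mm^2/ms), `fa`, `adc`, `daxi`, `drad` and the logical `valid` mask.
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_acquisition"))
  s0 <- dwi$s0_volume$values
  shp <- dim(s0)
  ndir <- nrow(dwi$directions)
  if (is.null(mask)) {
    mask <- array(TRUE, shp)
  } else {
    mask <- mask_values(mask, "mask")
    if (!identical(dim(mask), shp)) abort_input("`mask` shape mismatch")
  }
  sig <- matrix(0, sum(mask), ndir)
  for (i in seq_len(ndir)) sig[, i] <- dwi$dw_volumes[[i]]$values[mask]
  s0v <- s0[mask]
  ok <- s0v > 0 & apply(sig > 0, 1, all)
  b_ms <- dwi$b_value * 1000
  B <- tensor_design(dwi$directions)
  # least-squares operator: comps = pinv(B) %*% y, y = -ln(S/S0)/b
  pinv <- solve(crossprod(B), t(B))
  y <- -log(sig[ok, , drop = FALSE] / s0v[ok]) / b_ms
  comps_ok <- y %*% t(pinv)  # n_ok x 6 (xx, yy, zz, xy, xz, yz)

  nm <- c("xx", "yy", "zz", "xy", "xz", "yz")
  comps <- stats::setNames(lapply(nm, function(i) array(NA_real_, shp)), nm)
  okidx <- which(mask)[ok]
  for (j in 1:6) comps[[nm[j]]][okidx] <- comps_ok[, j]

  if (nrow(comps_ok) == 0) abort_input("no voxel has positive signal to fit")
  ev <- matrix(0, nrow(comps_ok), 3)
  for (r in seq_len(nrow(comps_ok))) {
    Dm <- matrix(c(comps_ok[r, 1], comps_ok[r, 4], comps_ok[r, 5],
                   comps_ok[r, 4], comps_ok[r, 2], comps_ok[r, 6],
                   comps_ok[r, 5], comps_ok[r, 6], comps_ok[r, 3]), 3, 3)
    ev[r, ] <- eigen(Dm, symmetric = TRUE, only.values = TRUE)$values
  }
  # eigen() returns descending order; enforce it anyway
  ev <- t(apply(ev, 1, sort, decreasing = TRUE))
  clamped <- ev[, 3] < 0 | ev[, 2] < 0 | ev[, 1] < 0
  ev[ev < 0] <- 0

  out <- list(l1 = array(NA_real_, shp), l2 = array(NA_real_, shp),
              l3 = array(NA_real_, shp), fa = array(NA_real_, shp),
              adc = array(NA_real_, shp), daxi = array(NA_real_, shp),
              drad = array(NA_real_, shp))
  out$l1[okidx] <- ev[, 1]; out$l2[okidx] <- ev[, 2]; out$l3[okidx] <- ev[, 3]
  out$fa[okidx] <- fa_from_eigenvalues(ev[, 1], ev[, 2], ev[, 3])
  out$adc[okidx] <- adc_from_eigenvalues(ev[, 1], ev[, 2], ev[, 3])
  dd <- daxi_drad(ev[, 1], ev[, 2], ev[, 3])
  out$daxi[okidx] <- dd$daxi; out$drad[okidx] <- dd$drad
  valid <- array(FALSE, shp)
  valid[okidx] <- !clamped
  structure(c(tensor_field(comps, dwi$s0_volume$spacing),
              out, list(valid = valid)),
            class = c("tensor_map", "tensor_field"))
}

#' Fractional anisotropy from sorted eigenvalues
#'
#' `FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l1-l3)^2 + (l2-l3)^2) /
#' sqrt(l1^2 + l2^2 + l3^2)`, a normalised measure of diffusion
#' directionality in `[0, 1]`. Vectorised; all-zero voxels yield `NA`
#' (undefined, to be masked).
#'
#' @param l1,l2,l3 Eigenvalues (any consistent units).
#' @return FA values in `[0, 1]`, `NA` where all three eigenvalues are zero.
#' @export
#' @examples
#' fa_from_eigenvalues(2, 1, 1)  # 1/sqrt(6)
fa_from_eigenvalues <- function(l1, l2, l3) {
  num <- (l1 - l2)^2 + (l1 - l3)^2 + (l2 - l3)^2
  den <- l1^2 + l2^2 + l3^2
  out <- sqrt(0.5 * num / den)
  out[den == 0] <- NA_real_
  pmin(out, 1)
}

#' Mean diffusivity (ADC) from eigenvalues
#'
#' @inheritParams fa_from_eigenvalues
#' @return `(l1 + l2 + l3) / 3`, the tensor trace over 3.
#' @export
adc_from_eigenvalues <- function(l1, l2, l3) {
  (l1 + l2 + l3) / 3
}

#' Axial and radial diffusivity from sorted eigenvalues
#'
#' Axial diffusivity is the principal eigenvalue, radial diffusivity the
#' mean of the two minor ones; requires eigenvalues sorted descending.
#'
#' @inheritParams fa_from_eigenvalues
#' @return A list with vectors `daxi = l1` and `drad = (l2 + l3) / 2`.
#' @export
daxi_drad <- function(l1, l2, l3) {
  if (any(l1 < l2 - 1e-15) || any(l2 < l3 - 1e-15)) {
    abort_input("eigenvalues must be sorted descending (l1 >= l2 >= l3)")
  }
  list(daxi = l1, drad = (l2 + l3) / 2)
}

#' ROI-mean water ADC from a fitted tensor map
#'
#' Mean and standard error of the water ADC over the valid voxels of an ROI;
#' the input to the tortuosity scaling stage.
#'
#' @param map A `tensor_map` from [fit_tensor()].
#' @param roi Logical array (or 0/1 volume).
#' @param region Region name for the report.
#' @return A [diffusivity_estimate()] with `method = "dti_water"`.
#' @export
roi_mean_adc <- function(map, roi, region = "roi") {
  stopifnot(inherits(map, "tensor_map"))
  roi <- mask_values(roi, "roi")
  sel <- roi & map$valid
  if (!any(sel)) abort_input("ROI does not intersect the validity mask")
  vals <- map$adc[sel]
  n <- length(vals)
  se <- if (n > 1) stats::sd(vals) / sqrt(n) else 0
  diffusivity_estimate(region, mean(vals), se, method = "dti_water", n = n)
}
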