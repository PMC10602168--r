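# Internal array helpers shared by the simulator and the segmentation code.

# 1 minute = 6e4 ms; diffusivities are carried in mm^2/ms throughout,
# simulator time in minutes.
MIN_TO_MS <- 6e4

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(msg) stop(msg, call. = FALSE)

#' @noRd
as_len3 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3 || anyNA(x)) {
    abort_input(sprintf("`%s` must be a numeric vector of length 3", what))
  }
  as.numeric(x)
}

# Shift a 3D array by one voxel along `ax` in direction `dir` (+1 pulls the
# upper neighbour into each cell), filling the vacated face with `fill`.
shift_array <- function(A, ax, dir, fill = 0) {
  d <- dim(A)
  n <- d[ax]
  out <- array(fill, d)
  if (n < 2L) return(out)
  if (dir > 0) {
    switch(ax,
      out[1:(n - 1), , ] <- A[2:n, , ],
      out[, 1:(n - 1), ] <- A[, 2:n, ],
      out[, , 1:(n - 1)] <- A[, , 2:n]
    )
  } else {
    switch(ax,
      out[2:n, , ] <- A[1:(n - 1), , ],
      out[, 2:n, ] <- A[, 1:(n - 1), ],
      out[, , 2:n] <- A[, , 1:(n - 1)]
    )
  }
  out
}

# 6-connectivity binary erosion; voxels on the lattice edge always erode
# (the outside world counts as background).
erode6 <- function(mask) {
  out <- mask
  for (ax in 1:3) {
    for (dir in c(-1, 1)) {
      out <- out & shift_array(mask, ax, dir, fill = FALSE)
    }
  }
  out
}

# 6-connectivity binary dilation, `iter` times.
dilate6 <- function(mask, iter = 1L) {
  for (i in seq_len(iter)) {
    grown <- mask
    for (ax in 1:3) {
      for (dir in c(-1, 1)) {
        grown <- grown | shift_array(mask, ax, dir, fill = FALSE)
      }
    }
    mask <- grown
  }
  mask
}

# Physical voxel-centre coordinate arrays (mm) for a grid; index 1 sits at 0.
coord_axes <- function(dims, spacing) {
  lapply(1:3, function(ax) (seq_len(dims[ax]) - 1) * spacing[ax])
}

# Voxel-centre coordinates (mm) for the voxels in `ijk` (matrix of 1-based
# array indices, one row per voxel).
ijk_to_mm <- function(ijk, spacing) {
  sweep(ijk - 1, 2, spacing, `*`)
}
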