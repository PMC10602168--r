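# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive Otsu: try every candidate cut on the 256-bin grid, computing
# class statistics directly from the raw values; first (lowest) maximum wins.
otsu_oracle <- function(values, n_bins = 256L) {
  rng <- range(values)
  width <- (rng[2] - rng[1]) / n_bins
  best <- -Inf
  best_thr <- NA_real_
  for (k in 1:(n_bins - 1)) {
    thr <- rng[1] + k * width
    lo <- values[values <= thr]
    hi <- values[values > thr]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values)
    bc <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bc > best) {
      best <- bc
      best_thr <- thr
    }
  }
  best_thr
}

# O(N^2) nearest-neighbour distances, plain double loop.
brute_nn <- function(A, B) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      d2 <- sum((A[i, ] - B[j, ])^2)
      if (d2 < best) best <- d2
    }
    out[i] <- sqrt(best)
  }
  out
}

# Boundary voxels by direct neighbour inspection (independent of erode6).
boundary_oracle <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!mask[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (p in nb) {
      if (any(p < 1) || p[1] > d[1] || p[2] > d[2] || p[3] > d[3] ||
          !mask[p[1], p[2], p[3]]) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

mk_surface <- function(mat, time_min = NA_real_) {
  tracer_surface(data.frame(x_mm = mat[, 1], y_mm = mat[, 2], z_mm = mat[, 3]),
                 time_min = time_min)
}

random_spd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  lam <- stats::runif(3, 0.2e-6, 2e-6)
  Q %*% diag(lam) %*% t(Q)
}

# tensor_field with one constant tensor everywhere
uniform_tensor_field <- function(D, dims = c(3, 3, 3), spacing = c(1, 1, 1)) {
  tensor_field(list(xx = array(D[1, 1], dims), yy = array(D[2, 2], dims),
                    zz = array(D[3, 3], dims), xy = array(D[1, 2], dims),
                    xz = array(D[1, 3], dims), yz = array(D[2, 3], dims)),
               spacing)
}
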