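# Shared phantom fixtures. Unit tests run on a coarse grid with the same
# physical geometry as the default phantom; physics checks use an
# instantaneous point release so closed forms apply.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 24), spacing = c(0.25, 0.25, 0.334),
               t1_noise_sigma = 0, dw_noise_sigma = 0, ...)
}

impulse_spec <- function(D = 1e-6, grid = c(48, 48, 48),
                         spacing = c(0.2, 0.2, 0.2), velocity = NULL,
                         amount = 1) {
  ext <- grid * spacing
  phantom_spec(
    grid_shape = grid, spacing = spacing,
    striatum_center = ext / 2, striatum_radius = min(ext) / 8,
    callosum_slab = list(x = c(0.4, ext[1] - 0.4), y = c(0.4, ext[2] - 0.4),
                         z = c(ext[3] - 1.2, ext[3] - 0.4)),
    tracer_diffusivity = D, velocity = velocity,
    source = list(center = ext / 2, total_amount = amount,
                  start_min = 0, stop_min = 0),
    t1_noise_sigma = 0, dw_noise_sigma = 0)
}

# mean and variance of the concentration cloud along each axis (mm, mm^2)
conc_moments <- function(vol) {
  vals <- vol$values
  sp <- vol$spacing
  t(vapply(1:3, function(ax) {
    marg <- apply(vals, ax, sum)
    x <- (seq_along(marg) - 1) * sp[ax]
    mu <- sum(marg * x) / sum(marg)
    c(mean = mu, var = sum(marg * (x - mu)^2) / sum(marg))
  }, c(mean = 0, var = 0)))
}

total_mass <- function(vol) sum(vol$values) * prod(vol$spacing)

# centroid (mm) of the half-maximum concentration region
halfmax_centroid <- function(vol) {
  m <- vol$values >= 0.5 * max(vol$values)
  ijk <- which(m, arr.ind = TRUE)
  colMeans(sweep(ijk - 1, 2, vol$spacing, `*`))
}
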