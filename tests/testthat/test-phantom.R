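test_that("phantom geometry is validated", {
  expect_error(phantom_spec(striatum_center = c(1, 1, 1),
                            striatum_radius = 3), "outside")
  expect_error(phantom_spec(callosum_slab = list(x = c(0, 9), y = c(0, 8),
                                                 z = c(5, 6))), "outside")
  expect_error(phantom_spec(d_axial = 1e-7, d_radial = 2e-7), "d_axial")
  expect_error(small_spec(source = list(center = c(40, 4, 4), total_amount = 1,
                                        start_min = 0, stop_min = 1)),
               "outside")
})

test_that("build_phantom returns consistent ground truth", {
  spec <- small_spec()
  ph <- build_phantom(spec)
  # striatum mask equals brute-force voxel-centre containment
  d <- spec$grid_shape
  count <- 0L
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    p <- (c(i, j, k) - 1) * spec$spacing
    if (sum((p - spec$striatum_center)^2) <= spec$striatum_radius^2) {
      count <- count + 1L
    }
  }
  expect_identical(sum(ph$roi_masks$striatum), count)
  # zero velocity requested -> identically zero field
  expect_true(all(ph$velocity$vx == 0) && all(ph$velocity$vy == 0) &&
                all(ph$velocity$vz == 0))
  # slab tensors are cigar-shaped along x with the specified eigenvalues
  sl <- ph$roi_masks$callosum
  expect_true(all(ph$truth_eigenvalues$l1[sl] == spec$d_axial))
  expect_true(all(ph$truth_eigenvalues$l3[sl] == spec$d_radial))
  expect_true(all(ph$tensors$comps$xy[!sl] == 0))
})

test_that("a degenerate slab (axial = radial) has zero anisotropy", {
  spec <- small_spec(d_axial = 5e-7, d_radial = 5e-7)
  ph <- build_phantom(spec)
  sl <- ph$roi_masks$callosum
  fa <- fa_from_eigenvalues(ph$truth_eigenvalues$l1[sl],
                            ph$truth_eigenvalues$l2[sl],
                            ph$truth_eigenvalues$l3[sl])
  expect_true(all(fa == 0))
})

test_that("total tracer amount is conserved with the source off", {
  spec <- small_spec()
  snaps <- simulate_tracer(spec, c(4.5, 24, 28.5))
  masses <- vapply(snaps, total_mass, 0)
  expect_equal(masses[1], spec$source$total_amount, tolerance = 1e-9)
  expect_lt(abs(masses[3] - masses[1]) / masses[1], 1e-6)
  # and with advection too
  specv <- with_bulk_flow(small_spec(), speed = 0.05)
  mv <- vapply(simulate_tracer(specv, c(4.5, 24)), total_mass, 0)
  expect_lt(abs(mv[2] - mv[1]) / mv[1], 1e-6)
})

test_that("a point release spreads with per-axis variance 2 D t", {
  D <- 1e-6
  spec <- impulse_spec(D = D)
  times <- c(2, 4)
  snaps <- simulate_tracer(spec, times)
  for (i in seq_along(times)) {
    mom <- conc_moments(snaps[[i]])
    expected <- 2 * D * times[i] * 6e4  # mm^2 (minutes -> ms)
    for (ax in 1:3) {
      expect_lt(abs(mom[ax, "var"] - expected) / expected, 0.05)
    }
  }
})

test_that("with pure advection the cloud translates by v t", {
  v <- c(0.3, 0, 0.15)
  spec <- impulse_spec(D = 0, velocity = v)
  tt <- 4
  snap <- simulate_tracer(spec, tt)[[1]]
  mom <- conc_moments(snap)
  start <- spec$source$center
  expect_true(all(abs(mom[, "mean"] - (start + v * tt)) < spec$spacing))
})

test_that("timepoint validation works", {
  spec <- small_spec()
  expect_error(simulate_tracer(spec, c(-1, 4)), ">= 0")
  expect_error(simulate_tracer(spec, c(4, 2)), "ascending")
})

test_that("stronger flow moves the half-max contour further", {
  disp <- vapply(c(0, 0.15, 0.3), function(speed) {
    spec <- impulse_spec(D = 5e-7, velocity = c(speed, 0, 0))
    snaps <- simulate_tracer(spec, c(1, 3))
    sqrt(sum((halfmax_centroid(snaps[[2]]) - halfmax_centroid(snaps[[1]]))^2))
  }, 0)
  expect_true(all(diff(disp) > 0))
})

test_that("concentration_to_t1 applies the affine model", {
  conc <- image_volume(array(0, c(4, 4, 4)), c(1, 1, 1), 5)
  out <- concentration_to_t1(conc, gain = 2, baseline = 1)
  expect_true(all(out$values == 1))
  expect_equal(out$time_min, 5)
  conc$values[2, 3, 1] <- 3
  out <- concentration_to_t1(conc, gain = 2, baseline = 1)
  expect_equal(out$values[2, 3, 1], 7)
  # fixed seed -> identical noise realisation
  a <- concentration_to_t1(conc, 2, 1, noise_sigma = 1, seed = 9)
  b <- concentration_to_t1(conc, 2, 1, noise_sigma = 1, seed = 9)
  expect_identical(a$values, b$values)
  expect_error(concentration_to_t1(conc, gain = 0, baseline = 1), "gain")
})

test_that("simulate_dwi follows the monoexponential tensor model", {
  dims <- c(3, 3, 3)
  # zero tensor -> every DW volume equals s0
  z <- uniform_tensor_field(matrix(0, 3, 3), dims)
  acq <- simulate_dwi(z, b_value = 900, s0 = 50)
  for (v in acq$dw_volumes) expect_true(all(v$values == 50))
  # isotropic tensor -> s0 exp(-b d) for every direction
  d_iso <- 7e-7  # mm^2/ms; exponent uses b in ms/mm^2
  iso <- uniform_tensor_field(diag(rep(d_iso, 3)), dims)
  acq <- simulate_dwi(iso, b_value = 900, s0 = 100)
  for (v in acq$dw_volumes) {
    expect_equal(unique(as.vector(v$values)), 100 * exp(-9e5 * d_iso),
                 tolerance = 1e-12)
  }
  # diagonal tensor, gradient on x: exponent is b * Dxx
  D <- diag(c(2, 1, 1)) * 1e-6
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(0, 1, 1) / sqrt(2),
                c(1, 0, 1) / sqrt(2))
  acq <- simulate_dwi(uniform_tensor_field(D, dims), b_value = 900,
                      directions = dirs, s0 = 100)
  expect_equal(unique(as.vector(acq$dw_volumes[[1]]$values)),
               100 * exp(-1.8), tolerance = 1e-12)
  # acquisition validation
  expect_error(simulate_dwi(iso, directions = dirs[1:5, ]), "at least 6")
  expect_error(simulate_dwi(iso, directions = dirs * 1.01), "unit norm")
  # fixed seed -> bit-identical noise
  a <- simulate_dwi(iso, rician_sigma = 2, seed = 3)
  b <- simulate_dwi(iso, rician_sigma = 2, seed = 3)
  expect_identical(a$dw_volumes[[4]]$values, b$dw_volumes[[4]]$values)
})

test_that("identical spec and seed reproduce volumes bit for bit", {
  spec <- small_spec(seed = 5)
  a <- simulate_tracer(spec, c(4.5, 24))
  b <- simulate_tracer(spec, c(4.5, 24))
  expect_identical(a[[2]]$values, b[[2]]$values)
})
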