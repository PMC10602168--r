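test_that("noiseless round trip recovers random SPD tensors to 1e-8", {
  set.seed(21)
  dims <- c(4, 4, 4)
  nm <- c("xx", "yy", "zz", "xy", "xz", "yz")
  comps <- stats::setNames(lapply(nm, function(i) array(0, dims)), nm)
  truth <- array(0, c(prod(dims), 6))
  for (v in seq_len(prod(dims))) {
    D <- random_spd_tensor()
    vals <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    truth[v, ] <- vals
    for (j in 1:6) comps[[nm[j]]][v] <- vals[j]
  }
  tf <- tensor_field(comps, c(1, 1, 1))
  acq <- simulate_dwi(tf, b_value = 900)
  map <- fit_tensor(acq)
  for (j in 1:6) {
    expect_lt(max(abs(as.vector(map$comps[[nm[j]]]) - truth[, j])), 1e-8)
  }
  expect_true(all(map$valid))
  # scalar-map identities hold voxelwise
  expect_equal(map$adc, (map$l1 + map$l2 + map$l3) / 3, tolerance = 1e-12)
  expect_equal(map$adc, (map$daxi + 2 * map$drad) / 3, tolerance = 1e-12)
  expect_equal(map$adc, (map$comps$xx + map$comps$yy + map$comps$zz) / 3,
               tolerance = 1e-10)
  expect_true(all(map$l1 >= map$l2 & map$l2 >= map$l3))
  expect_true(all(map$fa >= 0 & map$fa <= 1))
})

test_that("FA has its closed-form values at the landmarks", {
  expect_equal(fa_from_eigenvalues(1, 1, 1), 0)
  expect_equal(fa_from_eigenvalues(1, 0, 0), 1)
  expect_equal(fa_from_eigenvalues(2, 1, 1), 1 / sqrt(6), tolerance = 1e-12)
  expect_true(is.na(fa_from_eigenvalues(0, 0, 0)))
})

test_that("ADC and axial/radial diffusivities follow the eigenvalues", {
  expect_equal(adc_from_eigenvalues(2, 1, 1), 4 / 3)
  expect_equal(adc_from_eigenvalues(0, 0, 0), 0)
  dd <- daxi_drad(2, 1, 1)
  expect_equal(dd$daxi, 2)
  expect_equal(dd$drad, 1)
  expect_equal(daxi_drad(3, 2, 1)$drad, 1.5)
  dd_iso <- daxi_drad(5, 5, 5)
  expect_equal(dd_iso$daxi, dd_iso$drad)
  expect_error(daxi_drad(1, 2, 1), "sorted")
})

test_that("the phantom slab fit recovers axial and radial truth", {
  spec <- small_spec()
  ph <- build_phantom(spec)
  acq <- simulate_dwi(ph$tensors)
  map <- fit_tensor(acq, mask = ph$roi_masks$callosum)
  sl <- ph$roi_masks$callosum
  expect_lt(max(abs(map$daxi[sl] - spec$d_axial)), 1e-8)
  expect_lt(max(abs(map$drad[sl] - spec$d_radial)), 1e-8)
  expect_equal(roi_mean_adc(map, sl)$value,
               (spec$d_axial + 2 * spec$d_radial) / 3, tolerance = 1e-8)
  # isotropic striatum has FA 0 (tolerance 1e-6)
  map2 <- fit_tensor(acq, mask = ph$roi_masks$striatum)
  expect_lt(max(map2$fa[ph$roi_masks$striatum]), 1e-6)
})

test_that("rank-deficient direction sets are rejected", {
  coplanar <- cbind(cos(seq(0, pi, length.out = 6)),
                    sin(seq(0, pi, length.out = 6)), 0)
  iso <- uniform_tensor_field(diag(rep(1e-6, 3)))
  expect_error(simulate_dwi(iso, directions = coplanar), "full-rank")
})

test_that("FA and ADC maps are invariant under a joint rotation", {
  set.seed(33)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  D <- random_spd_tensor()
  Dr <- R %*% D %*% t(R)
  dirs <- default_directions()
  dirs_r <- dirs %*% t(R)
  m1 <- fit_tensor(simulate_dwi(uniform_tensor_field(D), directions = dirs))
  m2 <- fit_tensor(simulate_dwi(uniform_tensor_field(Dr),
                                directions = dirs_r))
  expect_lt(max(abs(m1$fa - m2$fa)), 1e-8)
  expect_lt(max(abs(m1$adc - m2$adc)), 1e-8)
})

test_that("roi_mean_adc averages valid voxels with a standard error", {
  spec <- small_spec()
  ph <- build_phantom(spec)
  map <- fit_tensor(simulate_dwi(ph$tensors), mask = ph$roi_masks$striatum)
  est <- roi_mean_adc(map, ph$roi_masks$striatum, region = "striatum")
  expect_equal(est$value, spec$d_striatum, tolerance = 1e-10)
  expect_lt(est$se, 1e-12)
  expect_identical(est$method, "dti_water")
  expect_error(roi_mean_adc(map, ph$roi_masks$striatum & FALSE), "intersect")
  # half a / half b split averages to (a + b) / 2
  dims <- c(4, 4, 2)
  comps <- list(xx = array(2e-7, dims), yy = array(2e-7, dims),
                zz = array(2e-7, dims), xy = array(0, dims),
                xz = array(0, dims), yz = array(0, dims))
  comps$xx[, , 2] <- 6e-7; comps$yy[, , 2] <- 6e-7; comps$zz[, , 2] <- 6e-7
  map2 <- fit_tensor(simulate_dwi(tensor_field(comps, c(1, 1, 1))))
  expect_equal(roi_mean_adc(map2, array(TRUE, dims))$value, 4e-7,
               tolerance = 1e-10)
})

test_that("manifest-driven DWI loading reproduces the in-memory fit", {
  dir <- withr::local_tempdir()
  iso <- uniform_tensor_field(diag(c(1.2e-6, 0.4e-6, 0.4e-6)), c(4, 4, 4))
  acq <- simulate_dwi(iso, b_value = 900)
  write_volume(acq$s0_volume, file.path(dir, "b0.nii.gz"))
  rows <- c("path,bval,gx,gy,gz", "b0.nii.gz,0,0,0,0")
  for (i in seq_len(nrow(acq$directions))) {
    p <- sprintf("dw%d.nii.gz", i)
    write_volume(acq$dw_volumes[[i]], file.path(dir, p))
    rows <- c(rows, sprintf("%s,900,%.10f,%.10f,%.10f", p,
                            acq$directions[i, 1], acq$directions[i, 2],
                            acq$directions[i, 3]))
  }
  writeLines(rows, file.path(dir, "dwi.csv"))
  acq2 <- read_dwi_manifest(file.path(dir, "dwi.csv"))
  map <- fit_tensor(acq2)
  expect_equal(unique(round(as.vector(map$adc), 12)),
               round((1.2e-6 + 0.8e-6) / 3, 12))
})
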