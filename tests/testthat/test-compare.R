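test_that("percent difference reproduces the published worked values", {
  expect_equal(round(percent_difference(3.64e-8, 1.75e-8)), 70)
  expect_equal(round(percent_difference(2.67e-8, 1.97e-8)), 30)
  expect_equal(percent_difference(5, 5), 0)
  # antisymmetry and sign convention
  expect_equal(percent_difference(3, 1), -percent_difference(1, 3))
  expect_gt(percent_difference(3, 1), 0)
  expect_error(percent_difference(1, -1), "positive")
})

test_that("the pooled-variance t-test matches a hand calculation", {
  a <- c(2.1, 2.9, 3.0, 2.5)
  b <- c(1.1, 1.5, 1.3, 1.2)
  got <- two_sample_ttest(a, b)
  # textbook pooled-variance formula, written out independently
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p_hand <- 2 * pt(-abs(t_hand), df = na + nb - 2)
  expect_equal(got$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(got$p_value, p_hand, tolerance = 1e-12)
  expect_equal(got$df, na + nb - 2)

  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  apart <- two_sample_ttest(c(1, 2, 3), c(101, 102, 103))
  expect_lt(apart$p_value, 1e-3)
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
  expect_error(two_sample_ttest(c(2, 2), c(2, 2)), "zero variance")
})

test_that("t-test and permutation test agree on the side of 0.05", {
  perm_p <- function(a, b) {
    pool <- c(a, b)
    obs <- abs(mean(a) - mean(b))
    ids <- utils::combn(length(pool), length(a))
    hits <- 0
    for (k in seq_len(ncol(ids))) {
      ga <- pool[ids[, k]]
      gb <- pool[-ids[, k]]
      if (abs(mean(ga) - mean(gb)) >= obs - 1e-12) hits <- hits + 1
    }
    hits / ncol(ids)
  }
  null_a <- c(1.02, 0.97, 1.05, 0.99)
  null_b <- c(1.01, 0.98, 1.04, 1.00)
  sep_a <- c(3.1, 3.3, 2.9, 3.2)
  sep_b <- c(1.0, 1.2, 0.9, 1.1)
  expect_gt(two_sample_ttest(null_a, null_b)$p_value, 0.05)
  expect_gt(perm_p(null_a, null_b), 0.05)
  expect_lt(two_sample_ttest(sep_a, sep_b)$p_value, 0.05)
  expect_lt(perm_p(sep_a, sep_b), 0.05)
})

test_that("a single-subject run reports estimates with NA statistics", {
  cfg <- phantom_config(small_spec(), n_subjects = 1)
  res <- run_pipeline(cfg)
  expect_s3_class(res, "group_result")
  expect_identical(sort(res$region), c("callosum", "striatum"))
  expect_true(all(is.na(res$t_stat)))
  expect_true(all(is.na(res$p_value)))
  expect_true(all(res$mean_adc_dti > 0))
  subj <- attr(res, "subjects")
  expect_identical(nrow(subj), 2L)
})

test_that("the pipeline writes report files and supports broom/ggplot", {
  out <- withr::local_tempdir()
  cfg <- phantom_config(small_spec(seed = 2), n_subjects = 2)
  res <- run_pipeline(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "report.tsv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  rep <- readr::read_tsv(file.path(out, "report.tsv"), show_col_types = FALSE)
  expect_identical(nrow(rep), 4L)  # 2 regions x 2 methods
  expect_true(all(c("region", "method", "mean", "se", "n", "t_stat",
                    "p_value", "pct_difference") %in% names(rep)))
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_identical(sort(names(js)), c("callosum", "striatum"))
  td <- tidy(res)
  expect_identical(nrow(td), 4L)
  gl <- glance(res)
  expect_identical(gl$n_regions, 2L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("phantom cohorts separate bulk flow from pure diffusion", {
  # noise-bearing cohorts on the coarse grid: the advected cohort's ADC*
  # exceeds its DTI-scaled prediction; the diffusion-only cohort stays below
  base <- small_spec(seed = 8)
  res0 <- run_pipeline(phantom_config(base, n_subjects = 3))
  resv <- run_pipeline(phantom_config(with_bulk_flow(base, speed = 0.05),
                                      n_subjects = 3))
  s0 <- res0[res0$region == "striatum", ]
  sv <- resv[resv$region == "striatum", ]
  expect_gt(sv$mean_adcstar, s0$mean_adcstar)
  expect_lt(s0$mean_adcstar, s0$mean_adc_dti)
  # DTI-scaled prediction is blind to flow
  expect_equal(sv$mean_adc_dti, s0$mean_adc_dti, tolerance = 1e-6)
})

test_that("the data-mode pipeline reproduces a phantom subject from disk", {
  dir <- withr::local_tempdir()
  spec <- small_spec()
  conc <- simulate_tracer(spec, c(4.5, 24, 28.5))
  ph <- build_phantom(spec)
  rows <- c("path,time_min")
  for (i in seq_along(conc)) {
    t1 <- concentration_to_t1(conc[[i]], gain = 100 / max(conc[[i]]$values),
                              baseline = 100)
    write_volume(t1, file.path(dir, sprintf("t1_%d.nii.gz", i)))
    rows <- c(rows, sprintf("t1_%d.nii.gz,%g", i, conc[[i]]$time_min))
  }
  writeLines(rows, file.path(dir, "series.csv"))
  roi <- tracer_roi(conc[[3]], region = !ph$roi_masks$callosum)
  write_volume(roi * 1, file.path(dir, "roi.nii.gz"), spacing = spec$spacing)
  acq <- simulate_dwi(ph$tensors)
  write_volume(acq$s0_volume, file.path(dir, "b0.nii.gz"))
  drows <- c("path,bval,gx,gy,gz", "b0.nii.gz,0,0,0,0")
  for (i in seq_len(nrow(acq$directions))) {
    write_volume(acq$dw_volumes[[i]], file.path(dir, sprintf("dw%d.nii.gz", i)))
    drows <- c(drows, sprintf("dw%d.nii.gz,900,%.10f,%.10f,%.10f", i,
                              acq$directions[i, 1], acq$directions[i, 2],
                              acq$directions[i, 3]))
  }
  writeLines(drows, file.path(dir, "dwi.csv"))
  cfg <- data_config(
    subjects = list(list(id = "rat1",
                         series_manifest = file.path(dir, "series.csv"),
                         dwi_manifest = file.path(dir, "dwi.csv"),
                         rois = list(striatum = file.path(dir, "roi.nii.gz")))),
    regions = "striatum")
  res <- suppressWarnings(run_pipeline(cfg))
  expect_identical(res$region, "striatum")
  expect_true(is.na(res$p_value))
  # the water ADC inside the ROI is striatal, so the scaled prediction is too
  expect_equal(res$mean_adc_dti,
               scale_to_tracer(spec$d_striatum), tolerance = 0.12)
})

test_that("stage failures name the subject, region and stage", {
  cfg <- data_config(subjects = list(list(id = "rat9",
                                          series_manifest = "missing.csv",
                                          dwi_manifest = "missing2.csv",
                                          rois = list(striatum = "m.nii"))),
                     regions = "striatum")
  expect_error(run_pipeline(cfg), "subject rat9.*read_series")
})
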