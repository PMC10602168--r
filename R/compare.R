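#' Symmetric percent difference between two group means
#'
#' `100 * (a - b) / ((a + b) / 2)`: the difference expressed relative to the
#' mean of the two values, so it is antisymmetric in its arguments and its
#' sign follows `a - b`. This symmetric definition is the one that
#' reproduces the published worked examples for both analysis regions, which
#' plain ratios to either group do not.
#'
#' @param a,b Group means (same units); `a + b` must be positive.
#' @return The percent difference.
#' @export
#' @examples
#' percent_difference(3.64e-8, 1.75e-8)  # about 70
#' percent_difference(2.67e-8, 1.97e-8)  # about 30
percent_difference <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) abort_input("a and b must be numeric")
  if (any(a + b <= 0)) abort_input("a + b must be positive")
  100 * (a - b) / ((a + b) / 2)
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided Student t-test with pooled variance on
#' `n_a + n_b - 2` degrees of freedom, the standard small-sample comparison
#' of two independent groups.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2, with
#'   non-zero pooled variance.
#' @return A list with `t_stat`, `p_value` and `df`.
#' @export
two_sample_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort_input("each group needs at least 2 values")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    abort_input("zero variance in both groups")
  }
  fit <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t_stat = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter))
}

#' Configuration for a synthetic-cohort study
#'
#' Bundles everything [run_pipeline()] needs to run the full analysis on
#' simulated subjects: a phantom, the number of replicate subjects
#' (independent noise realisations of the same physics), imaging timepoints,
#' the manual-ROI emulation parameters, and the free-diffusion constants.
#'
#' @param spec A [phantom_spec()] (add bulk flow with [with_striatal_flow()]
#'   for an advection cohort).
#' @param n_subjects Number of replicate subjects.
#' @param timepoints Imaging times in minutes after the end of infusion.
#' @param regions Regions to analyse (subset of `"striatum"`,
#'   `"callosum"`).
#' @param roi_frac,roi_margin Passed to [tracer_roi()].
#' @param largest_component Restrict tracer masks to their largest
#'   26-connected component; recommended whenever noise is simulated.
#' @param constants A [free_diffusion_constants()].
#' @param baseline,peak_enhancement T1 signal model: pre-contrast level and
#'   the enhancement assigned to the concentration maximum of the first
#'   timepoint (emulates scanner windowing).
#' @return A `phantom_config` list for [run_pipeline()].
#' @export
phantom_config <- function(spec, n_subjects = 5L,
                           timepoints = c(4.5, 24, 28.5),
                           regions = c("striatum", "callosum"),
                           roi_frac = 0.1, roi_margin = 2L,
                           largest_component = TRUE,
                           constants = free_diffusion_constants(),
                           baseline = 100, peak_enhancement = 100) {
  stopifnot(inherits(spec, "phantom_spec"))
  regions <- match.arg(regions, several.ok = TRUE)
  structure(list(mode = "phantom", spec = spec,
                 n_subjects = as.integer(n_subjects),
                 timepoints = timepoints, regions = regions,
                 roi_frac = roi_frac, roi_margin = roi_margin,
                 largest_component = largest_component,
                 constants = constants, baseline = baseline,
                 peak_enhancement = peak_enhancement),
            class = "phantom_config")
}

#' Configuration for a real-data study
#'
#' @param subjects A list, one element per subject, each a list with
#'   `series_manifest` (CSV `path,time_min`), `dwi_manifest` (CSV
#'   `path,bval,gx,gy,gz`) and `rois`: a named list mapping each region to
#'   one NIfTI mask path (reused at every timepoint) or one path per
#'   timepoint.
#' @param regions Region names to analyse.
#' @param constants A [free_diffusion_constants()].
#' @param largest_component Passed to the segmentation stage.
#' @return A `data_config` list for [run_pipeline()].
#' @export
data_config <- function(subjects, regions,
                        constants = free_diffusion_constants(),
                        largest_component = FALSE) {
  structure(list(mode = "data", subjects = subjects, regions = regions,
                 constants = constants,
                 largest_component = largest_component),
            class = "data_config")
}

stage <- function(subject, region, name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("subject %s, region %s, stage %s: %s",
                 subject, region %||% "-", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full bulk-flow analysis pipeline
#'
#' For every subject and region, estimates the tracer's pseudo-ADC from the
#' serial contrast-enhanced volumes ([region_adcstar()]), the water ADC from
#' the diffusion-weighted acquisition ([fit_tensor()], [roi_mean_adc()]),
#' and the predicted purely diffusive tracer ADC ([scale_to_tracer()]); then
#' compares the per-subject ADC* values with the per-subject DTI-scaled
#' predictions region by region: pooled-variance t-test, symmetric percent
#' difference, and means with standard errors. ADC* above the DTI-scaled
#' prediction indicates transport beyond diffusion, i.e. convective bulk
#' flow.
#'
#' With a single subject the group statistics are reported as `NA`.
#'
#' @param config A [phantom_config()] or [data_config()].
#' @param out_dir Optional directory; when given, writes `report.tsv`
#'   (region, method, mean, se, n, t, p, pct_diff) and `summary.json`.
#' @return A `group_result` tibble, one row per region, with columns
#'   `region`, `mean_adcstar`, `se_adcstar`, `mean_adc_dti`, `se_adc_dti`,
#'   `n_a`, `n_b`, `t_stat`, `p_value`, `pct_difference`. Per-subject
#'   estimates are attached as the `"subjects"` attribute.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  subjects_tab <- switch(class(config)[1],
    phantom_config = pipeline_phantom_subjects(config),
    data_config = pipeline_data_subjects(config),
    abort_input("`config` must come from phantom_config() or data_config()")
  )
  res <- group_compare(subjects_tab)
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

# Per-subject estimates for a synthetic cohort. The tracer physics is
# deterministic given the spec, so concentration fields are simulated once
# and subjects differ by their noise realisations.
pipeline_phantom_subjects <- function(config) {
  spec <- config$spec
  conc <- simulate_tracer(spec, config$timepoints)
  phantom <- build_phantom(spec)
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    subj <- sprintf("sim%02d", i)
    # each scan is windowed to its own peak enhancement, a crude emulation
    # of display windowing / enhancement saturation; Otsu is affine
    # invariant per volume, so this only matters relative to the noise floor
    t1_vols <- lapply(seq_along(conc), function(j) {
      concentration_to_t1(conc[[j]],
                          gain = config$peak_enhancement / max(conc[[j]]$values),
                          baseline = config$baseline,
                          noise_sigma = spec$t1_noise_sigma,
                          seed = spec$seed + 7919L * i + j)
    })
    series <- assemble_series(t1_vols)
    dwi <- stage(subj, NULL, "simulate_dwi",
      simulate_dwi(phantom$tensors, rician_sigma = spec$dw_noise_sigma,
                   seed = spec$seed + 104729L * i))
    fit_mask <- Reduce(`|`, phantom$roi_masks[config$regions])
    map <- stage(subj, NULL, "fit_tensor", fit_tensor(dwi, mask = fit_mask))
    for (region in config$regions) {
      # the "infusion site" ROI follows the tracer through all non-slab
      # tissue; the callosum ROI is the tracer inside the slab
      tr_region <- if (region == "striatum") {
        !phantom$roi_masks$callosum
      } else {
        phantom$roi_masks[[region]]
      }
      rois <- lapply(conc, function(cv) {
        tracer_roi(cv, frac = config$roi_frac, margin = config$roi_margin,
                   region = tr_region)
      })
      est_star <- stage(subj, region, "region_adcstar", suppressWarnings(
        region_adcstar(series, rois, region = region,
                       largest_component = config$largest_component)))
      water <- stage(subj, region, "roi_mean_adc",
                     roi_mean_adc(map, phantom$roi_masks[[region]], region))
      scaled <- stage(subj, region, "scale_to_tracer",
                      scale_to_tracer(water, config$constants))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = subj, region = region,
        adcstar = est_star$value, adcstar_se = est_star$se,
        adc_water = water$value, adc_scaled = scaled$value,
        adc_scaled_se = scaled$se)
    }
  }
  dplyr::bind_rows(rows)
}

pipeline_data_subjects <- function(config) {
  rows <- list()
  for (i in seq_along(config$subjects)) {
    sub <- config$subjects[[i]]
    subj <- sub$id %||% sprintf("subject%02d", i)
    series <- stage(subj, NULL, "read_series",
                    read_series_manifest(sub$series_manifest))
    dwi <- stage(subj, NULL, "read_dwi", read_dwi_manifest(sub$dwi_manifest))
    map <- stage(subj, NULL, "fit_tensor", fit_tensor(dwi))
    for (region in config$regions) {
      roi_paths <- sub$rois[[region]]
      if (is.null(roi_paths)) {
        stop(sprintf("subject %s: no ROI given for region %s", subj, region),
             call. = FALSE)
      }
      rois <- lapply(roi_paths, function(p) {
        stage(subj, region, "load_mask", load_mask(p, series$volumes[[1]]))
      })
      if (length(rois) == 1) rois <- rois[[1]]
      est_star <- stage(subj, region, "region_adcstar",
        region_adcstar(series, rois, region = region,
                       largest_component = config$largest_component))
      # DTI ROI: the last (largest) tracer ROI stands in for the map ROI
      droi <- if (is.list(rois)) rois[[length(rois)]] else rois
      water <- stage(subj, region, "roi_mean_adc",
                     roi_mean_adc(map, droi, region))
      scaled <- stage(subj, region, "scale_to_tracer",
                      scale_to_tracer(water, config$constants))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = subj, region = region,
        adcstar = est_star$value, adcstar_se = est_star$se,
        adc_water = water$value, adc_scaled = scaled$value,
        adc_scaled_se = scaled$se)
    }
  }
  dplyr::bind_rows(rows)
}

# Region-level comparison of per-subject ADC* vs DTI-scaled predictions.
group_compare <- function(subjects_tab) {
  out <- subjects_tab |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(function(df, key) {
      a <- df$adcstar
      b <- df$adc_scaled
      n <- nrow(df)
      tt <- if (n >= 2 && (stats::var(a) > 0 || stats::var(b) > 0)) {
        two_sample_ttest(a, b)
      } else {
        list(t_stat = NA_real_, p_value = NA_real_)
      }
      tibble::tibble(
        mean_adcstar = mean(a), se_adcstar = se_of(a),
        mean_adc_dti = mean(b), se_adc_dti = se_of(b),
        n_a = n, n_b = n,
        t_stat = tt$t_stat, p_value = tt$p_value,
        pct_difference = percent_difference(mean(a), mean(b)))
    }) |>
    dplyr::ungroup()
  structure(out, subjects = subjects_tab,
            class = c("group_result", class(out)))
}

se_of <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0

#' Write the pipeline report files
#'
#' `report.tsv` holds one row per region and method (mean, SE, n) plus the
#' group statistics; `summary.json` the same in machine-readable form,
#' rounded the way the report prints (percent differences to 1 decimal,
#' p-values to 3).
#'
#' @param result A `group_result` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  long <- tidy_group_rows(result)
  readr::write_tsv(long, file.path(out_dir, "report.tsv"))
  js <- lapply(seq_len(nrow(result)), function(i) {
    r <- result[i, ]
    list(region = r$region,
         adcstar = list(mean = r$mean_adcstar, se = r$se_adcstar, n = r$n_a),
         adc_dti_scaled = list(mean = r$mean_adc_dti, se = r$se_adc_dti,
                               n = r$n_b),
         t_stat = r$t_stat,
         p_value = if (is.na(r$p_value)) NA else round(r$p_value, 3),
         pct_difference = round(r$pct_difference, 1))
  })
  names(js) <- result$region
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

tidy_group_rows <- function(result) {
  dplyr::bind_rows(
    tibble::tibble(region = result$region, method = "surface_adcstar",
                   mean = result$mean_adcstar, se = result$se_adcstar,
                   n = result$n_a, t_stat = result$t_stat,
                   p_value = ifelse(is.na(result$p_value), NA,
                                    round(result$p_value, 3)),
                   pct_difference = round(result$pct_difference, 1)),
    tibble::tibble(region = result$region, method = "dti_scaled",
                   mean = result$mean_adc_dti, se = result$se_adc_dti,
                   n = result$n_b, t_stat = result$t_stat,
                   p_value = ifelse(is.na(result$p_value), NA,
                                    round(result$p_value, 3)),
                   pct_difference = round(result$pct_difference, 1))
  ) |> dplyr::arrange(.data$region, .data$method)
}
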