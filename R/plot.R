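#' Bar plot of ADC* versus the DTI-scaled prediction
#'
#' Means with standard-error bars per region and method, the standard way
#' these region-level comparisons are presented: an ADC* bar rising above
#' the DTI-scaled bar signals transport beyond diffusion.
#'
#' @param object A `group_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_result
#' @export
autoplot.group_result <- function(object, ...) {
  df <- tidy_group_rows(object) |>
    dplyr::mutate(method = factor(.data$method,
                                  levels = c("surface_adcstar", "dti_scaled"),
                                  labels = c("ADC* (T1 series)",
                                             "ADC (DTI, scaled)")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$mean,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "diffusivity (mm²/ms)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one slice of a scalar map
#'
#' @param map A `tensor_map` from [fit_tensor()].
#' @param which Scalar map to show: `"fa"`, `"adc"`, `"daxi"` or `"drad"`.
#' @param z Slice index along the third axis (defaults to the middle).
#' @return A ggplot object.
#' @export
plot_map_slice <- function(map, which = c("fa", "adc", "daxi", "drad"),
                           z = NULL) {
  stopifnot(inherits(map, "tensor_map"))
  which <- match.arg(which)
  arr <- map[[which]]
  z <- z %||% ceiling(dim(arr)[3] / 2)
  sl <- arr[, , z]
  df <- tibble::tibble(i = rep(seq_len(nrow(sl)), times = ncol(sl)),
                       j = rep(seq_len(ncol(sl)), each = nrow(sl)),
                       value = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = toupper(which), x = NULL, y = NULL,
                  fill = which) +
    ggplot2::theme_minimal()
}
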