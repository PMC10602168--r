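#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a group comparison
#'
#' One row per region and estimation method, with the group statistics
#' repeated on both rows -- the long form used by the report writer and the
#' bar plot.
#'
#' @param x A `group_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble with columns `region`, `method`, `mean`, `se`, `n`,
#'   `t_stat`, `p_value`, `pct_difference`.
#' @method tidy group_result
#' @export
tidy.group_result <- function(x, ...) {
  tidy_group_rows(x)
}

#' One-line summary of a group comparison
#'
#' @param x A `group_result`.
#' @param ... Unused.
#' @return A tibble with one row: number of regions, number of subjects,
#'   the smallest p-value and how many regions have ADC* above the
#'   DTI-scaled prediction.
#' @method glance group_result
#' @export
glance.group_result <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x),
    n_subjects = max(x$n_a),
    min_p_value = suppressWarnings(min(x$p_value, na.rm = TRUE)),
    n_regions_excess = sum(x$mean_adcstar > x$mean_adc_dti)
  )
}

#' Tidy a surface pair
#'
#' @param x A `surface_pair` from [surface_pair_adcstar()].
#' @param ... Unused.
#' @return The underlying tibble plus `dt_ms` and `d_dim` columns.
#' @method tidy surface_pair
#' @export
tidy.surface_pair <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(dt_ms = attr(x, "dt_ms"), d_dim = attr(x, "d_dim"))
}
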