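#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' @param x An `mp_sim`.
#' @param ... Unused.
#' @return The recorded time series as a tibble (one row per record time).
#' @method tidy mp_sim
#' @export
tidy.mp_sim <- function(x, ...) x$timeseries

#' One-row summary of a simulation
#'
#' @param x An `mp_sim`.
#' @param ... Unused.
#' @return A one-row tibble: horizon, final tumor area and counts, mean
#'   phenotypes, cumulative kills, and the bottleneck statistic of the area
#'   trajectory.
#' @method glance mp_sim
#' @export
glance.mp_sim <- function(x, ...) {
  ts <- x$timeseries
  fin <- ts[nrow(ts), ]
  tibble::tibble(
    duration = max(ts$time),
    final_area_mm2 = fin$tumor_area_mm2,
    final_lesion_mm2 = fin$lesion_area_mm2,
    final_n_tumor = fin$n_tumor,
    final_n_tcells = fin$n_tcell_free + fin$n_tcell_engaged +
      fin$n_tcell_inactivated,
    final_n_vessels = fin$n_vessels,
    mean_pG = fin$mean_pG, mean_pH = fin$mean_pH, mean_pP = fin$mean_pP,
    n_kills = fin$n_kills_cum,
    bottleneck = bottleneck_statistic(ts$tumor_area_mm2),
    seed = x$config$seed)
}

#' Plot a simulation result
#'
#' Tumor area and T-cell counts over time, faceted.
#'
#' @param object An `mp_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mp_sim
#' @export
autoplot.mp_sim <- function(object, ...) {
  ts <- object$timeseries
  df <- dplyr::bind_rows(
    tibble::tibble(time = ts$time, value = ts$tumor_area_mm2,
                   series = "tumor area (mm2)"),
    tibble::tibble(time = ts$time,
                   value = ts$n_tcell_free + ts$n_tcell_engaged +
                     ts$n_tcell_inactivated,
                   series = "T-cells"),
    tibble::tibble(time = ts$time, value = as.numeric(ts$n_vessels),
                   series = "vessels"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (days)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a metaphenotype distribution
#'
#' Bar chart of expression mass (or fraction) per metaphenotype, optionally
#' split by a grouping column such as the treatment arm.
#'
#' @param mp_summary A tibble with columns `MP` and `expression_sum` (and
#'   optionally `fraction` and a grouping column).
#' @param y Which column to plot (`"expression_sum"` or `"fraction"`).
#' @param by Optional name of a grouping column for dodged bars.
#' @return A ggplot.
#' @export
plot_mp_distribution <- function(mp_summary, y = "expression_sum", by = NULL) {
  lab <- mp_labels[mp_summary$MP]
  mp_summary$label <- factor(lab, levels = unname(mp_labels))
  p <- ggplot2::ggplot(mp_summary,
                       ggplot2::aes(.data$label, .data[[y]]))
  if (is.null(by)) {
    p <- p + ggplot2::geom_col()
  } else {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data[[by]]),
                               position = "dodge")
  }
  p + ggplot2::labs(x = NULL, y = y) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom rlang .data
NULL
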