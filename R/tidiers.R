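#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy scenario results
#'
#' One row per intervention and scenario point with the per-couple benefit,
#' total annual saving and ART-only saving in EUR.
#'
#' @param x A `bia_scenarios` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bia_scenarios <- function(x, ...) {
  x$costs
}

#' @rdname tidy.bia_scenarios
#' @export
glance.bia_scenarios <- function(x, ...) {
  central <- x$costs[x$costs$scenario == "central", ]
  tibble(
    n_interventions = dplyr::n_distinct(x$costs$intervention),
    mode = x$mode,
    max_total_saving = max(central$total),
    best_intervention = central$intervention[which.max(central$total)],
    sum_central_saving = sum(central$total)
  )
}

#' Tidy PSA results
#'
#' @param x A `bia_psa` object.
#' @param ... Unused.
#' @return The per-intervention summary tibble (mean, sd, percentiles of
#'   total annual saving, EUR).
#' @export
tidy.bia_psa <- function(x, ...) {
  x$summary
}

#' @rdname tidy.bia_psa
#' @export
glance.bia_psa <- function(x, ...) {
  tibble(n_draws = x$n_draws, seed = x$seed, distribution = x$distribution,
         n_interventions = nrow(x$summary))
}

#' Tidy an audit report
#'
#' @param x A `bia_audit` object.
#' @param ... Unused.
#' @return The cell-by-cell record tibble.
#' @export
tidy.bia_audit <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.bia_audit
#' @export
glance.bia_audit <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_match = sum(x$status == "match"),
    n_mismatch = sum(x$status == "mismatch"),
    n_flagged = sum(x$status == "flagged-inconsistency"),
    n_not_recomputable = sum(x$status == "not-recomputable")
  )
}

#' Plot total annual savings with scenario bounds
#'
#' Point ranges of the central total annual saving per intervention with
#' least/most-favorable bounds, in millions of EUR.
#'
#' @param object A `bia_scenarios` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bia_scenarios <- function(object, ...) {
  wide <- object$costs |>
    dplyr::select("intervention", "scenario", "total") |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "total")
  ggplot2::ggplot(wide, ggplot2::aes(
    x = stats::reorder(.data$intervention, .data$central),
    y = .data$central / 1e6, ymin = .data$least / 1e6,
    ymax = .data$most / 1e6
  )) +
    ggplot2::geom_pointrange() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Total annual saving (EUR million)",
      title = "Budget impact with least/most-favorable scenario bounds"
    )
}

#' Plot the PSA distribution of total savings
#'
#' Histogram of Monte Carlo total annual savings per intervention, faceted,
#' with the empirical mean marked.
#'
#' @param object A `bia_psa` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bia_psa <- function(object, bins = 50, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$total / 1e6)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(
      data = object$summary,
      ggplot2::aes(xintercept = .data$mean / 1e6), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$intervention), scales = "free") +
    ggplot2::labs(
      x = "Total annual saving (EUR million)", y = "Draws",
      title = sprintf("Probabilistic sensitivity analysis (%s draws, %s)",
                      format(object$n_draws, big.mark = ","),
                      object$distribution)
    )
}
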