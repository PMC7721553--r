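#' Round to the nearest multiple of a resolution, ties away from zero
#'
#' The display convention of the model's published tables: counts are
#' printed to the nearest 100 (so 5980 additional spontaneous pregnancies
#' print as +6000 and 237.6 avoided cases of gestational diabetes print as
#' -200), money totals to the nearest band-dependent grain. Half-way values
#' round away from zero. Idempotent: `display_round(display_round(x, r), r)
#' == display_round(x, r)`.
#'
#' @param x Numeric vector.
#' @param resolution Positive rounding grain.
#' @return `x` rounded to the nearest multiple of `resolution`.
#' @examples
#' display_round(5980, 100)   # 6000
#' display_round(-237.6, 100) # -200
#' display_round(1080, 100)   # 1100
#' @export
display_round <- function(x, resolution) {
  stopifnot(is.numeric(resolution), length(resolution) %in% c(1L, length(x)),
            all(resolution > 0))
  q <- abs(x) / resolution
  # guard against binary-float droop just below an exact half (e.g. 10.8/0.1)
  k <- floor(q + 0.5 + .Machine$double.eps^0.5 * pmax(1, q))
  sign(x) * k * resolution
}

#' Annual outcome deltas of the lifestyle interventions
#'
#' Converts each intervention's effect rates into unrounded annual changes
#' for the model population: spontaneous ongoing pregnancies gained, ART
#' cycles avoided per modality, and pregnancy-complication cases avoided
#' per type. Every delta is `rate * denominator`, where the denominator is
#' the intervention's target-group size (the whole subfertile cohort, the
#' obese subset, smoking men, or first-cycle women, as recorded per effect
#' row). Outcomes with no published evidence carry no effect row and so
#' contribute exactly zero; they are reported as em-dashes by
#' [render_tables()], never as zeros.
#'
#' @param config A [bia_config()].
#' @param scenario One of `"least"`, `"central"`, `"most"`.
#' @param interventions Optional character vector restricting which
#'   interventions to evaluate (default: all in the config).
#' @return A tibble with columns `intervention`, `outcome_class`,
#'   `outcome`, `rate`, `denominator`, `denominator_n` and `delta`
#'   (unrounded count of events gained/avoided per year).
#' @examples
#' intervention_deltas(netherlands_2016(), "central")
#' @export
intervention_deltas <- function(config, scenario = "central",
                                interventions = NULL) {
  scenario <- match.arg(scenario, SCENARIOS)
  eff <- config$effects
  if (!is.null(interventions)) {
    unknown <- setdiff(interventions, config$interventions$intervention)
    if (length(unknown)) {
      abort(paste("Unknown intervention:", paste(unknown, collapse = ", ")),
            class = "preconbia_usage_error")
    }
    eff <- dplyr::filter(eff, .data$intervention %in% .env$interventions)
  }
  base <- baseline_volumes(config)
  out <- eff |>
    dplyr::mutate(
      rate = .data[[scenario]],
      denominator_n = vapply(.data$denominator, function(g)
        group_size(config$population, g), numeric(1), USE.NAMES = FALSE),
      delta = .data$rate * .data$denominator_n
    ) |>
    dplyr::select("intervention", "outcome_class", "outcome", "rate",
                  "denominator", "denominator_n", "delta")
  over <- out |>
    dplyr::filter(.data$outcome_class == "cycles") |>
    dplyr::left_join(base[c("modality", "cycles")],
                     by = c(outcome = "modality")) |>
    dplyr::filter(.data$delta > .data$cycles + 1e-9)
  if (nrow(over)) {
    abort(c("Avoided cycles exceed baseline cycles:",
            stats::setNames(sprintf("%s/%s: %.1f > %.1f", over$intervention,
                                    over$outcome, over$delta, over$cycles),
                            rep("x", nrow(over)))),
          class = "preconbia_validation_error")
  }
  out
}

#' Compose two interventions with an overlap correction
#'
#' Helper for exploring what simple addition of two programs' deltas would
#' look like. A combined program is *not* the sum of its parts when the
#' target groups overlap (a cohort-wide program already reaches the obese
#' subset a second program targets), so the published combined program is
#' parameterised by its own rates; this helper only supports sensitivity
#' exploration. Deltas of the second intervention are down-weighted by
#' `1 - overlap` before adding.
#'
#' @param config A [bia_config()].
#' @param first,second Intervention ids present in the config.
#' @param overlap Fraction in `[0, 1]` of the second intervention's effect
#'   assumed already delivered by the first (default 0).
#' @param scenario Scenario point to evaluate.
#' @return A tibble like [intervention_deltas()] with
#'   `intervention = paste(first, second, sep = "+")`.
#' @export
compose_interventions <- function(config, first, second, overlap = 0,
                                  scenario = "central") {
  stopifnot(overlap >= 0, overlap <= 1)
  d <- intervention_deltas(config, scenario, interventions = c(first, second))
  d |>
    dplyr::mutate(weight = ifelse(.data$intervention == second, 1 - overlap, 1),
                  delta = .data$delta * .data$weight) |>
    dplyr::group_by(.data$outcome_class, .data$outcome) |>
    dplyr::summarise(delta = sum(.data$delta), .groups = "drop") |>
    dplyr::mutate(intervention = paste(first, second, sep = "+"),
                  .before = 1)
}
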