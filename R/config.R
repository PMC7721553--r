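#' @importFrom rlang .data .env abort %||%
#' @importFrom tibble tibble as_tibble
NULL

MODALITIES <- c("IVF", "ICSI", "IUI")
COMPLICATIONS <- c("IUGR", "gestational_diabetes", "hypertensive", "preterm")
TARGET_GROUPS <- c(
  whole_cohort      = "n_couples",
  obese_subset      = "n_obese_women",
  smoking_men       = "n_smoking_men",
  first_cycle_women = "n_first_cycle_women"
)
OUTCOME_CLASSES <- c("spontaneous", "cycles", "complication")
SCENARIOS <- c("least", "central", "most")

#' Assemble a budget-impact model configuration
#'
#' A `bia_config` bundles everything the cohort model needs: the model
#' population, the ART treatment mix, per-intervention effect-rate triples
#' (least/central/most-favorable), unit costs with provenance tags, the
#' published per-couple benefit triples used by the printed-benefit costing
#' mode, and display conventions. All pipeline functions
#' ([baseline_volumes()], [intervention_deltas()], [run_scenarios()],
#' [audit_printed()], ...) take this object first.
#'
#' @param population One-row data frame with columns `n_couples`,
#'   `n_obese_women`, `n_smoking_men`, `n_first_cycle_women`,
#'   `incidence_annual`, `prevalence_men`, `prevalence_women`. Counts are
#'   numbers of couples/individuals; prevalences are fractions in `[0, 1]`.
#' @param mix Data frame with columns `modality`, `share`, `mean_cycles`:
#'   the fraction of couples treated with each ART modality (shares sum to
#'   one) and the mean number of cycles per treated couple.
#' @param interventions Data frame with columns `intervention` (unique id),
#'   `label` (display name), `target_group` (one of `r
#'   paste0('\x60', names(TARGET_GROUPS), '\x60', collapse = ", ")`), and
#'   `incidence_annual` (annual inflow of newly presenting couples in the
#'   target group; stored for reference, not used in any computation).
#' @param effects Data frame with one row per (intervention, outcome):
#'   columns `intervention`, `outcome_class` (`"spontaneous"`, `"cycles"` or
#'   `"complication"`), `outcome` (modality or complication name;
#'   `"spontaneous"` for the pregnancy uplift), `least`, `central`, `most`
#'   (effect-rate magnitudes as fractions of the target group, ordered on
#'   the benefit scale), and `denominator` (target group the rate is a
#'   proportion of). Outcomes absent from the table mean "no published
#'   evidence" and contribute a structural zero.
#' @param costs Data frame with columns `intervention`, `component`
#'   (`"cycle"`, `"complication"` or `"program"`), `item` (modality,
#'   complication type, or `NA` for the program cost), `unit_cost` (EUR,
#'   2016 price level) and `provenance` (`"paper"` or `"assumption"`).
#' @param benefits_printed Data frame with columns `intervention`, `least`,
#'   `central`, `most`: per-couple annual benefit triples in EUR, the
#'   primitive inputs of the printed-benefit costing mode.
#' @param art_printed Optional data frame like `benefits_printed` holding
#'   published ART-only total savings (EUR) per scenario, or `NULL`.
#' @param printed Optional list of literal published table cells used by
#'   [audit_printed()] (see [netherlands_2016()] for the layout), or `NULL`.
#' @param anomalies Optional data frame of known internal inconsistencies in
#'   the published tables (`table`, `intervention`, `column`, `note`); audit
#'   mismatches matching a row here are reported as flagged inconsistencies
#'   rather than unexplained mismatches.
#' @param eur_to_usd EUR to USD conversion rate (display only).
#' @param display List of display conventions: `count_resolution` (rounding
#'   grain for count cells, default 100).
#'
#' @return A validated object of class `bia_config`.
#' @seealso [validate_config()], [load_config()], [netherlands_2016()],
#'   [generate_config()]
#' @export
bia_config <- function(population, mix, interventions, effects, costs,
                       benefits_printed, art_printed = NULL, printed = NULL,
                       anomalies = NULL, eur_to_usd = 1.1867,
                       display = list(count_resolution = 100)) {
  # canonical numeric storage is double, so save/load round-trips exactly
  dbl <- function(df) {
    if (is.null(df)) return(NULL)
    dplyr::mutate(as_tibble(df), dplyr::across(dplyr::where(is.integer),
                                               as.numeric))
  }
  cfg <- structure(
    list(
      population       = dbl(population),
      mix              = dbl(mix),
      interventions    = dbl(interventions),
      effects          = dbl(effects),
      costs            = dbl(costs),
      benefits_printed = dbl(benefits_printed),
      art_printed      = dbl(art_printed),
      printed          = if (!is.null(printed)) lapply(printed, dbl),
      anomalies        = dbl(anomalies),
      eur_to_usd       = as.numeric(eur_to_usd),
      display          = lapply(display, function(x)
        if (is.integer(x)) as.numeric(x) else x)
    ),
    class = "bia_config"
  )
  check_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks every structural invariant of a [bia_config()] — non-negative
#' integer population counts, subgroup sizes bounded by the cohort size,
#' modality shares summing to one, ordered effect triples with rates in
#' `[0, 1]`, non-negative finite unit costs with a provenance tag, ordered
#' benefit triples, a positive exchange rate — and returns *all* violations
#' rather than stopping at the first.
#'
#' @param config A `bia_config` (or a bare list with the same fields).
#' @return A tibble with columns `field` and `problem`, one row per
#'   violation; zero rows if the configuration is valid.
#' @export
validate_config <- function(config) {
  problems <- list()
  note <- function(field, problem) {
    problems[[length(problems) + 1L]] <<- tibble(field = field, problem = problem)
  }
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))

  pop <- config$population
  if (!is.data.frame(pop) || nrow(pop) != 1L) {
    note("population", "must be a one-row data frame")
  } else {
    counts <- c("n_couples", "n_obese_women", "n_smoking_men",
                "n_first_cycle_women", "incidence_annual")
    for (f in counts) {
      v <- pop[[f]]
      if (is.null(v) || !num_ok(v)) {
        note(paste0("population$", f), "missing or non-finite")
      } else if (v < 0 || abs(v - round(v)) > 1e-9) {
        note(paste0("population$", f), "must be a non-negative integer count")
      }
    }
    for (f in c("n_obese_women", "n_smoking_men", "n_first_cycle_women")) {
      if (num_ok(pop[[f]]) && num_ok(pop$n_couples) && pop[[f]] > pop$n_couples)
        note(paste0("population$", f), "subgroup exceeds n_couples")
    }
    for (f in c("prevalence_men", "prevalence_women")) {
      v <- pop[[f]]
      if (is.null(v) || !num_ok(v) || v < 0 || v > 1)
        note(paste0("population$", f), "prevalence must lie in [0, 1]")
    }
  }

  mix <- config$mix
  if (!is.data.frame(mix) || nrow(mix) == 0L) {
    note("mix", "must be a non-empty data frame")
  } else {
    if (anyDuplicated(mix$modality)) note("mix$modality", "duplicated modality")
    if (!num_ok(mix$share) || any(mix$share < 0 | mix$share > 1))
      note("mix$share", "shares must lie in [0, 1]")
    if (num_ok(mix$share) && abs(sum(mix$share) - 1) > 1e-9)
      note("mix$share", sprintf("shares must sum to 1 (got %.12g)", sum(mix$share)))
    if (!num_ok(mix$mean_cycles) || any(mix$mean_cycles <= 0))
      note("mix$mean_cycles", "mean cycles per couple must be > 0")
  }

  iv <- config$interventions
  if (!is.data.frame(iv) || nrow(iv) == 0L) {
    note("interventions", "must be a non-empty data frame")
    iv <- tibble(intervention = character(), target_group = character())
  } else {
    if (anyDuplicated(iv$intervention))
      note("interventions$intervention", "intervention ids must be unique")
    bad <- setdiff(iv$target_group, names(TARGET_GROUPS))
    if (length(bad))
      note("interventions$target_group",
           paste("unknown target group:", paste(bad, collapse = ", ")))
  }

  eff <- config$effects
  if (is.data.frame(eff) && nrow(eff) > 0L) {
    for (f in SCENARIOS) {
      v <- eff[[f]]
      if (!num_ok(v) || any(v < 0 | v > 1))
        note(paste0("effects$", f), "rates must lie in [0, 1]")
    }
    if (num_ok(eff$least) && num_ok(eff$central) && num_ok(eff$most) &&
        any(eff$least > eff$central | eff$central > eff$most))
      note("effects", "rate triples must be ordered least <= central <= most")
    bad <- setdiff(eff$outcome_class, OUTCOME_CLASSES)
    if (length(bad))
      note("effects$outcome_class",
           paste("unknown class:", paste(bad, collapse = ", ")))
    bad <- setdiff(eff$denominator, names(TARGET_GROUPS))
    if (length(bad))
      note("effects$denominator",
           paste("unknown denominator group:", paste(bad, collapse = ", ")))
    bad <- setdiff(eff$intervention, iv$intervention)
    if (length(bad))
      note("effects$intervention",
           paste("effect for unknown intervention:", paste(bad, collapse = ", ")))
    if (is.data.frame(mix)) {
      bad <- setdiff(eff$outcome[eff$outcome_class == "cycles"], mix$modality)
      if (length(bad))
        note("effects$outcome",
             paste("cycle effect for modality absent from mix:",
                   paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(eff[c("intervention", "outcome_class", "outcome")]))
      note("effects", "duplicated (intervention, outcome) row")
  }

  cost <- config$costs
  if (!is.data.frame(cost) || nrow(cost) == 0L) {
    note("costs", "must be a non-empty data frame")
  } else {
    if (!num_ok(cost$unit_cost) || any(cost$unit_cost < 0))
      note("costs$unit_cost", "unit costs must be finite and >= 0")
    bad <- setdiff(cost$provenance, c("paper", "assumption"))
    if (length(bad))
      note("costs$provenance",
           paste("provenance must be 'paper' or 'assumption', got:",
                 paste(bad, collapse = ", ")))
    bad <- setdiff(cost$component, c("cycle", "complication", "program"))
    if (length(bad))
      note("costs$component", paste("unknown component:", paste(bad, collapse = ", ")))
    missing_cost <- setdiff(unique(config$effects$intervention), unique(cost$intervention))
    if (length(missing_cost))
      note("costs", paste("no cost entry for intervention:",
                          paste(missing_cost, collapse = ", ")))
  }

  bp <- config$benefits_printed
  if (is.data.frame(bp) && nrow(bp) > 0L) {
    if (!num_ok(bp$least) || !num_ok(bp$central) || !num_ok(bp$most)) {
      note("benefits_printed", "benefit values must be finite numbers")
    } else if (any(bp$least > bp$central | bp$central > bp$most)) {
      note("benefits_printed", "benefit triples must be ordered least <= central <= most")
    }
  }

  if (!num_ok(config$eur_to_usd) || config$eur_to_usd <= 0)
    note("eur_to_usd", "exchange rate must be a finite number > 0")

  res <- config$display$count_resolution
  if (is.null(res) || !num_ok(res) || res <= 0)
    note("display$count_resolution", "resolution must be > 0")

  if (length(problems)) dplyr::bind_rows(problems)
  else tibble(field = character(), problem = character())
}

check_config <- function(config) {
  problems <- validate_config(config)
  if (nrow(problems)) {
    abort(c(
      "Invalid model configuration:",
      stats::setNames(paste0(problems$field, ": ", problems$problem),
                      rep("x", nrow(problems)))
    ), class = "preconbia_validation_error")
  }
  invisible(config)
}

#' @export
print.bia_config <- function(x, ...) {
  cat("<bia_config>\n")
  cat(sprintf("  population : %s couples (%s obese women, %s smoking men, %s first-cycle women)\n",
              format(x$population$n_couples, big.mark = ","),
              format(x$population$n_obese_women, big.mark = ","),
              format(x$population$n_smoking_men, big.mark = ","),
              format(x$population$n_first_cycle_women, big.mark = ",")))
  cat(sprintf("  mix        : %s\n",
              paste(sprintf("%s %.0f%% x %.1f cycles", x$mix$modality,
                            100 * x$mix$share, x$mix$mean_cycles),
                    collapse = ", ")))
  cat(sprintf("  interventions: %s\n",
              paste(x$interventions$intervention, collapse = ", ")))
  cat(sprintf("  effects    : %d rate triples; costs: %d entries (%d assumption-tagged)\n",
              nrow(x$effects), nrow(x$costs),
              sum(x$costs$provenance == "assumption")))
  cat(sprintf("  printed benefit triples: %d; EUR->USD %.4f\n",
              nrow(x$benefits_printed), x$eur_to_usd))
  invisible(x)
}

# Resolve a target-group name to its population count.
group_size <- function(population, group) {
  col <- TARGET_GROUPS[[group]]
  population[[col]]
}

#' Write a model configuration to a JSON file
#'
#' Serializes a [bia_config()] to the package's canonical JSON dialect
#' (UTF-8, 17 significant digits so doubles round-trip exactly, provenance
#' tags kept with each cost entry). The configuration is re-validated before
#' writing; invalid configurations (including non-finite costs) are refused.
#'
#' @param config A valid `bia_config`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @seealso [load_config()]
#' @export
save_config <- function(config, path) {
  check_config(config)
  body <- list(
    format           = "preconbia-config",
    version          = 1L,
    population       = config$population,
    mix              = config$mix,
    interventions    = config$interventions,
    effects          = config$effects,
    costs            = config$costs,
    benefits_printed = config$benefits_printed,
    art_printed      = config$art_printed,
    printed          = config$printed,
    anomalies        = config$anomalies,
    eur_to_usd       = config$eur_to_usd,
    display          = config$display
  )
  body <- body[!vapply(body, is.null, logical(1))]
  json <- jsonlite::toJSON(body, dataframe = "columns", digits = I(17),
                           auto_unbox = TRUE, null = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a model configuration from a JSON file
#'
#' Parses a configuration written by [save_config()] (or by hand in the same
#' dialect) and validates it. All invariant violations are collected and
#' reported together, naming every offending field.
#'
#' @param path Path to a configuration JSON file.
#' @return A validated `bia_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "preconbia_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_df <- function(x) if (is.null(x)) NULL else as_tibble(as.data.frame(x))
  printed <- raw$printed
  if (!is.null(printed)) printed <- lapply(printed, as_df)
  bia_config(
    population       = as_df(raw$population),
    mix              = as_df(raw$mix),
    interventions    = as_df(raw$interventions),
    effects          = as_df(raw$effects),
    costs            = as_df(raw$costs),
    benefits_printed = as_df(raw$benefits_printed),
    art_printed      = as_df(raw$art_printed),
    printed          = printed,
    anomalies        = as_df(raw$anomalies),
    eur_to_usd       = raw$eur_to_usd,
    display          = as.list(raw$display)
  )
}
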