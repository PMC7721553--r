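#' Generate a random valid model configuration
#'
#' Draws a complete parameter set with the structure the analysis assumes —
#' a population with subgroups no larger than the cohort, modality shares
#' on the unit simplex, ordered effect-rate triples capped so avoided
#' cycles never exceed baseline cycles, non-negative unit costs — and
#' derives its per-couple benefit triples by running the computed-from-
#' deltas costing mode, so the generated "printed" benefits are
#' self-consistent with the generated rates and costs. Deterministic per
#' seed; the caller's RNG state is left untouched.
#'
#' Boundary cases arise with positive probability: interventions with all
#' rates zero, degenerate scenario triples (least = central = most), and
#' program costs exceeding gross savings (negative per-couple benefit).
#'
#' @param seed Integer seed.
#' @param n_couples_range Integer range for the prevalent cohort size.
#' @param n_interventions Number of interventions to generate.
#' @param n_modalities Number of ART modalities (first three named IVF,
#'   ICSI, IUI).
#' @param n_complications Number of complication types.
#' @param rate_range Range of central effect-rate magnitudes.
#' @param cycle_cost_range,complication_cost_range,program_cost_range
#'   EUR ranges for the generated unit costs.
#' @param bound_spread Maximum relative half-width of the least/most
#'   scenario interval around the central rate (>= 0).
#' @return A validated [bia_config()].
#' @examples
#' cfg <- generate_config(seed = 42)
#' nrow(validate_config(cfg)) == 0
#' @export
generate_config <- function(seed,
                            n_couples_range = c(1000L, 100000L),
                            n_interventions = 5L,
                            n_modalities = 3L,
                            n_complications = 4L,
                            rate_range = c(0, 0.25),
                            cycle_cost_range = c(500, 5000),
                            complication_cost_range = c(1000, 20000),
                            program_cost_range = c(0, 1500),
                            bound_spread = 0.5) {
  ranges <- list(n_couples_range = n_couples_range, rate_range = rate_range,
                 cycle_cost_range = cycle_cost_range,
                 complication_cost_range = complication_cost_range,
                 program_cost_range = program_cost_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      abort(paste0("infeasible range ", nm, ": lo > hi"),
            class = "preconbia_domain_error")
    }
  }
  stopifnot(bound_spread >= 0, n_interventions >= 1, n_modalities >= 1)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  rint <- function(lo, hi) floor(stats::runif(1, lo, hi + 1))
  n_couples <- rint(n_couples_range[1], n_couples_range[2])
  population <- tibble(
    n_couples = n_couples,
    n_obese_women = rint(1, n_couples),
    n_smoking_men = rint(1, n_couples),
    n_first_cycle_women = rint(1, n_couples),
    incidence_annual = rint(0, n_couples),
    prevalence_men = stats::runif(1),
    prevalence_women = stats::runif(1)
  )

  modalities <- if (n_modalities <= 3L) MODALITIES[seq_len(n_modalities)]
    else c(MODALITIES, paste0("modality_", seq_len(n_modalities - 3L)))
  raw <- stats::rexp(n_modalities) + 1e-6
  mix <- tibble(modality = modalities, share = raw / sum(raw),
                mean_cycles = stats::runif(n_modalities, 0.5, 4))

  complications <- if (n_complications <= 4L)
    COMPLICATIONS[seq_len(n_complications)]
    else c(COMPLICATIONS, paste0("complication_", seq_len(n_complications - 4L)))

  interventions <- tibble(
    intervention = paste0("intervention_", seq_len(n_interventions)),
    label = paste("Synthetic intervention", seq_len(n_interventions)),
    target_group = sample(names(TARGET_GROUPS), n_interventions, replace = TRUE),
    incidence_annual = vapply(seq_len(n_interventions), function(i)
      rint(0, n_couples), numeric(1))
  )

  base <- mix$share * n_couples * mix$mean_cycles  # baseline cycles per modality
  eff_rows <- list()
  for (i in seq_len(n_interventions)) {
    id <- interventions$intervention[i]
    denom_group <- interventions$target_group[i]
    denom <- group_size(population, denom_group)
    all_zero <- stats::runif(1) < 0.15
    degenerate <- stats::runif(1) < 0.15
    draw_triple <- function(cap) {
      central <- if (all_zero) 0 else stats::runif(1, rate_range[1],
                                                   min(rate_range[2], cap))
      if (degenerate || central == 0) {
        c(central, central, central)
      } else {
        least <- central * (1 - bound_spread * stats::runif(1))
        most <- min(cap, central * (1 + bound_spread * stats::runif(1)), 1)
        c(least, central, max(central, most))
      }
    }
    add_eff <- function(class, outcome, cap = 1) {
      tr <- draw_triple(cap)
      eff_rows[[length(eff_rows) + 1L]] <<- tibble(
        intervention = id, outcome_class = class, outcome = outcome,
        least = tr[1], central = tr[2], most = tr[3],
        denominator = denom_group
      )
    }
    if (stats::runif(1) < 0.7) add_eff("spontaneous", "spontaneous")
    for (m in seq_along(modalities)) {
      if (stats::runif(1) < 0.7)
        add_eff("cycles", modalities[m], cap = min(1, base[m] / denom))
    }
    for (cc in complications) {
      if (stats::runif(1) < 0.5) add_eff("complication", cc)
    }
  }
  effects <- dplyr::bind_rows(eff_rows)

  costs <- dplyr::bind_rows(lapply(interventions$intervention, function(id) {
    dplyr::bind_rows(
      tibble(intervention = id, component = "cycle", item = modalities,
             unit_cost = stats::runif(n_modalities, cycle_cost_range[1],
                                      cycle_cost_range[2]),
             provenance = "assumption"),
      tibble(intervention = id, component = "complication",
             item = complications,
             unit_cost = stats::runif(length(complications),
                                      complication_cost_range[1],
                                      complication_cost_range[2]),
             provenance = "assumption"),
      tibble(intervention = id, component = "program", item = NA_character_,
             unit_cost = stats::runif(1, program_cost_range[1],
                                      program_cost_range[2]),
             provenance = "assumption")
    )
  }))

  cfg <- bia_config(
    population = population, mix = mix, interventions = interventions,
    effects = effects, costs = costs,
    benefits_printed = tibble(intervention = interventions$intervention,
                              least = 0, central = 0, most = 0),
    eur_to_usd = stats::runif(1, 0.5, 2),
    display = list(count_resolution = 100)
  )
  computed <- purrr::map_dfr(SCENARIOS, cost_results, config = cfg,
                             mode = "computed")
  cfg$benefits_printed <- computed |>
    dplyr::select("intervention", "scenario", "per_couple") |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "per_couple") |>
    dplyr::select("intervention", "least", "central", "most")
  check_config(cfg)
  cfg
}

#' Perturb a single configuration field
#'
#' Returns a modified copy of a configuration with `delta` added to one
#' addressable numeric field, for sensitivity and mutation testing. The
#' result is deliberately *not* re-validated — mutation tests rely on
#' producing configurations that [validate_config()] must reject.
#'
#' Field paths are dot-separated:
#' * `population.<field>` — e.g. `population.n_couples`
#' * `mix.share.<modality>` / `mix.mean_cycles.<modality>`
#' * `effects.<intervention>.<outcome>.<least|central|most>`
#' * `costs.<intervention>.<cycle|complication>.<item>` or
#'   `costs.<intervention>.program`
#' * `eur_to_usd`
#'
#' @param config A [bia_config()].
#' @param field_path Dot-separated path string (see Details).
#' @param delta Numeric amount added to the addressed field.
#' @return The modified configuration (original untouched).
#' @examples
#' cfg <- netherlands_2016()
#' cfg2 <- perturb_config(cfg, "costs.smarter.cycle.IVF", 100)
#' cfg2$costs$unit_cost[1] - cfg$costs$unit_cost[1]
#' @export
perturb_config <- function(config, field_path, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L)
  parts <- strsplit(field_path, ".", fixed = TRUE)[[1]]
  bad_path <- function() abort(paste0("Unknown field path: ", field_path),
                               class = "preconbia_usage_error")
  head <- parts[1]
  if (head == "eur_to_usd" && length(parts) == 1L) {
    config$eur_to_usd <- config$eur_to_usd + delta
  } else if (head == "population" && length(parts) == 2L) {
    if (is.null(config$population[[parts[2]]])) bad_path()
    config$population[[parts[2]]] <- config$population[[parts[2]]] + delta
  } else if (head == "mix" && length(parts) == 3L &&
             parts[2] %in% c("share", "mean_cycles")) {
    i <- match(parts[3], config$mix$modality)
    if (is.na(i)) bad_path()
    config$mix[[parts[2]]][i] <- config$mix[[parts[2]]][i] + delta
  } else if (head == "effects" && length(parts) == 4L &&
             parts[4] %in% SCENARIOS) {
    i <- which(config$effects$intervention == parts[2] &
                 config$effects$outcome == parts[3])
    if (length(i) != 1L) bad_path()
    config$effects[[parts[4]]][i] <- config$effects[[parts[4]]][i] + delta
  } else if (head == "costs" && length(parts) %in% c(3L, 4L)) {
    i <- if (length(parts) == 3L && parts[3] == "program") {
      which(config$costs$intervention == parts[2] &
              config$costs$component == "program")
    } else if (length(parts) == 4L) {
      which(config$costs$intervention == parts[2] &
              config$costs$component == parts[3] &
              config$costs$item == parts[4])
    } else integer(0)
    if (length(i) != 1L) bad_path()
    config$costs$unit_cost[i] <- config$costs$unit_cost[i] + delta
  } else {
    bad_path()
  }
  config
}
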