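# Small hand-built config used where the full fixture would obscure the
# arithmetic under test.
tiny_config <- function(program_cost = 50) {
  preconbia::bia_config(
    population = tibble::tibble(
      n_couples = 1000, n_obese_women = 200, n_smoking_men = 100,
      n_first_cycle_women = 300, incidence_annual = 50,
      prevalence_men = 0.01, prevalence_women = 0.02
    ),
    mix = tibble::tibble(
      modality = c("IVF", "ICSI", "IUI"),
      share = c(0.3, 0.2, 0.5),
      mean_cycles = c(2, 1.5, 3)
    ),
    interventions = tibble::tibble(
      intervention = "demo", label = "Demo program",
      target_group = "whole_cohort", incidence_annual = 10
    ),
    effects = tibble::tibble(
      intervention = "demo", outcome_class = "cycles", outcome = "IVF",
      least = 0.05, central = 0.1, most = 0.2, denominator = "whole_cohort"
    ),
    costs = tibble::tibble(
      intervention = "demo",
      component = c("cycle", "program"),
      item = c("IVF", NA),
      unit_cost = c(3000, program_cost),
      provenance = "assumption"
    ),
    benefits_printed = tibble::tibble(
      intervention = "demo", least = 100, central = 250, most = 550
    )
  )
}
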