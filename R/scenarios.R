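#' Evaluate the model at the least, central and most-favorable points
#'
#' Propagates the full parameter set through the cohort model at each of
#' the three scenario points: outcome deltas via [intervention_deltas()]
#' and cost results via [cost_results()], for every intervention,
#' deterministically. Each intervention's bounds are propagated
#' independently; no correlation across interventions is assumed, matching
#' the per-row bounds the published tables report.
#'
#' @param config A [bia_config()].
#' @param mode Costing mode passed to [cost_results()].
#' @return A `bia_scenarios` object: list with `deltas` (tibble over
#'   intervention x scenario x outcome), `costs` (tibble over intervention
#'   x scenario), `mode`, and the `config`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' scn <- run_scenarios(netherlands_2016())
#' tidy(scn)
#' @export
run_scenarios <- function(config, mode = c("printed", "computed")) {
  mode <- match.arg(mode)
  deltas <- purrr::map_dfr(SCENARIOS, function(s) {
    dplyr::mutate(intervention_deltas(config, s), scenario = s, .after = 1)
  })
  costs <- purrr::map_dfr(SCENARIOS, cost_results, config = config, mode = mode)
  structure(
    list(deltas = deltas, costs = costs, mode = mode, config = config),
    class = "bia_scenarios"
  )
}

#' @export
print.bia_scenarios <- function(x, ...) {
  cat(sprintf("<bia_scenarios> %s mode, %d interventions\n", x$mode,
              dplyr::n_distinct(x$costs$intervention)))
  wide <- x$costs |>
    dplyr::select("intervention", "scenario", "total") |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "total")
  cat("Total annual saving (EUR M), central (least, most):\n")
  for (i in seq_len(nrow(wide))) {
    cat(sprintf("  %-12s %8.2f (%8.2f, %8.2f)\n", wide$intervention[i],
                wide$central[i] / 1e6, wide$least[i] / 1e6, wide$most[i] / 1e6))
  }
  invisible(x)
}

#' Probabilistic sensitivity analysis by Monte Carlo
#'
#' Samples each intervention's per-couple benefit independently from its
#' scenario interval — uniformly on `[least, most]`, or from a triangular
#' distribution with mode at the central value — and summarises the induced
#' distribution of the total annual saving. One root seed spawns a
#' deterministic child stream per intervention, so results are reproducible
#' and adding an intervention to a configuration does not perturb the draws
#' of the others.
#'
#' @param config A [bia_config()].
#' @param n_draws Number of Monte Carlo draws per intervention (>= 1).
#' @param seed Integer root seed.
#' @param distribution `"uniform"` or `"triangular"`.
#' @return A `bia_psa` object: list with `summary` (tibble per intervention:
#'   empirical mean, sd, 2.5 and 97.5 percentiles of the total saving in
#'   EUR), `draws` (long tibble of sampled total savings), `n_draws`,
#'   `seed`, `distribution`.
#' @examples
#' psa <- run_psa(netherlands_2016(), n_draws = 1000, seed = 1)
#' tidy(psa)
#' @export
run_psa <- function(config, n_draws = 10000, seed = 1,
                    distribution = c("uniform", "triangular")) {
  distribution <- match.arg(distribution)
  stopifnot(n_draws >= 1)
  bp <- config$benefits_printed
  if (any(bp$least > bp$central | bp$central > bp$most)) {
    abort("benefit triples must be ordered least <= central <= most",
          class = "preconbia_domain_error")
  }
  iv <- config$interventions
  draws <- purrr::map_dfr(seq_len(nrow(iv)), function(i) {
    id <- iv$intervention[i]
    tri <- bp[bp$intervention == id, ]
    gs <- group_size(config$population, iv$target_group[i])
    withr_seed <- child_seed(seed, id)
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(withr_seed)
    u <- stats::runif(n_draws)
    pc <- if (distribution == "uniform") {
      tri$least + u * (tri$most - tri$least)
    } else {
      qtriangular(u, tri$least, tri$central, tri$most)
    }
    tibble(intervention = id, draw = seq_len(n_draws),
           per_couple = pc, total = pc * gs)
  })
  summary <- draws |>
    dplyr::group_by(.data$intervention) |>
    dplyr::summarise(
      mean = mean(.data$total), sd = stats::sd(.data$total),
      q2.5 = stats::quantile(.data$total, 0.025, names = FALSE),
      q97.5 = stats::quantile(.data$total, 0.975, names = FALSE),
      .groups = "drop"
    )
  structure(
    list(summary = summary, draws = draws, n_draws = n_draws, seed = seed,
         distribution = distribution),
    class = "bia_psa"
  )
}

# Deterministic 31-bit child seed from a root seed and an intervention id,
# so each intervention gets its own stream.
child_seed <- function(seed, id) {
  h <- sum(utf8ToInt(id) * (seq_along(utf8ToInt(id)) + 31L))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Inverse CDF of the triangular distribution on [a, b] with mode m.
qtriangular <- function(u, a, m, b) {
  if (b <= a) return(rep(a, length(u)))
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' @export
print.bia_psa <- function(x, ...) {
  cat(sprintf("<bia_psa> %s draws per intervention, %s distribution, seed %d\n",
              format(x$n_draws, big.mark = ","), x$distribution, x$seed))
  print(x$summary)
  invisible(x)
}
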