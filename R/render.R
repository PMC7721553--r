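#' Render the model's results as publication-style tables
#'
#' Formats a [run_scenarios()] result with the published display
#' conventions: counts to the nearest 100 with explicit signs (`+` for
#' spontaneous pregnancies gained, `-` for avoided treatments and
#' complications), percentages to one decimal, money totals in millions of
#' EUR at a magnitude-dependent precision, and an em-dash for outcomes with
#' no published evidence (which are structural zeros, not measured zeros).
#' Output is deterministic and locale-independent: `.` decimal separator,
#' ASCII minus.
#'
#' @param scenarios A `bia_scenarios` object from [run_scenarios()].
#' @param format `"markdown"`, `"csv"` or `"json"`.
#' @return A named character vector of rendered documents: `table2`
#'   (clinical ART outcomes), `table3` (pregnancy complications), `table4`
#'   (cost savings) for markdown/csv, or a single `tables` element of
#'   nested JSON.
#' @examples
#' scn <- run_scenarios(netherlands_2016())
#' cat(render_tables(scn)[["table2"]])
#' @export
render_tables <- function(scenarios, format = c("markdown", "csv", "json")) {
  format <- match.arg(format)
  cfg <- scenarios$config
  res <- cfg$display$count_resolution
  ids <- cfg$interventions$intervention
  labels <- stats::setNames(cfg$interventions$label, ids)

  avail <- unique(scenarios$deltas$scenario)
  shown <- if ("central" %in% avail || length(avail) == 0L) "central" else avail[1]
  central <- scenarios$deltas[scenarios$deltas$scenario == shown, ]
  cell_counts <- function(class, outcomes) {
    grid <- tidyr::expand_grid(intervention = ids, outcome = outcomes)
    grid |>
      dplyr::left_join(central[central$outcome_class %in% class,
                               c("intervention", "outcome", "rate", "delta")],
                       by = c("intervention", "outcome")) |>
      dplyr::mutate(cell = ifelse(
        is.na(.data$delta), "—",
        sprintf("%s%s (%s%.1f)",
                ifelse(.data$outcome == "spontaneous", "+", "-"),
                formatC(display_round(.data$delta, res), format = "d",
                        big.mark = ",", mode = "integer"),
                ifelse(.data$outcome == "spontaneous", "+", "-"),
                display_round(100 * .data$rate, 0.1))
      )) |>
      dplyr::select("intervention", "outcome", "cell") |>
      tidyr::pivot_wider(names_from = "outcome", values_from = "cell") |>
      dplyr::mutate(intervention = labels[.data$intervention])
  }
  table2 <- cell_counts(c("spontaneous", "cycles"),
                        c("spontaneous", cfg$mix$modality))
  compl <- unique(cfg$effects$outcome[cfg$effects$outcome_class == "complication"])
  if (length(compl) == 0L) compl <- COMPLICATIONS
  table3 <- cell_counts("complication", compl)

  wide <- scenarios$costs |>
    dplyr::select("intervention", "scenario", "group_size", "per_couple",
                  "total", "art_only") |>
    tidyr::pivot_wider(names_from = "scenario",
                       values_from = c("per_couple", "total", "art_only"))
  for (col in as.vector(outer(c("per_couple_", "total_", "art_only_"),
                              SCENARIOS, paste0))) {
    if (is.null(wide[[col]])) wide[[col]] <- NA_real_
  }
  if (!"central" %in% scenarios$costs$scenario && nrow(scenarios$costs)) {
    s <- scenarios$costs$scenario[1]
    for (v in c("per_couple", "total", "art_only")) {
      wide[[paste0(v, "_central")]] <- wide[[paste0(v, "_", s)]]
    }
  }
  triple <- function(l, c, m, fmt) {
    ifelse(is.na(c), "—",
           ifelse(is.na(l) | is.na(m), fmt(c),
                  sprintf("%s (%s, %s)", fmt(c), fmt(l), fmt(m))))
  }
  table4 <- tibble(
    intervention = labels[wide$intervention],
    per_couple = triple(wide$per_couple_least, wide$per_couple_central,
                        wide$per_couple_most, format_eur),
    group_size = formatC(wide$group_size, format = "d", big.mark = ",",
                         mode = "integer"),
    total_saving = triple(wide$total_least, wide$total_central,
                          wide$total_most, format_millions),
    art_saving = triple(wide$art_only_least, wide$art_only_central,
                        wide$art_only_most, format_millions)
  )

  tables <- list(table2 = table2, table3 = table3, table4 = table4)
  switch(format,
    markdown = vapply(tables, md_table, character(1)),
    csv = vapply(tables, function(tb) {
      paste(c(paste(names(tb), collapse = ","),
              apply(tb, 1, function(r) paste(shQuote(r, "cmd"), collapse = ","))),
            collapse = "\n")
    }, character(1)),
    json = c(tables = as.character(jsonlite::toJSON(
      lapply(tables, function(tb) tb), dataframe = "rows", pretty = TRUE)))
  )
}

format_eur <- function(x) {
  sprintf("€%s", formatC(display_round(x, 1), format = "d",
                              big.mark = ",", mode = "integer"))
}

# Millions of EUR at the precision band of the magnitude: whole millions
# from EUR 10 M up, one decimal above EUR 1 M, three decimals below.
format_millions <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    out[i] <- if (is.na(v)) "—"
      else if (abs(v) >= 10e6) sprintf("€%.0f M", display_round(v, 1e6) / 1e6)
      else if (abs(v) >= 1e6) sprintf("€%.1f M", display_round(v, 1e5) / 1e6)
      else sprintf("€%.3f M", display_round(v, 1e3) / 1e6)
  }
  out
}

md_table <- function(tb) {
  header <- paste0("| ", paste(names(tb), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(tb)), collapse = "|"), "|")
  rows <- apply(tb, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, rule, rows, ""), collapse = "\n")
}
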