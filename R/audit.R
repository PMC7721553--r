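#' Cell-by-cell audit of recomputed against published table values
#'
#' Recomputes every published table cell from the raw parameters — count
#' cells as `rate * denominator`, percentage cells as the rate itself,
#' total savings as `per-couple benefit * target-group size` — and compares
#' each to the literal printed value at that cell's printed resolution. A
#' cell matches when the recomputed value is within half the printed
#' resolution of the printed value. Mismatches that correspond to a
#' registered anomaly in `config$anomalies` are reported as
#' `flagged-inconsistency` (the published tables are never silently
#' "corrected"); any other mismatch is an unexplained `mismatch`.
#'
#' Published ART-only savings columns are not derivable from the per-couple
#' benefit chain (`not-recomputable`), but are screened by a consistency
#' rule: in the central and most-favorable scenarios the ART-only saving
#' cannot exceed the overall saving, since the overall figure adds
#' complication savings and only then subtracts intervention costs. The
#' least-favorable scenario is exempt — there the intervention-cost
#' subtraction can legitimately push the overall saving below the ART-only
#' component.
#'
#' @param config A [bia_config()] whose `$printed` tables are populated
#'   (the shipped [netherlands_2016()] fixture, or a synthetic config run
#'   through [printed_from_model()]).
#' @param mode Costing mode used for recomputation (see [cost_results()]).
#' @return A `bia_audit` object: tibble with columns `table`,
#'   `intervention`, `column`, `printed`, `recomputed`, `resolution`,
#'   `status` (`match`, `mismatch`, `flagged-inconsistency`,
#'   `not-recomputable`) and `note`.
#' @examples
#' audit <- audit_printed(netherlands_2016())
#' glance(audit)
#' @export
audit_printed <- function(config, mode = c("printed", "computed")) {
  mode <- match.arg(mode)
  if (is.null(config$printed)) {
    abort("config carries no printed tables to audit against",
          class = "preconbia_usage_error")
  }
  eps <- 1e-9
  deltas <- intervention_deltas(config, "central")
  records <- list()
  add <- function(table, intervention, column, printed, recomputed,
                  resolution, status = NA_character_, note = "") {
    status <- if (!is.na(status)) status
      else if (is.na(recomputed)) "not-recomputable"
      else if (abs(printed - recomputed) <= resolution / 2 + eps) "match"
      else "mismatch"
    records[[length(records) + 1L]] <<- tibble(
      table = table, intervention = intervention, column = column,
      printed = printed, recomputed = recomputed, resolution = resolution,
      status = status, note = note
    )
  }

  count_res <- config$display$count_resolution
  for (tb in intersect(c("table2", "table3"), names(config$printed))) {
    cells <- config$printed[[tb]]
    for (i in seq_len(nrow(cells))) {
      row <- deltas[deltas$intervention == cells$intervention[i] &
                      deltas$outcome == cells$outcome[i], ]
      delta <- if (nrow(row)) row$delta else NA_real_
      rate <- if (nrow(row)) row$rate else NA_real_
      add(tb, cells$intervention[i], paste(cells$outcome[i], "count"),
          cells$count[i], delta, count_res)
      add(tb, cells$intervention[i], paste(cells$outcome[i], "pct"),
          cells$pct[i], 100 * rate, 0.1)
    }
  }

  if ("table4" %in% names(config$printed)) {
    t4 <- config$printed$table4
    costs <- purrr::map_dfr(SCENARIOS, cost_results, config = config,
                            mode = mode)
    for (i in seq_len(nrow(t4))) {
      id <- t4$intervention[i]
      iv <- config$interventions[config$interventions$intervention == id, ]
      cr <- costs[costs$intervention == id, ]
      gs <- if (nrow(iv)) group_size(config$population, iv$target_group)
        else NA_real_
      if (!is.null(t4$group_size)) {
        add("table4", id, "group_size", t4$group_size[i], gs, 1)
      }
      if (!is.null(t4$incidence)) {
        add("table4", id, "incidence", t4$incidence[i],
            if (nrow(iv)) iv$incidence_annual else NA_real_, 1)
      }
      for (s in SCENARIOS) {
        crs <- cr[cr$scenario == s, ]
        pc_col <- paste0("per_couple_", s)
        if (!is.null(t4[[pc_col]])) {
          add("table4", id, paste("per_couple", s), t4[[pc_col]][i],
              if (nrow(crs)) crs$per_couple else NA_real_, 1)
        }
        tot_col <- paste0("total_", s)
        if (!is.null(t4[[tot_col]])) {
          add("table4", id, paste("total", s), t4[[tot_col]][i],
              if (nrow(crs)) crs$total else NA_real_,
              t4[[paste0("res_total_", s)]][i])
        }
        art_col <- paste0("art_", s)
        if (!is.null(t4[[art_col]]) && !is.na(t4[[art_col]][i])) {
          art_printed <- t4[[art_col]][i]
          art_res <- t4[[paste0("res_art_", s)]][i]
          if (mode == "computed") {
            add("table4", id, paste("art", s), art_printed,
                if (nrow(crs)) crs$art_only else NA_real_, art_res)
          } else {
            tot_rec <- if (nrow(crs)) crs$total else NA_real_
            violates <- s != "least" && !is.na(tot_rec) &&
              art_printed > tot_rec + art_res / 2
            add("table4", id, paste("art", s), art_printed, NA_real_, art_res,
                status = if (violates) "mismatch" else "not-recomputable",
                note = if (violates)
                  sprintf("ART-only saving exceeds the overall %s-favorable saving (%.3g > %.3g)",
                          s, art_printed, tot_rec) else "")
          }
        }
      }
    }
  }

  out <- dplyr::bind_rows(records)
  # promote registered anomalies from mismatch to flagged-inconsistency
  if (!is.null(config$anomalies) && nrow(config$anomalies)) {
    key <- paste(out$table, out$intervention, out$column)
    reg <- config$anomalies
    reg_key <- paste(reg$table, reg$intervention, reg$column)
    hit <- out$status == "mismatch" & key %in% reg_key
    out$status[hit] <- "flagged-inconsistency"
    out$note[hit] <- reg$note[match(key[hit], reg_key)]
  }
  structure(out, class = c("bia_audit", class(out)))
}

#' Publish-style table cells generated from the model itself
#'
#' Builds the `$printed` tables and per-cell resolutions for a
#' configuration by running the model and applying the display conventions
#' — the self-consistent counterpart of the literal published cells the
#' shipped fixture carries. Auditing a configuration against its own
#' generated cells must yield matches everywhere; this is how the audit
#' machinery is exercised on synthetic parameter sets.
#'
#' @param config A [bia_config()].
#' @param mode Costing mode (see [cost_results()]).
#' @return The config with `$printed` replaced by model-generated tables
#'   and `$anomalies` cleared.
#' @examples
#' cfg <- printed_from_model(netherlands_2016(), mode = "computed")
#' all(audit_printed(cfg, mode = "computed")$status == "match")
#' @export
printed_from_model <- function(config, mode = c("printed", "computed")) {
  mode <- match.arg(mode)
  res <- config$display$count_resolution
  deltas <- intervention_deltas(config, "central")
  cells <- deltas |>
    dplyr::mutate(count = display_round(.data$delta, res),
                  pct = display_round(100 * .data$rate, 0.1)) |>
    dplyr::select("intervention", "outcome_class", "outcome", "count", "pct")
  costs <- purrr::map_dfr(SCENARIOS, cost_results, config = config, mode = mode)
  money_res <- function(x) ifelse(abs(x) >= 10e6, 1e6,
                                  ifelse(abs(x) >= 1e6, 1e5, 1e3))
  t4 <- costs |>
    dplyr::select("intervention", "scenario", "group_size", "per_couple",
                  "total") |>
    tidyr::pivot_wider(names_from = "scenario",
                       values_from = c("per_couple", "total")) |>
    dplyr::left_join(config$interventions[c("intervention", "incidence_annual")],
                     by = "intervention") |>
    dplyr::rename(incidence = "incidence_annual")
  for (s in SCENARIOS) {
    tot <- t4[[paste0("total_", s)]]
    t4[[paste0("res_total_", s)]] <- money_res(tot)
    t4[[paste0("total_", s)]] <- display_round(tot, money_res(tot))
    t4[[paste0("per_couple_", s)]] <- display_round(t4[[paste0("per_couple_", s)]], 1)
  }
  config$printed <- list(
    table2 = cells[cells$outcome_class != "complication",
                   c("intervention", "outcome", "count", "pct")],
    table3 = cells[cells$outcome_class == "complication",
                   c("intervention", "outcome", "count", "pct")],
    table4 = t4
  )
  config$anomalies <- NULL
  config
}

#' @export
print.bia_audit <- function(x, ...) {
  counts <- table(factor(x$status, levels = c("match", "mismatch",
                                              "flagged-inconsistency",
                                              "not-recomputable")))
  cat(sprintf("<bia_audit> %d cells: %d match, %d mismatch, %d flagged-inconsistency, %d not-recomputable\n",
              nrow(x), counts[["match"]], counts[["mismatch"]],
              counts[["flagged-inconsistency"]], counts[["not-recomputable"]]))
  flagged <- x[x$status %in% c("mismatch", "flagged-inconsistency"), ]
  if (nrow(flagged)) {
    for (i in seq_len(nrow(flagged))) {
      cat(sprintf("  [%s] %s %s %s: printed %.4g vs recomputed %.4g\n",
                  flagged$status[i], flagged$table[i], flagged$intervention[i],
                  flagged$column[i], flagged$printed[i], flagged$recomputed[i]))
    }
  }
  invisible(x)
}
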