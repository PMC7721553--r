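#' Baseline annual ART activity before any intervention
#'
#' Multiplies the model population through the treatment mix: for each ART
#' modality, the number of couples treated per year (`share * n_couples`)
#' and the number of cycles they undergo (`couples * mean_cycles`). Values
#' are exact real numbers — rounding is purely a display concern handled by
#' [display_round()] and [render_tables()].
#'
#' @param config A [bia_config()].
#' @return A tibble with one row per modality (`modality`, `share`,
#'   `mean_cycles`, `couples`, `cycles`) and the grand total of cycles in
#'   attribute `total_cycles`.
#' @examples
#' baseline_volumes(netherlands_2016())
#' @export
baseline_volumes <- function(config) {
  out <- config$mix |>
    dplyr::mutate(
      couples = .data$share * config$population$n_couples,
      cycles  = .data$couples * .data$mean_cycles
    )
  attr(out, "total_cycles") <- sum(out$cycles)
  out
}
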