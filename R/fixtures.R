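#' Published Finnish reference tables
#'
#' CSV transcriptions of the published result tables for the Finnish adult
#' population that this package's machinery is designed to reproduce the
#' arithmetic of: the minimum-cost diet for an average adult male (food
#' level, with baseline comparison), the minimum-deviation cost/energy/GHGE
#' tables for an average adult female across the three scenarios, and the
#' additive intra/inter decomposition for an average adult male. They are
#' inputs for worked examples and consistency checks — shares, ratios,
#' aggregation and decomposition identities can all be recomputed from
#' them. GHGE values are stored in grams CO2e per capita per day
#' (converted from the printed kilogram cells), costs in EUR, energy in kJ,
#' quantities in grams; a \code{"Total"}/\code{"All"} row carries the
#' printed totals.
#'
#' @param table Which table to load: \code{"min_cost_male"} (food-level
#'   minimum-cost diet), \code{"min_deviation_cost_female"},
#'   \code{"min_deviation_energy_female"},
#'   \code{"min_deviation_ghge_female"} (main-category scenario tables with
#'   shares), or \code{"decomposition_male"} (intra/inter terms per main
#'   category, metric and scenario).
#' @return A tibble.
#' @export
finnish_reference <- function(table = c("min_cost_male",
                                        "min_deviation_cost_female",
                                        "min_deviation_energy_female",
                                        "min_deviation_ghge_female",
                                        "decomposition_male")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("finnish_", table, ".csv"),
                      package = "sustdiet", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
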