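#' Share-of-total columns
#'
#' Appends, for each requested value column, a companion \code{<col>_share}
#' column with the category's fraction of the column total.
#'
#' @param report Data frame of per-category values (no total row).
#' @param cols Character vector of numeric columns to compute shares for.
#' @return The report with share columns appended.
#' @export
shares <- function(report, cols) {
  report <- tibble::as_tibble(report)
  for (cl in cols) {
    total <- sum(report[[cl]])
    if (total <= 0) stop("zero total for column ", cl, call. = FALSE)
    report[[paste0(cl, "_share")]] <- report[[cl]] / total
  }
  report
}

#' Per-category scenario report
#'
#' The standard result surface for one diet: cost (EUR/cap/d), energy
#' (kJ/cap/d) and GHGE (kg CO2e/cap/d) per main food category, each with its
#' share of the total, plus a \code{"Total"} row. Shares of a valid report
#' sum to 1 up to rounding.
#'
#' @param diet Data frame with columns \code{food_id}, \code{quantity}, or a
#'   \code{diet_solution}.
#' @param universe A [food_universe()].
#' @return Tibble with columns \code{main_category}, \code{cost_eur},
#'   \code{energy_kj}, \code{ghge_kg} and the three share columns.
#' @export
scenario_report <- function(diet, universe) {
  if (inherits(diet, "diet_solution")) {
    stopifnot(diet$status == "optimal")
    diet <- diet$diet
  }
  agg <- aggregate_to_main(diet, universe) |>
    dplyr::mutate(ghge_kg = .data$ghge_g / 1000) |>
    dplyr::select("main_category", "cost_eur", "energy_kj", "ghge_kg") |>
    shares(c("cost_eur", "energy_kj", "ghge_kg"))
  total <- agg |>
    dplyr::summarise(main_category = "Total",
                     dplyr::across(dplyr::where(is.numeric), sum))
  dplyr::bind_rows(agg, total)
}

#' Baseline-relative summary ratios
#'
#' Percent-of-baseline and percent-change of solution totals, the form in
#' which headline results are quoted (e.g. a minimum-cost diet costing 27%
#' of the baseline diet). Values are kept at full precision; rounding to
#' integer percent happens only at presentation.
#'
#' @param baseline,solution One-row data frames of totals with common
#'   numeric columns (e.g. from [baseline_totals()] or a solution's
#'   \code{totals}).
#' @return Tibble with columns \code{metric}, \code{baseline},
#'   \code{solution}, \code{percent_of_baseline}, \code{percent_change}.
#' @export
summary_ratios <- function(baseline, solution) {
  baseline <- tibble::as_tibble(baseline)
  solution <- tibble::as_tibble(solution)
  metrics <- intersect(names(baseline), names(solution))
  metrics <- metrics[vapply(baseline[metrics], is.numeric, logical(1))]
  if (length(metrics) == 0) stop("no common numeric totals", call. = FALSE)
  if (any(unlist(baseline[metrics]) <= 0)) {
    stop("baseline totals must be positive", call. = FALSE)
  }
  tibble::tibble(
    metric = metrics,
    baseline = as.numeric(baseline[1, metrics]),
    solution = as.numeric(solution[1, metrics])) |>
    dplyr::mutate(percent_of_baseline = 100 * .data$solution /
                    .data$baseline,
                  percent_change = .data$percent_of_baseline - 100)
}

#' Count the foods actually consumed in a diet
#'
#' @param diet Data frame with columns \code{food_id}, \code{quantity}, or a
#'   \code{diet_solution}.
#' @param threshold Quantities strictly above this count as consumed;
#'   default 0 (so a 0.3 g/d trace still counts).
#' @return Integer count.
#' @export
nonzero_food_count <- function(diet, threshold = 0) {
  if (inherits(diet, "diet_solution")) diet <- diet$diet
  diet <- tibble::as_tibble(diet)
  sum(diet$quantity > threshold, na.rm = TRUE)
}

#' Stacked scenario bars
#'
#' Figure-style view of scenario reports: one stacked bar per scenario for
#' the chosen metric, filled by main category.
#'
#' @param reports Tibble of per-category reports (no total rows) with a
#'   \code{scenario} column, e.g. several [scenario_report()]s bound
#'   together.
#' @param metric One of \code{"cost_eur"}, \code{"energy_kj"},
#'   \code{"ghge_kg"}.
#' @return A ggplot object.
#' @export
plot_scenario_bars <- function(reports, metric = c("cost_eur", "energy_kj",
                                                   "ghge_kg")) {
  metric <- match.arg(metric)
  reports <- dplyr::filter(tibble::as_tibble(reports),
                           .data$main_category != "Total")
  lab <- c(cost_eur = "EUR/cap/d", energy_kj = "kJ/cap/d",
           ghge_kg = "kg CO2e/cap/d")[[metric]]
  ggplot2::ggplot(reports,
                  ggplot2::aes(x = .data$scenario, y = .data[[metric]],
                               fill = .data$main_category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = lab, fill = "Main category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
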