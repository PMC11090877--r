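#' Intra-/inter-category decomposition of a diet change
#'
#' Splits the change in a value aggregate (cost or GHGE) between two diets
#' into, per main category, an \emph{inter}-category term — the change
#' attributable to the category's total quantity, valued at its baseline
#' mean unit value (a Laspeyres-type weighting) — and an \emph{intra}
#' -category term — the residual attributable to substitutions within the
#' category that alter its mean unit value. With V_C = sum_{i in C} v_i x_i
#' and Q_C = sum_{i in C} x_i,
#' \deqn{inter_C = \bar v_C^0 (Q_C^1 - Q_C^0), \quad
#'       intra_C = V_C^1 - \bar v_C^0 Q_C^1,}
#' where \eqn{\bar v_C^0 = V_C^0 / Q_C^0}. The two terms add up to the total
#' change exactly. A category with zero baseline quantity has no baseline
#' unit value; by convention its whole change is inter-category.
#'
#' @param diets Data frame with columns \code{food_id}, \code{x0} (baseline
#'   diet, g/d) and \code{x1} (comparison diet, g/d).
#' @param universe A [food_universe()] supplying unit values and the mapping
#'   of the 74 foods to the 16 main categories.
#' @param metric \code{"cost"} (unit values EUR/g) or \code{"ghge"}
#'   (g CO2e/g).
#' @param values Optional numeric vector of unit values per food (in the
#'   universe's food order) overriding the metric column.
#' @return Tibble with columns \code{main_category}, \code{metric},
#'   \code{delta_total}, \code{intra}, \code{inter}, in the unit value's
#'   units times grams (EUR/d for cost, g CO2e/d for ghge).
#' @export
decompose_change <- function(diets, universe, metric = c("cost", "ghge"),
                             values = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(universe, "food_universe"))
  diets <- tibble::as_tibble(diets)
  if (!all(c("food_id", "x0", "x1") %in% names(diets))) {
    stop("diets needs columns food_id, x0, x1", call. = FALSE)
  }
  if (any(diets$x0 < 0) || any(diets$x1 < 0)) {
    stop("diet quantities must be >= 0", call. = FALSE)
  }
  unknown <- setdiff(diets$food_id, universe$foods$id)
  if (length(unknown) > 0) {
    stop("mapping missing for food(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(values)) {
    values <- switch(metric,
      cost = universe$foods$price_eur_per_g,
      ghge = universe$foods$ghge_g_per_g)
  }
  vals <- tibble::tibble(food_id = universe$foods$id,
                         main_category = universe$foods$main_category,
                         v = values)
  diets |>
    dplyr::inner_join(vals, by = "food_id") |>
    dplyr::group_by(.data$main_category) |>
    dplyr::summarise(
      q0 = sum(.data$x0), q1 = sum(.data$x1),
      v0 = sum(.data$v * .data$x0), v1 = sum(.data$v * .data$x1),
      .groups = "drop") |>
    dplyr::mutate(
      delta_total = .data$v1 - .data$v0,
      inter = dplyr::if_else(.data$q0 > 0,
                             .data$v0 / .data$q0 * (.data$q1 - .data$q0),
                             .data$delta_total),
      intra = .data$delta_total - .data$inter,
      metric = metric) |>
    dplyr::select("main_category", "metric", "delta_total", "intra",
                  "inter")
}

#' Decomposition table across scenarios
#'
#' Tabulates the intra/inter decomposition of cost (EUR/cap/d) and GHGE
#' (kg CO2e/cap/d) changes from the baseline diet to each scenario's
#' solution, with a \code{"Total"} row per metric and scenario. This is the
#' per-category substitution accounting used to ask how much of a diet
#' change's cost and emission savings come from within-category versus
#' across-category substitutions.
#'
#' @param solutions Named list of optimal \code{diet_solution}s (names are
#'   used as scenario labels; unnamed lists fall back to each solution's own
#'   scenario name).
#' @param universe The shared [food_universe()].
#' @return Tibble with columns \code{main_category}, \code{metric},
#'   \code{scenario}, \code{intra}, \code{inter}, \code{delta_total}.
#' @export
decomposition_table <- function(solutions, universe) {
  if (inherits(solutions, "diet_solution")) solutions <- list(solutions)
  labels <- names(solutions)
  if (is.null(labels)) labels <- rep(NA_character_, length(solutions))
  purrr::map2_dfr(solutions, labels, function(sol, lab) {
    stopifnot(inherits(sol, "diet_solution"), sol$status == "optimal",
              !is.null(sol$baseline))
    lab <- if (is.na(lab) || lab == "") sol$scenario$name else lab
    diets <- dplyr::inner_join(sol$baseline, sol$diet, by = "food_id") |>
      dplyr::rename(x1 = "quantity")
    purrr::map_dfr(c("cost", "ghge"), function(m) {
      d <- decompose_change(diets, universe, metric = m)
      if (m == "ghge") {  # report kg CO2e/cap/d
        d <- dplyr::mutate(d, dplyr::across(
          c("delta_total", "intra", "inter"), ~ .x / 1000))
      }
      total <- d |>
        dplyr::summarise(main_category = "Total", metric = m,
                         delta_total = sum(.data$delta_total),
                         intra = sum(.data$intra),
                         inter = sum(.data$inter))
      dplyr::bind_rows(d, total)
    }) |>
      dplyr::mutate(scenario = lab)
  }) |>
    dplyr::select("main_category", "metric", "scenario", "intra", "inter",
                  "delta_total")
}
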