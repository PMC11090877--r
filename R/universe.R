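#' Assemble a food universe
#'
#' A food universe bundles everything the optimization models need to know
#' about the food supply: the food categories themselves (with energy density,
#' price, greenhouse-gas emission coefficient, beef-carcass fraction and
#' raw-milk equivalent), the nutrient definitions, the per-gram nutrient
#' density matrix, the nutrient adequacy bounds, and the dairy-beef jointness
#' coefficient.
#'
#' Units are fixed by convention: quantities are g/capita/d, energy densities
#' kJ/g, prices EUR/g, emission coefficients g CO2e per g of food, nutrient
#' densities in the nutrient's own unit per g of food. The raw-milk equivalent
#' \code{raw_milk_equiv} is g of raw milk embodied per g of food (0 for
#' non-dairy foods) and \code{beef_fraction} is the share of a food's mass
#' counted as beef carcass for the jointness constraint.
#'
#' @param foods Data frame with columns \code{id}, \code{name},
#'   \code{main_category}, \code{energy_kj_per_g}, \code{price_eur_per_g},
#'   \code{ghge_g_per_g}, \code{beef_fraction}, \code{raw_milk_equiv}.
#' @param nutrients Data frame with columns \code{id}, \code{name},
#'   \code{unit} (one of \code{"g/d"}, \code{"mg/d"}, \code{"ug/d"},
#'   \code{"\%E"}), \code{kind} (one of \code{"macronutrient"},
#'   \code{"vitamin"}, \code{"mineral"}, \code{"amino_acid"}) and optionally
#'   \code{energy_component} (\code{"fat"}, \code{"protein"},
#'   \code{"carbohydrate"}, \code{"alcohol"} or \code{NA}) used to pick the
#'   energy conversion factor for \%E bounds.
#' @param density Numeric matrix, foods in rows and nutrients in columns
#'   (dimnames must match the id columns), giving the amount of each nutrient
#'   per g of each food.
#' @param bounds Data frame of nutrient bounds with columns
#'   \code{nutrient_id}, \code{sex}, \code{lower}, \code{upper},
#'   \code{source}; \code{NA} marks an absent side. May be \code{NULL} and
#'   attached later.
#' @param milk_per_beef Grams of raw milk co-produced with each gram of beef
#'   carcass in the dairy chain; the default 33.9 is the Finnish estimate.
#'
#' @return An object of class \code{food_universe}.
#' @seealso [generate_universe()] for a synthetic universe,
#'   [read_universe()] for the CSV schemas.
#' @export
food_universe <- function(foods, nutrients, density, bounds = NULL,
                          milk_per_beef = 33.9) {
  foods <- tibble::as_tibble(foods)
  nutrients <- tibble::as_tibble(nutrients)
  need_f <- c("id", "name", "main_category", "energy_kj_per_g",
              "price_eur_per_g", "ghge_g_per_g", "beef_fraction",
              "raw_milk_equiv")
  missing_f <- setdiff(need_f, names(foods))
  if (length(missing_f) > 0) {
    stop("foods is missing column(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  need_n <- c("id", "name", "unit", "kind")
  missing_n <- setdiff(need_n, names(nutrients))
  if (length(missing_n) > 0) {
    stop("nutrients is missing column(s): ", paste(missing_n, collapse = ", "),
         call. = FALSE)
  }
  if (!"energy_component" %in% names(nutrients)) {
    nutrients$energy_component <- NA_character_
  }
  if (anyDuplicated(foods$id)) stop("food ids must be unique", call. = FALSE)
  if (anyDuplicated(nutrients$id)) {
    stop("nutrient ids must be unique", call. = FALSE)
  }
  density <- as.matrix(density)
  if (!identical(rownames(density), foods$id) ||
      !identical(colnames(density), nutrients$id)) {
    # accept any ordering, but the ids must agree
    if (is.null(rownames(density)) || is.null(colnames(density)) ||
        !setequal(rownames(density), foods$id) ||
        !setequal(colnames(density), nutrients$id)) {
      stop("density dimnames must match food and nutrient ids", call. = FALSE)
    }
    density <- density[foods$id, nutrients$id, drop = FALSE]
  }
  num_cols <- c("energy_kj_per_g", "price_eur_per_g", "ghge_g_per_g",
                "beef_fraction", "raw_milk_equiv")
  for (cl in num_cols) {
    if (any(!is.finite(foods[[cl]])) || any(foods[[cl]] < 0)) {
      stop("foods$", cl, " must be finite and non-negative", call. = FALSE)
    }
  }
  if (any(foods$beef_fraction > 1)) {
    stop("beef_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(density < 0)) stop("nutrient densities must be >= 0", call. = FALSE)
  bad_unit <- setdiff(unique(nutrients$unit), c("g/d", "mg/d", "ug/d", "%E"))
  if (length(bad_unit) > 0) {
    stop("unknown nutrient unit(s): ", paste(bad_unit, collapse = ", "),
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(nutrients$kind),
                      c("macronutrient", "vitamin", "mineral", "amino_acid"))
  if (length(bad_kind) > 0) {
    stop("unknown nutrient kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  u <- structure(
    list(foods = foods, nutrients = nutrients, density = density,
         bounds = NULL, milk_per_beef = milk_per_beef),
    class = "food_universe")
  if (!is.null(bounds)) u <- set_bounds(u, bounds)
  u
}

#' Attach nutrient bounds to a universe
#'
#' @param universe A [food_universe()].
#' @param bounds Data frame with columns \code{nutrient_id}, \code{sex},
#'   \code{lower}, \code{upper}, \code{source}. At least one of lower/upper
#'   must be present per row and every referenced nutrient must exist.
#' @return The universe with bounds attached.
#' @export
set_bounds <- function(universe, bounds) {
  stopifnot(inherits(universe, "food_universe"))
  bounds <- tibble::as_tibble(bounds)
  need <- c("nutrient_id", "sex", "lower", "upper", "source")
  missing_b <- setdiff(need, names(bounds))
  if (length(missing_b) > 0) {
    stop("bounds is missing column(s): ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(bounds$nutrient_id, universe$nutrients$id)
  if (length(unknown) > 0) {
    stop("bounds reference unknown nutrient(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(bounds$lower) & is.na(bounds$upper))) {
    stop("every bound needs at least one of lower/upper", call. = FALSE)
  }
  both <- !is.na(bounds$lower) & !is.na(bounds$upper)
  if (any(bounds$lower[both] > bounds$upper[both])) {
    stop("bound lower > upper for some nutrient", call. = FALSE)
  }
  universe$bounds <- bounds
  universe
}

#' @export
print.food_universe <- function(x, ...) {
  nb <- if (is.null(x$bounds)) 0L else nrow(x$bounds)
  cat("<food_universe> ", nrow(x$foods), " foods in ",
      dplyr::n_distinct(x$foods$main_category), " main categories, ",
      nrow(x$nutrients), " nutrients, ", nb, " bound rows; milk_per_beef = ",
      x$milk_per_beef, "\n", sep = "")
  invisible(x)
}

#' Define a population group
#'
#' A population group carries the observed baseline diet of a
#' sex-by-sociodemographic stratum together with its food-habit percentiles:
#' \code{x0} is the mean observed intake of each food (g/capita/d), and
#' \code{p10}/\code{p90} are the 10th and 90th centiles of the consumption
#' distribution used as habit bounds in the minimum-deviation model.
#'
#' @param diet Data frame with columns \code{food_id}, \code{x0}, \code{p10},
#'   \code{p90} (all g/capita/d).
#' @param sex \code{"female"} or \code{"male"}.
#' @param label Group label, e.g. \code{"all"}, \code{"edu_low"},
#'   \code{"inc_q5"}.
#' @return An object of class \code{population_group}.
#' @export
population_group <- function(diet, sex = c("female", "male"), label = "all") {
  sex <- match.arg(sex)
  diet <- tibble::as_tibble(diet)
  need <- c("food_id", "x0", "p10", "p90")
  missing_d <- setdiff(need, names(diet))
  if (length(missing_d) > 0) {
    stop("diet is missing column(s): ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  if (any(diet$x0 < 0) || any(diet$p10 < 0) || any(diet$p90 < 0)) {
    stop("x0, p10 and p90 must be non-negative", call. = FALSE)
  }
  if (any(diet$p10 > diet$p90)) {
    stop("p10 must not exceed p90 for any food", call. = FALSE)
  }
  structure(list(sex = sex, label = label, diet = diet),
            class = "population_group")
}

#' @export
print.population_group <- function(x, ...) {
  cat("<population_group> sex = ", x$sex, ", label = ", x$label, ", ",
      nrow(x$diet), " foods\n", sep = "")
  invisible(x)
}

# Baseline vector x0 aligned with the universe's food order.
baseline_vector <- function(universe, group) {
  idx <- match(universe$foods$id, group$diet$food_id)
  if (anyNA(idx)) {
    stop("group diet does not cover every food in the universe",
         call. = FALSE)
  }
  stats::setNames(group$diet$x0[idx], universe$foods$id)
}

habit_matrix <- function(universe, group) {
  idx <- match(universe$foods$id, group$diet$food_id)
  if (anyNA(idx)) {
    stop("group diet does not cover every food in the universe",
         call. = FALSE)
  }
  cbind(p10 = group$diet$p10[idx], p90 = group$diet$p90[idx])
}

#' Baseline totals of a population group
#'
#' Energy (kJ/d), cost (EUR/d) and GHGE (g CO2e/d) of the group's observed
#' baseline diet, computed as dot products of the baseline intake vector with
#' the universe's per-gram coefficients.
#'
#' @inheritParams build_constraints
#' @return One-row tibble with columns \code{energy_kj}, \code{cost_eur},
#'   \code{ghge_g}, \code{quantity_g}.
#' @export
baseline_totals <- function(universe, group) {
  x0 <- baseline_vector(universe, group)
  tibble::tibble(
    energy_kj = sum(universe$foods$energy_kj_per_g * x0),
    cost_eur = sum(universe$foods$price_eur_per_g * x0),
    ghge_g = sum(universe$foods$ghge_g_per_g * x0),
    quantity_g = sum(x0))
}

#' Scenario definitions
#'
#' The three study scenarios: \code{"health_only"} imposes nutritional
#' constraints only; \code{"health_ghge_minus33"} and
#' \code{"health_ghge_minus50"} additionally cap dietary GHGE at two-thirds
#' and half of its baseline level respectively.
#'
#' @param name Scenario name, one of the above, or any name combined with an
#'   explicit \code{ghge_fraction}.
#' @param ghge_fraction Optional cap expressed as a fraction of baseline GHGE
#'   (in (0, 1]); overrides the fraction implied by \code{name}.
#' @return A list with elements \code{name} and \code{ghge_fraction}
#'   (\code{NA} when no cap applies), of class \code{diet_scenario}.
#' @export
scenario <- function(name = c("health_only", "health_ghge_minus33",
                              "health_ghge_minus50"),
                     ghge_fraction = NULL) {
  if (is.null(ghge_fraction)) {
    name <- match.arg(name)
    ghge_fraction <- switch(name,
      health_only = NA_real_,
      health_ghge_minus33 = 2 / 3,
      health_ghge_minus50 = 1 / 2)
  } else {
    if (!is.na(ghge_fraction) &&
        (ghge_fraction <= 0 || ghge_fraction > 1)) {
      stop("ghge_fraction must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(name = name, ghge_fraction = ghge_fraction),
            class = "diet_scenario")
}

default_scenarios <- function() {
  list(scenario("health_only"), scenario("health_ghge_minus33"),
       scenario("health_ghge_minus50"))
}

as_scenario <- function(x) {
  if (inherits(x, "diet_scenario")) x else scenario(x)
}

#' Aggregate a diet to main food categories
#'
#' Sums quantity, cost, energy and GHGE of a diet over the 16 main food
#' categories. Grand totals over categories equal the ungrouped totals
#' exactly (conservation).
#'
#' @param diet Data frame with columns \code{food_id} and \code{quantity}
#'   (g/capita/d).
#' @param universe A [food_universe()].
#' @return Tibble with one row per main category: \code{main_category},
#'   \code{quantity_g}, \code{cost_eur}, \code{energy_kj}, \code{ghge_g}.
#' @export
aggregate_to_main <- function(diet, universe) {
  stopifnot(inherits(universe, "food_universe"))
  diet <- tibble::as_tibble(diet)
  if (!all(c("food_id", "quantity") %in% names(diet))) {
    stop("diet needs columns food_id and quantity", call. = FALSE)
  }
  unknown <- setdiff(diet$food_id, universe$foods$id)
  if (length(unknown) > 0) {
    stop("diet references unknown food(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(diet$quantity < 0)) stop("quantities must be >= 0", call. = FALSE)
  diet |>
    dplyr::left_join(universe$foods, by = c(food_id = "id")) |>
    dplyr::group_by(.data$main_category) |>
    dplyr::summarise(
      quantity_g = sum(.data$quantity),
      cost_eur = sum(.data$quantity * .data$price_eur_per_g),
      energy_kj = sum(.data$quantity * .data$energy_kj_per_g),
      ghge_g = sum(.data$quantity * .data$ghge_g_per_g),
      .groups = "drop")
}
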