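#' Configuration for the constraint builder
#'
#' @param energy_conversion Named vector of energy conversion factors (kJ per
#'   g) for the energy-yielding components, used to linearize bounds stated
#'   in percent of energy (\%E) under the isocaloric constraint. Defaults:
#'   fat 37, protein 17, carbohydrate 17, alcohol 29.
#' @param amino_safety_multiplier Multiplier applied to amino-acid lower
#'   bounds (requirement plus safety margin); default 1.24.
#' @param iron_rule_female If \code{TRUE} (default), the iron lower bound for
#'   female groups is replaced by the baseline iron intake: under the
#'   isocaloric constraint this pins the iron concentration of the solution
#'   diet at its observed level.
#' @param iron_nutrient Id of the iron nutrient; default \code{"iron"}.
#' @param include_habit_bounds \code{NULL} (default) applies habit bounds for
#'   the minimum-deviation model and plain non-negativity for the
#'   minimum-cost model; \code{TRUE}/\code{FALSE} overrides.
#' @param milk_per_beef Optional override of the universe's raw-milk per
#'   beef-carcass coefficient.
#' @return A list of class \code{builder_config}.
#' @export
builder_config <- function(energy_conversion = c(fat = 37, protein = 17,
                                                 carbohydrate = 17,
                                                 alcohol = 29),
                           amino_safety_multiplier = 1.24,
                           iron_rule_female = TRUE,
                           iron_nutrient = "iron",
                           include_habit_bounds = NULL,
                           milk_per_beef = NULL) {
  if (any(energy_conversion <= 0)) {
    stop("energy conversion factors must be > 0", call. = FALSE)
  }
  if (amino_safety_multiplier < 1) {
    stop("amino_safety_multiplier must be >= 1", call. = FALSE)
  }
  structure(list(energy_conversion = energy_conversion,
                 amino_safety_multiplier = amino_safety_multiplier,
                 iron_rule_female = iron_rule_female,
                 iron_nutrient = iron_nutrient,
                 include_habit_bounds = include_habit_bounds,
                 milk_per_beef = milk_per_beef),
            class = "builder_config")
}

#' Construct a constraint system directly
#'
#' Low-level constructor for a labelled linear constraint system over a food
#' vector: rows \code{lower <= A x <= upper} (equality when the two sides
#' coincide) plus variable box bounds. [build_constraints()] is the usual
#' way to obtain one; this constructor is for hand-built systems.
#'
#' @param A Coefficient matrix, one column per food.
#' @param lower,upper Row bounds (\code{-Inf}/\code{Inf} for one-sided rows).
#' @param label Row labels; defaults to \code{row1, row2, ...}.
#' @param family Row families (e.g. \code{"energy"}, \code{"nutrient"});
#'   recycled.
#' @param x_lower,x_upper Variable bounds; default non-negativity.
#' @param food_id Food identifiers; default \code{food1, food2, ...}.
#' @param model,scen Metadata recorded on the system.
#' @return A \code{constraint_system}.
#' @export
constraint_system <- function(A, lower, upper, label = NULL,
                              family = "row", x_lower = NULL,
                              x_upper = NULL, food_id = NULL,
                              model = "min_cost",
                              scen = scenario("health_only")) {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  label <- label %||% paste0("row", seq_len(m))
  stopifnot(length(lower) == m, length(upper) == m, length(label) == m)
  structure(
    list(A = A, lower = lower, upper = upper, label = label,
         family = rep_len(family, m),
         x_lower = x_lower %||% rep(0, n),
         x_upper = x_upper %||% rep(Inf, n),
         food_id = food_id %||% paste0("food", seq_len(n)),
         model = model, scenario = as_scenario(scen)),
    class = "constraint_system")
}

row_set <- function(A, lower, upper, label, family) {
  A <- matrix(A, nrow = length(label))
  list(A = A, lower = lower, upper = upper, label = label,
       family = rep_len(family, length(label)))
}

#' Isocaloric energy equality
#'
#' Row imposing that total dietary energy equals its observed baseline level
#' E0 = sum(e_i * x0_i); all simulated diets are isocaloric.
#'
#' @param universe A [food_universe()].
#' @param group A [population_group()].
#' @return A row set (coefficients, lower = upper = E0).
#' @export
energy_equality <- function(universe, group) {
  x0 <- baseline_vector(universe, group)
  e <- universe$foods$energy_kj_per_g
  E0 <- sum(e * x0)
  if (E0 <= 0) stop("baseline energy must be positive", call. = FALSE)
  row_set(e, E0, E0, "energy", "energy")
}

#' Nutrient adequacy rows
#'
#' One two-sided inequality per bounded nutrient: L_j <= sum_i a_ji x_i <=
#' U_j in the nutrient's own unit. Bounds in \%E are linearized with the
#' configured energy conversion factors (valid because total energy is fixed
#' at E0): L_j/100 * E0 <= sum_i conv_j a_ji x_i <= U_j/100 * E0. Amino-acid
#' lower bounds are multiplied by the safety margin, and for female groups
#' the iron lower bound is replaced by baseline iron intake when the iron
#' rule is on.
#'
#' @inheritParams energy_equality
#' @param config A [builder_config()].
#' @return A row set with one row per bounded nutrient, labelled
#'   \code{nutrient:<id>}.
#' @export
nutrient_rows <- function(universe, group, config = builder_config()) {
  if (is.null(universe$bounds)) {
    stop("universe has no nutrient bounds attached", call. = FALSE)
  }
  x0 <- baseline_vector(universe, group)
  E0 <- sum(universe$foods$energy_kj_per_g * x0)
  b <- universe$bounds |>
    dplyr::filter(.data$sex %in% c(group$sex, "both")) |>
    dplyr::group_by(.data$nutrient_id) |>
    dplyr::summarise(
      lower = if (all(is.na(.data$lower))) NA_real_ else
        max(.data$lower, na.rm = TRUE),
      upper = if (all(is.na(.data$upper))) NA_real_ else
        min(.data$upper, na.rm = TRUE),
      .groups = "drop")
  b <- b[match(intersect(universe$nutrients$id, b$nutrient_id),
               b$nutrient_id), ]
  nut <- universe$nutrients[match(b$nutrient_id, universe$nutrients$id), ]

  A <- t(universe$density[, b$nutrient_id, drop = FALSE])
  lower <- ifelse(is.na(b$lower), -Inf, b$lower)
  upper <- ifelse(is.na(b$upper), Inf, b$upper)

  amino <- nut$kind == "amino_acid"
  lower[amino & is.finite(lower)] <-
    lower[amino & is.finite(lower)] * config$amino_safety_multiplier

  pct_e <- nut$unit == "%E"
  if (any(pct_e)) {
    conv <- config$energy_conversion[nut$energy_component[pct_e]]
    if (anyNA(conv)) {
      stop("%E nutrient without an energy conversion factor: ",
           paste(b$nutrient_id[pct_e][is.na(conv)], collapse = ", "),
           call. = FALSE)
    }
    A[pct_e, ] <- A[pct_e, , drop = FALSE] * conv
    lower[pct_e] <- ifelse(is.finite(lower[pct_e]),
                           lower[pct_e] / 100 * E0, -Inf)
    upper[pct_e] <- ifelse(is.finite(upper[pct_e]),
                           upper[pct_e] / 100 * E0, Inf)
  }

  if (config$iron_rule_female && group$sex == "female" &&
      config$iron_nutrient %in% b$nutrient_id) {
    k <- which(b$nutrient_id == config$iron_nutrient)
    lower[k] <- sum(universe$density[, config$iron_nutrient] * x0)
    if (is.finite(upper[k]) && upper[k] < lower[k]) upper[k] <- Inf
  }

  row_set(A, lower, upper, paste0("nutrient:", b$nutrient_id), "nutrient")
}

#' Greenhouse-gas emission cap
#'
#' Row capping dietary GHGE at a fraction of its baseline level,
#' sum_i g_i x_i <= theta * G0. Returns \code{NULL} for the health-only
#' scenario (no cap).
#'
#' @inheritParams energy_equality
#' @param scen A [scenario()] or scenario name.
#' @return A row set with one row, or \code{NULL}.
#' @export
ghge_cap <- function(universe, group, scen) {
  scen <- as_scenario(scen)
  if (is.na(scen$ghge_fraction)) return(NULL)
  x0 <- baseline_vector(universe, group)
  g <- universe$foods$ghge_g_per_g
  G0 <- sum(g * x0)
  if (G0 <= 0) stop("baseline GHGE must be positive", call. = FALSE)
  row_set(g, -Inf, scen$ghge_fraction * G0, "ghge", "ghge")
}

#' Dairy-beef jointness row
#'
#' Dairy production co-produces beef: each gram of beef carcass comes with
#' \code{milk_per_beef} grams of raw milk, so the raw-milk demand of a diet
#' cannot exceed the milk supplied by its beef-carcass demand. The row is
#' rho * sum_i b_i x_i - sum_i r_i x_i >= 0 with b_i the beef-carcass
#' fraction and r_i the raw-milk equivalent of food i.
#'
#' @inheritParams nutrient_rows
#' @return A row set with one row labelled \code{dairy_beef}.
#' @export
dairy_beef_row <- function(universe, config = builder_config()) {
  rho <- config$milk_per_beef %||% universe$milk_per_beef
  bf <- universe$foods$beef_fraction
  rm <- universe$foods$raw_milk_equiv
  if (all(bf == 0) && any(rm > 0)) {
    warning("universe has dairy foods but no beef-bearing food: ",
            "dairy-containing diets are structurally infeasible",
            call. = FALSE)
  }
  row_set(rho * bf - rm, 0, Inf, "dairy_beef", "dairy_beef")
}

#' Habit box bounds
#'
#' Per-food variable bounds. For the minimum-deviation model these are the
#' food-habit bounds p10 <= x <= p90; for the minimum-cost model only
#' non-negativity applies.
#'
#' @param group A [population_group()].
#' @param model \code{"min_deviation"} or \code{"min_cost"}.
#' @param universe Optional universe fixing the food order; defaults to the
#'   group's own order.
#' @param include Optional override of the model default.
#' @return List with vectors \code{x_lower} and \code{x_upper}.
#' @export
habit_rows <- function(group, model = c("min_deviation", "min_cost"),
                       universe = NULL, include = NULL) {
  model <- match.arg(model)
  use_habit <- include %||% (model == "min_deviation")
  if (!use_habit) {
    n <- nrow(group$diet)
    return(list(x_lower = rep(0, n), x_upper = rep(Inf, n)))
  }
  hb <- if (is.null(universe)) {
    cbind(p10 = group$diet$p10, p90 = group$diet$p90)
  } else {
    habit_matrix(universe, group)
  }
  if (any(hb[, "p10"] > hb[, "p90"])) {
    stop("p10 exceeds p90 for some food", call. = FALSE)
  }
  list(x_lower = hb[, "p10"], x_upper = hb[, "p90"])
}

#' Assemble the full constraint system
#'
#' Combines the isocaloric energy equality, one adequacy row per bounded
#' nutrient, the GHGE cap (when the scenario has one), the dairy-beef
#' jointness row, and the model-specific variable bounds into a single
#' labelled constraint system.
#'
#' @inheritParams nutrient_rows
#' @param scen A [scenario()] or scenario name.
#' @param model \code{"min_cost"} or \code{"min_deviation"}.
#' @return An object of class \code{constraint_system}: matrix \code{A} with
#'   row labels/families, vectors \code{lower}/\code{upper} (equal for
#'   equality rows), variable bounds \code{x_lower}/\code{x_upper}, and the
#'   food ids.
#' @export
build_constraints <- function(universe, group, scen, model = c("min_deviation",
                                                               "min_cost"),
                              config = builder_config()) {
  model <- match.arg(model)
  scen <- as_scenario(scen)
  parts <- list(energy_equality(universe, group),
                nutrient_rows(universe, group, config),
                ghge_cap(universe, group, scen),
                dairy_beef_row(universe, config))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  box <- habit_rows(group, model, universe = universe,
                    include = config$include_habit_bounds)
  constraint_system(
    A = do.call(rbind, lapply(parts, `[[`, "A")),
    lower = unlist(lapply(parts, `[[`, "lower")),
    upper = unlist(lapply(parts, `[[`, "upper")),
    label = unlist(lapply(parts, `[[`, "label")),
    family = unlist(lapply(parts, `[[`, "family")),
    x_lower = box$x_lower, x_upper = box$x_upper,
    food_id = universe$foods$id, model = model, scen = scen)
}

#' @export
print.constraint_system <- function(x, ...) {
  cat("<constraint_system> ", length(x$food_id), " foods, ",
      nrow(x$A), " rows (", paste(table(x$family)[unique(x$family)],
                                  unique(x$family), collapse = ", "),
      "); model = ", x$model, ", scenario = ", x$scenario$name, "\n",
      sep = "")
  invisible(x)
}

solution_x <- function(solution, system = NULL) {
  if (inherits(solution, "diet_solution")) {
    stats::setNames(solution$diet$quantity, solution$diet$food_id)
  } else if (is.numeric(solution)) {
    solution
  } else {
    stop("solution must be a diet_solution or a numeric vector",
         call. = FALSE)
  }
}

#' Verify a solution against a constraint system
#'
#' Recomputes every constraint row (and variable bound) at the given diet and
#' reports its value, slack, and whether it is binding or violated. The
#' report is independent of any solver internals: it is a direct dense
#' matrix-vector evaluation.
#'
#' @param solution A \code{diet_solution} or numeric diet vector in the
#'   system's food order.
#' @param system A [build_constraints()] system.
#' @param tol Feasibility/binding tolerance, default \code{1e-6}
#'   (constraint rows are compared on the scale of their coefficients).
#' @return Tibble with one row per constraint and per finite variable bound:
#'   \code{label}, \code{family}, \code{value}, \code{lower}, \code{upper},
#'   \code{slack} (negative = violated), \code{binding}, \code{violated}.
#'   Attributes \code{feasible} (logical) and \code{worst_violation}.
#' @export
verify_solution <- function(solution, system, tol = 1e-6) {
  stopifnot(inherits(system, "constraint_system"))
  x <- solution_x(solution)
  if (length(x) != length(system$food_id)) {
    stop("solution length ", length(x), " does not match system size ",
         length(system$food_id), call. = FALSE)
  }
  scale_row <- pmax(apply(abs(system$A), 1, max), 1)
  value <- as.numeric(system$A %*% x)
  slack_row <- pmin(value - system$lower, system$upper - value) / scale_row
  rows <- tibble::tibble(
    label = system$label, family = system$family, value = value,
    lower = system$lower, upper = system$upper, slack = slack_row)
  bscale <- pmax(abs(x), 1)
  bnd <- tibble::tibble(
    label = paste0("bound:", system$food_id), family = "habit",
    value = x, lower = system$x_lower, upper = system$x_upper,
    slack = pmin(x - system$x_lower, system$x_upper - x) / bscale)
  out <- dplyr::bind_rows(rows, bnd) |>
    dplyr::mutate(binding = abs(.data$slack) <= tol,
                  violated = .data$slack < -tol)
  worst <- max(0, -min(out$slack))
  attr(out, "worst_violation") <- worst
  attr(out, "feasible") <- worst <= tol
  out
}

#' @rdname verify_solution
#' @export
is_feasible <- function(solution, system, tol = 1e-6) {
  attr(verify_solution(solution, system, tol), "feasible")
}
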