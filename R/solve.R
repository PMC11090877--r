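#' Solver settings
#'
#' @param feasibility_tol Maximum allowed (row-scaled) constraint violation
#'   for a solution to be reported optimal; default \code{1e-6}.
#' @param binding_tol Absolute slack below which a constraint is reported as
#'   binding; default \code{1e-6}.
#' @param max_iter Optional iteration cap for the simplex solver; defaults to
#'   a generous multiple of the problem size.
#' @return A list of class \code{solver_settings}.
#' @export
solver_settings <- function(feasibility_tol = 1e-6, binding_tol = 1e-6,
                            max_iter = NULL) {
  if (feasibility_tol <= 0 || binding_tol <= 0) {
    stop("tolerances must be > 0", call. = FALSE)
  }
  structure(list(feasibility_tol = feasibility_tol,
                 binding_tol = binding_tol, max_iter = max_iter),
            class = "solver_settings")
}

# Split a constraint system into simplex-ready one-sided rows, scaled so
# every row has unit max coefficient. boot::simplex() wants non-negative
# right-hand sides, so rows are flipped between the <= and >= blocks when
# needed.
lp_blocks <- function(system) {
  n <- length(system$food_id)
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL; A3 <- NULL; b3 <- NULL
  add <- function(row, rhs, type) {
    s <- max(abs(row), 1e-12)
    row <- row / s; rhs <- rhs / s
    if (type == "eq") {
      if (rhs < 0) { row <- -row; rhs <- -rhs }
      A3 <<- rbind(A3, row); b3 <<- c(b3, rhs)
    } else if (type == "le") {
      if (rhs < 0) { A2 <<- rbind(A2, -row); b2 <<- c(b2, -rhs) }
      else { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
    } else {
      if (rhs < 0) { A1 <<- rbind(A1, -row); b1 <<- c(b1, -rhs) }
      else { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
    }
  }
  for (k in seq_along(system$label)) {
    row <- system$A[k, ]
    lo <- system$lower[k]; up <- system$upper[k]
    if (is.finite(lo) && is.finite(up) && lo == up) {
      add(row, lo, "eq")
    } else {
      if (is.finite(up)) add(row, up, "le")
      if (is.finite(lo)) add(row, lo, "ge")
    }
  }
  # simplex works on x >= 0; other finite variable bounds become rows
  ei <- diag(n)
  for (i in seq_len(n)) {
    if (system$x_lower[i] > 0) add(ei[i, ], system$x_lower[i], "ge")
    if (is.finite(system$x_upper[i])) add(ei[i, ], system$x_upper[i], "le")
  }
  if (is.null(A1)) {
    # boot::simplex mishandles an empty <= block; add a redundant row
    add(rep(1, n), 1e9, "le")
  }
  list(A1 = A1, b1 = b1, A2 = A2, b2 = b2, A3 = A3, b3 = b3)
}

lp_solve_raw <- function(system, objective, settings) {
  blocks <- lp_blocks(system)
  m <- length(blocks$b1) + length(blocks$b2) + length(blocks$b3)
  n <- length(objective)
  iter <- settings$max_iter %||% (100 + 20 * (n + m))
  res <- boot::simplex(a = objective, A1 = blocks$A1, b1 = blocks$b1,
                       A2 = blocks$A2, b2 = blocks$b2, A3 = blocks$A3,
                       b3 = blocks$b3, maxi = FALSE, n.iter = iter)
  res
}

# One-at-a-time relaxation: which single constraint family, when dropped,
# restores feasibility? Bounded-effort alternative to a full IIS.
diagnose_infeasibility <- function(system, settings = solver_settings()) {
  families <- unique(c(system$family, "habit"))
  restored <- character(0)
  for (f in families) {
    relaxed <- system
    if (f == "habit") {
      relaxed$x_lower <- rep(0, length(system$food_id))
      relaxed$x_upper <- rep(Inf, length(system$food_id))
    } else {
      keep <- system$family != f
      relaxed$A <- system$A[keep, , drop = FALSE]
      relaxed$lower <- system$lower[keep]
      relaxed$upper <- system$upper[keep]
      relaxed$label <- system$label[keep]
      relaxed$family <- system$family[keep]
    }
    res <- try(lp_solve_raw(relaxed, rep(0, length(system$food_id)),
                            settings), silent = TRUE)
    if (!inherits(res, "try-error") && res$solved == 1) {
      restored <- c(restored, f)
    }
  }
  restored
}

new_diet_solution <- function(system, x, status, objective, model,
                              universe = NULL, group = NULL,
                              settings = solver_settings()) {
  n <- length(system$food_id)
  if (is.null(x)) x <- rep(NA_real_, n)
  diet <- tibble::tibble(food_id = system$food_id, quantity = as.numeric(x))
  verification <- NULL
  binding <- character(0)
  if (status == "optimal") {
    verification <- verify_solution(as.numeric(x), system,
                                    settings$feasibility_tol)
    binding <- verification$label[verification$binding]
  }
  totals <- tibble::tibble(cost_eur = NA_real_, energy_kj = NA_real_,
                           ghge_g = NA_real_, quantity_g = NA_real_)
  if (status == "optimal" && !is.null(universe)) {
    totals <- tibble::tibble(
      cost_eur = sum(universe$foods$price_eur_per_g * x),
      energy_kj = sum(universe$foods$energy_kj_per_g * x),
      ghge_g = sum(universe$foods$ghge_g_per_g * x),
      quantity_g = sum(x))
  }
  structure(
    list(model = model, scenario = system$scenario,
         sex = if (is.null(group)) NA_character_ else group$sex,
         group = if (is.null(group)) NA_character_ else group$label,
         status = status, objective = objective, diet = diet,
         totals = totals, binding = binding, verification = verification,
         infeasible_families = character(0), system = system),
    class = "diet_solution")
}

#' Solve the minimum-cost diet problem
#'
#' Linear program: minimize total diet cost sum(p_i x_i) subject to the
#' constraint system. Solved with the simplex method; the reported objective
#' and totals are always recomputed from the returned diet, never copied
#' from solver internals. Minimum-cost optima can be degenerate, so the
#' returned diet is "a" minimum-cost diet; only the objective value is
#' unique.
#'
#' @param system A [build_constraints()] system.
#' @param prices Price vector, EUR/g, in the system's food order.
#' @param settings A [solver_settings()].
#' @param universe Optional [food_universe()] used to fill in energy/GHGE
#'   totals of the solution.
#' @param group Optional [population_group()] recorded in the solution.
#' @return A \code{diet_solution}.
#' @export
solve_min_cost <- function(system, prices, settings = solver_settings(),
                           universe = NULL, group = NULL) {
  stopifnot(inherits(system, "constraint_system"))
  n <- length(system$food_id)
  if (length(prices) != n) stop("prices length mismatch", call. = FALSE)
  if (any(prices < 0)) stop("prices must be >= 0", call. = FALSE)
  if (!is.null(universe) &&
      any(prices == 0 & universe$foods$energy_kj_per_g == 0)) {
    warning("zero-price, zero-energy food present: the LP may be unbounded",
            call. = FALSE)
  }
  res <- try(lp_solve_raw(system, prices, settings), silent = TRUE)
  if (inherits(res, "try-error")) {
    return(new_diet_solution(system, NULL, "error", NA_real_, "min_cost",
                             universe, group, settings))
  }
  if (res$solved != 1) {
    status <- if (res$solved == -1) "infeasible" else "error"
    sol <- new_diet_solution(system, NULL, status, NA_real_, "min_cost",
                             universe, group, settings)
    if (status == "infeasible") {
      sol$infeasible_families <- diagnose_infeasibility(system, settings)
    }
    return(sol)
  }
  # snap solver roundoff onto the variable box (well within tolerance)
  x <- pmin(pmax(as.numeric(res$soln), system$x_lower), system$x_upper)
  ver <- verify_solution(x, system, settings$feasibility_tol)
  if (!attr(ver, "feasible")) {
    return(new_diet_solution(system, NULL, "error", NA_real_, "min_cost",
                             universe, group, settings))
  }
  new_diet_solution(system, x, "optimal", sum(prices * x), "min_cost",
                    universe, group, settings)
}

# Quadratic program via the dual active-set method: minimize
# 0.5 x' D x - d' x with D = diag(2 / x0^2), d = 2 / x0, which equals
# sum(((x - x0) / x0)^2) up to the constant n. Two-sided rows are split,
# fixed variables (p10 == p90) and equality rows go into the meq block, and
# every row is scaled to unit max coefficient for conditioning.
qp_solve_raw <- function(system, x0) {
  n <- length(x0)
  Dmat <- diag(2 / x0^2, n)
  dvec <- 2 / x0
  eq_rows <- list(); in_rows <- list()
  push <- function(store, row, rhs) {
    s <- max(abs(row), 1e-12)
    store[[length(store) + 1]] <- c(row / s, rhs / s)
    store
  }
  for (k in seq_along(system$label)) {
    row <- system$A[k, ]; lo <- system$lower[k]; up <- system$upper[k]
    if (is.finite(lo) && is.finite(up) && lo == up) {
      eq_rows <- push(eq_rows, row, lo)
    } else {
      if (is.finite(lo)) in_rows <- push(in_rows, row, lo)
      if (is.finite(up)) in_rows <- push(in_rows, -row, -up)
    }
  }
  ei <- diag(n)
  for (i in seq_len(n)) {
    lo <- system$x_lower[i]; up <- system$x_upper[i]
    if (is.finite(lo) && is.finite(up) && lo == up) {
      eq_rows <- push(eq_rows, ei[i, ], lo)
    } else {
      if (is.finite(lo)) in_rows <- push(in_rows, ei[i, ], lo)
      if (is.finite(up)) in_rows <- push(in_rows, -ei[i, ], -up)
    }
  }
  all_rows <- c(eq_rows, in_rows)
  M <- do.call(rbind, all_rows)
  quadprog::solve.QP(Dmat = Dmat, dvec = dvec,
                     Amat = t(M[, seq_len(n), drop = FALSE]),
                     bvec = M[, n + 1], meq = length(eq_rows))
}

#' Solve the minimum-deviation diet problem
#'
#' Quadratic program: minimize the sum of squared relative deviations from
#' the observed baseline diet, sum_i ((x_i - x0_i) / x0_i)^2, subject to the
#' constraint system. The curvature matrix diag(2 / x0_i^2) is symmetric
#' positive definite, so the problem is strictly convex and the solution is
#' the unique global minimum. The objective is recomputed from the returned
#' diet.
#'
#' @param system A [build_constraints()] system.
#' @param x0 Baseline diet vector (g/capita/d), strictly positive, in the
#'   system's food order.
#' @inheritParams solve_min_cost
#' @return A \code{diet_solution}.
#' @export
solve_min_deviation <- function(system, x0, settings = solver_settings(),
                                universe = NULL, group = NULL) {
  stopifnot(inherits(system, "constraint_system"))
  n <- length(system$food_id)
  if (length(x0) != n) stop("x0 length mismatch", call. = FALSE)
  if (any(x0 <= 0)) {
    stop("relative deviation undefined: non-positive baseline for food(s) ",
         paste(system$food_id[x0 <= 0], collapse = ", "), call. = FALSE)
  }
  res <- try(qp_solve_raw(system, x0), silent = TRUE)
  if (inherits(res, "try-error")) {
    msg <- attr(res, "condition")$message
    status <- if (grepl("inconsistent|no solution", msg)) "infeasible"
              else "error"
    sol <- new_diet_solution(system, NULL, status, NA_real_,
                             "min_deviation", universe, group, settings)
    if (status == "infeasible") {
      sol$infeasible_families <- diagnose_infeasibility(system, settings)
    }
    return(sol)
  }
  x <- pmin(pmax(res$solution, system$x_lower), system$x_upper)
  ver <- verify_solution(x, system, settings$feasibility_tol)
  if (!attr(ver, "feasible")) {
    return(new_diet_solution(system, NULL, "error", NA_real_,
                             "min_deviation", universe, group, settings))
  }
  new_diet_solution(system, x, "optimal", sum(((x - x0) / x0)^2),
                    "min_deviation", universe, group, settings)
}

#' Build and solve one model for one group and scenario
#'
#' Composition of [build_constraints()], the model-specific solver and
#' [verify_solution()]. The returned solution always carries recomputed
#' totals, the binding-constraint set, and (for capped scenarios) whether
#' the GHGE cap is binding.
#'
#' @inheritParams build_constraints
#' @param settings A [solver_settings()].
#' @return A \code{diet_solution}.
#' @export
run_model <- function(universe, group, scen,
                      model = c("min_deviation", "min_cost"),
                      config = builder_config(),
                      settings = solver_settings()) {
  model <- match.arg(model)
  scen <- as_scenario(scen)
  system <- build_constraints(universe, group, scen, model, config)
  x0 <- baseline_vector(universe, group)
  sol <- if (model == "min_cost") {
    solve_min_cost(system, universe$foods$price_eur_per_g, settings,
                   universe, group)
  } else {
    solve_min_deviation(system, x0, settings, universe, group)
  }
  sol$baseline <- tibble::tibble(food_id = universe$foods$id, x0 = x0)
  sol$ghge_binding <- "ghge" %in% sol$binding
  sol
}

#' @export
print.diet_solution <- function(x, ...) {
  cat("<diet_solution> ", x$model, " / ", x$scenario$name,
      " (sex = ", x$sex, ", group = ", x$group, ")\n", sep = "")
  cat("  status: ", x$status, ", objective: ",
      format(x$objective, digits = 6), "\n", sep = "")
  if (x$status == "optimal") {
    cat("  totals: cost ", round(x$totals$cost_eur, 3), " EUR/d, energy ",
        round(x$totals$energy_kj, 1), " kJ/d, GHGE ",
        round(x$totals$ghge_g / 1000, 3), " kg CO2e/d\n", sep = "")
    cat("  binding rows: ", length(x$binding), "\n", sep = "")
  }
  if (x$status == "infeasible" && length(x$infeasible_families) > 0) {
    cat("  relaxing any of {", paste(x$infeasible_families, collapse = ", "),
        "} restores feasibility\n", sep = "")
  }
  invisible(x)
}

#' Tidy a diet solution into a per-food tibble
#'
#' @param x A \code{diet_solution}.
#' @param ... Unused.
#' @return Tibble with columns \code{food_id}, \code{quantity} and, when the
#'   baseline is recorded, \code{x0} and \code{relative_change}.
#' @export
tidy.diet_solution <- function(x, ...) {
  out <- x$diet
  if (!is.null(x$baseline)) {
    out <- out |>
      dplyr::left_join(x$baseline, by = "food_id") |>
      dplyr::mutate(relative_change = (.data$quantity - .data$x0) / .data$x0)
  }
  out
}

#' One-row summary of a diet solution
#'
#' @param x A \code{diet_solution}.
#' @param ... Unused.
#' @return One-row tibble: model, scenario, sex, group, status, objective,
#'   totals, number of binding rows, number of consumed foods and whether
#'   the GHGE cap binds.
#' @export
glance.diet_solution <- function(x, ...) {
  tibble::tibble(
    model = x$model, scenario = x$scenario$name, sex = x$sex,
    group = x$group, status = x$status, objective = x$objective,
    cost_eur = x$totals$cost_eur, energy_kj = x$totals$energy_kj,
    ghge_g = x$totals$ghge_g,
    n_binding = length(x$binding),
    n_foods = sum(!is.na(x$diet$quantity) & x$diet$quantity > 1e-9),
    ghge_binding = isTRUE(x$ghge_binding))
}

#' Plot a diet solution against its baseline
#'
#' Side-by-side main-category quantities of the baseline and solution diets.
#' Requires the universe used to solve, for the category mapping.
#'
#' @param object A \code{diet_solution}.
#' @param universe The [food_universe()] the solution was solved on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diet_solution <- function(object, universe, ...) {
  stopifnot(object$status == "optimal", !is.null(object$baseline))
  sol <- aggregate_to_main(
    dplyr::rename(object$diet, quantity = "quantity"), universe) |>
    dplyr::mutate(diet = "solution")
  base <- aggregate_to_main(
    dplyr::transmute(object$baseline, food_id = .data$food_id,
                     quantity = .data$x0), universe) |>
    dplyr::mutate(diet = "baseline")
  dplyr::bind_rows(base, sol) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$main_category,
                                 y = .data$quantity_g, fill = .data$diet)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "g/capita/d",
                  title = paste(object$model, object$scenario$name,
                                sep = " / ")) +
    ggplot2::theme_minimal()
}

#' Export a diet solution (and its verification report) as JSON
#'
#' @param solution A \code{diet_solution}.
#' @param path File path to write.
#' @return \code{path}, invisibly.
#' @export
write_solution_json <- function(solution, path) {
  stopifnot(inherits(solution, "diet_solution"))
  payload <- list(
    model = solution$model, scenario = solution$scenario$name,
    sex = solution$sex, group = solution$group, status = solution$status,
    objective = solution$objective, totals = as.list(solution$totals),
    binding = solution$binding,
    diet = solution$diet,
    verification = solution$verification)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
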