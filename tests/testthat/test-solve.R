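test_that("a single-food energy equality forces the whole solution", {
  sys <- constraint_system(matrix(10, 1, 1), lower = 1000, upper = 1000,
                           label = "energy", family = "energy")
  sol <- solve_min_cost(sys, prices = 0.001)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$diet$quantity, 100)
  expect_equal(sol$objective, 0.1)
})

test_that("the minimum-cost objective never exceeds any feasible diet's cost", {
  ds <- generate_dataset(tiny_config(seed = 31))
  sys <- build_constraints(ds$universe, ds$group, "health_only", "min_cost")
  p <- ds$universe$foods$price_eur_per_g
  sol <- solve_min_cost(sys, p, universe = ds$universe)
  expect_equal(sol$status, "optimal")
  # x0 is feasible by construction, so C0 bounds the optimum
  expect_lte(sol$objective,
             baseline_totals(ds$universe, ds$group)$cost_eur + 1e-9)
  # objective is recomputed from the diet, not read off the solver
  expect_equal(sol$objective, sum(p * sol$diet$quantity))
})

test_that("scaling all prices scales the LP objective and keeps the argmin", {
  withr::with_seed(32, {
    sys <- random_lp_system(5, 3)
    p <- stats::runif(5, 0.001, 0.01)
    base <- solve_min_cost(sys, p)
    scaled <- solve_min_cost(sys, 7 * p)
    expect_equal(scaled$objective, 7 * base$objective, tolerance = 1e-8)
    expect_equal(scaled$diet$quantity, base$diet$quantity,
                 tolerance = 1e-6)
  })
})

test_that("solutions are invariant to permuting the food order", {
  ds <- generate_dataset(tiny_config(seed = 33, stress = TRUE))
  u <- ds$universe
  g <- ds$group
  for (model in c("min_cost", "min_deviation")) {
    sol <- run_model(u, g, "health_ghge_minus33", model)
    perm <- sample(nrow(u$foods))
    u2 <- u
    u2$foods <- u$foods[perm, ]
    u2$density <- u$density[perm, ]
    g2 <- g
    g2$diet <- g$diet[perm, ]
    sol2 <- run_model(u2, g2, "health_ghge_minus33", model)
    expect_equal(sol2$objective, sol$objective, tolerance = 1e-8)
  }
})

test_that("the minimum-deviation model recovers a feasible baseline exactly", {
  ds <- generate_dataset(tiny_config(seed = 34))
  sys <- build_constraints(ds$universe, ds$group, "health_only",
                           "min_deviation")
  x0 <- ds$group$diet$x0
  sol <- solve_min_deviation(sys, x0)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0, tolerance = 1e-10)
  expect_equal(sol$diet$quantity, x0, tolerance = 1e-6)
})

test_that("non-positive baselines are rejected by name", {
  sys <- constraint_system(matrix(c(1, 1), 1), lower = 100, upper = 100)
  expect_error(solve_min_deviation(sys, c(50, 0)), "food2")
})

test_that("infeasible systems are reported with an offending family", {
  ds <- generate_dataset(tiny_config(seed = 35))
  u <- ds$universe
  b <- u$bounds
  k <- which(b$nutrient_id == "vit_c")
  b$lower[k] <- b$upper[k] <- 1e6 * b$upper[k]
  u <- set_bounds(u, b)
  for (model in c("min_cost", "min_deviation")) {
    sys <- build_constraints(u, ds$group, "health_only", model)
    sol <- if (model == "min_cost") {
      solve_min_cost(sys, u$foods$price_eur_per_g)
    } else {
      solve_min_deviation(sys, ds$group$diet$x0)
    }
    expect_equal(sol$status, "infeasible")
    expect_true("nutrient" %in% sol$infeasible_families)
  }
})

test_that("run_model audits solutions, binding sets and the GHGE cap", {
  ds <- generate_dataset(tiny_config(seed = 36))
  G0 <- sum(ds$universe$foods$ghge_g_per_g * ds$group$diet$x0)

  # a capped minimum-deviation run must attain the cap when it binds
  qp <- run_model(ds$universe, ds$group, "health_ghge_minus50",
                  "min_deviation")
  expect_equal(qp$status, "optimal")
  expect_true(qp$ghge_binding)
  expect_equal(qp$totals$ghge_g, 0.5 * G0, tolerance = 1e-6)
  expect_true(attr(qp$verification, "feasible"))

  # the minimum-cost optimum in this regime is low-emission: cap slack
  lp <- run_model(ds$universe, ds$group, "health_ghge_minus50", "min_cost")
  expect_equal(lp$status, "optimal")
  expect_false(lp$ghge_binding)
  expect_lt(lp$totals$ghge_g, 0.5 * G0)

  # totals recomputed from x
  expect_equal(lp$totals$cost_eur,
               sum(ds$universe$foods$price_eur_per_g * lp$diet$quantity))
})

test_that("tidy, glance and JSON export expose the solution surface", {
  ds <- generate_dataset(tiny_config(seed = 37, stress = TRUE))
  sol <- run_model(ds$universe, ds$group, "health_only", "min_deviation")
  td <- tidy(sol)
  expect_true(all(c("food_id", "quantity", "x0", "relative_change") %in%
                    names(td)))
  gl <- glance(sol)
  expect_equal(gl$status, "optimal")
  expect_equal(gl$energy_kj, 7311, tolerance = 1e-8)
  path <- withr::local_tempfile(fileext = ".json")
  write_solution_json(sol, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$status, "optimal")
  expect_equal(length(back$diet), nrow(ds$universe$foods))
  p <- autoplot(sol, ds$universe)
  expect_s3_class(p, "ggplot")
})
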