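make_ds <- function(seed = 3, ...) generate_dataset(tiny_config(seed, ...))

test_that("energy equality holds at the baseline and is scale-invariant", {
  ds <- make_ds()
  row <- energy_equality(ds$universe, ds$group)
  x0 <- ds$group$diet$x0
  expect_equal(as.numeric(row$A %*% x0), row$lower)
  expect_equal(row$lower, row$upper)

  # doubling energy densities while halving the baseline leaves E0 unchanged
  u2 <- ds$universe
  u2$foods$energy_kj_per_g <- 2 * u2$foods$energy_kj_per_g
  g2 <- ds$group
  g2$diet$x0 <- g2$diet$x0 / 2
  g2$diet$p10 <- g2$diet$p10 / 2
  row2 <- energy_equality(u2, g2)
  expect_equal(row2$lower, row$lower)
})

test_that("nutrient rows convert %E, add the amino safety margin and apply the iron rule", {
  ds <- make_ds()
  u <- ds$universe
  g <- ds$group
  x0 <- g$diet$x0
  E0 <- sum(u$foods$energy_kj_per_g * x0)
  rows <- nutrient_rows(u, g)
  expect_equal(nrow(rows$A), nrow(u$bounds))

  # %E rows: coefficients are conv * density and bounds scale with E0
  k <- which(rows$label == "nutrient:protein")
  expect_equal(as.numeric(rows$A[k, ]), 17 * u$density[, "protein"],
               ignore_attr = TRUE)
  b <- u$bounds[u$bounds$nutrient_id == "protein", ]
  expect_equal(rows$lower[k], b$lower / 100 * E0)

  # amino acids: lower-only rows, multiplied by the 24% safety margin
  k <- which(rows$label == "nutrient:lys")
  b <- u$bounds[u$bounds$nutrient_id == "lys", ]
  expect_equal(rows$lower[k], 1.24 * b$lower)
  expect_identical(rows$upper[k], Inf)

  # sodium: upper-only row carries a -Inf lower sentinel
  k <- which(rows$label == "nutrient:sodium")
  expect_identical(rows$lower[k], -Inf)

  # iron rule (female): lower bound equals baseline iron intake
  k <- which(rows$label == "nutrient:iron")
  expect_equal(rows$lower[k], sum(u$density[, "iron"] * x0))
  male <- generate_group(u, tiny_config(3), sex = "male")
  bounds_m <- generate_feasible_bounds(u, male, tiny_config(3))
  um <- set_bounds(u, bounds_m)
  rows_m <- nutrient_rows(um, male)
  b <- um$bounds[um$bounds$nutrient_id == "iron", ]
  expect_equal(rows_m$lower[which(rows_m$label == "nutrient:iron")],
               b$lower)

  # %E nutrient without a conversion factor errors
  u_bad <- u
  u_bad$nutrients$energy_component[u_bad$nutrients$id == "protein"] <- NA
  expect_error(nutrient_rows(u_bad, g), "conversion factor")
})

test_that("the GHGE cap scales baseline emissions and vanishes for health-only", {
  ds <- make_ds()
  x0 <- ds$group$diet$x0
  G0 <- sum(ds$universe$foods$ghge_g_per_g * x0)
  cap <- ghge_cap(ds$universe, ds$group, scenario("health_ghge_minus50"))
  expect_equal(cap$upper, 0.5 * G0)
  expect_null(ghge_cap(ds$universe, ds$group, scenario("health_only")))
  full <- ghge_cap(ds$universe, ds$group,
                   scenario("custom", ghge_fraction = 1))
  expect_equal(as.numeric(full$A %*% x0) - full$upper, 0)
})

test_that("the dairy-beef row encodes milk-per-beef jointness", {
  foods <- tibble::tibble(
    id = c("milk", "beef", "carrot"), name = id,
    main_category = c("Dairy", "Meat", "Vegetables"),
    energy_kj_per_g = c(2, 9, 1.5), price_eur_per_g = 0.002,
    ghge_g_per_g = c(1, 25, 0.5), beef_fraction = c(0, 1, 0),
    raw_milk_equiv = c(1, 0, 0))
  nutrients <- tibble::tibble(id = "protein_g", name = "protein",
                              unit = "g/d", kind = "macronutrient")
  density <- matrix(0.1, 3, 1, dimnames = list(foods$id, nutrients$id))
  u <- food_universe(foods, nutrients, density)
  row <- dairy_beef_row(u)
  expect_equal(as.numeric(row$A %*% c(33.9, 1, 0)), 0)   # binding
  expect_equal(as.numeric(row$A %*% c(0, 0, 100)), 0)    # all-plant
  withr::with_seed(21, {
    for (i in 1:20) {
      x <- stats::runif(3, 0, 50)
      direct <- 33.9 * sum(foods$beef_fraction * x) -
        sum(foods$raw_milk_equiv * x)
      expect_equal(as.numeric(row$A %*% x), direct)
    }
  })
  u_nobeef <- u
  u_nobeef$foods$beef_fraction <- 0
  expect_warning(dairy_beef_row(u_nobeef), "structurally infeasible")
})

test_that("habit bounds apply per model kind and pin degenerate foods", {
  ds <- make_ds()
  hb <- habit_rows(ds$group, "min_deviation")
  expect_equal(hb$x_lower, ds$group$diet$p10)
  expect_equal(hb$x_upper, ds$group$diet$p90)
  lp <- habit_rows(ds$group, "min_cost")
  expect_true(all(lp$x_lower == 0) && all(lp$x_upper == Inf))

  g <- ds$group
  g$diet$p10[3] <- g$diet$p90[3]  # food fixed at a point
  hb <- habit_rows(g, "min_deviation")
  expect_equal(hb$x_lower[3], hb$x_upper[3])
  g$diet$p10[3] <- g$diet$p90[3] + 1
  expect_error(habit_rows(g, "min_deviation"), "p10")
})

test_that("the assembled system has the expected rows and nests with the cap", {
  ds <- make_ds()
  n_bounded <- nrow(ds$universe$bounds)
  sys_h <- build_constraints(ds$universe, ds$group, "health_only",
                             "min_cost")
  expect_equal(nrow(sys_h$A), 1 + n_bounded + 1)
  expect_false("ghge" %in% sys_h$family)
  expect_true(all(sys_h$x_lower == 0))

  sys_50 <- build_constraints(ds$universe, ds$group,
                              "health_ghge_minus50", "min_deviation")
  expect_equal(nrow(sys_50$A), 1 + n_bounded + 1 + 1)
  G0 <- sum(ds$universe$foods$ghge_g_per_g * ds$group$diet$x0)
  expect_equal(sys_50$upper[sys_50$family == "ghge"], 0.5 * G0)
  expect_equal(sys_50$x_lower, ds$group$diet$p10)

  # any diet feasible under theta = 1/2 is feasible under theta = 2/3
  sys_33 <- build_constraints(ds$universe, ds$group,
                              "health_ghge_minus33", "min_deviation")
  sol <- solve_min_deviation(sys_50, ds$group$diet$x0)
  expect_equal(sol$status, "optimal")
  expect_true(is_feasible(sol$diet$quantity, sys_33, tol = 1e-6))

  # baseline always satisfies energy equality and habit bounds
  ver <- verify_solution(ds$group$diet$x0, sys_33)
  sub <- ver[ver$family %in% c("energy", "habit"), ]
  expect_true(all(!sub$violated))
})

test_that("verification agrees with independent dense recomputation", {
  # trivial cases first
  sys <- constraint_system(matrix(c(1, 2), 1), lower = 10, upper = 10,
                           family = "energy")
  ver <- verify_solution(c(2, 4), sys)
  expect_true(attr(ver, "feasible"))
  expect_true(ver$binding[ver$label == "row1"])
  ver0 <- verify_solution(c(0, 0), constraint_system(
    matrix(c(1, 1), 1), lower = 5, upper = Inf, label = "nutrient:x",
    family = "nutrient"))
  expect_false(attr(ver0, "feasible"))
  expect_true(ver0$violated[ver0$label == "nutrient:x"])
  expect_error(verify_solution(c(1, 2, 3), sys), "does not match")

  withr::with_seed(22, {
    for (i in 1:100) {
      n <- sample(2:6, 1)
      m <- sample(1:4, 1)
      sys <- random_lp_system(n, m)
      x <- stats::runif(n, 0, 3)
      ver <- verify_solution(x, sys)
      rows <- ver[!startsWith(ver$label, "bound:"), ]
      v <- as.numeric(sys$A %*% x)
      sc <- pmax(apply(abs(sys$A), 1, max), 1)
      expect_equal(rows$value, v)
      expect_equal(rows$slack, pmin(v - sys$lower, sys$upper - v) / sc)
      feas <- all(v >= sys$lower - 1e-6 * sc, v <= sys$upper + 1e-6 * sc,
                  x >= sys$x_lower - 1e-6, x <= sys$x_upper + 1e-6)
      expect_equal(attr(ver, "feasible"), feas)
    }
  })
})
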