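test_that("generation is deterministic under a seed", {
  cfg <- generator_config(seed = 99)
  u1 <- generate_universe(cfg)
  u2 <- generate_universe(cfg)
  expect_equal(u1$foods, u2$foods)
  expect_equal(u1$density, u2$density)
  g1 <- generate_group(u1, cfg)
  g2 <- generate_group(u2, cfg)
  expect_equal(g1$diet, g2$diet)
  # different seeds differ
  u3 <- generate_universe(generator_config(seed = 100))
  expect_false(isTRUE(all.equal(u1$foods$price_eur_per_g,
                                u3$foods$price_eur_per_g)))
})

test_that("the default universe carries the study's structure", {
  u <- generate_universe(generator_config(seed = 2))
  expect_equal(nrow(u$foods), 74)
  expect_equal(dplyr::n_distinct(u$foods$main_category), 16)
  expect_equal(nrow(u$nutrients), 61)
  expect_equal(as.integer(table(u$nutrients$kind)[c("macronutrient",
                                                    "vitamin", "mineral",
                                                    "amino_acid")]),
               c(21L, 13L, 18L, 9L))

  # beef-carcass fractions follow the published list
  bf <- setNames(u$foods$beef_fraction, u$foods$id)
  expect_equal(unname(bf["meat_beef"]), 1)
  expect_equal(unname(bf["meat_offal"]), 0.88)
  expect_equal(unname(bf["meat_meat_products"]), 0.5)
  expect_equal(unname(bf[c("meat_sausages", "meat_sausage_cuts",
                           "meat_meat_cuts")]), rep(0.075, 3))
  expect_true(all(bf[!startsWith(names(bf), "meat_")] == 0))

  # raw milk equivalents only on dairy
  dairy <- u$foods$main_category == "Dairy"
  expect_true(all(u$foods$raw_milk_equiv[dairy] > 0))
  expect_true(all(u$foods$raw_milk_equiv[!dairy] == 0))

  # animal categories are dearer and dirtier per gram
  mean_by <- function(col, cat) {
    mean(u$foods[[col]][u$foods$main_category == cat])
  }
  expect_gt(mean_by("ghge_g_per_g", "Meat"), mean_by("ghge_g_per_g",
                                                     "Cereals"))
  expect_gt(mean_by("price_eur_per_g", "Meat"),
            mean_by("price_eur_per_g", "Potatoes"))
  expect_true(all(u$density > 0))
})

test_that("groups hit the energy target exactly and respect habit bounds", {
  cfg <- generator_config(seed = 8)
  u <- generate_universe(cfg)
  gf <- generate_group(u, cfg, sex = "female")
  expect_equal(sum(u$foods$energy_kj_per_g * gf$diet$x0), 7311,
               tolerance = 1e-12)
  gm <- generate_group(u, cfg, sex = "male")
  expect_equal(sum(u$foods$energy_kj_per_g * gm$diet$x0),
               round(1.28 * 7311), tolerance = 1e-12)
  for (g in list(gf, gm)) {
    expect_true(all(g$diet$p10 <= g$diet$x0))
    expect_true(all(g$diet$x0 <= g$diet$p90))
    expect_true(all(g$diet$x0 > 0))
    # baseline satisfies the dairy-beef jointness row
    expect_gte(u$milk_per_beef * sum(u$foods$beef_fraction * g$diet$x0) -
                 sum(u$foods$raw_milk_equiv * g$diet$x0), -1e-9)
  }
  # rarely eaten foods can be excluded by habit (P10 of zero)
  expect_gt(sum(gf$diet$p10 == 0), 0)
})

test_that("generated bounds bracket the baseline-implied intakes", {
  cfg <- generator_config(seed = 9)
  u <- generate_universe(cfg)
  g <- generate_group(u, cfg)
  b <- generate_feasible_bounds(u, g, cfg)
  x0 <- g$diet$x0
  E0 <- sum(u$foods$energy_kj_per_g * x0)
  conv <- c(fat = 37, protein = 17, carbohydrate = 17, alcohol = 29)
  for (k in seq_len(nrow(b))) {
    nid <- b$nutrient_id[k]
    nut <- u$nutrients[u$nutrients$id == nid, ]
    level <- sum(u$density[, nid] * x0)  # independent dot product
    if (nut$unit == "%E") level <- 100 * conv[[nut$energy_component]] *
        level / E0
    if (!is.na(b$lower[k])) {
      expected <- if (nut$kind == "amino_acid") 0.8 * level / 1.24
                  else 0.8 * level
      expect_equal(b$lower[k], expected, tolerance = 1e-9)
    }
    if (!is.na(b$upper[k])) expect_equal(b$upper[k], 1.5 * level,
                                         tolerance = 1e-9)
  }

  # default bounds make the baseline feasible...
  u <- set_bounds(u, b)
  sys <- build_constraints(u, g, "health_only", "min_deviation")
  expect_true(is_feasible(g$diet$x0, sys))
  # ...and stress mode makes it infeasible, forcing real optimization
  bs <- generate_feasible_bounds(u, g, generator_config(seed = 9,
                                                        stress = TRUE))
  us <- set_bounds(u, bs)
  sys_s <- build_constraints(us, g, "health_only", "min_deviation")
  expect_false(is_feasible(g$diet$x0, sys_s))
  sol <- solve_min_deviation(sys_s, g$diet$x0)
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)
})

test_that("the dataset generator certifies the deepest emission cut", {
  ds <- generate_dataset(tiny_config(seed = 10, stress = TRUE))
  G0 <- sum(ds$universe$foods$ghge_g_per_g * ds$group$diet$x0)
  expect_lte(ds$min_ghge_g, 0.5 * G0)
  expect_true(all(ds$group$diet$p10 <= ds$group$diet$x0))
})
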