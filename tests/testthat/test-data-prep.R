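test_that("unit values are pooled ratios, not means of ratios", {
  one <- tibble::tibble(source_category = "x", expenditure_eur = 2,
                        quantity_g = 1000)
  expect_equal(unit_value_price(one)$price_eur_per_g, 0.002)

  two <- tibble::tibble(source_category = "x",
                        expenditure_eur = c(1, 3), quantity_g = c(500, 500))
  # pooled: 4/1000, not mean(1/500, 3/500) = 0.004 too -- use asymmetric case
  expect_equal(unit_value_price(two)$price_eur_per_g, 0.004)
  asym <- tibble::tibble(source_category = "x",
                         expenditure_eur = c(1, 3),
                         quantity_g = c(100, 900))
  expect_equal(unit_value_price(asym)$price_eur_per_g, 4 / 1000)

  withr::with_seed(11, {
    recs <- tibble::tibble(
      source_category = sample(letters[1:4], 50, replace = TRUE),
      expenditure_eur = stats::runif(50, 0, 10),
      quantity_g = stats::runif(50, 10, 1000))
    got <- unit_value_price(recs)
    for (sc in unique(recs$source_category)) {
      sub <- recs[recs$source_category == sc, ]
      expect_equal(got$price_eur_per_g[got$source_category == sc],
                   sum(sub$expenditure_eur) / sum(sub$quantity_g))
    }
    # scale equivariance
    doubled <- dplyr::mutate(recs, expenditure_eur = 2 * expenditure_eur)
    expect_equal(unit_value_price(doubled)$price_eur_per_g,
                 2 * got$price_eur_per_g)
    halved <- dplyr::mutate(recs, quantity_g = 2 * quantity_g)
    expect_equal(unit_value_price(halved)$price_eur_per_g,
                 got$price_eur_per_g / 2)
  })
  expect_error(unit_value_price(
    tibble::tibble(source_category = "x", expenditure_eur = 1,
                   quantity_g = 0)), "zero total quantity")
})

test_that("category prices are weighted means within the source price hull", {
  single <- tibble::tibble(food_id = "f", price_eur_per_g = 0.004,
                           weight = 3)
  expect_equal(category_price(single)$price_eur_per_g, 0.004)
  even <- tibble::tibble(food_id = "f", price_eur_per_g = c(0.002, 0.004),
                         weight = c(1, 1))
  expect_equal(category_price(even)$price_eur_per_g, 0.003)
  withr::with_seed(12, {
    for (i in 1:10) {
      m <- tibble::tibble(food_id = "f",
                          price_eur_per_g = stats::runif(5, 0.001, 0.02),
                          weight = stats::runif(5, 0, 2))
      got <- category_price(m)$price_eur_per_g
      expect_equal(got, sum(m$weight * m$price_eur_per_g) / sum(m$weight))
      expect_gte(got, min(m$price_eur_per_g))
      expect_lte(got, max(m$price_eur_per_g))
    }
  })
  unmatched <- category_price(single, food_ids = c("f", "g"))
  expect_false(unmatched$priced[unmatched$food_id == "g"])
})

test_that("nutrient aggregation uses consumption shares and stays in the hull", {
  items <- tibble::tibble(item_id = c("a", "b"), intake_g = c(5, 5))
  dens <- tibble::tibble(item_id = c("a", "b"), nutrient_id = "n",
                         density = c(1, 3))
  expect_equal(aggregate_nutrients(items, dens)$density, 2)
  withr::with_seed(13, {
    items <- tibble::tibble(item_id = letters[1:10],
                            intake_g = stats::runif(10, 0.1, 50))
    dens <- tidyr::expand_grid(item_id = letters[1:10],
                               nutrient_id = c("n1", "n2")) |>
      dplyr::mutate(density = stats::runif(20, 0, 5))
    got <- aggregate_nutrients(items, dens)
    w <- items$intake_g / sum(items$intake_g)
    for (nid in c("n1", "n2")) {
      d <- dens$density[dens$nutrient_id == nid]
      expect_equal(got$density[got$nutrient_id == nid], sum(w * d))
      expect_gte(got$density[got$nutrient_id == nid], min(d))
      expect_lte(got$density[got$nutrient_id == nid], max(d))
    }
  })
  expect_error(aggregate_nutrients(
    tibble::tibble(item_id = "a", intake_g = 0), dens), "zero")
})

test_that("equivalized income follows the OECD scale and strata match a sort oracle", {
  hh <- tibble::tibble(total_income = c(10000, 22000),
                       n_adults = c(1, 2), n_minors = c(0, 1))
  got <- equivalized_income(hh)
  expect_equal(got$equivalized_income, c(10000, 10000))
  expect_equal(got$consumption_units, c(1, 2.2))
  expect_error(equivalized_income(
    tibble::tibble(total_income = 1, n_adults = 0, n_minors = 0)),
    "at least one adult")

  withr::with_seed(14, {
    x <- stats::rlnorm(200, 10, 0.6)
    for (n in c(3, 5)) {
      strata <- assign_quantile_strata(x, n)
      # brute-force sort-and-cut oracle (ties to the lower stratum)
      cuts <- stats::quantile(x, seq_len(n - 1) / n, type = 7)
      oracle <- vapply(x, function(v) 1L + sum(v > cuts), integer(1))
      expect_identical(strata, oracle)
      # invariance to monotone rescaling
      expect_identical(assign_quantile_strata(exp(x / max(x)), n), strata)
    }
  })
})

test_that("habit percentiles match an independent order-statistic interpolation", {
  const <- tibble::tibble(food_id = "f", value = rep(7, 25))
  expect_equal(habit_percentiles(const),
               tibble::tibble(food_id = "f", p10 = 7, p90 = 7))
  grid <- tibble::tibble(food_id = "f", value = 0:100)
  got <- habit_percentiles(grid)
  expect_equal(c(got$p10, got$p90), c(10, 90))

  withr::with_seed(15, {
    v <- stats::rlnorm(137, 3, 0.9)
    got <- habit_percentiles(tibble::tibble(food_id = "f", value = v))
    # from-scratch type-7 interpolation between order statistics
    o <- sort(v)
    interp <- function(p) {
      h <- (length(o) - 1) * p + 1
      o[floor(h)] + (h - floor(h)) * (o[ceiling(h)] - o[floor(h)])
    }
    expect_equal(got$p10, interp(0.10))
    expect_equal(got$p90, interp(0.90))
  })
  expect_error(habit_percentiles(tibble::tibble(food_id = character(),
                                                value = numeric())),
               "empty")
})
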