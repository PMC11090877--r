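# Seeded evaluation that restores the caller's RNG state.
local_seed_eval <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Deterministic small offset so each (sex, label) group gets its own stream.
group_seed <- function(seed, sex, label) {
  (seed * 131 + sum(utf8ToInt(label)) * 7 +
     ifelse(sex == "male", 104729, 0)) %% .Machine$integer.max
}

# Structural blueprint of the default 16 main categories: per-food counts,
# typical per-gram energy/price/GHGE levels, mean per-food intake, whether
# the category is animal-source and the probability that a given person
# never eats a given food (zero inflation). Animal price/GHGE levels are
# stated before the animal multipliers are applied.
category_blueprint <- function() {
  tibble::tribble(
    ~main_category,     ~n, ~energy, ~price,  ~ghge, ~intake, ~animal, ~zi,
    "Cereals",           8,   13.0, 0.0016,  0.90,     25,  FALSE, 0.10,
    "Dairy",            14,    3.0, 0.00125, 0.60,     35,   TRUE, 0.25,
    "Meat",              8,    9.0, 0.0040,  2.70,     20,   TRUE, 0.25,
    "Vegetables",        7,    1.5, 0.0030,  1.00,     25,  FALSE, 0.20,
    "Fruits",            7,    2.5, 0.0028,  0.80,     35,  FALSE, 0.20,
    "Fats",              7,   30.0, 0.0060,  3.50,      7,  FALSE, 0.30,
    "Fish",              2,    7.0, 0.0065,  1.17,     15,   TRUE, 0.30,
    "Potatoes",          2,    3.5, 0.0008,  0.30,     40,  FALSE, 0.20,
    "Beverages",         3,    0.5, 0.0020,  0.30,    200,  FALSE, 0.20,
    "Alcohol",           2,    1.5, 0.0040,  1.00,     60,  FALSE, 0.45,
    "Eggs",              1,    6.0, 0.0020,  0.67,     25,   TRUE, 0.15,
    "Legumes and nuts",  3,   12.0, 0.0070,  1.50,      8,  FALSE, 0.40,
    "Sugar",             4,   17.0, 0.0070,  1.50,      8,  FALSE, 0.30,
    "Ingredients",       3,    8.0, 0.0030,  1.00,      4,  FALSE, 0.40,
    "Flavoring",         2,    5.0, 0.0100,  1.50,      5,  FALSE, 0.30,
    "Diet products",     1,   15.0, 0.0300,  2.00,      2,  FALSE, 0.70)
}

# Beef-carcass fractions of the meat foods, in within-category order.
meat_beef_fractions <- c(beef = 1, offal = 0.88, meat_products = 0.5,
                         sausages = 0.075, sausage_cuts = 0.075,
                         meat_cuts = 0.075, pork = 0, poultry = 0)

# Raw-milk equivalents recycled over the dairy foods: liquid/fermented milks
# ~1 g/g, fresh products ~2.5, cheeses ~9.
dairy_milk_equivalents <- c(1, 1, 1, 1, 1, 1, 2.5, 2.5, 2.5, 2.5, 9, 9, 9, 9)

nutrient_catalogue <- function() {
  macro <- tibble::tibble(
    id = c("protein", "fat", "carbohydrate",
           "his", "ile", "leu", "lys", "met", "phe", "thr", "trp", "val",
           "fiber", "sugars", "sfa", "mufa", "pufa", "omega3", "omega6",
           "starch", "cholesterol", paste0("macro_", 10:18)),
    kind = c(rep("macronutrient", 3), rep("amino_acid", 9),
             rep("macronutrient", 18)),
    unit = c(rep("%E", 3), rep("g/d", 9), rep("g/d", 18)),
    energy_component = c("protein", "fat", "carbohydrate",
                         rep(NA_character_, 27)))
  vitamins <- tibble::tibble(
    id = c("vit_a", "vit_d", "vit_e", "vit_k", "vit_c", "thiamin",
           "riboflavin", "niacin", "vit_b6", "folate", "vit_b12",
           "pantothenate", "biotin"),
    kind = "vitamin", unit = "ug/d", energy_component = NA_character_)
  minerals <- tibble::tibble(
    id = c("calcium", "phosphorus", "potassium", "magnesium", "iron",
           "zinc", "copper", "iodine", "selenium", "sodium", "manganese",
           "chromium", "molybdenum", "fluoride", "chloride", "sulfur",
           "boron", "nickel"),
    kind = "mineral", unit = "mg/d", energy_component = NA_character_)
  out <- dplyr::bind_rows(macro, vitamins, minerals)
  out$name <- gsub("_", " ", out$id)
  out[, c("id", "name", "unit", "kind", "energy_component")]
}

#' Configuration of the synthetic-data generator
#'
#' The generator emulates the statistical structure of the Finnish study
#' data: a 74-category food universe mapped to 16 main categories, 61
#' bounded nutrients (30 macronutrients including 9 amino acids, 13
#' vitamins, 18 minerals), right-skewed zero-inflated person-level
#' consumption yielding P10/P90 habit bounds, higher price and GHGE for
#' animal-source categories, and a feasible baseline diet at 7311 kJ/d for
#' females (28\% higher for males).
#'
#' @param seed Integer seed; all generation is deterministic given it.
#' @param sex Default sex for [generate_group()].
#' @param n_foods,n_main Size of the food universe (defaults 74 and 16).
#' @param n_persons Number of simulated persons behind the habit
#'   percentiles; default 780.
#' @param target_energy_kj Named vector of baseline energy targets (kJ/d).
#' @param animal_price_multiplier,animal_ghge_multiplier Factors applied to
#'   the price and emission levels of animal-source categories (meat, dairy,
#'   fish, eggs) on top of the structural blueprint.
#' @param consumption_sigma Log-scale SD of person-level consumption.
#' @param slack_lo,slack_hi Fractions of the baseline-implied nutrient
#'   intake used as effective lower/upper bounds; must straddle 1 so that
#'   the baseline diet is feasible by construction.
#' @param stress If \code{TRUE}, the lower bounds of \code{stress_nutrients}
#'   are raised above baseline intake by \code{stress_factor}, making the
#'   baseline infeasible and forcing non-trivial optimization.
#' @param stress_factor,stress_nutrients Stress-mode parameters; the default
#'   nutrients are plant-rich (vitamin C, folate, fiber) so that tightening
#'   them pushes the solution in the same direction as the emission cap.
#' @return A list of class \code{generator_config}.
#' @export
generator_config <- function(seed = 1L, sex = c("female", "male"),
                             n_foods = 74L, n_main = 16L, n_persons = 780L,
                             target_energy_kj = c(female = 7311,
                                                  male = round(1.28 * 7311)),
                             animal_price_multiplier = 2,
                             animal_ghge_multiplier = 3,
                             consumption_sigma = 0.8,
                             slack_lo = 0.8, slack_hi = 1.5,
                             stress = FALSE, stress_factor = 1.1,
                             stress_nutrients = c("vit_c", "folate",
                                                  "fiber")) {
  sex <- match.arg(sex)
  if (n_main > n_foods) stop("n_main must not exceed n_foods", call. = FALSE)
  if (n_main > 16) stop("at most 16 main categories are defined",
                        call. = FALSE)
  if (animal_price_multiplier <= 0 || animal_ghge_multiplier <= 0) {
    stop("multipliers must be > 0", call. = FALSE)
  }
  if (!(slack_lo < 1 && slack_hi > 1)) {
    stop("slack factors must satisfy slack_lo < 1 < slack_hi", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), sex = sex,
                 n_foods = as.integer(n_foods), n_main = as.integer(n_main),
                 n_persons = as.integer(n_persons),
                 target_energy_kj = target_energy_kj,
                 animal_price_multiplier = animal_price_multiplier,
                 animal_ghge_multiplier = animal_ghge_multiplier,
                 consumption_sigma = consumption_sigma,
                 slack_lo = slack_lo, slack_hi = slack_hi,
                 stress = stress, stress_factor = stress_factor,
                 stress_nutrients = stress_nutrients),
            class = "generator_config")
}

# Allocate n_foods across the first n_main blueprint categories,
# proportionally to the default counts (largest-remainder rounding, at
# least one food per category).
allocate_foods <- function(n_foods, n_main) {
  bp <- category_blueprint()[seq_len(n_main), ]
  quota <- bp$n / sum(bp$n) * n_foods
  n <- pmax(1L, floor(quota))
  while (sum(n) < n_foods) {
    i <- which.max(quota - n)
    n[i] <- n[i] + 1L
  }
  while (sum(n) > n_foods) {
    i <- which.max(ifelse(n > 1L, n - quota, -Inf))
    n[i] <- n[i] - 1L
  }
  bp$n <- n
  bp
}

#' Generate a synthetic food universe
#'
#' Builds a seeded, reproducible [food_universe()] with the structure
#' described in [generator_config()]: meat and other animal-source
#' categories get elevated prices and emission coefficients (beef and offal
#' markedly so), beef-carcass fractions follow the standard list (beef 1.0,
#' offal 0.88, meat products 0.5, sausages/sausage cuts/meat cuts 0.075),
#' raw-milk equivalents are positive only for dairy foods, and nutrient
#' densities are strictly positive with plausible category structure (iron
#' concentrated in meat and offal, calcium in dairy, vitamin C in produce,
#' fiber in plant staples). The three \%E macronutrient densities are
#' derived from per-food energy-component fractions, so that 17 a_protein +
#' 37 a_fat + 17 a_carbohydrate + 29 a_alcohol = e_i holds for every food.
#'
#' @param config A [generator_config()].
#' @return A [food_universe()] (without bounds; see
#'   [generate_feasible_bounds()]).
#' @export
generate_universe <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  local_seed_eval(config$seed, {
    bp <- allocate_foods(config$n_foods, config$n_main)
    foods <- bp |>
      dplyr::rowwise() |>
      dplyr::reframe(main_category = .data$main_category,
                     idx = seq_len(.data$n),
                     energy = .data$energy, price = .data$price,
                     ghge = .data$ghge, animal = .data$animal)
    slug <- tolower(gsub("[^a-z]+", "_", tolower(foods$main_category)))
    foods$id <- paste0(slug, "_", foods$idx)
    # named meat foods carry the beef-carcass fractions
    meat <- foods$main_category == "Meat"
    if (any(meat)) {
      nm <- names(meat_beef_fractions)
      k <- seq_len(sum(meat))
      foods$id[meat] <- paste0("meat_", nm[((k - 1) %% length(nm)) + 1],
                               ifelse(k > length(nm), paste0("_", k), ""))
    }
    n <- nrow(foods)
    e <- foods$energy * exp(stats::rnorm(n, 0, 0.25))
    price <- foods$price * exp(stats::rnorm(n, 0, 0.35)) *
      ifelse(foods$animal, config$animal_price_multiplier, 1)
    ghge <- foods$ghge * exp(stats::rnorm(n, 0, 0.35)) *
      ifelse(foods$animal, config$animal_ghge_multiplier, 1)
    beef_fraction <- rep(0, n)
    if (any(meat)) {
      k <- seq_len(sum(meat))
      bfr <- meat_beef_fractions[((k - 1) %% length(meat_beef_fractions)) + 1]
      beef_fraction[meat] <- bfr
      ghge[meat] <- ghge[meat] *
        ifelse(grepl("meat_beef", foods$id[meat]), 3.5,
               ifelse(grepl("meat_offal", foods$id[meat]), 2, 1))
    }
    raw_milk <- rep(0, n)
    dairy <- foods$main_category == "Dairy"
    if (any(dairy)) {
      k <- seq_len(sum(dairy))
      raw_milk[dairy] <-
        dairy_milk_equivalents[((k - 1) %% length(dairy_milk_equivalents)) + 1]
    }

    nutrients <- nutrient_catalogue()
    density <- synth_density(foods$main_category, e, nutrients)
    rownames(density) <- foods$id

    foods_tbl <- tibble::tibble(
      id = foods$id, name = gsub("_", " ", foods$id),
      main_category = foods$main_category,
      energy_kj_per_g = e, price_eur_per_g = price, ghge_g_per_g = ghge,
      beef_fraction = beef_fraction, raw_milk_equiv = raw_milk)
    food_universe(foods_tbl, nutrients, density)
  })
}

# Energy-component fractions (protein, fat, carbohydrate, alcohol) by
# category, jittered per food; the %E and amino-acid densities derive from
# them, everything else is lognormal noise around category multipliers.
synth_density <- function(main_category, energy, nutrients) {
  base_frac <- list(
    "Alcohol"          = c(0.02, 0.00, 0.23, 0.75),
    "Beverages"        = c(0.05, 0.02, 0.93, 0.00),
    "Cereals"          = c(0.13, 0.07, 0.80, 0.00),
    "Diet products"    = c(0.40, 0.20, 0.40, 0.00),
    "Eggs"             = c(0.35, 0.60, 0.05, 0.00),
    "Fats"             = c(0.01, 0.97, 0.02, 0.00),
    "Fish"             = c(0.50, 0.45, 0.05, 0.00),
    "Flavoring"        = c(0.10, 0.30, 0.60, 0.00),
    "Fruits"           = c(0.04, 0.04, 0.92, 0.00),
    "Ingredients"      = c(0.10, 0.10, 0.80, 0.00),
    "Legumes and nuts" = c(0.22, 0.48, 0.30, 0.00),
    "Meat"             = c(0.40, 0.52, 0.08, 0.00),
    "Dairy"            = c(0.25, 0.45, 0.30, 0.00),
    "Potatoes"         = c(0.09, 0.02, 0.89, 0.00),
    "Sugar"            = c(0.03, 0.15, 0.82, 0.00),
    "Vegetables"       = c(0.20, 0.12, 0.68, 0.00))
  conv <- c(17, 37, 17, 29)  # protein, fat, carbohydrate, alcohol kJ/g
  n <- length(main_category)
  frac <- t(vapply(main_category, function(mc) {
    f <- base_frac[[mc]] + 0.015
    g <- f * exp(stats::rnorm(4, 0, 0.15))
    g / sum(g)
  }, numeric(4)))
  grams <- frac * energy / rep(conv, each = n)  # g of component per g food

  density <- matrix(0, n, nrow(nutrients),
                    dimnames = list(NULL, nutrients$id))
  density[, "protein"] <- grams[, 1]
  density[, "fat"] <- grams[, 2]
  density[, "carbohydrate"] <- grams[, 3]

  amino_share <- c(his = 0.027, ile = 0.050, leu = 0.080, lys = 0.070,
                   met = 0.025, phe = 0.047, thr = 0.042, trp = 0.012,
                   val = 0.055)
  for (a in names(amino_share)) {
    density[, a] <- grams[, 1] * amino_share[[a]] *
      exp(stats::rnorm(n, 0, 0.10))
  }

  boost <- function(categories, factor) {
    ifelse(main_category %in% categories, factor, 1)
  }
  plain <- setdiff(nutrients$id,
                   c("protein", "fat", "carbohydrate", names(amino_share)))
  for (j in plain) {
    mult <- switch(j,
      iron = boost("Meat", 3),
      calcium = boost("Dairy", 6),
      vit_c = boost(c("Fruits", "Vegetables"), 5) * boost("Potatoes", 3),
      vit_d = boost("Fish", 5) * boost(c("Fats", "Eggs"), 3),
      vit_b12 = boost(c("Meat", "Fish", "Eggs", "Dairy"), 4),
      folate = boost(c("Vegetables", "Legumes and nuts", "Cereals"), 3),
      fiber = boost(c("Cereals", "Legumes and nuts", "Fruits",
                      "Vegetables"), 4),
      sodium = boost(c("Flavoring", "Ingredients"), 5),
      sfa = boost(c("Dairy", "Meat", "Fats"), 3),
      pufa = boost(c("Fats", "Fish", "Legumes and nuts"), 3),
      1)
    density[, j] <- mult * exp(stats::rnorm(n, 0, 0.5))
  }
  density
}

#' Generate a synthetic population group
#'
#' Simulates \code{n_persons} individual consumption profiles per food
#' (zero-inflated lognormal, so that rarely eaten foods can have a 10th
#' centile of zero), takes the group mean as the baseline diet \code{x0},
#' the empirical 10th/90th centiles as habit bounds, then rescales
#' everything so that baseline energy hits the sex-specific target exactly.
#' The baseline is nudged, if necessary, to satisfy the dairy-beef
#' jointness constraint, and the habit bounds are widened where needed so
#' that p10 <= x0 <= p90 holds elementwise.
#'
#' @param universe A universe from [generate_universe()].
#' @param config The same [generator_config()].
#' @param sex,label Group identity; the seed is offset deterministically per
#'   group so groups differ but are reproducible.
#' @return A [population_group()].
#' @export
generate_group <- function(universe, config = generator_config(),
                           sex = config$sex, label = "all") {
  stopifnot(inherits(universe, "food_universe"))
  local_seed_eval(group_seed(config$seed, sex, label), {
    foods <- universe$foods
    n <- nrow(foods)
    bp <- category_blueprint()
    lvl <- bp$intake[match(foods$main_category, bp$main_category)]
    zi <- bp$zi[match(foods$main_category, bp$main_category)]
    food_level <- lvl * exp(stats::rnorm(n, 0, 0.4))
    if (label != "all") {
      food_level <- food_level * exp(stats::rnorm(n, 0, 0.10))
    }
    np <- config$n_persons
    sig <- config$consumption_sigma
    sample_mat <- vapply(seq_len(n), function(i) {
      eats <- stats::runif(np) > zi[i]
      if (!any(eats)) eats[1] <- TRUE
      v <- numeric(np)
      v[eats] <- stats::rlnorm(sum(eats), log(food_level[i]), sig)
      v
    }, numeric(np))
    x0 <- colMeans(sample_mat)
    p10 <- apply(sample_mat, 2, stats::quantile, probs = 0.10, type = 7,
                 names = FALSE)
    p90 <- apply(sample_mat, 2, stats::quantile, probs = 0.90, type = 7,
                 names = FALSE)

    # dairy-beef jointness of the baseline: scale beef-bearing foods up
    # until the raw-milk demand is covered
    rho <- universe$milk_per_beef
    bf <- foods$beef_fraction; rm_ <- foods$raw_milk_equiv
    if (any(bf > 0)) {
      milk_need <- sum(rm_ * x0); beef_supply <- rho * sum(bf * x0)
      if (milk_need > beef_supply) {
        k <- 1.05 * milk_need / beef_supply
        up <- bf > 0
        x0[up] <- x0[up] * k
        p90[up] <- p90[up] * k
      }
    }

    target <- config$target_energy_kj[[sex]]
    sc <- target / sum(foods$energy_kj_per_g * x0)
    x0 <- x0 * sc; p10 <- p10 * sc; p90 <- p90 * sc
    p10 <- pmin(p10, x0)
    p90 <- pmax(p90, x0)
    population_group(
      tibble::tibble(food_id = foods$id, x0 = x0, p10 = p10, p90 = p90),
      sex = sex, label = label)
  })
}

#' Generate feasibility-by-construction nutrient bounds
#'
#' For each nutrient the effective lower/upper bounds are \code{slack_lo}
#' and \code{slack_hi} times the baseline-implied intake, so the baseline
#' diet satisfies every nutrient row and the health-only minimum-deviation
#' solution is the baseline itself. Amino acids get lower bounds only,
#' stated before the safety margin (the builder multiplies them by 1.24, so
#' the effective bound is \code{slack_lo} times baseline); sodium gets an
#' upper bound only; \%E nutrients are bounded in \%E units. In stress mode
#' the lower bounds of the configured stress nutrients are raised above
#' baseline, making the baseline infeasible and the optimization
#' non-trivial.
#'
#' @inheritParams generate_group
#' @param group The [generate_group()] the bounds are anchored to.
#' @return A bounds tibble suitable for [set_bounds()].
#' @export
generate_feasible_bounds <- function(universe, group,
                                     config = generator_config()) {
  stopifnot(inherits(universe, "food_universe"),
            inherits(group, "population_group"))
  x0 <- baseline_vector(universe, group)
  E0 <- sum(universe$foods$energy_kj_per_g * x0)
  intake <- as.numeric(crossprod(universe$density, x0))
  nut <- universe$nutrients
  conv_map <- c(fat = 37, protein = 17, carbohydrate = 17, alcohol = 29)
  baseline_level <- ifelse(
    nut$unit == "%E",
    100 * conv_map[nut$energy_component] * intake / E0,
    intake)
  lower <- config$slack_lo * baseline_level
  upper <- config$slack_hi * baseline_level
  # amino-acid requirements are stated before the 24% safety margin
  amino <- nut$kind == "amino_acid"
  lower[amino] <- lower[amino] / 1.24
  upper[amino] <- NA_real_
  na_lower <- nut$id == "sodium"
  lower[na_lower] <- NA_real_
  source <- ifelse(amino, "safe", "recommended")
  if (config$stress) {
    hit <- nut$id %in% config$stress_nutrients
    lower[hit] <- config$stress_factor * baseline_level[hit]
    upper[hit] <- pmax(upper[hit], config$slack_hi *
                         config$stress_factor * baseline_level[hit])
  }
  tibble::tibble(nutrient_id = nut$id, sex = group$sex,
                 lower = lower, upper = upper, source = source)
}

#' Generate a complete, scenario-feasible synthetic dataset
#'
#' One-stop generator: universe, group and bounds, followed by a
#' feasibility audit that certifies all three scenarios are solvable for
#' the group. The audit minimizes dietary GHGE subject to the health-only
#' minimum-deviation constraint set (an LP); if even that minimum exceeds
#' half the baseline GHGE, the habit bounds are widened deterministically
#' (raising p90 for low-emission foods, lowering p10 for high-emission
#' ones) until the -50\% scenario is attainable.
#'
#' @inheritParams generate_group
#' @param max_repair Maximum habit-widening rounds; default 4.
#' @return List with elements \code{universe} (bounds attached),
#'   \code{group}, and \code{min_ghge_g}, the certified minimum achievable
#'   GHGE.
#' @export
generate_dataset <- function(config = generator_config(),
                             sex = config$sex, label = "all",
                             max_repair = 4) {
  universe <- generate_universe(config)
  group <- generate_group(universe, config, sex = sex, label = label)
  bounds <- generate_feasible_bounds(universe, group, config)
  universe <- set_bounds(universe, bounds)
  G0 <- sum(universe$foods$ghge_g_per_g * baseline_vector(universe, group))
  min_g <- NA_real_
  for (round in seq_len(max_repair + 1)) {
    system <- build_constraints(universe, group, scenario("health_only"),
                                model = "min_deviation")
    probe <- solve_min_cost(system, universe$foods$ghge_g_per_g)
    min_g <- if (probe$status == "optimal") probe$objective else Inf
    if (is.finite(min_g) && min_g <= 0.5 * G0) break
    if (round > max_repair) {
      warning("could not certify the -50% scenario feasible after ",
              max_repair, " habit-widening rounds", call. = FALSE)
      break
    }
    gk <- universe$foods$ghge_g_per_g / universe$foods$energy_kj_per_g
    low <- gk <= stats::median(gk)
    group$diet$p90[low] <- group$diet$p90[low] * 1.3
    group$diet$p10[!low] <- pmax(0, group$diet$p10[!low] * 0.7)
  }
  list(universe = universe, group = group, min_ghge_g = min_g)
}
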