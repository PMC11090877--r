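#' Unit-value prices from expenditure records
#'
#' Price per gram of each source (expenditure-survey) category, computed as
#' the pooled ratio of total expenditure to total physical quantity — the
#' standard household-budget-survey unit value, not the mean of per-record
#' ratios.
#'
#' @param records Data frame with columns \code{source_category},
#'   \code{expenditure_eur} and \code{quantity_g}.
#' @return Tibble with columns \code{source_category} and
#'   \code{price_eur_per_g}.
#' @export
unit_value_price <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("source_category", "expenditure_eur", "quantity_g")
  if (!all(need %in% names(records))) {
    stop("records needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$expenditure_eur < 0) || any(records$quantity_g < 0)) {
    stop("expenditure and quantity must be non-negative", call. = FALSE)
  }
  out <- records |>
    dplyr::group_by(.data$source_category) |>
    dplyr::summarise(expenditure_eur = sum(.data$expenditure_eur),
                     quantity_g = sum(.data$quantity_g), .groups = "drop")
  if (any(out$quantity_g <= 0)) {
    stop("zero total quantity for source category: ",
         paste(out$source_category[out$quantity_g <= 0], collapse = ", "),
         call. = FALSE)
  }
  out |>
    dplyr::transmute(.data$source_category,
                     price_eur_per_g = .data$expenditure_eur /
                       .data$quantity_g)
}

#' Food-category price as a weighted mean of matched source prices
#'
#' Each food category's price is the quantity-weighted average of the prices
#' of the source categories matched to it. Foods with no matched source are
#' returned with \code{NA} price and flagged in the \code{priced} column.
#'
#' @param matches Data frame with columns \code{food_id},
#'   \code{price_eur_per_g} and \code{weight} (non-negative; typically
#'   matched quantities).
#' @param food_ids Optional character vector of all food ids; foods absent
#'   from \code{matches} are then reported as unpriced instead of dropped.
#' @return Tibble with columns \code{food_id}, \code{price_eur_per_g},
#'   \code{priced}.
#' @export
category_price <- function(matches, food_ids = NULL) {
  matches <- tibble::as_tibble(matches)
  need <- c("food_id", "price_eur_per_g", "weight")
  if (!all(need %in% names(matches))) {
    stop("matches needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(matches$weight < 0)) stop("weights must be >= 0", call. = FALSE)
  out <- matches |>
    dplyr::group_by(.data$food_id) |>
    dplyr::summarise(
      price_eur_per_g = if (sum(.data$weight) > 0) {
        sum(.data$weight * .data$price_eur_per_g) / sum(.data$weight)
      } else {
        NA_real_
      },
      .groups = "drop") |>
    dplyr::mutate(priced = !is.na(.data$price_eur_per_g))
  if (!is.null(food_ids)) {
    out <- tibble::tibble(food_id = food_ids) |>
      dplyr::left_join(out, by = "food_id") |>
      dplyr::mutate(priced = !is.na(.data$price_eur_per_g))
  }
  out
}

#' Consumption-share aggregation of item nutrient densities
#'
#' The nutrient density of a food category is the weighted sum of the
#' densities of the items it contains, with weights equal to each item's
#' share of total category consumption.
#'
#' @param items Data frame with columns \code{item_id} and \code{intake_g}.
#' @param densities Data frame with columns \code{item_id},
#'   \code{nutrient_id}, \code{density} (amount per g of item).
#' @return Tibble with columns \code{nutrient_id} and \code{density} — the
#'   category-level amount per g.
#' @export
aggregate_nutrients <- function(items, densities) {
  items <- tibble::as_tibble(items)
  densities <- tibble::as_tibble(densities)
  if (!all(c("item_id", "intake_g") %in% names(items))) {
    stop("items needs columns item_id, intake_g", call. = FALSE)
  }
  if (!all(c("item_id", "nutrient_id", "density") %in% names(densities))) {
    stop("densities needs columns item_id, nutrient_id, density",
         call. = FALSE)
  }
  total <- sum(items$intake_g)
  if (total <= 0) stop("total category consumption is zero", call. = FALSE)
  items |>
    dplyr::mutate(share = .data$intake_g / total) |>
    dplyr::inner_join(densities, by = "item_id",
                      relationship = "one-to-many") |>
    dplyr::group_by(.data$nutrient_id) |>
    dplyr::summarise(density = sum(.data$share * .data$density),
                     .groups = "drop")
}

#' OECD-equivalized household income
#'
#' Total household income divided by the OECD equivalence scale: weight 1.0
#' for the first adult, 0.7 for each additional adult, 0.5 for each underage
#' member.
#'
#' @param households Data frame with columns \code{total_income},
#'   \code{n_adults} (>= 1) and \code{n_minors} (>= 0).
#' @return The input as a tibble with columns \code{consumption_units} and
#'   \code{equivalized_income} appended.
#' @export
equivalized_income <- function(households) {
  households <- tibble::as_tibble(households)
  need <- c("total_income", "n_adults", "n_minors")
  if (!all(need %in% names(households))) {
    stop("households needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(households$n_adults < 1)) {
    stop("each household needs at least one adult", call. = FALSE)
  }
  if (any(households$n_minors < 0) ||
      any(households$n_adults != round(households$n_adults)) ||
      any(households$n_minors != round(households$n_minors))) {
    stop("member counts must be non-negative integers", call. = FALSE)
  }
  households |>
    dplyr::mutate(
      consumption_units = 1 + 0.7 * (.data$n_adults - 1) +
        0.5 * .data$n_minors,
      equivalized_income = .data$total_income / .data$consumption_units)
}

#' Assign quantile strata (tertiles, quintiles, ...)
#'
#' Cuts a numeric vector into \code{n} equal-probability strata at its
#' empirical type-7 quantiles. Values tied with an interior cut point all
#' fall in the lower stratum, which makes the assignment deterministic and
#' invariant to monotone increasing rescaling of the input.
#'
#' @param x Numeric vector (e.g. equivalized incomes within one sex).
#' @param n Number of strata (3 for tertiles, 5 for quintiles).
#' @return Integer vector of stratum indices in \code{1:n}.
#' @export
assign_quantile_strata <- function(x, n = 5) {
  if (length(x) == 0) stop("x is empty", call. = FALSE)
  if (anyNA(x)) stop("x must not contain NA", call. = FALSE)
  cuts <- stats::quantile(x, probs = seq_len(n - 1) / n, type = 7,
                          names = FALSE)
  # right-closed intervals: a value equal to a cut goes to the lower stratum
  as.integer(cut(x, breaks = c(-Inf, cuts, Inf), right = TRUE,
                 labels = FALSE))
}

#' Food-habit percentiles of a consumption sample
#'
#' Empirical 10th and 90th centiles (linear interpolation between order
#' statistics, type 7) of per-person consumption, per food. These become the
#' habit box bounds of the minimum-deviation model.
#'
#' @param sample Data frame with columns \code{food_id} and \code{value}
#'   (g/d per person; zeros allowed).
#' @param probs Two probabilities, default \code{c(0.10, 0.90)}.
#' @return Tibble with columns \code{food_id}, \code{p10}, \code{p90} (the
#'   column names follow the default probs).
#' @export
habit_percentiles <- function(sample, probs = c(0.10, 0.90)) {
  sample <- tibble::as_tibble(sample)
  if (!all(c("food_id", "value") %in% names(sample))) {
    stop("sample needs columns food_id, value", call. = FALSE)
  }
  if (nrow(sample) == 0) stop("sample is empty", call. = FALSE)
  if (any(sample$value < 0)) stop("values must be >= 0", call. = FALSE)
  stopifnot(length(probs) == 2, probs[1] <= probs[2])
  sample |>
    dplyr::group_by(.data$food_id) |>
    dplyr::summarise(
      p10 = stats::quantile(.data$value, probs[1], type = 7, names = FALSE),
      p90 = stats::quantile(.data$value, probs[2], type = 7, names = FALSE),
      .groups = "drop")
}
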