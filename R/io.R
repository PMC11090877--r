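#' Read and write the delimited-text schemas
#'
#' A universe is stored as four CSV files in a directory: \code{foods.csv}
#' (id, name, main_category, energy_kj_per_g, price_eur_per_g, ghge_g_per_g,
#' beef_fraction, raw_milk_equiv), \code{nutrients.csv} (id, name, unit,
#' kind, energy_component), \code{densities.csv} (food_id, nutrient_id,
#' density; long form) and, when bounds are attached, \code{bounds.csv}
#' (nutrient_id, sex, lower, upper, source). A group is one
#' \code{group_<sex>_<label>.csv} with columns sex, label, food_id, x0,
#' p10, p90.
#'
#' @param universe A [food_universe()].
#' @param dir Directory to write to / read from (created if missing).
#' @return \code{write_*} return the directory/path invisibly;
#'   \code{read_universe} returns a [food_universe()], \code{read_group} a
#'   [population_group()].
#' @name universe_io
NULL

#' @rdname universe_io
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "food_universe"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(universe$foods, file.path(dir, "foods.csv"))
  readr::write_csv(universe$nutrients, file.path(dir, "nutrients.csv"))
  long <- tibble::as_tibble(as.table(universe$density), .name_repair =
                              ~ c("food_id", "nutrient_id", "density"))
  readr::write_csv(long, file.path(dir, "densities.csv"))
  if (!is.null(universe$bounds)) {
    readr::write_csv(universe$bounds, file.path(dir, "bounds.csv"))
  }
  readr::write_csv(tibble::tibble(milk_per_beef = universe$milk_per_beef),
                   file.path(dir, "meta.csv"))
  invisible(dir)
}

#' @rdname universe_io
#' @export
read_universe <- function(dir) {
  foods <- readr::read_csv(file.path(dir, "foods.csv"),
                           show_col_types = FALSE)
  nutrients <- readr::read_csv(file.path(dir, "nutrients.csv"),
                               show_col_types = FALSE)
  long <- readr::read_csv(file.path(dir, "densities.csv"),
                          show_col_types = FALSE)
  density <- matrix(0, nrow(foods), nrow(nutrients),
                    dimnames = list(foods$id, nutrients$id))
  density[cbind(match(long$food_id, foods$id),
                match(long$nutrient_id, nutrients$id))] <- long$density
  meta_path <- file.path(dir, "meta.csv")
  milk <- if (file.exists(meta_path)) {
    readr::read_csv(meta_path, show_col_types = FALSE)$milk_per_beef[1]
  } else {
    33.9
  }
  bounds_path <- file.path(dir, "bounds.csv")
  bounds <- if (file.exists(bounds_path)) {
    readr::read_csv(bounds_path, show_col_types = FALSE)
  }
  food_universe(foods, nutrients, density, bounds, milk_per_beef = milk)
}

#' @rdname universe_io
#' @param group A [population_group()].
#' @export
write_group <- function(group, dir) {
  stopifnot(inherits(group, "population_group"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0("group_", group$sex, "_", group$label,
                                ".csv"))
  readr::write_csv(dplyr::mutate(group$diet, sex = group$sex,
                                 label = group$label, .before = 1), path)
  invisible(path)
}

#' @rdname universe_io
#' @param path Path of a group CSV written by [write_group()].
#' @export
read_group <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  population_group(tbl[, c("food_id", "x0", "p10", "p90")],
                   sex = tbl$sex[1], label = tbl$label[1])
}

#' Write a complete generated dataset
#'
#' Convenience wrapper emitting the full CSV schema set for a
#' [generate_dataset()] result, so a worked dataset can be inspected or fed
#' back in through [read_universe()]/[read_group()].
#'
#' @param dataset List with \code{universe} and \code{group}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  write_universe(dataset$universe, dir)
  write_group(dataset$group, dir)
  invisible(dir)
}
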