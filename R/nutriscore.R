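ns_cache <- new.env(parent = emptyenv())

#' Load the NutriScore threshold tables
#'
#' The 2017 Sante Publique France / FSA nutrient-profiling thresholds are
#' shipped as an editable YAML resource: component point thresholds
#' (with beverage, cheese and added-fats variants), the protein-cap rule
#' and the A-E letter cut-points.  All point logic reads from this
#' resource, so a revised table can be dropped in without code changes.
#'
#' @param path Optional path to an alternative YAML resource.
#' @return Nested list of thresholds.
#' @export
ns_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(ns_cache$default)) {
      ns_cache$default <- yaml::read_yaml(
        system.file("extdata", "nutriscore_2017.yaml", package = "foodprint"))
    }
    return(ns_cache$default)
  }
  yaml::read_yaml(path)
}

ns_food_types <- c("general", "beverage", "cheese", "added_fat")

# points = number of thresholds strictly exceeded
points_from_thresholds <- function(value, thresholds) {
  sum(value > unlist(thresholds))
}

#' NutriScore component points
#'
#' Assigns 0-10 penalty points for energy, saturated fat, sugars and
#' sodium, and 0-5 reward points for protein, fiber and
#' fruit/vegetable/nut/oil content, from the shipped threshold tables.
#' Beverages use the beverage variant for energy, sugars and fvno (fvno
#' reward reaching 10 points); added fats score saturated fat on the
#' saturated-to-total-fat ratio, which requires `total_fat_g` in the
#' panel.
#'
#' @param panel A [nutrition_panel()].
#' @param food_type One of `"general"`, `"beverage"`, `"cheese"`,
#'   `"added_fat"`.
#' @param thresholds Threshold resource from [ns_thresholds()].
#' @return List with integer vectors `negative` (energy, satfat, sodium,
#'   sugars) and `positive` (protein, fiber, fvno).
#' @export
component_points <- function(panel, food_type = "general",
                             thresholds = ns_thresholds()) {
  if (!food_type %in% ns_food_types)
    stop("unknown food_type '", food_type, "'; expected one of: ",
         paste(ns_food_types, collapse = ", "))
  tab <- thresholds$components
  gen <- tab$general
  bev <- food_type == "beverage"
  energy <- points_from_thresholds(
    panel$energy_kj, if (bev) tab$beverage$energy_kj else gen$energy_kj)
  sugars <- points_from_thresholds(
    panel$sugars_g, if (bev) tab$beverage$sugars_g else gen$sugars_g)
  if (food_type == "added_fat") {
    if (is.na(panel$total_fat_g))
      stop("added_fat scoring requires total_fat_g in the nutrition panel")
    ratio <- if (panel$total_fat_g > 0)
      100 * panel$saturated_fat_g / panel$total_fat_g else 0
    satfat <- points_from_thresholds(ratio, tab$added_fat$satfat_ratio_percent)
  } else {
    satfat <- points_from_thresholds(panel$saturated_fat_g, gen$saturated_fat_g)
  }
  sodium <- points_from_thresholds(panel$sodium_mg, gen$sodium_mg)
  fvno <- points_from_thresholds(
    panel$fvno_percent, if (bev) tab$beverage$fvno_percent else gen$fvno_percent)
  protein <- points_from_thresholds(panel$protein_g, gen$protein_g)
  fiber <- points_from_thresholds(panel$fiber_g, gen$fiber_g)
  list(negative = c(energy = energy, satfat = satfat, sodium = sodium,
                    sugars = sugars),
       positive = c(protein = protein, fiber = fiber, fvno = fvno))
}

#' Total NutriScore points
#'
#' The positive (reward) sum is subtracted from the negative (penalty)
#' sum, giving a total in -15..40 for general foods.  The protein cap
#' applies: when the negative sum reaches 11 points, protein points are
#' not counted unless the fruit/vegetable/nut/oil component is at its
#' food-type maximum; cheese is exempt from the cap.
#'
#' @param points A [component_points()] result.
#' @param food_type Food type, as in [component_points()].
#' @param thresholds Threshold resource.
#' @return Integer total.
#' @export
total_score <- function(points, food_type = "general",
                        thresholds = ns_thresholds()) {
  neg <- sum(points$negative)
  pos <- points$positive
  cap <- thresholds$protein_cap
  exempt <- food_type %in% unlist(cap$exempt_food_types)
  fvno_full <- cap$fvno_full[[food_type]]
  counted <- if (!exempt && neg >= cap$negative_threshold &&
                 pos[["fvno"]] < fvno_full)
    pos[["fiber"]] + pos[["fvno"]]
  else sum(pos)
  as.integer(neg - counted)
}

#' Letter class, numeric 1-5 and scaled 0-100 nutrition impact score
#'
#' The total is mapped to the A-E letter by the food-type cut-points
#' (beverages use their own, stricter cut-points; class A is reserved for
#' plain water), to the numeric score 1 (A, most nutritious) .. 5 (E,
#' least nutritious), and to the 0-100 nutrition impact scale via the
#' affine map `100 * (total + 15) / 55` (0 = best, 100 = worst).
#'
#' @param total Integer total points.
#' @param food_type Food type.
#' @param is_drink Logical; drinks use beverage cut-points.
#' @param is_water Logical; plain water is the only class-A beverage.
#' @param thresholds Threshold resource.
#' @return List with `letter`, `numeric`, `scaled`.
#' @export
letter_and_scales <- function(total, food_type = "general", is_drink = FALSE,
                              is_water = FALSE, thresholds = ns_thresholds()) {
  bev <- is_drink || food_type == "beverage"
  lo <- if (bev) -20 else -15
  if (is.na(total) || total < lo || total > 40)
    stop("total NutriScore points out of range [", lo, ", 40]: ", total)
  if (bev) {
    cuts <- thresholds$letters$beverage
    letter <- if (is_water) "A"
      else if (total <= cuts$B) "B"
      else if (total <= cuts$C) "C"
      else if (total <= cuts$D) "D"
      else "E"
  } else {
    cuts <- thresholds$letters$food
    letter <- if (total <= cuts$A) "A"
      else if (total <= cuts$B) "B"
      else if (total <= cuts$C) "C"
      else if (total <= cuts$D) "D"
      else "E"
  }
  sc <- thresholds$scaled
  list(letter = letter,
       numeric = match(letter, LETTERS[1:5]),
       scaled = 100 * (total + sc$offset) / sc$range)
}

#' Full NutriScore of a nutrition panel or product
#'
#' Computes component points, the total, the A-E letter, the numeric 1-5
#' score and the scaled 0-100 nutrition impact score.  Alcoholic
#' beverages are rejected: the profiling model does not account for
#' alcohol.
#'
#' @param x A [nutrition_panel()] or a [product_record()] carrying one.
#' @param food_type Food type; for a product, defaults to `"beverage"`
#'   when `is_drink` is set and `"general"` otherwise.
#' @param is_drink Logical (panels only; inferred for products).
#' @param is_water Logical, plain water.
#' @param thresholds Threshold resource.
#' @return An object of class `nutriscore_result`.
#' @export
nutri_score <- function(x, food_type = NULL, is_drink = FALSE,
                        is_water = FALSE, thresholds = ns_thresholds()) {
  if (inherits(x, "product_record")) {
    if (x$is_alcoholic)
      stop("product '", x$product_id,
           "' is an alcoholic beverage; NutriScore does not account for alcohol")
    if (is.null(x$nutrition))
      stop("product '", x$product_id, "' has no nutrition panel")
    is_drink <- x$is_drink
    if (is.null(food_type)) food_type <- if (is_drink) "beverage" else "general"
    panel <- x$nutrition
  } else {
    panel <- x
    if (is.null(food_type)) food_type <- if (is_drink) "beverage" else "general"
  }
  pts <- component_points(panel, food_type, thresholds)
  total <- total_score(pts, food_type, thresholds)
  ls <- letter_and_scales(total, food_type, is_drink, is_water, thresholds)
  structure(list(negative_points = pts$negative,
                 positive_points = pts$positive,
                 total = total, letter = ls$letter, numeric = ls$numeric,
                 scaled = ls$scaled, food_type = food_type),
            class = "nutriscore_result")
}

#' @export
print.nutriscore_result <- function(x, ...) {
  cat("<nutriscore>", x$letter, sprintf("(total %d, scaled %.1f)", x$total,
                                        x$scaled), "\n")
  invisible(x)
}
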