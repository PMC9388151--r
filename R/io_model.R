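#' Create an ingredient entry
#'
#' One element of a product's ordered ingredient list.  UK/EU labeling
#' requires ingredients to be listed in decreasing order of mass; `rank` 1
#' is the most abundant ingredient.  `declared_percent` carries a QUID
#' declaration when present and may exceed 100 for dried or concentrated
#' ingredients (e.g. more than 100 g of raw beef per 100 g of biltong);
#' `raw_equivalent_factor` is the mass of raw commodity per unit mass of
#' the ingredient in the final product.
#'
#' @param name Free-text ingredient name as printed on the pack.
#' @param rank Positive integer position in the ingredient list.
#' @param declared_percent Declared percent of product mass, or `NA`.
#' @param category_id Environmental-database category id, or `NA` when the
#'   ingredient has not (yet) been mapped.
#' @param organic Logical, ingredient labeled organic.
#' @param raw_equivalent_factor Positive scalar, defaults to 1.
#' @return An object of class `ingredient_entry`.
#' @export
ingredient_entry <- function(name, rank, declared_percent = NA_real_,
                             category_id = NA_character_, organic = FALSE,
                             raw_equivalent_factor = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  rank <- as.integer(rank)
  if (is.na(rank) || rank < 1L) stop("rank must be a positive integer")
  declared_percent <- parse_percent(declared_percent)
  if (!is.na(declared_percent) && declared_percent <= 0)
    stop("declared_percent must be > 0 when present (ingredient '", name, "')")
  raw_equivalent_factor <- as.numeric(raw_equivalent_factor)
  if (is.na(raw_equivalent_factor) || raw_equivalent_factor <= 0)
    stop("raw_equivalent_factor must be a positive number")
  structure(list(name = name, rank = rank,
                 declared_percent = declared_percent,
                 category_id = as.character(category_id),
                 organic = isTRUE(organic),
                 raw_equivalent_factor = raw_equivalent_factor),
            class = "ingredient_entry")
}

#' Strip percent annotations from a declared value
#'
#' Accepts numbers or strings such as `"60%"` / `" 60 % "`; returns a
#' numeric percent.
#' @param x Numeric or character scalar/vector.
#' @return Numeric vector.
#' @export
parse_percent <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NA_real_)
  if (is.character(x)) x <- gsub("[% ]", "", x)
  suppressWarnings(as.numeric(x))
}

#' Create a per-100 g nutrition panel
#'
#' All values are per 100 g (per 100 mL for drinks): energy in kJ,
#' saturated fat / sugars / protein / fiber in g, sodium in mg, and the
#' percentage of the product that is fruit, vegetables, nuts or
#' olive/walnut/rapeseed oil (`fvno_percent`).  `total_fat_g` is optional
#' and only used for the added-fats NutriScore variant (saturated-to-total
#' fat ratio).
#'
#' @param energy_kj,saturated_fat_g,sugars_g,sodium_mg,protein_g,fiber_g
#'   Non-negative per-100 g amounts.
#' @param fvno_percent Percent in \[0, 100\].
#' @param total_fat_g Optional total fat, g per 100 g.
#' @return An object of class `nutrition_panel`.
#' @export
nutrition_panel <- function(energy_kj = 0, saturated_fat_g = 0, sugars_g = 0,
                            sodium_mg = 0, protein_g = 0, fiber_g = 0,
                            fvno_percent = 0, total_fat_g = NA_real_) {
  vals <- c(energy_kj = energy_kj, saturated_fat_g = saturated_fat_g,
            sugars_g = sugars_g, sodium_mg = sodium_mg,
            protein_g = protein_g, fiber_g = fiber_g,
            fvno_percent = fvno_percent)
  vals <- vapply(vals, as.numeric, numeric(1))
  if (anyNA(vals)) stop("nutrition panel values must be numeric")
  if (any(vals < 0)) stop("nutrition panel values must be >= 0")
  if (vals[["fvno_percent"]] > 100) stop("fvno_percent must be <= 100")
  structure(c(as.list(vals), list(total_fat_g = as.numeric(total_fat_g))),
            class = "nutrition_panel")
}

#' Create a product record
#'
#' One retail product: taxonomy labels (a product may belong to several
#' Departments/Aisles/Shelves), the ordered ingredient list, the nutrition
#' panel and an optional serving size.
#'
#' @param product_id Unique identifier.
#' @param ingredients List of [ingredient_entry()] objects; ranks must be
#'   the consecutive integers 1..n.  May be empty, in which case the
#'   product is loaded but not scorable.
#' @param nutrition A [nutrition_panel()] or `NULL`.
#' @param retailer Retailer name.
#' @param departments,aisles,shelves Character vectors of taxonomy labels.
#' @param serving_size_g Serving size in g, or `NA` when not printed.
#' @param is_drink Logical; beverages use the NutriScore beverage tables.
#' @param is_organic_product Logical, whole product labeled organic.
#' @param is_alcoholic Logical; alcoholic drinks cannot be nutrition-scored.
#' @return An object of class `product_record`.
#' @export
product_record <- function(product_id, ingredients = list(), nutrition = NULL,
                           retailer = "", departments = character(),
                           aisles = character(), shelves = character(),
                           serving_size_g = NA_real_, is_drink = FALSE,
                           is_organic_product = FALSE, is_alcoholic = FALSE) {
  product_id <- as.character(product_id)
  stopifnot(length(product_id) == 1L, nzchar(product_id))
  if (length(ingredients)) {
    stopifnot(all(vapply(ingredients, inherits, logical(1), "ingredient_entry")))
    ranks <- vapply(ingredients, `[[`, integer(1), "rank")
    if (!identical(sort(ranks), seq_along(ingredients)))
      stop("product '", product_id,
           "': ingredient ranks must be consecutive integers 1..n without duplicates")
    ingredients <- ingredients[order(ranks)]
  }
  if (!is.null(nutrition) && !inherits(nutrition, "nutrition_panel"))
    stop("nutrition must be a nutrition_panel or NULL")
  structure(list(product_id = product_id, retailer = as.character(retailer),
                 departments = as.character(departments),
                 aisles = as.character(aisles),
                 shelves = as.character(shelves),
                 ingredients = ingredients, nutrition = nutrition,
                 serving_size_g = as.numeric(serving_size_g),
                 is_drink = isTRUE(is_drink),
                 is_organic_product = isTRUE(is_organic_product),
                 is_alcoholic = isTRUE(is_alcoholic)),
            class = "product_record")
}

#' @export
print.product_record <- function(x, ...) {
  cat("<product_record>", x$product_id, "-", length(x$ingredients),
      "ingredients", if (x$is_drink) "(drink)" else "", "\n")
  invisible(x)
}

#' Declared percentages of a product, by rank
#' @param product A [product_record()].
#' @return Numeric vector (NA where undeclared), ordered by rank.
#' @export
declared_percents <- function(product) {
  vapply(product$ingredients, `[[`, numeric(1), "declared_percent")
}

#' Is a product scorable?
#'
#' A product needs a non-empty ingredient list to be scored.
#' @param product A [product_record()].
#' @return Logical.
#' @export
is_scorable <- function(product) length(product$ingredients) > 0L

#' Create a food category of production observations
#'
#' Observations are farm/production-system level impact intensities per kg
#' of raw commodity with a production-share sampling weight.  Fish
#' categories additionally carry aquaculture/capture system labels and are
#' sampled with a 50:50 split between the two systems.
#'
#' @param category_id Category identifier.
#' @param name Human-readable name.
#' @param observations `data.frame` with columns `ghg` (kg CO2e/kg),
#'   `land` (m2/kg), `water` (scarcity-weighted L-eq/kg), `eutro`
#'   (g PO4e/kg), and optionally `weight`, `organic`, `system_label`.
#' @param is_fish Logical.
#' @return An object of class `food_category`.
#' @export
food_category <- function(category_id, name = category_id, observations,
                          is_fish = FALSE) {
  observations <- as.data.frame(observations)
  if (nrow(observations) == 0L)
    stop("category '", category_id, "' must have at least one observation")
  need <- c("ghg", "land", "water", "eutro")
  missing <- setdiff(need, names(observations))
  if (length(missing))
    stop("category '", category_id, "' observations lack columns: ",
         paste(missing, collapse = ", "))
  if (is.null(observations$weight)) observations$weight <- 1
  if (is.null(observations$organic)) observations$organic <- FALSE
  if (is.null(observations$system_label)) observations$system_label <- ""
  im <- as.matrix(observations[, need])
  if (anyNA(im) || any(im < 0))
    stop("category '", category_id, "' has missing or negative intensities")
  if (any(is.na(observations$weight)) || any(observations$weight < 0))
    stop("category '", category_id, "' has negative or missing weights")
  structure(list(category_id = as.character(category_id),
                 name = as.character(name),
                 observations = observations, is_fish = isTRUE(is_fish)),
            class = "food_category")
}

#' Create an environmental intensity database
#' @param categories List of [food_category()] objects.
#' @return An object of class `env_database`, keyed by category id.
#' @export
env_database <- function(categories) {
  stopifnot(all(vapply(categories, inherits, logical(1), "food_category")))
  ids <- vapply(categories, `[[`, character(1), "category_id")
  if (anyDuplicated(ids)) stop("duplicate category_id in environmental database")
  structure(setNames(categories, ids), class = "env_database")
}

#' @export
print.env_database <- function(x, ...) {
  nobs <- sum(vapply(x, function(cc) nrow(cc$observations), integer(1)))
  cat("<env_database>", length(x), "categories,", nobs, "observations\n")
  invisible(x)
}

# columns of the long-format product CSV
product_csv_cols <- c("product_id", "retailer", "departments", "aisles",
                      "shelves", "serving_size_g", "is_drink",
                      "is_organic_product", "is_alcoholic", "energy_kj",
                      "saturated_fat_g", "sugars_g", "sodium_mg", "protein_g",
                      "fiber_g", "fvno_percent", "total_fat_g", "ingredient",
                      "rank", "declared_percent", "organic",
                      "raw_equivalent_factor")

#' Read a product corpus
#'
#' Two equivalent on-disk schemas are supported: a JSON array with one
#' object per product (ingredients as an ordered array), and a long-format
#' CSV with one row per ingredient.  Ingredient order in the file is
#' preserved exactly; ranks are assigned from file order when absent.
#' Multi-valued taxonomy fields are `";"`-separated in the CSV.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return List of [product_record()] objects.
#' @export
read_products <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") read_products_json(path) else read_products_csv(path)
}

read_products_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  products <- lapply(raw, function(p) {
    pid <- p$product_id
    if (is.null(pid)) stop("product without product_id in ", path)
    ings <- lapply(seq_along(p$ingredients), function(i) {
      ig <- p$ingredients[[i]]
      if (is.null(ig$name))
        stop("product '", pid, "': ingredient ", i, " lacks field 'name'")
      ingredient_entry(
        name = ig$name,
        rank = if (is.null(ig$rank)) i else ig$rank,
        declared_percent = if (is.null(ig$declared_percent)) NA_real_
                           else ig$declared_percent,
        category_id = if (is.null(ig$category_id)) NA_character_
                      else ig$category_id,
        organic = isTRUE(ig$organic),
        raw_equivalent_factor = if (is.null(ig$raw_equivalent_factor)) 1
                                else ig$raw_equivalent_factor)
    })
    nut <- if (is.null(p$nutrition)) NULL else do.call(nutrition_panel, p$nutrition)
    product_record(
      product_id = pid,
      ingredients = ings, nutrition = nut,
      retailer = if (is.null(p$retailer)) "" else p$retailer,
      departments = unlist(p$departments), aisles = unlist(p$aisles),
      shelves = unlist(p$shelves),
      serving_size_g = if (is.null(p$serving_size_g)) NA_real_ else p$serving_size_g,
      is_drink = isTRUE(p$is_drink),
      is_organic_product = isTRUE(p$is_organic_product),
      is_alcoholic = isTRUE(p$is_alcoholic))
  })
  ids <- vapply(products, `[[`, character(1), "product_id")
  if (anyDuplicated(ids))
    stop("duplicate product_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  products
}

split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

read_products_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), product_csv_cols)
  if (length(unknown))
    stop("unknown product CSV column(s): ", paste(unknown, collapse = ", "))
  if (!"product_id" %in% names(df)) stop("product CSV lacks product_id column")
  if (!"ingredient" %in% names(df)) stop("product CSV lacks ingredient column")
  if (!"declared_percent" %in% names(df)) df$declared_percent <- NA_real_
  # preserve file order of products and of rows within product
  pids <- unique(df$product_id)
  lapply(pids, function(pid) {
    rows <- df[df$product_id == pid, , drop = FALSE]
    r1 <- rows[1, ]
    ranks <- if ("rank" %in% names(rows) && !anyNA(rows$rank)) rows$rank
             else seq_len(nrow(rows))
    has_ing <- nzchar(rows$ingredient) & !is.na(rows$ingredient)
    ings <- lapply(which(has_ing), function(i) {
      ingredient_entry(
        name = rows$ingredient[i], rank = ranks[i],
        declared_percent = parse_percent(rows$declared_percent[i]),
        organic = "organic" %in% names(rows) && isTRUE(as.logical(rows$organic[i])),
        raw_equivalent_factor = if ("raw_equivalent_factor" %in% names(rows) &&
                                    !is.na(rows$raw_equivalent_factor[i]))
          rows$raw_equivalent_factor[i] else 1)
    })
    nut_cols <- c("energy_kj", "saturated_fat_g", "sugars_g", "sodium_mg",
                  "protein_g", "fiber_g", "fvno_percent")
    nut <- NULL
    if (all(nut_cols %in% names(rows)) && !anyNA(unlist(r1[nut_cols]))) {
      nut <- nutrition_panel(
        energy_kj = r1$energy_kj, saturated_fat_g = r1$saturated_fat_g,
        sugars_g = r1$sugars_g, sodium_mg = r1$sodium_mg,
        protein_g = r1$protein_g, fiber_g = r1$fiber_g,
        fvno_percent = r1$fvno_percent,
        total_fat_g = if ("total_fat_g" %in% names(r1)) r1$total_fat_g else NA_real_)
    }
    product_record(
      product_id = pid, ingredients = ings, nutrition = nut,
      retailer = if ("retailer" %in% names(r1)) r1$retailer else "",
      departments = split_multi(as.character(
        if ("departments" %in% names(r1)) r1$departments else NA)),
      aisles = split_multi(as.character(if ("aisles" %in% names(r1)) r1$aisles else NA)),
      shelves = split_multi(as.character(if ("shelves" %in% names(r1)) r1$shelves else NA)),
      serving_size_g = if ("serving_size_g" %in% names(r1))
        as.numeric(r1$serving_size_g) else NA_real_,
      is_drink = isTRUE(as.logical(r1$is_drink)),
      is_organic_product = isTRUE(as.logical(r1$is_organic_product)),
      is_alcoholic = isTRUE(as.logical(r1$is_alcoholic)))
  })
}

#' Write a product corpus
#'
#' Inverse of [read_products()]; round-trips all fields.
#' @param products List of [product_record()] objects.
#' @param path Output path.
#' @param format `"auto"`, `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    out <- lapply(products, function(p) {
      obj <- list(
        product_id = p$product_id, retailer = p$retailer,
        departments = as.list(p$departments), aisles = as.list(p$aisles),
        shelves = as.list(p$shelves),
        ingredients = lapply(p$ingredients, function(ig) {
          keep <- !vapply(ig, function(v) length(v) == 1 && is.na(v), logical(1))
          ig[keep]
        }),
        is_drink = p$is_drink, is_organic_product = p$is_organic_product,
        is_alcoholic = p$is_alcoholic)
      if (!is.na(p$serving_size_g)) obj$serving_size_g <- p$serving_size_g
      if (!is.null(p$nutrition)) {
        nut <- unclass(p$nutrition)
        obj$nutrition <- nut[!vapply(nut, is.na, logical(1))]
      }
      obj
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    rows <- do.call(rbind, lapply(products, function(p) {
      n <- max(1L, length(p$ingredients))
      nut <- p$nutrition
      g <- function(f) if (is.null(nut)) NA_real_ else nut[[f]]
      data.frame(
        product_id = rep(p$product_id, n), retailer = p$retailer,
        departments = paste(p$departments, collapse = ";"),
        aisles = paste(p$aisles, collapse = ";"),
        shelves = paste(p$shelves, collapse = ";"),
        serving_size_g = p$serving_size_g, is_drink = p$is_drink,
        is_organic_product = p$is_organic_product, is_alcoholic = p$is_alcoholic,
        energy_kj = g("energy_kj"), saturated_fat_g = g("saturated_fat_g"),
        sugars_g = g("sugars_g"), sodium_mg = g("sodium_mg"),
        protein_g = g("protein_g"), fiber_g = g("fiber_g"),
        fvno_percent = g("fvno_percent"), total_fat_g = g("total_fat_g"),
        ingredient = if (length(p$ingredients))
          vapply(p$ingredients, `[[`, character(1), "name") else "",
        rank = if (length(p$ingredients))
          vapply(p$ingredients, `[[`, integer(1), "rank") else NA_integer_,
        declared_percent = if (length(p$ingredients))
          vapply(p$ingredients, `[[`, numeric(1), "declared_percent") else NA_real_,
        organic = if (length(p$ingredients))
          vapply(p$ingredients, `[[`, logical(1), "organic") else FALSE,
        raw_equivalent_factor = if (length(p$ingredients))
          vapply(p$ingredients, `[[`, numeric(1), "raw_equivalent_factor") else NA_real_,
        stringsAsFactors = FALSE)
    }))
    write.csv(rows, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read an environmental intensity database
#'
#' CSV with one row per production observation.  Required columns:
#' `category_id`, `ghg`, `land`, `water`, `eutro`.  Optional: `name`,
#' `weight` (defaults to 1), `organic`, `system_label`, `is_fish` (when
#' absent, a category is flagged as fish if any of its observations carry
#' an `"aquaculture"` or `"capture"` system label).
#'
#' @param path CSV file path.
#' @return An [env_database()].
#' @export
read_env_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  allowed <- c("category_id", "name", "ghg", "land", "water", "eutro",
               "weight", "organic", "system_label", "is_fish")
  unknown <- setdiff(names(df), allowed)
  if (length(unknown))
    stop("unknown environmental DB column(s): ", paste(unknown, collapse = ", "))
  required <- c("category_id", "ghg", "land", "water", "eutro")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("environmental DB lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(df$weight)) df$weight <- 1
  if (is.null(df$organic)) df$organic <- FALSE
  if (is.null(df$system_label)) df$system_label <- ""
  cats <- lapply(split(df, df$category_id), function(rows) {
    fish <- if ("is_fish" %in% names(rows)) isTRUE(as.logical(rows$is_fish[1]))
            else any(rows$system_label %in% c("aquaculture", "capture"))
    food_category(
      category_id = rows$category_id[1],
      name = if ("name" %in% names(rows)) rows$name[1] else rows$category_id[1],
      observations = rows[, intersect(names(rows),
        c("ghg", "land", "water", "eutro", "weight", "organic", "system_label"))],
      is_fish = fish)
  })
  env_database(cats[unique(df$category_id)])
}

#' Write an environmental intensity database
#' @param db An [env_database()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_env_db <- function(db, path) {
  rows <- do.call(rbind, lapply(db, function(cc) {
    obs <- cc$observations
    data.frame(category_id = cc$category_id, name = cc$name,
               ghg = obs$ghg, land = obs$land, water = obs$water,
               eutro = obs$eutro, weight = obs$weight, organic = obs$organic,
               system_label = obs$system_label, is_fish = cc$is_fish,
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
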