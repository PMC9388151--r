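syn_cache <- new.env(parent = emptyenv())

#' The shipped food-category table
#'
#' 111 food categories (109 commodity categories plus zero-impact water
#' and salt) with a broad class, fish flag, per-100 g nutrient profile and
#' median environmental intensity per kg of raw commodity.  Used by the
#' synthetic generator and by the starter lexicon.
#'
#' @return `data.frame` with one row per category.
#' @export
category_table <- function() {
  if (is.null(syn_cache$categories)) {
    syn_cache$categories <- read.csv(
      system.file("extdata", "categories.csv", package = "foodprint"),
      stringsAsFactors = FALSE)
  }
  syn_cache$categories
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults mirror the labeling conditions the estimator is designed for:
#' 111 food categories, at least five production observations per
#' category, right-skewed (lognormal) intensity distributions, and a
#' 10.4% share of ingredients carrying a declared (QUID) percentage,
#' biased toward the characterizing rank-1 ingredient.
#'
#' @param n_categories Number of categories drawn from the shipped table
#'   (water and salt always included), default 111.
#' @param obs_per_category Production observations per category (>= 5),
#'   default 10.
#' @param n_products Number of products, default 200.
#' @param ingredients_range Integer range of ingredients per product,
#'   default `c(1, 10)` with ~4% single-ingredient products.
#' @param declared_fraction Target share of ingredients with a declared
#'   percent, default 0.104.
#' @param organic_fraction Share of ingredients labeled organic, default
#'   0.05.
#' @param intensity_sdlog Lognormal sigma of the per-observation intensity
#'   spread, default 0.5.
#' @param dirichlet_concentration Symmetric Dirichlet concentration for
#'   true compositions (sorted descending), default 1 (uniform on the
#'   simplex before sorting).
#' @param serving_fraction Share of products with a printed serving size,
#'   default 0.7.
#' @param seed Integer seed driving all generator randomness.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_categories = 111, obs_per_category = 10,
                             n_products = 200, ingredients_range = c(1, 10),
                             declared_fraction = 0.104,
                             organic_fraction = 0.05,
                             intensity_sdlog = 0.5,
                             dirichlet_concentration = 1,
                             serving_fraction = 0.7, seed = 1) {
  stopifnot(obs_per_category >= 5, n_products >= 1,
            declared_fraction >= 0, declared_fraction <= 1,
            length(ingredients_range) == 2,
            ingredients_range[1] >= 1,
            ingredients_range[2] >= ingredients_range[1],
            intensity_sdlog >= 0, dirichlet_concentration > 0)
  structure(list(n_categories = n_categories,
                 obs_per_category = as.integer(obs_per_category),
                 n_products = as.integer(n_products),
                 ingredients_range = as.integer(ingredients_range),
                 declared_fraction = declared_fraction,
                 organic_fraction = organic_fraction,
                 intensity_sdlog = intensity_sdlog,
                 dirichlet_concentration = dirichlet_concentration,
                 serving_fraction = serving_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

syn_categories <- function(config) {
  cats <- category_table()
  keep_always <- cats$class %in% c("water", "salt")
  n_extra <- max(0, min(config$n_categories - sum(keep_always),
                        sum(!keep_always)))
  rbind(cats[!keep_always, ][seq_len(n_extra), ], cats[keep_always, ])
}

#' Generate a synthetic environmental intensity database
#'
#' Per category, `obs_per_category` production observations with
#' right-skewed lognormal intensities around the category's median
#' intensity, positive production-share weights, a deterministic subset
#' flagged organic (alternating categories get 6 vs 2 organic
#' observations, so the five-observation organic rule is exercised both
#' ways), and aquaculture/capture system labels for fish categories.
#' Water and salt carry all-zero intensities.
#'
#' @param config A [synthetic_config()].
#' @return An [env_database()].
#' @export
generate_env_db <- function(config = synthetic_config()) {
  set.seed(config$seed)
  cats <- syn_categories(config)
  sdl <- config$intensity_sdlog
  n <- config$obs_per_category
  lst <- lapply(seq_len(nrow(cats)), function(i) {
    row <- cats[i, ]
    base <- c(row$ghg_base, row$land_base, row$water_base, row$eutro_base)
    if (all(base == 0)) {
      obs <- data.frame(ghg = numeric(n), land = numeric(n),
                        water = numeric(n), eutro = numeric(n),
                        weight = rep(1, n), organic = rep(FALSE, n),
                        system_label = rep("conventional", n))
    } else {
      # shared farm-quality factor induces cross-indicator correlation
      common <- rlnorm(n, -sdl^2 / 2, sdl)
      draw <- function(b) b * common * rlnorm(n, -(sdl / 2)^2 / 2, sdl / 2)
      n_org <- if (i %% 2 == 0) min(6L, n) else 2L
      obs <- data.frame(
        ghg = draw(base[1]), land = draw(base[2]),
        water = draw(base[3]), eutro = draw(base[4]),
        weight = rlnorm(n, 0, 0.5),
        organic = seq_len(n) <= n_org,
        system_label = if (row$is_fish)
          rep_len(c("aquaculture", "capture"), n) else
          rep("conventional", n))
    }
    food_category(row$category_id, row$name, obs, is_fish = row$is_fish)
  })
  env_database(lst)
}

syn_department <- c(vegetable = "Produce", fruit = "Produce", nut = "Pantry",
                    oil = "Pantry", grain = "Bakery", legume = "Pantry",
                    meat = "Meat", fish = "Fish", dairy = "Dairy",
                    egg = "Dairy", sugar = "Pantry", other = "Pantry",
                    water = "Drinks", salt = "Pantry")

#' Generate a synthetic product corpus with known compositions
#'
#' True compositions are drawn from a symmetric Dirichlet and sorted
#' descending, guaranteeing the mass-ordering labeling constraint;
#' ingredient categories are sampled from the database (water is common,
#' mirroring real assortments); declared percentages are revealed for a
#' Bernoulli subset biased toward rank 1 (the characterizing-ingredient
#' convention); the nutrition panel is accumulated from fixed per-category
#' nutrient profiles so NutriScore spans the A-E classes; and the ground
#' truth is returned alongside the corpus.
#'
#' @param config A [synthetic_config()].
#' @param db An [env_database()] from [generate_env_db()] (only category
#'   ids are used).
#' @return List with `products` (list of [product_record()]) and `truth`
#'   (`data.frame`: product_id, rank, category_id, true_percent).
#' @export
generate_products <- function(config = synthetic_config(),
                              db = generate_env_db(config)) {
  set.seed(config$seed + 1L)
  cats <- syn_categories(config)
  ids <- cats$category_id
  w_cat <- ifelse(ids == "water", 8, ifelse(ids == "salt", 2, 1))
  lohi <- config$ingredients_range
  sizes <- lohi[1]:lohi[2]
  w_size <- rep(1, length(sizes))
  if (sizes[1] == 1 && length(sizes) > 1) w_size[1] <- 0.375
  products <- vector("list", config$n_products)
  truth <- vector("list", config$n_products)
  for (j in seq_len(config$n_products)) {
    pid <- sprintf("SYN%04d", j)
    k <- if (length(sizes) == 1) sizes else sample(sizes, 1, prob = w_size)
    k <- min(k, length(ids))
    cat_idx <- sample.int(length(ids), k, prob = w_cat)
    g <- rgamma(k, shape = config$dirichlet_concentration)
    p_true <- sort(100 * g / sum(g), decreasing = TRUE)
    w_rank <- c(2.5, rep(1, k - 1))[seq_len(k)]
    p_reveal <- config$declared_fraction * k * w_rank / sum(w_rank)
    # cap at 1 and redistribute the excess so the mean reveal probability
    # stays at declared_fraction (and a fraction of 1 reveals everything)
    for (it in 1:10) {
      over <- pmax(p_reveal - 1, 0)
      if (all(over == 0)) break
      p_reveal <- pmin(p_reveal, 1)
      open <- p_reveal < 1
      if (!any(open)) break
      p_reveal[open] <- p_reveal[open] + sum(over) / sum(open)
    }
    reveal <- runif(k) < p_reveal
    organic <- runif(k) < config$organic_fraction
    crow <- cats[cat_idx, ]
    ings <- lapply(seq_len(k), function(i) {
      ingredient_entry(
        name = if (organic[i]) paste("organic", crow$name[i]) else crow$name[i],
        rank = i,
        declared_percent = if (reveal[i]) p_true[i] else NA_real_,
        organic = organic[i])
    })
    frac <- p_true / 100
    panel <- nutrition_panel(
      energy_kj = sum(frac * crow$energy_kj),
      saturated_fat_g = sum(frac * crow$satfat_g),
      sugars_g = sum(frac * crow$sugars_g),
      sodium_mg = sum(frac * crow$sodium_mg),
      protein_g = sum(frac * crow$protein_g),
      fiber_g = sum(frac * crow$fiber_g),
      fvno_percent = min(100, sum(p_true * crow$fvno)))
    is_drink <- crow$class[1] == "water" && p_true[1] >= 50
    serving <- if (runif(1) < config$serving_fraction)
      round(runif(1, 20, 400)) else NA_real_
    cls1 <- crow$class[1]
    aisles <- paste0(toupper(substring(cls1, 1, 1)), substring(cls1, 2),
                     " aisle")
    if (runif(1) < 0.2) aisles <- c(aisles, "Mixed aisle")
    products[[j]] <- product_record(
      product_id = pid, ingredients = ings, nutrition = panel,
      retailer = "synthetic",
      departments = unname(syn_department[cls1]),
      aisles = aisles, shelves = paste(crow$name[1], "shelf"),
      serving_size_g = serving, is_drink = is_drink)
    truth[[j]] <- data.frame(product_id = pid, rank = seq_len(k),
                             category_id = crow$category_id,
                             true_percent = p_true,
                             stringsAsFactors = FALSE)
  }
  list(products = products, truth = do.call(rbind, truth))
}
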