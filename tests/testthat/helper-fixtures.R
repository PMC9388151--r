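# Shared fixtures: tiny deterministic environmental databases and product
# builders used across the unit tests.

# a category with explicitly given observations
make_cat <- function(id, ghg, land = ghg, water = ghg, eutro = ghg,
                     weight = NULL, organic = NULL, system_label = NULL,
                     is_fish = FALSE) {
  n <- length(ghg)
  food_category(id, id, data.frame(
    ghg = ghg, land = land, water = water, eutro = eutro,
    weight = if (is.null(weight)) rep(1, n) else weight,
    organic = if (is.null(organic)) rep(FALSE, n) else organic,
    system_label = if (is.null(system_label)) rep("conventional", n)
                   else system_label), is_fish = is_fish)
}

# product with given ingredient names / declared percents / categories
make_product <- function(id, names, declared = rep(NA_real_, length(names)),
                         categories = rep(NA_character_, length(names)),
                         ref = rep(1, length(names)), ...) {
  ings <- lapply(seq_along(names), function(i) {
    ingredient_entry(names[i], i, declared_percent = declared[i],
                     category_id = categories[i],
                     raw_equivalent_factor = ref[i])
  })
  product_record(id, ings, ...)
}

# identity estimate for a product whose composition is fully known
identity_estimate <- function(product) infer_composition(product, prior = NULL)
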