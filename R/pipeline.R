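#' Read a run configuration from YAML
#'
#' Recognized keys: `products`, `envdb`, `lexicon`, `lexicon_fallbacks`,
#' `output_dir`, `n_iter`, `seed`, `coverage_threshold`,
#' `nutriscore_thresholds`, `max_combos`, `n_mask`.
#'
#' @param path YAML file path.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(n_iter = 1000L, seed = 1L, coverage_threshold = 0.75,
                   max_combos = 100L)
  modifyList(defaults, cfg)
}

#' Score a product corpus end to end
#'
#' Maps ingredients to food categories, builds the composition prior from
#' the corpus's own declared percentages, infers every composition, runs
#' the Monte-Carlo impact analysis, condenses the indicators into the
#' composite 0-100 score, computes NutriScore, and estimates per-serving
#' impacts.  Products whose category coverage falls below the threshold
#' are emitted with `presented = FALSE` and no impact values rather than
#' being dropped.
#'
#' @param products List of [product_record()] objects, or a path readable
#'   by [read_products()].
#' @param db An [env_database()], or a path readable by [read_env_db()].
#' @param lex A [lexicon()], default the shipped starter lexicon.
#' @param n_iter Monte-Carlo iterations per product, default 1000.
#' @param seed Integer seed, default 1.
#' @param coverage_threshold Coverage gate, default 0.75 (inclusive).
#' @param reference Optional frozen composite-score reference.
#' @param thresholds NutriScore threshold resource.
#' @return `data.frame` with one row per product (composition coverage,
#'   per-indicator mean/sd/quantiles, composite score, NutriScore fields,
#'   serving size and per-serving score); the composite reference is
#'   attached as attribute `"reference"` and per-product compositions as
#'   attribute `"estimates"`.
#' @export
run_score <- function(products, db, lex = default_lexicon(), n_iter = 1000,
                      seed = 1, coverage_threshold = 0.75, reference = NULL,
                      thresholds = ns_thresholds()) {
  if (is.character(products)) products <- read_products(products)
  if (is.character(db)) db <- read_env_db(db)
  if (!length(products)) {
    warning("empty corpus; returning empty results")
    return(data.frame())
  }
  products <- map_products(products, lex)
  prior <- build_prior_table(products)
  scorable <- vapply(products, is_scorable, logical(1))
  message("scoring ", sum(scorable), " of ", length(products),
          " products (", nrow(prior$cells), " declared priors)")
  estimates <- vector("list", length(products))
  mcs <- vector("list", length(products))
  rows <- vector("list", length(products))
  for (j in seq_along(products)) {
    p <- products[[j]]
    if (!scorable[j]) {
      rows[[j]] <- data.frame(product_id = p$product_id, n_ingredients = 0L,
                              coverage = NA_real_, presented = FALSE)
      next
    }
    est <- infer_composition(p, prior)
    estimates[[j]] <- est
    presented <- coverage_gate(est, coverage_threshold)
    row <- data.frame(product_id = p$product_id,
                      n_ingredients = length(p$ingredients),
                      coverage = est$coverage, presented = presented)
    if (presented) {
      mc <- monte_carlo(est, p, db, n_iter = n_iter, seed = seed + j)
      mcs[[j]] <- mc
      s <- mc$summary
      for (i in seq_len(nrow(s))) {
        ind <- s$indicator[i]
        row[[paste0(ind, "_mean")]] <- s$mean[i]
        row[[paste0(ind, "_sd")]] <- s$sd[i]
        row[[paste0(ind, "_q05")]] <- s$q05[i]
        row[[paste0(ind, "_q50")]] <- s$q50[i]
        row[[paste0(ind, "_q95")]] <- s$q95[i]
      }
    }
    rows[[j]] <- row
  }
  res <- do.call(rbind, c(lapply(rows, function(r) {
    # pad rows lacking impact columns
    all_cols <- unique(unlist(lapply(rows, names)))
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })))
  pres <- which(res$presented %in% TRUE)
  res$composite <- NA_real_
  if (length(pres)) {
    means <- data.frame(product_id = res$product_id[pres],
                        ghg = res$ghg_mean[pres], land = res$land_mean[pres],
                        water = res$water_mean[pres],
                        eutro = res$eutro_mean[pres])
    cs <- composite_score(means, reference)
    res$composite[pres] <- cs$composite
    reference <- attr(cs, "reference")
  }
  res$nutri_letter <- NA_character_
  res$nutri_numeric <- NA_integer_
  res$nutri_scaled <- NA_real_
  for (j in seq_along(products)) {
    p <- products[[j]]
    if (is.null(p$nutrition) || p$is_alcoholic) next
    ns <- nutri_score(p, thresholds = thresholds)
    i <- match(p$product_id, res$product_id)
    res$nutri_letter[i] <- ns$letter
    res$nutri_numeric[i] <- ns$numeric
    res$nutri_scaled[i] <- ns$scaled
  }
  res$serving_size_g <- vapply(products, estimate_serving_size, numeric(1),
                               corpus = products)
  res$composite_per_serving <- per_serving(res$composite, res$serving_size_g)
  message(sum(res$presented %in% TRUE), " products presented (coverage >= ",
          coverage_threshold, "), ",
          sum(!(res$presented %in% TRUE)), " withheld")
  attr(res, "reference") <- reference
  attr(res, "estimates") <- estimates
  rownames(res) <- NULL
  res
}

#' Run the masking-based accuracy validation
#'
#' Selects the validation set (products with fully known composition),
#' computes each product's known impact score, freezes the composite
#' reference on those known scores, then masks random subsets of `n_mask`
#' declared percentages per product, re-estimates, and summarizes
#' accuracy overall and per masking level.
#'
#' @param products List of [product_record()] objects (mapped or not).
#' @param db An [env_database()].
#' @param lex A [lexicon()].
#' @param n_mask_grid Masking levels; integers and/or `Inf` meaning "all
#'   ingredients".  Default `c(2, Inf)`.  Levels exceeding a product's
#'   ingredient count are skipped for that product.
#' @param max_combos Maximum combinations per product and level.
#' @param n_iter Monte-Carlo iterations per trial.
#' @param seed Integer seed.
#' @return List with `trials` (one row per masking trial), `pooled`
#'   ([summarize_accuracy()] over all trials), `by_n_mask` (list of
#'   summaries keyed by level) and `reference`.
#' @export
run_validate <- function(products, db, lex = default_lexicon(),
                         n_mask_grid = c(2, Inf), max_combos = 100,
                         n_iter = 1000, seed = 1) {
  if (is.character(products)) products <- read_products(products)
  if (is.character(db)) db <- read_env_db(db)
  products <- map_products(products, lex)
  prior <- build_prior_table(products)
  vset <- select_validation_set(products)
  if (!length(vset))
    stop("validation set is empty: no product has all (or all but one) ",
         "ingredient percentages declared and summing to 100")
  message("validation set: ", length(vset), " of ", length(products),
          " products")
  known_means <- t(vapply(seq_along(vset), function(j) {
    p <- vset[[j]]
    est <- infer_composition(p, prior = NULL)
    mean_impacts(monte_carlo(est, p, db, n_iter = n_iter, seed = seed + j))
  }, numeric(4)))
  colnames(known_means) <- INDICATORS
  cs <- composite_score(as.data.frame(known_means))
  reference <- attr(cs, "reference")
  trials <- list()
  for (j in seq_along(vset)) {
    p <- vset[[j]]
    n <- length(p$ingredients)
    levels <- unique(vapply(n_mask_grid, function(m) {
      if (is.infinite(m)) n else as.integer(m)
    }, integer(1)))
    levels <- levels[levels >= 2 & levels <= n]
    for (m in levels) {
      trials[[length(trials) + 1L]] <-
        mask_and_estimate(p, m, prior, db, reference,
                          max_combos = max_combos, n_iter = n_iter,
                          seed = seed + j)
    }
  }
  trials <- do.call(rbind, trials)
  if (is.null(trials) || nrow(trials) == 0L)
    stop("no masking trials produced; check n_mask_grid against the corpus")
  by_level <- lapply(split(trials, trials$n_mask), summarize_accuracy)
  list(trials = trials, pooled = summarize_accuracy(trials),
       by_n_mask = by_level, reference = reference)
}
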