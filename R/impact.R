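INDICATORS <- c("ghg", "land", "water", "eutro")

# observation pool for one ingredient draw: organic ingredients use the
# organic production subset only when the category has at least five
# organic observations; otherwise all systems are used.
observation_pool <- function(category, organic) {
  obs <- category$observations
  if (isTRUE(organic) && sum(obs$organic) >= 5L)
    obs <- obs[obs$organic, , drop = FALSE]
  obs
}

#' Draw one production observation for an ingredient
#'
#' Observations are drawn with probability proportional to their
#' production-share weight.  For fish categories the production system is
#' first chosen between aquaculture and capture with probability 1/2 each
#' (the assumed 50:50 split between farmed and wild-caught fish), then an
#' observation is drawn within that system.  Organic ingredients draw
#' from the organic subset when the category has at least five organic
#' observations, and from all systems otherwise.  Uses the current RNG
#' state; seed with [set.seed()] for reproducibility.
#'
#' @param category A [food_category()].
#' @param organic Logical, ingredient labeled organic.
#' @return One-row `data.frame` with the four intensities and metadata.
#' @export
sample_observation <- function(category, organic = FALSE) {
  obs <- observation_pool(category, organic)
  if (category$is_fish) {
    label <- if (runif(1) < 0.5) "aquaculture" else "capture"
    sub <- obs[obs$system_label == label, , drop = FALSE]
    if (nrow(sub)) obs <- sub
  }
  idx <- if (nrow(obs) == 1L) 1L
         else sample.int(nrow(obs), 1L, prob = obs$weight)
  obs[idx, , drop = FALSE]
}

# vectorized n-draw version of sample_observation; consumes RNG in a
# fixed order per ingredient so that masked/unmasked runs under a shared
# seed see identical draws (common random numbers).
draw_intensities <- function(category, organic, n) {
  obs <- observation_pool(category, organic)
  if (category$is_fish) {
    aqua <- which(obs$system_label == "aquaculture")
    capt <- which(obs$system_label == "capture")
    pick_aqua <- runif(n) < 0.5
    draw_in <- function(rows) {
      if (!length(rows)) rows <- seq_len(nrow(obs))
      if (length(rows) == 1L) rep.int(rows, n)
      else sample(rows, n, replace = TRUE, prob = obs$weight[rows])
    }
    ia <- draw_in(aqua); ic <- draw_in(capt)
    idx <- ifelse(pick_aqua, ia, ic)
  } else {
    idx <- if (nrow(obs) == 1L) rep.int(1L, n)
           else sample.int(nrow(obs), n, replace = TRUE, prob = obs$weight)
  }
  as.matrix(obs[idx, INDICATORS])
}

#' Single Monte-Carlo draw of a product's per-100 g impacts
#'
#' Each mapped ingredient contributes
#' `(percent/100) * raw_equivalent_factor * intensity * 0.1`, converting
#' per-kg commodity intensities to impacts per 100 g of product; unmapped
#' ingredients contribute zero.
#'
#' @param estimate A [infer_composition()] result.
#' @param product The corresponding [product_record()].
#' @param db An [env_database()].
#' @return Named numeric vector (`ghg`, `land`, `water`, `eutro`) per
#'   100 g of product.
#' @export
impact_once <- function(estimate, product, db) {
  out <- setNames(numeric(4), INDICATORS)
  for (i in seq_along(product$ingredients)) {
    ig <- product$ingredients[[i]]
    if (is.na(ig$category_id)) next
    category <- db[[ig$category_id]]
    if (is.null(category)) next
    obs <- sample_observation(category, ig$organic)
    out <- out + (estimate$percents[i] / 100) *
      estimate$raw_equivalent_factor[i] * 0.1 *
      unlist(obs[1, INDICATORS])
  }
  out
}

#' Monte-Carlo distribution of a product's per-100 g impacts
#'
#' Repeatedly pairs the estimated composition with randomly selected
#' production observations to propagate sourcing uncertainty, and
#' summarizes each indicator by its mean, SD and the 5th, 10th, 25th,
#' 50th, 75th, 90th and 95th percentiles.
#'
#' @param estimate A [infer_composition()] result.
#' @param product The corresponding [product_record()].
#' @param db An [env_database()].
#' @param n_iter Number of Monte-Carlo iterations (>= 1), default 1000.
#' @param seed Optional integer seed; identical seeds give identical
#'   distributions.
#' @return An object of class `impact_distribution`: `summary` data frame
#'   (one row per indicator), `n_iterations`, `seed`.
#' @export
monte_carlo <- function(estimate, product, db, n_iter = 1000, seed = NULL) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  total <- matrix(0, n_iter, 4, dimnames = list(NULL, INDICATORS))
  for (i in seq_along(product$ingredients)) {
    ig <- product$ingredients[[i]]
    if (is.na(ig$category_id)) next
    category <- db[[ig$category_id]]
    if (is.null(category)) next
    draws <- draw_intensities(category, ig$organic, n_iter)
    total <- total + (estimate$percents[i] / 100) *
      estimate$raw_equivalent_factor[i] * 0.1 * draws
  }
  probs <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)
  qs <- t(apply(total, 2, quantile, probs = probs, names = FALSE))
  colnames(qs) <- sprintf("q%02d", probs * 100)
  summary <- data.frame(indicator = INDICATORS,
                        mean = colMeans(total),
                        sd = apply(total, 2, sd),
                        qs, row.names = NULL)
  structure(list(product_id = product$product_id, summary = summary,
                 n_iterations = n_iter, seed = seed),
            class = "impact_distribution")
}

#' @export
print.impact_distribution <- function(x, ...) {
  cat("<impact_distribution>", x$product_id, "-", x$n_iterations,
      "iterations\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Mean impacts of a Monte-Carlo distribution
#' @param dist An [monte_carlo()] result.
#' @return Named numeric vector over the four indicators.
#' @export
mean_impacts <- function(dist) {
  setNames(dist$summary$mean, dist$summary$indicator)
}

#' Composite 0-100 environmental impact score
#'
#' Condenses the four indicators into a single linear index with equal
#' weights: each indicator is scaled so that the corpus-maximum product
#' scores 100 (a product with half the impact scores 50), the four scaled
#' scores are averaged, and the average is rescaled so the corpus maximum
#' is 100.  Scores are therefore only comparable within one scored corpus;
#' the reference maxima are attached to the result (and can be passed
#' back via `reference`) so new products can be scored against a frozen
#' reference.
#'
#' @param means `data.frame` or matrix of per-product mean impacts with
#'   columns `ghg`, `land`, `water`, `eutro` (and optionally
#'   `product_id`).
#' @param reference Optional reference list (fields `indicator_max`,
#'   `mean_scaled_max`) from a previous call.
#' @return `data.frame` with per-indicator scaled components and the
#'   `composite` score; the reference is attached as attribute
#'   `"reference"`.
#' @export
composite_score <- function(means, reference = NULL) {
  df <- as.data.frame(means)
  m <- as.matrix(df[, INDICATORS])
  if (nrow(m) == 0L) stop("no products to score")
  if (is.null(reference)) {
    maxima <- apply(m, 2, max)
    if (any(maxima == 0)) {
      warning("indicator(s) with all-zero impacts across the corpus: ",
              paste(INDICATORS[maxima == 0], collapse = ", "),
              "; their scaled component is set to 0")
    }
    reference <- list(indicator_max = maxima, mean_scaled_max = NA_real_)
  }
  maxima <- reference$indicator_max
  scaled <- sweep(m, 2, ifelse(maxima > 0, maxima, Inf), "/") * 100
  raw <- rowMeans(scaled)
  if (is.na(reference$mean_scaled_max))
    reference$mean_scaled_max <- max(raw)
  composite <- if (reference$mean_scaled_max > 0)
    100 * raw / reference$mean_scaled_max else raw * 0
  out <- data.frame(scaled, composite = composite)
  names(out)[1:4] <- paste0("scaled_", INDICATORS)
  if ("product_id" %in% names(df))
    out <- cbind(product_id = df$product_id, out)
  attr(out, "reference") <- reference
  out
}

#' Composite score of one product against a frozen reference
#' @param means Named vector of mean impacts (`ghg`, `land`, `water`,
#'   `eutro`).
#' @param reference Reference list from [composite_score()].
#' @return Numeric composite score.
#' @export
composite_from_reference <- function(means, reference) {
  maxima <- reference$indicator_max
  scaled <- 100 * means[INDICATORS] / ifelse(maxima > 0, maxima, Inf)
  if (reference$mean_scaled_max > 0)
    100 * mean(scaled) / reference$mean_scaled_max else 0
}

#' Estimate a product's serving size
#'
#' Uses the product's own declared serving size when present; otherwise
#' the average serving size of products categorized to the same Shelf
#' (the mean of the per-Shelf means when the product sits on several
#' Shelves); otherwise the same at Aisle level; otherwise `NA`.
#'
#' @param product A [product_record()].
#' @param corpus List of [product_record()] objects to borrow from.
#' @return Serving size in grams, or `NA`.
#' @export
estimate_serving_size <- function(product, corpus) {
  if (!is.na(product$serving_size_g)) return(product$serving_size_g)
  level_mean <- function(field) {
    labels <- product[[field]]
    if (!length(labels)) return(NA_real_)
    per_label <- vapply(labels, function(lab) {
      sizes <- vapply(corpus, function(p) {
        if (p$product_id != product$product_id && lab %in% p[[field]])
          p$serving_size_g else NA_real_
      }, numeric(1))
      if (all(is.na(sizes))) NA_real_ else mean(sizes, na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(per_label))) NA_real_ else mean(per_label, na.rm = TRUE)
  }
  est <- level_mean("shelves")
  if (is.na(est)) est <- level_mean("aisles")
  est
}

#' Impact score per serving
#'
#' Linear conversion of a per-100 g score to the serving basis.
#' @param score_per_100g Numeric score(s) per 100 g.
#' @param serving_g Serving size(s) in grams.
#' @return Numeric score per serving (`NA` when the serving is unknown).
#' @export
per_serving <- function(score_per_100g, serving_g) {
  score_per_100g * serving_g / 100
}
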