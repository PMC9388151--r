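#' Select the validation set for the masking accuracy test
#'
#' A product qualifies when (i) the percent composition of all or all but
#' one of its ingredients is declared, (ii) it contains more than one
#' ingredient, and (iii) the declared percentages sum to 100 (for the
#' all-but-one case the missing ingredient is filled with the residual
#' mass).  Returned products have fully declared compositions.
#'
#' @param corpus List of [product_record()] objects.
#' @param tol Tolerance on the sum-to-100 check, default 0.01.
#' @return List of completed [product_record()] objects.
#' @export
select_validation_set <- function(corpus, tol = 0.01) {
  out <- lapply(corpus, function(p) {
    n <- length(p$ingredients)
    if (n < 2L) return(NULL)
    d <- declared_percents(p)
    k <- sum(!is.na(d))
    s <- sum(d, na.rm = TRUE)
    if (k == n && abs(s - 100) <= tol) return(p)
    if (k == n - 1L) {
      resid <- 100 - s
      if (resid <= tol) return(NULL)
      i <- which(is.na(d))
      p$ingredients[[i]]$declared_percent <- resid
      return(p)
    }
    NULL
  })
  Filter(Negate(is.null), out)
}

sample_combinations <- function(n, k, max_combos) {
  total <- choose(n, k)
  if (total <= max_combos) {
    m <- combn(n, k)
    return(lapply(seq_len(ncol(m)), function(j) m[, j]))
  }
  seen <- character()
  combos <- list()
  tries <- 0L
  while (length(combos) < max_combos && tries < 100L * max_combos) {
    tries <- tries + 1L
    cc <- sort(sample.int(n, k))
    key <- paste(cc, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      combos[[length(combos) + 1L]] <- cc
    }
  }
  combos
}

#' Mask declared percentages and re-estimate a product's impact
#'
#' For up to `max_combos` randomly selected unique combinations of
#' `n_mask` ingredients, hides those ingredients' declared percentages
#' (retaining the ingredient order), re-infers the composition, reruns
#' the Monte-Carlo impact analysis under the same seed as the
#' known-composition run (common random numbers), and records one
#' masking trial comparing the estimated against the known impact score
#' as `log2(estimated / known)`.
#'
#' @param product A completed validation product (see
#'   [select_validation_set()]).
#' @param n_mask Number of ingredients to mask: 0 (control; one trial
#'   with nothing masked) or 2..n.
#' @param prior A [build_prior_table()] result used for re-estimation.
#' @param db An [env_database()].
#' @param reference Composite-score reference (see [composite_score()]).
#' @param max_combos Maximum number of combinations per product (default
#'   100).
#' @param n_iter Monte-Carlo iterations per trial.
#' @param seed Integer seed; drives combination sampling and both
#'   Monte-Carlo runs.
#' @return `data.frame` of masking trials.
#' @export
mask_and_estimate <- function(product, n_mask, prior, db, reference,
                              max_combos = 100, n_iter = 1000, seed = 1) {
  n <- length(product$ingredients)
  if (!(n_mask == 0 || (n_mask >= 2 && n_mask <= n)))
    stop("n_mask must be 0 or between 2 and the ingredient count (", n, ")")
  d <- declared_percents(product)
  if (anyNA(d))
    stop("product '", product$product_id,
         "' is not fully declared; complete it with select_validation_set()")
  known_est <- infer_composition(product, prior = NULL)
  known_mc <- monte_carlo(known_est, product, db, n_iter = n_iter, seed = seed)
  known_means <- mean_impacts(known_mc)
  known_score <- composite_from_reference(known_means, reference)
  set.seed(seed)
  combos <- if (n_mask == 0) list(integer()) else
    sample_combinations(n, n_mask, max_combos)
  rows <- lapply(seq_along(combos), function(j) {
    cc <- combos[[j]]
    masked <- product
    for (i in cc) masked$ingredients[[i]]$declared_percent <- NA_real_
    est <- infer_composition(masked, prior = prior)
    mc <- monte_carlo(est, masked, db, n_iter = n_iter, seed = seed)
    means <- mean_impacts(mc)
    score <- composite_from_reference(means, reference)
    data.frame(product_id = product$product_id, n_ingredients = n,
               n_mask = n_mask, combo = j,
               masked_ranks = paste(cc, collapse = ","),
               percent_known = sum(d[setdiff(seq_len(n), cc)]),
               known_ghg = known_means[["ghg"]], est_ghg = means[["ghg"]],
               known_land = known_means[["land"]], est_land = means[["land"]],
               known_water = known_means[["water"]], est_water = means[["water"]],
               known_eutro = known_means[["eutro"]], est_eutro = means[["eutro"]],
               known_score = known_score, estimated_score = score,
               log_ratio = log2(score / known_score),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize masking-trial accuracy
#'
#' Accuracy per trial is the percent difference
#' `(estimated - known) / known * 100`; mischaracterization fractions are
#' computed on the ratio `estimated / known`: outside \[2/3, 3/2\] and
#' outside \[1/2, 2\].  Trials with a zero known score are excluded with
#' a warning.  The CI is `mean +/- 1.96 SE`.
#'
#' @param trials Trial table from [mask_and_estimate()].
#' @return An object of class `accuracy_summary`.
#' @export
summarize_accuracy <- function(trials) {
  if (NROW(trials) == 0L) stop("no trials to summarize")
  bad <- trials$known_score <= 0
  if (any(bad)) {
    warning(sum(bad), " trial(s) with zero known score excluded")
    trials <- trials[!bad, , drop = FALSE]
  }
  ratio <- trials$estimated_score / trials$known_score
  pct <- (trials$estimated_score - trials$known_score) / trials$known_score * 100
  se <- sd(pct) / sqrt(length(pct))
  frac <- function(x) mean(x)
  per_ind <- lapply(INDICATORS, function(ind) {
    k <- trials[[paste0("known_", ind)]]
    e <- trials[[paste0("est_", ind)]]
    ok <- k > 0
    r <- e[ok] / k[ok]
    c(within_10pct = frac(abs(r - 1) <= 0.10),
      within_25pct = frac(abs(r - 1) <= 0.25))
  })
  names(per_ind) <- INDICATORS
  structure(list(
    n_trials = nrow(trials),
    mean_percent_diff = mean(pct),
    ci_lower = mean(pct) - 1.96 * se,
    ci_upper = mean(pct) + 1.96 * se,
    fraction_within_10pct = frac(abs(ratio - 1) <= 0.10),
    fraction_within_25pct = frac(abs(ratio - 1) <= 0.25),
    fraction_outside_two_thirds_three_halves = frac(ratio < 2/3 | ratio > 3/2),
    fraction_outside_half_double = frac(ratio < 1/2 | ratio > 2),
    mean_abs_log_ratio = mean(abs(log2(ratio))),
    per_indicator = per_ind), class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat("<accuracy_summary>", x$n_trials, "trials\n")
  cat(sprintf("  mean %% diff: %.2f%% (95%% CI %.2f to %.2f)\n",
              x$mean_percent_diff, x$ci_lower, x$ci_upper))
  cat(sprintf("  within 10%%: %.1f%%; within 25%%: %.1f%%\n",
              100 * x$fraction_within_10pct, 100 * x$fraction_within_25pct))
  cat(sprintf("  outside [2/3, 3/2]: %.1f%%; outside [1/2, 2]: %.1f%%\n",
              100 * x$fraction_outside_two_thirds_three_halves,
              100 * x$fraction_outside_half_double))
  invisible(x)
}

#' Aisle-level environment and nutrition profiles
#'
#' Aggregates per-product composite environmental scores and numeric
#' nutrition scores to retail-Aisle means with standard errors; products
#' categorized to several Aisles contribute to each of them.  The rank
#' correlation (Spearman) between the Aisle-mean environmental and
#' nutrition scores quantifies the tendency of more sustainable Aisles to
#' be more nutritious.
#'
#' @param products List of [product_record()] objects with Aisle labels.
#' @param env_scores `data.frame` with `product_id` and `composite`.
#' @param nutri_scores `data.frame` with `product_id` and `numeric`.
#' @return List with `aisles` (per-Aisle table: n, mean and SEM of both
#'   scores), `spearman_rho`, `p_value`.
#' @export
aisle_profiles <- function(products, env_scores, nutri_scores) {
  rows <- do.call(rbind, lapply(products, function(p) {
    if (!length(p$aisles)) return(NULL)
    e <- env_scores$composite[match(p$product_id, env_scores$product_id)]
    nn <- nutri_scores$numeric[match(p$product_id, nutri_scores$product_id)]
    if (is.na(e) || is.na(nn)) return(NULL)
    data.frame(aisle = p$aisles, env = e, nutri = nn,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) stop("no products with Aisle labels and scores")
  sem <- function(x) if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_
  agg <- do.call(rbind, lapply(split(rows, rows$aisle), function(g) {
    data.frame(aisle = g$aisle[1], n = nrow(g),
               env_mean = mean(g$env), env_sem = sem(g$env),
               nutri_mean = mean(g$nutri), nutri_sem = sem(g$nutri),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  if (nrow(agg) >= 3) {
    ct <- suppressWarnings(
      cor.test(agg$env_mean, agg$nutri_mean, method = "spearman",
               exact = FALSE))
    rho <- unname(ct$estimate); pv <- ct$p.value
  } else {
    rho <- suppressWarnings(cor(agg$env_mean, agg$nutri_mean,
                                method = "spearman"))
    pv <- NA_real_
  }
  list(aisles = agg, spearman_rho = rho, p_value = pv)
}
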