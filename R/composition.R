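#' Rank bucket used by the composition prior
#'
#' Ingredient list positions are bucketed 1, 2, 3, 4 and 5+ so that prior
#' cells stay populated down the sparse tail of long ingredient lists.
#' @param rank Integer rank(s).
#' @return Integer bucket(s) in 1..5.
#' @export
rank_bucket <- function(rank) pmin(as.integer(rank), 5L)

#' Build a composition prior from declared percentages
#'
#' Collects every declared (QUID) percentage in a mapped corpus into cells
#' keyed by (food category, rank bucket).  The cell statistic used at
#' inference time is the median, which is robust to the right skew of
#' declared compositions.  Marginals (per category pooled over buckets,
#' and per bucket pooled over categories) serve as fallbacks for empty
#' cells.
#'
#' @param corpus List of [product_record()] objects with mapped
#'   ingredients (see [map_products()]).
#' @return An object of class `prior_table`.
#' @export
build_prior_table <- function(corpus) {
  rows <- lapply(corpus, function(p) {
    keep <- Filter(function(ig) !is.na(ig$declared_percent) &&
                     !is.na(ig$category_id), p$ingredients)
    if (!length(keep)) return(NULL)
    data.frame(category_id = vapply(keep, `[[`, character(1), "category_id"),
               bucket = rank_bucket(vapply(keep, `[[`, integer(1), "rank")),
               percent = vapply(keep, `[[`, numeric(1), "declared_percent"),
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, rows)
  if (is.null(cells))
    cells <- data.frame(category_id = character(), bucket = integer(),
                        percent = numeric())
  cells <- cells[cells$percent > 0, , drop = FALSE]
  structure(list(cells = cells), class = "prior_table")
}

#' @export
print.prior_table <- function(x, ...) {
  cat("<prior_table>", nrow(x$cells), "declared observations,",
      length(unique(x$cells$category_id)), "categories\n")
  invisible(x)
}

#' Look up the prior estimate for one ingredient
#'
#' Fallback order: (category, rank bucket) cell median, then the category
#' marginal median, then the rank-bucket marginal median, then `NA` (the
#' caller falls back to the midpoint of the ingredient's feasible
#' interval).
#'
#' @param prior A [build_prior_table()] result (or `NULL`).
#' @param category_id Category id (may be `NA`).
#' @param rank Ingredient rank.
#' @return Median declared percent, or `NA`.
#' @export
prior_median <- function(prior, category_id, rank) {
  if (is.null(prior) || nrow(prior$cells) == 0L) return(NA_real_)
  b <- rank_bucket(rank)
  cells <- prior$cells
  if (!is.na(category_id)) {
    v <- cells$percent[cells$category_id == category_id & cells$bucket == b]
    if (length(v)) return(median(v))
    v <- cells$percent[cells$category_id == category_id]
    if (length(v)) return(median(v))
  }
  v <- cells$percent[cells$bucket == b]
  if (length(v)) return(median(v))
  NA_real_
}

# Adjacent declared pairs that invert the mass ordering.  UK rules let
# ingredients at <= 2% be listed in any order, so an inversion between two
# such declared values is accepted (the chain constraint is dropped
# there); any larger inversion makes the label infeasible.
declared_relaxations <- function(declared, tol = 1e-9) {
  n <- length(declared)
  relaxed <- rep(FALSE, n - 1L)
  if (n < 2L) return(relaxed)
  for (i in seq_len(n - 1L)) {
    d1 <- declared[i]; d2 <- declared[i + 1L]
    if (!is.na(d1) && !is.na(d2) && d1 + tol < d2) {
      if (d1 <= 2 + tol && d2 <= 2 + tol) relaxed[i] <- TRUE
      else stop("declared percentages invert the mass ordering at ranks ",
                i, "-", i + 1L, " (", d1, " < ", d2, ")")
    }
  }
  relaxed
}

#' Exact feasible bounds for each ingredient's percent
#'
#' Computes, for every ingredient, the exact minimum and maximum percent
#' attainable over the labeling polytope: percents are non-negative, sum
#' to 100, are non-increasing in rank, and declared values are fixed.
#' The ordering constraint is dropped between adjacent declared pairs
#' that are both at or below 2% (ingredients at <= 2% may be listed in any
#' order).  Bounds are computed exactly from the chain structure of the
#' polytope: each free ingredient's envelope from the nearest declared
#' values, tightened by the attainable-mass conditions (see the package
#' vignette for the construction).
#'
#' @param declared Numeric vector of declared percents by rank, `NA` where
#'   undeclared, after any QUID normalization (see [normalize_quid()]).
#'   A [product_record()] may be given instead.
#' @param total Total mass percent, default 100.
#' @return Matrix with columns `lo`, `hi` (percent), one row per
#'   ingredient; attribute `relaxed_pairs` marks accepted declared
#'   inversions.
#' @export
feasible_bounds <- function(declared, total = 100) {
  if (inherits(declared, "product_record"))
    declared <- normalize_quid(declared_percents(declared))$declared
  declared <- as.numeric(declared)
  n <- length(declared)
  if (n == 0L) stop("product has no ingredients")
  if (any(!is.na(declared) & declared < 0))
    stop("declared percentages must be positive")
  s <- sum(declared, na.rm = TRUE)
  if (s > total + 1e-9)
    stop("sum of declared percentages (", round(s, 4), ") exceeds ", total,
         "; apply QUID normalization first")
  relaxed <- declared_relaxations(declared)
  if (n == 1L) {
    if (!is.na(declared[1]) && abs(declared[1] - total) > 1e-9)
      stop("single-ingredient product must have 100% of mass; declared ",
           declared[1])
    out <- matrix(c(total, total), 1, 2,
                  dimnames = list(NULL, c("lo", "hi")))
    attr(out, "relaxed_pairs") <- relaxed
    return(out)
  }
  fixed <- !is.na(declared)
  free <- which(!fixed)
  lo <- hi <- declared            # fixed entries have degenerate bounds
  if (length(free) == 0L) {
    if (abs(s - total) > 1e-9)
      stop("all percentages declared but they sum to ", round(s, 4),
           ", not ", total)
  } else {
    b <- chain_bounds(declared, relaxed, total)
    lo[free] <- b$lo
    hi[free] <- b$hi
  }
  lo <- pmin(pmax(lo, 0), total)
  hi <- pmin(pmax(hi, 0), total)
  lo[abs(lo) < 1e-9] <- 0
  out <- cbind(lo = lo, hi = hi)
  attr(out, "relaxed_pairs") <- relaxed
  out
}

# Exact per-coordinate bounds over the chain polytope
# {x >= 0, sum(x) = total, non-increasing within chain segments, declared
# entries fixed}.  Segments are the maximal runs between relaxed links.
#
# Every free position i has an envelope [L0_i, U0_i] from the nearest
# declared values in its segment (L0_i = largest declared value after i,
# U0_i = smallest declared value before i, or 0 / +Inf at the segment
# ends).  A candidate value c at position j is attainable iff the minimal
# free mass compatible with it (predecessors in the segment pushed down
# to max(L0, c), everything else at L0) does not exceed the undeclared
# mass R, and the maximal compatible free mass (successors capped at c,
# everything else at U0) reaches R.  Both mass functions are monotone in
# c, so each bound is found by bisection; the all-L0 and all-U0 profiles
# are themselves valid monotone fillings, which makes the interval
# characterization exact.
chain_bounds <- function(declared, relaxed, total) {
  n <- length(declared)
  fixed <- !is.na(declared)
  free <- which(!fixed)
  seg <- cumsum(c(1L, as.integer(relaxed)))  # segment id per position
  L0 <- U0 <- numeric(n)
  for (i in seq_len(n)) {
    after <- declared[fixed & seg == seg[i] & seq_len(n) > i]
    before <- declared[fixed & seg == seg[i] & seq_len(n) < i]
    L0[i] <- if (length(after)) max(after) else 0
    U0[i] <- if (length(before)) min(before) else Inf
  }
  R <- total - sum(declared, na.rm = TRUE)
  if (sum(L0[free]) > R + 1e-9 || sum(pmin(U0[free], total)) < R - 1e-9)
    stop("declared percentages are infeasible under the labeling ",
         "constraints (ordering and sum-to-", total, ")")
  min_free_mass <- function(j, c) {
    others <- setdiff(free, j)
    pred <- others[seg[others] == seg[j] & others < j]
    c + sum(pmax(L0[pred], c)) + sum(L0[setdiff(others, pred)])
  }
  max_free_mass <- function(j, c) {
    others <- setdiff(free, j)
    succ <- others[seg[others] == seg[j] & others > j]
    c + sum(pmin(U0[succ], c)) + sum(pmin(U0[setdiff(others, succ)], total))
  }
  bisect <- function(lower, upper, ok, want_max) {
    # largest (want_max) or smallest c in [lower, upper] with ok(c) TRUE;
    # ok is monotone (TRUE below / above a threshold respectively)
    if (ok(if (want_max) upper else lower))
      return(if (want_max) upper else lower)
    for (it in 1:80) {
      mid <- (lower + upper) / 2
      hit <- ok(mid)
      if (want_max) { if (hit) lower <- mid else upper <- mid }
      else          { if (hit) upper <- mid else lower <- mid }
    }
    if (want_max) lower else upper
  }
  lo <- hi <- numeric(length(free))
  for (k in seq_along(free)) {
    j <- free[k]
    top <- min(U0[j], total)
    hi[k] <- bisect(L0[j], top, function(c) min_free_mass(j, c) <= R + 1e-12,
                    want_max = TRUE)
    lo[k] <- bisect(L0[j], hi[k],
                    function(c) max_free_mass(j, c) >= R - 1e-12,
                    want_max = FALSE)
  }
  list(lo = lo, hi = hi)
}

#' Normalize QUID declarations exceeding 100%
#'
#' Dried or concentrated ingredients may legally declare more than 100 g
#' of raw commodity per 100 g of final product.  When the declared sum
#' exceeds 100, all declared values are rescaled to sum to 100 and the
#' excess is carried as a raw-equivalent factor (declared / normalized)
#' so that impact scoring still accounts for the full raw commodity mass.
#'
#' @param declared Numeric vector of declared percents (NA where
#'   undeclared).
#' @return List with `declared` (normalized), `raw_factor` (per-ingredient
#'   multiplier, 1 where untouched) and `note` (`NULL` or a description).
#' @export
normalize_quid <- function(declared) {
  raw_factor <- rep(1, length(declared))
  note <- NULL
  s <- sum(declared, na.rm = TRUE)
  if (s > 100 + 1e-9) {
    scale <- 100 / s
    idx <- !is.na(declared)
    raw_factor[idx] <- 1 / scale
    declared[idx] <- declared[idx] * scale
    note <- sprintf("quid_normalized: declared sum %.4g rescaled to 100", s)
  }
  list(declared = declared, raw_factor = raw_factor, note = note)
}

# weighted pool-adjacent-violators fit, non-increasing
pava_nonincreasing <- function(y, w) {
  n <- length(y)
  if (n <= 1L) return(y)
  # fit non-decreasing to reversed series, then reverse back
  yr <- rev(y); wr <- rev(w)
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- yr[i]; wt[top] <- wr[i]; len[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      wsum <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (val[top - 1L] * wt[top - 1L] + val[top] * wt[top]) / wsum
      wt[top - 1L] <- wsum
      len[top - 1L] <- len[top - 1L] + len[top]
      top <- top - 1L
    }
  }
  rev(rep(val[seq_len(top)], len[seq_len(top)]))
}

# project onto the ordering constraints, keeping fixed entries exact and
# splitting the chain at accepted declared inversions
pava_project <- function(p, fixed, declared, relaxed) {
  n <- length(p)
  if (n <= 1L) return(p)
  cut <- c(0L, which(relaxed), n)
  w <- ifelse(fixed, 1e9, 1)
  for (k in seq_len(length(cut) - 1L)) {
    idx <- (cut[k] + 1L):cut[k + 1L]
    if (length(idx) > 1L) p[idx] <- pava_nonincreasing(p[idx], w[idx])
  }
  p[fixed] <- declared[fixed]
  p
}

# distribute a mass residual over free entries within their bounds
spread_residual <- function(p, free, lo, hi, target, max_rounds = 50L) {
  for (r in seq_len(max_rounds)) {
    resid <- target - sum(p)
    if (abs(resid) < 1e-9) break
    if (resid > 0) {
      cap <- pmax(hi[free] - p[free], 0)
      tot <- sum(cap)
      if (tot <= 0) break
      p[free] <- p[free] + cap * min(1, resid / tot)
    } else {
      cap <- pmax(p[free] - lo[free], 0)
      tot <- sum(cap)
      if (tot <= 0) break
      p[free] <- p[free] - cap * min(1, -resid / tot)
    }
  }
  p
}

#' Infer the percent composition of a product
#'
#' Implements the composition-inference step: declared (QUID) percentages
#' are taken as ground truth; every undeclared ingredient is initialized
#' from the most specific non-empty prior cell (category x rank bucket,
#' then category marginal, then rank-bucket marginal, then the midpoint of
#' its feasible interval) and the vector is then repeatedly (a) rescaled
#' so the unknowns absorb the undeclared mass, (b) projected onto the
#' non-increasing order constraint by pool-adjacent-violators with
#' declared entries held fixed, and (c) clipped to the exact feasible
#' bounds, until the composition stabilizes.  The procedure is
#' deterministic (no randomness).
#'
#' @param product A [product_record()] with mapped ingredients.
#' @param prior A [build_prior_table()] result, or `NULL` for no prior.
#' @param config Optional list: `tol` (convergence tolerance on mass
#'   change, default `1e-6`), `max_iter` (default 100).
#' @return An object of class `composition_estimate` with fields
#'   `percents` (by rank, summing to 100), `coverage` (fraction of mass in
#'   mapped categories), `raw_equivalent_factor`, `feasible`, `notes`.
#' @export
infer_composition <- function(product, prior = NULL, config = list()) {
  cfg <- modifyList(list(tol = 1e-6, max_iter = 100L), config)
  ings <- product$ingredients
  n <- length(ings)
  if (n == 0L) stop("product '", product$product_id, "' has no ingredients")
  notes <- character()
  declared_raw <- declared_percents(product)
  quid <- normalize_quid(declared_raw)
  declared <- quid$declared
  if (!is.null(quid$note)) notes <- c(notes, quid$note)
  ref <- vapply(ings, `[[`, numeric(1), "raw_equivalent_factor") * quid$raw_factor
  bounds <- feasible_bounds(declared)
  relaxed <- attr(bounds, "relaxed_pairs")
  if (any(relaxed))
    notes <- c(notes, paste0("declared order inversion accepted at pair(s) ",
                             paste(which(relaxed), collapse = ",")))
  fixed <- !is.na(declared)
  lo <- bounds[, "lo"]; hi <- bounds[, "hi"]
  if (all(fixed)) {
    p <- declared
  } else {
    cats <- vapply(ings, `[[`, character(1), "category_id")
    ranks <- vapply(ings, `[[`, integer(1), "rank")
    p <- declared
    for (i in which(!fixed)) {
      v <- prior_median(prior, cats[i], ranks[i])
      if (is.na(v)) v <- (lo[i] + hi[i]) / 2
      p[i] <- min(max(v, lo[i]), hi[i])
    }
    free <- which(!fixed)
    rem <- 100 - sum(declared[fixed])
    for (iter in seq_len(cfg$max_iter)) {
      old <- p
      s <- sum(p[free])
      p[free] <- if (s > 0) p[free] * rem / s else rem / length(free)
      p <- pava_project(p, fixed, declared, relaxed)
      p[free] <- pmin(pmax(p[free], lo[free]), hi[free])
      if (max(abs(p - old)) < cfg$tol) break
    }
    p <- spread_residual(p, free, lo, hi, target = 100)
  }
  if (abs(sum(p) - 100) > 1e-6)
    notes <- c(notes, sprintf("residual mass %.3g%% unassigned", 100 - sum(p)))
  mapped <- !is.na(vapply(ings, `[[`, character(1), "category_id"))
  structure(list(product_id = product$product_id,
                 percents = unname(p),
                 declared = declared_raw,
                 raw_equivalent_factor = unname(ref),
                 mapped = mapped,
                 coverage = min(1, max(0, sum(p[mapped]) / 100)),
                 feasible = TRUE,
                 notes = notes),
            class = "composition_estimate")
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat("<composition_estimate>", x$product_id, "-",
      paste(sprintf("%.1f", x$percents), collapse = "/"),
      sprintf("(coverage %.0f%%)", 100 * x$coverage), "\n")
  invisible(x)
}

#' Coverage gate for presenting estimates
#'
#' Estimates are only presented when at least 75% (by default) of the
#' product's estimated mass was sorted into a food category, to avoid
#' skewing results with poorly characterized products.  The threshold is
#' inclusive.
#'
#' @param estimate A [infer_composition()] result.
#' @param threshold Coverage fraction in \[0, 1\], default 0.75.
#' @return Logical.
#' @export
coverage_gate <- function(estimate, threshold = 0.75) {
  isTRUE(estimate$coverage >= threshold)
}
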