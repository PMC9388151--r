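test_that("prior table cells and marginals use the median statistic", {
  mk <- function(id, d) make_product(id, c("tomatoes", "water"),
                                     declared = c(d, NA),
                                     categories = c("tomatoes", "water"))
  prior <- build_prior_table(list(mk("p1", 80), mk("p2", 60)))
  expect_equal(nrow(prior$cells), 2)
  expect_equal(prior_median(prior, "tomatoes", 1), 70)  # median of 80, 60
  # fallback chain: category marginal, then rank-bucket marginal, then NA
  expect_equal(prior_median(prior, "tomatoes", 3), 70)
  expect_equal(prior_median(prior, "beef", 1), 70)
  empty <- build_prior_table(list(make_product("q", c("a", "b"))))
  expect_equal(nrow(empty$cells), 0)
  expect_true(is.na(prior_median(empty, "tomatoes", 1)))
})

test_that("feasible bounds match hand-derived values", {
  b <- feasible_bounds(rep(NA_real_, 4))
  expect_equal(b[1, ], c(lo = 25, hi = 100))
  expect_equal(b[4, ], c(lo = 0, hi = 25))
  # declared rank-2 at 30: p1 + p3 = 70 with p1 >= 30 >= p3 forces p1 >= 40
  b2 <- feasible_bounds(c(NA, 30, NA))
  expect_equal(b2[1, ], c(lo = 40, hi = 70))
  expect_equal(b2[2, ], c(lo = 30, hi = 30))
  expect_equal(b2[3, ], c(lo = 0, hi = 30))
  expect_error(feasible_bounds(c(40, NA)), "infeasible")
  expect_error(feasible_bounds(c(NA, 60, NA, 50)), "exceeds")
})

test_that("feasible bounds agree with the brute-force grid oracle", {
  cases <- list(rep(NA_real_, 2), rep(NA_real_, 3), rep(NA_real_, 4),
                c(NA, 30, NA), c(50, NA, NA), c(NA, NA, 10),
                c(NA, 25, NA, NA), c(NA, NA, 20, NA), c(40, NA, 15, NA),
                c(NA, 30, NA, 5))
  for (d in cases) {
    lp <- feasible_bounds(d)
    gr <- grid_bounds(d, step = 0.1)
    expect_equal(unname(lp), unname(gr), tolerance = 0.2, ignore_attr = TRUE,
                 info = paste("declared:", paste(d, collapse = ",")))
  }
})

test_that("inference reproduces declared values and frozen policy cases", {
  # identity: fully declared composition is returned unchanged
  p <- make_product("id", c("a", "b", "c"), declared = c(60, 30, 10))
  est <- infer_composition(p)
  expect_equal(est$percents, c(60, 30, 10))
  # single ingredient
  expect_equal(infer_composition(make_product("s", "water"))$percents, 100)
  # no declarations, empty prior: midpoints of the feasible intervals
  # (66.67, 25, 16.67) rescaled to the full mass
  est3 <- infer_composition(make_product("u", c("a", "b", "c")))
  expect_equal(est3$percents, c(800, 300, 200) / 13, tolerance = 1e-6)
  # declared rank-2 at 30: midpoints (55, -, 15) already absorb the
  # remaining 70
  est4 <- infer_composition(make_product("v", c("a", "b", "c"),
                                         declared = c(NA, 30, NA)))
  expect_equal(est4$percents, c(55, 30, 15), tolerance = 1e-6)
})

test_that("inference respects bounds, mass balance and ordering on random products", {
  set.seed(42)
  lex <- default_lexicon()
  cfg <- synthetic_config(n_products = 60, declared_fraction = 0.3, seed = 17)
  corpus <- map_products(generate_products(cfg, generate_env_db(cfg))$products)
  prior <- build_prior_table(corpus)
  for (p in corpus) {
    d <- normalize_quid(declared_percents(p))$declared
    b <- feasible_bounds(d)
    est <- infer_composition(p, prior)
    expect_equal(sum(est$percents), 100, tolerance = 1e-6)
    expect_true(all(est$percents >= b[, "lo"] - 1e-6))
    expect_true(all(est$percents <= b[, "hi"] + 1e-6))
    # declared values reproduced exactly (no QUID excess in this corpus)
    keep <- !is.na(d)
    expect_equal(est$percents[keep], d[keep])
    # monotone wherever no declared pair violates order
    relaxed <- attr(b, "relaxed_pairs")
    diffs <- diff(est$percents)
    expect_true(all(diffs[!relaxed] <= 1e-6))
  }
})

test_that("declaring an ingredient never widens another's feasible interval", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    d <- rep(NA_real_, n)
    # possibly pre-declare one ingredient at a feasible value
    if (runif(1) < 0.5) {
      i <- sample(n, 1)
      b0 <- feasible_bounds(d)
      d[i] <- (b0[i, "lo"] + b0[i, "hi"]) / 2
    }
    b1 <- feasible_bounds(d)
    j <- sample(which(is.na(d)), 1)
    d2 <- d
    d2[j] <- (b1[j, "lo"] + b1[j, "hi"]) / 2
    b2 <- feasible_bounds(d2)
    w1 <- b1[, "hi"] - b1[, "lo"]
    w2 <- b2[, "hi"] - b2[, "lo"]
    expect_true(all(w2 <= w1 + 1e-6))
  }
})

test_that("QUID declarations above 100 are normalized with raw factors", {
  p <- make_product("biltong", c("beef", "salt"), declared = c(150, NA))
  est <- infer_composition(p)
  expect_equal(sum(est$percents), 100, tolerance = 1e-6)
  expect_equal(est$percents[1], 100, tolerance = 1e-6)
  expect_equal(est$raw_equivalent_factor[1], 1.5, tolerance = 1e-9)
  expect_match(paste(est$notes, collapse = " "), "quid")
})

test_that("small declared inversions are accepted, larger ones rejected", {
  # both at or below 2%: legal any-order listing
  p <- make_product("ok", c("a", "b", "c", "d"),
                    declared = c(NA, NA, 1, 2))
  est <- infer_composition(p)
  expect_equal(est$percents[3:4], c(1, 2))
  expect_match(paste(est$notes, collapse = " "), "inversion")
  expect_error(feasible_bounds(c(NA, 10, 20, NA)), "invert")
})

test_that("coverage reflects mapped mass and the gate is inclusive", {
  p <- make_product("c1", c("a", "b"), declared = c(75, 25),
                    categories = c("beef", NA))
  est <- infer_composition(p)
  expect_equal(est$coverage, 0.75)
  expect_true(coverage_gate(est))            # inclusive at the threshold
  expect_true(coverage_gate(est, 0.75))
  expect_false(coverage_gate(est, 0.8))
  # all unmapped: estimate still produced, coverage 0
  p0 <- make_product("c0", c("x", "y"))
  est0 <- infer_composition(p0)
  expect_equal(est0$coverage, 0)
  expect_equal(sum(est0$percents), 100, tolerance = 1e-6)
})

test_that("composition error shrinks as more percentages are declared", {
  err_at <- function(df) {
    cfg <- synthetic_config(n_products = 200, declared_fraction = df,
                            seed = 29)
    syn <- generate_products(cfg, generate_env_db(cfg))
    corpus <- map_products(syn$products)
    prior <- build_prior_table(corpus)
    errs <- vapply(seq_along(corpus), function(j) {
      est <- infer_composition(corpus[[j]], prior)
      truth <- syn$truth$true_percent[syn$truth$product_id ==
                                        corpus[[j]]$product_id]
      mean(abs(est$percents - truth))
    }, numeric(1))
    mean(errs)
  }
  e0 <- err_at(0)
  e5 <- err_at(0.5)
  e9 <- err_at(0.9)
  expect_lt(e5, e0)
  expect_lt(e9, e5)
})
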