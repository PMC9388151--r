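test_that("single-draw impacts follow the per-100 g unit arithmetic", {
  db <- env_database(list(make_cat("a", ghg = 2), make_cat("b", ghg = 4)))
  p1 <- make_product("p1", "x", declared = 100, categories = "a")
  expect_equal(impact_once(identity_estimate(p1), p1, db)[["ghg"]], 0.2)
  p2 <- make_product("p2", c("x", "y"), declared = c(50, 50),
                     categories = c("a", "b"))
  expect_equal(impact_once(identity_estimate(p2), p2, db)[["ghg"]], 0.3)
  # dried-meat accounting: 100% at raw-equivalent factor 2.5, ghg 20/kg
  db3 <- env_database(list(make_cat("beef", ghg = 20)))
  p3 <- make_product("p3", "beef", declared = 100, categories = "beef",
                     ref = 2.5)
  expect_equal(impact_once(identity_estimate(p3), p3, db3)[["ghg"]], 5.0)
  # unmapped ingredients contribute zero
  p4 <- make_product("p4", c("x", "y"), declared = c(50, 50),
                     categories = c("a", NA))
  expect_equal(impact_once(identity_estimate(p4), p4, db)[["ghg"]], 0.1)
})

test_that("observation sampling honors weights, organic rule and fish split", {
  cat1 <- make_cat("one", ghg = 3)
  expect_equal(sample_observation(cat1)$ghg, 3)  # sole observation, always
  # organic subset used only with >= 5 organic observations
  cat4 <- make_cat("c4", ghg = c(1, 1, 1, 1, 9, 9, 9, 9, 9, 9),
                   organic = rep(c(TRUE, FALSE), c(4, 6)))
  cat5 <- make_cat("c5", ghg = c(1, 1, 1, 1, 1, 9, 9, 9, 9, 9),
                   organic = rep(c(TRUE, FALSE), c(5, 5)))
  set.seed(1)
  d4 <- replicate(200, sample_observation(cat4, organic = TRUE)$ghg)
  d5 <- replicate(200, sample_observation(cat5, organic = TRUE)$ghg)
  expect_true(any(d4 == 9))     # falls back to all systems
  expect_true(all(d5 == 1))     # organic subset only
  # fish categories split 50:50 between aquaculture and capture
  fish <- make_cat("fish", ghg = c(rep(1, 5), rep(9, 5)),
                   system_label = rep(c("aquaculture", "capture"), each = 5),
                   is_fish = TRUE)
  set.seed(2)
  draws <- replicate(1e4, sample_observation(fish)$ghg)
  expect_equal(mean(draws == 1), 0.5, tolerance = 0.02)
  expect_error(food_category("empty", observations = data.frame()),
               "at least one")
})

test_that("monte carlo summarizes draws and is seed-reproducible", {
  db1 <- env_database(list(make_cat("a", ghg = 2)))
  p <- make_product("p", "x", declared = 100, categories = "a")
  est <- identity_estimate(p)
  mc <- monte_carlo(est, p, db1, n_iter = 50, seed = 5)
  # degenerate database: zero variance, all quantiles equal the mean
  expect_equal(mc$summary$sd, rep(0, 4))
  expect_equal(mc$summary$q05, mc$summary$mean)
  expect_equal(mc$summary$q95, mc$summary$mean)
  # determinism under a shared seed
  db2 <- env_database(list(make_cat("a", ghg = c(1, 3))))
  m1 <- monte_carlo(est, p, db2, n_iter = 200, seed = 11)
  m2 <- monte_carlo(est, p, db2, n_iter = 200, seed = 11)
  expect_identical(m1$summary, m2$summary)
  expect_error(monte_carlo(est, p, db2, n_iter = 0), "n_iter")
})

test_that("monte carlo mean matches the analytic expectation at 1/sqrt(n) rate", {
  # two equal-weight observations ghg {1, 3}: E[impact] = 0.1 * 2 = 0.2,
  # per-draw SD = 0.1
  db <- env_database(list(make_cat("a", ghg = c(1, 3))))
  p <- make_product("p", "x", declared = 100, categories = "a")
  est <- identity_estimate(p)
  for (n in c(100, 1000, 10000)) {
    mc <- monte_carlo(est, p, db, n_iter = n, seed = 101)
    expect_lt(abs(mc$summary$mean[1] - 0.2), 3 * 0.1 / sqrt(n))
  }
  # quantiles are monotone in the percentile
  mc <- monte_carlo(est, p, db, n_iter = 1000, seed = 3)
  qcols <- grep("^q", names(mc$summary))
  for (i in 1:4)
    expect_true(!is.unsorted(as.numeric(mc$summary[i, qcols])))
})

test_that("composite score endpoints, linearity and invariances hold", {
  m <- data.frame(product_id = c("max", "fifth", "zero"),
                  ghg = c(10, 2, 0), land = c(20, 4, 0),
                  water = c(1000, 200, 0), eutro = c(50, 10, 0))
  cs <- composite_score(m)
  expect_equal(cs$composite, c(100, 20, 0))
  # scale invariance: multiplying one indicator's corpus values is a no-op
  m2 <- m; m2$water <- m2$water * 1e3
  expect_equal(composite_score(m2)$composite, cs$composite)
  # order preservation under componentwise dominance
  set.seed(4)
  mm <- as.data.frame(matrix(runif(40, 0, 5), ncol = 4,
                             dimnames = list(NULL, c("ghg", "land", "water",
                                                     "eutro"))))
  mm[11, ] <- mm[3, ] * 1.3   # dominates row 3
  cs2 <- composite_score(mm)
  expect_gte(cs2$composite[11], cs2$composite[3])
  # all-zero indicator across the corpus warns and scores 0 on it
  m3 <- m; m3$eutro <- 0
  expect_warning(cs3 <- composite_score(m3), "all-zero")
  expect_equal(cs3$scaled_eutro, c(0, 0, 0))
  # frozen reference reproduces scores for new products
  ref <- attr(cs, "reference")
  expect_equal(composite_from_reference(c(ghg = 2, land = 4, water = 200,
                                          eutro = 10), ref), 20)
})

test_that("serving sizes fall back Shelf then Aisle, averaging over labels", {
  mk <- function(id, serving, shelves = character(), aisles = character())
    make_product(id, "water", serving_size_g = serving, shelves = shelves,
                 aisles = aisles)
  corpus <- list(mk("own", 45, "S1"),
                 mk("a", 30, "S1"), mk("b", 50, "S1"),
                 mk("c", 30, "S2"), mk("d", 50, "S3"),
                 mk("e", 70, aisles = "A1"))
  expect_equal(estimate_serving_size(corpus[[1]], corpus), 45)
  p <- mk("q", NA, "S1")
  expect_equal(estimate_serving_size(p, corpus), (45 + 30 + 50) / 3)
  # product on two shelves: mean of the per-Shelf means
  p2 <- mk("r", NA, c("S2", "S3"))
  expect_equal(estimate_serving_size(p2, corpus), 40)
  # aisle fallback, then absent
  p3 <- mk("s", NA, "S9", "A1")
  expect_equal(estimate_serving_size(p3, corpus), 70)
  expect_true(is.na(estimate_serving_size(mk("t", NA, "S9"), corpus)))
  # per-serving score is linear in the serving size
  expect_equal(per_serving(c(10, 20), 50), c(5, 10))
})
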