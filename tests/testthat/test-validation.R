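val_fixture <- function() {
  db <- env_database(list(make_cat("a", ghg = c(1, 3)),
                          make_cat("b", ghg = c(2, 6), land = c(1, 1)),
                          make_cat("c", ghg = 4)))
  products <- list(
    make_product("full", c("x", "y", "z"), declared = c(60, 30, 10),
                 categories = c("a", "b", "c")),
    make_product("allbutone", c("x", "y", "z"), declared = c(60, 30, NA),
                 categories = c("a", "b", "c")),
    make_product("short", c("x", "y"), declared = c(55, NA),
                 categories = c("a", "b")),
    make_product("single", "x", declared = 100, categories = "a"),
    make_product("undeclared", c("x", "y", "z"),
                 categories = c("a", "b", "c")))
  list(db = db, products = products)
}

test_that("validation set selection applies all three criteria", {
  fx <- val_fixture()
  vset <- select_validation_set(fx$products)
  ids <- vapply(vset, `[[`, character(1), "product_id")
  expect_setequal(ids, c("full", "allbutone", "short"))
  # the missing ingredient is completed with the residual mass
  ab <- vset[[which(ids == "allbutone")]]
  expect_equal(declared_percents(ab), c(60, 30, 10))
  # a fully-declared set not summing to 100 is excluded
  bad <- make_product("bad", c("x", "y"), declared = c(60, 30))
  expect_length(select_validation_set(list(bad)), 0)
})

test_that("masking with no masks reproduces the known score exactly", {
  fx <- val_fixture()
  vset <- select_validation_set(fx$products)
  prior <- build_prior_table(fx$products)
  known <- t(vapply(vset, function(p) {
    mean_impacts(monte_carlo(identity_estimate(p), p, fx$db,
                             n_iter = 100, seed = 1))
  }, numeric(4)))
  ref <- attr(composite_score(as.data.frame(known)), "reference")
  for (p in vset) {
    tr <- mask_and_estimate(p, 0, prior, fx$db, ref, n_iter = 100, seed = 1)
    expect_equal(tr$log_ratio, 0)
    expect_equal(tr$estimated_score, tr$known_score)
  }
})

test_that("masking enumerates combinations and validates n_mask", {
  fx <- val_fixture()
  vset <- select_validation_set(fx$products)
  prior <- build_prior_table(fx$products)
  ref <- list(indicator_max = c(ghg = 1, land = 1, water = 1, eutro = 1),
              mean_scaled_max = 100)
  p <- vset[[1]]  # 3 ingredients
  tr3 <- mask_and_estimate(p, 3, prior, fx$db, ref, n_iter = 50, seed = 2)
  expect_equal(nrow(tr3), 1)          # C(3,3) = 1 combination
  expect_equal(tr3$masked_ranks, "1,2,3")
  expect_equal(tr3$percent_known, 0)  # rank-only information
  tr2 <- mask_and_estimate(p, 2, prior, fx$db, ref, n_iter = 50, seed = 2)
  expect_equal(nrow(tr2), 3)          # C(3,2) = 3 combinations
  expect_false(anyDuplicated(tr2$masked_ranks) > 0)
  expect_error(mask_and_estimate(p, 1, prior, fx$db, ref), "n_mask")
  expect_error(mask_and_estimate(p, 4, prior, fx$db, ref), "n_mask")
  # capped sampling yields unique combinations
  p6 <- make_product("six", letters[1:6], declared = rep(100 / 6, 6),
                     categories = rep("a", 6))
  tr6 <- mask_and_estimate(p6, 3, prior, fx$db, ref, max_combos = 5,
                           n_iter = 10, seed = 3)
  expect_equal(nrow(tr6), 5)
  expect_false(anyDuplicated(tr6$masked_ranks) > 0)
})

test_that("accuracy summary matches an independent brute-force pass", {
  mk_trial <- function(known, est)
    data.frame(product_id = "t", n_ingredients = 3, n_mask = 2, combo = 1,
               masked_ranks = "1,2", percent_known = 50,
               known_ghg = known, est_ghg = est, known_land = known,
               est_land = est, known_water = known, est_water = est,
               known_eutro = known, est_eutro = est,
               known_score = known, estimated_score = est,
               log_ratio = log2(est / known))
  trials <- rbind(mk_trial(10, 10.5), mk_trial(10, 9.5), mk_trial(10, 16),
                  mk_trial(10, 25), mk_trial(10, 12), mk_trial(10, 10))
  s <- summarize_accuracy(trials)
  ratio <- trials$estimated_score / trials$known_score
  # independent recomputation of every fraction
  expect_equal(s$fraction_within_10pct, sum(abs(ratio - 1) <= 0.1) / 6)
  expect_equal(s$fraction_within_25pct, sum(abs(ratio - 1) <= 0.25) / 6)
  expect_equal(s$fraction_outside_two_thirds_three_halves,
               sum(ratio < 2 / 3 | ratio > 3 / 2) / 6)
  expect_equal(s$fraction_outside_half_double,
               sum(ratio < 0.5 | ratio > 2) / 6)
  expect_equal(s$mean_percent_diff, mean((ratio - 1) * 100))
  # ratio 1.6 is a two-thirds/three-halves outlier but not a half/double one
  s16 <- summarize_accuracy(mk_trial(10, 16))
  expect_equal(s16$fraction_outside_two_thirds_three_halves, 1)
  expect_equal(s16$fraction_outside_half_double, 0)
  # a perfect single trial
  s1 <- summarize_accuracy(mk_trial(10, 10))
  expect_equal(s1$mean_percent_diff, 0)
  expect_equal(s1$fraction_outside_two_thirds_three_halves, 0)
  # zero known scores are excluded with a warning
  expect_warning(sz <- summarize_accuracy(rbind(mk_trial(10, 10),
                                                mk_trial(0, 1))),
                 "excluded")
  expect_equal(sz$n_trials, 1)
})

test_that("aisle profiles aggregate means, SEMs and rank correlation", {
  mk <- function(id, aisles) make_product(id, "water", aisles = aisles)
  products <- list(mk("p1", "A"), mk("p2", "A"), mk("p3", c("A", "B")),
                   mk("p4", "B"), mk("p5", "C"), mk("p6", "C"))
  env <- data.frame(product_id = paste0("p", 1:6),
                    composite = c(2, 4, 6, 10, 20, 30))
  nut <- data.frame(product_id = paste0("p", 1:6),
                    numeric = c(1, 1, 2, 3, 4, 5))
  ap <- aisle_profiles(products, env, nut)
  a <- ap$aisles[ap$aisles$aisle == "A", ]
  expect_equal(a$n, 3)               # multi-aisle product counted here
  expect_equal(a$env_mean, mean(c(2, 4, 6)))
  b <- ap$aisles[ap$aisles$aisle == "B", ]
  expect_equal(b$n, 2)               # ... and here
  expect_equal(b$env_mean, 8)
  expect_equal(b$env_sem, sd(c(6, 10)) / sqrt(2))
  # identical environment and nutrition rank orders: rho = 1
  expect_equal(ap$spearman_rho, 1)
  # two products in one aisle: mean 3, SEM 1
  ap2 <- aisle_profiles(list(mk("q1", "Z"), mk("q2", "Z")),
                        data.frame(product_id = c("q1", "q2"),
                                   composite = c(2, 4)),
                        data.frame(product_id = c("q1", "q2"),
                                   numeric = c(1, 2)))
  expect_equal(ap2$aisles$env_mean, 3)
  expect_equal(ap2$aisles$env_sem, 1)
})

test_that("run_validate produces per-level summaries and errors on empty sets", {
  cfg <- synthetic_config(n_products = 15, declared_fraction = 1, seed = 21)
  db <- generate_env_db(cfg)
  corpus <- generate_products(cfg, db)$products
  v <- run_validate(corpus, db, n_mask_grid = c(2, Inf), max_combos = 2,
                    n_iter = 50, seed = 4)
  expect_s3_class(v$pooled, "accuracy_summary")
  expect_true(all(c("2") %in% names(v$by_n_mask)))
  expect_true(all(v$trials$known_score > 0))
  # determinism
  v2 <- run_validate(corpus, db, n_mask_grid = c(2, Inf), max_combos = 2,
                     n_iter = 50, seed = 4)
  expect_identical(v$trials, v2$trials)
  # a corpus with no declared percentages has no validation set
  cfg0 <- synthetic_config(n_products = 10, declared_fraction = 0, seed = 21)
  corpus0 <- generate_products(cfg0, generate_env_db(cfg0))$products
  expect_error(run_validate(corpus0, db), "validation set is empty")
})
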