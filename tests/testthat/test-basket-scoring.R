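test_that("catalog loading validates schema and ids", {
  cat_df <- fixture_catalog()
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalog(cat_df, path)
  reloaded <- load_catalog(path, n_categories = 125)
  expect_identical(nrow(reloaded), nrow(cat_df))
  expect_identical(reloaded$fsa_score, cat_df$fsa_score)

  dup <- rbind(as.data.frame(cat_df)[1:3, ], as.data.frame(cat_df)[1, ])
  expect_error(as_catalog(dup, 125), "A1")
  bad_cat <- as.data.frame(cat_df)
  bad_cat$category_id[2] <- 400
  expect_error(as_catalog(bad_cat, 125), "category_id")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("product_id,name,category_id,unit_mass_g", empty)
  expect_warning(ec <- load_catalog(empty), "empty")
  expect_identical(nrow(ec), 0L)
})

test_that("single-item and symmetric baskets score as their products", {
  catal <- fixture_catalog()
  one <- data.frame(product_id = "A1", quantity = 1, mass_g = 500)
  sc <- score_basket(one, catal)
  expect_equal(sc$solid_di,
               catal$fsa_score[catal$product_id == "A1"])
  # two solids with equal purchased energy average their scores
  a2 <- catal[catal$product_id == "A2", ]
  b1 <- catal[catal$product_id == "B1", ]
  mass_b1 <- 1000 * a2$energy_kj / b1$energy_kj  # equalise energy
  two <- data.frame(product_id = c("A2", "B1"), quantity = 1,
                    mass_g = c(1000, mass_b1))
  sc2 <- score_basket(two, catal)
  expect_equal(sc2$solid_di, mean(c(a2$fsa_score, b1$fsa_score)))
})

test_that("mixed baskets match an explicit weighted-mean oracle", {
  catal <- fixture_catalog()
  items <- data.frame(product_id = c("A2", "B1", "B2"), quantity = 1,
                      mass_g = c(400, 150, 700))
  sc <- score_basket(items, catal)
  rows <- catal[match(items$product_id, catal$product_id), ]
  w_energy <- items$mass_g * rows$energy_kj / 100
  expect_equal(sc$solid_di, wmean_oracle(rows$fsa_score, w_energy))
  sc_mass <- score_basket(items, catal, weighting = "mass")
  expect_equal(sc_mass$solid_di, wmean_oracle(rows$fsa_score, items$mass_g))
  for (cc in c("sugar_pts", "sodium_pts", "protein_pts"))
    expect_equal(unname(sc$component_means[cc]),
                 wmean_oracle(rows[[cc]], w_energy))
})

test_that("beverages are scored separately and non-food lines are skipped", {
  catal <- fixture_catalog()
  items <- data.frame(product_id = c("A1", "D1", "NF1"), quantity = 1,
                      mass_g = c(500, 1500, 100))
  sc <- score_basket(items, catal)
  expect_equal(sc$solid_di, catal$fsa_score[catal$product_id == "A1"])
  expect_equal(sc$beverage_di, catal$fsa_score[catal$product_id == "D1"])
  expect_identical(sc$n_skipped_nonfood, 1L)
  expect_identical(sc$n_items, 2L)
  solid_only <- data.frame(product_id = "A1", quantity = 1, mass_g = 500)
  expect_true(is.na(score_basket(solid_only, catal)$beverage_di))
})

test_that("unresolvable product ids are reported", {
  catal <- fixture_catalog()
  items <- data.frame(product_id = c("A1", "GHOST"), quantity = 1,
                      mass_g = c(100, 100))
  expect_error(score_basket(items, catal), "GHOST")
})

test_that("basket scores are permutation invariant and bounded", {
  catal <- fixture_catalog()
  items <- data.frame(product_id = c("A1", "A2", "B1", "B2", "C1"),
                      quantity = c(2, 1, 1, 3, 1),
                      mass_g = c(1000, 400, 200, 750, 1000))
  sc <- score_basket(items, catal)
  set.seed(9)
  for (i in 1:5) {
    perm <- items[sample(nrow(items)), ]
    expect_equal(score_basket(perm, catal)$solid_di, sc$solid_di)
  }
  scores <- catal$fsa_score[match(items$product_id, catal$product_id)]
  expect_gte(sc$solid_di, min(scores))
  expect_lte(sc$solid_di, max(scores))
})

test_that("energy weighting equals mass weighting at constant energy density", {
  df <- data.frame(
    product_id = c("X1", "X2"), name = c("x1", "x2"), category_id = c(1, 1),
    is_beverage = FALSE, is_food = TRUE, unit_mass_g = 100,
    energy_kj = 800, sugars_g = c(2, 30), satfat_g = c(1, 9),
    sodium_mg = c(50, 600), fvln_pct = 0, fiber_g = 0, protein_g = c(2, 8))
  catal <- as_catalog(df, 125)
  items <- data.frame(product_id = c("X1", "X2"), quantity = 1,
                      mass_g = c(130, 870))
  expect_equal(score_basket(items, catal, "energy")$solid_di,
               score_basket(items, catal, "mass")$solid_di)
})

test_that("rolling component means respect the basket window", {
  catal <- fixture_catalog()
  rc <- fixture_receipts()
  one <- rc[rc$basket_id == "b1", ]
  r1 <- rolling_component_means(one, catal, window_n = 12)
  expect_identical(r1$used_count, 1L)
  expect_equal(r1$means, score_basket(one, catal)$component_means)
  # identical baskets: idempotent means
  rep14 <- do.call(rbind, lapply(1:14, function(i) {
    b <- one
    b$basket_id <- paste0("r", i)
    b$date <- as.Date("2021-01-01") + i
    b
  }))
  r14 <- rolling_component_means(rep14, catal, window_n = 12)
  expect_identical(r14$used_count, 12L)
  expect_equal(r14$means, r1$means)
  # 13 distinct baskets, window 12: oldest excluded
  set.seed(33)
  prods <- c("A1", "A2", "A3", "B1", "B2", "C1")
  b13 <- do.call(rbind, lapply(1:13, function(i) {
    pick <- sample(prods, 2)
    data.frame(basket_id = sprintf("w%02d", i), participant_id = "p1",
               date = as.Date("2021-03-01") + i, retailer = "A",
               product_id = pick, quantity = 1,
               mass_g = c(300, 500), stringsAsFactors = FALSE)
  }))
  r13 <- rolling_component_means(b13, catal, window_n = 12)
  expect_identical(r13$used_count, 12L)
  per_basket <- sapply(sprintf("w%02d", 2:13), function(bid) {
    score_basket(b13[b13$basket_id == bid, ], catal)$component_means
  })
  expect_equal(r13$means, rowMeans(per_basket))
  # empty history
  r0 <- rolling_component_means(b13[0, ], catal, 12)
  expect_identical(r0$status, "insufficient history")
  expect_null(r0$means)
})

test_that("period DI pools items rather than averaging basket means", {
  catal <- fixture_catalog()
  rc <- fixture_receipts()
  b1 <- rc[rc$basket_id == "b1", ]
  expect_equal(period_di(rc, catal, "2021-01-01", "2021-01-05"),
               score_basket(b1, catal)$solid_di)
  expect_true(is.na(period_di(rc, catal, "2020-01-01", "2020-02-01")))
  # asymmetric two-basket range: pooled oracle differs from mean of baskets
  sel <- rc[rc$basket_id %in% c("b1", "b2"), ]
  pooled <- period_di(rc, catal, "2021-01-01", "2021-01-12")
  rows <- catal[match(sel$product_id, catal$product_id), ]
  keep <- rows$is_food & !rows$is_beverage
  w <- (sel$mass_g * rows$energy_kj / 100)[keep]
  expect_equal(pooled, wmean_oracle(rows$fsa_score[keep], w))
  per_basket_mean <- mean(c(score_basket(rc[rc$basket_id == "b1", ], catal)$solid_di,
                            score_basket(rc[rc$basket_id == "b2", ], catal)$solid_di))
  expect_false(isTRUE(all.equal(pooled, per_basket_mean)))
})

test_that("receipts survive a CSV and JSONL round trip", {
  rc <- fixture_receipts()
  for (ext in c(".csv", ".jsonl")) {
    path <- withr::local_tempfile(fileext = ext)
    write_receipts(rc, path)
    back <- read_receipts(path)
    rownames(back) <- NULL
    expect_equal(back[names(rc)], rc, ignore_attr = TRUE)
  }
})
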