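test_that("category contributions match item-level brute force and conserve", {
  catal <- fixture_catalog()
  set.seed(55)
  prods <- c("A1", "A2", "A3", "B1", "B2", "C1", "D1")
  rc <- do.call(rbind, lapply(1:7, function(i) {
    n <- sample(2:4, 1)
    data.frame(basket_id = sprintf("c%02d", i), participant_id = "p1",
               date = as.Date("2021-02-01") + i, retailer = "A",
               product_id = sample(prods, n, replace = TRUE),
               quantity = sample(1:3, n, replace = TRUE),
               mass_g = NA_real_, stringsAsFactors = FALSE)
  }))
  contrib <- category_contributions(rc, catal, n_baskets = 7)
  # brute force: accumulate every (item, dimension) pair explicitly
  rows <- catal[match(rc$product_id, catal$product_id), ]
  mass <- rc$quantity * rows$unit_mass_g
  keep <- rows$is_food
  dims <- c(sugar = "sugar_pts", sodium = "sodium_pts",
            saturated_fat = "satfat_pts", energy = "energy_pts")
  total_mass <- sum(mass[keep])
  for (cid in contrib$category_id) {
    in_cat <- keep & rows$category_id == cid
    for (d in names(dims)) {
      acc <- 0
      for (i in which(in_cat)) acc <- acc + mass[i] * rows[[dims[d]]][i]
      expect_equal(contrib[[d]][contrib$category_id == cid],
                   acc / total_mass, info = paste(cid, d))
    }
  }
  # conservation: per-dimension sums equal the pooled weighted mean points
  for (d in names(dims)) {
    pooled <- sum(mass[keep] * rows[[dims[d]]][keep]) / total_mass
    expect_equal(sum(contrib[[d]]), pooled, tolerance = 1e-12)
  }
  expect_equal(sum(contrib$share_of_mass), 1)
  # combined is the unweighted mean across the four dimensions
  expect_equal(contrib$combined,
               unname(rowMeans(contrib[, names(dims)])))
})

test_that("single-category and zero-point boundaries behave", {
  catal <- fixture_catalog()
  rc <- data.frame(basket_id = "b", participant_id = "p",
                   date = as.Date("2021-01-04"), retailer = "A",
                   product_id = c("A1", "A2"), quantity = 1,
                   mass_g = c(500, 400))
  contrib <- category_contributions(rc, catal)
  expect_identical(nrow(contrib), 1L)
  rows <- catal[match(rc$product_id, catal$product_id), ]
  mean_neg <- sapply(c("sugar_pts", "sodium_pts", "satfat_pts", "energy_pts"),
                     function(cc) wmean_oracle(rows[[cc]], rc$mass_g))
  expect_equal(contrib$combined, mean(mean_neg))
  # apples only: all four negative dimensions are zero
  rc0 <- data.frame(basket_id = "b", participant_id = "p",
                    date = as.Date("2021-01-04"), retailer = "A",
                    product_id = "C1", quantity = 1, mass_g = 1000)
  c0 <- category_contributions(rc0, catal)
  expect_true(all(c0[, c("sugar", "sodium", "saturated_fat", "energy")] == 0))
  expect_identical(rank_problem_categories(c0), integer(0))
  # no scoreable items
  empty <- category_contributions(rc0[0, ], catal)
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "status"), "no scoreable items")
})

test_that("ranking is deterministic under the documented tie-break", {
  contrib <- data.frame(
    category_id = c(10, 3, 7, 12, 5),
    sugar = 0, sodium = 0, saturated_fat = 0, energy = 0,
    combined = c(0.5, 0.5, 0.9, 0.2, 0.1),
    share_of_mass = c(0.3, 0.3, 0.2, 0.1, 0.1))
  # tie between 10 and 3 at combined 0.5 and equal mass share: smaller id wins
  expect_identical(rank_problem_categories(contrib),
                   c(7, 3, 10, 12))
  # larger mass share breaks the tie first
  contrib$share_of_mass[1] <- 0.4
  expect_identical(rank_problem_categories(contrib, k = 4), c(7, 10, 3, 12))
  # verify against full enumeration of permutations of the tied pair
  perms <- list(c(1, 2), c(2, 1))
  for (p in perms) {
    shuffled <- contrib[c(p, 3:5), ]
    expect_identical(rank_problem_categories(shuffled, k = 4),
                     c(7, 10, 3, 12))
  }
  # k truncates; appending a zero-contribution category changes nothing
  expect_identical(rank_problem_categories(contrib, k = 2), c(7, 10))
  extra <- rbind(contrib, data.frame(category_id = 99, sugar = 0, sodium = 0,
                                     saturated_fat = 0, energy = 0,
                                     combined = 0, share_of_mass = 0))
  expect_identical(rank_problem_categories(extra, k = 4),
                   rank_problem_categories(contrib, k = 4))
})

test_that("healthier alternatives are the strict filter-and-sort set", {
  catal <- fixture_catalog()
  # category 1 scores: A1 < A3 < A2 (verify ordering assumption first)
  s <- catal$fsa_score[match(c("A1", "A3", "A2"), catal$product_id)]
  expect_true(s[1] < s[2] && s[2] < s[3])
  purchased <- data.frame(product_id = "A2", quantity = 1, mass_g = 400)
  alts <- healthier_alternatives(1, purchased, catal)
  expect_identical(alts$product_id, c("A1", "A3"))
  # buying the category-best leaves nothing to recommend
  best <- data.frame(product_id = "A1", quantity = 1, mass_g = 400)
  expect_identical(nrow(healthier_alternatives(1, best, catal)), 0L)
  expect_error(healthier_alternatives(99, purchased, catal), "not in catalog")
})

test_that("alternatives equal brute force on a randomized catalog", {
  set.seed(66)
  n <- 40
  df <- data.frame(
    product_id = sprintf("R%02d", 1:n), name = "r", category_id = 7,
    is_beverage = FALSE, is_food = TRUE, unit_mass_g = 100,
    energy_kj = runif(n, 100, 3000), sugars_g = runif(n, 0, 40),
    satfat_g = runif(n, 0, 12), sodium_mg = runif(n, 0, 1000),
    fvln_pct = runif(n, 0, 100), fiber_g = runif(n, 0, 6),
    protein_g = runif(n, 0, 10))
  catal <- as_catalog(df, 125)
  purchased <- data.frame(product_id = c("R01", "R02"), quantity = c(2, 1),
                          mass_g = c(300, 150))
  alts <- healthier_alternatives(7, purchased, catal, n_max = 6)
  ref <- wmean_oracle(catal$fsa_score[match(purchased$product_id,
                                            catal$product_id)],
                      purchased$mass_g)
  brute <- catal[catal$fsa_score < ref &
                   !(catal$product_id %in% purchased$product_id), ]
  brute <- brute[order(brute$fsa_score, brute$product_id), ]
  expect_identical(alts$product_id, head(brute$product_id, 6))
})

test_that("substituting any emitted alternative strictly improves the DI", {
  catal <- fixture_catalog()
  rc <- fixture_receipts()
  contrib <- category_contributions(rc, catal)
  ranked <- rank_problem_categories(contrib)
  for (cid in ranked) {
    alts <- healthier_alternatives(cid, rc, catal)
    purch <- rc[catal$category_id[match(rc$product_id,
                                        catal$product_id)] %in% cid, ]
    if (nrow(alts) == 0 || nrow(purch) == 0) next
    before <- period_di(rc, catal, min(rc$date), max(rc$date),
                        weighting = "mass")
    for (alt in alts$product_id) {
      rc_sub <- rc
      rc_sub$product_id[rc_sub$product_id == purch$product_id[1]] <- alt
      after <- period_di(rc_sub, catal, min(rc$date), max(rc$date),
                         weighting = "mass")
      expect_lt(after, before)
    }
  }
})

test_that("tip selection is keyed to categories and rotates before repeating", {
  pack <- list(categories = list("4" = c("tip_a", "tip_b"),
                                 "2" = "tip_c"),
               fallback = "tip_generic")
  expect_identical(select_tip(c(4, 2), pack), "tip_a")
  expect_identical(select_tip(c(9, 2), pack), "tip_c")
  expect_identical(select_tip(c(9, 8), pack), "tip_generic")
  expect_message(
    expect_identical(select_tip(4, list(categories = list(),
                                        fallback = "tip_generic")),
                     "tip_generic"),
    "empty tip pack")
  # four weekly calls: both mapped tips appear before any repetition
  history <- character(0)
  shown <- character(0)
  for (wk in 1:4) {
    tip <- select_tip(c(4, 2), pack, history = history)
    shown <- c(shown, tip)
    history <- c(history, tip)
  }
  expect_identical(shown, c("tip_a", "tip_b", "tip_a", "tip_b"))
})

test_that("the assembled report respects window and count limits", {
  catal <- fixture_catalog()
  rc <- fixture_receipts()
  rep <- recommendation_report(rc, catal, k = 4, n_baskets = 7)
  expect_lte(nrow(rep$problem_categories), 4)
  expect_lte(rep$baskets_used, 7)
  expect_true(nzchar(rep$tip_id))
  for (cid in names(rep$alternatives)) {
    a <- rep$alternatives[[cid]]
    if (nrow(a)) expect_true(all(a$category_id == as.integer(cid)))
  }
})
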