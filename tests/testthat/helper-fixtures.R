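# Fixtures are built in code; oracles here are deliberately brute-force and
# independent of the package's lookup/aggregation paths.

# linear-scan band oracle: first band whose upper bound is >= value
scan_points <- function(value, bands) {
  vapply(value, function(v) {
    for (i in seq_len(nrow(bands))) {
      if (v <= bands$upper_bound[i]) return(as.integer(bands$points[i]))
    }
    stop("no band matched")
  }, integer(1))
}

# the package's interval-lookup path, accessed for oracle comparison
points_for_test <- function(value, bands) fsanps:::points_for(value, bands)

# explicit weighted mean oracle
wmean_oracle <- function(x, w) sum(w * x) / sum(w)

# exhaustive signed-rank enumeration over all 2^n sign assignments
wilcoxon_enum_p <- function(before, after) {
  d <- after - before
  stopifnot(all(d != 0))
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exhaustive Mann-Whitney enumeration over all group assignments
mwu_enum_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  combos <- utils::combn(n_a + n_b, n_a)
  u_all <- apply(combos, 2, u_of)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# small hand-written catalog: 3 food categories + a beverage + a non-food line
fixture_catalog <- function() {
  df <- data.frame(
    product_id = c("A1", "A2", "A3", "B1", "B2", "C1", "D1", "NF1"),
    name = c("oat flakes", "granola", "muesli", "cheddar", "cottage cheese",
             "apples", "cola", "sponge"),
    category_id = c(1, 1, 1, 2, 2, 3, 4, NA),
    is_beverage = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    is_food = c(rep(TRUE, 7), FALSE),
    unit_mass_g = c(500, 400, 500, 200, 250, 1000, 1500, 100),
    energy_kj =  c(1500, 1900, 1600, 1700, 400, 220, 180, NA),
    sugars_g =   c(1, 25, 14, 0.5, 3, 4.2, 10.6, NA),
    satfat_g =   c(0.5, 6, 2, 21, 2, 0.1, 0, NA),
    sodium_mg =  c(5, 100, 50, 700, 330, 1, 10, NA),
    fvln_pct =   c(0, 10, 25, 0, 0, 100, 0, NA),
    fiber_g =    c(9, 5, 7, 0, 0, 2.2, 0, NA),
    protein_g =  c(13, 8, 10, 25, 12, 0.3, 0, NA),
    stringsAsFactors = FALSE
  )
  as_catalog(df, n_categories = 125)
}

# receipts for one participant: one basket per row-group, ISO dates
fixture_receipts <- function() {
  data.frame(
    basket_id = c("b1", "b1", "b1", "b2", "b2", "b3", "b3", "b3"),
    participant_id = "p1",
    date = as.Date(c("2021-01-04", "2021-01-04", "2021-01-04",
                     "2021-01-11", "2021-01-11",
                     "2021-01-18", "2021-01-18", "2021-01-18")),
    retailer = "A",
    product_id = c("A2", "B1", "C1", "A1", "D1", "B2", "C1", "NF1"),
    quantity = c(1, 2, 1, 1, 1, 2, 3, 1),
    mass_g = c(400, 400, 1000, 500, 1500, 500, 3000, 100),
    stringsAsFactors = FALSE
  )
}

fixture_steps <- function(dates, steps) {
  data.frame(participant_id = rep("p1", length(steps)),
             date = as.Date(dates), steps = steps)
}

# small fast cohort configuration used across tests; ... overrides defaults
small_cohort_config <- function(...) {
  args <- list(
    n_total = 10, allocation = c(intervention = 5, control = 5),
    attrition_schedule = rbind(intervention = c(4, 3, 2),
                               control = c(5, 4, 3)),
    card_failures = c(intervention = 1, control = 1),
    accel_failures = c(intervention = 1, control = 0),
    n_products = 150, n_categories = 25, n_nonfood = 3)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}
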