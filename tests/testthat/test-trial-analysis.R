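test_that("period aggregation matches brute-force window means", {
  cfg <- small_cohort_config()
  co <- generate_cohort(cfg, seed = 51)
  per <- aggregate_periods(co, outcomes = c("steps", "solid_di", "logins"))
  start <- cfg$trial_start
  st_all <- co$steps
  for (pid in unique(per$participant_id)) {
    row <- per[per$outcome == "steps" & per$participant_id == pid, ]
    if (nrow(row) == 0) next
    st <- st_all[st_all$participant_id == pid, ]
    brute <- function(d1, d2) {
      v <- st$steps[st$date >= d1 & st$date <= d2]
      if (length(v)) mean(v) else NA_real_
    }
    expect_equal(row$T0, brute(start - 6, start - 1))
    expect_equal(row$T1, brute(start, start + 27))
    expect_equal(row$T2, brute(start + 28, start + 55))
    expect_equal(row$T3, brute(start + 56, start + 83))
  }
  # dropout at week 5 leaves T2 and T3 absent for every outcome
  p <- co$participants
  dropped5 <- p$participant_id[!is.na(p$dropout_week) & p$dropout_week == 5]
  for (pid in dropped5) {
    rows <- per[per$participant_id == pid, ]
    expect_true(all(is.na(rows$T2)))
    expect_true(all(is.na(rows$T3)))
  }
  # constant steps: all trial periods equal the constant
  flat <- co
  flat$steps$steps <- 6000
  pf <- aggregate_periods(flat, outcomes = "steps")
  done <- pf[!is.na(pf$T3), ]
  expect_true(all(done$T1 == 6000 & done$T2 == 6000 & done$T3 == 6000))
})

test_that("signed-rank test matches exhaustive enumeration and closed forms", {
  # all ties: no evidence of difference
  t_ties <- wilcoxon_signed_rank(c(3, 4, 5), c(3, 4, 5))
  expect_identical(t_ties$p_value, 1)
  # all positive differences, n = 6: two-sided p = 2/64
  t6 <- wilcoxon_signed_rank(rep(0, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(t6$p_value, 2 / 64)
  # n = 8 fixture against full 2^8 enumeration
  set.seed(71)
  before <- rnorm(8); after <- before + rnorm(8)
  t8 <- wilcoxon_signed_rank(before, after)
  expect_equal(t8$p_value, wilcoxon_enum_p(before, after))
  # random fixtures n <= 10: exact path equals enumeration
  for (r in 1:20) {
    n <- sample(5:10, 1)
    b <- rnorm(n); a <- b + rnorm(n)
    expect_equal(wilcoxon_signed_rank(b, a)$p_value, wilcoxon_enum_p(b, a))
  }
  # exact path also agrees with stats::wilcox.test
  expect_equal(wilcoxon_signed_rank(before, after)$p_value,
               wilcox.test(after, before, paired = TRUE)$p.value)
  # complete-case: NA pairs are dropped and n_used reported
  t_na <- wilcoxon_signed_rank(c(1, 2, NA, 4, 5, 6), c(2, 3, 4, NA, 7, 8))
  expect_identical(t_na$n_used, 4L)
  expect_true(t_na$underpowered)
})

test_that("signed-rank normal path is tie-corrected and Pratt-handled", {
  # ties in |d| force the normal approximation
  b <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  a <- b + c(2, 2, -1, 3, 3, -1, 2, 4, -2, 3, 2, 1)
  t_n <- wilcoxon_signed_rank(b, a)
  expect_match(t_n$method, "tie-corrected")
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(t_n$p_value, ref$p.value)
  # zeros under Pratt shift the null mean; p stays in (0, 1]
  t_z <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 6, 8, 9))
  expect_match(t_z$method, "Pratt")
  expect_true(t_z$p_value > 0 && t_z$p_value <= 1)
})

test_that("Mann-Whitney matches enumeration, symmetry and stats::wilcox.test", {
  # separated groups: U = 0, exact two-sided p = 2/20
  t0 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(t0$statistic), 0)
  expect_equal(t0$p_value, 0.1)
  # identical groups: U = n*m/2, p = 1
  t_eq <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(unname(t_eq$statistic), 4.5)
  expect_identical(t_eq$p_value, 1)
  # random small fixtures equal the permutation oracle and wilcox.test
  set.seed(72)
  for (r in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    t <- mann_whitney_u(a, b)
    expect_equal(t$p_value, mwu_enum_p(a, b))
    expect_equal(t$p_value, wilcox.test(a, b)$p.value)
    expect_equal(unname(t$statistic),
                 unname(wilcox.test(a, b)$statistic))
  }
  # tie-corrected normal path agrees with wilcox.test(correct = FALSE)
  a <- c(1, 2, 2, 3, 5, 5, 6, 7); b <- c(2, 2, 4, 5, 5, 8, 9, 9)
  expect_equal(mann_whitney_u(a, b)$p_value,
               wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
  expect_error(mann_whitney_u(numeric(0), 1:3), "at least one")
})

test_that("chi-square matches the direct formula and handles degeneracy", {
  # perfectly proportional table: statistic 0, p = 1
  t_prop <- pearson_chi_square(matrix(c(10, 20, 30, 60), 2))
  expect_equal(unname(t_prop$statistic), 0)
  expect_equal(t_prop$p_value, 1)
  # gender-by-group table of the emulated trial: p rounds to > .99
  tab <- matrix(c(19, 23, 24, 29), 2,
                dimnames = list(c("male", "female"), c("int", "ctl")))
  t_g <- pearson_chi_square(tab)
  expect_lt(t_g$statistic, 0.01)
  expect_gt(t_g$p_value, 0.99)
  # direct formula oracle on an arbitrary 2x2
  tab2 <- matrix(c(12, 5, 9, 14), 2)
  e <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
  expect_equal(unname(pearson_chi_square(tab2)$statistic),
               sum((tab2 - e)^2 / e))
  expect_equal(pearson_chi_square(tab2)$p_value,
               pchisq(sum((tab2 - e)^2 / e), df = 1, lower.tail = FALSE))
  expect_warning(pearson_chi_square(matrix(c(2, 3, 4, 1), 2)), "below 5")
  expect_error(pearson_chi_square(matrix(c(0, 0, 4, 1), 2), ), "marginal")
  expect_error(pearson_chi_square(matrix(1:3, 1)), "2x2")
})

test_that("median/IQR summaries use the pinned quantile convention", {
  s <- summarize_group(c(1, 2, 3, 4, 5))
  expect_identical(s$median, 3)
  expect_identical(s$iqr, 2)
  s1 <- summarize_group(7)
  expect_identical(s1$median, 7)
  expect_identical(s1$iqr, 0)
  expect_identical(summarize_group(c(NA, NA))$n, 0L)
  set.seed(73)
  v <- rnorm(37)
  s_r <- summarize_group(v)
  # sort-and-interpolate oracle, type-7: h = (n-1)p + 1
  q_oracle <- function(p) {
    sv <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); sv[lo] + (h - lo) * (sv[lo + 1] - sv[lo])
  }
  expect_equal(s_r$median, q_oracle(0.5))
  expect_equal(s_r$iqr, q_oracle(0.75) - q_oracle(0.25))
})

test_that("sample size reproduces the closed form and design numbers", {
  eq <- sample_size(delta = 1, sd = 1)
  expect_identical(eq$per_group, 16L)
  expect_identical(eq$total, 32L)
  design <- sample_size(delta = 1566, sd = 2620)
  expect_identical(design$total, 88L)
  infl <- sample_size(delta = 1566, sd = 2620, dropout_rate = 0.2)
  expect_identical(infl$inflated_total, 110L)
  expect_error(sample_size(0, 1), "delta")
  expect_error(sample_size(1, 1, dropout_rate = 1), "dropout_rate")
})

test_that("sensitivity analysis compares dropouts to completers at baseline", {
  cfg <- small_cohort_config()
  co <- generate_cohort(cfg, seed = 61)
  sens <- suppressWarnings(sensitivity_analysis(co))
  expect_true(all(c("age", "baseline_steps") %in% sens$variable))
  expect_true(all(sens$p_value >= 0 & sens$p_value <= 1))
  # no dropouts: empty comparison with explicit status
  cfg_full <- small_cohort_config(
    attrition_schedule = rbind(intervention = c(5, 5, 5),
                               control = c(5, 5, 5)))
  co_full <- generate_cohort(cfg_full, seed = 62)
  s0 <- sensitivity_analysis(co_full)
  expect_identical(nrow(s0), 0L)
  expect_identical(attr(s0, "status"), "no dropouts")
})

test_that("age-linked dropout is flagged more often than MCAR", {
  reps <- 30
  p_mcar <- p_age <- numeric(reps)
  for (r in seq_len(reps)) {
    co_m <- generate_cohort(cohort_config(streams = "steps",
                                          attrition_mode = "mcar"),
                            seed = 100 + r)
    co_a <- generate_cohort(cohort_config(streams = "steps",
                                          attrition_mode = "age_linked"),
                            seed = 100 + r)
    sens_m <- suppressWarnings(sensitivity_analysis(co_m))
    sens_a <- suppressWarnings(sensitivity_analysis(co_a))
    p_mcar[r] <- sens_m$p_value[sens_m$variable == "age"]
    p_age[r] <- sens_a$p_value[sens_a$variable == "age"]
  }
  expect_gt(mean(p_age < 0.05), mean(p_mcar < 0.05))
})

test_that("the full trial report assembles complete-case tables", {
  cfg <- small_cohort_config()
  co <- generate_cohort(cfg, seed = 63)
  rep <- suppressWarnings(trial_report(co, outcomes = c("steps", "solid_di",
                                                        "surveys")))
  expect_s3_class(rep, "trial_report")
  expect_true(all(c("outcome", "group", "timepoint", "median", "iqr", "n")
                  %in% names(rep$summaries)))
  # summaries report n only over observed values (absent is not zero)
  st3 <- rep$summaries[rep$summaries$outcome == "steps" &
                         rep$summaries$timepoint == "T3", ]
  per <- rep$periods[rep$periods$outcome == "steps", ]
  expect_identical(sum(st3$n), sum(!is.na(per$T3)))
  expect_true(all(rep$within$p_value >= 0 & rep$within$p_value <= 1))
  expect_true(all(rep$between$p_value >= 0 & rep$between$p_value <= 1))
})
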