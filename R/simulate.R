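# Seed hygiene: run code under a temporary RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Cohort simulation configuration
#'
#' Defaults emulate the FutureMe trial's conditions: 95 participants
#' randomized 42/53 into intervention and control over 12 weeks, baseline
#' windows of 6 step-days and 4 food-weeks, baseline medians of 4624 steps/day
#' and 6.13 FSA-NPS DI points, loyalty-card connection failures (15/13 per
#' group, no food data), accelerometer failures (1/2, no step data), and a
#' per-period app-usage retention schedule (intervention 35/18/12, control
#' 43/24/18 at T1/T2/T3) reproducing the trial funnel of 30 completers.
#'
#' @param n_total Participants randomized.
#' @param allocation Named counts `c(intervention=, control=)`.
#' @param weeks Trial length in weeks.
#' @param baseline_step_days Days of step data before enrollment.
#' @param baseline_food_weeks Weeks of basket data before enrollment.
#' @param baseline_steps_median Participant-level median steps/day.
#' @param baseline_di Target baseline solid-food DI (energy-weighted).
#' @param group_effect_steps Additive steps/day drift per 4-week period,
#'   applied to the intervention group.
#' @param group_effect_di Additive DI drift per period (negative = healthier),
#'   applied to the intervention group.
#' @param attrition_schedule 2x3 matrix of retained counts per group at
#'   T1/T2/T3 (rows `intervention`, `control`); non-increasing, at most the
#'   allocation.
#' @param card_failures,accel_failures Per-group counts of loyalty-card /
#'   accelerometer connection failures.
#' @param attrition_mode `"mcar"` (missing completely at random, the trial's
#'   sensitivity-analysis conclusion) or `"age_linked"` (older participants
#'   drop out more, mirroring the observed younger completers).
#' @param sigma_participant,sigma_week,week_rho,sigma_day Lognormal step-noise
#'   parameters: participant random effect SD, weekly AR(1) effect SD and
#'   autocorrelation, daily noise SD (all on the log scale).
#' @param di_participant_sd SD of the participant-level DI target offset.
#' @param baskets_per_week Basket cadence (integer = deterministic count per
#'   week, otherwise Poisson mean).
#' @param items_per_basket Mean solid items per basket.
#' @param beverage_items Mean beverage items per basket.
#' @param nonfood_rate Probability that a receipt line is a non-food product.
#' @param login_lambda Weekly login Poisson means per period (length 3).
#' @param n_products,n_categories Synthetic catalog size.
#' @param n_nonfood Non-food products in the catalog.
#' @param trial_start Enrollment date (all participants; ISO date).
#' @param streams Which data streams to generate (subset for speed in
#'   simulation studies).
#' @param seed Default seed for [generate_cohort()].
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_total = 95,
                          allocation = c(intervention = 42, control = 53),
                          weeks = 12,
                          baseline_step_days = 6,
                          baseline_food_weeks = 4,
                          baseline_steps_median = 4624,
                          baseline_di = 6.13,
                          group_effect_steps = 0,
                          group_effect_di = 0,
                          attrition_schedule = rbind(
                            intervention = c(35, 18, 12),
                            control = c(43, 24, 18)),
                          card_failures = c(intervention = 15, control = 13),
                          accel_failures = c(intervention = 1, control = 2),
                          attrition_mode = c("mcar", "age_linked"),
                          sigma_participant = 0.7,
                          sigma_week = 0.25,
                          week_rho = 0.3,
                          sigma_day = 0.4,
                          di_participant_sd = 2.5,
                          baskets_per_week = 1,
                          items_per_basket = 12,
                          beverage_items = 1,
                          nonfood_rate = 0.02,
                          login_lambda = c(5.5, 1.5, 1.5),
                          n_products = 2000,
                          n_categories = 125,
                          n_nonfood = 20,
                          trial_start = as.Date("2020-11-16"),
                          streams = c("steps", "baskets", "logins", "surveys"),
                          seed = NULL) {
  attrition_mode <- match.arg(attrition_mode)
  cfg <- as.list(environment())
  cfg$trial_start <- as.Date(trial_start)
  if (sum(allocation) != n_total)
    stop("allocation must sum to n_total")
  sched <- attrition_schedule
  if (!is.matrix(sched) || nrow(sched) != 2 || ncol(sched) != 3)
    stop("attrition_schedule must be a 2x3 matrix (groups x periods)")
  for (g in 1:2) {
    row <- c(allocation[g], sched[g, ])
    if (any(diff(row) > 0))
      stop("retention must be non-increasing and at most the allocation")
  }
  structure(cfg, class = "cohort_config")
}

archetype_params <- function() {
  # per-archetype nutrient medians per 100 g; archetype = ((category-1) %% 6)+1
  data.frame(
    archetype = c("produce", "dairy", "meat", "snacks", "staples", "beverage"),
    energy_kj = c(250, 700, 900, 1900, 1400, 160),
    sugars_g = c(6, 5, 1, 30, 3, 8),
    satfat_g = c(0.2, 6, 5, 8, 1, 0.1),
    sodium_mg = c(20, 300, 500, 450, 250, 20),
    fvln_pct = c(90, 0, 0, 2, 8, 15),
    fiber_g = c(2.5, 0.2, 0.2, 2, 4, 0.2),
    protein_g = c(1.5, 10, 18, 5, 8, 0.5),
    unit_mass_g = c(500, 250, 400, 150, 500, 1000)
  )
}

#' Generate a synthetic product catalog
#'
#' Emulates the study's food composition database at desk scale: products
#' spread over 125 categories built from six archetypes (produce, dairy,
#' meat, snacks/sweets, staples, beverages; archetype =
#' `((category_id - 1) %% 6) + 1`, so every sixth category holds beverages).
#' Nutrients are lognormal around category-level medians, giving each
#' category a within-category score spread so that healthier in-category
#' alternatives exist. A few non-food products (no nutrient profile) are
#' included to exercise receipt-line skipping.
#'
#' @param n_products Food products to generate (default 2000); must be at
#'   least `n_categories` (every category is populated).
#' @param n_categories Food categories (default 125).
#' @param seed Seed (RNG state restored afterwards); `NULL` uses the current
#'   stream.
#' @param n_nonfood Non-food products appended (default 20).
#' @param category_sigma,product_sigma Log-scale SDs of the category and
#'   within-category nutrient variation.
#' @param thresholds Threshold table to score with.
#' @return An `fsa_catalog`.
#' @export
generate_catalog <- function(n_products = 2000, n_categories = 125,
                             seed = NULL, n_nonfood = 20,
                             category_sigma = 0.3, product_sigma = 0.45,
                             thresholds = fsa_thresholds()) {
  if (n_products < n_categories)
    stop("n_products must be at least n_categories")
  with_seed(seed, {
    arch <- archetype_params()
    nut <- c("energy_kj", "sugars_g", "satfat_g", "sodium_mg",
             "fvln_pct", "fiber_g", "protein_g")
    cat_arch <- ((seq_len(n_categories) - 1L) %% 6L) + 1L
    # category-level multipliers around the archetype medians
    cat_mult <- matrix(exp(stats::rnorm(n_categories * length(nut),
                                        0, category_sigma)),
                       n_categories, length(nut),
                       dimnames = list(NULL, nut))
    counts <- rep(1L, n_categories)
    extra <- n_products - n_categories
    if (extra > 0) {
      add <- table(factor(sample.int(n_categories, extra, replace = TRUE),
                          levels = seq_len(n_categories)))
      counts <- counts + as.integer(add)
    }
    cid <- rep(seq_len(n_categories), counts)
    a <- cat_arch[cid]
    df <- data.frame(
      product_id = sprintf("P%05d", seq_len(n_products)),
      name = sprintf("%s-%03d-%02d", arch$archetype[a], cid,
                     stats::ave(cid, cid, FUN = seq_along)),
      category_id = cid,
      is_beverage = arch$archetype[a] == "beverage",
      is_food = TRUE,
      unit_mass_g = round(arch$unit_mass_g[a] *
                            exp(stats::rnorm(n_products, 0, 0.3))),
      stringsAsFactors = FALSE
    )
    for (v in nut) {
      base <- arch[[v]][a] * cat_mult[cid, v]
      val <- base * exp(stats::rnorm(n_products, 0, product_sigma))
      if (v == "fvln_pct") val <- pmin(100, val)
      df[[v]] <- round(val, 2)
    }
    df$unit_mass_g <- pmax(10, df$unit_mass_g)
    if (n_nonfood > 0) {
      nf <- df[rep(1, n_nonfood), ]
      nf$product_id <- sprintf("NF%04d", seq_len(n_nonfood))
      nf$name <- sprintf("nonfood-%02d", seq_len(n_nonfood))
      nf$category_id <- NA_integer_
      nf$is_beverage <- FALSE
      nf$is_food <- FALSE
      nf$unit_mass_g <- 300
      for (v in nut) nf[[v]] <- NA_real_
      df <- rbind(df, nf)
    }
    rownames(df) <- NULL
    as_catalog(df, n_categories = n_categories, thresholds = thresholds)
  })
}

# Solve the exponential-tilt parameter so that the energy-weighted mean score
# of the participant's product-choice distribution hits `target`.
solve_tilt <- function(scores, base_weight, target, range = c(-3, 3)) {
  f <- function(lambda) {
    w <- base_weight * exp(lambda * (scores - mean(scores)))
    sum(w * scores) / sum(w) - target
  }
  lo <- f(range[1]); hi <- f(range[2])
  if (lo >= 0) return(range[1])   # target below what the tilt can reach
  if (hi <= 0) return(range[2])   # target above what the tilt can reach
  stats::uniroot(f, range, tol = 1e-6)$root
}

survey_constructs <- function() {
  list(motivational_self_efficacy = list(mu = 5.8, k = 4),
       recovery_self_efficacy = list(mu = 5.8, k = 2),
       outcome_expectancy = list(mu = 6.0, k = 6),
       intrinsic_motivation = list(mu = 5.8, k = 3),
       extrinsic_motivation = list(mu = 3.2, k = 3))
}

draw_survey <- function(defs = survey_constructs(), item_sd = 1.2) {
  vapply(defs, function(d) {
    items <- pmin(7, pmax(1, round(stats::rnorm(d$k, d$mu, item_sd))))
    mean(items)
  }, numeric(1))
}

#' Generate one synthetic participant
#'
#' Steps follow a lognormal daily model with a participant random effect,
#' AR(1) weekly effects and daily noise; group effects enter as additive
#' steps/day drifts per 4-week period (intervention group only). Baskets are
#' generated weekly with participant category preferences exponentially
#' tilted so the participant's expected energy-weighted solid-food DI equals
#' the configured baseline (plus a participant offset and the per-period DI
#' drift). Surveys are Likert 1-7 item means; logins weekly Poisson counts.
#' No data are generated at or after `dropout_week`; baseline data are always
#' present.
#'
#' @param config A [cohort_config()].
#' @param group `"intervention"` or `"control"`.
#' @param catalog An `fsa_catalog` (one is generated when omitted).
#' @param participant_id Identifier.
#' @param seed Optional seed (RNG state restored); `NULL` continues the
#'   current stream (used by [generate_cohort()]).
#' @param dropout_week Week the participant stops (`NA` = completer).
#' @param card_failure,accel_failure Stream-connection failures.
#' @param demographics Optional pre-drawn list (age, gender, bmi_class,
#'   household_size).
#' @return List of class `participant_record` with `steps`, `receipts`,
#'   `logins`, `surveys` data.frames plus attributes.
#' @export
generate_participant <- function(config, group, catalog = NULL,
                                 participant_id = "P001", seed = NULL,
                                 dropout_week = NA, card_failure = FALSE,
                                 accel_failure = FALSE, demographics = NULL) {
  with_seed(seed, {
    need_catalog <- "baskets" %in% config$streams && !card_failure
    if (is.null(catalog) && need_catalog)
      catalog <- generate_catalog(config$n_products, config$n_categories,
                                  n_nonfood = config$n_nonfood)
    if (is.null(demographics)) {
      demographics <- list(
        age = max(18, round(stats::rnorm(1, 44, 14))),
        gender = sample(c("female", "male"), 1, prob = c(0.55, 0.45)),
        bmi_class = sample(c("<25", "25-30", ">30"), 1,
                           prob = c(0.59, 0.29, 0.12)),
        household_size = sample(1:5, 1, prob = c(0.25, 0.35, 0.2, 0.15, 0.05))
      )
    }
    weeks_active <- if (is.na(dropout_week)) config$weeks
                    else min(config$weeks, dropout_week - 1L)
    start <- config$trial_start
    is_int <- group == "intervention"

    steps <- NULL
    if ("steps" %in% config$streams && !accel_failure) {
      dates <- c(seq(start - config$baseline_step_days, start - 1, by = "day"),
                 if (weeks_active > 0)
                   seq(start, start + weeks_active * 7 - 1, by = "day"))
      nd <- length(dates)
      b <- stats::rnorm(1, 0, config$sigma_participant)
      week_idx <- as.integer(floor(as.numeric(dates - start) / 7))  # <0 baseline
      uw <- sort(unique(week_idx))
      w_eff <- numeric(length(uw)); prev <- 0
      for (j in seq_along(uw)) {
        prev <- config$week_rho * prev +
          stats::rnorm(1, 0, config$sigma_week * sqrt(1 - config$week_rho^2))
        w_eff[j] <- prev
      }
      day_off <- as.numeric(dates - start)
      period <- ifelse(day_off < 0, 0L, pmin(3L, day_off %/% 28 + 1L))
      drift <- if (is_int) config$group_effect_steps * period else 0
      raw <- exp(log(config$baseline_steps_median) + b +
                   w_eff[match(week_idx, uw)] +
                   stats::rnorm(nd, 0, config$sigma_day))
      steps <- data.frame(participant_id = participant_id, date = dates,
                          steps = pmax(0, round(raw + drift)))
    }

    receipts <- NULL
    if ("baskets" %in% config$streams && !card_failure) {
      solid <- catalog[catalog$is_food & !catalog$is_beverage, , drop = FALSE]
      bev <- catalog[catalog$is_food & catalog$is_beverage, , drop = FALSE]
      nonfood <- catalog[!catalog$is_food, , drop = FALSE]
      pref <- stats::rgamma(config$n_categories, shape = 2, rate = 2) + 0.05
      base_w <- pref[solid$category_id] * solid$unit_mass_g * solid$energy_kj
      di_offset <- stats::rnorm(1, 0, config$di_participant_sd)
      score_rng <- range(solid$fsa_score)
      week_list <- c(-(config$baseline_food_weeks:1),
                     if (weeks_active > 0) seq_len(weeks_active))
      rows <- list(); bcount <- 0L
      whole_cadence <- abs(config$baskets_per_week -
                             round(config$baskets_per_week)) < 1e-9
      lambda_cache <- list()
      for (wk in week_list) {
        n_b <- if (whole_cadence) as.integer(round(config$baskets_per_week))
               else stats::rpois(1, config$baskets_per_week)
        if (n_b <= 0) next
        period <- if (wk < 1) 0L else min(3L, (wk - 1L) %/% 4L + 1L)
        target <- config$baseline_di +
          (if (is_int) config$group_effect_di * period else 0) + di_offset
        target <- min(max(target, score_rng[1] + 0.25), score_rng[2] - 0.25)
        key <- as.character(period)
        if (is.null(lambda_cache[[key]]))
          lambda_cache[[key]] <- solve_tilt(solid$fsa_score, base_w, target)
        lam <- lambda_cache[[key]]
        # sampling prob excludes unit mass: the realized DI weight is
        # mass * energy, and E[mass | product] is proportional to unit mass,
        # so unit mass enters the tilt solve (base_w) exactly once
        samp_w <- pref[solid$category_id] *
          exp(lam * (solid$fsa_score - mean(solid$fsa_score)))
        week_start <- start + (if (wk < 1) wk * 7 else (wk - 1) * 7)
        for (bi in seq_len(n_b)) {
          bcount <- bcount + 1L
          n_solid <- max(1L, stats::rpois(1, config$items_per_basket))
          pick <- sample.int(nrow(solid), n_solid, replace = TRUE,
                             prob = samp_w)
          items <- solid[pick, c("product_id", "unit_mass_g"), drop = FALSE]
          n_bev <- stats::rpois(1, config$beverage_items)
          if (n_bev > 0 && nrow(bev) > 0) {
            pickb <- sample.int(nrow(bev), n_bev, replace = TRUE,
                                prob = pref[bev$category_id] * bev$unit_mass_g)
            items <- rbind(items,
                           bev[pickb, c("product_id", "unit_mass_g"),
                               drop = FALSE])
          }
          n_nf <- stats::rbinom(1, n_solid, config$nonfood_rate)
          if (n_nf > 0 && nrow(nonfood) > 0) {
            picknf <- sample.int(nrow(nonfood), n_nf, replace = TRUE)
            items <- rbind(items,
                           nonfood[picknf, c("product_id", "unit_mass_g"),
                                   drop = FALSE])
          }
          qty <- sample(1:3, nrow(items), replace = TRUE,
                        prob = c(0.6, 0.3, 0.1))
          rows[[length(rows) + 1L]] <- data.frame(
            basket_id = sprintf("%s-B%03d", participant_id, bcount),
            participant_id = participant_id,
            date = week_start + sample(0:6, 1),
            retailer = sample(c("A", "B"), 1),
            product_id = items$product_id,
            quantity = qty,
            mass_g = qty * items$unit_mass_g,
            stringsAsFactors = FALSE)
        }
      }
      receipts <- if (length(rows)) do.call(rbind, rows) else NULL
      if (!is.null(receipts))
        receipts <- receipts[order(receipts$date,
                                   receipts$basket_id), , drop = FALSE]
    }

    logins <- NULL
    if ("logins" %in% config$streams && weeks_active > 0) {
      wk <- seq_len(weeks_active)
      period <- pmin(3L, (wk - 1L) %/% 4L + 1L)
      logins <- data.frame(participant_id = participant_id, week = wk,
                           logins = stats::rpois(length(wk),
                                                 config$login_lambda[period]))
    }

    surveys <- NULL
    if ("surveys" %in% config$streams) {
      s0 <- draw_survey()
      surveys <- data.frame(participant_id = participant_id,
                            construct = names(s0), timepoint = "T0",
                            score = unname(s0), stringsAsFactors = FALSE)
      if (is.na(dropout_week)) {
        s3 <- draw_survey()
        surveys <- rbind(surveys,
                         data.frame(participant_id = participant_id,
                                    construct = names(s3), timepoint = "T3",
                                    score = unname(s3),
                                    stringsAsFactors = FALSE))
      }
    }

    structure(list(participant_id = participant_id, group = group,
                   demographics = demographics, dropout_week = dropout_week,
                   card_failure = card_failure, accel_failure = accel_failure,
                   steps = steps, receipts = receipts, logins = logins,
                   surveys = surveys),
              class = "participant_record")
  })
}

#' Generate a two-arm synthetic trial cohort
#'
#' Group sizes honor the allocation exactly; loyalty-card and accelerometer
#' failures and the per-period dropout schedule are assigned to exactly the
#' configured counts (MCAR by default, or biased toward older participants in
#' `age_linked` mode). Fully deterministic given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param catalog Optional pre-built catalog (otherwise generated from the
#'   same seed stream).
#' @return List of class `trial_cohort` with `participants` (demographics,
#'   flags, `dropout_week`), combined `steps`, `receipts`, `logins`,
#'   `surveys` data.frames, the `catalog` and the `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed,
                            catalog = NULL) {
  with_seed(seed, {
    if (is.null(catalog) && "baskets" %in% config$streams)
      catalog <- generate_catalog(config$n_products, config$n_categories,
                                  n_nonfood = config$n_nonfood)
    n <- config$n_total
    groups <- sample(rep(names(config$allocation), config$allocation))
    ids <- sprintf("P%03d", seq_len(n))
    age <- pmax(18, round(stats::rnorm(n, 44, 14)))
    gender <- sample(c("female", "male"), n, replace = TRUE,
                     prob = c(0.55, 0.45))
    bmi <- sample(c("<25", "25-30", ">30"), n, replace = TRUE,
                  prob = c(0.59, 0.29, 0.12))
    hh <- sample(1:5, n, replace = TRUE,
                 prob = c(0.25, 0.35, 0.2, 0.15, 0.05))
    card_fail <- accel_fail <- logical(n)
    dropout <- rep(NA_integer_, n)
    for (g in names(config$allocation)) {
      members <- which(groups == g)
      card_fail[sample(members, config$card_failures[[g]])] <- TRUE
      accel_fail[sample(members, config$accel_failures[[g]])] <- TRUE
      ret <- config$attrition_schedule[g, ]
      score <- if (config$attrition_mode == "age_linked")
        as.numeric(scale(age[members])) + stats::rnorm(length(members))
      else stats::rnorm(length(members))
      ord <- members[order(-score)]   # most dropout-prone first
      n_g <- length(members)
      cuts <- c(n_g - ret[1], ret[1] - ret[2], ret[2] - ret[3])
      at <- 0L
      for (p in 1:3) {
        take <- seq_len(cuts[p]) + at
        if (cuts[p] > 0)
          dropout[ord[take]] <- c(1L, 5L, 9L)[p]
        at <- at + cuts[p]
      }
    }
    parts <- lapply(seq_len(n), function(i) {
      generate_participant(config, groups[i], catalog = catalog,
                           participant_id = ids[i],
                           dropout_week = dropout[i],
                           card_failure = card_fail[i],
                           accel_failure = accel_fail[i],
                           demographics = list(age = age[i],
                                               gender = gender[i],
                                               bmi_class = bmi[i],
                                               household_size = hh[i]))
    })
    bind <- function(field) {
      pieces <- Filter(Negate(is.null), lapply(parts, `[[`, field))
      if (length(pieces)) do.call(rbind, pieces) else NULL
    }
    structure(list(
      participants = data.frame(
        participant_id = ids, group = groups, age = age, gender = gender,
        bmi_class = bmi, household_size = hh, card_failure = card_fail,
        accel_failure = accel_fail, dropout_week = dropout,
        stringsAsFactors = FALSE),
      steps = bind("steps"), receipts = bind("receipts"),
      logins = bind("logins"), surveys = bind("surveys"),
      catalog = catalog, config = config
    ), class = "trial_cohort")
  })
}

#' @export
print.trial_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf("Synthetic trial cohort: %d participants (%s)\n", nrow(p),
              paste(sprintf("%s n=%d", names(table(p$group)),
                            as.integer(table(p$group))), collapse = ", ")))
  cat(sprintf("  completers: %d; card failures: %d; accel failures: %d\n",
              sum(is.na(p$dropout_week)), sum(p$card_failure),
              sum(p$accel_failure)))
  cat(sprintf("  streams: %s\n", paste(x$config$streams, collapse = ", ")))
  invisible(x)
}

#' Completer flags of a cohort
#'
#' A completer has no dropout week (data through T3).
#'
#' @param cohort A `trial_cohort`.
#' @return Logical vector aligned with `cohort$participants`.
#' @export
completers <- function(cohort) is.na(cohort$participants$dropout_week)

#' Write a cohort to a directory of plain-text files
#'
#' Writes `products.csv`, `receipts.jsonl`, `steps.csv`, `logins.csv`,
#' `surveys.csv`, `participants.csv` and a `manifest.json` describing the
#' configuration.
#'
#' @param cohort A `trial_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_catalog(cohort$catalog, file.path(dir, "products.csv"))
  if (!is.null(cohort$receipts))
    write_receipts(cohort$receipts, file.path(dir, "receipts.jsonl"))
  wcsv <- function(df, f) {
    if (!is.null(df)) {
      if ("date" %in% names(df)) df$date <- format(df$date)
      utils::write.csv(df, file.path(dir, f), row.names = FALSE)
    }
  }
  wcsv(cohort$steps, "steps.csv")
  wcsv(cohort$logins, "logins.csv")
  wcsv(cohort$surveys, "surveys.csv")
  wcsv(cohort$participants, "participants.csv")
  cfg <- unclass(cohort$config)
  cfg$trial_start <- format(cfg$trial_start)
  cfg$attrition_schedule <- as.data.frame(cfg$attrition_schedule)
  manifest <- list(package = "fsanps",
                   version = as.character(utils::packageVersion("fsanps")),
                   config = cfg)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort back from a directory
#'
#' Inverse of [write_cohort()]; reconstructs the data.frames (configuration is
#' restored from the manifest for the scalar fields needed by the analysis).
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list of class `trial_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  cfg$trial_start <- as.Date(cfg$trial_start)
  cfg$attrition_schedule <- as.matrix(cfg$attrition_schedule)
  rownames(cfg$attrition_schedule) <- c("intervention", "control")
  cfg$allocation <- unlist(cfg$allocation)
  class(cfg) <- "cohort_config"
  rcsv <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    if ("date" %in% names(df)) df$date <- as.Date(df$date)
    df
  }
  steps <- rcsv("steps.csv")
  receipts_path <- file.path(dir, "receipts.jsonl")
  structure(list(
    participants = rcsv("participants.csv"),
    steps = steps,
    receipts = if (file.exists(receipts_path)) read_receipts(receipts_path)
               else NULL,
    logins = rcsv("logins.csv"),
    surveys = rcsv("surveys.csv"),
    catalog = load_catalog(file.path(dir, "products.csv"),
                           n_categories = cfg$n_categories),
    config = cfg
  ), class = "trial_cohort")
}
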