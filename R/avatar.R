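avatar_features <- function() {
  c("fitness_state", "heart_health", "mental_wellbeing",
    "bone_health", "blood_sugar")
}

#' Default avatar state thresholds
#'
#' Cut points mapping each feature's driver to a state 1 (worst) .. 5 (best).
#' Boundaries are lower-inclusive. Defaults: fitness (steps/day) states split
#' at 2500/5000/7500/10000, anchored on the 7500 steps/day activity target;
#' drivers on the 0-10 negative point scale split at 2/4/6/8 (lower points =
#' better, so the scale is reversed); drivers on the 0-5 positive point scale
#' split at 1/2/3/4.
#'
#' @param path Optional YAML file overriding the defaults, with top-level keys
#'   `fitness`, `negative`, `positive`, each `{cuts: [...], higher_is_better:
#'   true/false}`.
#' @return Named list of scale definitions.
#' @export
avatar_thresholds <- function(path = NULL) {
  defaults <- list(
    fitness  = list(cuts = c(2500, 5000, 7500, 10000), higher_is_better = TRUE,
                    domain = c(0, Inf)),
    negative = list(cuts = c(2, 4, 6, 8), higher_is_better = FALSE,
                    domain = c(0, 10)),
    positive = list(cuts = c(1, 2, 3, 4), higher_is_better = TRUE,
                    domain = c(0, 5))
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in intersect(names(user), names(defaults))) {
      if (!is.null(user[[nm]]$cuts))
        defaults[[nm]]$cuts <- as.numeric(user[[nm]]$cuts)
      if (!is.null(user[[nm]]$higher_is_better))
        defaults[[nm]]$higher_is_better <- isTRUE(user[[nm]]$higher_is_better)
    }
  }
  defaults
}

feature_scale <- function(feature) {
  switch(feature,
         fitness_state = "fitness",
         heart_health = "negative",
         blood_sugar = "negative",
         mental_wellbeing = "positive",
         bone_health = "positive",
         stop("unknown avatar feature: ", feature))
}

#' Map a driver value to an avatar state
#'
#' @param driver Driver value: mean steps/day for `fitness_state`, a
#'   component-point combination otherwise.
#' @param feature One of `fitness_state`, `heart_health`, `mental_wellbeing`,
#'   `bone_health`, `blood_sugar`.
#' @param thresholds An [avatar_thresholds()] configuration.
#' @return Integer state in 1..5 (5 best). Monotone non-decreasing in the
#'   driver for steps and positive-point drivers, non-increasing for
#'   negative-point drivers; boundaries are lower-inclusive.
#' @export
#' @examples
#' map_state(11702, "fitness_state")  # 5
#' map_state(0, "blood_sugar")        # 5 (zero sugar points is best)
map_state <- function(driver, feature, thresholds = avatar_thresholds()) {
  sc <- thresholds[[feature_scale(feature)]]
  if (!is.numeric(driver) || anyNA(driver))
    stop("driver must be numeric and non-missing")
  if (any(driver < sc$domain[1] | driver > sc$domain[2]))
    stop(sprintf("driver outside domain [%g, %g] for feature '%s'",
                 sc$domain[1], sc$domain[2], feature))
  band <- findInterval(driver, sc$cuts) + 1L   # lower-inclusive
  if (isTRUE(sc$higher_is_better)) band else length(sc$cuts) + 2L - band
}

#' Compute the five avatar feature drivers
#'
#' Fitness: mean steps/day over the 7 days ending at `as_of` (inclusive).
#' Nutritional drivers are built from the rolling 12-basket component-point
#' means: heart health = 50% sodium + 50% saturated-fat points; mental
#' well-being = 50% fruits/vegetables + 50% fiber points; bone health =
#' protein points; blood sugar = sugar points.
#'
#' @param steps Data.frame with columns `date`, `steps` (daily) for one
#'   participant.
#' @param receipts Receipt items of the same participant.
#' @param catalog An `fsa_catalog`.
#' @param as_of Evaluation date.
#' @param steps_days,baskets_n Window sizes (defaults 7 days / 12 baskets).
#' @param weighting Within-basket weighting.
#' @return Data.frame with columns `feature`, `driver`, `status`
#'   (`"ok"`/`"no data"`), `window_used`.
#' @export
compute_drivers <- function(steps, receipts, catalog, as_of,
                            steps_days = 7, baskets_n = 12,
                            weighting = c("energy", "mass")) {
  weighting <- match.arg(weighting)
  as_of <- as.Date(as_of)
  win <- seq(as_of - steps_days + 1, as_of, by = "day")
  sv <- steps$steps[steps$date %in% win]
  sv <- sv[!is.na(sv)]
  fitness <- if (length(sv)) mean(sv) else NA_real_
  roll <- rolling_component_means(receipts, catalog, window_n = baskets_n,
                                  as_of = as_of, weighting = weighting)
  m <- roll$means
  nut <- function(x) if (is.null(m)) NA_real_ else x
  drv <- data.frame(
    feature = avatar_features(),
    driver = c(fitness,
               nut(0.5 * m[["sodium_pts"]] + 0.5 * m[["satfat_pts"]]),
               nut(0.5 * m[["fvln_pts"]] + 0.5 * m[["fiber_pts"]]),
               nut(m[["protein_pts"]]),
               nut(m[["sugar_pts"]])),
    window_used = c(length(sv), rep(roll$used_count, 4)),
    stringsAsFactors = FALSE
  )
  drv$status <- ifelse(is.na(drv$driver), "no data", "ok")
  drv
}

#' Assemble the avatar state
#'
#' Evaluates all five features at `as_of` from a participant's step and basket
#' history. Features with no data in their window are reported as `"no data"`,
#' never as the worst state. The avatar itself depicts the participant aged
#' +20 years.
#'
#' @inheritParams compute_drivers
#' @param user_age Participant age in years.
#' @param thresholds An [avatar_thresholds()] configuration.
#' @return List of class `avatar_state`: `features` (data.frame with `feature`,
#'   `driver`, `state`, `status`, `window_used`), `avatar_age`, `as_of`.
#' @export
avatar_state <- function(steps, receipts, catalog, as_of, user_age,
                         steps_days = 7, baskets_n = 12,
                         thresholds = avatar_thresholds(),
                         weighting = c("energy", "mass")) {
  drv <- compute_drivers(steps, receipts, catalog, as_of,
                         steps_days = steps_days, baskets_n = baskets_n,
                         weighting = weighting)
  drv$state <- NA_integer_
  ok <- drv$status == "ok"
  drv$state[ok] <- vapply(which(ok), function(i) {
    map_state(drv$driver[i], drv$feature[i], thresholds)
  }, integer(1))
  structure(list(features = drv, avatar_age = user_age + 20,
                 as_of = as.Date(as_of)),
            class = "avatar_state")
}

#' @export
print.avatar_state <- function(x, ...) {
  cat(sprintf("Future-self avatar (age %d) as of %s\n", x$avatar_age,
              format(x$as_of)))
  f <- x$features
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-17s %s\n", f$feature[i],
                if (f$status[i] == "no data") "no data"
                else sprintf("state %d/5 (driver %.2f, window %d)",
                             f$state[i], f$driver[i], f$window_used[i])))
  }
  invisible(x)
}
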