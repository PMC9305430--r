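#' Nutrient profile of a product
#'
#' Bundles the per-100 g nutrient values consumed by the FSA-NPS scoring
#' functions. All mass-based fields are per 100 g of product; sodium is in mg
#' (use [salt_to_sodium()] if the catalog lists salt); `fvln_pct` is the
#' percentage of fruits, vegetables, legumes and nuts.
#'
#' @param energy_kj Energy density, kJ per 100 g.
#' @param sugars_g Sugars, g per 100 g.
#' @param satfat_g Saturated fatty acids, g per 100 g.
#' @param sodium_mg Sodium, mg per 100 g.
#' @param fvln_pct Fruits/vegetables/legumes/nuts, percent (0-100).
#' @param fiber_g Fiber, g per 100 g.
#' @param protein_g Protein, g per 100 g.
#' @param is_beverage Logical; beverages are scored but reported separately
#'   from solid foods.
#' @return A list of class `nutrient_profile`.
#' @export
#' @examples
#' nutrient_profile(energy_kj = 1500, sugars_g = 20, satfat_g = 5,
#'                  sodium_mg = 300, fvln_pct = 0, fiber_g = 1, protein_g = 4)
nutrient_profile <- function(energy_kj, sugars_g, satfat_g, sodium_mg,
                             fvln_pct, fiber_g, protein_g,
                             is_beverage = FALSE) {
  p <- list(energy_kj = energy_kj, sugars_g = sugars_g, satfat_g = satfat_g,
            sodium_mg = sodium_mg, fvln_pct = fvln_pct, fiber_g = fiber_g,
            protein_g = protein_g, is_beverage = isTRUE(is_beverage))
  validate_profile(p)
  structure(p, class = "nutrient_profile")
}

validate_profile <- function(p) {
  num <- c("energy_kj", "sugars_g", "satfat_g", "sodium_mg",
           "fvln_pct", "fiber_g", "protein_g")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop(sprintf("field '%s' must be finite numeric", f))
    if (any(v < 0))
      stop(sprintf("field '%s' must be non-negative", f))
  }
  if (any(p$fvln_pct > 100))
    stop("field 'fvln_pct' must be within [0, 100]")
  invisible(p)
}

#' Negative (unfavourable) component points
#'
#' Scores the four unfavourable dimensions — energy density, sugars, saturated
#' fat and sodium — each on a 0 (most healthy) to +10 (least healthy) point
#' scale, by band lookup in the threshold table.
#'
#' @param profile A [nutrient_profile()], or a data.frame with columns
#'   `energy_kj`, `sugars_g`, `satfat_g`, `sodium_mg` (vectorised).
#' @param thresholds An [fsa_thresholds()] table.
#' @return Named list (or data.frame for data.frame input) with integer
#'   `energy_pts`, `sugar_pts`, `satfat_pts`, `sodium_pts`.
#' @export
score_negative_components <- function(profile, thresholds = fsa_thresholds()) {
  df <- as_profile_frame(profile)
  out <- data.frame(
    energy_pts = points_for(df$energy_kj, thresholds$components$energy),
    sugar_pts  = points_for(df$sugars_g, thresholds$components$sugars),
    satfat_pts = points_for(df$satfat_g, thresholds$components$saturated_fat),
    sodium_pts = points_for(df$sodium_mg, thresholds$components$sodium)
  )
  if (is.data.frame(profile)) out else as.list(out)
}

#' Positive (favourable) component points
#'
#' Scores fruits/vegetables/legumes/nuts, fiber and protein, each on a
#' 0 (least healthy) to +5 (most healthy) point scale.
#'
#' @inheritParams score_negative_components
#' @return Named list (or data.frame) with integer `fvln_pts`, `fiber_pts`,
#'   `protein_pts`.
#' @export
score_positive_components <- function(profile, thresholds = fsa_thresholds()) {
  df <- as_profile_frame(profile)
  out <- data.frame(
    fvln_pts    = points_for(df$fvln_pct, thresholds$components$fvln),
    fiber_pts   = points_for(df$fiber_g, thresholds$components$fiber),
    protein_pts = points_for(df$protein_g, thresholds$components$protein)
  )
  if (is.data.frame(profile)) out else as.list(out)
}

as_profile_frame <- function(profile) {
  if (inherits(profile, "nutrient_profile")) {
    as.data.frame(unclass(profile)[1:7])
  } else if (is.data.frame(profile)) {
    need <- c("energy_kj", "sugars_g", "satfat_g", "sodium_mg",
              "fvln_pct", "fiber_g", "protein_g")
    miss <- setdiff(need, names(profile))
    if (length(miss))
      stop("profile data.frame lacks columns: ", paste(miss, collapse = ", "))
    validate_profile(profile[need])
    profile
  } else if (is.list(profile)) {
    validate_profile(profile)
    as.data.frame(profile[c("energy_kj", "sugars_g", "satfat_g", "sodium_mg",
                            "fvln_pct", "fiber_g", "protein_g")])
  } else {
    stop("profile must be a nutrient_profile, list or data.frame")
  }
}

#' Total FSA-NPS score from component points
#'
#' Total score = negative points − counted positive points, on the −15 (most
#' healthy) to +40 (least healthy) scale. Under the protein-cap rule (default
#' on), protein points are not counted when negative points reach 11 or more
#' unless the fruits/vegetables component is at its 5-point maximum.
#'
#' @param points Named list or data.frame holding the seven component point
#'   fields produced by [score_negative_components()] and
#'   [score_positive_components()].
#' @param protein_cap Logical; apply the protein-cap rule.
#' @param thresholds Threshold table whose `protein_cap` entry supplies the
#'   trigger (negative total at least 11) and exemption (fvln points = 5).
#' @return Integer score(s) in −15..+40.
#' @export
#' @examples
#' pts <- list(energy_pts = 10, sugar_pts = 10, satfat_pts = 10,
#'             sodium_pts = 10, fvln_pts = 0, fiber_pts = 0, protein_pts = 0)
#' total_fsa_score(pts)  # +40
total_fsa_score <- function(points, protein_cap = TRUE,
                            thresholds = fsa_thresholds()) {
  neg_names <- c("energy_pts", "sugar_pts", "satfat_pts", "sodium_pts")
  pos_names <- c("fvln_pts", "fiber_pts", "protein_pts")
  miss <- setdiff(c(neg_names, pos_names), names(points))
  if (length(miss))
    stop("points lacks components: ", paste(miss, collapse = ", "))
  for (nm in neg_names)
    if (any(points[[nm]] < 0 | points[[nm]] > 10))
      stop(sprintf("component '%s' outside 0..10", nm))
  for (nm in pos_names)
    if (any(points[[nm]] < 0 | points[[nm]] > 5))
      stop(sprintf("component '%s' outside 0..5", nm))
  neg <- points$energy_pts + points$sugar_pts + points$satfat_pts +
    points$sodium_pts
  cap <- thresholds$protein_cap
  trigger <- if (is.null(cap)) 11L else as.integer(cap$negative_total_at_least)
  exempt <- if (is.null(cap)) 5L else as.integer(cap$fvln_exemption_points)
  count_protein <- if (isTRUE(protein_cap)) {
    !(neg >= trigger & points$fvln_pts < exempt)
  } else {
    rep(TRUE, length(neg))
  }
  pos_counted <- points$fvln_pts + points$fiber_pts +
    ifelse(count_protein, points$protein_pts, 0L)
  as.integer(neg - pos_counted)
}

#' Full component-point breakdown of a product
#'
#' Convenience wrapper combining [score_negative_components()],
#' [score_positive_components()] and [total_fsa_score()].
#'
#' @inheritParams score_negative_components
#' @inheritParams total_fsa_score
#' @return For a single profile, a list of class `fsa_points` with the seven
#'   component point fields, `negative_total`, `positive_total` (uncapped) and
#'   `fsa_score`. For a data.frame, the same fields as columns.
#' @export
fsa_component_points <- function(profile, thresholds = fsa_thresholds(),
                                 protein_cap = TRUE) {
  df <- as_profile_frame(profile)
  neg <- score_negative_components(df, thresholds)
  pos <- score_positive_components(df, thresholds)
  pts <- cbind(neg[c("energy_pts", "sugar_pts", "satfat_pts", "sodium_pts")],
               pos[c("fvln_pts", "fiber_pts", "protein_pts")])
  pts$negative_total <- pts$energy_pts + pts$sugar_pts + pts$satfat_pts +
    pts$sodium_pts
  pts$positive_total <- pts$fvln_pts + pts$fiber_pts + pts$protein_pts
  pts$fsa_score <- total_fsa_score(pts, protein_cap = protein_cap,
                                   thresholds = thresholds)
  if (is.data.frame(profile)) pts else structure(as.list(pts), class = "fsa_points")
}

#' Total FSA-NPS score of a nutrient profile
#'
#' @inheritParams fsa_component_points
#' @return Integer score in −15..+40.
#' @export
#' @examples
#' p <- nutrient_profile(4000, 60, 20, 1200, 0, 0, 0)
#' fsa_score(p)  # +40, the least healthy possible product
fsa_score <- function(profile, thresholds = fsa_thresholds(),
                      protein_cap = TRUE) {
  pts <- fsa_component_points(profile, thresholds, protein_cap)
  if (is.data.frame(pts)) pts$fsa_score else pts$fsa_score
}

#' @export
print.fsa_points <- function(x, ...) {
  cat("FSA-NPS component points\n")
  cat(sprintf("  negative: energy %d, sugars %d, sat fat %d, sodium %d (total %d)\n",
              x$energy_pts, x$sugar_pts, x$satfat_pts, x$sodium_pts,
              x$negative_total))
  cat(sprintf("  positive: fvln %d, fiber %d, protein %d (total %d)\n",
              x$fvln_pts, x$fiber_pts, x$protein_pts, x$positive_total))
  cat(sprintf("  total score: %+d  (-15 most healthy .. +40 least healthy)\n",
              x$fsa_score))
  invisible(x)
}
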