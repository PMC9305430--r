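#' Read digital receipts
#'
#' Receipts are the item lines of loyalty-card shopping baskets. Two on-disk
#' forms are supported: a flat CSV with columns `basket_id`, `participant_id`,
#' `date` (ISO-8601), `retailer`, `product_id`, `quantity`, `mass_g`; or JSONL
#' with one basket object per line
#' (`{"basket_id":..,"participant_id":..,"date":..,"retailer":..,"items":[..]}`).
#'
#' @param path `.csv` or `.jsonl` file.
#' @return A data.frame with one row per receipt item; `date` is a `Date`.
#' @export
read_receipts <- function(path) {
  if (!file.exists(path)) stop("receipts file not found: ", path)
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      b <- jsonlite::fromJSON(lines[i])
      items <- as.data.frame(b$items)
      if (nrow(items) == 0)
        stop("basket without items at line ", i)
      if (!"mass_g" %in% names(items)) items$mass_g <- NA_real_
      if (!"quantity" %in% names(items)) items$quantity <- 1
      data.frame(basket_id = b$basket_id, participant_id = b$participant_id,
                 date = b$date, retailer = b$retailer,
                 product_id = items$product_id, quantity = items$quantity,
                 mass_g = items$mass_g, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_receipts(df)
}

validate_receipts <- function(df) {
  need <- c("basket_id", "participant_id", "date", "retailer",
            "product_id", "quantity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("receipts lack columns: ", paste(miss, collapse = ", "))
  if (!"mass_g" %in% names(df)) df$mass_g <- NA_real_
  d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(df$date))
  if (length(bad))
    stop("invalid ISO-8601 date in receipts at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  df$date <- d
  df
}

#' Write receipts as JSONL (one basket per line) or CSV
#'
#' @param receipts Receipt item data.frame (see [read_receipts()]).
#' @param path Output path; format chosen by extension (`.jsonl` or `.csv`).
#' @export
write_receipts <- function(receipts, path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    split_idx <- split(seq_len(nrow(receipts)),
                       factor(receipts$basket_id,
                              levels = unique(receipts$basket_id)))
    con <- file(path, "w")
    on.exit(close(con))
    for (idx in split_idx) {
      b <- receipts[idx, , drop = FALSE]
      obj <- list(basket_id = b$basket_id[1],
                  participant_id = b$participant_id[1],
                  date = format(b$date[1]), retailer = b$retailer[1],
                  items = data.frame(product_id = b$product_id,
                                     quantity = b$quantity,
                                     mass_g = b$mass_g))
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  } else {
    out <- receipts
    out$date <- format(out$date)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

component_point_cols <- function() {
  c("energy_pts", "sugar_pts", "satfat_pts", "sodium_pts",
    "fvln_pts", "fiber_pts", "protein_pts")
}

# Resolve receipt items against the catalog; returns items with nutrients,
# points, mass and aggregation weight. Non-food lines are dropped and counted.
resolve_items <- function(items, catalog, weighting = c("energy", "mass")) {
  weighting <- match.arg(weighting)
  idx <- match(items$product_id, catalog$product_id)
  if (anyNA(idx))
    stop("unresolvable product ids: ",
         paste(unique(items$product_id[is.na(idx)]), collapse = ", "))
  res <- cbind(items,
               catalog[idx, c("category_id", "is_beverage", "is_food",
                              "unit_mass_g", "energy_kj",
                              component_point_cols(), "fsa_score")])
  n_nonfood <- sum(!res$is_food)
  res <- res[res$is_food, , drop = FALSE]
  mass <- ifelse(is.na(res$mass_g), res$quantity * res$unit_mass_g, res$mass_g)
  res$item_mass_g <- mass
  res$item_energy_kj <- mass * res$energy_kj / 100
  res$weight <- if (weighting == "energy") res$item_energy_kj else res$item_mass_g
  attr(res, "n_skipped_nonfood") <- n_nonfood
  res
}

weighted_mean_safe <- function(x, w, mass) {
  # falls back to mass weighting when all weights are zero (e.g. energy
  # weighting of zero-energy items); NA when nothing is scoreable
  if (length(x) == 0) return(NA_real_)
  if (sum(w) <= 0) w <- mass
  if (sum(w) <= 0) return(NA_real_)
  sum(w * x) / sum(w)
}

#' Score one basket
#'
#' Computes the basket's FSA-NPS dietary index (DI): the weighted mean of
#' per-product total scores, separately for solid foods and beverages, plus
#' the weighted means of the seven component points over solid items. Weights
#' are purchased energy by default (the energy-intake weighting of the DI) or
#' purchased mass.
#'
#' @param basket Receipt item rows of a single basket (data.frame with at
#'   least `product_id` and `quantity`; `mass_g` optional).
#' @param catalog An `fsa_catalog`.
#' @param weighting `"energy"` (default) or `"mass"`.
#' @return A list of class `basket_score`: `solid_di`, `beverage_di` (NA when
#'   no beverage present), `component_means` (named length-7), `total_mass_g`,
#'   `total_energy_kj`, `n_items`, `n_skipped_nonfood`.
#' @export
score_basket <- function(basket, catalog, weighting = c("energy", "mass")) {
  weighting <- match.arg(weighting)
  if (nrow(basket) == 0) stop("basket has no items")
  res <- resolve_items(basket, catalog, weighting)
  solid <- res[!res$is_beverage, , drop = FALSE]
  bev <- res[res$is_beverage, , drop = FALSE]
  comp <- vapply(component_point_cols(), function(cc) {
    weighted_mean_safe(solid[[cc]], solid$weight, solid$item_mass_g)
  }, numeric(1))
  structure(list(
    solid_di = weighted_mean_safe(solid$fsa_score, solid$weight,
                                  solid$item_mass_g),
    beverage_di = weighted_mean_safe(bev$fsa_score, bev$weight,
                                     bev$item_mass_g),
    component_means = comp,
    total_mass_g = sum(res$item_mass_g),
    total_energy_kj = sum(res$item_energy_kj),
    n_items = nrow(res),
    n_skipped_nonfood = attr(res, "n_skipped_nonfood")
  ), class = "basket_score")
}

#' @export
print.basket_score <- function(x, ...) {
  cat(sprintf("Basket score: solid DI %.2f, beverage DI %s (%d items, %.0f g, %.0f kJ)\n",
              x$solid_di,
              if (is.na(x$beverage_di)) "absent" else sprintf("%.2f", x$beverage_di),
              x$n_items, x$total_mass_g, x$total_energy_kj))
  invisible(x)
}

# Most recent `window_n` basket ids at or before `as_of` (ties on date broken
# by basket order of appearance, most recent last).
recent_basket_ids <- function(receipts, window_n = NULL, as_of = NULL) {
  if (!is.null(as_of)) receipts <- receipts[receipts$date <= as.Date(as_of), ,
                                            drop = FALSE]
  if (nrow(receipts) == 0) return(character(0))
  first_row <- !duplicated(receipts$basket_id)
  b <- data.frame(basket_id = as.character(receipts$basket_id[first_row]),
                  date = receipts$date[first_row])
  b <- b[order(b$date, seq_len(nrow(b))), , drop = FALSE]
  ids <- b$basket_id
  if (!is.null(window_n) && length(ids) > window_n)
    ids <- ids[(length(ids) - window_n + 1):length(ids)]
  ids
}

#' Rolling component-point means over recent baskets
#'
#' Averages the per-basket component-point means over the `window_n` most
#' recent baskets (fewer when history is short), each basket counting equally.
#' This is the "average past 12 baskets" input of the avatar rules.
#'
#' @param receipts Receipt items of one participant.
#' @param catalog An `fsa_catalog`.
#' @param window_n Window length in baskets (default 12).
#' @param as_of Only baskets dated at or before this date are used
#'   (default: all).
#' @param weighting Within-basket weighting, `"energy"` or `"mass"`.
#' @return List with `means` (named length-7, NA-free when data present),
#'   `used_count`, and `status` (`"ok"` or `"insufficient history"`).
#' @export
rolling_component_means <- function(receipts, catalog, window_n = 12,
                                    as_of = NULL,
                                    weighting = c("energy", "mass")) {
  weighting <- match.arg(weighting)
  ids <- recent_basket_ids(receipts, window_n, as_of)
  if (length(ids) == 0)
    return(list(means = NULL, used_count = 0L, status = "insufficient history"))
  per_basket <- vapply(ids, function(bid) {
    sc <- score_basket(receipts[as.character(receipts$basket_id) == bid, ,
                                drop = FALSE],
                       catalog, weighting)
    sc$component_means
  }, numeric(7))
  list(means = rowMeans(per_basket, na.rm = TRUE),
       used_count = length(ids), status = "ok")
}

#' Pooled dietary index over a date range
#'
#' Pools all solid-food items purchased within `[start, end]` (inclusive) and
#' returns their item-level weighted mean FSA-NPS score — the period DI used
#' for the 4-week trial periods. This is a pooled item-level mean, not a mean
#' of basket means.
#'
#' @param receipts Receipt items of one participant.
#' @param catalog An `fsa_catalog`.
#' @param start,end Date range (inclusive).
#' @param weighting `"energy"` (default) or `"mass"`.
#' @return Numeric DI, or NA when no baskets fall in range.
#' @export
period_di <- function(receipts, catalog, start, end,
                      weighting = c("energy", "mass")) {
  period_components(receipts, catalog, start, end, weighting)$di
}

#' Pooled component-point means over a date range
#'
#' Same pooling as [period_di()] but returning the seven component means as
#' well; used for the nutritional subcategory outcomes.
#'
#' @inheritParams period_di
#' @return List with `di`, `components` (named length-7), `n_items`.
#' @export
period_components <- function(receipts, catalog, start, end,
                              weighting = c("energy", "mass")) {
  weighting <- match.arg(weighting)
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid date range")
  sel <- receipts[receipts$date >= start & receipts$date <= end, ,
                  drop = FALSE]
  if (nrow(sel) == 0)
    return(list(di = NA_real_, components = stats::setNames(
      rep(NA_real_, 7), component_point_cols()), n_items = 0L))
  res <- resolve_items(sel, catalog, weighting)
  solid <- res[!res$is_beverage, , drop = FALSE]
  comp <- vapply(component_point_cols(), function(cc) {
    weighted_mean_safe(solid[[cc]], solid$weight, solid$item_mass_g)
  }, numeric(1))
  list(di = weighted_mean_safe(solid$fsa_score, solid$weight,
                               solid$item_mass_g),
       components = comp, n_items = nrow(solid))
}
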