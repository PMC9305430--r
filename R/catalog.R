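#' Load a product catalog
#'
#' Reads a catalog of products (CSV or JSON) and scores every food product
#' under the FSA-NPS point system. Required columns: `product_id`, `name`,
#' `category_id`, `unit_mass_g`, `is_beverage`, and the seven nutrient columns
#' (`energy_kj`, `sugars_g`, `satfat_g`, `sodium_mg`, `fvln_pct`, `fiber_g`,
#' `protein_g`). An optional logical `is_food` column marks non-food lines
#' (cleaning products etc.); such rows carry no nutrient profile and are
#' skipped, with a counter, wherever baskets are scored.
#'
#' @param path CSV (or `.json`) file.
#' @param n_categories Number of food categories in the classification
#'   (default 125); food rows must have `category_id` in `1..n_categories`.
#' @param thresholds Threshold table used to score the products.
#' @return A data.frame of class `fsa_catalog` with the input columns plus the
#'   seven component point columns and `fsa_score` (NA for non-food rows).
#' @export
load_catalog <- function(path, n_categories = 125,
                         thresholds = fsa_thresholds()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  cat_df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(cat_df) == 0) {
    warning("catalog file '", path, "' is empty")
    return(as_catalog(cat_df, n_categories, thresholds, validate = FALSE))
  }
  as_catalog(cat_df, n_categories, thresholds)
}

#' Build a catalog object from a data.frame
#'
#' @param cat_df Catalog data.frame (see [load_catalog()] for the schema).
#' @inheritParams load_catalog
#' @param validate Check invariants (unique ids, categories within range,
#'   complete nutrient rows for food products).
#' @return A data.frame of class `fsa_catalog`.
#' @export
as_catalog <- function(cat_df, n_categories = 125,
                       thresholds = fsa_thresholds(), validate = TRUE) {
  if (!"is_food" %in% names(cat_df))
    cat_df$is_food <- rep(TRUE, nrow(cat_df))
  if (!"is_beverage" %in% names(cat_df))
    cat_df$is_beverage <- rep(FALSE, nrow(cat_df))
  cat_df$is_food <- as.logical(cat_df$is_food)
  cat_df$is_beverage <- as.logical(cat_df$is_beverage)
  if (validate && nrow(cat_df) > 0) {
    need <- c("product_id", "name", "category_id", "unit_mass_g")
    miss <- setdiff(need, names(cat_df))
    if (length(miss))
      stop("catalog lacks columns: ", paste(miss, collapse = ", "))
    dup <- unique(cat_df$product_id[duplicated(cat_df$product_id)])
    if (length(dup))
      stop("duplicate product_id in catalog: ", paste(dup, collapse = ", "))
    food <- which(cat_df$is_food)
    bad_cat <- food[is.na(cat_df$category_id[food]) |
                      cat_df$category_id[food] < 1 |
                      cat_df$category_id[food] > n_categories]
    if (length(bad_cat))
      stop("catalog rows with category_id outside 1..", n_categories,
           " (rows ", paste(utils::head(bad_cat, 5), collapse = ", "), ")")
    if (any(!is.na(cat_df$unit_mass_g) & cat_df$unit_mass_g <= 0))
      stop("catalog unit_mass_g must be > 0")
    nut <- c("energy_kj", "sugars_g", "satfat_g", "sodium_mg",
             "fvln_pct", "fiber_g", "protein_g")
    miss_nut <- setdiff(nut, names(cat_df))
    if (length(miss_nut))
      stop("catalog lacks nutrient columns: ", paste(miss_nut, collapse = ", "))
    bad_row <- food[rowSums(is.na(cat_df[food, nut, drop = FALSE])) > 0]
    if (length(bad_row))
      stop("malformed catalog rows (missing nutrients) at rows: ",
           paste(utils::head(bad_row, 5), collapse = ", "))
  }
  pts_cols <- c("energy_pts", "sugar_pts", "satfat_pts", "sodium_pts",
                "fvln_pts", "fiber_pts", "protein_pts",
                "negative_total", "positive_total", "fsa_score")
  for (cc in pts_cols) cat_df[[cc]] <- rep(NA_integer_, nrow(cat_df))
  if ("category_id" %in% names(cat_df))
    cat_df$category_id <- as.integer(cat_df$category_id)
  food <- which(cat_df$is_food)
  if (length(food)) {
    nut <- c("energy_kj", "sugars_g", "satfat_g", "sodium_mg",
             "fvln_pct", "fiber_g", "protein_g")
    pts <- fsa_component_points(cat_df[food, nut, drop = FALSE],
                                thresholds = thresholds)
    for (cc in pts_cols) cat_df[[cc]][food] <- pts[[cc]]
  }
  attr(cat_df, "n_categories") <- n_categories
  class(cat_df) <- c("fsa_catalog", "data.frame")
  cat_df
}

#' Write a catalog to CSV
#'
#' Point columns are dropped on write; they are recomputed on load.
#'
#' @param catalog An `fsa_catalog`.
#' @param path Output CSV path.
#' @export
write_catalog <- function(catalog, path) {
  drop <- c("energy_pts", "sugar_pts", "satfat_pts", "sodium_pts",
            "fvln_pts", "fiber_pts", "protein_pts",
            "negative_total", "positive_total", "fsa_score")
  out <- catalog[setdiff(names(catalog), drop)]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
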