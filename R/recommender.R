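negative_dimensions <- function() {
  c(sugar = "sugar_pts", sodium = "sodium_pts",
    saturated_fat = "satfat_pts", energy = "energy_pts")
}

#' Food-category contributions to negative FSA-NPS points
#'
#' Over the (up to) `n_baskets` most recent baskets, items are pooled and each
#' food category's weight-averaged contribution to the four negative point
#' dimensions (sugar, sodium, saturated fat, energy density) is computed:
#' for dimension d and category c,
#' `contribution(c, d) = sum(mass_i * points_d_i, i in c) / sum(mass_i, all i)`.
#' Contributions therefore sum, over categories, to the basket-set weighted
#' mean points of each dimension (conservation). The combined contribution is
#' the unweighted mean across the four dimensions.
#'
#' @param receipts Receipt items of one participant.
#' @param catalog An `fsa_catalog`.
#' @param n_baskets Number of most recent baskets (default 7).
#' @param as_of Optional cutoff date.
#' @param weighting Item weighting within dimensions, `"mass"` (default, the
#'   purchased-mass weighting) or `"energy"`.
#' @return Data.frame of class `category_contributions` with columns
#'   `category_id`, one per dimension, `combined`, `share_of_mass`;
#'   attributes `baskets_used`, `status`. Empty with status
#'   `"no scoreable items"` when nothing can be scored.
#' @export
category_contributions <- function(receipts, catalog, n_baskets = 7,
                                   as_of = NULL,
                                   weighting = c("mass", "energy")) {
  weighting <- match.arg(weighting)
  empty <- structure(
    data.frame(category_id = integer(0), sugar = numeric(0),
               sodium = numeric(0), saturated_fat = numeric(0),
               energy = numeric(0), combined = numeric(0),
               share_of_mass = numeric(0)),
    baskets_used = 0L, status = "no scoreable items",
    class = c("category_contributions", "data.frame"))
  ids <- recent_basket_ids(receipts, n_baskets, as_of)
  if (length(ids) == 0) return(empty)
  sel <- receipts[as.character(receipts$basket_id) %in% ids, , drop = FALSE]
  res <- resolve_items(sel, catalog,
                       weighting = if (weighting == "mass") "mass" else "energy")
  if (nrow(res) == 0) return(empty)
  w <- res$weight
  total_w <- sum(w)
  if (total_w <= 0) return(empty)
  dims <- negative_dimensions()
  agg <- stats::aggregate(
    cbind(res[, dims, drop = FALSE] * w, .w = w),
    by = list(category_id = res$category_id), FUN = sum)
  out <- data.frame(category_id = as.integer(agg$category_id))
  for (d in names(dims)) out[[d]] <- agg[[dims[[d]]]] / total_w
  out$combined <- unname(rowMeans(out[names(dims)]))
  out$share_of_mass <- agg$.w / total_w
  out <- out[order(out$category_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, baskets_used = length(ids), status = "ok",
            class = c("category_contributions", "data.frame"))
}

#' Rank problem categories
#'
#' Orders categories by descending combined contribution to negative points;
#' ties broken by larger mass share, then smaller category id. Categories
#' with zero contribution are never reported, and at most `k` are returned.
#'
#' @param contributions A [category_contributions()] result.
#' @param k Maximum number of categories (default 4, the app's limit).
#' @return Integer vector of category ids (possibly shorter than `k`).
#' @export
rank_problem_categories <- function(contributions, k = 4) {
  if (k > 4)
    warning("k > 4 exceeds the default up-to-four-categories design")
  c0 <- contributions[contributions$combined > 0, , drop = FALSE]
  if (nrow(c0) == 0) return(integer(0))
  ord <- order(-c0$combined, -c0$share_of_mass, c0$category_id)
  utils::head(c0$category_id[ord], k)
}

#' Healthier in-category product alternatives
#'
#' Candidates are same-category catalog products whose FSA-NPS score is
#' strictly below the mass-weighted mean score of the user's purchases in
#' that category, excluding the purchased products themselves, sorted by
#' ascending score (ties by product id) and truncated to `n_max`.
#'
#' @param category_id Category to search.
#' @param purchased Receipt items the user bought (data.frame with
#'   `product_id`, `quantity`, optional `mass_g`); items outside
#'   `category_id` are ignored.
#' @param catalog An `fsa_catalog`.
#' @param n_max Maximum number of alternatives (default 5).
#' @return Data.frame of catalog rows (possibly empty).
#' @export
healthier_alternatives <- function(category_id, purchased, catalog,
                                   n_max = 5) {
  in_cat <- catalog[catalog$is_food & !is.na(catalog$category_id) &
                      catalog$category_id == category_id, , drop = FALSE]
  if (nrow(in_cat) == 0) stop("category ", category_id, " not in catalog")
  res <- resolve_items(purchased, catalog, weighting = "mass")
  res <- res[res$category_id == category_id, , drop = FALSE]
  if (nrow(res) == 0) return(in_cat[0, , drop = FALSE])
  ref <- sum(res$item_mass_g * res$fsa_score) / sum(res$item_mass_g)
  cand <- in_cat[!(in_cat$product_id %in% res$product_id) &
                   in_cat$fsa_score < ref, , drop = FALSE]
  cand <- cand[order(cand$fsa_score, cand$product_id), , drop = FALSE]
  utils::head(cand, n_max)
}

#' Load a tip pack
#'
#' A tip pack maps food categories to nutrition tip ids, with a generic
#' fallback. YAML structure: `fallback: <tip id>` and `categories: {<category
#' id>: [tip ids...]}`.
#'
#' @param path YAML file; `NULL` loads the bundled pack.
#' @return List with `categories` (named list of character vectors) and
#'   `fallback`.
#' @export
tip_pack <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tips.yaml", package = "fsanps")
  raw <- yaml::read_yaml(path)
  list(categories = lapply(raw$categories, as.character),
       fallback = if (is.null(raw$fallback)) "tip_generic" else raw$fallback)
}

#' Select a nutrition tip for the top problem categories
#'
#' Deterministic: the highest-ranked category with mapped tips supplies the
#' tip; among that category's tips the least-used one (per `history`, earliest
#' listed wins ties) is chosen, so repeated weekly calls rotate through the
#' mapped tips before repeating any. With no mapped tips the generic fallback
#' is returned.
#'
#' @param top_categories Ranked category ids (from
#'   [rank_problem_categories()]).
#' @param pack A [tip_pack()].
#' @param history Character vector of previously shown tip ids.
#' @return A tip id (character scalar).
#' @export
select_tip <- function(top_categories, pack = tip_pack(),
                       history = character(0)) {
  if (length(pack$categories) == 0) {
    message("empty tip pack; using fallback tip")
    return(pack$fallback)
  }
  for (cat_id in top_categories) {
    tips <- pack$categories[[as.character(cat_id)]]
    if (!is.null(tips) && length(tips)) {
      used <- vapply(tips, function(t) sum(history == t), numeric(1))
      return(tips[[which.min(used)]])
    }
  }
  pack$fallback
}

#' Personalized basket-analysis report
#'
#' Full recommender pass: category contributions over the last `n_baskets`
#' baskets, up to `k` problem categories, healthier in-category substitutes
#' and an adapted tip.
#'
#' @inheritParams category_contributions
#' @param k Maximum problem categories (default 4).
#' @param n_alternatives Alternatives per category (default 5).
#' @param pack A [tip_pack()].
#' @param history Previously shown tip ids (for rotation).
#' @return List of class `recommendation_report`: `problem_categories`
#'   (contributions of the ranked categories, ranked order), `alternatives`
#'   (named list of catalog data.frames), `tip_id`, `baskets_used`, `status`.
#' @export
recommendation_report <- function(receipts, catalog, k = 4, n_baskets = 7,
                                  n_alternatives = 5, pack = tip_pack(),
                                  history = character(0), as_of = NULL,
                                  weighting = c("mass", "energy")) {
  weighting <- match.arg(weighting)
  contrib <- category_contributions(receipts, catalog, n_baskets = n_baskets,
                                    as_of = as_of, weighting = weighting)
  ranked <- rank_problem_categories(contrib, k = k)
  ids <- recent_basket_ids(receipts, n_baskets, as_of)
  window_items <- receipts[as.character(receipts$basket_id) %in% ids, ,
                           drop = FALSE]
  alts <- stats::setNames(lapply(ranked, function(cid) {
    healthier_alternatives(cid, window_items, catalog, n_max = n_alternatives)
  }), as.character(ranked))
  structure(list(
    problem_categories = contrib[match(ranked, contrib$category_id), ,
                                 drop = FALSE],
    alternatives = alts,
    tip_id = select_tip(ranked, pack, history),
    baskets_used = attr(contrib, "baskets_used"),
    status = attr(contrib, "status")
  ), class = "recommendation_report")
}

#' @export
print.recommendation_report <- function(x, ...) {
  cat(sprintf("Basket analysis over %d basket(s)\n", x$baskets_used))
  pc <- x$problem_categories
  if (is.null(pc) || nrow(pc) == 0) {
    cat("  no problem categories identified\n")
  } else {
    for (i in seq_len(nrow(pc))) {
      cid <- pc$category_id[i]
      n_alt <- nrow(x$alternatives[[as.character(cid)]])
      cat(sprintf("  %d. category %d: combined contribution %.3f pts (%d alternative%s)\n",
                  i, cid, pc$combined[i], n_alt, if (n_alt == 1) "" else "s"))
    }
  }
  cat("  tip:", x$tip_id, "\n")
  invisible(x)
}
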