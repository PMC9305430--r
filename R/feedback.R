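#' Default consequential feedback templates
#'
#' One template per (feature, state) pair plus a `no_data` prompt per feature.
#' Templates contain `%s`, which is replaced by the rendered driver value
#' (steps formatted with thousands separators, point drivers to one decimal).
#' The tone stays encouraging at every state.
#'
#' @param path Optional YAML file overriding individual templates; structure
#'   `feature: {state_1: ..., ..., state_5: ..., no_data: ...}`.
#' @return Nested list `templates[[feature]][[state_key]]`.
#' @export
feedback_templates <- function(path = NULL) {
  t <- list(
    fitness_state = list(
      state_1 = "You averaged %s steps/day last week. Every walk counts - even a short stroll today moves your future self forward!",
      state_2 = "You took an average %s steps/day last week. A little more movement each day will add up - you can do it!",
      state_3 = "You averaged %s steps/day last week - a solid base! Aim for 7,500 steps/day to unlock real health benefits.",
      state_4 = "Great going: %s steps/day on average last week! You are close to the top - keep walking!",
      state_5 = "You were very active last week and took an average %s steps/day! Physical activity improves your heart health, strengthens your bones, and also benefits your mental well-being! Well done, next week you can do even more.",
      no_data = "No step data for the past week yet - carry your phone with you and your fitness will show up here."
    ),
    heart_health = list(
      state_1 = "Your recent purchases average %s salt and saturated-fat points. Swapping a few items for lower-salt options will do your heart good - small steps!",
      state_2 = "Salt and saturated fat in your recent baskets average %s points. Try a lower-salt cheese or cured-meat alternative next time - your heart will thank you.",
      state_3 = "Your heart score sits mid-range (%s points). A couple of lower-fat swaps will nudge it up - you are on your way!",
      state_4 = "Nice: salt and saturated fat in your baskets are low (%s points). Keep picking those heart-friendly products!",
      state_5 = "Excellent! Your recent baskets are very low in salt and saturated fat (%s points). Your future heart is in great shape - keep it up!",
      no_data = "Connect your loyalty card and your shopping will tell us how your future heart is doing."
    ),
    mental_wellbeing = list(
      state_1 = "Fruit, vegetables and fiber average %s points in your recent baskets. Adding one portion of veg to your next shop is a great start!",
      state_2 = "Your baskets carry %s fruit-and-fiber points. A few more greens or wholegrain picks will brighten your future mood!",
      state_3 = "Fruit, vegetables and fiber are at a decent %s points. A bit more colour in the basket and you will feel the difference!",
      state_4 = "Well done - plenty of fruit, vegetables and fiber in your baskets (%s points). Keep that basket colourful!",
      state_5 = "Fantastic! Your baskets are rich in fruit, vegetables and fiber (%s points). That nourishes your future well-being - wonderful!",
      no_data = "Connect your loyalty card so your fruit and veg purchases can cheer up your future self."
    ),
    bone_health = list(
      state_1 = "Protein in your recent purchases averages %s points. Beans, dairy or fish in the next basket will strengthen your future bones!",
      state_2 = "Your baskets average %s protein points. A little more protein-rich food keeps your bones sturdy - you can build on this!",
      state_3 = "Protein sits at %s points - a fair base for your bones. One more protein-rich pick per shop and you are there!",
      state_4 = "Good work: your purchases are protein-rich (%s points). Your future bones are getting solid support!",
      state_5 = "Excellent! Plenty of protein in your baskets (%s points) - your future bones are well looked after. Keep it up!",
      no_data = "Connect your loyalty card and we will show how your purchases support your bones."
    ),
    blood_sugar = list(
      state_1 = "Sugar in your recent baskets averages %s points. Swapping one sweet item for a low-sugar option is a great first step!",
      state_2 = "Your baskets carry %s sugar points. A few low-sugar swaps will smooth your future blood sugar - nearly there!",
      state_3 = "Sugar is at a moderate %s points. Keep an eye on sweetened drinks and snacks and you will improve further!",
      state_4 = "Nice: only %s sugar points in your recent purchases. Your future blood sugar likes that!",
      state_5 = "Excellent! Your baskets are very low in sugar (%s points). Your future blood sugar is in great balance - keep going!",
      no_data = "Connect your loyalty card so we can track sugar in your purchases."
    )
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (f in intersect(names(user), names(t)))
      for (k in intersect(names(user[[f]]), names(t[[f]])))
        t[[f]][[k]] <- user[[f]][[k]]
  }
  t
}

render_driver <- function(feature, driver) {
  if (feature == "fitness_state")
    format(round(driver), big.mark = ",", scientific = FALSE, trim = TRUE)
  else
    sprintf("%.1f", driver)
}

#' Consequential feedback message for an avatar feature
#'
#' Selects the (feature, state) template and interpolates the driver value.
#' A feature without data gets its connect-your-data prompt; a missing
#' template falls back to a neutral default (logged via `message()`).
#'
#' @param feature Feature name (see [avatar_features]).
#' @param state Integer state 1..5, or `NA` for "no data".
#' @param driver Driver value to render into the template.
#' @param templates A [feedback_templates()] pack.
#' @return A non-empty character string.
#' @export
#' @examples
#' feedback_message("fitness_state", 5, 11702)
feedback_message <- function(feature, state, driver = NA,
                             templates = feedback_templates()) {
  fallback <- "Keep tracking - every healthy choice helps your future self."
  pack <- templates[[feature]]
  if (is.null(pack)) {
    message("no feedback templates for feature '", feature,
            "'; using neutral default")
    return(fallback)
  }
  key <- if (is.na(state)) "no_data" else paste0("state_", as.integer(state))
  tpl <- pack[[key]]
  if (is.null(tpl)) {
    message("no feedback template for (", feature, ", ", key,
            "); using neutral default")
    return(fallback)
  }
  if (grepl("%s", tpl, fixed = TRUE)) {
    if (is.na(driver)) driver <- 0
    sprintf(tpl, render_driver(feature, driver))
  } else {
    tpl
  }
}
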