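#' FSA-NPS band thresholds
#'
#' Loads the nutrient-profiling band table used to convert per-100 g nutrient
#' values into component points. The package ships the 2005 UK FSA band table
#' (the table underlying the Nutri-Score framework) as a YAML config; an
#' alternative table with the same schema can be supplied instead, e.g. a
#' beverage-specific variant.
#'
#' Band semantics are lower-exclusive / upper-inclusive: a value scores the
#' points of the first band whose `upper_bound` is greater than or equal to it.
#'
#' @param path Path to a YAML threshold config. `NULL` (default) loads the
#'   bundled 2005 FSA table.
#' @return A list of class `fsa_thresholds` with elements `version`,
#'   `components` (named list of band data.frames with columns `upper_bound`,
#'   `points`) and `protein_cap` (the rule that drops protein points when
#'   negative points reach a trigger level and fruit/vegetable points are below
#'   the exemption level).
#' @export
#' @examples
#' th <- fsa_thresholds()
#' th$components$sugars
fsa_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("thresholds", envir = .fsanps_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "fsa_thresholds_2005.yaml", package = "fsanps")
    default <- TRUE
  } else {
    default <- FALSE
  }
  raw <- yaml::read_yaml(path)
  comps <- lapply(raw$components, function(comp) {
    bands <- do.call(rbind, lapply(comp$bands, function(b) {
      data.frame(upper_bound = as.numeric(b$upper_bound), points = as.integer(b$points))
    }))
    if (is.unsorted(bands$upper_bound, strictly = TRUE))
      stop("threshold bands must have strictly increasing upper bounds")
    if (is.unsorted(bands$points))
      stop("threshold band points must be non-decreasing")
    if (!is.infinite(bands$upper_bound[nrow(bands)]))
      stop("last band must be unbounded (upper_bound: .inf)")
    bands
  })
  out <- structure(
    list(version = raw$version, components = comps,
         protein_cap = raw$protein_cap),
    class = "fsa_thresholds"
  )
  if (default) assign("thresholds", out, envir = .fsanps_cache)
  out
}

.fsanps_cache <- new.env(parent = emptyenv())

# Vectorised band lookup: smallest band whose upper bound is >= value.
points_for <- function(value, bands) {
  idx <- findInterval(value, bands$upper_bound, left.open = TRUE) + 1L
  bands$points[idx]
}

#' Convert salt to sodium
#'
#' Product databases sometimes list salt rather than sodium. Sodium makes up
#' 393.4 mg of every gram of sodium chloride (22.99 / 58.44 by molar mass).
#'
#' @param salt_g Salt (NaCl) in g per 100 g.
#' @return Sodium in mg per 100 g.
#' @export
#' @examples
#' salt_to_sodium(1)   # 393.4 mg
salt_to_sodium <- function(salt_g) {
  stopifnot(is.numeric(salt_g))
  if (any(salt_g < 0, na.rm = TRUE)) stop("salt_g must be non-negative")
  salt_g * 393.4
}
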