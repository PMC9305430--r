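#' Published reference values of the FutureMe trial
#'
#' The trial whose conditions the simulator emulates published group medians
#' (IQR, n) of its primary outcomes by timepoint, and its participant-flow
#' counts. These tables ship with the package as plain CSV so that headline
#' arithmetic (end-of-trial changes, attrition and gender shares) can be
#' recomputed from the printed values; they are reference inputs, not numbers
#' the package computes.
#'
#' @return `reference_outcomes()`: data.frame with `outcome`, `group`,
#'   `timepoint`, `median`, `iqr`, `n`. `reference_consort()`: named integer
#'   vector of participant-flow counts.
#' @export
reference_outcomes <- function() {
  utils::read.csv(system.file("extdata", "trial_reference_outcomes.csv",
                              package = "fsanps"), stringsAsFactors = FALSE)
}

#' @rdname reference_outcomes
#' @export
reference_consort <- function() {
  df <- utils::read.csv(system.file("extdata", "trial_reference_consort.csv",
                                    package = "fsanps"),
                        stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$count), df$stage)
}

#' Median change between two timepoints from the reference table
#'
#' @param outcome,group Row selectors of [reference_outcomes()].
#' @param from,to Timepoints (default T0 to T3).
#' @return Difference of the published medians (`to` minus `from`).
#' @export
#' @examples
#' reference_delta("steps", "intervention")     # +242.11 steps/day
#' reference_delta("solid_di", "intervention")  # -1.28 DI points
reference_delta <- function(outcome, group, from = "T0", to = "T3") {
  ref <- reference_outcomes()
  pick <- function(tp) {
    v <- ref$median[ref$outcome == outcome & ref$group == group &
                      ref$timepoint == tp]
    if (length(v) != 1) stop("no reference median for ", outcome, "/",
                             group, "/", tp)
    v
  }
  pick(to) - pick(from)
}

#' Read a daily step log
#'
#' CSV with columns `participant_id`, `date` (ISO-8601), `steps`.
#'
#' @param path CSV file.
#' @return Data.frame with `date` as `Date`.
#' @export
read_steps <- function(path) {
  if (!file.exists(path)) stop("steps file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "date", "steps")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("steps file lacks columns: ", paste(miss, collapse = ", "))
  d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad))
    stop("invalid ISO-8601 date in steps file at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  df$date <- d
  if (any(df$steps < 0, na.rm = TRUE)) stop("negative step counts")
  df
}

#' Validate a set of input files
#'
#' Checks schemas, ISO-8601 dates (with line numbers) and referential
#' integrity (every receipt product id present in the catalog) without
#' stopping at the first problem.
#'
#' @param paths Named list with any of `catalog`, `receipts`, `steps`.
#' @param n_categories Category count for catalog validation.
#' @return Data.frame `file`, `line` (NA when not line-specific), `message`;
#'   zero rows means all inputs are valid.
#' @export
validate_inputs <- function(paths, n_categories = 125) {
  report <- list()
  note <- function(file, line, msg) {
    report[[length(report) + 1L]] <<- data.frame(
      file = file, line = line, message = msg, stringsAsFactors = FALSE)
  }
  catalog <- NULL
  if (!is.null(paths$catalog)) {
    if (!file.exists(paths$catalog)) {
      note(paths$catalog, NA, "file not found")
    } else {
      catalog <- tryCatch(load_catalog(paths$catalog, n_categories),
                          error = function(e) {
                            note(paths$catalog, NA, conditionMessage(e))
                            NULL
                          },
                          warning = function(w) {
                            note(paths$catalog, NA, conditionMessage(w))
                            suppressWarnings(load_catalog(paths$catalog,
                                                          n_categories))
                          })
    }
  }
  if (!is.null(paths$receipts)) {
    if (!file.exists(paths$receipts)) {
      note(paths$receipts, NA, "file not found")
    } else if (grepl("\\.csv$", paths$receipts, ignore.case = TRUE)) {
      raw <- utils::read.csv(paths$receipts, stringsAsFactors = FALSE)
      need <- c("basket_id", "participant_id", "date", "retailer",
                "product_id", "quantity")
      miss <- setdiff(need, names(raw))
      if (length(miss)) {
        note(paths$receipts, NA,
             paste("missing columns:", paste(miss, collapse = ", ")))
      } else {
        d <- as.Date(as.character(raw$date), format = "%Y-%m-%d")
        for (i in which(is.na(d)))
          note(paths$receipts, i + 1L, "invalid ISO-8601 date")  # +header
        if (!is.null(catalog)) {
          unknown <- !(raw$product_id %in% catalog$product_id)
          for (i in which(unknown))
            note(paths$receipts, i + 1L,
                 paste0("product id '", raw$product_id[i],
                        "' not in catalog"))
        }
      }
    } else {
      rec <- tryCatch(read_receipts(paths$receipts),
                      error = function(e) {
                        note(paths$receipts, NA, conditionMessage(e))
                        NULL
                      })
      if (!is.null(rec) && !is.null(catalog)) {
        unknown <- unique(rec$product_id[!(rec$product_id %in%
                                             catalog$product_id)])
        for (u in unknown)
          note(paths$receipts, NA,
               paste0("product id '", u, "' not in catalog"))
      }
    }
  }
  if (!is.null(paths$steps)) {
    if (!file.exists(paths$steps)) {
      note(paths$steps, NA, "file not found")
    } else {
      raw <- utils::read.csv(paths$steps, stringsAsFactors = FALSE)
      need <- c("participant_id", "date", "steps")
      miss <- setdiff(need, names(raw))
      if (length(miss)) {
        note(paths$steps, NA,
             paste("missing columns:", paste(miss, collapse = ", ")))
      } else {
        d <- as.Date(as.character(raw$date), format = "%Y-%m-%d")
        for (i in which(is.na(d)))
          note(paths$steps, i + 1L, "invalid ISO-8601 date")
      }
    }
  }
  if (length(report)) do.call(rbind, report)
  else data.frame(file = character(0), line = integer(0),
                  message = character(0))
}

#' Pipeline run configuration
#'
#' @param catalog,receipts,steps Input file paths.
#' @param out Output directory.
#' @param steps_days,baskets_n,recommender_baskets,k_categories Window sizes
#'   (defaults 7 days, 12 baskets, 7 baskets, up to 4 categories).
#' @param weighting DI weighting mode.
#' @param cadence `"weekly"` or `"daily"` avatar evaluation dates.
#' @param user_age Age used for the +20-year avatar (single value applied to
#'   all participants unless a `participants.csv` with an `age` column sits
#'   next to the receipts).
#' @param thresholds,avatar_config,tips Optional config file paths.
#' @param seed Seed recorded in the manifest.
#' @return List of class `run_config`.
#' @export
run_config <- function(catalog, receipts, steps = NULL, out = tempfile("run"),
                       steps_days = 7, baskets_n = 12,
                       recommender_baskets = 7, k_categories = 4,
                       weighting = c("energy", "mass"),
                       cadence = c("weekly", "daily"), user_age = 44,
                       thresholds = NULL, avatar_config = NULL, tips = NULL,
                       seed = 1) {
  weighting <- match.arg(weighting)
  cadence <- match.arg(cadence)
  if (any(c(steps_days, baskets_n, recommender_baskets, k_categories) < 1))
    stop("window sizes must be >= 1")
  if (k_categories > 4)
    warning("k_categories > 4 exceeds the up-to-four-categories design")
  structure(list(paths = list(catalog = catalog, receipts = receipts,
                              steps = steps, thresholds = thresholds,
                              avatar_config = avatar_config, tips = tips),
                 out = out, steps_days = steps_days, baskets_n = baskets_n,
                 recommender_baskets = recommender_baskets,
                 k_categories = k_categories, weighting = weighting,
                 cadence = cadence, user_age = user_age, seed = seed),
            class = "run_config")
}

#' Run the daily-update pipeline over a set of inputs
#'
#' Mirrors the app's automated update: for every participant found in the
#' receipts (and step log), evaluates the avatar state at each cadence date
#' and produces the basket-analysis recommendation report at the final date.
#' Failures are isolated per participant (logged to stderr, run continues).
#' Outputs are written as JSON under `config$out` together with a manifest
#' carrying the package version and a hash of the configuration; equal inputs
#' and configuration yield byte-identical manifests.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `avatars` (per participant, list of
#'   `avatar_state`), `reports` (per participant `recommendation_report`),
#'   `errors` (named character), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  issues <- validate_inputs(config$paths)
  if (nrow(issues))
    stop("invalid inputs:\n",
         paste(sprintf("  %s:%s %s", issues$file, issues$line,
                       issues$message), collapse = "\n"))
  thresholds <- fsa_thresholds(config$paths$thresholds)
  catalog <- load_catalog(config$paths$catalog, thresholds = thresholds)
  receipts <- read_receipts(config$paths$receipts)
  steps <- if (!is.null(config$paths$steps)) read_steps(config$paths$steps)
           else NULL
  av_thr <- avatar_thresholds(config$paths$avatar_config)
  tips <- tip_pack(config$paths$tips)
  pids <- sort(unique(c(receipts$participant_id,
                        if (!is.null(steps)) steps$participant_id)))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  avatars <- list(); reports <- list(); errors <- character(0)
  for (pid in pids) {
    res <- tryCatch({
      rc <- receipts[receipts$participant_id == pid, , drop = FALSE]
      st <- if (is.null(steps)) data.frame(date = as.Date(character(0)),
                                           steps = numeric(0))
            else steps[steps$participant_id == pid, , drop = FALSE]
      dates <- range(c(rc$date, st$date))
      eval_dates <- seq(dates[1], dates[2],
                        by = if (config$cadence == "weekly") "week" else "day")
      if (utils::tail(eval_dates, 1) != dates[2])
        eval_dates <- c(eval_dates, dates[2])
      states <- lapply(eval_dates, function(d) {
        avatar_state(st, rc, catalog, d, user_age = config$user_age,
                     steps_days = config$steps_days,
                     baskets_n = config$baskets_n, thresholds = av_thr,
                     weighting = config$weighting)
      })
      report <- recommendation_report(rc, catalog, k = config$k_categories,
                                      n_baskets = config$recommender_baskets,
                                      pack = tips, as_of = dates[2],
                                      weighting = "mass")
      list(states = states, report = report)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[pid] <- conditionMessage(res)
      message("participant ", pid, " failed: ", conditionMessage(res))
      next
    }
    avatars[[pid]] <- res$states
    reports[[pid]] <- res$report
    out_p <- list(
      participant_id = pid,
      avatar_series = lapply(res$states, function(s) {
        list(as_of = format(s$as_of), avatar_age = s$avatar_age,
             features = s$features)
      }),
      recommendation = list(
        problem_categories = res$report$problem_categories,
        tip_id = res$report$tip_id,
        baskets_used = res$report$baskets_used,
        alternatives = lapply(res$report$alternatives, function(a) {
          a[, c("product_id", "name", "fsa_score")]
        })
      )
    )
    jsonlite::write_json(out_p,
                         file.path(config$out, paste0(pid, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(package = "fsanps",
                   version = as.character(utils::packageVersion("fsanps")),
                   config_hash = unname(tools::md5sum(tmp)),
                   n_participants = length(pids),
                   n_failed = length(errors),
                   participants = pids)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(avatars = avatars, reports = reports, errors = errors,
                 manifest = manifest))
}
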