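## FPQ scoring: ordinal consumption-frequency categories -> times-per-month
## frequencies -> component / HFC / combined-fiber-sources scores.

## Printed conversion constants for categories 1..5; category 6 maps to the
## item's daily tier (30, 45 or 60 times per month).
FREQ_BASE <- c(0.5, 1.5, 4.3, 8.6, 21.5)
VALID_TIERS <- c(30, 45, 60)

#' Default FPQ item configuration
#'
#' Returns the 18-item scoring configuration: each item's component, its
#' category-6 times-per-month tier (30/45/60 depending on how often the food
#' is plausibly eaten per day), whether it is inverse scored (the four
#' red/processed-meat items), and whether it contributes to the combined
#' fiber sources score (fiber-rich breads, vegetables, fruits, berries and
#' fresh juices).
#'
#' @return A data.frame with columns `item_id`, `component`, `daily_tier`,
#'   `inverse_scored`, `fiber_source`, `label`.
#' @seealso [read_scoring_config()] to load an alternative configuration.
#' @export
#' @examples
#' items <- default_food_items()
#' table(items$component)
default_food_items <- function() {
  path <- system.file("extdata", "fpq_items.tsv", package = "dietbiome")
  read_scoring_config(path)
}

#' Read an FPQ scoring configuration file
#'
#' The configuration is a tab-separated table (comment lines start with `#`)
#' with columns `item_id`, `component`, `daily_tier`, `inverse_scored`,
#' `fiber_source` and optionally `label`. Shipping the item-to-component map
#' as a file allows the score to be extended to the full 42-item FPQ without
#' code changes.
#'
#' @param path Path to the configuration file.
#' @return A validated data.frame of food item specifications.
#' @export
read_scoring_config <- function(path) {
  if (!file.exists(path)) stop_dietbiome("scoring config not found: ", path)
  items <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  validate_food_items(items)
}

validate_food_items <- function(items) {
  need <- c("item_id", "component", "daily_tier", "inverse_scored",
            "fiber_source")
  missing <- setdiff(need, names(items))
  if (length(missing))
    stop_dietbiome("scoring config lacks columns: ",
                   paste(missing, collapse = ", "))
  if (anyDuplicated(items$item_id))
    stop_dietbiome("duplicated item_id in scoring config")
  if (!all(items$daily_tier %in% VALID_TIERS))
    stop_dietbiome("daily_tier must be one of ",
                   paste(VALID_TIERS, collapse = ", "))
  items$inverse_scored <- as.logical(items$inverse_scored)
  items$fiber_source <- as.logical(items$fiber_source)
  if (anyNA(items$inverse_scored) || anyNA(items$fiber_source))
    stop_dietbiome("inverse_scored / fiber_source must be logical")
  items
}

#' Invert an FPQ response category
#'
#' Order-reversing bijection `c -> 7 - c` on the six consumption-frequency
#' categories, applied to red/processed-meat items before frequency
#' conversion so that low meat consumption scores high. Applying the
#' inversion twice is the identity.
#'
#' @param category Integer vector of categories in 1..6.
#' @return The inverted categories.
#' @export
#' @examples
#' invert_category(c(1, 3, 6))  # 6 4 1
invert_category <- function(category) {
  category <- check_category(category, allow_na = FALSE)
  7L - category
}

check_category <- function(category, allow_na = TRUE) {
  if (is.logical(category) && all(is.na(category)))
    category <- as.integer(category)
  if (!is.numeric(category))
    stop_dietbiome("response categories must be numeric")
  ok <- is.na(category) | (category %in% 1:6)
  if (!all(ok))
    stop_dietbiome("response categories must be integers in 1..6; offending ",
                   "values: ", paste(unique(category[!ok]), collapse = ", "))
  if (!allow_na && anyNA(category))
    stop_dietbiome("missing category not allowed here")
  as.integer(category)
}

#' Convert an FPQ response category to a times-per-month frequency
#'
#' Categories 1-5 map to the fixed constants 0.5, 1.5, 4.3, 8.6 and 21.5
#' times per month; category 6 ("once a day or more often") maps to the
#' item's daily tier (30, 45 or 60). For inverse-scored items the category
#' is first passed through [invert_category()]. Missing responses propagate
#' as `NA` (never silently zero).
#'
#' @param item A one-row data.frame (or list) with at least `daily_tier` and
#'   `inverse_scored`, as in [default_food_items()].
#' @param category Integer vector of response categories in 1..6 (NA allowed).
#' @return Numeric vector of times-per-month values.
#' @export
#' @examples
#' veg <- default_food_items()[3, ]  # fresh vegetables, tier 60
#' convert_response(veg, c(1, 3, 6)) # 0.5 4.3 60
convert_response <- function(item, category) {
  tier <- item$daily_tier
  if (is.null(tier) || !tier %in% VALID_TIERS)
    stop_dietbiome("item has no valid daily_tier")
  category <- check_category(category)
  inv <- isTRUE(as.logical(item$inverse_scored))
  eff <- category
  idx <- !is.na(category)
  if (inv) eff[idx] <- 7L - category[idx]
  out <- rep(NA_real_, length(category))
  low <- idx & eff <= 5L
  out[low] <- FREQ_BASE[eff[low]]
  out[idx & eff == 6L] <- tier
  out
}

#' Convert an FPQ response table to monthly frequencies
#'
#' @param responses A data.frame with a `participant_id` column and one
#'   column per `item_id` of the configuration, holding ordinal categories
#'   1..6 (NA for missing).
#' @param items Food item configuration; defaults to [default_food_items()].
#' @return A data.frame with `participant_id` and one times-per-month column
#'   per item; missing responses stay `NA`.
#' @export
frequencies_from_responses <- function(responses, items = default_food_items()) {
  items <- validate_food_items(items)
  if (!"participant_id" %in% names(responses))
    stop_dietbiome("response table needs a participant_id column")
  missing_items <- setdiff(items$item_id, names(responses))
  if (length(missing_items))
    stop_dietbiome("response table lacks item columns: ",
                   paste(missing_items, collapse = ", "))
  if (anyDuplicated(responses$participant_id))
    stop_dietbiome("duplicated participant_id in response table")
  out <- data.frame(participant_id = as.character(responses$participant_id),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(items))) {
    id <- items$item_id[i]
    out[[id]] <- convert_response(items[i, ], responses[[id]])
  }
  out
}

#' Component, HFC and combined fiber sources scores
#'
#' Computes the 11 component scores (each the sum of its items'
#' times-per-month frequencies), the healthy food choices (HFC) score (the
#' sum of all 11 components, red/processed meat inverse scored), and the
#' combined fiber sources score (the plain sum over the fiber-source items:
#' fiber-rich breads, vegetables, fruits, berries and fresh juices).
#' Participants with any missing scored item are flagged `complete = FALSE`
#' and get `NA` scores; they are excluded, never imputed.
#'
#' @param responses FPQ response table (see [frequencies_from_responses()]).
#' @param items Food item configuration.
#' @return A data.frame with `participant_id`, one column per component,
#'   `hfc_score`, `fiber_score` and `complete`.
#' @export
#' @examples
#' resp <- data.frame(participant_id = "p1",
#'                    as.list(setNames(rep(3, 18), default_food_items()$item_id)))
#' score_fpq(resp)$hfc_score  # 94.6 (meat categories invert 3 -> 4)
score_fpq <- function(responses, items = default_food_items()) {
  items <- validate_food_items(items)
  freqs <- frequencies_from_responses(responses, items)
  comp <- compute_component_scores(freqs, items)
  components <- setdiff(names(comp), "participant_id")
  hfc <- compute_hfc_score(comp)
  fib <- compute_fiber_score(freqs, items)
  complete <- !Reduce(`|`, lapply(freqs[items$item_id], is.na))
  n_excl <- sum(!complete)
  if (n_excl > 0)
    message(sprintf("score_fpq: %d participant(s) excluded for missing FPQ items",
                    n_excl))
  out <- comp
  out$hfc_score <- hfc
  out$fiber_score <- fib
  out$complete <- complete
  out
}

#' Per-component scores from a frequency table
#'
#' @param freqs Frequency table from [frequencies_from_responses()].
#' @param items Food item configuration.
#' @return A data.frame with `participant_id` and one column per component;
#'   a participant missing any item of a component gets `NA` for it.
#' @export
compute_component_scores <- function(freqs, items = default_food_items()) {
  items <- validate_food_items(items)
  unknown <- setdiff(items$item_id, names(freqs))
  if (length(unknown))
    stop_dietbiome("frequency table lacks item columns: ",
                   paste(unknown, collapse = ", "))
  out <- data.frame(participant_id = freqs$participant_id,
                    stringsAsFactors = FALSE)
  for (comp in unique(items$component)) {
    ids <- items$item_id[items$component == comp]
    m <- as.matrix(freqs[ids])
    out[[comp]] <- rowSums(m)          # NA if any constituent item missing
  }
  out
}

#' HFC score from component scores
#'
#' Exact sum of the 11 component scores; `NA` when any component is missing.
#'
#' @param component_scores Output of [compute_component_scores()].
#' @return Numeric vector of HFC scores.
#' @export
compute_hfc_score <- function(component_scores) {
  cols <- setdiff(names(component_scores), "participant_id")
  if (length(cols) < 1L) stop_dietbiome("no component columns present")
  rowSums(as.matrix(component_scores[cols]))
}

#' Combined fiber sources score
#'
#' Plain sum of times-per-month frequencies over the fiber-source items
#' (fiber-rich breads, vegetables, fruits, berries, fresh juices); no
#' inversion is ever applied to these items.
#'
#' @inheritParams compute_component_scores
#' @return Numeric vector of fiber scores.
#' @export
compute_fiber_score <- function(freqs, items = default_food_items()) {
  items <- validate_food_items(items)
  ids <- items$item_id[items$fiber_source]
  if (!length(ids)) stop_dietbiome("configuration defines no fiber-source items")
  unknown <- setdiff(ids, names(freqs))
  if (length(unknown))
    stop_dietbiome("frequency table lacks fiber item columns: ",
                   paste(unknown, collapse = ", "))
  rowSums(as.matrix(freqs[ids]))
}
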