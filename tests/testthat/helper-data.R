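## Small in-code fixtures shared across test files.

ITEMS <- default_food_items()

## response table where every item gets the same category
uniform_responses <- function(category, ids = "p1") {
  resp <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (it in ITEMS$item_id) resp[[it]] <- category
  resp
}

## the HFC-minimising pattern: category 1 on ordinary items, 6 on the
## inverse-scored meat items
minimizing_responses <- function(ids = "p1") {
  resp <- uniform_responses(1L, ids)
  for (it in ITEMS$item_id[ITEMS$inverse_scored]) resp[[it]] <- 6L
  resp
}

## covariate frame matching a simulated cohort
cohort_covariates <- function(cohort) {
  C <- cohort$covariates[c("age", "sex", "bmi", "smoking", "medication")]
  rownames(C) <- cohort$covariates$sample_id
  C
}

hfc_named <- function(cohort) {
  stats::setNames(cohort$scores$hfc_score, cohort$covariates$sample_id)
}
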