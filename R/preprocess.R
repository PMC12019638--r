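#' Score an 8-item CES-D battery
#'
#' Sums the eight binary CES-D items into a 0-8 depressive-symptom score.
#' Negative-statement items (e.g. "I felt depressed") count 1 when answered
#' "yes"; positive-statement items (e.g. "I enjoyed life") are reverse-coded
#' and count 1 when answered "no".
#'
#' @param items numeric or logical vector of length 8 with values 0/1
#'   ("yes" = 1). `NA` entries yield an `NA` score so the record can be
#'   excluded downstream rather than silently scored 0.
#' @param polarity character vector of length 8, each `"negative"` or
#'   `"positive"`. Default: items 1-6 negative, 7-8 positive.
#' @return integer score in 0-8, or `NA_integer_` if any item is missing.
#' @export
#' @examples
#' score_cesd(c(1, 1, 1, 0, 0, 0, 1, 1)) # 3 negatives endorsed, positives "yes"
score_cesd <- function(items, polarity = default_cesd_polarity()) {
  if (length(items) != 8L) stop_depcare("CES-D battery must have exactly 8 items")
  if (length(polarity) != 8L || !all(polarity %in% c("negative", "positive"))) {
    stop_depcare("polarity must be 8 entries of 'negative'/'positive'")
  }
  items <- as.numeric(items)
  if (any(is.na(items))) return(NA_integer_)
  if (!all(items %in% c(0, 1))) stop_depcare("CES-D items must be binary 0/1")
  as.integer(sum(items[polarity == "negative"]) +
    sum(1 - items[polarity == "positive"]))
}

#' @rdname score_cesd
#' @export
default_cesd_polarity <- function() {
  c(rep("negative", 6), rep("positive", 2))
}

# Row-wise scoring of an n x 8 item matrix; returns integer vector with NA
# for rows containing missing items.
score_cesd_matrix <- function(item_matrix, polarity = default_cesd_polarity()) {
  if (ncol(item_matrix) != 8L) stop_depcare("item matrix must have 8 columns")
  neg <- polarity == "negative"
  raw <- rowSums(item_matrix[, neg, drop = FALSE]) +
    rowSums(1 - item_matrix[, !neg, drop = FALSE])
  out <- as.integer(round(raw))
  out[!complete.cases(item_matrix)] <- NA_integer_
  out
}

#' Classify a CES-D score into a depression-severity state
#'
#' Cutoffs: 0 = none, 1-2 = mild, 3-5 = moderate, 6-8 = severe.
#'
#' @param score integer vector with values in 0-8 (`NA` allowed, propagated).
#' @return character vector over `c("none","mild","moderate","severe")`.
#' @export
classify_depression <- function(score) {
  ok <- is.na(score) | (score %in% 0:8)
  if (!all(ok)) stop_depcare("CES-D scores must be integers in [0, 8]")
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score == 0] <- "none"
  out[!is.na(score) & score >= 1 & score <= 2] <- "mild"
  out[!is.na(score) & score >= 3 & score <= 5] <- "moderate"
  out[!is.na(score) & score >= 6] <- "severe"
  out
}

#' Classify functional difficulty from ADL/IADL counts
#'
#' Categories: no difficulties; IADL difficulties only; 1-2 ADL difficulties;
#' 3 or more ADL difficulties.
#'
#' @param adl_count,iadl_count nonnegative integer vectors.
#' @return character vector over
#'   `c("none","iadl_only","adl_1_2","adl_3plus")`.
#' @export
classify_functional <- function(adl_count, iadl_count) {
  if (any(adl_count < 0, na.rm = TRUE) || any(iadl_count < 0, na.rm = TRUE)) {
    stop_depcare("ADL/IADL counts must be nonnegative")
  }
  out <- rep(NA_character_, length(adl_count))
  out[adl_count == 0 & iadl_count == 0] <- "none"
  out[adl_count == 0 & iadl_count > 0] <- "iadl_only"
  out[adl_count >= 1 & adl_count <= 2] <- "adl_1_2"
  out[adl_count >= 3] <- "adl_3plus"
  out
}

#' Derive the care mode from the two receipt flags
#'
#' @param unpaid,home logical vectors: receipt of unpaid care / formal home
#'   care.
#' @return character vector over `c("none","home_only","unpaid_only","both")`.
#' @export
derive_care_mode <- function(unpaid, home) {
  unpaid <- as.logical(unpaid)
  home <- as.logical(home)
  dplyr::case_when(
    unpaid & home ~ "both",
    unpaid & !home ~ "unpaid_only",
    !unpaid & home ~ "home_only",
    TRUE ~ "none"
  )
}

#' Total weekly care hours across ADL/IADL tasks
#'
#' @param task_hours numeric vector of per-task weekly hours (possibly empty).
#' @return total hours per week.
#' @export
total_weekly_hours <- function(task_hours) {
  if (length(task_hours) == 0) return(0)
  if (any(task_hours < 0)) stop_depcare("task hours must be nonnegative")
  sum(task_hours)
}

#' Equivalise household income
#'
#' Divides weekly household income by the household weight: 1.0 for the first
#' adult, 0.5 for each further person aged 14 and over, 0.3 for each child
#' under 14.
#'
#' @param household_income weekly income in pounds (nonnegative).
#' @param adults_14plus number of household members aged 14+ (at least 1).
#' @param children_under14 number of children under 14.
#' @return equivalised weekly income in pounds.
#' @export
#' @examples
#' equivalise_income(600, 2, 0) # 400
equivalise_income <- function(household_income, adults_14plus,
                              children_under14 = 0) {
  if (any(adults_14plus < 1)) stop_depcare("household must have at least one adult")
  if (any(household_income < 0)) stop_depcare("income must be nonnegative")
  weight <- 1 + 0.5 * (adults_14plus - 1) + 0.3 * children_under14
  household_income / weight
}

#' Build the analysis table from raw panel records
#'
#' Scores the CES-D battery, classifies depression severity and functional
#' difficulty, derives the care mode, and adds the indicator columns used by
#' the regression models. Person-waves with incomplete CES-D batteries get an
#' `NA` state and are dropped by the fitting functions.
#'
#' @param panel a panel data frame as produced by [generate_panel()] (one row
#'   per person-wave; CES-D items in columns `cesd_1` ... `cesd_8`).
#' @param polarity CES-D item polarity, see [score_cesd()].
#' @return a tibble with one row per person-wave and added columns
#'   `cesd_score`, `state`, `functional`, `care_mode`, `female`, `rented`,
#'   `educ_mid`, `educ_high`.
#' @export
prepare_panel <- function(panel, polarity = default_cesd_polarity()) {
  item_cols <- paste0("cesd_", 1:8)
  if (!all(item_cols %in% names(panel))) {
    stop_depcare("panel must contain columns ", paste(item_cols, collapse = ", "))
  }
  if (any(panel$housing_problems < 0 | panel$housing_problems > 12, na.rm = TRUE)) {
    stop_depcare("housing_problems must lie in 0-12 (instrument has 12 types)")
  }
  score <- score_cesd_matrix(as.matrix(panel[item_cols]), polarity)
  tibble::as_tibble(panel) |>
    dplyr::mutate(
      cesd_score = score,
      state = classify_depression(score),
      functional = classify_functional(.data$adl_count, .data$iadl_count),
      care_mode = derive_care_mode(.data$unpaid_care, .data$home_care),
      female = as.numeric(.data$gender == "female"),
      rented = as.numeric(.data$tenure == "rented"),
      educ_mid = as.numeric(.data$education == "nvq_gce_cse"),
      educ_high = as.numeric(.data$education == "degree_or_below")
    )
}
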