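# Annual cohort projection over single age x gender x depression state with
# absorbing mortality, boundary entrants at the youngest modelled age, and
# an open 100+ group. Counts are real-valued (expected-value cohort model).

#' Construct a state distribution
#'
#' @param year calendar year of the stock (start-of-year convention).
#' @param counts 3-d array `[age, gender, state]` over `MODEL_AGES`,
#'   `GENDERS` and the four living states; nonnegative.
#' @param cumulative_deaths deaths accumulated since the base year.
#' @return object of class `state_distribution`.
#' @export
state_distribution <- function(year, counts, cumulative_deaths = 0) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  if (any(counts < 0)) stop_depcare("state counts must be nonnegative")
  dimnames(counts) <- list(MODEL_AGES, GENDERS, DEP_STATES)
  structure(list(year = year, counts = counts,
                 cumulative_deaths = cumulative_deaths),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("State distribution, year", x$year, "\n")
  cat("  living:", format(sum(x$counts), big.mark = ","),
      " cumulative deaths:", format(round(x$cumulative_deaths),
                                    big.mark = ","), "\n")
  by_state <- apply(x$counts, 3, sum)
  cat("  by state:", paste(sprintf("%s %.0f", names(by_state), by_state),
                           collapse = ", "), "\n")
  invisible(x)
}

total_living <- function(state) sum(state$counts)

#' Initialize the base-year state distribution
#'
#' Splits the base-year population counts across depression states using
#' baseline prevalence shares (either one 4-vector for all strata, or a
#' tibble `age`, `gender`, plus one column per state).
#'
#' @param population_table tibble `age`, `gender`, `count` covering
#'   `MODEL_AGES`.
#' @param prevalence shares over the four living states; each row must sum
#'   to 1 (tolerance 1e-9).
#' @param year base year (default 2022).
#' @return a [state_distribution()].
#' @export
initialize_state <- function(population_table, prevalence, year = 2022) {
  counts <- array(0, dim = c(length(MODEL_AGES), 2, 4))
  dimnames(counts) <- list(MODEL_AGES, GENDERS, DEP_STATES)
  pt <- population_table
  if (!all(c("age", "gender", "count") %in% names(pt))) {
    stop_depcare("population table must have columns age, gender, count")
  }
  if (any(pt$count < 0)) stop_depcare("population counts must be nonnegative")
  if (!all(pt$age %in% MODEL_AGES) || !all(pt$gender %in% GENDERS)) {
    stop_depcare("population table ages/genders outside the model domain")
  }
  if (is.numeric(prevalence) && is.null(dim(prevalence))) {
    check_prob_vector(prevalence, "baseline prevalence")
    shares <- function(age, gender) prevalence
  } else {
    prev <- tibble::as_tibble(prevalence)
    if (!all(c("age", "gender", DEP_STATES) %in% names(prev))) {
      stop_depcare("prevalence table must have age, gender and state columns")
    }
    shares <- function(age, gender) {
      row <- prev[prev$age == age & prev$gender == gender, DEP_STATES]
      if (nrow(row) != 1L) stop_depcare("no prevalence row for age ", age)
      p <- as.numeric(row)
      check_prob_vector(p, "baseline prevalence row")
      p
    }
  }
  for (i in seq_len(nrow(pt))) {
    a <- as.character(pt$age[i])
    counts[a, pt$gender[i], ] <- counts[a, pt$gender[i], ] +
      pt$count[i] * shares(pt$age[i], pt$gender[i])
  }
  state_distribution(year, counts)
}

#' Advance the state distribution by one year
#'
#' Each (age, gender) living vector is multiplied by its 5x5 annual matrix;
#' survivors advance one year of age (the open 100+ group retains its
#' survivors), deaths accumulate, and entrants are injected at the youngest
#' modelled age. Conservation holds exactly:
#' `living(t+1) + new_deaths = living(t) + entrants`.
#'
#' @param state a [state_distribution()].
#' @param matrices array `[age, gender, from, to]` from
#'   [materialize_matrices()].
#' @param entrant_counts named vector `c(male=, female=)` of people entering
#'   at the youngest modelled age (default 0).
#' @param entrant_mix probability 4-vector splitting entrants across states.
#' @return the next year's [state_distribution()].
#' @export
project_one_year <- function(state, matrices,
                             entrant_counts = c(male = 0, female = 0),
                             entrant_mix = c(1, 0, 0, 0)) {
  stopifnot(inherits(state, "state_distribution"))
  dm <- dim(matrices)
  if (length(dm) != 4L || dm[1] != length(MODEL_AGES) || dm[2] != 2L ||
      dm[3] != 5L || dm[4] != 5L) {
    stop_depcare("matrices must be an [age, gender, 5, 5] array over MODEL_AGES")
  }
  check_prob_vector(entrant_mix, "entrant mix")
  new_counts <- array(0, dim = dim(state$counts),
                      dimnames = dimnames(state$counts))
  deaths <- 0
  n_age <- length(MODEL_AGES)
  for (gi in 1:2) {
    for (ai in seq_len(n_age)) {
      v <- state$counts[ai, gi, ]
      if (all(v == 0)) next
      out <- unname(drop(v %*% matrices[ai, gi, 1:4, ]))
      deaths <- deaths + out[5]
      dest <- min(ai + 1L, n_age) # 100+ pools survivors
      new_counts[dest, gi, ] <- new_counts[dest, gi, ] + out[1:4]
    }
    g <- GENDERS[gi]
    if (!is.na(entrant_counts[g]) && entrant_counts[g] > 0) {
      new_counts[1, gi, ] <- new_counts[1, gi, ] +
        entrant_counts[g] * entrant_mix
    }
  }
  state_distribution(state$year + 1L, new_counts,
                     state$cumulative_deaths + deaths)
}

#' Run the multi-year cohort projection
#'
#' Repeated application of [project_one_year()] under time-constant
#' transition matrices (homogeneous-chain assumption). By default each year
#' injects entrants at the youngest modelled age equal to the base year's
#' youngest-age stock, with its state mix.
#'
#' @param initial base-year [state_distribution()].
#' @param matrices array `[age, gender, from, to]`.
#' @param horizon_years number of annual steps (0 gives the initial state
#'   only).
#' @param entrant_counts named vector or `NULL` for the base-year default.
#' @param entrant_mix probability 4-vector or `NULL` for the base-year
#'   youngest-age mix.
#' @return named list of [state_distribution()]s, one per year including the
#'   base year.
#' @export
run_projection <- function(initial, matrices, horizon_years,
                           entrant_counts = NULL, entrant_mix = NULL) {
  stopifnot(horizon_years >= 0)
  if (is.null(entrant_counts)) {
    entrant_counts <- c(male = sum(initial$counts[1, "male", ]),
                        female = sum(initial$counts[1, "female", ]))
  }
  if (is.null(entrant_mix)) {
    tot <- sum(initial$counts[1, , ])
    entrant_mix <- if (tot > 0) {
      colSums(initial$counts[1, , , drop = TRUE]) / tot
    } else {
      c(1, 0, 0, 0)
    }
  }
  out <- vector("list", horizon_years + 1L)
  out[[1]] <- initial
  st <- initial
  for (k in seq_len(horizon_years)) {
    st <- project_one_year(st, matrices, entrant_counts, entrant_mix)
    out[[k + 1L]] <- st
  }
  names(out) <- vapply(out, function(s) as.character(s$year), character(1))
  out
}

#' Aggregate a state distribution to banded prevalence
#'
#' Pools single-year counts into age bands and reports within-band state
#' shares by gender.
#'
#' @param state a [state_distribution()].
#' @param bands named list of age vectors partitioning 65+ (default
#'   `DEFAULT_BANDS`).
#' @return tibble `year`, `band`, `gender`, `state`, `count`, `share`; the
#'   share is `NA` for empty bands.
#' @export
aggregate_prevalence <- function(state, bands = DEFAULT_BANDS) {
  stopifnot(inherits(state, "state_distribution"))
  rows <- list()
  for (b in names(bands)) {
    ages <- as.character(bands[[b]])
    for (g in GENDERS) {
      cnt <- colSums(state$counts[ages, g, , drop = FALSE][, 1, ])
      tot <- sum(cnt)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        year = state$year, band = b, gender = g, state = DEP_STATES,
        count = as.numeric(cnt),
        share = if (tot > 0) as.numeric(cnt) / tot else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Overall 65+ prevalence shares of the living states
#'
#' @param state a [state_distribution()].
#' @return named 4-vector of shares across everyone aged 65+.
#' @export
prevalence_overall <- function(state) {
  ages <- as.character(65:100)
  cnt <- apply(state$counts[ages, , , drop = FALSE], 3, sum)
  cnt / sum(cnt)
}
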