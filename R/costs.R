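# Macrosimulation: decompose the projected population into care cells,
# attach predicted utilisation probabilities and weekly hours, annualize
# with 52.14 weeks, and attach unit costs with a real growth path.

#' Cost parameters for the macrosimulation
#'
#' Unit costs are hourly, in constant 2022 prices. Under the replacement
#' approach unpaid care is valued at the home-care rate (23 pounds/hour,
#' 2022); under the opportunity approach at forgone earnings (14.8
#' pounds/hour, 2022 prices). Both unit costs follow the same real growth
#' path with a one-off 2024 uplift.
#'
#' @param unit_cost_home hourly cost of formal home care in the base year.
#' @param unit_cost_unpaid hourly value of unpaid care; defaults to the
#'   home-care rate (replacement) or 14.8 (opportunity).
#' @param weeks_per_year annualization constant (52.14).
#' @param growth scalar or per-year real growth rate of unit costs.
#' @param uplift_2024 one-off uplift factor applied at 2024.
#' @param base_year,horizon first and last year of the cost path.
#' @param costing_approach `"replacement"` or `"opportunity"`.
#' @return object of class `cost_parameters` with per-year unit-cost paths.
#' @export
cost_parameters <- function(unit_cost_home = 23,
                            unit_cost_unpaid = NULL,
                            weeks_per_year = 52.14,
                            growth = 0.013,
                            uplift_2024 = 1.035,
                            base_year = 2022,
                            horizon = 2042,
                            costing_approach = c("replacement", "opportunity")) {
  costing_approach <- match.arg(costing_approach)
  if (is.null(unit_cost_unpaid)) {
    unit_cost_unpaid <- if (costing_approach == "replacement")
      unit_cost_home else 14.8
  }
  if (unit_cost_home <= 0 || unit_cost_unpaid <= 0) {
    stop_depcare("unit costs must be positive")
  }
  if (weeks_per_year <= 0) stop_depcare("weeks_per_year must be positive")
  structure(
    list(
      unit_cost_home = unit_cost_home,
      unit_cost_unpaid = unit_cost_unpaid,
      weeks_per_year = weeks_per_year,
      costing_approach = costing_approach,
      base_year = base_year,
      horizon = horizon,
      path_home = generate_unit_cost_path(unit_cost_home, growth,
                                          uplift_2024, base_year, horizon),
      path_unpaid = generate_unit_cost_path(unit_cost_unpaid, growth,
                                            uplift_2024, base_year, horizon)
    ),
    class = "cost_parameters"
  )
}

#' Unit cost per hour in a given year
#'
#' @param params a [cost_parameters()].
#' @param year calendar year inside the cost path.
#' @param care_type `"home"` or `"unpaid"`.
#' @return pounds per hour (2022 prices, grown along the real path).
#' @export
unit_cost <- function(params, year, care_type = c("home", "unpaid")) {
  care_type <- match.arg(care_type)
  path <- if (care_type == "home") params$path_home else params$path_unpaid
  i <- match(year, path$year)
  if (any(is.na(i))) stop_depcare("year outside the unit-cost path")
  path$unit_cost[i]
}

#' Decompose banded state counts into care cells
#'
#' Splits each (band, gender, depression) count across functional-difficulty
#' categories with a conditional distribution; totals are preserved exactly.
#'
#' @param banded tibble `band`, `gender`, `depression`, `count`.
#' @param functional_conditional either a 4 x 4 matrix, rows = depression
#'   states, columns = `FUNC_LEVELS` (shared across bands and genders), or a
#'   tibble `band`, `gender`, `depression`, `functional`, `share`.
#' @return tibble of care cells `band`, `gender`, `functional`, `depression`,
#'   `count`.
#' @export
decompose_population <- function(banded, functional_conditional) {
  banded <- tibble::as_tibble(banded)
  if (!all(c("band", "gender", "depression", "count") %in% names(banded))) {
    stop_depcare("banded counts need columns band, gender, depression, count")
  }
  if (is.matrix(functional_conditional)) {
    for (i in seq_len(nrow(functional_conditional))) {
      check_prob_vector(functional_conditional[i, ],
                        "functional conditional row")
    }
    cond <- tidyr::expand_grid(
      depression = rownames(functional_conditional) %||% DEP_STATES,
      functional = FUNC_LEVELS
    )
    cond$share <- as.vector(t(functional_conditional))
    cells <- dplyr::inner_join(banded, cond, by = "depression",
                               relationship = "many-to-many")
  } else {
    cond <- tibble::as_tibble(functional_conditional)
    sums <- cond |>
      dplyr::summarise(s = sum(.data$share),
                       .by = c("band", "gender", "depression"))
    if (any(abs(sums$s - 1) > 1e-9)) {
      stop_depcare("functional conditional rows must sum to 1")
    }
    cells <- dplyr::inner_join(banded, cond,
                               by = c("band", "gender", "depression"))
  }
  if (nrow(cells) != nrow(banded) * length(FUNC_LEVELS)) {
    stop_depcare("functional conditional does not cover the cell domain")
  }
  cells |>
    dplyr::mutate(count = .data$count * .data$share) |>
    dplyr::select("band", "gender", "functional", "depression", "count")
}

#' Attach care-mode probabilities and user counts to cells
#'
#' Unpaid users per cell are `count * (p(unpaid only) + p(both))`; home-care
#' users `count * (p(home only) + p(both))`.
#'
#' @param cells care-cell tibble from [decompose_population()].
#' @param care_fit a [care_fit()].
#' @return the cells with `p_none`, `p_home_only`, `p_unpaid_only`, `p_both`,
#'   `unpaid_users`, `home_users` columns.
#' @export
compute_care_users <- function(cells, care_fit) {
  p <- predict_care_probs(care_fit, cells)
  cells$p_none <- p[, "none"]
  cells$p_home_only <- p[, "home_only"]
  cells$p_unpaid_only <- p[, "unpaid_only"]
  cells$p_both <- p[, "both"]
  cells$unpaid_users <- cells$count * (cells$p_unpaid_only + cells$p_both)
  cells$home_users <- cells$count * (cells$p_home_only + cells$p_both)
  cells
}

#' Annualize weekly care hours
#'
#' @param users number of care users.
#' @param weekly_hours average weekly hours per user.
#' @param weeks_per_year annualization constant (default 52.14).
#' @return total hours per year.
#' @export
compute_annual_hours <- function(users, weekly_hours, weeks_per_year = 52.14) {
  if (any(users < 0) || any(weekly_hours < 0)) {
    stop_depcare("users and weekly hours must be nonnegative")
  }
  users * weekly_hours * weeks_per_year
}

#' Cost of a block of annual care hours
#'
#' @param annual_hours total hours in the year.
#' @param params a [cost_parameters()].
#' @param year calendar year (must lie on the cost path).
#' @param care_type `"home"` or `"unpaid"`.
#' @return cost in pounds (2022 prices).
#' @export
compute_costs <- function(annual_hours, params, year,
                          care_type = c("home", "unpaid")) {
  care_type <- match.arg(care_type)
  if (any(annual_hours < 0)) stop_depcare("annual hours must be nonnegative")
  annual_hours * unit_cost(params, year, care_type)
}

#' Run the macrosimulation over a projected trajectory
#'
#' For every projection year: pools the 65+ population into age bands,
#' decomposes it into (band, gender, functional, depression) cells with a
#' fixed conditional functional-difficulty distribution, attaches predicted
#' care-mode probabilities and weekly hours, annualizes with
#' `weeks_per_year`, and attaches per-year unit costs. People without
#' depressive symptoms are excluded from the cost table unless
#' `include_no_symptoms = TRUE`.
#'
#' @param trajectory list of [state_distribution()]s from [run_projection()].
#' @param care_fit a [care_fit()].
#' @param hours_fit an [hours_fit()].
#' @param functional_conditional see [decompose_population()].
#' @param params a [cost_parameters()].
#' @param include_no_symptoms also cost the symptom-free population.
#' @param bands reporting age bands.
#' @return cost-table tibble: `year`, `severity`, `care_type`, `users`,
#'   `annual_hours`, `cost`.
#' @export
project_costs <- function(trajectory, care_fit, hours_fit,
                          functional_conditional, params,
                          include_no_symptoms = FALSE,
                          bands = DEFAULT_BANDS) {
  out <- vector("list", length(trajectory))
  for (i in seq_along(trajectory)) {
    state <- trajectory[[i]]
    banded <- aggregate_prevalence(state, bands) |>
      dplyr::rename(depression = "state") |>
      dplyr::select("band", "gender", "depression", "count")
    if (!include_no_symptoms) {
      banded <- dplyr::filter(banded, .data$depression != "none")
    }
    cells <- decompose_population(banded, functional_conditional)
    cells <- compute_care_users(cells, care_fit)
    cells$unpaid_weekly <- predict_hours(hours_fit, cells, "unpaid")
    cells$home_weekly <- predict_hours(hours_fit, cells, "home")
    cells$unpaid_annual <- compute_annual_hours(cells$unpaid_users,
                                                cells$unpaid_weekly,
                                                params$weeks_per_year)
    cells$home_annual <- compute_annual_hours(cells$home_users,
                                              cells$home_weekly,
                                              params$weeks_per_year)
    by_sev <- cells |>
      dplyr::summarise(
        unpaid_users = sum(.data$unpaid_users),
        home_users = sum(.data$home_users),
        unpaid_annual = sum(.data$unpaid_annual),
        home_annual = sum(.data$home_annual),
        .by = "depression"
      )
    out[[i]] <- dplyr::bind_rows(
      tibble::tibble(
        year = state$year, severity = by_sev$depression, care_type = "unpaid",
        users = by_sev$unpaid_users, annual_hours = by_sev$unpaid_annual,
        cost = compute_costs(by_sev$unpaid_annual, params, state$year,
                             "unpaid")
      ),
      tibble::tibble(
        year = state$year, severity = by_sev$depression, care_type = "home",
        users = by_sev$home_users, annual_hours = by_sev$home_annual,
        cost = compute_costs(by_sev$home_annual, params, state$year, "home")
      )
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("cost_table", class(res))
  res
}

#' Totals of a cost table by year and care type
#'
#' Sums users, hours and costs across severities; exact (pre-rounding).
#'
#' @param cost_table a cost table from [project_costs()].
#' @return tibble `year`, `care_type`, `users`, `annual_hours`, `cost`.
#' @export
summarise_cost_table <- function(cost_table) {
  dplyr::summarise(
    tibble::as_tibble(cost_table),
    users = sum(.data$users),
    annual_hours = sum(.data$annual_hours),
    cost = sum(.data$cost),
    .by = c("year", "care_type")
  )
}

#' Presentation rounding of a cost table
#'
#' Rounds user counts to thousands and costs to 0.1 billion pounds; internal
#' arithmetic stays full precision, so totals are computed before rounding.
#'
#' @param cost_table a cost table from [project_costs()].
#' @return tibble `year`, `severity`, `care_type`, `users_thousand`,
#'   `cost_bn`.
#' @export
present_cost_table <- function(cost_table) {
  tibble::as_tibble(cost_table) |>
    dplyr::transmute(
      .data$year, .data$severity, .data$care_type,
      users_thousand = round(.data$users / 1e3),
      cost_bn = round(.data$cost / 1e9, 1)
    )
}
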