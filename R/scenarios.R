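# Scenario orchestration and sensitivity machinery: housing caps,
# accelerated/delayed progression, intervention-effectiveness scaling,
# costing-approach switch, and Monte Carlo credible intervals.

#' Specify a projection scenario
#'
#' The base case is no housing intervention (`housing_cap = Inf`), no
#' progression perturbation, effectiveness factor 1 and replacement costing.
#'
#' @param name scenario label.
#' @param housing_cap maximum housing problems per dwelling
#'   (`Inf`, 2, 1 or 0).
#' @param progression_perturbation `"none"`, `"accelerated"` or `"delayed"`.
#' @param effectiveness_scale factor scaling the intervention's effect on
#'   annual transition probabilities (1 = as estimated).
#' @param costing_approach `"replacement"` or `"opportunity"`.
#' @param perturbation_magnitude multiplicative perturbation size (0.05).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = "base",
                          housing_cap = Inf,
                          progression_perturbation = c("none", "accelerated",
                                                       "delayed"),
                          effectiveness_scale = 1,
                          costing_approach = c("replacement", "opportunity"),
                          perturbation_magnitude = 0.05) {
  progression_perturbation <- match.arg(progression_perturbation)
  costing_approach <- match.arg(costing_approach)
  if (housing_cap < 0) stop_depcare("housing cap must be nonnegative")
  if (effectiveness_scale < 0) stop_depcare("effectiveness scale must be nonnegative")
  structure(list(name = name, housing_cap = housing_cap,
                 progression_perturbation = progression_perturbation,
                 effectiveness_scale = effectiveness_scale,
                 costing_approach = costing_approach,
                 perturbation_magnitude = perturbation_magnitude),
            class = "scenario_spec")
}

#' Perturb a transition matrix toward accelerated or delayed progression
#'
#' Under `"accelerated"`, every worsening entry (toward a more severe living
#' state) is multiplied by `1 + magnitude` and every improving entry by
#' `1 - magnitude`; `"delayed"` reverses the roles. The death column is
#' untouched and the diagonal is reset to restore row sums; if the perturbed
#' moves exceed the living mass, they are rescaled proportionally with a
#' warning.
#'
#' @param m 5x5 annual transition matrix.
#' @param direction `"accelerated"` or `"delayed"`.
#' @param magnitude perturbation size (default 0.05; 0 is the identity).
#' @return perturbed 5x5 row-stochastic matrix.
#' @export
perturb_transitions <- function(m, direction = c("accelerated", "delayed"),
                                magnitude = 0.05) {
  direction <- match.arg(direction)
  stopifnot(all(dim(m) == c(5, 5)))
  if (magnitude < 0) stop_depcare("magnitude must be nonnegative")
  up <- if (direction == "accelerated") 1 + magnitude else 1 - magnitude
  down <- if (direction == "accelerated") 1 - magnitude else 1 + magnitude
  out <- m
  for (i in 1:4) {
    moves <- setdiff(1:4, i)
    out[i, moves[moves > i]] <- m[i, moves[moves > i]] * up
    out[i, moves[moves < i]] <- m[i, moves[moves < i]] * down
    living_mass <- 1 - out[i, 5]
    move_sum <- sum(out[i, moves])
    if (move_sum > living_mass) {
      warning("perturbed moves exceed living mass; rescaling row ", i)
      out[i, moves] <- out[i, moves] * living_mass / move_sum
      move_sum <- living_mass
    }
    out[i, i] <- living_mass - move_sum
  }
  out
}

#' Scale the intervention effect between a base and a scenario matrix
#'
#' Off-diagonal entries are interpolated/extrapolated as
#' `base + factor * (scenario - base)` and clipped to `[0, 1]`; the diagonal
#' is restored as the row complement (proportional rescaling if needed).
#'
#' @param base,scenario 5x5 annual matrices on the same domain.
#' @param factor effectiveness factor (1 returns `scenario`, 0 returns
#'   `base`).
#' @return 5x5 row-stochastic matrix.
#' @export
scale_intervention_effect <- function(base, scenario, factor) {
  stopifnot(all(dim(base) == c(5, 5)), all(dim(scenario) == c(5, 5)))
  out <- base + factor * (scenario - base)
  for (i in 1:4) {
    off <- setdiff(1:5, i)
    out[i, off] <- pmin(pmax(out[i, off], 0), 1)
    s <- sum(out[i, off])
    if (s > 1) {
      out[i, off] <- out[i, off] / s
      s <- 1
    }
    out[i, i] <- 1 - s
  }
  out[5, ] <- c(0, 0, 0, 0, 1)
  out
}

apply_to_strata <- function(arr, f) {
  for (ai in seq_len(dim(arr)[1])) {
    for (gi in 1:2) {
      arr[ai, gi, , ] <- f(arr[ai, gi, , ])
    }
  }
  arr
}

# Assemble the transition-matrix array for one scenario spec.
scenario_matrices <- function(spec, fit, inputs) {
  base_dist <- inputs$housing_dist
  arr_base <- materialize_matrices(
    fit, dist = base_dist, mortality = inputs$mortality,
    multipliers = inputs$multipliers, state_shares = inputs$state_shares
  )
  arr <- arr_base
  if (is.finite(spec$housing_cap)) {
    scen_dist <- apply_housing_scenario(base_dist, spec$housing_cap)
    arr <- materialize_matrices(
      fit, dist = scen_dist, mortality = inputs$mortality,
      multipliers = inputs$multipliers, state_shares = inputs$state_shares
    )
    if (spec$effectiveness_scale != 1) {
      for (ai in seq_len(dim(arr)[1])) {
        for (gi in 1:2) {
          arr[ai, gi, , ] <- scale_intervention_effect(
            arr_base[ai, gi, , ], arr[ai, gi, , ], spec$effectiveness_scale
          )
        }
      }
    }
  }
  if (spec$progression_perturbation != "none") {
    arr <- apply_to_strata(arr, function(m) {
      perturb_transitions(m, spec$progression_perturbation,
                          spec$perturbation_magnitude)
    })
  }
  arr
}

default_projection_inputs <- function(config, growth = 0.013,
                                      uplift_2024 = 1.035,
                                      base_year = 2022, horizon = 2042) {
  # Expand the 4-band housing distribution of the generator config onto
  # counts 0..12 with the same truncated-geometric tail the generator uses.
  band <- config$housing_distribution
  tail_p <- 0.6
  tail <- tail_p * (1 - tail_p)^(0:9)
  tail[10] <- 1 - sum(tail[1:9]) # fold remaining mass onto 12
  dist <- c(band[1:3], band[4] * tail)
  names(dist) <- 0:12
  list(
    population = generate_population_table(config),
    mortality = generate_mortality_schedule(config),
    housing_dist = dist,
    baseline_prevalence = config$baseline_prevalence,
    functional_conditional = config$functional_conditional,
    multipliers = c(1, 1.1, 1.3, 1.6),
    state_shares = unname(config$baseline_prevalence),
    base_year = base_year,
    horizon = horizon,
    growth = growth,
    uplift_2024 = uplift_2024
  )
}

#' Run one projection scenario end to end
#'
#' Deterministic composition: scenario transition matrices, Markov cohort
#' trajectory, banded prevalence, macrosimulation costs.
#'
#' @param spec a [scenario_spec()].
#' @param fits list with elements `transition` ([transition_fit()]), `care`
#'   ([care_fit()]) and `hours` ([hours_fit()]).
#' @param inputs list with `population`, `mortality`, `housing_dist`,
#'   `baseline_prevalence`, `functional_conditional`, `multipliers`,
#'   `state_shares`, `base_year`, `horizon`, `growth`, `uplift_2024`
#'   (see [default_projection_inputs()]).
#' @return list with `spec`, `trajectory`, `prevalence` (all years) and
#'   `costs`.
#' @export
run_scenario <- function(spec, fits, inputs) {
  stopifnot(inherits(spec, "scenario_spec"))
  arr <- scenario_matrices(spec, fits$transition, inputs)
  initial <- initialize_state(inputs$population, inputs$baseline_prevalence,
                              year = inputs$base_year)
  horizon_years <- inputs$horizon - inputs$base_year
  trajectory <- run_projection(initial, arr, horizon_years)
  prevalence <- dplyr::bind_rows(lapply(trajectory, aggregate_prevalence))
  params <- cost_parameters(growth = inputs$growth,
                            uplift_2024 = inputs$uplift_2024,
                            base_year = inputs$base_year,
                            horizon = inputs$horizon,
                            costing_approach = spec$costing_approach)
  costs <- project_costs(trajectory, fits$care, fits$hours,
                         inputs$functional_conditional, params)
  list(spec = spec, trajectory = trajectory, prevalence = prevalence,
       costs = costs)
}

#' Count people with depressive symptoms (65+) per projection year
#'
#' @param result a [run_scenario()] result.
#' @return tibble `year`, `persons` (mild + moderate + severe, aged 65+).
#' @export
symptomatic_totals <- function(result) {
  dplyr::bind_rows(lapply(result$trajectory, function(s) {
    ages <- as.character(65:100)
    tibble::tibble(
      year = s$year,
      persons = sum(s$counts[ages, , DEP_STATES[-1]])
    )
  }))
}

# Default Monte Carlo measures: cost totals by care type and the number of
# people with symptoms, per year.
default_mc_measures <- function(result) {
  totals <- summarise_cost_table(result$costs)
  dplyr::bind_rows(
    tibble::tibble(measure = paste0(totals$care_type, "_cost"),
                   year = totals$year, value = totals$cost),
    tibble::tibble(measure = "people_with_symptoms",
                   year = symptomatic_totals(result)$year,
                   value = symptomatic_totals(result)$persons)
  )
}

draw_fits <- function(fits) {
  tf <- fits$transition
  if (is.null(tf$se)) stop_depcare("transition fit carries no standard errors")
  tf$coef <- tf$coef + matrix(rnorm(length(tf$coef)), nrow(tf$coef)) * tf$se
  cf <- fits$care
  if (is.null(cf$se)) stop_depcare("care fit carries no standard errors")
  cf$coef <- cf$coef + matrix(rnorm(length(cf$coef)), nrow(cf$coef)) * cf$se
  hf <- fits$hours
  if (is.null(hf$se)) stop_depcare("hours fit carries no standard errors")
  hf$coef <- hf$coef + matrix(rnorm(length(hf$coef)), nrow(hf$coef)) * hf$se
  list(transition = tf, care = cf, hours = hf)
}

#' Monte Carlo credible intervals for scenario outputs
#'
#' Each draw samples every regression coefficient independently from a
#' normal distribution on its estimation scale (log-RRR or linear), reruns
#' the full scenario pipeline, and records the measures; the 2.5th and
#' 97.5th percentiles across draws form the credible interval. Each draw
#' uses a deterministic substream derived from `(seed, draw index)`, so the
#' result is reproducible and invariant to draw order.
#'
#' @param specs list of [scenario_spec()]s.
#' @param fits fitted models as in [run_scenario()]; all three must carry
#'   standard errors.
#' @param inputs projection inputs as in [run_scenario()].
#' @param n_draws number of Monte Carlo draws (default 1000).
#' @param seed integer master seed.
#' @param measures function mapping a scenario result to a tibble
#'   `measure`, `year`, `value` (default: cost totals and symptomatic
#'   counts).
#' @return tibble `scenario`, `measure`, `year`, `point`, `lower`, `upper`,
#'   `n_draws`, with an attribute `n_rescaled` counting annualization
#'   rescaling events across draws.
#' @export
monte_carlo <- function(specs, fits, inputs, n_draws = 1000, seed = 1L,
                        measures = default_mc_measures) {
  stopifnot(n_draws >= 1)
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  draw_seeds <- withr::with_seed(seed,
                                 sample.int(.Machine$integer.max - 1L, n_draws))
  n_rescaled <- 0L
  results <- vector("list", length(specs))
  names(results) <- vapply(specs, function(s) s$name, character(1))
  point <- lapply(specs, function(sp) measures(run_scenario(sp, fits, inputs)))
  draws <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    fits_d <- withr::with_seed(draw_seeds[d], draw_fits(fits))
    per_spec <- lapply(seq_along(specs), function(si) {
      res <- run_scenario(specs[[si]], fits_d, inputs)
      m <- measures(res)
      m$scenario <- specs[[si]]$name
      m
    })
    draws[[d]] <- dplyr::bind_rows(per_spec)
  }
  all_draws <- dplyr::bind_rows(draws, .id = "draw")
  ci <- all_draws |>
    dplyr::summarise(
      lower = quantile(.data$value, 0.025, names = FALSE, type = 7),
      upper = quantile(.data$value, 0.975, names = FALSE, type = 7),
      .by = c("scenario", "measure", "year")
    )
  pts <- dplyr::bind_rows(lapply(seq_along(specs), function(si) {
    p <- point[[si]]
    p$scenario <- specs[[si]]$name
    p
  })) |>
    dplyr::rename(point = "value")
  out <- dplyr::inner_join(pts, ci, by = c("scenario", "measure", "year")) |>
    dplyr::mutate(n_draws = n_draws) |>
    dplyr::select("scenario", "measure", "year", "point", "lower", "upper",
                  "n_draws")
  if (any(out$lower > out$upper)) stop_depcare("invalid credible interval")
  attr(out, "n_rescaled") <- n_rescaled
  out
}
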