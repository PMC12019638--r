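make_counts <- function() {
  array(0, dim = c(56, 2, 4),
        dimnames = list(45:100, c("male", "female"),
                        c("none", "mild", "moderate", "severe")))
}

# array with the same 5x5 matrix in every (age, gender) stratum
uniform_matrices <- function(m) {
  arr <- array(0, dim = c(56, 2, 5, 5),
               dimnames = list(45:100, c("male", "female"),
                               c("none", "mild", "moderate", "severe", "dead"),
                               c("none", "mild", "moderate", "severe", "dead")))
  for (a in 1:56) for (g in 1:2) arr[a, g, , ] <- m
  arr
}

identity5 <- diag(5)
all_death <- rbind(cbind(matrix(0, 4, 4), rep(1, 4)), c(0, 0, 0, 0, 1))

test_that("initialization splits population counts by prevalence shares", {
  pop <- tibble::tibble(age = 70, gender = "female", count = 1000)
  st <- initialize_state(pop, c(0.48, 0.32, 0.14, 0.06))
  expect_equal(unname(st$counts["70", "female", ]), c(480, 320, 140, 60))
  expect_equal(sum(st$counts), 1000)
  zero <- initialize_state(tibble::tibble(age = 70, gender = "female",
                                          count = 0),
                           c(0.48, 0.32, 0.14, 0.06))
  expect_equal(sum(zero$counts), 0)
  expect_error(initialize_state(pop, c(0.5, 0.2, 0.1, 0.1)), "sum to 1")
  expect_error(initialize_state(tibble::tibble(age = 30, gender = "female",
                                               count = 5),
                                c(0.48, 0.32, 0.14, 0.06)), "domain")
})

test_that("identity dynamics shift ages and preserve counts", {
  counts <- make_counts()
  counts["70", "male", ] <- c(100, 50, 25, 10)
  st <- state_distribution(2022, counts)
  nxt <- project_one_year(st, uniform_matrices(identity5))
  expect_equal(unname(nxt$counts["71", "male", ]), c(100, 50, 25, 10))
  expect_equal(sum(nxt$counts), sum(st$counts))
  expect_equal(nxt$cumulative_deaths, 0)
  expect_identical(nxt$year, 2023)
})

test_that("all-death matrices absorb the whole living population", {
  counts <- make_counts()
  counts["80", "female", ] <- c(10, 20, 30, 40)
  counts["45", "male", "none"] <- 5
  st <- state_distribution(2022, counts)
  nxt <- project_one_year(st, uniform_matrices(all_death))
  expect_equal(sum(nxt$counts), 0)
  expect_equal(nxt$cumulative_deaths, 105)
})

test_that("a single-age hand example matches the matrix-vector product", {
  m <- identity5
  m[1, ] <- c(0.7, 0.2, 0.05, 0.03, 0.02)
  m[2, ] <- c(0.1, 0.6, 0.2, 0.05, 0.05)
  counts <- make_counts()
  counts["60", "female", c("none", "mild")] <- c(200, 100)
  st <- state_distribution(2022, counts)
  nxt <- project_one_year(st, uniform_matrices(m))
  hand <- 200 * m[1, 1:4] + 100 * m[2, 1:4]
  expect_equal(unname(nxt$counts["61", "female", ]), unname(hand),
               tolerance = 1e-12)
  expect_equal(nxt$cumulative_deaths, 200 * 0.02 + 100 * 0.05,
               tolerance = 1e-12)
})

test_that("the open 100+ group pools its survivors", {
  counts <- make_counts()
  counts["100", "male", "none"] <- 50
  counts["99", "male", "none"] <- 30
  st <- state_distribution(2022, counts)
  nxt <- project_one_year(st, uniform_matrices(identity5))
  expect_equal(unname(nxt$counts["100", "male", "none"]), 80)
})

test_that("trajectories equal closed-form matrix powers on an age-stable chain", {
  # everyone in the open 100+ group: no age shift, so the state vector is
  # exactly v %*% M^t
  m <- rbind(
    c(0.80, 0.15, 0.04, 0.01, 0.00),
    c(0.20, 0.60, 0.15, 0.05, 0.00),
    c(0.05, 0.25, 0.55, 0.15, 0.00),
    c(0.01, 0.09, 0.30, 0.60, 0.00),
    c(0, 0, 0, 0, 1)
  )
  counts <- make_counts()
  v <- c(400, 300, 200, 100)
  counts["100", "female", ] <- v
  st <- state_distribution(2022, counts)
  traj <- run_projection(st, uniform_matrices(m), horizon_years = 8,
                         entrant_counts = c(male = 0, female = 0))
  mk <- diag(5)
  for (k in 1:8) mk <- mk %*% m
  expect_equal(unname(traj[[9]]$counts["100", "female", ]),
               unname(drop(c(v, 0) %*% mk)[1:4]), tolerance = 1e-10)
  # horizon 0 returns the initial state only
  expect_length(run_projection(st, uniform_matrices(m), 0), 1)
})

test_that("zero-mortality chains converge to their stationary distribution", {
  m <- rbind(
    c(0.85, 0.10, 0.04, 0.01, 0),
    c(0.25, 0.60, 0.10, 0.05, 0),
    c(0.10, 0.20, 0.55, 0.15, 0),
    c(0.05, 0.10, 0.25, 0.60, 0),
    c(0, 0, 0, 0, 1)
  )
  pi_star <- depcare:::stationary_distribution(m[1:4, 1:4])
  counts <- make_counts()
  counts["100", "male", ] <- c(1000, 0, 0, 0)
  st <- state_distribution(2022, counts)
  for (i in 1:500) st <- project_one_year(st, uniform_matrices(m))
  shares <- st$counts["100", "male", ] / sum(st$counts["100", "male", ])
  expect_equal(unname(shares), pi_star, tolerance = 1e-6)
})

test_that("closed-population accounting holds exactly with entrants", {
  tf <- published_fits()$transition
  inputs <- small_inputs()
  arr <- materialize_matrices(tf, dist = inputs$housing_dist,
                              mortality = inputs$mortality)
  st <- initialize_state(inputs$population, inputs$baseline_prevalence)
  entrants <- c(male = 500, female = 600)
  mix <- c(0.5, 0.3, 0.15, 0.05)
  for (k in 1:20) {
    nxt <- project_one_year(st, arr, entrants, mix)
    lhs <- sum(nxt$counts) + (nxt$cumulative_deaths - st$cumulative_deaths)
    rhs <- sum(st$counts) + sum(entrants)
    expect_equal(lhs, rhs, tolerance = 1e-9)
    st <- nxt
  }
})

test_that("prevalence aggregation pools bands and normalizes within cells", {
  counts <- make_counts()
  counts["66", "female", ] <- c(40, 30, 20, 10)
  counts["68", "female", ] <- c(10, 20, 30, 40)
  st <- state_distribution(2030, counts)
  prev <- aggregate_prevalence(st)
  cell <- prev[prev$band == "65-69" & prev$gender == "female", ]
  expect_equal(cell$count, c(50, 50, 50, 50))
  expect_equal(cell$share, rep(0.25, 4))
  empty <- prev[prev$band == "90+" & prev$gender == "male", ]
  expect_true(all(is.na(empty$share)))

  mono <- make_counts()
  mono[as.character(65:100), , "mild"] <- 7
  stm <- state_distribution(2030, mono)
  pm <- aggregate_prevalence(stm)
  expect_true(all(pm$share[pm$state == "mild"] == 1))
  expect_equal(unname(prevalence_overall(stm)), c(0, 1, 0, 0))
})

test_that("projection of a zero population stays identically zero", {
  cfg <- generator_config(n_individuals = 10, seed = 3, population_scale = 0)
  pop <- generate_population_table(cfg)
  st <- initialize_state(pop, c(0.48, 0.32, 0.14, 0.06))
  traj <- run_projection(st, uniform_matrices(identity5), 5)
  expect_true(all(vapply(traj, function(s) sum(s$counts) == 0, logical(1))))
})
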