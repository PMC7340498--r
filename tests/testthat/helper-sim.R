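# Small simulation worlds shared across test files.

tiny_config <- function(n_units = 40, seed = 99, ...) {
  sim_config(n_units = n_units, seed = seed, ...)
}

# a compact fully simulated world
small_world <- function(config = tiny_config()) {
  units <- generate_units(config)
  population <- generate_population(units, config)
  surface <- generate_true_surface(units, config)
  deaths <- generate_deaths(units, population, surface, config)
  list(config = config, units = units, population = population,
       surface = surface, deaths = deaths)
}

# the generator's analytic risk-before-70 under its default age pattern
true_risk70 <- function(base_rate) {
  risk_before_70(unname(base_rate *
    snakeburden:::snakebite_age_multipliers()[1:14]))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
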