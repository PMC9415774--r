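# Shared fixture builders. Everything is generated in code, at small sizes.

tiny_config <- function(...) {
  world_config(
    n_districts = 3L, n_coastal = 1L,
    layers_interior = c(2L, 3L), layers_coastal = c(3L, 4L),
    capacity_mean = 8,
    ...
  )
}

tiny_world <- function(seed = 42L, ...) generate_world(tiny_config(...), seed = seed)

default_world <- function(seed = 1L, ...) generate_world(world_config(...), seed = seed)

# A minimal hand-built world with fully controlled layers, for decision tests.
# Two districts at distance 10; incomes and costs chosen to be easy to reason
# about.
toy_world <- function(credit_multiplier = 1, moving_cost_base = 5,
                      moving_cost_per_dist = 1, informal_income = 0,
                      layers = NULL) {
  districts <- data.frame(
    id = 1:2, name = c("A", "B"), coastal = c(TRUE, FALSE),
    x = c(0, 10), y = c(0, 0), base_depth = c(0.5, 0), flood_sens = c(1, 0)
  )
  if (is.null(layers)) {
    layers <- data.frame(
      id = 1:4,
      district = c(1L, 1L, 2L, 2L),
      sector = c("ag", "nonag", "ag", "nonag"),
      base_income = c(100, 150, 120, 200),
      capacity = c(5L, 5L, 5L, 5L),
      access_cost = c(10, 20, 15, 30),
      time_req = c(0.5, 0.5, 0.5, 0.5),
      amenity_value = 0,
      current_income = c(100, 150, 120, 200)
    )
  }
  cfg <- world_config(n_districts = 2L, n_coastal = 1L)
  w <- list(
    districts = districts,
    layers = layers,
    dist = as.matrix(stats::dist(districts[, c("x", "y")])),
    params = list(
      credit_multiplier = credit_multiplier,
      moving_cost_base = moving_cost_base,
      moving_cost_per_dist = moving_cost_per_dist,
      debt_interest_rate = 0,
      informal_income = informal_income,
      consumption_need = 0,
      consumption_mpc = 0,
      consumption_wealth_rate = 0,
      endowment_fraction = 0,
      income_floor = 0.01,
      quarters_per_year = 4L
    ),
    damages = data.frame(
      district = integer(), shock = numeric(),
      q_from = integer(), q_until = integer()
    ),
    config = cfg,
    seed = 0L
  )
  class(w) <- c("world", "list")
  w
}

# A bare population of n identical adults in district 1 of `world`, with
# direct control over wealth/capital/rho.
toy_population <- function(world, n = 2, wealth = 100, capital = 0, rho = 1,
                           district = 1L, disc = 0.1) {
  pop <- pop_new(max(8L, 2L * n), nrow(world$layers), world$config)
  for (i in seq_len(n)) {
    add_agent(pop, district, 30, wealth, rho, disc,
      p_rec = 0.1, p_meet = 0.05, p_int = 0.2
    )
  }
  class(pop) <- c("population", "environment")
  pop
}

# Access to internal helpers in tests regardless of how the package is loaded.
ns <- asNamespace("moorings")
pop_new <- ns$pop_new
add_agent <- ns$add_agent
mem_append <- ns$mem_append
mem_expected <- ns$mem_expected
enumerate_options <- ns$enumerate_options
option_layers <- ns$option_layers
district_subsets <- ns$district_subsets
build_subset_cache <- ns$build_subset_cache
with_seed <- ns$with_seed
kill_agent <- ns$kill_agent
expected_option_income <- ns$expected_option_income
flows_from_moves <- ns$flows_from_moves
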