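#' Build a synthetic-world configuration
#'
#' Returns the full configuration list controlling world generation: district
#' counts and geography, income-layer densities, wage/cost/capacity
#' distributions, agent heterogeneity ranges, demographic schedules, network
#' and decision parameters. Two presets are provided: `"default"`, a 20-district
#' desk-scale world, and `"bangladesh"`, a 64-district layout of which 19 are
#' flagged coastal. Any element can be overridden through `...`.
#'
#' Wages are log-normal with sector- and coastal-specific location parameters,
#' preserving the right skew of household income data without requiring any
#' restricted survey input. Geography is an abstract planar layout (coastal
#' districts along one edge) with Euclidean distances; the model only ever uses
#' relative distances for moving costs and link decay.
#'
#' @param preset `"default"` (20 districts, 6 coastal) or `"bangladesh"`
#'   (64 districts, 19 coastal).
#' @param ... named overrides of any configuration element.
#' @return A list of class `world_config`.
#' @export
#' @examples
#' cfg <- world_config(n_districts = 5, n_coastal = 2)
#' w <- generate_world(cfg, seed = 1)
world_config <- function(preset = c("default", "bangladesh"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    # geography
    n_districts = 20L,
    n_coastal = 6L,
    extent = 100,
    coastal_band = 0.2,
    # income layers: ranges of layers per district; coastal gets more
    layers_interior = c(2L, 4L),
    layers_coastal = c(3L, 6L),
    frac_nonag_interior = 0.4,
    frac_nonag_coastal = 0.6,
    # wage distribution (currency / quarter)
    wage_meanlog = log(100),
    wage_sdlog = 0.5,
    nonag_premium = 1.3,
    coastal_premium = 1.25,
    # layer capacity (concurrent holders) and access costs; entering a layer
    # costs a multiple of its quarterly wage (better jobs cost more to enter)
    capacity_mean = 10,
    access_wage_multiple = 2,
    access_sdlog = 0.4,
    access_nonag_factor = 1.4,
    time_req_values = c(0.25, 1 / 3, 0.5, 1),
    time_req_probs = c(0.2, 0.3, 0.35, 0.15),
    # place amenities (off by default; value is an income-equivalent)
    amenity = FALSE,
    amenity_value = 20,
    # flood exposure
    base_depth_coastal_meanlog = log(0.6),
    base_depth_coastal_sdlog = 0.4,
    base_depth_interior_max = 0.1,
    sens_coastal = c(0.8, 1.6),
    sens_interior = c(0, 0.15),
    # global economics
    credit_multiplier = 1.0,
    moving_cost_base = 150,
    moving_cost_per_dist = 1.5,
    debt_interest_rate = 0.05,
    informal_income = 75,
    consumption_need = 60,
    consumption_mpc = 0.5,
    consumption_wealth_rate = 0.05,
    endowment_fraction = 0.3,
    income_floor = 0.01,
    # initial agents
    wealth_meanlog = log(300),
    wealth_sdlog = 0.7,
    rho_range = c(0.3, 1.8),
    discount_range = c(0.05, 0.15),
    p_reconsider_mean = 0.1,
    p_reconsider_rel_range = c(0.5, 1.5),
    p_meet_range = c(0.02, 0.08),
    p_interact_range = c(0.1, 0.3),
    init_links_mean = 1.5,
    init_links_local_frac = 0.7,
    guarantee_placement = FALSE,
    # sub-configurations
    schedules = demography_schedules(),
    network = network_params(),
    decision = decision_params(),
    damage = damage_params()
  )
  if (preset == "bangladesh") {
    cfg$n_districts <- 64L
    cfg$n_coastal <- 19L
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop_arg("unknown config element(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_world_config(cfg)
  class(cfg) <- c("world_config", "list")
  cfg
}

validate_world_config <- function(cfg) {
  if (cfg$n_districts < 1L) stop_arg("need at least one district")
  if (cfg$n_coastal > cfg$n_districts) {
    stop_arg("coastal district count exceeds total district count")
  }
  if (cfg$n_coastal < 0L) stop_arg("coastal district count must be >= 0")
  if (!is.finite(cfg$wage_meanlog)) stop_arg("wage_meanlog must be finite")
  for (nm in c(
    "capacity_mean", "moving_cost_base", "moving_cost_per_dist",
    "consumption_need", "wage_sdlog", "access_sdlog", "access_wage_multiple"
  )) {
    check_nonneg(cfg[[nm]], nm)
  }
  if (cfg$credit_multiplier < 0 || cfg$credit_multiplier > 2) {
    stop_arg("credit_multiplier must lie in [0, 2]")
  }
  if (min(cfg$sens_coastal) <= max(cfg$sens_interior)) {
    stop_arg("coastal flood sensitivity range must sit strictly above interior range")
  }
  invisible(cfg)
}

#' Generate a synthetic world of districts and income layers
#'
#' Lays out `n_districts` districts on an abstract plane (coastal districts
#' along the low-`y` edge), assigns each a base flood depth and a flood
#' sensitivity (metres of extra peak flood depth per metre of sea-level rise;
#' strictly higher for coastal districts), and populates each district with
#' agricultural and non-agricultural income layers. Coastal districts receive
#' both a higher layer density and a wage premium, encoding the premise that
#' livelihood alternatives concentrate in coastal cities. Generation is a pure
#' function of `(config, seed)`.
#'
#' @param config a [world_config()] list.
#' @param seed integer seed; identical `(config, seed)` give identical worlds.
#' @return A list of class `world` with elements `districts` (data frame),
#'   `layers` (data frame), `dist` (district distance matrix), `params`
#'   (global economic parameters), `config`, and `seed`.
#' @export
generate_world <- function(config = world_config(), seed = 1L) {
  validate_world_config(config)
  with_seed(seed, {
    D <- config$n_districts
    nc <- config$n_coastal
    coastal <- c(rep(TRUE, nc), rep(FALSE, D - nc))
    ex <- config$extent
    band <- config$coastal_band * ex
    x <- runif(D, 0, ex)
    y <- ifelse(coastal, runif(D, 0, band), runif(D, band, ex))
    base_depth <- ifelse(
      coastal,
      rlnorm(D, config$base_depth_coastal_meanlog, config$base_depth_coastal_sdlog),
      runif(D, 0, config$base_depth_interior_max)
    )
    sens <- ifelse(
      coastal,
      runif(D, config$sens_coastal[1], config$sens_coastal[2]),
      runif(D, config$sens_interior[1], config$sens_interior[2])
    )
    districts <- data.frame(
      id = seq_len(D),
      name = sprintf("D%02d", seq_len(D)),
      coastal = coastal,
      x = x, y = y,
      base_depth = base_depth,
      flood_sens = sens
    )

    n_lay <- integer(D)
    for (d in seq_len(D)) {
      rng <- if (coastal[d]) config$layers_coastal else config$layers_interior
      n_lay[d] <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    }
    lay_district <- rep(seq_len(D), n_lay)
    nL <- length(lay_district)
    frac_nonag <- ifelse(coastal[lay_district], config$frac_nonag_coastal,
      config$frac_nonag_interior
    )
    sector <- ifelse(runif(nL) < frac_nonag, "nonag", "ag")
    premium <- ifelse(sector == "nonag", config$nonag_premium, 1) *
      ifelse(coastal[lay_district], config$coastal_premium, 1)
    base_income <- rlnorm(nL, config$wage_meanlog + log(premium), config$wage_sdlog)
    capacity <- 1L + rpois(nL, max(config$capacity_mean - 1, 0))
    access_cost <- config$access_wage_multiple * base_income *
      ifelse(sector == "nonag", config$access_nonag_factor, 1) *
      rlnorm(nL, 0, config$access_sdlog)
    time_req <- sample(config$time_req_values, nL,
      replace = TRUE, prob = config$time_req_probs
    )
    amenity_value <- rep(0, nL)
    layers <- data.frame(
      id = seq_len(nL),
      district = lay_district,
      sector = sector,
      base_income = base_income,
      capacity = capacity,
      access_cost = access_cost,
      time_req = time_req,
      amenity_value = amenity_value,
      current_income = base_income
    )
    if (isTRUE(config$amenity)) {
      am <- data.frame(
        id = nL + seq_len(D),
        district = seq_len(D),
        sector = "amenity",
        base_income = 0,
        capacity = .Machine$integer.max,
        access_cost = 0,
        time_req = 1e-6,
        amenity_value = config$amenity_value,
        current_income = 0
      )
      layers <- rbind(layers, am)
    }

    dist_mat <- as.matrix(stats::dist(cbind(x, y)))
    world <- list(
      districts = districts,
      layers = layers,
      dist = dist_mat,
      params = list(
        credit_multiplier = config$credit_multiplier,
        moving_cost_base = config$moving_cost_base,
        moving_cost_per_dist = config$moving_cost_per_dist,
        debt_interest_rate = config$debt_interest_rate,
        informal_income = config$informal_income,
        consumption_need = config$consumption_need,
        consumption_mpc = config$consumption_mpc,
        consumption_wealth_rate = config$consumption_wealth_rate,
        endowment_fraction = config$endowment_fraction,
        income_floor = config$income_floor,
        quarters_per_year = 4L
      ),
      damages = data.frame(
        district = integer(), shock = numeric(),
        q_from = integer(), q_until = integer()
      ),
      config = config,
      seed = seed
    )
    class(world) <- c("world", "list")
    world
  })
}

#' @export
print.world <- function(x, ...) {
  cat(
    "<world>", nrow(x$districts), "districts (",
    sum(x$districts$coastal), "coastal ),", nrow(x$layers), "layers\n"
  )
  invisible(x)
}

#' Write / read a world configuration document
#'
#' Configurations serialize to YAML (sub-configurations included). Reading
#' rebuilds the object through [world_config()], so all validation applies.
#' A complete example of the schema ships with the package:
#' `system.file("extdata", "example-world-config.yaml", package = "moorings")`.
#'
#' @param config a [world_config()] list.
#' @param path file path.
#' @export
write_world_config <- function(config, path) {
  plain <- rapply(unclass(config), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else unclass(x)
  }, how = "replace")
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname write_world_config
#' @export
read_world_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$schedules <- demography_schedules(
    fertility = as.data.frame(raw$schedules$fertility),
    mortality = as.data.frame(raw$schedules$mortality),
    adult_age = raw$schedules$adult_age
  )
  raw$network <- do.call(network_params, c(
    raw$network[setdiff(names(raw$network), "meet_weights")],
    list(meet_weights = unlist(raw$network$meet_weights))
  ))
  raw$decision <- do.call(decision_params, raw$decision)
  raw$damage <- do.call(damage_params, raw$damage)
  preset <- raw$preset
  raw$preset <- NULL
  do.call(world_config, c(list(preset = preset), raw))
}

#' Serialize a world to JSON / read it back
#'
#' @param world a `world` object.
#' @param path file path.
#' @return `write_world` invisibly returns `path`; `read_world` returns the
#'   `world`.
#' @export
write_world <- function(world, path) {
  out <- list(
    districts = world$districts,
    layers = world$layers,
    params = world$params,
    seed = world$seed
  )
  jsonlite::write_json(out, path,
    dataframe = "columns", auto_unbox = TRUE,
    digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_world
#' @export
read_world <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  world <- list(
    districts = as.data.frame(raw$districts),
    layers = as.data.frame(raw$layers),
    dist = as.matrix(stats::dist(cbind(raw$districts$x, raw$districts$y))),
    params = raw$params,
    damages = data.frame(
      district = integer(), shock = numeric(),
      q_from = integer(), q_until = integer()
    ),
    config = NULL,
    seed = raw$seed
  )
  class(world) <- c("world", "list")
  world
}
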