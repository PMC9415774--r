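#' Sea-level / flood scenarios
#'
#' A flood scenario couples a piecewise-linear sea-level-rise trajectory to
#' the per-district flood model. Named presets follow the usual emissions
#' pathway labels with end-of-century rise of 0.40 m (`rcp26`), 0.55 m
#' (`rcp45`) and 0.85 m (`rcp85`), linear from the start year; `baseline` has
#' zero rise throughout (the null-hazard control). Annual peak depths get
#' zero-mean Gumbel annual-extreme noise of scale `beta` metres. The
#' perceived-normal multiplier `m` (in `[0.5, 1.5]`) sets the depth, as a
#' multiple of the expected depth, below which flooding is experienced as
#' normal and causes no damage.
#'
#' @param name one of `"rcp26"`, `"rcp45"`, `"rcp85"`, `"baseline"`.
#' @param m perceived-normal multiplier in `[0.5, 1.5]`.
#' @param beta Gumbel scale (metres) of annual-extreme noise.
#' @param start_year,end_year trajectory domain.
#' @param slr_end metres of sea-level rise at `end_year`; defaults by preset.
#' @return A list of class `flood_scenario` with a `slr(year)` function.
#' @export
flood_scenario <- function(name = c("baseline", "rcp26", "rcp45", "rcp85"),
                           m = 1, beta = 0.4,
                           start_year = 2010, end_year = 2100,
                           slr_end = NULL) {
  name <- match.arg(name)
  if (m < 0.5 || m > 1.5) stop_arg("perceived-normal multiplier m must lie in [0.5, 1.5]")
  check_nonneg(beta, "beta")
  if (is.null(slr_end)) {
    slr_end <- switch(name, baseline = 0, rcp26 = 0.40, rcp45 = 0.55, rcp85 = 0.85)
  }
  force(start_year); force(end_year); force(slr_end)
  structure(
    list(
      name = name, m = m, beta = beta,
      start_year = start_year, end_year = end_year, slr_end = slr_end,
      slr = function(year) {
        if (any(year < start_year | year > end_year)) {
          stop_arg("year outside scenario trajectory domain [", start_year, ", ", end_year, "]")
        }
        slr_end * (year - start_year) / max(end_year - start_year, 1)
      }
    ),
    class = c("flood_scenario", "list")
  )
}

#' Expected annual peak flood depth
#'
#' Deterministic component of the flood model: `b_d + s_d * SLR(year)`, where
#' `b_d` is the district's base peak depth and `s_d` its sensitivity to
#' sea-level rise.
#'
#' @param world a world.
#' @param district district id(s).
#' @param year calendar year within the scenario trajectory domain.
#' @param scenario a [flood_scenario()].
#' @return expected peak depth in metres (vectorized over `district`).
#' @export
expected_peak_depth <- function(world, district, year, scenario) {
  d <- world$districts
  if (any(!district %in% d$id)) stop_arg("unknown district id")
  d$base_depth[district] + d$flood_sens[district] * scenario$slr(year)
}

#' Sample a realized annual peak flood depth
#'
#' Expected peak depth plus a zero-mean Gumbel annual-extreme deviate of scale
#' `scenario$beta`, truncated below at zero.
#'
#' @inheritParams expected_peak_depth
#' @return realized depth in metres (vectorized over `district`).
#' @export
sample_annual_flood <- function(world, district, year, scenario) {
  mu <- expected_peak_depth(world, district, year, scenario)
  pmax(0, mu + rgumbel0(length(mu), scenario$beta))
}

#' Flood shock relative to the perceived-normal depth
#'
#' `max(0, depth - m * expected_depth)`: only flooding beyond `m` times the
#' expected (statistical-mean) depth is experienced as a shock. The bound
#' `m` in `[0.5, 1.5]` is the fixed Monte-Carlo experiment range.
#'
#' @param depth realized peak depth (m).
#' @param expected_depth expected peak depth (m).
#' @param m perceived-normal multiplier in `[0.5, 1.5]`.
#' @return shock in metres, `>= 0`.
#' @export
flood_shock <- function(depth, expected_depth, m) {
  check_nonneg(depth, "depth")
  check_nonneg(expected_depth, "expected_depth")
  if (any(m < 0.5 | m > 1.5)) stop_arg("m must lie in [0.5, 1.5]")
  pmax(0, depth - m * expected_depth)
}

#' Damage parameters
#'
#' Per-metre damage rates for agricultural and non-agricultural wages and the
#' number of quarters a damage window persists. Agricultural wages must be at
#' least as flood-sensitive as non-agricultural wages (`delta_ag >=
#' delta_nonag`), which drives the flood-induced transition from agricultural
#' to non-agricultural income.
#'
#' @param delta_ag,delta_nonag per-metre damage rates (1/m).
#' @param recovery_quarters quarters a damage window lasts (`>= 1`).
#' @export
damage_params <- function(delta_ag = 0.5, delta_nonag = 0.2, recovery_quarters = 4L) {
  check_nonneg(delta_nonag, "delta_nonag")
  if (delta_ag < delta_nonag) stop_arg("delta_ag must be >= delta_nonag")
  if (recovery_quarters < 1) stop_arg("recovery_quarters must be >= 1")
  structure(
    list(
      delta_ag = delta_ag, delta_nonag = delta_nonag,
      recovery_quarters = as.integer(recovery_quarters)
    ),
    class = c("damage_params", "list")
  )
}

#' Wage damage fraction from a flood shock
#'
#' Saturating-exponential damage: `1 - exp(-delta * shock)`, strictly
#' increasing in the shock, zero at zero shock, and bounded below 1 for any
#' finite shock.
#'
#' @param shock flood shock in metres (`>= 0`).
#' @param delta per-metre damage rate (`>= 0`).
#' @return damaged fraction of the wage, in `[0, 1)`.
#' @export
wage_damage_fraction <- function(shock, delta) {
  check_nonneg(shock, "shock")
  check_nonneg(delta, "delta")
  -expm1(-delta * shock)
}

#' Apply flood shocks to a world's wages
#'
#' For every income layer in a shocked district, the current income becomes
#' `base_income * (1 - wage_damage_fraction(shock, delta_sector))` for the next
#' `recovery_quarters` quarters. Overlapping damage windows take the maximum
#' damage fraction, not the product. Damages affect wages, never agent wealth
#' stocks directly.
#'
#' @param world a world.
#' @param shocks data frame with columns `district`, `year`, `depth`,
#'   `expected_depth`, `shock` (see [flood_shock()]); at most one row per
#'   district-year.
#' @param params a [damage_params()] object.
#' @param quarter simulation quarter at which the shocks land (damage windows
#'   run from `quarter` to `quarter + recovery_quarters - 1`).
#' @return the world with its damage registry and current incomes updated.
#' @export
apply_damages <- function(world, shocks, params, quarter = 1L) {
  if (nrow(shocks)) {
    if (any(!shocks$district %in% world$districts$id)) {
      stop_arg("shock references an unknown district id")
    }
    keep <- shocks$shock > 0
    if (any(keep)) {
      world$damages <- rbind(world$damages, data.frame(
        district = shocks$district[keep],
        shock = shocks$shock[keep],
        q_from = as.integer(quarter),
        q_until = as.integer(quarter) + params$recovery_quarters - 1L
      ))
    }
  }
  refresh_layer_incomes(world, quarter, params)
}

#' @rdname apply_damages
#' @export
refresh_layer_incomes <- function(world, quarter, params) {
  reg <- world$damages
  reg <- reg[reg$q_until >= quarter, , drop = FALSE]
  world$damages <- reg
  active <- reg[reg$q_from <= quarter, , drop = FALSE]
  D <- nrow(world$districts)
  max_shock <- numeric(D)
  if (nrow(active)) {
    mx <- vapply(split(active$shock, active$district), max, numeric(1))
    max_shock[as.integer(names(mx))] <- mx
  }
  lay <- world$layers
  delta <- ifelse(lay$sector == "ag", params$delta_ag, params$delta_nonag)
  frac <- wage_damage_fraction(max_shock[lay$district], delta)
  world$layers$current_income <- lay$base_income * (1 - frac)
  world
}
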