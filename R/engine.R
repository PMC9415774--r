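# The quarterly scheduler: initialization, one step, and a full run.

#' Initialize simulation state
#'
#' Bundles the world, population, link set, scenario and caches into a mutable
#' state environment that [sim_step()] advances one quarter at a time. Initial
#' links are seeded per agent (Poisson count, mostly same-district partners)
#' so that early candidate rankings have social structure to work with.
#'
#' @param world a world.
#' @param pop a population (its contents are advanced in place).
#' @param scenario a [flood_scenario()].
#' @param start_year,end_year simulation window (inclusive); four quarters per
#'   year.
#' @param record_histories record per-agent quarterly life histories (needed
#'   for audits; summaries work without).
#' @param init_links seed the network with initial links.
#' @return state environment of class `sim_state`.
#' @export
sim_init <- function(world, pop, scenario, start_year = 2010L, end_year = 2100L,
                     record_histories = TRUE, init_links = TRUE) {
  if (end_year < start_year) stop_arg("end_year must be >= start_year")
  cfg <- world$config
  if (is.null(cfg)) cfg <- world_config()
  st <- new.env(parent = emptyenv())
  st$world <- world
  st$pop <- pop
  st$links <- links_new(max(256L, pop$n * 2L))
  st$scenario <- scenario
  st$start_year <- as.integer(start_year)
  st$end_year <- as.integer(end_year)
  st$quarters <- 4L * (end_year - start_year + 1L)
  st$cfg <- cfg
  st$nw <- cfg$network
  st$dp <- cfg$decision
  st$dmg <- cfg$damage
  st$schedules <- cfg$schedules
  st$cache <- build_subset_cache(world, cfg$decision$max_layers)
  st$record_histories <- record_histories
  st$hist <- vector("list", st$quarters)
  st$occupancy <- matrix(0L, nrow(world$layers), st$quarters)
  st$pop_counts <- matrix(0L, st$quarters, 4L,
    dimnames = list(NULL, c("alive", "births", "deaths", "moves"))
  )
  st$move_q <- integer(0)
  st$move_agent <- integer(0)
  st$move_from <- integer(0)
  st$move_to <- integer(0)
  st$shock_log <- vector("list", 0L)
  st$decisions <- list(n_reconsider = 0L, n_moored_events = 0L)
  st$lay_cur <- world$layers$current_income
  if (init_links && pop$n > 1L) seed_initial_links(st)
  if (record_histories) {
    # quarter-0 baseline snapshot, so that flows reconstructed from histories
    # also capture first-quarter moves
    a0 <- which(pop$alive[seq_len(pop$n)])
    z <- numeric(length(a0))
    st$hist0 <- list(
      quarter = rep.int(0L, length(a0)), agent = a0,
      district = pop$district[a0], portfolio = pop$port_str[a0],
      income = z, consumption = z, transfers_net = z, costs_paid = z,
      inherited = z, wealth = pop$wealth[a0],
      moored = pop$moored[a0],
      adult = pop$age[a0] >= cfg$schedules$adult_age
    )
  }
  class(st) <- c("sim_state", "environment")
  st
}

seed_initial_links <- function(st) {
  pop <- st$pop
  cfg <- st$cfg
  n <- pop$n
  counts <- rpois(n, cfg$init_links_mean)
  for (i in seq_len(n)) {
    for (k in seq_len(counts[i])) {
      local <- runif(1) < cfg$init_links_local_frac
      cand <- if (local) {
        which(pop$alive[seq_len(n)] & pop$district[seq_len(n)] == pop$district[i] &
          seq_len(n) != i)
      } else {
        setdiff(which(pop$alive[seq_len(n)]), i)
      }
      cand <- setdiff(cand, link_partners(st$links, i))
      if (length(cand)) {
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        add_link(st$links, i, j, st$nw$w0)
      }
    }
  }
}

#' Advance the simulation one quarter
#'
#' The quarterly schedule: (1) at the first quarter of each simulation year,
#' sample annual peak floods, convert them to shocks relative to the
#' perceived-normal depth, and apply wage damages; (2) shuffle the agent
#' order; (3) run demography (ageing, deaths, births) over that order; (4) for
#' each surviving adult, with its agent-specific probabilities: meet a new
#' agent, interact (strengthen a link, share income observations, share
#' surplus resources), and reconsider its livelihood portfolio; (5) pay
#' quarterly portfolio incomes into wealth, deduct consumption, and append
#' own-income observations to memory; (6) decay links; (7) append life-history
#' records.
#'
#' @param st a `sim_state` from [sim_init()].
#' @param t quarter index in `1..quarters`.
#' @return the state, invisibly.
#' @export
sim_step <- function(st, t) {
  pop <- st$pop
  world <- st$world
  nw <- st$nw
  row <- ((t - 1L) %% 4L) + 1L

  # -- annual hazard, then per-quarter expiry of damage windows
  if ((t - 1L) %% 4L == 0L) {
    year <- st$start_year + (t - 1L) %/% 4L
    ids <- world$districts$id
    # "normal" flooding is anchored to the reference-period expectation (the
    # run's start year, zero rise): perceptions do not track rising seas
    expected <- expected_peak_depth(world, ids, st$start_year, st$scenario)
    depth <- sample_annual_flood(world, ids, year, st$scenario)
    shock <- flood_shock(depth, expected, st$scenario$m)
    shocks <- data.frame(
      district = ids, year = year, depth = depth,
      expected_depth = expected, shock = shock
    )
    st$shock_log[[length(st$shock_log) + 1L]] <- shocks
    world <- apply_damages(world, shocks, st$dmg, t)
  } else {
    world <- refresh_layer_incomes(world, t, st$dmg)
  }
  st$world <- world
  st$lay_cur <- world$layers$current_income
  st$cache$cur <- st$lay_cur

  # -- zero this quarter's ledger accumulators and transfer-history row
  n <- pop$n
  pop$transfer_net[seq_len(n)] <- 0
  pop$costs_paid[seq_len(n)] <- 0
  pop$inherit_in[seq_len(n)] <- 0
  pop$transfer_hist[row, ] <- 0

  alive_idx <- which(pop$alive[seq_len(n)])
  ord <- if (length(alive_idx) > 1L) sample(alive_idx) else alive_idx

  # -- demography
  dem <- step_demography(pop, ord, st$schedules, st$links, t)

  # -- agent events, in shuffled order
  actors <- ord[pop$alive[ord] & pop$age[ord] >= st$schedules$adult_age]
  n_moves_q <- 0L
  if (length(actors)) {
    u_meet <- runif(length(actors))
    u_int <- runif(length(actors))
    u_rec <- runif(length(actors))
    fire <- u_meet < pop$p_meet[actors] | u_int < pop$p_int[actors] |
      u_rec < pop$p_rec[actors]
    for (k in which(fire)) {
      i <- actors[k]
      if (!pop$alive[i]) next
      if (u_meet[k] < pop$p_meet[i]) {
        meet_new(pop, st$links, i, nw)
      }
      if (u_int[k] < pop$p_int[i]) {
        e <- link_indices(st$links, i)
        e <- e[pop$alive[link_partners(st$links, i, e)]]
        if (length(e)) {
          pick <- if (length(e) == 1L) e else e[sample.int(length(e), 1L)]
          strengthen(st$links, pick, nw$alpha)
          share_information(pop, st$links, i, nw, current_income = st$lay_cur)
          # surplus to share is capped by borrowing headroom so transfers
          # can never push the sender past its credit limit
          headroom_i <- pop$wealth[i] +
            world$params$credit_multiplier * pop$capital[i]
          surplus <- max(0, min(
            pop$last_income[i] - world$params$consumption_need, headroom_i
          ))
          if (surplus > 0) share_resources(pop, st$links, i, surplus, nw, row)
        }
      }
      if (u_rec[k] < pop$p_rec[i]) {
        origin <- pop$district[i]
        out <- reconsider(pop, st$links, i, world, st$dp, nw, t, st$cache)
        st$decisions$n_reconsider <- st$decisions$n_reconsider + 1L
        if (out$moored_event) {
          st$decisions$n_moored_events <- st$decisions$n_moored_events + 1L
        }
        if (out$action == "move") {
          n_moves_q <- n_moves_q + 1L
          st$move_q <- c(st$move_q, t)
          st$move_agent <- c(st$move_agent, i)
          st$move_from <- c(st$move_from, origin)
          st$move_to <- c(st$move_to, out$district)
        }
      }
    }
  }

  # -- pay incomes, consume, observe own wages
  n <- pop$n # births may have extended the population
  alive2 <- which(pop$alive[seq_len(n)])
  adults <- alive2[pop$age[alive2] >= st$schedules$adult_age]
  income <- numeric(n)
  if (length(adults)) {
    plist <- pop$port[adults]
    len <- lengths(plist)
    has <- adults[len > 0L]
    time_used <- numeric(n)
    if (length(has)) {
      lay_flat <- unlist(pop$port[has], use.names = FALSE)
      ag_flat <- rep(has, lengths(pop$port[has]))
      inc_flat <- st$lay_cur[lay_flat]
      s <- rowsum(inc_flat, ag_flat)
      income[as.integer(rownames(s))] <- s[, 1]
      tu <- rowsum(world$layers$time_req[lay_flat], ag_flat)
      time_used[as.integer(rownames(tu))] <- tu[, 1]
      mem_append(pop, lay_flat, ag_flat, inc_flat)
    }
    # residual time earns informal-sector subsistence income
    income[adults] <- income[adults] +
      world$params$informal_income * pmax(1 - time_used[adults], 0)
    pop$wealth[adults] <- pop$wealth[adults] + income[adults]
    desired <- world$params$consumption_need +
      world$params$consumption_mpc *
        pmax(income[adults] - world$params$consumption_need, 0) +
      world$params$consumption_wealth_rate * pmax(pop$wealth[adults], 0)
    headroom <- pop$wealth[adults] +
      world$params$credit_multiplier * pop$capital[adults]
    cons <- pmin(desired, pmax(headroom, 0))
    pop$wealth[adults] <- pop$wealth[adults] - cons
    # cost of credit: interest accrues on debt, but never past the credit limit
    wa <- pop$wealth[adults]
    interest <- pmin(
      world$params$debt_interest_rate * pmax(-wa, 0),
      pmax(wa + world$params$credit_multiplier * pop$capital[adults], 0)
    )
    pop$wealth[adults] <- wa - interest
    cons <- cons + interest
    pop$last_income[adults] <- income[adults]
  }

  # -- network decay
  decay_links(st$links, nw$decay, nw, pop)

  # -- records
  st$occupancy[, t] <- pop$holders
  st$pop_counts[t, ] <- c(length(alive2), length(dem$births), length(dem$deaths), n_moves_q)
  if (st$record_histories) {
    cons_full <- numeric(n)
    if (length(adults)) cons_full[adults] <- cons
    st$hist[[t]] <- list(
      quarter = rep.int(t, length(alive2)),
      agent = alive2,
      district = pop$district[alive2],
      portfolio = pop$port_str[alive2],
      income = income[alive2],
      consumption = cons_full[alive2],
      transfers_net = pop$transfer_net[alive2],
      costs_paid = pop$costs_paid[alive2],
      inherited = pop$inherit_in[alive2],
      wealth = pop$wealth[alive2],
      moored = pop$moored[alive2],
      adult = pop$age[alive2] >= st$schedules$adult_age
    )
  }
  invisible(st)
}

#' Run a full simulation
#'
#' Generates (or accepts) a population, seeds the network, and executes
#' `4 * (end_year - start_year + 1)` quarterly steps of [sim_step()] under a
#' single RNG stream, so that a run is a pure function of its inputs and
#' seed. Returns life histories, the inter-district flow matrix, and a run
#' summary.
#'
#' @param world a world.
#' @param scenario a [flood_scenario()].
#' @param start_year,end_year projection window (default 2010-2100).
#' @param seed integer seed for everything: population generation, floods,
#'   scheduling, network and decisions.
#' @param n_agents initial population size (used when `pop` is `NULL`).
#' @param age_dist optional age distribution for [generate_population()].
#' @param point optional named list of calibration-dimension overrides:
#'   `credit_multiplier`, `k_locations`, `rho_scale`, `info_share_prob`,
#'   `p_reconsider_mean`.
#' @param record_histories record per-agent quarterly life histories.
#' @return A list of class `sim_result`: `histories` (data frame), `flows`
#'   (a [flow_matrix()] over the whole run), `summary` (see details), plus
#'   `moves`, `shocks`, `occupancy`, `pop_counts` and the final `state`.
#'   The summary holds per-district normalized net migration, the migrant
#'   count (agents with at least one move), the move count, moored shares,
#'   final population, mean final wealth, and the parameter echo.
#' @export
run_simulation <- function(world, scenario = flood_scenario("baseline"),
                           start_year = 2010L, end_year = 2100L, seed = 1L,
                           n_agents = 500L, age_dist = NULL, point = NULL,
                           record_histories = TRUE) {
  if (end_year < start_year) stop_arg("simulation horizon must be at least one year")
  world <- apply_point_world(world, point)
  with_seed(seed, {
    pop <- generate_population(world, n_agents, age_dist, seed = NULL)
    apply_point_pop(pop, point)
    st <- sim_init(world, pop, scenario, start_year, end_year, record_histories)
    for (t in seq_len(st$quarters)) sim_step(st, t)
    finalize_run(st, point)
  })
}

# Overrides along the five calibration-sensitive dimensions. World-level:
apply_point_world <- function(world, point) {
  if (is.null(point)) return(world)
  cfg <- world$config
  if (is.null(cfg)) cfg <- world_config()
  if (!is.null(point$credit_multiplier)) {
    world$params$credit_multiplier <- point$credit_multiplier
    cfg$credit_multiplier <- point$credit_multiplier
  }
  if (!is.null(point$k_locations)) {
    cfg$decision$k_locations <- as.integer(round(point$k_locations))
  }
  if (!is.null(point$info_share_prob)) {
    cfg$network$info_share_prob <- point$info_share_prob
  }
  if (!is.null(point$p_reconsider_mean)) {
    cfg$p_reconsider_mean <- point$p_reconsider_mean
  }
  world$config <- cfg
  world
}

# ...and population-level (rho scaling applies to initial draws and newborns).
apply_point_pop <- function(pop, point) {
  if (is.null(point)) return(invisible(pop))
  if (!is.null(point$rho_scale)) {
    pop$rho_scale <- point$rho_scale
    n <- pop$n
    pop$rho[seq_len(n)] <- pop$rho[seq_len(n)] * point$rho_scale
  }
  invisible(pop)
}

finalize_run <- function(st, point = NULL) {
  pop <- st$pop
  D <- nrow(st$world$districts)
  histories <- NULL
  if (st$record_histories) {
    chunks <- c(list(st$hist0), st$hist)
    cols <- names(st$hist0)
    histories <- as.data.frame(lapply(stats::setNames(cols, cols), function(cn) {
      unlist(lapply(chunks, `[[`, cn), use.names = FALSE)
    }))
  }
  flows <- flows_from_moves(st$move_from, st$move_to, D, c(1L, st$quarters))
  total_pop <- pop$n
  net <- if (total_pop > 0) {
    net_migration_by_district(flows, total_pop)
  } else {
    numeric(D)
  }
  n <- pop$n
  alive <- which(pop$alive[seq_len(n)])
  adults <- alive[pop$age[alive] >= st$schedules$adult_age]
  moored_share_d <- rep(NA_real_, D)
  if (length(adults)) {
    tot <- tabulate(pop$district[adults], D)
    moo <- tabulate(pop$district[adults][pop$moored[adults]], D)
    moored_share_d <- ifelse(tot > 0, moo / tot, NA_real_)
  }
  movers <- sum(pop$n_moves[seq_len(n)] > 0L)
  summary <- list(
    net_migration_by_district = net,
    net_coastal_migration = sum(net[st$world$districts$coastal]),
    total_migrations = movers,
    total_moves = length(st$move_q),
    moored_share = if (length(adults)) mean(pop$moored[adults]) else NA_real_,
    moored_share_by_district = moored_share_d,
    final_population = length(alive),
    mean_final_wealth = if (length(adults)) mean(pop$wealth[adults]) else NA_real_,
    parameter_echo = list(
      scenario = st$scenario$name, m = st$scenario$m,
      credit_multiplier = st$world$params$credit_multiplier,
      point = point,
      start_year = st$start_year, end_year = st$end_year,
      n_agents_created = total_pop
    )
  )
  res <- list(
    histories = histories,
    flows = flows,
    summary = summary,
    moves = data.frame(
      quarter = st$move_q, agent = st$move_agent,
      origin = st$move_from, destination = st$move_to
    ),
    shocks = do.call(rbind, st$shock_log),
    occupancy = st$occupancy,
    pop_counts = st$pop_counts,
    state = st
  )
  class(res) <- c("sim_result", "list")
  res
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$summary
  cat(
    "<sim_result>", s$parameter_echo$scenario,
    sprintf(
      "m=%.2f credit=%.2f | pop %d, migrants %d (%d moves), moored %.3f, net coastal %.4f\n",
      s$parameter_echo$m, s$parameter_echo$credit_multiplier,
      s$final_population, s$total_migrations, s$total_moves,
      s$moored_share, s$net_coastal_migration
    )
  )
  invisible(x)
}
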