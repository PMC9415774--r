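#' Decision parameters
#'
#' @param k_locations number of candidate districts an agent considers
#'   (including its current district).
#' @param lambda loss-aversion coefficient (`>= 1`); the canonical
#'   prospect-theory estimate 2.25 is the default.
#' @param horizon_quarters planning horizon `H` over which a portfolio's
#'   discounted prospect value is accumulated.
#' @param max_layers maximum number of layers per portfolio.
#' @export
decision_params <- function(k_locations = 4L, lambda = 2.25,
                            horizon_quarters = 20L, max_layers = 3L) {
  if (k_locations < 1) stop_arg("k_locations must be >= 1")
  if (lambda < 1) stop_arg("lambda must be >= 1")
  if (horizon_quarters < 1) stop_arg("horizon_quarters must be >= 1")
  if (max_layers < 1) stop_arg("max_layers must be >= 1")
  structure(
    list(
      k_locations = as.integer(k_locations), lambda = lambda,
      horizon_quarters = as.integer(horizon_quarters),
      max_layers = as.integer(max_layers)
    ),
    class = c("decision_params", "list")
  )
}

#' Constant-relative-risk-aversion utility
#'
#' `(income^(1 - rho) - 1) / (1 - rho)` for `rho != 1` and `log(income)` at
#' `rho = 1`, computed with `expm1` so the function is continuous in `rho`
#' through 1. Utility is normalized to 0 at income 1.
#'
#' @param income positive income (vectorized); callers floor incomes at a
#'   small positive epsilon before transforming.
#' @param rho relative risk aversion (`>= 0`, scalar).
#' @return utility.
#' @export
crra_utility <- function(income, rho) {
  if (any(income <= 0)) stop_arg("income must be positive (floor before transforming)")
  if (rho < 0) stop_arg("rho must be >= 0")
  if (abs(1 - rho) < 1e-12) return(log(income))
  pow_utility(income, 1 - rho)
}

#' Reference-dependent (prospect) value of an income level
#'
#' The CRRA utility gain over a reference income, with losses amplified by the
#' loss-aversion coefficient: `g = u(income) - u(reference)`; returns `g` for
#' gains and `lambda * g` for losses. At `lambda = 1` this reduces to a plain
#' utility difference (the expected-utility limit).
#'
#' @param income,reference_income positive incomes (vectorized over `income`).
#' @param rho relative risk aversion.
#' @param lambda loss aversion `>= 1`.
#' @export
prospect_value <- function(income, reference_income, rho, lambda) {
  if (lambda < 1) stop_arg("lambda must be >= 1")
  g <- crra_utility(income, rho) - crra_utility(reference_income, rho)
  ifelse(g >= 0, g, lambda * g)
}

# Enumerate all portfolios (layer subsets) of a district that respect the unit
# time budget and the portfolio size cap. Rows are ordered by subset size then
# lexicographically by layer index; the empty portfolio is always row 1. The
# order is the documented tie-break order for option selection.
district_subsets <- function(world, district, max_layers) {
  lay <- which(world$layers$district == district)
  treq <- world$layers$time_req[lay]
  nl <- length(lay)
  rows <- list(integer())
  if (nl) {
    for (k in seq_len(min(max_layers, nl))) {
      for (comb in utils::combn(nl, k, simplify = FALSE)) {
        if (sum(treq[comb]) <= 1 + 1e-12) rows[[length(rows) + 1L]] <- comb
      }
    }
  }
  S <- matrix(0, nrow = length(rows), ncol = nl)
  for (r in seq_along(rows)) S[r, rows[[r]]] <- 1
  list(
    lay = lay, S = S, sizes = lengths(rows),
    # cached per-layer columns so the hot path avoids data-frame indexing
    treq = treq,
    capn = world$layers$capacity[lay],
    acc = world$layers$access_cost[lay],
    amen = world$layers$amenity_value[lay],
    informal_free = pmax(1 - as.numeric(S %*% treq), 0)
  )
}

# The cache is an environment so the engine can refresh the current-income
# vector each quarter without rebuilding the subset tables.
build_subset_cache <- function(world, max_layers) {
  ce <- new.env(parent = emptyenv())
  ce$sub <- lapply(seq_len(nrow(world$districts)), district_subsets,
    world = world, max_layers = max_layers
  )
  ce$cur <- world$layers$current_income
  ce
}

#' Rank candidate districts for an agent
#'
#' Returns the agent's current district first, followed by the `k - 1` other
#' districts with the highest pull score — the agent's total link strength to
#' residents of that district — with ties broken by smaller distance and then
#' smaller district id. Social ties, not wages, determine which places an
#' agent considers at all; wages enter only through the valuation of what it
#' finds there.
#'
#' @param pop population.
#' @param ln link set.
#' @param i agent id.
#' @param world world.
#' @param k number of districts considered (`>= 1`).
#' @param e optional precomputed incident-edge indices for agent `i`.
#' @return integer vector of district ids, length `min(k, D)`.
#' @export
rank_candidate_districts <- function(pop, ln, i, world, k, e = NULL) {
  if (k < 1) stop_arg("k must be >= 1")
  D <- nrow(world$districts)
  cur <- pop$district[i]
  if (k == 1L || D == 1L) return(cur)
  score <- numeric(D)
  if (is.null(e)) e <- link_indices(ln, i)
  if (length(e)) {
    partners <- link_partners(ln, i, e)
    keep <- pop$alive[partners]
    if (any(keep)) {
      s <- rowsum(ln$w[e][keep], pop$district[partners[keep]])
      score[as.integer(rownames(s))] <- s[, 1]
    }
  }
  others <- setdiff(seq_len(D), cur)
  ord <- others[order(-score[others], world$dist[cur, others], others)]
  c(cur, ord[seq_len(min(k - 1L, length(ord)))])
}

#' One-time cost of adopting an option
#'
#' Access costs of portfolio layers the agent has never accessed, plus the
#' moving cost `c0 + c1 * distance` when the option is in a different
#' district. Moving costs are spending, but not capital: only access spending
#' counts toward the credit base.
#'
#' @param pop population.
#' @param i agent id.
#' @param district destination district id.
#' @param layers integer vector of layer ids of the candidate portfolio.
#' @param world world.
#' @return non-negative cost; attribute `access` carries the access-cost part.
#' @export
option_cost <- function(pop, i, district, layers, world) {
  new_lay <- setdiff(layers, pop$accessed[[i]])
  access <- sum(world$layers$access_cost[new_lay])
  move <- 0
  cur <- pop$district[i]
  if (district != cur) {
    move <- world$params$moving_cost_base +
      world$params$moving_cost_per_dist * world$dist[cur, district]
  }
  structure(access + move, access = access)
}

#' Affordability under the credit constraint
#'
#' An option is affordable when its one-time cost does not exceed the agent's
#' wealth plus its credit limit, the credit multiplier times its capital
#' (cumulative access spending). The boundary case is affordable.
#'
#' @param cost non-negative one-time cost.
#' @param wealth current wealth (may be negative within the credit limit).
#' @param capital cumulative access spending.
#' @param credit_multiplier scalar in `[0, 2]`.
#' @return logical.
#' @export
affordable <- function(cost, wealth, capital, credit_multiplier) {
  check_nonneg(cost, "cost")
  if (credit_multiplier < 0 || credit_multiplier > 2) {
    stop_arg("credit_multiplier must lie in [0, 2]")
  }
  cost == 0 | cost <= wealth + credit_multiplier * capital
}

# Expected quarterly income of a portfolio for agent i: per-layer memory means
# (falling back to current income), plus amenity values, plus the expected
# remittance rate at the candidate district.
expected_option_income <- function(pop, ln, i, district, layers, world, nw, t,
                                   e = NULL) {
  y <- 0
  time_used <- 0
  if (length(layers)) {
    y <- sum(mem_expected(pop, i, layers, world$layers$current_income)) +
      sum(world$layers$amenity_value[layers])
    time_used <- sum(world$layers$time_req[layers])
  }
  y + world$params$informal_income * max(1 - time_used, 0) +
    expected_remittances(pop, ln, i, district, nw, t, e = e)
}

#' Prospect value of a candidate portfolio
#'
#' Expected quarterly income of the candidate (per-layer income-memory means,
#' falling back to current wages, plus amenity value and expected
#' remittances), valued against the agent's current-portfolio expected income
#' as the reference point and summed over the discounted planning horizon:
#' `sum_{tau=1..H} (1 + r_q)^(-tau) * v(y_hat, y_ref)` with `v` the
#' loss-averse CRRA gain of [prospect_value()]. Evaluating the current
#' portfolio against itself yields exactly 0.
#'
#' @param pop population.
#' @param ln link set.
#' @param i agent id.
#' @param district candidate district.
#' @param layers candidate portfolio (integer layer ids).
#' @param world world.
#' @param params a [decision_params()] object.
#' @param nw a [network_params()] object.
#' @param t current quarter.
#' @return discounted prospect value (0 for the current portfolio).
#' @export
portfolio_value <- function(pop, ln, i, district, layers, world,
                            params = world$config$decision,
                            nw = world$config$network, t = 4L) {
  floor_y <- world$params$income_floor
  y <- max(floor_y, expected_option_income(pop, ln, i, district, layers, world, nw, t))
  ref <- max(floor_y, expected_option_income(
    pop, ln, i, pop$district[i], pop$port[[i]], world, nw, t
  ))
  pop$dh[i] * prospect_value(y, ref, pop$rho[i], params$lambda)
}

#' Best portfolio in a district
#'
#' Exhaustively enumerates every subset of the district's layers that fits the
#' unit time budget and the portfolio size cap, restricted to layers with open
#' capacity (or already held by the agent), and returns the subset with the
#' highest [portfolio_value()]. The empty portfolio is always a candidate.
#' Ties go to the earlier subset in enumeration order (smaller, then
#' lexicographically first).
#'
#' @inheritParams portfolio_value
#' @param cache optional precomputed subset cache (see internals); built on
#'   the fly when absent.
#' @return list with `layers`, `value`, and `cost` (an [option_cost()]).
#' @export
best_portfolio_in_district <- function(pop, ln, i, district, world,
                                       params = world$config$decision,
                                       nw = world$config$network, t = 4L,
                                       cache = NULL) {
  opts <- enumerate_options(pop, ln, i, district, world, params, nw, t, cache)
  j <- which.max(opts$value) # first maximum wins: enumeration order tie-break
  list(
    layers = option_layers(opts, j), value = opts$value[j],
    cost = structure(opts$cost[j], access = opts$access[j])
  )
}

# Vectorized evaluation of all feasible options in one district.
enumerate_options <- function(pop, ln, i, district, world, params, nw, t,
                              cache = NULL, ref = NULL, e = NULL) {
  if (is.null(cache)) {
    sub <- district_subsets(world, district, params$max_layers)
    cur_income <- world$layers$current_income
  } else {
    sub <- cache$sub[[district]]
    cur_income <- cache$cur
  }
  lay <- sub$lay
  S <- sub$S
  informal_free <- sub$informal_free
  held <- lay %in% pop$port[[i]]
  open <- pop$holders[lay] < sub$capn | held
  if (!all(open)) {
    feas <- S %*% (!open) == 0
    S <- S[feas, , drop = FALSE]
    informal_free <- informal_free[feas]
  }
  contrib <- if (length(lay)) {
    mem_expected(pop, i, lay, cur_income) + sub$amen
  } else {
    numeric(0)
  }
  remit <- expected_remittances(pop, ln, i, district, nw, t, e = e)
  if (length(lay)) {
    informal <- world$params$informal_income * informal_free
    y <- as.numeric(S %*% contrib) + informal + remit
  } else {
    y <- rep(world$params$informal_income + remit, nrow(S))
  }
  new_cost <- if (length(lay)) {
    sub$acc * !(lay %in% pop$accessed[[i]])
  } else {
    numeric(0)
  }
  move <- 0
  if (district != pop$district[i]) {
    move <- world$params$moving_cost_base +
      world$params$moving_cost_per_dist * world$dist[pop$district[i], district]
  }
  access <- if (length(lay)) as.numeric(S %*% new_cost) else numeric(nrow(S))
  floor_y <- world$params$income_floor
  if (is.null(ref)) {
    ref <- max(floor_y, expected_option_income(
      pop, ln, i, pop$district[i], pop$port[[i]], world, nw, t, e = e
    ))
  }
  value <- pop$dh[i] * prospect_value(pmax(y, floor_y), ref, pop$rho[i], params$lambda)
  list(
    lay = lay, S = S,
    value = value, cost = access + move, access = access, ref = ref
  )
}

# layer ids of subset row j of an enumerate_options() result
option_layers <- function(opts, j) opts$lay[opts$S[j, ] > 0]

#' Reconsider an agent's livelihood portfolio
#'
#' The central decision step. The agent ranks its candidate districts
#' ([rank_candidate_districts()]), enumerates every feasible portfolio in each
#' and values it against the current portfolio (whose value is identically 0).
#' Let `B` be the options with strictly positive value:
#'
#' * `B` empty: the agent is satisfied where it is — action `"stay"`, no
#'   moored event.
#' * `B` contains an affordable option: the highest-valued affordable option
#'   is adopted. Its cost is paid from wealth (which may go negative within
#'   the credit limit), access spending is added to capital, capacity slots
#'   are released and claimed, and a change of district is a migration —
#'   action `"move"` or `"stay"`.
#' * `B` non-empty but no member affordable: the agent is moored — action
#'   `"stay-moored"`, the moored flag is set. Agents with no strictly better
#'   option are never tagged: mooring means wanting to do better and being
#'   unable to afford it.
#'
#' A successful (non-moored) reconsideration clears the moored flag, so the
#' flag always reflects the agent's most recent reconsideration.
#'
#' @inheritParams portfolio_value
#' @param cache optional precomputed subset cache.
#' @return list with `action` (`"stay"`, `"move"`, `"stay-moored"`),
#'   `district`, `layers`, `value`, `cost`, `moored_event`.
#' @export
reconsider <- function(pop, ln, i, world,
                       params = world$config$decision,
                       nw = world$config$network, t = 4L, cache = NULL) {
  if (!pop$alive[i]) stop_arg("reconsider called on a dead agent")
  e <- link_indices(ln, i)
  cands <- rank_candidate_districts(pop, ln, i, world, params$k_locations, e = e)
  cm <- world$params$credit_multiplier
  budget <- pop$wealth[i] + cm * pop$capital[i]
  best_val <- 0
  best <- NULL
  any_better <- FALSE
  ref <- NULL
  for (d in cands) {
    opts <- enumerate_options(pop, ln, i, d, world, params, nw, t, cache,
      ref = ref, e = e)
    ref <- opts$ref
    pos <- opts$value > 0
    if (any(pos)) any_better <- TRUE
    ok <- which(pos & opts$cost <= budget)
    if (length(ok)) {
      j <- ok[which.max(opts$value[ok])]
      if (opts$value[j] > best_val) {
        best_val <- opts$value[j]
        best <- list(
          district = d, layers = option_layers(opts, j),
          value = opts$value[j], cost = opts$cost[j], access = opts$access[j]
        )
      }
    }
  }
  if (!any_better) {
    pop$moored[i] <- FALSE
    return(list(
      action = "stay", district = pop$district[i], layers = pop$port[[i]],
      value = 0, cost = 0, moored_event = FALSE
    ))
  }
  if (is.null(best)) {
    pop$moored[i] <- TRUE
    if (is.na(pop$first_moor_q[i])) {
      pop$first_moor_q[i] <- t
      pop$moves_at_moor[i] <- pop$n_moves[i]
    }
    return(list(
      action = "stay-moored", district = pop$district[i], layers = pop$port[[i]],
      value = 0, cost = 0, moored_event = TRUE
    ))
  }
  res <- adopt_option(pop, i, best, world, t)
  pop$moored[i] <- FALSE
  if (!res$ok) {
    return(list(
      action = "stay", district = pop$district[i], layers = pop$port[[i]],
      value = 0, cost = 0, moored_event = FALSE
    ))
  }
  list(
    action = if (res$moved) "move" else "stay",
    district = best$district, layers = best$layers,
    value = best$value, cost = best$cost, moored_event = FALSE
  )
}

# Pay for and switch to an option; list(ok, moved).
adopt_option <- function(pop, i, best, world, t) {
  old_port <- pop$port[[i]]
  if (length(old_port)) pop$holders[old_port] <- pop$holders[old_port] - 1L
  new_port <- best$layers
  # capacity re-check (defensive; single-threaded stepping cannot race)
  if (length(new_port)) {
    over <- pop$holders[new_port] >= world$layers$capacity[new_port] &
      !(new_port %in% old_port)
    if (any(over)) {
      if (length(old_port)) pop$holders[old_port] <- pop$holders[old_port] + 1L
      return(list(ok = FALSE, moved = FALSE))
    }
    pop$holders[new_port] <- pop$holders[new_port] + 1L
  }
  pop$wealth[i] <- pop$wealth[i] - best$cost
  pop$costs_paid[i] <- pop$costs_paid[i] + best$cost
  pop$capital[i] <- pop$capital[i] + best$access
  pop$accessed[[i]] <- union(pop$accessed[[i]], new_port)
  moved <- best$district != pop$district[i]
  pop$district[i] <- best$district
  pop$port[[i]] <- new_port
  set_portfolio_meta(pop, i, world)
  if (moved) pop$n_moves[i] <- pop$n_moves[i] + 1L
  list(ok = TRUE, moved = moved)
}
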