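# Population container: an environment of parallel vectors, one slot per agent
# ever created. Reference semantics keep the quarterly loop cheap; all mutation
# goes through the helpers in this file and in the operation functions.

pop_new <- function(capacity, n_layers, cfg, mem_cap = 8L) {
  # parent is baseenv() so small update expressions can be eval()ed inside
  # the environment (in-place subassignment on the big memory arrays)
  pop <- new.env(parent = baseenv())
  pop$cap <- as.integer(capacity)
  pop$n <- 0L
  pop$nL <- as.integer(n_layers)
  pop$cfg <- cfg
  pop$rho_scale <- 1
  pop$mem_cap <- as.integer(mem_cap)
  for (nm in c(
    "age", "wealth", "capital", "rho", "disc", "p_rec", "p_meet",
    "p_int", "last_income", "dh"
  )) {
    pop[[nm]] <- numeric(capacity)
  }
  pop$alive <- logical(capacity)
  pop$moored <- logical(capacity)
  pop$district <- integer(capacity)
  pop$n_moves <- integer(capacity)
  pop$moves_at_moor <- rep(NA_integer_, capacity)
  pop$first_moor_q <- rep(NA_integer_, capacity)
  pop$port <- vector("list", capacity)
  pop$accessed <- vector("list", capacity)
  pop$port_str <- character(capacity)
  pop$sector_mask <- integer(capacity)
  pop$holders <- integer(n_layers)
  # per-layer income memory: bounded FIFO, stored flat with running sums
  pop$mem_vals <- numeric(mem_cap * n_layers * capacity)
  pop$mem_pos <- integer(n_layers * capacity)
  pop$mem_len <- integer(n_layers * capacity)
  pop$mem_sum <- numeric(n_layers * capacity)
  # trailing four-quarter net transfer history
  pop$transfer_hist <- matrix(0, nrow = 4L, ncol = capacity)
  # per-quarter ledger accumulators (zeroed by the engine each quarter)
  pop$transfer_net <- numeric(capacity)
  pop$costs_paid <- numeric(capacity)
  pop$inherit_in <- numeric(capacity)
  pop
}

pop_grow <- function(pop) {
  old <- pop$cap
  newcap <- old * 2L
  grow_num <- function(x) c(x, numeric(old))
  for (nm in c(
    "age", "wealth", "capital", "rho", "disc", "p_rec", "p_meet", "p_int",
    "last_income", "dh", "transfer_net", "costs_paid", "inherit_in"
  )) {
    pop[[nm]] <- grow_num(pop[[nm]])
  }
  pop$alive <- c(pop$alive, logical(old))
  pop$moored <- c(pop$moored, logical(old))
  pop$district <- c(pop$district, integer(old))
  pop$n_moves <- c(pop$n_moves, integer(old))
  pop$moves_at_moor <- c(pop$moves_at_moor, rep(NA_integer_, old))
  pop$first_moor_q <- c(pop$first_moor_q, rep(NA_integer_, old))
  pop$port <- c(pop$port, vector("list", old))
  pop$accessed <- c(pop$accessed, vector("list", old))
  pop$port_str <- c(pop$port_str, character(old))
  pop$sector_mask <- c(pop$sector_mask, integer(old))
  pop$mem_vals <- c(pop$mem_vals, numeric(pop$mem_cap * pop$nL * old))
  pop$mem_pos <- c(pop$mem_pos, integer(pop$nL * old))
  pop$mem_len <- c(pop$mem_len, integer(pop$nL * old))
  pop$mem_sum <- c(pop$mem_sum, numeric(pop$nL * old))
  pop$transfer_hist <- cbind(pop$transfer_hist, matrix(0, 4L, old))
  pop$cap <- newcap
  invisible(pop)
}

add_agent <- function(pop, district, age, wealth, rho, disc, p_rec, p_meet, p_int) {
  if (pop$n >= pop$cap) pop_grow(pop)
  i <- pop$n + 1L
  pop$n <- i
  pop$alive[i] <- TRUE
  pop$district[i] <- district
  pop$age[i] <- age
  pop$wealth[i] <- wealth
  pop$capital[i] <- 0
  pop$rho[i] <- rho
  pop$disc[i] <- disc
  pop$p_rec[i] <- p_rec
  pop$p_meet[i] <- p_meet
  pop$p_int[i] <- p_int
  pop$port[[i]] <- integer()
  pop$accessed[[i]] <- integer()
  pop$port_str[i] <- ""
  rq <- (1 + disc)^0.25 - 1
  pop$dh[i] <- sum((1 + rq)^-(seq_len(pop$cfg$decision$horizon_quarters)))
  i
}

# --- income memory (bounded FIFO per (agent, layer)) -------------------------

# flat index of the (layer, agent) cell in the length-nL*cap bookkeeping vectors
mem_cell <- function(pop, layer, agent) (agent - 1L) * pop$nL + layer

# The memory arrays are large, so subassignment must not trigger R's
# copy-on-modify: the update runs inside the population environment itself,
# where the bindings have a single reference and `[<-` mutates in place.
MEM_APPEND_EXPR <- quote({
  ..cell <- (..agent - 1L) * nL + ..layer
  ..pos <- mem_pos[..cell] # 0-based next write slot
  ..idx <- (..cell - 1L) * mem_cap + ..pos + 1L
  ..len <- mem_len[..cell]
  ..full <- ..len >= mem_cap
  ..old <- numeric(length(..idx))
  ..old[..full] <- mem_vals[..idx[..full]]
  mem_vals[..idx] <- ..value
  mem_sum[..cell] <- mem_sum[..cell] + ..value - ..old
  mem_len[..cell] <- ..len + !..full
  mem_pos[..cell] <- (..pos + 1L) %% mem_cap
  NULL
})

# Append observations `value` for (layer, agent) pairs; vectors are parallel.
# Pairs must be unique within one call.
mem_append <- function(pop, layer, agent, value) {
  if (length(layer) == 0L) return(invisible())
  pop$..layer <- as.integer(layer)
  pop$..agent <- as.integer(agent)
  pop$..value <- value
  eval(MEM_APPEND_EXPR, pop)
  invisible()
}

# Expected income per layer for one agent: memory mean where observations
# exist, falling back to the layer's current income.
mem_expected <- function(pop, agent, layers, current_income) {
  cell <- mem_cell(pop, layers, agent)
  len <- pop$mem_len[cell]
  out <- current_income[layers]
  has <- len > 0L
  if (any(has)) out[has] <- pop$mem_sum[cell[has]] / len[has]
  out
}

#' Generate an initial agent population for a world
#'
#' Creates `n` agents placed across districts with probability proportional to
#' each district's total layer capacity. Ages are drawn from `age_dist` (a
#' stylized population pyramid by default); initial wealth is log-normal; risk
#' aversion (CRRA rho), discount rates and per-quarter event probabilities are
#' drawn from the world configuration ranges. Each adult is assigned a greedy
#' initial portfolio in its home district: layers are taken in decreasing
#' income order while time budget, capacity and affordability (initial wealth;
#' capital starts at zero so no credit applies yet) allow, paying access costs
#' from wealth into capital. Agents that cannot afford any layer, and all
#' children, start with empty portfolios.
#'
#' If the world configuration sets `guarantee_placement`, total layer capacity
#' must be at least the adult population, otherwise an error is raised.
#'
#' @param world a [generate_world()] object.
#' @param n number of agents (`n >= 0`).
#' @param age_dist optional list with `breaks` (ascending ages) and `weights`
#'   (band probabilities); ages are uniform within bands.
#' @param seed integer seed.
#' @return A population environment of class `population`.
#' @export
generate_population <- function(world, n, age_dist = NULL, seed = 1L) {
  if (n < 0) stop_arg("population size must be >= 0")
  cfg <- world$config
  if (is.null(cfg)) cfg <- world_config()
  with_seed(seed, {
    nL <- nrow(world$layers)
    pop <- pop_new(max(64L, as.integer(ceiling(n * 2.5))), nL, cfg)
    if (n == 0L) {
      class(pop) <- c("population", "environment")
      return(pop)
    }
    if (is.null(age_dist)) {
      age_dist <- list(
        breaks = c(0, 15, 30, 45, 60, 80),
        weights = c(0.35, 0.28, 0.18, 0.12, 0.07)
      )
    }
    # capacity-proportional placement
    cap_by_d <- tapply_sum(world$layers$capacity, world$layers$district,
      nrow(world$districts))
    district <- sample.int(nrow(world$districts), n,
      replace = TRUE, prob = cap_by_d
    )
    band <- sample.int(length(age_dist$weights), n,
      replace = TRUE, prob = age_dist$weights
    )
    lo <- age_dist$breaks[band]
    hi <- age_dist$breaks[band + 1L]
    age <- runif(n, lo, hi)
    wealth <- rlnorm(n, cfg$wealth_meanlog, cfg$wealth_sdlog)
    rho <- runif(n, cfg$rho_range[1], cfg$rho_range[2])
    disc <- runif(n, cfg$discount_range[1], cfg$discount_range[2])
    p_rec <- cfg$p_reconsider_mean *
      runif(n, cfg$p_reconsider_rel_range[1], cfg$p_reconsider_rel_range[2])
    p_meet <- runif(n, cfg$p_meet_range[1], cfg$p_meet_range[2])
    p_int <- runif(n, cfg$p_interact_range[1], cfg$p_interact_range[2])
    for (i in seq_len(n)) {
      add_agent(
        pop, district[i], age[i], wealth[i], rho[i], disc[i],
        p_rec[i], p_meet[i], p_int[i]
      )
    }
    adult <- age >= cfg$schedules$adult_age
    if (isTRUE(cfg$guarantee_placement) && sum(world$layers$capacity) < sum(adult)) {
      stop_arg("guarantee_placement set but total layer capacity < adult population")
    }
    assign_initial_portfolios(pop, world, which(adult))
    class(pop) <- c("population", "environment")
    pop
  })
}

tapply_sum <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

assign_initial_portfolios <- function(pop, world, idx) {
  lay_d <- world$layers$district
  income <- world$layers$base_income
  treq <- world$layers$time_req
  acost <- world$layers$access_cost
  capn <- world$layers$capacity
  max_layers <- pop$cfg$decision$max_layers
  by_district <- split(seq_along(lay_d), lay_d)
  ord_in_d <- lapply(by_district, function(l) l[order(-income[l])])
  for (i in idx) {
    cands <- ord_in_d[[as.character(pop$district[i])]]
    if (is.null(cands)) next
    t_left <- 1
    for (l in cands) {
      if (length(pop$port[[i]]) >= max_layers) break
      if (pop$holders[l] >= capn[l]) next
      if (treq[l] > t_left) next
      if (acost[l] > pop$wealth[i]) next
      pop$wealth[i] <- pop$wealth[i] - acost[l]
      pop$capital[i] <- pop$capital[i] + acost[l]
      pop$port[[i]] <- c(pop$port[[i]], l)
      pop$accessed[[i]] <- c(pop$accessed[[i]], l)
      pop$holders[l] <- pop$holders[l] + 1L
      t_left <- t_left - treq[l]
    }
    set_portfolio_meta(pop, i, world)
  }
  invisible(pop)
}

# cache the printable portfolio and the agent's sector bitmask (1 = ag,
# 2 = nonag); both only change when the portfolio changes
set_portfolio_meta <- function(pop, i, world) {
  port <- pop$port[[i]]
  pop$port_str[i] <- paste(sort(port), collapse = ";")
  sec <- world$layers$sector[port]
  pop$sector_mask[i] <- as.integer(any(sec == "ag")) + 2L * as.integer(any(sec == "nonag"))
  invisible()
}

#' @export
print.population <- function(x, ...) {
  cat("<population>", sum(x$alive), "alive of", x$n, "created\n")
  invisible(x)
}
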