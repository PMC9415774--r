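#' Demographic schedules
#'
#' Stylized age-band schedules of annual fertility and mortality probabilities,
#' applied on the quarterly clock through [quarterly_prob()]. The defaults are
#' a coarse, roughly-stationary approximation of a South-Asian demographic
#' profile; they are configuration, not data, and can be replaced wholesale.
#' Fertility attaches to every agent in the reproductive band (the model does
#' not track sex), so default rates are roughly half of per-woman rates.
#'
#' @param fertility data frame with columns `age_lo` and `rate` (annual birth
#'   probability for ages in `[age_lo, next age_lo)`).
#' @param mortality data frame with columns `age_lo` and `rate` (annual death
#'   probability).
#' @param adult_age age (years) at which agents begin making livelihood
#'   decisions.
#' @return A list of class `demography_schedules`.
#' @export
demography_schedules <- function(
    fertility = data.frame(
      age_lo = c(0, 15, 20, 30, 40, 50),
      rate = c(0, 0.05, 0.08, 0.04, 0.01, 0)
    ),
    mortality = data.frame(
      age_lo = c(0, 1, 5, 15, 40, 60, 70, 80),
      rate = c(0.04, 0.005, 0.001, 0.002, 0.005, 0.02, 0.06, 0.15)
    ),
    adult_age = 15) {
  check_prob(fertility$rate, "fertility rates")
  check_prob(mortality$rate, "mortality rates")
  check_nonneg(adult_age, "adult_age")
  if (is.unsorted(fertility$age_lo) || is.unsorted(mortality$age_lo)) {
    stop_arg("age bands must be given in increasing order of age_lo")
  }
  structure(
    list(fertility = fertility, mortality = mortality, adult_age = adult_age),
    class = c("demography_schedules", "list")
  )
}

band_rate <- function(age, table) {
  table$rate[findInterval(age, table$age_lo)]
}

#' Convert an annual probability to a quarterly probability
#'
#' Returns `1 - (1 - p)^(1/4)`, the per-quarter probability whose compounding
#' over four quarterly draws reproduces the annual probability `p`.
#'
#' @param annual_prob annual event probability in `[0, 1]` (vectorized).
#' @return quarterly probability.
#' @export
#' @examples
#' quarterly_prob(0.08) # 1 - 0.92^0.25
quarterly_prob <- function(annual_prob) {
  check_prob(annual_prob, "annual_prob")
  1 - (1 - annual_prob)^0.25
}

#' Apply one quarter of ageing, mortality and fertility
#'
#' Ages the given agents by 0.25 years, draws deaths from the quarterly
#' mortality probability of each agent's age band, and draws births for agents
#' in the reproductive band. A newborn starts at the parent's district with age
#' 0, zero wealth and capital, no portfolio, and a maximal-strength network
#' link to the parent. On death the agent's layer slots are released, its
#' network links dissolve, and its wealth passes to the strongest-linked
#' surviving agent (destroyed if none).
#'
#' Newborn heterogeneity (risk aversion, discounting, event probabilities) is
#' drawn fresh from the world configuration ranges; layer access is not
#' inherited.
#'
#' @param pop a population (see [generate_population()]).
#' @param idx indices of alive agents to step, in processing order.
#' @param schedules a [demography_schedules()] object.
#' @param links a link set (see [links_new()]); may be `NULL` for isolated
#'   demography tests.
#' @param t current quarter (integer), recorded on events.
#' @return A list with integer vectors `deaths` (agent ids that died) and
#'   `births` (ids of newborns).
#' @export
step_demography <- function(pop, idx, schedules, links = NULL, t = 0L) {
  if (any(!pop$alive[idx])) stop_arg("step_demography called on a dead agent")
  if (length(idx) == 0L) return(list(deaths = integer(), births = integer()))
  was_minor <- pop$age[idx] < schedules$adult_age
  pop$age[idx] <- pop$age[idx] + 0.25
  came_of_age <- idx[was_minor & pop$age[idx] >= schedules$adult_age]
  for (i in came_of_age) endow_new_adult(pop, links, i)

  p_die <- quarterly_prob(band_rate(pop$age[idx], schedules$mortality))
  dying <- idx[runif(length(idx)) < p_die]

  p_birth <- quarterly_prob(band_rate(pop$age[idx], schedules$fertility))
  parents <- idx[runif(length(idx)) < p_birth]
  parents <- setdiff(parents, dying)

  for (i in dying) {
    kill_agent(pop, links, i)
  }
  births <- integer(length(parents))
  for (k in seq_along(parents)) {
    births[k] <- spawn_agent(pop, links, parents[k])
  }
  list(deaths = dying, births = births)
}

# Death bookkeeping: release slots, inherit wealth across the strongest link,
# dissolve links. Returns the amount inherited (0 if destroyed).
kill_agent <- function(pop, links, i) {
  pop$alive[i] <- FALSE
  port <- pop$port[[i]]
  if (length(port)) pop$holders[port] <- pop$holders[port] - 1L
  pop$port[[i]] <- integer()
  pop$port_str[i] <- ""
  pop$sector_mask[i] <- 0L
  inherited <- 0
  heir <- NA_integer_
  # only positive wealth passes on: debts die with the debtor
  if (!is.null(links) && pop$wealth[i] > 0) {
    e <- link_indices(links, i)
    if (length(e)) {
      partner <- ifelse(links$a[e] == i, links$b[e], links$a[e])
      ok <- pop$alive[partner]
      if (any(ok)) {
        j <- which(ok)[which.max(links$w[e][ok])]
        heir <- partner[j]
        inherited <- pop$wealth[i]
        pop$wealth[heir] <- pop$wealth[heir] + inherited
        pop$inherit_in[heir] <- pop$inherit_in[heir] + inherited
      }
      links$act[e] <- FALSE
    }
  }
  pop$wealth[i] <- 0
  invisible(inherited)
}

# Household-formation transfer: an agent reaching the decision-making age
# receives a share of the wealth of its strongest-linked alive contact
# (normally the parent). Zero-sum, booked as a transfer in the ledger.
endow_new_adult <- function(pop, links, i) {
  frac <- pop$cfg$endowment_fraction
  if (is.null(links) || is.null(frac) || frac <= 0) return(invisible())
  e <- link_indices(links, i)
  if (!length(e)) return(invisible())
  partner <- link_partners(links, i, e)
  ok <- pop$alive[partner] & pop$wealth[partner] > 0
  if (!any(ok)) return(invisible())
  j <- partner[which(ok)[which.max(links$w[e][ok])]]
  amt <- frac * pop$wealth[j]
  pop$wealth[j] <- pop$wealth[j] - amt
  pop$wealth[i] <- pop$wealth[i] + amt
  pop$transfer_net[j] <- pop$transfer_net[j] - amt
  pop$transfer_net[i] <- pop$transfer_net[i] + amt
  invisible(amt)
}

spawn_agent <- function(pop, links, parent) {
  cfg <- pop$cfg
  id <- add_agent(
    pop,
    district = pop$district[parent],
    age = 0,
    wealth = 0,
    rho = runif(1, cfg$rho_range[1], cfg$rho_range[2]) * pop$rho_scale,
    disc = runif(1, cfg$discount_range[1], cfg$discount_range[2]),
    p_rec = cfg$p_reconsider_mean *
      runif(1, cfg$p_reconsider_rel_range[1], cfg$p_reconsider_rel_range[2]),
    p_meet = runif(1, cfg$p_meet_range[1], cfg$p_meet_range[2]),
    p_int = runif(1, cfg$p_interact_range[1], cfg$p_interact_range[2])
  )
  if (!is.null(links)) add_link(links, parent, id, 1)
  id
}
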