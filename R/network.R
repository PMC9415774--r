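#' Social network parameters
#'
#' Links are undirected, weighted in `(0, 1]`, fade geometrically each quarter
#' (faster across districts, realizing "moorings" that lose force with
#' distance) and are strengthened by interaction. They carry income
#' observations (information) and resource transfers (remittances).
#'
#' @param decay per-quarter strength decay fraction `d` in `[0, 1)`.
#' @param alpha strengthening gain in `(0, 1)`: `w <- w + alpha * (1 - w)`.
#' @param w0 initial strength of a new link.
#' @param w_min prune threshold; links below it dissolve.
#' @param phi fraction of an agent's surplus shared across its links.
#' @param info_share_prob probability an income observation crosses a
#'   full-strength link; scales with link strength.
#' @param distance_penalty extra decay multiplier for cross-district links:
#'   their decay rate is `decay * (1 + distance_penalty)`.
#' @param meet_weights sampling weights for meeting a new partner:
#'   same-district, friend-of-friend, same-sector-anywhere, any other agent.
#' @export
network_params <- function(decay = 0.08, alpha = 0.25, w0 = 0.5, w_min = 0.05,
                           phi = 0.2, info_share_prob = 0.5,
                           distance_penalty = 1,
                           meet_weights = c(same_district = 3, fof = 2,
                                            same_sector = 2, other = 1)) {
  if (decay < 0 || decay >= 1) stop_arg("decay must lie in [0, 1)")
  if (alpha <= 0 || alpha >= 1) stop_arg("alpha must lie in (0, 1)")
  if (w0 <= 0 || w0 > 1) stop_arg("w0 must lie in (0, 1]")
  if (w_min < 0 || w_min >= w0) stop_arg("w_min must lie in [0, w0)")
  check_prob(phi, "phi")
  check_prob(info_share_prob, "info_share_prob")
  structure(
    list(
      decay = decay, alpha = alpha, w0 = w0, w_min = w_min, phi = phi,
      info_share_prob = info_share_prob, distance_penalty = distance_penalty,
      meet_weights = meet_weights
    ),
    class = c("network_params", "list")
  )
}

#' Create an empty link set
#'
#' Links are stored as parallel vectors in an environment (unordered agent
#' pairs, strength, active flag) so the quarterly decay sweep is a single
#' vectorized pass.
#'
#' @param capacity initial edge-slot capacity.
#' @return environment of class `link_set`.
#' @export
links_new <- function(capacity = 256L) {
  ln <- new.env(parent = emptyenv())
  ln$a <- integer(capacity)
  ln$b <- integer(capacity)
  ln$w <- numeric(capacity)
  ln$act <- logical(capacity)
  ln$n <- 0L
  ln$cap <- as.integer(capacity)
  # adjacency index: per-agent edge-slot ids (edge slots are never reused, so
  # stored ids stay valid; stale entries are filtered lazily on read)
  ln$adj <- list()
  class(ln) <- c("link_set", "environment")
  ln
}

#' @rdname links_new
#' @param ln a link set.
#' @param i,j agent ids (no self-links).
#' @param w initial strength in `(0, 1]`.
#' @export
add_link <- function(ln, i, j, w) {
  if (i == j) stop_arg("self-links are not allowed")
  if (ln$n >= ln$cap) {
    old <- ln$cap
    ln$a <- c(ln$a, integer(old)); ln$b <- c(ln$b, integer(old))
    ln$w <- c(ln$w, numeric(old)); ln$act <- c(ln$act, logical(old))
    ln$cap <- old * 2L
  }
  k <- ln$n + 1L
  ln$n <- k
  ln$a[k] <- min(i, j)
  ln$b[k] <- max(i, j)
  ln$w[k] <- w
  ln$act[k] <- TRUE
  top <- max(i, j)
  if (length(ln$adj) < top) ln$adj[[top]] <- integer(0)
  ln$adj[[i]] <- c(ln$adj[[i]], k)
  ln$adj[[j]] <- c(ln$adj[[j]], k)
  invisible(k)
}

#' @rdname links_new
#' @export
link_indices <- function(ln, i) {
  if (length(ln$adj) < i) return(integer(0))
  e <- ln$adj[[i]]
  if (is.null(e) || !length(e)) return(integer(0))
  keep <- ln$act[e]
  if (!all(keep)) {
    e <- e[keep]
    ln$adj[[i]] <- e
  }
  e
}

# one endpoint of each incident edge is i, so the partner is a + b - i
link_partners <- function(ln, i, e = link_indices(ln, i)) {
  ln$a[e] + ln$b[e] - i
}

#' Decay all link strengths
#'
#' Every strength decays to `w * (1 - d_eff)` where `d_eff = d` for links
#' whose endpoints share a district and `d * (1 + distance_penalty)`
#' otherwise; links falling below the prune threshold dissolve.
#'
#' @param ln a link set.
#' @param d per-quarter decay fraction in `[0, 1)`.
#' @param nw a [network_params()] object (prune threshold, distance penalty).
#' @param pop optionally, the population (to classify links as cross-district);
#'   when `NULL` all links decay at the base rate.
#' @return the link set, invisibly.
#' @export
decay_links <- function(ln, d, nw = network_params(), pop = NULL) {
  if (d < 0 || d >= 1) stop_arg("decay must lie in [0, 1)")
  if (ln$n == 0L || d == 0) return(invisible(ln))
  s <- which(ln$act[seq_len(ln$n)])
  if (!length(s)) return(invisible(ln))
  d_eff <- rep(d, length(s))
  if (!is.null(pop) && nw$distance_penalty > 0) {
    cross <- pop$district[ln$a[s]] != pop$district[ln$b[s]]
    d_eff[cross] <- pmin(d * (1 + nw$distance_penalty), 1 - 1e-12)
  }
  ln$w[s] <- ln$w[s] * (1 - d_eff)
  drop <- s[ln$w[s] < nw$w_min]
  ln$act[drop] <- FALSE
  invisible(ln)
}

#' Strengthen a link by interaction
#'
#' `w <- w + alpha * (1 - w)`; strength 1 is a fixed point so links never
#' exceed full strength.
#'
#' @param ln a link set.
#' @param e edge index (from [link_indices()]).
#' @param alpha gain in `(0, 1)`.
#' @export
strengthen <- function(ln, e, alpha) {
  if (alpha <= 0 || alpha >= 1) stop_arg("alpha must lie in (0, 1)")
  ln$w[e] <- ln$w[e] + alpha * (1 - ln$w[e])
  invisible(ln)
}

#' Meet a new agent
#'
#' Forms one new link at strength `w0` to a partner sampled among alive agents
#' with categorical weights: same-district agents, friends-of-friends,
#' same-sector agents anywhere, and all others. Existing partners and the
#' agent itself are excluded; a single-agent world never forms a link.
#' (The per-quarter meet probability is applied by the caller.)
#'
#' @param pop population.
#' @param ln link set.
#' @param i agent id.
#' @param nw a [network_params()] object.
#' @return id of the new partner, or `NA` if none was available.
#' @export
meet_new <- function(pop, ln, i, nw) {
  n <- pop$n
  wts <- numeric(n)
  alive <- pop$alive[seq_len(n)]
  wts[alive] <- nw$meet_weights[["other"]]
  if (nw$meet_weights[["same_sector"]] > 0 && pop$sector_mask[i] > 0L) {
    same_sec <- alive & bitwAnd(pop$sector_mask[seq_len(n)], pop$sector_mask[i]) > 0L
    wts[same_sec] <- pmax(wts[same_sec], nw$meet_weights[["same_sector"]])
  }
  e <- link_indices(ln, i)
  partners <- link_partners(ln, i, e)
  if (length(partners) && nw$meet_weights[["fof"]] > 0) {
    fof <- unique(unlist(lapply(partners, function(p) link_partners(ln, p))))
    fof <- fof[fof != i & pop$alive[fof]]
    wts[fof] <- pmax(wts[fof], nw$meet_weights[["fof"]])
  }
  same_d <- alive & pop$district[seq_len(n)] == pop$district[i]
  wts[same_d] <- pmax(wts[same_d], nw$meet_weights[["same_district"]])
  wts[i] <- 0
  wts[partners] <- 0
  if (all(wts == 0)) return(NA_integer_)
  j <- sample.int(n, 1L, prob = wts)
  add_link(ln, i, j, nw$w0)
  j
}

#' Share surplus resources across links
#'
#' Transfers `phi * surplus` in total, split across the agent's links in
#' proportion to link strength; each transfer is credited to the recipient and
#' debited from the sender, and accumulated into both agents' trailing
#' transfer histories for remittance expectations.
#'
#' @param pop population.
#' @param ln link set.
#' @param i sending agent.
#' @param surplus non-negative income above the consumption need.
#' @param nw a [network_params()] object.
#' @param row row of the trailing transfer-history buffer to accumulate into.
#' @return list with parallel `recipient` and `amount` vectors (possibly
#'   empty), invisibly.
#' @export
share_resources <- function(pop, ln, i, surplus, nw, row = 1L) {
  if (surplus < 0) stop_arg("surplus must be non-negative")
  e <- link_indices(ln, i)
  e <- e[pop$alive[link_partners(ln, i, e)]]
  if (!length(e) || surplus == 0 || nw$phi == 0) {
    return(invisible(list(recipient = integer(), amount = numeric())))
  }
  rec <- link_partners(ln, i, e)
  amt <- nw$phi * surplus * ln$w[e] / sum(ln$w[e])
  pop$wealth[i] <- pop$wealth[i] - sum(amt)
  pop$wealth[rec] <- pop$wealth[rec] + amt
  pop$transfer_net[i] <- pop$transfer_net[i] - sum(amt)
  pop$transfer_net[rec] <- pop$transfer_net[rec] + amt
  pop$transfer_hist[row, i] <- pop$transfer_hist[row, i] - sum(amt)
  pop$transfer_hist[row, rec] <- pop$transfer_hist[row, rec] + amt
  invisible(list(recipient = rec, amount = amt))
}

#' Share income observations across links
#'
#' Each (link, observation) pair propagates with probability
#' `info_share_prob * strength`; delivered observations enter the recipient's
#' bounded per-layer income memory. By default the observations shared are the
#' current wages of the agent's own portfolio layers.
#'
#' @param pop population.
#' @param ln link set.
#' @param i sharing agent.
#' @param nw a [network_params()] object.
#' @param obs optional list/data frame with `layer` and `value` vectors of
#'   observations to share; defaults to the agent's portfolio layers at
#'   `current_income`.
#' @param current_income per-layer current income vector (used for the default
#'   observations).
#' @return number of delivered observations.
#' @export
share_information <- function(pop, ln, i, nw, obs = NULL, current_income = NULL) {
  if (is.null(obs)) {
    port <- pop$port[[i]]
    if (!length(port)) return(0L)
    obs <- list(layer = port, value = current_income[port])
  }
  k <- length(obs$layer)
  if (!k || nw$info_share_prob == 0) return(0L)
  e <- link_indices(ln, i)
  rec <- link_partners(ln, i, e)
  keep <- pop$alive[rec]
  e <- e[keep]; rec <- rec[keep]
  if (!length(e)) return(0L)
  p <- rep(nw$info_share_prob * ln$w[e], each = k)
  hit <- runif(length(p)) < p
  if (!any(hit)) return(0L)
  lay <- rep(obs$layer, times = length(e))[hit]
  val <- rep(obs$value, times = length(e))[hit]
  to <- rep(rec, each = k)[hit]
  # collapse duplicate (agent, layer) deliveries within this call
  dup <- duplicated(to * (pop$nL + 1) + lay)
  mem_append(pop, lay[!dup], to[!dup], val[!dup])
  sum(hit)
}

#' Expected remittance rate at a candidate district
#'
#' The agent's trailing-four-quarter mean net transfer rate, scaled by the
#' fraction of total link strength that would be retained after moving to the
#' candidate district relative to staying put. Links to residents of the
#' candidate district are retained in full; other links are discounted by the
#' cross-district retention factor `1 / (1 + distance_penalty)`. Evaluating the
#' current district therefore returns the trailing mean unchanged.
#'
#' @param pop population.
#' @param ln link set.
#' @param i agent id.
#' @param candidate candidate district id.
#' @param nw a [network_params()] object.
#' @param t current quarter (trailing window is `min(t, 4)` quarters).
#' @param e optional precomputed incident-edge indices for agent `i`.
#' @return expected net transfer rate, currency per quarter (may be negative).
#' @export
expected_remittances <- function(pop, ln, i, candidate, nw, t = 4L, e = NULL) {
  denom <- max(1L, min(t, 4L))
  base_rate <- sum(pop$transfer_hist[, i]) / denom
  if (base_rate == 0) return(0)
  if (is.null(e)) e <- link_indices(ln, i)
  if (!length(e)) return(base_rate)
  partners <- link_partners(ln, i, e)
  kappa <- 1 / (1 + nw$distance_penalty)
  pd <- pop$district[partners]
  ret <- function(dst) sum(ln$w[e] * (kappa + (1 - kappa) * (pd == dst)))
  s_cur <- ret(pop$district[i])
  if (s_cur == 0) return(base_rate)
  base_rate * ret(candidate) / s_cur
}
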