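test_that("CRRA utility matches closed forms and is continuous through rho = 1", {
  expect_equal(crra_utility(1, 0), 0)
  expect_equal(crra_utility(1, 1), 0)
  expect_equal(crra_utility(1, 3.7), 0)
  expect_equal(crra_utility(4, 0.5), 2)
  expect_equal(crra_utility(exp(1), 1), 1)
  expect_lt(abs(crra_utility(exp(1), 0.999999) - crra_utility(exp(1), 1)), 1e-5)
  expect_error(crra_utility(0, 1), "positive")
  expect_error(crra_utility(-2, 1), "positive")
})

test_that("prospect value is reference-anchored and loss-averse", {
  expect_equal(prospect_value(5, 5, 0.7, 2.25), 0)
  # lambda = 1 reduces to a plain utility difference
  expect_equal(
    prospect_value(3, 2, 0.5, 1),
    crra_utility(3, 0.5) - crra_utility(2, 0.5)
  )
  # rho = 0 is linear: losing 0.5 against lambda = 2 doubles the pain
  expect_equal(prospect_value(0.5, 1, 0, 2), -1)
  expect_error(prospect_value(1, 1, 0, 0.5), "lambda")
  # monotone in income
  y <- seq(0.5, 4, by = 0.25)
  v <- prospect_value(y, 2, 1.2, 2.25)
  expect_true(all(diff(v) > 0))
  # losses hurt more than equal-sized utility gains please
  g <- prospect_value(3, 2, 0.5, 2.25)
  l <- prospect_value(2, 3, 0.5, 2.25)
  expect_gt(abs(l) / g, 2.24)
})

test_that("portfolio enumeration respects time budget, size cap and ordering", {
  w <- toy_world()
  sub <- district_subsets(w, 1L, max_layers = 3L)
  # two 0.5-time layers: {}, {1}, {2}, {1,2}
  expect_equal(nrow(sub$S), 4)
  expect_equal(sub$sizes, c(0, 1, 1, 2))
  # a full-time layer excludes combinations
  w2 <- toy_world()
  w2$layers$time_req <- c(1, 0.5, 0.5, 0.5)
  sub2 <- district_subsets(w2, 1L, max_layers = 3L)
  expect_equal(nrow(sub2$S), 3) # {}, {1}, {2}
  # size cap
  w3 <- toy_world()
  w3$layers$time_req <- rep(0.25, 4)
  w3$layers$district <- rep(1L, 4)
  sub3 <- district_subsets(w3, 1L, max_layers = 2L)
  expect_equal(max(sub3$sizes), 2)
})

test_that("option cost adds unaccessed layers and distance-based moving cost", {
  w <- toy_world(moving_cost_base = 5, moving_cost_per_dist = 1)
  pop <- toy_population(w, n = 1, wealth = 100)
  pop$accessed[[1]] <- 1L
  expect_equal(as.numeric(option_cost(pop, 1, 1L, 1L, w)), 0)
  # district 2 at distance 10: move 5 + 1 * 10; layer 3 access 15
  cost <- option_cost(pop, 1, 2L, 3L, w)
  expect_equal(as.numeric(cost), 15 + 15)
  expect_equal(attr(cost, "access"), 15)
  # re-held accessed layers are free
  expect_equal(as.numeric(option_cost(pop, 1, 1L, 1L, w)), 0)
})

test_that("affordability uses wealth plus credit against capital, boundary inclusive", {
  expect_true(affordable(0, -5, 10, 0)) # zero cost always affordable
  expect_true(affordable(20, 10, 5, 2)) # boundary met with equality
  expect_false(affordable(20.0001, 10, 5, 2))
  expect_false(affordable(11, 10, 5, 0)) # creditless agents live on wealth
  expect_error(affordable(1, 0, 0, 3), "credit_multiplier")
})

test_that("candidate districts are ranked by link pull with distance tie-breaks", {
  w <- generate_world(world_config(n_districts = 5L, n_coastal = 1L), seed = 2)
  pop <- toy_population(w, n = 4, district = 1L)
  pop$district[2] <- 3L
  pop$district[3] <- 4L
  pop$district[4] <- 4L
  ln <- links_new()
  add_link(ln, 1, 2, 0.3) # pull 0.3 toward district 3
  add_link(ln, 1, 3, 0.5)
  add_link(ln, 1, 4, 0.4) # pull 0.9 toward district 4
  expect_equal(rank_candidate_districts(pop, ln, 1, w, 1L), 1L)
  expect_equal(rank_candidate_districts(pop, ln, 1, w, 3L), c(1L, 4L, 3L))
  # k >= D: all districts, current first, zero-pull ones by distance then id
  all5 <- rank_candidate_districts(pop, ln, 1, w, 99L)
  expect_equal(length(all5), 5L)
  expect_equal(all5[1], 1L)
  expect_setequal(all5, 1:5)
  rest <- setdiff(all5[-(1:3)], integer())
  expect_equal(rest, rest[order(w$dist[1, rest])])
})

test_that("best portfolio in a district is the exhaustive argmax", {
  w <- toy_world()
  pop <- toy_population(w, n = 1, wealth = 1000, rho = 1)
  ln <- links_new()
  # two non-overlapping positive-income layers in district 2: hold both
  best <- best_portfolio_in_district(pop, ln, 1, 2L, w, w$config$decision,
    w$config$network,
    t = 4L
  )
  expect_setequal(best$layers, c(3L, 4L))
  # empty district yields the empty portfolio
  w0 <- toy_world()
  w0$layers <- w0$layers[0, ]
  pop0 <- toy_population(w0, n = 1)
  pop0$nL <- 0L
  b0 <- best_portfolio_in_district(pop0, ln, 1, 2L, w0, w0$config$decision,
    w0$config$network,
    t = 4L
  )
  expect_length(b0$layers, 0)
})

test_that("evaluating the current portfolio against itself scores zero", {
  w <- toy_world()
  pop <- toy_population(w, n = 1, wealth = 100)
  pop$port[[1]] <- c(1L, 2L)
  pop$accessed[[1]] <- c(1L, 2L)
  pop$holders[1:2] <- 1L
  ln <- links_new()
  expect_equal(
    portfolio_value(pop, ln, 1, 1L, c(1L, 2L), w, t = 4L),
    0
  )
  # single-period linear case: H = 1, r = 0, lambda = 1, rho = 0, y = ref + 1
  w1 <- toy_world()
  w1$layers$current_income[1] <- 1
  w1$layers$base_income[1] <- 1
  pop1 <- toy_population(w1, n = 1, wealth = 10, rho = 0, disc = 0)
  pop1$dh[1] <- 1 # H = 1, r = 0
  mem_append(pop1, 2L, 1L, 2) # candidate layer 2 expected at 2
  mem_append(pop1, 1L, 1L, 1) # current layer 1 expected at 1
  pop1$port[[1]] <- 1L
  pop1$accessed[[1]] <- 1L
  dp <- decision_params(lambda = 1)
  expect_equal(
    portfolio_value(pop1, links_new(), 1, 1L, 2L, w1, dp, w1$config$network, 4L),
    1
  )
})


test_that("reconsider agrees with the brute-force argmax over random agent states", {
  n_states <- 60
  with_seed(314, {
    for (rep in seq_len(n_states)) {
      w <- tiny_world(seed = sample.int(1e6, 1))
      w$params$credit_multiplier <- runif(1, 0, 2)
      pop <- generate_population(w, 6, seed = sample.int(1e6, 1))
      i <- sample.int(6, 1)
      pop$age[i] <- max(pop$age[i], 20)
      pop$wealth[i] <- runif(1, -0.5 * pop$capital[i], 600)
      ln <- links_new()
      for (j in setdiff(1:6, i)) {
        if (runif(1) < 0.6) add_link(ln, i, j, runif(1, 0.1, 1))
      }
      # random income memories so expectations differ from current wages
      for (l in sample(nrow(w$layers), 4)) {
        mem_append(pop, l, i, w$layers$base_income[l] * runif(1, 0.5, 2))
      }
      dp <- decision_params(k_locations = 5L) # >= D: all districts considered
      nw <- w$config$network
      oracle <- brute_force_choice(pop, ln, i, w, dp, nw, t = 8L)

      out <- reconsider(pop, ln, i, w, dp, nw, t = 8L)
      expect_equal(out$action, oracle$action, info = paste("state", rep))
      expect_equal(out$moored_event, oracle$moored, info = paste("state", rep))
      if (!is.null(oracle$layers)) {
        expect_equal(out$district, oracle$district, info = paste("state", rep))
        expect_setequal(out$layers, oracle$layers)
      }
    }
  })
})

test_that("reconsider pays costs, claims capacity, builds capital, and tags mooring", {
  w <- toy_world(credit_multiplier = 0, moving_cost_base = 5, moving_cost_per_dist = 1)
  nw <- w$config$network
  dp <- decision_params(k_locations = 2L)
  # agent in district 1 with modest wealth; district 2 wages are better
  pop <- toy_population(w, n = 1, wealth = 100, rho = 0.5)
  ln <- links_new()
  out <- reconsider(pop, ln, 1, w, dp, nw, t = 4L)
  expect_equal(out$action, "move")
  expect_equal(out$district, 2L)
  expect_setequal(out$layers, c(3L, 4L))
  expect_equal(pop$district[1], 2L)
  expect_equal(pop$wealth[1], 100 - (15 + 30) - (5 + 10))
  expect_equal(pop$capital[1], 45) # moving costs are not capital
  expect_equal(pop$holders[3:4], c(1L, 1L))
  expect_equal(pop$n_moves[1], 1L)
  expect_false(pop$moored[1])

  # an agent that cannot afford any strictly better option is moored
  pop2 <- toy_population(w, n = 1, wealth = 1)
  out2 <- reconsider(pop2, ln, 1, w, dp, nw, t = 4L)
  expect_equal(out2$action, "stay-moored")
  expect_true(out2$moored_event)
  expect_true(pop2$moored[1])
  expect_equal(pop2$moves_at_moor[1], 0L)
  # and the wealth never moved
  expect_equal(pop2$wealth[1], 1)

  # an agent already holding the global best has no better option: stay, no tag
  pop3 <- toy_population(w, n = 1, wealth = 1000, district = 2L)
  pop3$port[[1]] <- c(3L, 4L)
  pop3$accessed[[1]] <- c(3L, 4L)
  pop3$holders[3:4] <- 1L
  mem_append(pop3, 3L, 1L, 120)
  mem_append(pop3, 4L, 1L, 200)
  out3 <- reconsider(pop3, ln, 1, w, dp, nw, t = 4L)
  expect_equal(out3$action, "stay")
  expect_false(out3$moored_event)
  expect_false(pop3$moored[1])
})

test_that("capacity-saturated layers are not candidates", {
  w <- toy_world()
  w$layers$capacity <- c(5L, 5L, 1L, 1L)
  pop <- toy_population(w, n = 2, wealth = 500)
  ln <- links_new()
  dp <- decision_params(k_locations = 2L)
  # first mover takes district 2 slots
  reconsider(pop, ln, 1, w, dp, w$config$network, 4L)
  expect_equal(pop$district[1], 2L)
  # second agent sees district 2 full; best remaining is at home
  out2 <- reconsider(pop, ln, 2, w, dp, w$config$network, 4L)
  expect_false(identical(sort(out2$layers), c(3L, 4L)))
  expect_true(all(pop$holders <= w$layers$capacity))
})
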