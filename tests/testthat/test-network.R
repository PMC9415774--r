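test_that("link decay is geometric, prunes weak links, and respects identity at d = 0", {
  ln <- links_new()
  add_link(ln, 1, 2, 0.5)
  decay_links(ln, 0.1, network_params(w_min = 0))
  expect_equal(ln$w[1], 0.45)
  decay_links(ln, 0, network_params(w_min = 0))
  expect_equal(ln$w[1], 0.45)
  # repeated decay with a positive prune threshold empties the set
  nw <- network_params(w_min = 0.05)
  for (k in 1:100) decay_links(ln, 0.1, nw)
  expect_length(link_indices(ln, 1), 0)
  expect_error(decay_links(ln, 1), "decay")
})

test_that("cross-district links decay faster than co-located links", {
  w <- toy_world()
  pop <- toy_population(w, n = 3)
  pop$district[3] <- 2L
  ln <- links_new()
  add_link(ln, 1, 2, 0.8) # same district
  add_link(ln, 1, 3, 0.8) # cross-district
  decay_links(ln, 0.1, network_params(distance_penalty = 1, w_min = 0), pop)
  expect_equal(ln$w[1], 0.8 * 0.9)
  expect_equal(ln$w[2], 0.8 * 0.8)
})

test_that("strengthening is bounded by full strength", {
  ln <- links_new()
  add_link(ln, 1, 2, 0.5)
  strengthen(ln, 1, 0.2)
  expect_equal(ln$w[1], 0.6)
  ln$w[1] <- 1
  strengthen(ln, 1, 0.3)
  expect_equal(ln$w[1], 1)
  for (k in 1:50) {
    strengthen(ln, 1, 0.9)
    decay_links(ln, 0.5, network_params(w_min = 0))
  }
  expect_lte(ln$w[1], 1)
  expect_error(strengthen(ln, 1, 1.2), "alpha")
})

test_that("meeting respects exclusions and the same-district weighting", {
  w <- toy_world()
  pop <- toy_population(w, n = 1)
  ln <- links_new()
  expect_true(is.na(meet_new(pop, ln, 1, network_params()))) # nobody to meet
  expect_equal(ln$n, 0L)

  # with only same-district weight nonzero, all new links are intra-district
  pop2 <- toy_population(w, n = 40)
  pop2$district[21:40] <- 2L
  nw <- network_params(meet_weights = c(
    same_district = 1, fof = 0, same_sector = 0, other = 0
  ))
  with_seed(21, {
    for (k in 1:200) {
      i <- sample.int(40, 1)
      j <- meet_new(pop2, ln, i, nw)
      if (!is.na(j)) expect_equal(pop2$district[j], pop2$district[i])
    }
  })
  # no self-links or duplicates ever
  act <- which(ln$act[seq_len(ln$n)])
  expect_true(all(ln$a[act] != ln$b[act]))
  expect_equal(anyDuplicated(cbind(ln$a[act], ln$b[act])), 0)
})

test_that("resource sharing splits by strength and conserves money", {
  w <- toy_world()
  pop <- toy_population(w, n = 3, wealth = 100)
  ln <- links_new()
  add_link(ln, 1, 2, 0.6)
  add_link(ln, 1, 3, 0.2)
  nw <- network_params(phi = 0.2)
  out <- share_resources(pop, ln, 1, 10, nw, row = 1L)
  expect_equal(sort(out$amount), c(0.5, 1.5)) # 2 split 3:1
  expect_equal(out$amount[out$recipient == 2], 1.5)
  expect_equal(pop$wealth[1], 98)
  expect_equal(sum(pop$wealth[1:3]), 300) # zero-sum
  expect_equal(sum(pop$transfer_net[1:3]), 0)
  # no links, or zero surplus: no transfers
  expect_length(share_resources(pop, ln, 2, 0, nw)$amount, 0)
  expect_error(share_resources(pop, ln, 1, -1, nw), "non-negative")
  # total transferred never exceeds the surplus
  out2 <- share_resources(pop, ln, 1, 50, network_params(phi = 1), row = 1L)
  expect_lte(sum(out2$amount), 50 + 1e-12)
})

test_that("information propagates in proportion to strength and share probability", {
  w <- toy_world()
  pop <- toy_population(w, n = 2)
  pop$port[[1]] <- 1L
  ln <- links_new()
  add_link(ln, 1, 2, 0.5)
  # p = 0: nothing delivered
  expect_equal(
    share_information(pop, ln, 1, network_params(info_share_prob = 0),
      current_income = w$layers$current_income
    ), 0L
  )
  # p = 1 and full strength: everything delivered
  ln$w[1] <- 1
  n_del <- share_information(pop, ln, 1, network_params(info_share_prob = 1),
    current_income = w$layers$current_income
  )
  expect_equal(n_del, 1L)
  expect_equal(mem_expected(pop, 2L, 1L, w$layers$current_income), 100)
  # Bernoulli expectation at p = 0.5, strength 0.5
  ln$w[1] <- 0.5
  nw <- network_params(info_share_prob = 0.5)
  tot <- with_seed(31, {
    sum(replicate(10000, share_information(pop, ln, 1, nw,
      current_income = w$layers$current_income
    )))
  })
  expect_gt(tot, 2500 - 3 * sqrt(10000 * 0.25 * 0.75))
  expect_lt(tot, 2500 + 3 * sqrt(10000 * 0.25 * 0.75))
})

test_that("income memory is a bounded FIFO with exact running means", {
  w <- toy_world()
  pop <- toy_population(w, n = 1)
  vals <- 1:12
  for (v in vals) mem_append(pop, 1L, 1L, v)
  # capacity 8: only the last 8 observations remain
  expect_equal(
    mem_expected(pop, 1L, 1L, w$layers$current_income),
    mean(5:12)
  )
  # untouched layer falls back to current income
  expect_equal(mem_expected(pop, 1L, 2L, w$layers$current_income), 150)
})

test_that("remittance expectations scale with retained link strength", {
  w <- toy_world()
  pop <- toy_population(w, n = 3)
  pop$district[2] <- 1L
  pop$district[3] <- 2L
  nw <- network_params(distance_penalty = 1) # kappa = 0.5
  ln <- links_new()
  # zero transfer history: zero expectation
  expect_equal(expected_remittances(pop, ln, 1, 2L, nw, t = 8), 0)
  pop$transfer_hist[, 1] <- c(4, 4, 4, 4) # trailing mean +4 per quarter
  # no links: the rate carries over unchanged
  expect_equal(expected_remittances(pop, ln, 1, 1L, nw, t = 8), 4)
  add_link(ln, 1, 2, 0.5) # co-located partner
  add_link(ln, 1, 3, 0.5) # partner in district 2
  # staying home: scale exactly 1
  expect_equal(expected_remittances(pop, ln, 1, 1L, nw, t = 8), 4)
  # moving to district 2 swaps which link is discounted; symmetric here
  expect_equal(expected_remittances(pop, ln, 1, 2L, nw, t = 8), 4)
  # drop the distant link: moving away now halves retained strength
  ln$act[2] <- FALSE
  expect_equal(
    expected_remittances(pop, ln, 1, 2L, nw, t = 8),
    4 * 0.5 / 1
  )
})

test_that("an isolated decaying network monotonically loses total strength", {
  w <- toy_world()
  pop <- toy_population(w, n = 10)
  ln <- links_new()
  with_seed(77, {
    for (k in 1:15) {
      p <- sample.int(10, 2)
      add_link(ln, p[1], p[2], runif(1, 0.3, 1))
    }
  })
  nw <- network_params()
  tot <- function() sum(ln$w[which(ln$act[seq_len(ln$n)])])
  prev <- tot()
  for (k in 1:20) {
    decay_links(ln, nw$decay, nw, pop)
    expect_lte(tot(), prev + 1e-12)
    prev <- tot()
  }
})
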