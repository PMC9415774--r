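test_that("expected peak depth is the linear flood model and respects its domain", {
  w <- toy_world() # district 1: b = 0.5, s = 1; district 2: b = 0, s = 0
  base <- flood_scenario("baseline")
  expect_equal(expected_peak_depth(w, 1L, 2050, base), 0.5)
  # b = 0.5, s = 1, SLR = 0.25 at mid-century under a 0.5 m trajectory
  sc <- flood_scenario("rcp45", slr_end = 0.5, start_year = 2010, end_year = 2100)
  expect_equal(expected_peak_depth(w, 1L, 2055, sc), 0.5 + 1 * 0.25)
  # hand-set district: b = 0.5, s = 1.2, SLR = 0.25 -> 0.8
  w2 <- toy_world()
  w2$districts$flood_sens[1] <- 1.2
  expect_equal(expected_peak_depth(w2, 1L, 2055, sc), 0.8)
  # non-decreasing in year
  years <- 2010:2100
  d <- vapply(years, function(y) expected_peak_depth(w, 1L, y, sc), numeric(1))
  expect_true(all(diff(d) >= 0))
  expect_error(expected_peak_depth(w, 1L, 2101, sc), "domain")
})

test_that("sampled floods are unbiased, non-negative, and exact when noiseless", {
  w <- toy_world()
  sc0 <- flood_scenario("rcp85", beta = 0)
  expect_equal(
    sample_annual_flood(w, 1L, 2080, sc0),
    expected_peak_depth(w, 1L, 2080, sc0)
  )
  # mean of many draws matches the analytic mean when truncation is inactive
  w$districts$base_depth[1] <- 10
  sc <- flood_scenario("rcp85", beta = 0.4)
  mu <- expected_peak_depth(w, 1L, 2050, sc)
  draws <- with_seed(5, replicate(1e5, sample_annual_flood(w, 1L, 2050, sc)))
  expect_true(all(draws >= 0))
  expect_lt(abs(mean(draws) - mu) / mu, 0.01)
})

test_that("flood_shock follows the perceived-normal rule and its bounds", {
  expect_equal(flood_shock(1, 1, 1), 0)
  expect_equal(flood_shock(2, 1, 1.5), 0.5)
  expect_equal(flood_shock(0.3, 1, 0.5), 0)
  expect_error(flood_shock(1, 1, 0.4), "0.5, 1.5")
  expect_error(flood_shock(1, 1, 1.6), "0.5, 1.5")
  expect_error(flood_shock(-1, 1, 1), "non-negative")
  # larger m gives pointwise smaller-or-equal shocks
  depth <- seq(0, 3, by = 0.1)
  expect_true(all(flood_shock(depth, 1, 1.2) <= flood_shock(depth, 1, 0.8)))
})

test_that("wage damage saturates exponentially", {
  expect_equal(wage_damage_fraction(0, 0.4), 0)
  expect_equal(wage_damage_fraction(1, 0.4), 1 - exp(-0.4), tolerance = 1e-12)
  expect_lt(wage_damage_fraction(40, 0.4), 1)
  s <- seq(0, 5, by = 0.25)
  expect_true(all(diff(wage_damage_fraction(s, 0.4)) > 0))
  expect_error(wage_damage_fraction(-1, 0.4), "non-negative")
})

test_that("damage params require ag at least as exposed as non-ag", {
  expect_error(damage_params(delta_ag = 0.1, delta_nonag = 0.2), "delta_ag")
  expect_error(damage_params(recovery_quarters = 0), "recovery_quarters")
})

test_that("apply_damages scales wages by sector, overlaps take the max, windows expire", {
  w <- toy_world()
  dp <- damage_params(delta_ag = 0.4, delta_nonag = 0.2, recovery_quarters = 4L)
  shock1 <- data.frame(
    district = 1L, year = 2010, depth = 2, expected_depth = 1, shock = 1
  )
  w1 <- apply_damages(w, shock1, dp, quarter = 1L)
  lay <- w1$layers
  expect_equal(
    lay$current_income[lay$district == 1 & lay$sector == "ag"],
    100 * exp(-0.4),
    tolerance = 1e-12
  )
  expect_equal(
    lay$current_income[lay$district == 1 & lay$sector == "nonag"],
    150 * exp(-0.2),
    tolerance = 1e-12
  )
  # untouched district keeps base income
  expect_equal(lay$current_income[lay$district == 2], c(120, 200))
  # ag damaged at least as much as nonag, proportionally
  expect_true(exp(-0.4) <= exp(-0.2))
  # overlapping window: a smaller shock does not dilute the bigger one
  shock2 <- shock1
  shock2$shock <- 0.5
  w2 <- apply_damages(w1, shock2, dp, quarter = 3L)
  expect_equal(
    w2$layers$current_income[w2$layers$district == 1 & w2$layers$sector == "ag"],
    100 * exp(-0.4)
  )
  # expiry: after the recovery window wages return to base
  w3 <- refresh_layer_incomes(w2, 7L, dp)
  expect_equal(w3$layers$current_income, w3$layers$base_income)
  # zero shocks leave wages untouched
  z <- data.frame(district = 1L, year = 2010, depth = 1, expected_depth = 1, shock = 0)
  expect_equal(apply_damages(w, z, dp, 1L)$layers$current_income, w$layers$base_income)
  bad <- data.frame(district = 99L, year = 2010, depth = 1, expected_depth = 1, shock = 1)
  expect_error(apply_damages(w, bad, dp, 1L), "unknown district")
})

test_that("cumulative shocks are ordered rcp26 <= rcp45 <= rcp85 at fixed seed and m", {
  w <- default_world(seed = 3)
  coastal <- w$districts$id[w$districts$coastal]
  cum <- sapply(c("rcp26", "rcp45", "rcp85"), function(nm) {
    sc <- flood_scenario(nm, m = 1)
    # the perceived-normal baseline is the reference-period expectation
    mu_ref <- expected_peak_depth(w, w$districts$id, 2010, sc)
    with_seed(99, {
      tot <- numeric(nrow(w$districts))
      for (y in seq(2010, 2100, by = 5)) {
        # common noise across scenarios comes from the shared seed sequence
        depth <- sample_annual_flood(w, w$districts$id, y, sc)
        tot <- tot + flood_shock(depth, mu_ref, 1)
      }
      tot
    })
  })
  expect_true(all(cum[coastal, "rcp45"] >= cum[coastal, "rcp26"]))
  expect_true(all(cum[coastal, "rcp85"] >= cum[coastal, "rcp45"]))
  expect_gt(sum(cum[coastal, "rcp85"]), sum(cum[coastal, "rcp26"]))
})
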