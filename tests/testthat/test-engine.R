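test_that("behavioural constraints gate the conversion likelihood", {
  expect_equal(apply_constraints(0.2, "Forestry", "Dairy", 3), 0)
  expect_equal(apply_constraints(0.35, "CarbonForestry", "SheepBeef", 1), 0)
  expect_equal(apply_constraints(0.2, "SheepBeef", "Dairy", 0), 0.05)
  expect_equal(apply_constraints(0.3, "Dairy", "SheepBeef", 0), 0.3)
  # expired lock no longer binds
  expect_equal(apply_constraints(0.3, "Forestry", "SheepBeef", 0), 0.3)
  # clamping applies after the deltas under user-modified parameters
  expect_equal(apply_constraints(1.4, "SheepBeef", "Forestry", 0), 1)
})

test_that("a decision matching the current enterprise consumes no draws", {
  cf <- dominant_coeffs("SheepBeef")
  parcel <- list(parcel_id = "x", area_ha = 200, zone = "Plains",
                 enterprise = "SheepBeef", forest_lock_steps = 0L)
  farmer <- list(farmer_id = "A1")
  set.seed(123)
  before <- .Random.seed
  out <- evaluate_decision(farmer, parcel, market_state(1, 0), cf)
  expect_identical(.Random.seed, before)
  expect_false(out$record$converted)
  expect_equal(out$enterprise, "SheepBeef")
  expect_equal(out$net_revenue,
               enterprise_net_revenue(parcel, "SheepBeef",
                                      market_state(1, 0), cf))
})

test_that("zero final likelihood never converts", {
  cf <- dominant_coeffs("SheepBeef")
  parcel <- list(parcel_id = "x", area_ha = 200, zone = "Plains",
                 enterprise = "Dairy", forest_lock_steps = 0L)
  set.seed(4)
  for (i in 1:200) {
    out <- evaluate_decision(list(farmer_id = "A1"), parcel,
                             market_state(1, 0), cf,
                             initial_likelihood = 0)
    expect_false(out$record$converted)
    expect_equal(out$record$likelihood_final, 0)
  }
})

test_that("conversion into a forest enterprise starts the rotation lock", {
  cf <- dominant_coeffs("Forestry")
  parcel <- list(parcel_id = "x", area_ha = 200, zone = "Plains",
                 enterprise = "SheepBeef", forest_lock_steps = 0L)
  set.seed(1)
  out <- evaluate_decision(list(farmer_id = "A1"), parcel,
                           market_state(1, 0), cf, initial_likelihood = 1)
  expect_true(out$record$converted)
  expect_equal(out$enterprise, "Forestry")
  expect_equal(out$lock, 5L)
})

test_that("decision records satisfy converted <=> draw < likelihood", {
  tr <- run_simulation(small_cfg(scenario = list(ghg_price = 40)), seed = 3)
  d <- tr$decisions
  expect_gt(nrow(d), 0)
  expect_true(all(d$likelihood_final >= 0 & d$likelihood_final <= 1))
  expect_identical(d$converted, d$uniform_draw < d$likelihood_final)
})

test_that("a zero base likelihood freezes the landscape", {
  # networks disabled: endorsement/imitation deltas could otherwise lift
  # the zero base
  cfg <- small_cfg(behaviour = list(initial_likelihood = 0,
                                    network_effects = FALSE))
  tr <- run_simulation(cfg, seed = 6)
  for (col in paste0("area_", modelled_enterprises())) {
    expect_equal(unique(tr$ledger[[col]]), tr$ledger[[col]][1])
  }
  expect_true(all(!tr$decisions$converted))
})

test_that("identical (config, seed) pairs give identical trajectories", {
  cfg <- small_cfg(scenario = list(ghg_price = 20))
  a <- run_simulation(cfg, seed = 17)
  b <- run_simulation(cfg, seed = 17)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$decisions, b$decisions)
  expect_identical(a$enterprise_by_step, b$enterprise_by_step)
  c <- run_simulation(cfg, seed = 18)
  expect_false(identical(a$decisions, c$decisions))
})

test_that("total catchment area is conserved across every step", {
  for (s in c(1, 2)) {
    tr <- run_simulation(small_cfg(scenario = list(ghg_price = 60)), seed = s)
    tot <- rowSums(tr$ledger[, paste0("area_", modelled_enterprises())])
    expect_equal(unique(round(tot, 9)), tot[1])
    expect_equal(tot[1], sum(tr$landscape$parcels$area_ha))
  }
})

test_that("forest conversions hold for five steps", {
  # push conversions hard so plenty of forest entries occur
  cfg <- small_cfg(behaviour = list(initial_likelihood = 0.9),
                   scenario = list(ghg_price = 60))
  for (s in 1:3) {
    tr <- run_simulation(cfg, seed = s)
    ebs <- tr$enterprise_by_step
    steps <- as.integer(colnames(ebs))
    for (i in seq_len(nrow(ebs))) {
      for (t in steps[-1]) {
        was_forest <- ebs[i, as.character(t - 1)] %in%
          c("Forestry", "CarbonForestry")
        now <- ebs[i, as.character(t)]
        if (!was_forest && now %in% c("Forestry", "CarbonForestry")) {
          horizon <- seq(t, min(t + 4, max(steps)))
          expect_equal(unique(ebs[i, as.character(horizon)]), now)
        }
      }
    }
  }
})

test_that("with networks off the likelihood algebra has three values", {
  cfg <- small_cfg(behaviour = list(network_effects = FALSE),
                   scenario = list(ghg_price = 40))
  d <- do.call(rbind, lapply(1:3, function(s) {
    run_simulation(cfg, seed = s)$decisions
  }))
  expect_gt(nrow(d), 0)
  expect_true(all(d$likelihood_final %in% c(0, 0.05, 0.2)))
})

test_that("with networks on deltas shift the base by at most 0.15", {
  cfg <- small_cfg(scenario = list(ghg_price = 20))
  d <- run_simulation(cfg, seed = 2)$decisions
  d <- d[d$phase == "decision", ]
  allowed <- unique(round(c(
    0,
    outer(0.2 + c(-0.1, 0, 0.1), c(-0.05, 0, 0.05), "+"),
    outer(0.2 + c(-0.1, 0, 0.1), c(-0.05, 0, 0.05), "+") * 0.25), 10))
  expect_true(all(round(d$likelihood_final, 10) %in% allowed))
})

test_that("the deterministic decision rule reaches its fixed point", {
  # no price growth, no GHG price, certain conversion, no Dairy penalty,
  # no rotation lock: every farm is at its zone argmax after step 1 and
  # the allocation is absorbing
  cfg <- small_cfg(
    economics = list(annual_price_growth = 0),
    behaviour = list(initial_likelihood = 1, dairy_penalty = 0,
                     forest_lock_steps = 0L),
    scenario = list(ghg_price = 0, n_steps = 4)
  )
  tr <- run_simulation(cfg, seed = 8)
  p0 <- tr$landscape$parcels
  cf <- default_coefficients()
  mkt <- market_state(1, 0, annual_growth = 0)
  want <- vapply(seq_len(nrow(p0)), function(i) {
    optimize_farm(list(area_ha = p0$area_ha[i], zone = p0$zone[i]),
                  mkt, cf)$proposed
  }, character(1))
  for (t in 1:4) {
    expect_identical(unname(tr$enterprise_by_step[, as.character(t)]), want)
  }
})

test_that("a zero-step run records only the initial state", {
  tr <- run_simulation(small_cfg(scenario = list(n_steps = 0)), seed = 1)
  expect_equal(nrow(tr$ledger), 1)
  expect_equal(tr$ledger$step, 0)
  # the default horizon appends ten post-initial rows
  tr10 <- run_simulation(small_cfg(), seed = 1)
  expect_equal(tr10$ledger$step, 0:10)
})
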