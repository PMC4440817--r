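test_that("commodity price index compounds annual growth over 5-yr steps", {
  expect_equal(price_index(0), 1)
  expect_equal(price_index(1, 0.02, 5), 1.02^5)
  expect_equal(price_index(10, 0.02, 5), 1.02^50)
  expect_equal(price_index(3, 0, 5), 1)
  expect_error(price_index(-1), ">= 0")
})

test_that("enterprise net revenue follows the annualised budget identity", {
  cf <- default_coefficients()
  cf$revenue_per_ha[cf$enterprise == "SheepBeef" & cf$zone == "Plains"] <- 1000
  cf$cost_per_ha[cf$enterprise == "SheepBeef" & cf$zone == "Plains"] <- 400
  cf$emissions_per_ha[cf$enterprise == "SheepBeef" & cf$zone == "Plains"] <- 0
  p <- list(area_ha = 100, zone = "Plains")
  expect_equal(enterprise_net_revenue(p, "SheepBeef", market_state(0, 0), cf),
               60000)
  expect_error(
    enterprise_net_revenue(list(area_ha = 100, zone = "Hills"), "Dairy",
                           market_state(0, 0), default_coefficients()),
    "infeasible")
})

test_that("plantation forestry revenue is invariant to the GHG price", {
  cf <- default_coefficients()
  p <- list(area_ha = 250, zone = "Hills")
  v0 <- enterprise_net_revenue(p, "Forestry", market_state(2, 0), cf)
  v60 <- enterprise_net_revenue(p, "Forestry", market_state(2, 60), cf)
  expect_identical(v0, v60)
})

test_that("carbon forestry revenue is linear in the GHG price", {
  cf <- default_coefficients()
  cf$sequestration_per_ha[cf$enterprise == "CarbonForestry"] <- 8
  p <- list(area_ha = 100, zone = "Hills")
  v1 <- enterprise_net_revenue(p, "CarbonForestry", market_state(0, 30), cf)
  v2 <- enterprise_net_revenue(p, "CarbonForestry", market_state(0, 40), cf)
  expect_equal(v2 - v1, 10 * 8 * 100)
})

test_that("livestock revenue decreases and carbon forestry increases in tau", {
  cf <- default_coefficients()
  p <- list(area_ha = 100, zone = "Foothills")
  taus <- c(0, 20, 40, 60)
  dairy <- vapply(taus, function(t)
    enterprise_net_revenue(p, "Dairy", market_state(1, t), cf), numeric(1))
  carbon <- vapply(taus, function(t)
    enterprise_net_revenue(p, "CarbonForestry", market_state(1, t), cf),
    numeric(1))
  expect_true(all(diff(dairy) < 0))
  expect_true(all(diff(carbon) > 0))
})

test_that("the farm optimiser agrees with a brute-force argmax", {
  set.seed(20251)
  for (i in 1:1000) {
    cf <- random_coeffs()
    z <- sample(zones(), 1)
    feas_ent <- cf$enterprise[cf$zone == z & cf$feasible]
    parcel <- list(area_ha = round(stats::runif(1, 101, 1000)), zone = z,
                   enterprise = sample(feas_ent, 1))
    mkt <- market_state(sample(0:10, 1), sample(c(0, 20, 40, 60), 1))
    expect_identical(optimize_farm(parcel, mkt, cf)$proposed,
                     brute_force_argmax(parcel, mkt, cf))
  }
})

test_that("optimiser tie-breaks are deterministic", {
  cf <- default_coefficients()
  # craft an exact two-way tie on Plains between SheepBeef and Forestry
  cf$revenue_per_ha[cf$zone == "Plains"] <- c(0, 1000, 1000, 0)[
    match(cf$enterprise[cf$zone == "Plains"], modelled_enterprises())]
  cf$cost_per_ha[cf$zone == "Plains"] <- 400
  cf$feasible[cf$zone == "Plains" & cf$enterprise == "Dairy"] <- FALSE
  cf$feasible[cf$zone == "Plains" & cf$enterprise == "CarbonForestry"] <- FALSE
  mkt <- market_state(0, 0)
  # neither tied enterprise is current: first in the fixed order wins
  p <- list(area_ha = 200, zone = "Plains", enterprise = "SheepBeef")
  p$enterprise <- NULL
  expect_identical(optimize_farm(p, mkt, cf)$proposed, "SheepBeef")
  # current enterprise among the maxima: current wins
  p$enterprise <- "Forestry"
  expect_identical(optimize_farm(p, mkt, cf)$proposed, "Forestry")
})

test_that("Dairy is never proposed on Hills under the default table", {
  cf <- default_coefficients()
  for (tau in c(0, 20, 40, 60)) {
    for (st in c(0, 1, 5, 10)) {
      opt <- optimize_farm(list(area_ha = 300, zone = "Hills",
                                enterprise = "SheepBeef"),
                           market_state(st, tau), cf)
      expect_false(opt$proposed == "Dairy")
      expect_false("Dairy" %in% names(opt$net_revenue))
    }
  }
})

test_that("environmental outputs are exact area-weighted sums", {
  cf <- default_coefficients()
  cf$emissions_per_ha[cf$enterprise == "Dairy" & cf$zone == "Plains"] <- 10
  one <- data.frame(parcel_id = "x", area_ha = 100, centroid_x = 0,
                    centroid_y = 0, zone = "Plains", enterprise = "Dairy")
  env <- environmental_outputs(new_landscape(one), cf)
  expect_equal(env$gross_ghg, 1000)

  forest <- data.frame(parcel_id = c("f1", "f2"), area_ha = c(200, 300),
                       centroid_x = 1:2, centroid_y = 0, zone = "Hills",
                       enterprise = c("Forestry", "CarbonForestry"))
  envf <- environmental_outputs(new_landscape(forest), cf)
  expect_equal(envf$gross_ghg, 0)
  expect_true(envf$sequestration > 0)
  expect_identical(envf$net_ghg, envf$gross_ghg - envf$sequestration)
})

test_that("environmental outputs and revenue scale linearly with area", {
  cf <- default_coefficients()
  ls <- generate_synthetic_landscape(default_gen_config(nx = 12, ny = 9), 3)
  env1 <- environmental_outputs(ls, cf)
  ls2 <- ls
  ls2$parcels$area_ha <- 2 * ls2$parcels$area_ha
  env2 <- environmental_outputs(ls2, cf)
  for (k in names(env1)) expect_equal(env2[[k]], 2 * env1[[k]])
  mkt <- market_state(2, 40)
  p1 <- list(area_ha = 170, zone = "Foothills")
  p2 <- list(area_ha = 340, zone = "Foothills")
  expect_equal(enterprise_net_revenue(p2, "SheepBeef", mkt, cf),
               2 * enterprise_net_revenue(p1, "SheepBeef", mkt, cf))
})
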