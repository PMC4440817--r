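# Shared fixtures: all built in code at test time.

# A small catchment (300 cells, ~40 farms) for fast engine tests.
small_cfg <- function(...) {
  cfg <- default_config()
  cfg$landscape$generator$nx <- 20
  cfg$landscape$generator$ny <- 15
  cfg$landscape$seed <- 4242L
  mods <- list(...)
  if (length(mods) > 0) cfg <- utils::modifyList(unclass(cfg), mods)
  structure(cfg, class = "fs_config")
}

# Hand-built 5-parcel tabular landscape (areas > 100 ha).
toy_parcel_table <- function() {
  data.frame(
    parcel_id = paste0("T", 1:5),
    landuse = c("Dairy", "SheepBeef", "Forestry", "SheepBeef", "Dairy"),
    luc_class = c(2L, 5L, 8L, 3L, 6L),
    area_ha = c(150, 300, 500, 120, 200),
    centroid_x = c(0, 1000, 2000, 3000, 4000),
    centroid_y = c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

# A coefficient table with strictly dominant enterprises per zone, handy
# for forcing deterministic proposals.
dominant_coeffs <- function(winner = "SheepBeef") {
  cf <- default_coefficients()
  cf$revenue_per_ha[cf$enterprise == winner & cf$feasible] <- 50000
  cf
}

# Random coefficient table for oracle tests; at least one feasible
# enterprise per zone.
random_coeffs <- function() {
  cf <- expand.grid(enterprise = modelled_enterprises(), zone = zones(),
                    stringsAsFactors = FALSE)
  n <- nrow(cf)
  cf$revenue_per_ha <- round(stats::runif(n, 0, 8000), 2)
  cf$cost_per_ha <- round(stats::runif(n, 0, 4000), 2)
  cf$emissions_per_ha <- ifelse(cf$enterprise %in% c("Dairy", "SheepBeef"),
                                round(stats::runif(n, 0, 12), 2), 0)
  cf$sequestration_per_ha <- ifelse(
    cf$enterprise %in% c("Forestry", "CarbonForestry"),
    round(stats::runif(n, 0.1, 15), 2), 0)
  cf$n_leach_per_ha <- round(stats::runif(n, 0, 50), 2)
  cf$p_loss_per_ha <- round(stats::runif(n, 0, 2), 2)
  cf$feasible <- stats::runif(n) < 0.8
  for (z in zones()) {  # guarantee feasibility per zone
    rows <- which(cf$zone == z)
    if (!any(cf$feasible[rows])) cf$feasible[sample(rows, 1)] <- TRUE
  }
  cf
}

# Independent re-derivation of the optimiser contract used as an oracle.
brute_force_argmax <- function(parcel, market, cf) {
  feas <- cf[cf$zone == parcel$zone & cf$feasible, ]
  nr <- parcel$area_ha * (
    feas$revenue_per_ha * market$price_index - feas$cost_per_ha -
      market$ghg_price * feas$emissions_per_ha +
      market$ghg_price * feas$sequestration_per_ha *
        (feas$enterprise == "CarbonForestry"))
  names(nr) <- feas$enterprise
  winners <- names(nr)[nr == max(nr)]
  cur <- parcel$enterprise
  if (!is.null(cur) && cur %in% winners) return(cur)
  modelled_enterprises()[min(match(winners, modelled_enterprises()))]
}

# Cached default-calibration scenario ensemble shared by the qualitative
# acceptance checks: tau in {0,20,40,60} x both network arms x 50 seeds.
acceptance_ensemble <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    out <- list()
    for (tau in c(0, 20, 40, 60)) {
      for (nw in c(TRUE, FALSE)) {
        finals <- lapply(1:50, function(s) {
          cfg <- default_config()
          cfg$scenario$ghg_price <- tau
          cfg$behaviour$network_effects <- nw
          tr <- run_simulation(cfg, seed = s)
          last <- tr$ledger[tr$ledger$step == max(tr$ledger$step), ]
          last$seed <- s
          last
        })
        led <- do.call(rbind, finals)
        led$scen_network <- nw
        out[[sprintf("t%d_n%d", tau, nw)]] <- led
      }
    }
    cache <<- do.call(rbind, out)
    cache
  }
})
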