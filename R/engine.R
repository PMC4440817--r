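#' Apply behavioural constraints to a conversion likelihood
#'
#' Two enterprise-level constraints shape the final conversion
#' likelihood: a farm currently in a forest enterprise and still inside
#' its rotation lock cannot convert at all (likelihood 0 for the 25-year
#' minimum stand age, i.e. 5 model steps); and a proposal to convert into
#' Dairy is reduced by the Dairy penalty (default 75%), standing in for
#' the up-front capital and lifestyle costs of dairy conversion that the
#' model does not represent as cash flows. The result is clamped to
#' [0, 1].
#'
#' @param likelihood Conversion likelihood before constraints.
#' @param current Current enterprise label.
#' @param proposed Proposed enterprise label.
#' @param forest_lock_steps Remaining locked steps on the parcel.
#' @param dairy_penalty Proportional reduction for Dairy proposals
#'   (default 0.75).
#' @return Constrained likelihood in [0, 1].
#' @export
#' @examples
#' apply_constraints(0.2, "Forestry", "Dairy", 3)   # locked: 0
#' apply_constraints(0.2, "SheepBeef", "Dairy", 0)  # 0.2 * 0.25 = 0.05
apply_constraints <- function(likelihood, current, proposed,
                              forest_lock_steps, dairy_penalty = 0.75) {
  out <- likelihood
  locked <- current %in% forest_enterprises() & forest_lock_steps > 0
  out[locked] <- 0
  dairy <- !locked & proposed == "Dairy"
  out[dairy] <- out[dairy] * (1 - dairy_penalty)
  clamp01(out)
}

#' Evaluate one farmer's land-use decision
#'
#' Runs the per-farm optimiser and compares the proposal with the current
#' enterprise. If they agree, the farmer's net revenue is updated and no
#' random draw is consumed. Otherwise the conversion likelihood is
#' assembled as initial likelihood plus the endorsement and imitation
#' deltas (both zero when network effects are disabled), behavioural
#' constraints are applied, the result is clamped to [0, 1], and a
#' uniform draw decides conversion. Conversion into a forest enterprise
#' starts the rotation lock. The likelihood is reset to its initial value
#' after every decision.
#'
#' @param farmer One-row population data.frame (or list) for the farmer.
#' @param parcel One-row parcel data.frame (or list) for the farm.
#' @param market Market state from [market_state()].
#' @param coeffs Coefficient table.
#' @param networks_enabled If `FALSE`, both network deltas are forced to
#'   zero (the decision pipeline is structurally identical in both arms).
#' @param endorsement_delta,imitation_delta Network adjustments computed
#'   by [endorsement_adjustment()] and [imitation_adjustment()].
#' @param initial_likelihood Base conversion likelihood (default 0.2).
#' @param dairy_penalty,forest_lock_steps Constraint parameters.
#' @return A list with `record` (a one-row decision data.frame),
#'   `enterprise` (the farm's enterprise after the decision), `lock`
#'   (updated lock counter) and `net_revenue`.
#' @export
evaluate_decision <- function(farmer, parcel, market, coeffs,
                              networks_enabled = TRUE,
                              endorsement_delta = 0, imitation_delta = 0,
                              initial_likelihood = 0.2,
                              dairy_penalty = 0.75,
                              forest_lock_steps = 5L) {
  opt <- optimize_farm(parcel, market, coeffs)
  cur <- as.character(parcel$enterprise)
  lock <- parcel$forest_lock_steps %||% 0L
  if (identical(opt$proposed, cur)) {
    rec <- data.frame(
      farmer_id = farmer$farmer_id %||% NA_character_,
      step = market$step, current = cur, proposed = cur,
      likelihood_final = NA_real_, uniform_draw = NA_real_,
      converted = FALSE, phase = "decision", stringsAsFactors = FALSE
    )
    return(list(record = rec, enterprise = cur, lock = lock,
                net_revenue = unname(opt$net_revenue[cur])))
  }
  if (!networks_enabled) {
    endorsement_delta <- 0
    imitation_delta <- 0
  }
  lf <- clamp01(initial_likelihood + endorsement_delta + imitation_delta)
  lf <- apply_constraints(lf, cur, opt$proposed, lock, dairy_penalty)
  u <- stats::runif(1)
  converted <- u < lf
  ent <- if (converted) opt$proposed else cur
  new_lock <- if (converted && ent %in% forest_enterprises()) {
    as.integer(forest_lock_steps)
  } else {
    lock
  }
  rec <- data.frame(
    farmer_id = farmer$farmer_id %||% NA_character_,
    step = market$step, current = cur, proposed = opt$proposed,
    likelihood_final = lf, uniform_draw = u, converted = converted,
    phase = "decision", stringsAsFactors = FALSE
  )
  list(record = rec, enterprise = ent, lock = new_lock,
       net_revenue = unname(opt$net_revenue[ent]))
}

#' Initialise a simulation state
#'
#' Builds or loads the landscape, applies the farm filter, constructs the
#' adjacency relation and centroid distance matrix, creates one farmer
#' per farm, and seeds named RNG substreams for landscape generation,
#' initial stages, decisions and demography (so toggling one mechanism
#' never shifts another's draws). The landscape substream is keyed to
#' `config$landscape$seed` when set, so an ensemble of runs over one
#' configuration shares a single landscape.
#'
#' @param config An `fs_config`, see [default_config()].
#' @param seed Integer run seed.
#' @return A simulation state (class `fs_state`).
#' @export
sim_init <- function(config = default_config(), seed = 1L) {
  config <- validate_config(config)
  coeffs <- resolve_coefficients(config)
  cm <- coef_matrices(coeffs)
  ls_seed <- config$landscape$seed %||% mix_seed(seed, 1L)
  streams <- make_streams(c(
    landscape = ls_seed,
    stages = mix_seed(seed, 2L),
    decisions = mix_seed(seed, 3L),
    demography = mix_seed(seed, 4L)
  ))
  if (is.null(config$landscape$source)) {
    res <- with_stream(streams, "landscape",
      generate_synthetic_landscape(config$landscape$generator, seed = NULL))
    streams <- res$streams
    landscape <- res$value
  } else {
    landscape <- load_landscape(config$landscape$source)
  }
  landscape <- suppressMessages(
    filter_parcels(landscape, config$landscape$min_area_ha))
  p <- landscape$parcels
  # initial enterprises must be feasible on their zones
  m0 <- margin_matrix(cm, 1, config$scenario$ghg_price)
  feas0 <- !is.na(m0[cbind(p$enterprise, p$zone)])
  if (!all(feas0)) {
    stop("initial enterprise infeasible on its zone for parcel(s): ",
         paste(p$parcel_id[!feas0], collapse = ", "), call. = FALSE)
  }
  res <- with_stream(streams, "stages", init_population(landscape, config))
  streams <- res$streams
  pop <- res$value
  landscape$parcels$owner_id <- pop$farmer_id

  market <- market_state(0, config$scenario$ghg_price,
                         config$economics$annual_price_growth,
                         config$economics$years_per_step)
  # realised step-0 economics of the current enterprises
  margin0 <- m0[cbind(p$enterprise, p$zone)]
  pop$profitability_per_ha <- unname(margin0)
  pop$net_revenue <- unname(margin0 * p$area_ha)

  dist_mat <- as.matrix(stats::dist(cbind(p$centroid_x, p$centroid_y)))
  adj_idx <- lapply(landscape$adjacency[p$parcel_id],
                    function(nb) match(nb, p$parcel_id))

  state <- structure(list(
    config = config, coeffs = coeffs, cm = cm,
    landscape = landscape, pop = pop,
    dist = dist_mat, adj_idx = adj_idx,
    market = market, step = 0L, streams = streams,
    ledger = list(), decisions = list(), ent_by_step = list()
  ), class = "fs_state")
  state$ledger[["0"]] <- ledger_row(state, n_conversions = 0L, n_sales = 0L)
  state$ent_by_step[["0"]] <- state$landscape$parcels$enterprise
  state
}

# First feasible enterprise (fixed order) attaining the zone's maximum
# per-ha margin.
zone_argmax <- function(m) {
  vapply(zones(), function(z) {
    v <- m[, z]
    ok <- !is.na(v)
    names(v)[ok][which.max(v[ok])]
  }, character(1))
}

#' Advance a simulation state by one step
#'
#' Ordered phases: (1) market update (commodity price index, GHG price);
#' (2) decrement forest rotation locks; (3) all farmers evaluated in a
#' seeded random order -- proposals come from the per-farm optimiser,
#' network adjustments read start-of-step enterprises and previous-step
#' profitability (synchronous read, asynchronous write), uniform draws
#' are consumed only by farmers whose proposal differs from their current
#' enterprise; (4) demography: life-cycle advancement and farm sales;
#' (5) a ledger row is appended (areas, net revenue, GHG, nutrients,
#' decision records).
#'
#' @param state An `fs_state` from [sim_init()].
#' @return The advanced state.
#' @export
sim_step <- function(state) {
  cfg <- state$config
  beh <- cfg$behaviour
  state$step <- state$step + 1L
  state$market <- market_state(state$step, cfg$scenario$ghg_price,
                               cfg$economics$annual_price_growth,
                               cfg$economics$years_per_step)
  p <- state$landscape$parcels
  n <- nrow(p)
  p$forest_lock_steps <- pmax(p$forest_lock_steps - 1L, 0L)

  m <- margin_matrix(state$cm, state$market$price_index,
                     state$market$ghg_price)
  zmax <- zone_argmax(m)
  zone_i <- p$zone
  proposed <- unname(zmax[zone_i])
  cur_m <- m[cbind(p$enterprise, zone_i)]
  best_m <- m[cbind(proposed, zone_i)]
  stay <- !is.na(cur_m) & cur_m >= best_m  # current wins ties
  proposed[stay] <- p$enterprise[stay]

  ent0 <- p$enterprise            # start-of-step reads for imitation
  prof_prev <- state$pop$profitability_per_ha
  changers <- which(proposed != p$enterprise)

  res <- with_stream(state$streams, "decisions", {
    order_all <- sample.int(n)
    ch_ord <- order_all[order_all %in% changers]
    e_delta <- numeric(length(ch_ord))
    i_delta <- numeric(length(ch_ord))
    if (isTRUE(beh$network_effects) && length(ch_ord) > 0) {
      for (j in seq_along(ch_ord)) {
        f <- ch_ord[j]
        cand <- which(ent0 == ent0[f])
        cand <- cand[cand != f]
        if (length(cand) > 0) {
          ord <- order(state$dist[f, cand], p$parcel_id[cand])
          sel <- cand[ord[seq_len(min(beh$k_social, length(cand)))]]
          e_delta[j] <- endorsement_adjustment(prof_prev[f], prof_prev[sel])
        }
        nb <- state$adj_idx[[f]]
        memb <- nb[ent0[nb] == proposed[f]]
        if (length(memb) > 0) {
          i_delta[j] <- imitation_adjustment(prof_prev[f], prof_prev[memb])
        }
      }
    }
    lf <- clamp01(beh$initial_likelihood + e_delta + i_delta)
    lf <- apply_constraints(lf, p$enterprise[ch_ord], proposed[ch_ord],
                            p$forest_lock_steps[ch_ord], beh$dairy_penalty)
    u <- stats::runif(length(ch_ord))
    list(ch_ord = ch_ord, lf = lf, u = u)
  })
  state$streams <- res$streams
  dec <- res$value
  converted <- dec$u < dec$lf
  conv_rows <- dec$ch_ord[converted]
  p$enterprise[conv_rows] <- proposed[conv_rows]
  to_forest <- conv_rows[p$enterprise[conv_rows] %in% forest_enterprises()]
  p$forest_lock_steps[to_forest] <- as.integer(beh$forest_lock_steps)

  step_decisions <- if (length(dec$ch_ord) > 0) {
    data.frame(
      farmer_id = state$pop$farmer_id[dec$ch_ord], step = state$step,
      current = ent0[dec$ch_ord], proposed = proposed[dec$ch_ord],
      likelihood_final = dec$lf, uniform_draw = dec$u,
      converted = converted, phase = "decision", stringsAsFactors = FALSE
    )
  } else {
    empty_decisions()
  }
  state$landscape$parcels <- p

  # demography: advance the life cycle, then sell successor-less farms
  res <- with_stream(state$streams, "demography", {
    pop2 <- advance_life_cycle(state$pop, cfg$demography$succession_rate,
                               cfg$demography$steps_per_stage)
    n_sales <- sum(pop2$for_sale)
    sales <- resolve_sales(pop2, state$landscape, state$market,
                           state$cm, cfg, step = state$step)
    c(sales, list(n_sales = n_sales))
  })
  state$streams <- res$streams
  state$pop <- res$value$population
  state$landscape <- res$value$landscape
  sale_decisions <- res$value$decisions

  # end-of-step accounting: realised net revenue of operated enterprises
  p <- state$landscape$parcels
  margin_now <- m[cbind(p$enterprise, p$zone)]
  state$pop$profitability_per_ha <- unname(margin_now)
  state$pop$net_revenue <- unname(margin_now * p$area_ha)
  state$pop$likelihood <- beh$initial_likelihood  # reset after decisions

  key <- as.character(state$step)
  state$decisions[[key]] <- rbind(step_decisions, sale_decisions)
  state$ledger[[key]] <- ledger_row(
    state,
    n_conversions = length(conv_rows) + sum(sale_decisions$converted),
    n_sales = res$value$n_sales
  )
  state$ent_by_step[[key]] <- p$enterprise
  state
}

ledger_row <- function(state, n_conversions, n_sales) {
  p <- state$landscape$parcels
  env <- environmental_outputs(p, state$cm)
  es <- modelled_enterprises()
  area_e <- vapply(es, function(e) sum(p$area_ha[p$enterprise == e]),
                   numeric(1))
  nr_e <- vapply(es, function(e) sum(state$pop$net_revenue[
    p$enterprise == e]), numeric(1))
  row <- data.frame(step = state$step,
                    ghg_price = state$market$ghg_price,
                    price_index = state$market$price_index,
                    stringsAsFactors = FALSE)
  for (e in es) row[[paste0("area_", e)]] <- area_e[[e]]
  for (z in zones()) {
    for (e in es) {
      row[[paste0("area_", z, "_", e)]] <-
        sum(p$area_ha[p$zone == z & p$enterprise == e])
    }
  }
  row$net_revenue <- sum(state$pop$net_revenue)
  for (e in es) row[[paste0("nr_", e)]] <- nr_e[[e]]
  row$gross_ghg <- env$gross_ghg
  row$sequestration <- env$sequestration
  row$net_ghg <- env$net_ghg
  row$n_leach <- env$n_leach
  row$p_loss <- env$p_loss
  row$n_conversions <- n_conversions
  row$n_sales <- n_sales
  row
}

#' Run a full simulation
#'
#' Initialises a state from the configuration and applies [sim_step()]
#' `n_steps` times (default 10 steps of 5 years: a 50-year horizon).
#' Identical `(config, seed)` pairs yield identical trajectories.
#'
#' @inheritParams sim_init
#' @return An `fs_trajectory`: a list with `ledger` (one row per step,
#'   including the initial state at step 0), `decisions` (one row per
#'   evaluated conversion), `enterprise_by_step` (parcels x steps
#'   character matrix), `landscape` (final state), `config`, `seed`.
#' @export
#' @examples
#' \donttest{
#' tr <- run_simulation(default_config(), seed = 1)
#' head(tr$ledger[, c("step", "area_Dairy", "net_ghg")])
#' }
run_simulation <- function(config = default_config(), seed = 1L) {
  state <- sim_init(config, seed)
  n_steps <- config$scenario$n_steps
  for (i in seq_len(n_steps)) state <- sim_step(state)
  ledger <- do.call(rbind, state$ledger)
  rownames(ledger) <- NULL
  decisions <- if (length(state$decisions) > 0) {
    do.call(rbind, state$decisions)
  } else {
    empty_decisions()
  }
  rownames(decisions) <- NULL
  ebs <- do.call(cbind, state$ent_by_step)
  colnames(ebs) <- names(state$ent_by_step)
  rownames(ebs) <- state$landscape$parcels$parcel_id
  structure(list(
    ledger = ledger, decisions = decisions, enterprise_by_step = ebs,
    landscape = state$landscape, config = config, seed = seed
  ), class = "fs_trajectory")
}

#' @export
print.fs_trajectory <- function(x, ...) {
  n_steps <- max(x$ledger$step)
  cat("<fs_trajectory> ", nrow(x$landscape$parcels), " farms, ",
      n_steps, " steps, GHG price $",
      x$config$scenario$ghg_price, "/tCO2e, seed ", x$seed, "\n", sep = "")
  last <- x$ledger[x$ledger$step == n_steps, ]
  cat(sprintf("  final: net revenue $%.2fM, net GHG %.3f ktCO2e/yr\n",
              last$net_revenue / 1e6, last$net_ghg / 1e3))
  invisible(x)
}
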