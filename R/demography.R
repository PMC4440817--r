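#' Initialise the farmer population
#'
#' Creates one farmer per farm. Life-cycle stages are drawn uniformly
#' from `initial_stages` (uniform initialisation avoids synchronised
#' waves of farm sales); every farmer receives a successor assessment at
#' creation (a Bernoulli draw at the configured succession rate, the same
#' assessment that fires on every Stage-1 entry), so agents initialised
#' mid-cycle are not deterministically successor-less. Uses the current
#' RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param farms An `fs_landscape` or a vector of farm identifiers.
#' @param config Model configuration, see [default_config()]; the
#'   `demography` and `behaviour` blocks are used.
#' @return A data.frame with columns `farmer_id`, `farm_id`,
#'   `life_stage`, `steps_in_stage`, `has_successor`, `likelihood`,
#'   `profitability_per_ha`, `net_revenue`, `for_sale`.
#' @export
#' @examples
#' set.seed(1)
#' pop <- init_population(paste0("P", 1:5))
#' pop
init_population <- function(farms, config = default_config()) {
  farm_id <- if (inherits(farms, "fs_landscape")) farms$parcels$parcel_id
             else as.character(farms)
  n <- length(farm_id)
  dem <- config$demography
  stages <- dem$initial_stages %||% 1:5
  life_stage <- if (length(stages) == 1L) rep(as.integer(stages), n)
                else as.integer(sample(stages, n, replace = TRUE))
  has_successor <- stats::runif(n) < dem$succession_rate
  pop <- data.frame(
    farmer_id = sprintf("A%05d", seq_len(n)),
    farm_id = farm_id,
    life_stage = life_stage,
    steps_in_stage = 0L,
    has_successor = has_successor,
    likelihood = config$behaviour$initial_likelihood,
    profitability_per_ha = NA_real_,
    net_revenue = NA_real_,
    for_sale = FALSE,
    stringsAsFactors = FALSE
  )
  attr(pop, "next_id") <- n + 1L
  pop
}

#' Advance the farmer life cycle by one model step
#'
#' Implements the five-stage generational cycle. Each step advances every
#' farmer's stage clock by one; a completed stage below 5 moves to the
#' next stage. Completing Stage 5 with a successor resets the farmer to
#' Stage 1 (the successor takes over the same farm) and triggers a fresh
#' Stage-1 succession assessment (Bernoulli at `succession_rate`);
#' completing Stage 5 without a successor flags the farm for sale.
#' Intermediate stages are pass-through: only Stages 1 and 5 carry
#' events. Uses the current RNG state.
#'
#' @param population Population data.frame from [init_population()].
#' @param succession_rate Probability a successor is found at the
#'   Stage-1 assessment (default 0.75).
#' @param steps_per_stage Model steps per life-cycle stage (default 1).
#' @return The updated population; farms to be sold have `for_sale =
#'   TRUE` and are handled by [resolve_sales()].
#' @export
advance_life_cycle <- function(population, succession_rate = 0.75,
                               steps_per_stage = 1) {
  stopifnot(succession_rate >= 0, succession_rate <= 1)
  pop <- population
  pop$steps_in_stage <- pop$steps_in_stage + 1L
  done <- pop$steps_in_stage >= steps_per_stage
  mid <- done & pop$life_stage < 5L
  pop$life_stage[mid] <- pop$life_stage[mid] + 1L
  pop$steps_in_stage[mid] <- 0L
  final <- which(done & pop$life_stage == 5L & !mid)
  takeover <- final[pop$has_successor[final]]
  sale <- final[!pop$has_successor[final]]
  if (length(takeover) > 0) {
    pop$life_stage[takeover] <- 1L
    pop$steps_in_stage[takeover] <- 0L
    pop$has_successor[takeover] <- stats::runif(length(takeover)) <
      succession_rate
  }
  if (length(sale) > 0) pop$for_sale[sale] <- TRUE
  pop
}

#' Sell successor-less farms to new operators
#'
#' Runs after all conversion decisions in a step. Every farmer flagged
#' for sale is replaced by a new Stage-1 farmer on the same farm (farmer
#' count is conserved); the sale itself leaves the enterprise unchanged,
#' but the new owner immediately performs one conversion evaluation at
#' the initial likelihood with behavioural constraints applied and
#' network adjustments omitted -- the sale is the new owner's opportunity
#' to shift land use. Uses the current RNG state.
#'
#' @param population Population data.frame with `for_sale` flags set.
#' @param landscape Current `fs_landscape`.
#' @param market Market state from [market_state()].
#' @param coeffs Coefficient table.
#' @param config Model configuration.
#' @param step Step index recorded on decision records.
#' @return A list with the updated `population`, `landscape`, and a
#'   `decisions` data.frame of the new owners' evaluations.
#' @export
resolve_sales <- function(population, landscape, market, coeffs,
                          config = default_config(), step = NA_integer_) {
  pop <- population
  flagged <- which(pop$for_sale)
  decisions <- empty_decisions()
  if (length(flagged) == 0) {
    return(list(population = pop, landscape = landscape,
                decisions = decisions))
  }
  cm <- if (is.data.frame(coeffs)) coef_matrices(coeffs) else coeffs
  next_id <- attr(pop, "next_id") %||% (nrow(pop) + 1L)
  beh <- config$behaviour
  p <- landscape$parcels
  recs <- vector("list", length(flagged))
  for (j in seq_along(flagged)) {
    f <- flagged[j]
    new_id <- sprintf("A%05d", next_id)
    next_id <- next_id + 1L
    i <- match(pop$farm_id[f], p$parcel_id)
    pop$farmer_id[f] <- new_id
    pop$life_stage[f] <- 1L
    pop$steps_in_stage[f] <- 0L
    pop$has_successor[f] <- stats::runif(1) < config$demography$succession_rate
    pop$likelihood[f] <- beh$initial_likelihood
    pop$for_sale[f] <- FALSE
    p$owner_id[i] <- new_id
    # new owner's one-off conversion evaluation (no network information)
    opt <- optimize_farm(p[i, ], market, cm)
    cur <- p$enterprise[i]
    if (!identical(opt$proposed, cur)) {
      lf <- apply_constraints(beh$initial_likelihood, cur, opt$proposed,
                              p$forest_lock_steps[i],
                              dairy_penalty = beh$dairy_penalty)
      u <- stats::runif(1)
      converted <- u < lf
      if (converted) {
        p$enterprise[i] <- opt$proposed
        p$forest_lock_steps[i] <-
          if (opt$proposed %in% forest_enterprises()) {
            as.integer(beh$forest_lock_steps)
          } else 0L
      }
      recs[[j]] <- data.frame(
        farmer_id = new_id, step = step, current = cur,
        proposed = opt$proposed, likelihood_final = lf, uniform_draw = u,
        converted = converted, phase = "sale", stringsAsFactors = FALSE
      )
    }
    pop$net_revenue[f] <- NA_real_  # refreshed at end-of-step accounting
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) > 0) decisions <- do.call(rbind, recs)
  attr(pop, "next_id") <- next_id
  landscape$parcels <- p
  list(population = pop, landscape = landscape, decisions = decisions)
}

empty_decisions <- function() {
  data.frame(
    farmer_id = character(0), step = integer(0), current = character(0),
    proposed = character(0), likelihood_final = numeric(0),
    uniform_draw = numeric(0), converted = logical(0), phase = character(0),
    stringsAsFactors = FALSE
  )
}
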