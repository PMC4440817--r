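#' Commodity price index at a model step
#'
#' Commodity prices (milk, meat, timber) grow at a constant real annual
#' rate; each model step spans a fixed number of years, so the index at
#' step `t` is `(1 + annual_growth)^(years_per_step * t)` with index 1 at
#' step 0.
#'
#' @param step Non-negative integer step index (vectorised).
#' @param annual_growth Real annual growth rate as a fraction
#'   (default 0.02).
#' @param years_per_step Years represented by one model step (default 5).
#' @return Numeric multiplier(s) >= 0.
#' @export
#' @examples
#' price_index(0)            # 1
#' price_index(1)            # 1.02^5
#' price_index(10)           # 1.02^50
price_index <- function(step, annual_growth = 0.02, years_per_step = 5) {
  if (any(step < 0)) stop("step must be >= 0", call. = FALSE)
  (1 + annual_growth)^(years_per_step * step)
}

# Per-hectare annual net margin for every (enterprise, zone) pair at the
# given market state, NA where infeasible. The GHG price is charged on
# livestock emissions and paid on Carbon Forestry sequestration only;
# plantation Forestry neither pays nor is paid.
margin_matrix <- function(cm, price_idx, ghg_price) {
  m <- cm$revenue_per_ha * price_idx - cm$cost_per_ha -
    ghg_price * cm$emissions_per_ha
  seq_pay <- ghg_price * cm$sequestration_per_ha
  seq_pay[rownames(m) != "CarbonForestry", ] <- 0
  m <- m + seq_pay
  m[!cm$feasible] <- NA_real_
  m
}

#' Expected annual net revenue of an enterprise on a parcel
#'
#' Computes `area_ha * (revenue_per_ha * price_index - cost_per_ha -
#' ghg_price * emissions_per_ha + ghg_price * sequestration_per_ha)`,
#' where the emissions charge applies to livestock enterprises and the
#' sequestration payment applies only to Carbon Forestry: plantation
#' Forestry faces neither term, mirroring its treatment under the NZ
#' Emissions Trading Scheme as modelled (rotational forests neither pay
#' for emissions nor are paid for sequestration).
#'
#' @param parcel A one-row data.frame (or list) with `area_ha` and `zone`.
#' @param enterprise Enterprise label, one of [modelled_enterprises()].
#' @param market A list with `price_index` and `ghg_price` (see
#'   [market_state()]).
#' @param coeffs Coefficient table from [default_coefficients()] or
#'   [read_coefficients()].
#' @return Net revenue in NZD/yr.
#' @export
#' @examples
#' cf <- default_coefficients()
#' p <- list(area_ha = 150, zone = "Plains")
#' enterprise_net_revenue(p, "Dairy", market_state(0, 0), cf)
enterprise_net_revenue <- function(parcel, enterprise, market, coeffs) {
  cm <- if (is.list(coeffs) && !is.data.frame(coeffs)) coeffs
        else coef_matrices(coeffs)
  m <- margin_matrix(cm, market$price_index, market$ghg_price)
  val <- m[enterprise, parcel$zone]
  if (is.na(val)) {
    stop(sprintf("enterprise %s is infeasible on zone %s",
                 enterprise, parcel$zone), call. = FALSE)
  }
  unname(parcel$area_ha * val)
}

#' Market state at a model step
#'
#' @param step Step index (0-based).
#' @param ghg_price GHG price in NZD/tCO2e.
#' @param annual_growth,years_per_step Passed to [price_index()].
#' @return A list with `step`, `price_index`, `ghg_price`.
#' @export
market_state <- function(step, ghg_price, annual_growth = 0.02,
                         years_per_step = 5) {
  list(step = step,
       price_index = price_index(step, annual_growth, years_per_step),
       ghg_price = ghg_price)
}

#' Revenue-maximising enterprise for a farm
#'
#' Evaluates the expected annual net revenue of every feasible enterprise
#' on the parcel's zone and returns the maximiser. Ties are broken
#' deterministically: if the parcel's current enterprise is among the
#' maxima it wins, otherwise the first maximiser in the fixed order
#' Dairy, SheepBeef, Forestry, CarbonForestry.
#'
#' @inheritParams enterprise_net_revenue
#' @param parcel A one-row data.frame (or list) with `area_ha`, `zone` and
#'   optionally `enterprise` (the current enterprise, used for the
#'   tie-break).
#' @return A list with `proposed` (enterprise label) and
#'   `net_revenue` (named numeric vector over feasible enterprises,
#'   NZD/yr).
#' @export
#' @examples
#' cf <- default_coefficients()
#' optimize_farm(list(area_ha = 200, zone = "Hills"), market_state(0, 0), cf)
optimize_farm <- function(parcel, market, coeffs) {
  cm <- if (is.list(coeffs) && !is.data.frame(coeffs)) coeffs
        else coef_matrices(coeffs)
  m <- margin_matrix(cm, market$price_index, market$ghg_price)
  vals <- m[, parcel$zone] * parcel$area_ha
  feas <- !is.na(vals)
  if (!any(feas)) {
    stop(sprintf("no feasible enterprise on zone %s", parcel$zone),
         call. = FALSE)
  }
  nr <- vals[feas]
  best <- max(nr)
  winners <- names(nr)[nr == best]
  cur <- if (!is.null(parcel$enterprise)) as.character(parcel$enterprise)
         else NA_character_
  proposed <- if (!is.na(cur) && cur %in% winners) cur else winners[1]
  list(proposed = proposed, net_revenue = nr)
}

#' Catchment environmental outputs of a landscape
#'
#' Sums per-hectare export and emission coefficients over all parcels
#' under their current enterprises. Net GHG emissions are gross livestock
#' emissions minus forest carbon sequestration (both plantation and
#' carbon forests sequester; only Carbon Forestry is paid for it).
#'
#' @param landscape An `fs_landscape` (or its `parcels` data.frame).
#' @param coeffs Coefficient table.
#' @return A list with `gross_ghg`, `sequestration`, `net_ghg` (tCO2e/yr),
#'   `n_leach`, `p_loss` (kg/yr).
#' @export
environmental_outputs <- function(landscape, coeffs) {
  parcels <- if (inherits(landscape, "fs_landscape")) landscape$parcels
             else landscape
  cm <- if (is.list(coeffs) && !is.data.frame(coeffs)) coeffs
        else coef_matrices(coeffs)
  idx <- cbind(match(parcels$enterprise, modelled_enterprises()),
               match(parcels$zone, zones()))
  a <- parcels$area_ha
  gross <- sum(a * cm$emissions_per_ha[idx])
  seqn <- sum(a * cm$sequestration_per_ha[idx])
  list(
    gross_ghg = gross,
    sequestration = seqn,
    net_ghg = gross - seqn,
    n_leach = sum(a * cm$n_leach_per_ha[idx]),
    p_loss = sum(a * cm$p_loss_per_ha[idx])
  )
}
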