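#' Default enterprise-by-zone coefficient table
#'
#' Annualised per-hectare enterprise budgets and environmental export
#' coefficients for each (enterprise, zone) pair. Revenue is at base
#' (step-0) commodity prices in NZD/ha/yr and is the only column scaled by
#' the commodity price index; costs are held in real terms. Emissions are
#' livestock gross emissions (tCO2e/ha/yr, zero for forests);
#' sequestration is forest carbon uptake (tCO2e/ha/yr, zero for
#' livestock). Nitrogen leaching and phosphorus loss are export
#' coefficients in kg/ha/yr.
#'
#' The default values are a qualitative calibration, not a fitted one:
#' they reproduce the orderings the model's behaviour depends on (Dairy
#' most profitable on Plains and Foothills at a zero GHG price; Forestry
#' more profitable than Sheep & Beef on Hills; Carbon Forestry
#' overtaking plantation Forestry only as the GHG price reaches $60/tCO2e;
#' Dairy infeasible on Hills) rather than any particular catchment's
#' magnitudes. See the package vignette for the reasoning.
#'
#' @return A data.frame with one row per (enterprise, zone) pair and
#'   columns `enterprise`, `zone`, `revenue_per_ha`, `cost_per_ha`,
#'   `emissions_per_ha`, `sequestration_per_ha`, `n_leach_per_ha`,
#'   `p_loss_per_ha`, `feasible`.
#' @seealso [read_coefficients()] to load a table from CSV.
#' @export
#' @examples
#' default_coefficients()
default_coefficients <- function() {
  tab <- rbind(
    c("Dairy",          "Plains",    6500, 3600, 10, 0,  45, 1.20, TRUE),
    c("Dairy",          "Foothills", 2650, 2110, 10, 0,  40, 1.10, TRUE),
    c("Dairy",          "Hills",        0,    0,  0, 0,   0, 0.00, FALSE),
    c("SheepBeef",      "Plains",    1450,  600,  4, 0,  12, 0.90, TRUE),
    c("SheepBeef",      "Foothills", 1100,  540,  4, 0,  10, 0.80, TRUE),
    c("SheepBeef",      "Hills",      900,  500,  4, 0,   8, 0.60, TRUE),
    c("Forestry",       "Plains",    1050,  450,  0, 7,   3, 0.20, TRUE),
    c("Forestry",       "Foothills",  950,  420,  0, 7,   3, 0.20, TRUE),
    c("Forestry",       "Hills",      900,  400,  0, 7,   3, 0.20, TRUE),
    c("CarbonForestry", "Plains",       0,  120,  0, 12,  2, 0.15, TRUE),
    c("CarbonForestry", "Foothills",    0,  120,  0, 12,  2, 0.15, TRUE),
    c("CarbonForestry", "Hills",        0,  120,  0, 12,  2, 0.15, TRUE)
  )
  out <- data.frame(
    enterprise = tab[, 1], zone = tab[, 2],
    revenue_per_ha = as.numeric(tab[, 3]),
    cost_per_ha = as.numeric(tab[, 4]),
    emissions_per_ha = as.numeric(tab[, 5]),
    sequestration_per_ha = as.numeric(tab[, 6]),
    n_leach_per_ha = as.numeric(tab[, 7]),
    p_loss_per_ha = as.numeric(tab[, 8]),
    feasible = as.logical(tab[, 9]),
    stringsAsFactors = FALSE
  )
  validate_coefficients(out)
}

#' Read an enterprise-by-zone coefficient table from CSV
#'
#' @param path Path to a CSV file with the columns documented in
#'   [default_coefficients()].
#' @return A validated coefficient data.frame.
#' @export
read_coefficients <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$feasible <- as.logical(tab$feasible)
  validate_coefficients(tab)
}

rate_cols <- function() {
  c("revenue_per_ha", "cost_per_ha", "emissions_per_ha",
    "sequestration_per_ha", "n_leach_per_ha", "p_loss_per_ha")
}

validate_coefficients <- function(tab) {
  need <- c("enterprise", "zone", rate_cols(), "feasible")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("coefficient table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$enterprise %in% modelled_enterprises())) {
    stop("unknown enterprise label(s) in coefficient table", call. = FALSE)
  }
  if (!all(tab$zone %in% zones())) {
    stop("unknown zone label(s) in coefficient table", call. = FALSE)
  }
  if (anyDuplicated(paste(tab$enterprise, tab$zone))) {
    stop("duplicate (enterprise, zone) rows in coefficient table",
         call. = FALSE)
  }
  pairs <- expand.grid(enterprise = modelled_enterprises(), zone = zones(),
                       stringsAsFactors = FALSE)
  have <- paste(tab$enterprise, tab$zone)
  missing_pairs <- setdiff(paste(pairs$enterprise, pairs$zone), have)
  if (length(missing_pairs) > 0) {
    stop("coefficient table missing (enterprise, zone) pair(s): ",
         paste(missing_pairs, collapse = "; "), call. = FALSE)
  }
  rates <- as.matrix(tab[, rate_cols()])
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all per-ha rates must be finite and >= 0", call. = FALSE)
  }
  if (any(tab$sequestration_per_ha[tab$enterprise == "CarbonForestry"] <= 0)) {
    stop("CarbonForestry must have sequestration_per_ha > 0", call. = FALSE)
  }
  tab
}

# Reshape the long coefficient table into one enterprise x zone matrix per
# rate column (plus the feasibility mask) for fast lookups in the engine.
coef_matrices <- function(tab) {
  es <- modelled_enterprises()
  zs <- zones()
  out <- lapply(c(rate_cols(), "feasible"), function(col) {
    m <- matrix(NA_real_, nrow = length(es), ncol = length(zs),
                dimnames = list(es, zs))
    m[cbind(match(tab$enterprise, es), match(tab$zone, zs))] <- tab[[col]]
    m
  })
  names(out) <- c(rate_cols(), "feasible")
  out$feasible <- out$feasible > 0
  out
}
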