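#' Define a scenario grid
#'
#' A full experiment crosses GHG prices with the network-effects toggle
#' and a seed ensemble over one shared model configuration. The defaults
#' reproduce the published experiment design: prices $0-$60/tCO2e in $10
#' increments, both network arms, 50 seeds -- 700 runs in total.
#'
#' @param ghg_prices Numeric vector of GHG prices (NZD/tCO2e).
#' @param network_effects Logical vector of network-toggle settings.
#' @param seeds Integer vector of run seeds.
#' @param config Shared model configuration (see [default_config()]).
#' @return An `fs_grid` list with the grid definition and a `runs`
#'   data.frame of one row per (price, network, seed) triple.
#' @export
#' @examples
#' g <- scenario_grid(ghg_prices = c(0, 60), seeds = 1:2)
#' nrow(g$runs)
scenario_grid <- function(ghg_prices = seq(0, 60, by = 10),
                          network_effects = c(TRUE, FALSE),
                          seeds = 1:50,
                          config = default_config()) {
  runs <- expand.grid(seed = as.integer(seeds),
                      network_effects = network_effects,
                      ghg_price = ghg_prices,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  runs <- runs[, c("ghg_price", "network_effects", "seed")]
  structure(list(ghg_prices = ghg_prices,
                 network_effects = network_effects,
                 seeds = as.integer(seeds),
                 config = config, runs = runs),
            class = "fs_grid")
}

#' Run every scenario in a grid
#'
#' Executes one simulation per (GHG price, network setting, seed) triple.
#' Runs are independent, so results are identical regardless of execution
#' order; `jobs > 1` parallelises over forked workers where the platform
#' supports it.
#'
#' @param grid An `fs_grid` from [scenario_grid()].
#' @param jobs Number of parallel workers (default 1).
#' @return An `fs_ensemble`: a list of `fs_trajectory` objects, each
#'   carrying its `ghg_price`, `network_effects` and `seed`, plus the
#'   grid definition.
#' @export
run_experiment <- function(grid, jobs = 1L) {
  stopifnot(inherits(grid, "fs_grid"))
  run_one <- function(i) {
    row <- grid$runs[i, ]
    cfg <- grid$config
    cfg$scenario$ghg_price <- row$ghg_price
    cfg$behaviour$network_effects <- row$network_effects
    tr <- tryCatch(
      run_simulation(cfg, seed = row$seed),
      error = function(e) {
        stop(sprintf(
          "scenario failed (ghg_price=%s, network_effects=%s, seed=%d): %s",
          row$ghg_price, row$network_effects, row$seed,
          conditionMessage(e)), call. = FALSE)
      })
    tr$ghg_price <- row$ghg_price
    tr$network_effects <- row$network_effects
    tr
  }
  idx <- seq_len(nrow(grid$runs))
  trajectories <- if (jobs > 1L) {
    parallel::mclapply(idx, run_one, mc.cores = jobs)
  } else {
    lapply(idx, run_one)
  }
  structure(list(trajectories = trajectories, grid = grid),
            class = "fs_ensemble")
}

#' @export
print.fs_ensemble <- function(x, ...) {
  cat("<fs_ensemble> ", length(x$trajectories), " runs (",
      length(x$grid$ghg_prices), " prices x ",
      length(x$grid$network_effects), " network settings x ",
      length(x$grid$seeds), " seeds)\n", sep = "")
  invisible(x)
}

ensemble_trajectories <- function(x) {
  if (inherits(x, "fs_ensemble")) x$trajectories else x
}

# Stack all ledgers with scenario identity columns.
ensemble_ledger <- function(trajectories) {
  trajectories <- ensemble_trajectories(trajectories)
  rows <- lapply(trajectories, function(tr) {
    led <- tr$ledger
    led$scen_ghg_price <- tr$ghg_price %||% tr$config$scenario$ghg_price
    led$scen_network <- tr$network_effects %||%
      tr$config$behaviour$network_effects
    led$seed <- tr$seed
    led
  })
  do.call(rbind, rows)
}

#' Summarise an ensemble of runs
#'
#' Computes, for every (scenario, step, output) cell, the across-seed
#' mean, standard deviation and normal-approximation 95% confidence
#' interval (mean +/- 1.96 sd / sqrt(n)). Single-run scenarios get means
#' only, with the CI columns set to `NA`.
#'
#' @param trajectories An `fs_ensemble` or list of `fs_trajectory`.
#' @return A long data.frame with columns `ghg_price`, `network_effects`,
#'   `step`, `output`, `mean`, `sd`, `n`, `ci_lo`, `ci_hi`.
#' @export
summarize_ensemble <- function(trajectories) {
  led <- ensemble_ledger(trajectories)
  id_cols <- c("step", "ghg_price", "price_index", "scen_ghg_price",
               "scen_network", "seed")
  outputs <- setdiff(names(led), id_cols)
  long <- stats::reshape(
    led[, c("scen_ghg_price", "scen_network", "step", "seed", outputs)],
    direction = "long", varying = outputs, v.names = "value",
    times = outputs, timevar = "output", idvar = c("scen_ghg_price",
    "scen_network", "step", "seed"))
  agg <- stats::aggregate(
    value ~ scen_ghg_price + scen_network + step + output, data = long,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out <- data.frame(
    ghg_price = agg$scen_ghg_price,
    network_effects = agg$scen_network,
    step = agg$step,
    output = agg$output,
    mean = agg$value[, "mean"],
    sd = agg$value[, "sd"],
    n = agg$value[, "n"],
    stringsAsFactors = FALSE
  )
  half <- 1.96 * out$sd / sqrt(out$n)
  out$ci_lo <- ifelse(out$n >= 2, out$mean - half, NA_real_)
  out$ci_hi <- ifelse(out$n >= 2, out$mean + half, NA_real_)
  out[order(out$ghg_price, out$network_effects, out$step, out$output), ]
}

#' Land-use shares by zone with network-effect deltas
#'
#' For each GHG price, computes the mean share of total catchment area
#' under every (zone, enterprise) pair at the given step, separately for
#' the network-on and network-off arms, and their difference (on minus
#' off). Both arms must be present for every price.
#'
#' @param trajectories An `fs_ensemble` or list of `fs_trajectory`; must
#'   contain both network arms for each price.
#' @param step Step at which shares are taken (default: final step).
#' @return A data.frame with columns `ghg_price`, `zone`, `enterprise`,
#'   `share_off`, `share_on`, `delta` (percentage points of catchment
#'   area).
#' @export
land_use_share_table <- function(trajectories, step = NULL) {
  led <- ensemble_ledger(trajectories)
  if (is.null(step)) step <- max(led$step)
  led <- led[led$step == step, ]
  total_area <- rowSums(led[, paste0("area_", modelled_enterprises())])
  prices <- sort(unique(led$scen_ghg_price))
  out <- list()
  for (pr in prices) {
    for (arm in c(FALSE, TRUE)) {
      if (!any(led$scen_ghg_price == pr & led$scen_network == arm)) {
        stop("missing network arm (", arm, ") for ghg_price ", pr,
             call. = FALSE)
      }
    }
    sel <- led$scen_ghg_price == pr
    for (z in zones()) {
      for (e in modelled_enterprises()) {
        col <- paste0("area_", z, "_", e)
        sh <- 100 * led[[col]][sel] / total_area[sel]
        arm <- led$scen_network[sel]
        out[[length(out) + 1L]] <- data.frame(
          ghg_price = pr, zone = z, enterprise = e,
          share_off = mean(sh[!arm]), share_on = mean(sh[arm]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- do.call(rbind, out)
  tab$delta <- tab$share_on - tab$share_off
  tab
}

#' Parcel-level enterprise probabilities across an ensemble
#'
#' For every scenario (GHG price by network setting) and parcel, the
#' probability of each enterprise is the fraction of that scenario's runs
#' in which the parcel is under the enterprise at the given step.
#' Requires all runs of a scenario to share one landscape (the default
#' configuration fixes the landscape seed).
#'
#' @inheritParams land_use_share_table
#' @return A data.frame with columns `ghg_price`, `network_effects`,
#'   `parcel_id`, `enterprise`, `probability`; probabilities sum to 1 per
#'   (scenario, parcel).
#' @export
parcel_enterprise_probability <- function(trajectories, step = NULL) {
  trs <- ensemble_trajectories(trajectories)
  if (length(trs) == 0) stop("no runs supplied", call. = FALSE)
  key <- vapply(trs, function(tr) {
    paste(tr$ghg_price %||% tr$config$scenario$ghg_price,
          tr$network_effects %||% tr$config$behaviour$network_effects)
  }, character(1))
  out <- list()
  for (k in unique(key)) {
    group <- trs[key == k]
    ids <- rownames(group[[1]]$enterprise_by_step)
    for (tr in group) {
      if (!identical(rownames(tr$enterprise_by_step), ids)) {
        stop("runs within a scenario must share one landscape ",
             "(fix config$landscape$seed)", call. = FALSE)
      }
    }
    st <- step %||% (ncol(group[[1]]$enterprise_by_step) - 1L)
    ents <- vapply(group, function(tr) {
      tr$enterprise_by_step[, as.character(st)]
    }, character(length(ids)))
    ents <- matrix(ents, nrow = length(ids))
    pr <- group[[1]]$ghg_price %||% group[[1]]$config$scenario$ghg_price
    nw <- group[[1]]$network_effects %||%
      group[[1]]$config$behaviour$network_effects
    for (e in modelled_enterprises()) {
      out[[length(out) + 1L]] <- data.frame(
        ghg_price = pr, network_effects = nw, parcel_id = ids,
        enterprise = e, probability = rowMeans(ents == e),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
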