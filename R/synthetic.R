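#' Default synthetic-landscape generator configuration
#'
#' Describes a rectangular catchment of 25-ha raster cells partitioned
#' into contiguous farm parcels by seeded region growing. Zones form
#' three horizontal bands (Plains nearest the coast, Hills furthest);
#' initial enterprises are drawn per zone to match target area shares in
#' expectation, placing most area in Sheep & Beef with minor Dairy on the
#' Plains and Forestry concentrated on the Hills.
#'
#' Parcel target sizes are log-normal in cell units, truncated below at
#' `min_cells` (4 cells = 100 ha by default; parcels of exactly 100 ha
#' are subsequently removed by the strict farm filter, mirroring a
#' cadastre that contains sub-threshold blocks).
#'
#' @param nx,ny Grid dimensions in cells.
#' @param cell_size_ha Cell area in hectares (default 25).
#' @param zone_fractions Named fractions of rows per zone, summing to 1.
#' @param shares Named list (per zone) of initial enterprise share
#'   targets, each summing to 1.
#' @param size_meanlog,size_sdlog Log-normal parcel-size parameters
#'   (cells).
#' @param min_cells Minimum parcel size in cells.
#' @return A list suitable for [generate_synthetic_landscape()].
#' @export
default_gen_config <- function(nx = 40, ny = 30, cell_size_ha = 25,
                               zone_fractions = c(Plains = 0.35,
                                                  Foothills = 0.35,
                                                  Hills = 0.30),
                               shares = list(
                                 Plains = c(Dairy = 0.15, SheepBeef = 0.65,
                                            Forestry = 0.20),
                                 Foothills = c(Dairy = 0.05,
                                               SheepBeef = 0.85,
                                               Forestry = 0.10),
                                 Hills = c(SheepBeef = 0.75,
                                           Forestry = 0.25)),
                               size_meanlog = log(7), size_sdlog = 0.5,
                               min_cells = 4) {
  list(nx = nx, ny = ny, cell_size_ha = cell_size_ha,
       zone_fractions = zone_fractions, shares = shares,
       size_meanlog = size_meanlog, size_sdlog = size_sdlog,
       min_cells = min_cells)
}

validate_gen_config <- function(gc) {
  if (abs(sum(gc$zone_fractions) - 1) > 1e-8) {
    stop("zone_fractions must sum to 1", call. = FALSE)
  }
  if (!setequal(names(gc$zone_fractions), zones())) {
    stop("zone_fractions must be named over ", paste(zones(), collapse = ", "),
         call. = FALSE)
  }
  for (z in names(gc$shares)) {
    s <- gc$shares[[z]]
    if (abs(sum(s) - 1) > 1e-8) {
      stop("enterprise shares for zone ", z, " must sum to 1", call. = FALSE)
    }
    if (!all(names(s) %in% modelled_enterprises())) {
      stop("unknown enterprise in shares for zone ", z, call. = FALSE)
    }
  }
  if (gc$min_cells * gc$cell_size_ha < 100) {
    stop("min_cells x cell_size_ha is below the 100 ha farm scale; ",
         "generated parcels would all fall under the farm filter",
         call. = FALSE)
  }
  if (gc$nx < 2 || gc$ny < 3) stop("grid too small", call. = FALSE)
  gc
}

#' Generate a synthetic parcel landscape
#'
#' Partitions an `nx` by `ny` grid of raster cells into contiguous
#' parcels by seeded region growing: a random unassigned cell seeds each
#' parcel, a log-normal target size is drawn, and the region grows by
#' annexing random unassigned edge-neighbouring cells until the target is
#' reached or the region is enclosed. Undersized remnants are merged into
#' adjacent parcels. Zones are three row bands; each parcel's initial
#' enterprise is drawn from its zone's target shares, so realised area
#' shares match the targets in expectation. Output is deterministic for
#' a fixed seed.
#'
#' @param gen_config Configuration list, see [default_gen_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An `fs_landscape` with cells and rook-contiguity adjacency.
#' @export
#' @examples
#' ls <- generate_synthetic_landscape(default_gen_config(), seed = 1)
#' ls
generate_synthetic_landscape <- function(gen_config = default_gen_config(),
                                         seed = NULL) {
  gc <- validate_gen_config(gen_config)
  if (!is.null(seed)) set.seed(seed)
  nx <- gc$nx; ny <- gc$ny
  n <- nx * ny
  owner <- integer(n)  # 0 = unassigned
  # 4-neighbour offsets with edge masks, computed per cell on demand
  neighbours_of <- function(c0) {
    x <- ((c0 - 1L) %% nx) + 1L
    y <- ((c0 - 1L) %/% nx) + 1L
    nb <- c(if (x > 1L) c0 - 1L, if (x < nx) c0 + 1L,
            if (y > 1L) c0 - nx, if (y < ny) c0 + nx)
    nb
  }
  k <- 0L
  unassigned <- which(owner == 0L)
  while (length(unassigned) > 0) {
    k <- k + 1L
    seed_cell <- if (length(unassigned) == 1L) unassigned
                 else unassigned[sample.int(length(unassigned), 1L)]
    target <- max(gc$min_cells,
                  round(stats::rlnorm(1, gc$size_meanlog, gc$size_sdlog)))
    owner[seed_cell] <- k
    size <- 1L
    frontier <- neighbours_of(seed_cell)
    frontier <- frontier[owner[frontier] == 0L]
    while (size < target && length(frontier) > 0) {
      i <- if (length(frontier) == 1L) 1L
           else sample.int(length(frontier), 1L)
      cell <- frontier[i]
      frontier <- frontier[-i]
      if (owner[cell] != 0L) next
      owner[cell] <- k
      size <- size + 1L
      nb <- neighbours_of(cell)
      frontier <- c(frontier, nb[owner[nb] == 0L])
    }
    unassigned <- which(owner == 0L)
  }
  # merge undersized remnants into an adjacent parcel
  repeat {
    sizes <- tabulate(owner)
    small <- which(sizes > 0 & sizes < gc$min_cells)
    if (length(small) == 0) break
    p <- small[1]
    cells_p <- which(owner == p)
    nb_owners <- setdiff(unique(owner[unlist(lapply(cells_p, neighbours_of))]),
                         p)
    if (length(nb_owners) == 0) break  # isolated grid fragment, keep as is
    tgt <- if (length(nb_owners) == 1L) nb_owners
           else nb_owners[sample.int(length(nb_owners), 1L)]
    owner[cells_p] <- tgt
  }
  # compact parcel ids
  ids_used <- sort(unique(owner))
  owner <- match(owner, ids_used)
  n_parcels <- length(ids_used)

  x <- ((seq_len(n) - 1L) %% nx) + 1L
  y <- ((seq_len(n) - 1L) %/% nx) + 1L
  r1 <- round(ny * gc$zone_fractions[["Plains"]])
  r2 <- round(ny * (gc$zone_fractions[["Plains"]] +
                    gc$zone_fractions[["Foothills"]]))
  cell_zone <- ifelse(y <= r1, "Plains", ifelse(y <= r2, "Foothills",
                                                "Hills"))
  side <- sqrt(gc$cell_size_ha * 1e4)
  pid <- sprintf("P%04d", seq_len(n_parcels))

  zone <- character(n_parcels)
  area <- numeric(n_parcels)
  cx <- numeric(n_parcels)
  cy <- numeric(n_parcels)
  for (p in seq_len(n_parcels)) {
    cc <- which(owner == p)
    zone[p] <- predominant(cell_zone[cc], zones())
    area[p] <- length(cc) * gc$cell_size_ha
    cx[p] <- mean((x[cc] - 0.5) * side)
    cy[p] <- mean((y[cc] - 0.5) * side)
  }
  # initial enterprise drawn per parcel from its zone's target shares
  enterprise <- character(n_parcels)
  for (z in zones()) {
    idx <- which(zone == z)
    if (length(idx) == 0) next
    s <- gc$shares[[z]]
    if (is.null(s)) stop("no enterprise shares configured for zone ", z,
                         call. = FALSE)
    enterprise[idx] <- names(s)[sample.int(length(s), length(idx),
                                           replace = TRUE, prob = s)]
  }
  parcels <- data.frame(
    parcel_id = pid, area_ha = area, centroid_x = cx, centroid_y = cy,
    zone = zone, enterprise = enterprise, stringsAsFactors = FALSE
  )
  cells <- data.frame(x = x, y = y, parcel_id = pid[owner],
                      stringsAsFactors = FALSE)
  ls <- new_landscape(parcels, cells = cells,
                      cell_size_ha = gc$cell_size_ha)
  build_adjacency(ls)
}
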