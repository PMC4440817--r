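#' Construct and validate a parcel landscape
#'
#' An `fs_landscape` bundles the spatial substrate of a simulation: a
#' parcel table, a symmetric geographic adjacency relation, and (when the
#' landscape was built from a raster or generated synthetically) the
#' underlying 25-ha cell memberships.
#'
#' @param parcels data.frame with columns `parcel_id`, `area_ha`,
#'   `centroid_x`, `centroid_y` (planar metres), `zone`, `enterprise`,
#'   and optionally `forest_lock_steps` and `owner_id`.
#' @param adjacency Named list mapping each `parcel_id` to a character
#'   vector of neighbouring `parcel_id`s (symmetric, irreflexive), or
#'   `NULL` for no adjacency information.
#' @param cells Optional data.frame of raster cells with columns `x`, `y`
#'   (integer cell coordinates) and `parcel_id`.
#' @param cell_size_ha Area of one raster cell in hectares (default 25).
#' @return An object of class `fs_landscape`.
#' @export
new_landscape <- function(parcels, adjacency = NULL, cells = NULL,
                          cell_size_ha = 25) {
  if (!("forest_lock_steps" %in% names(parcels))) {
    parcels$forest_lock_steps <- 0L
  }
  if (!("owner_id" %in% names(parcels))) {
    parcels$owner_id <- paste0("F", parcels$parcel_id)
  }
  parcels$parcel_id <- as.character(parcels$parcel_id)
  rownames(parcels) <- NULL
  if (is.null(adjacency)) {
    adjacency <- stats::setNames(
      rep(list(character(0)), nrow(parcels)), parcels$parcel_id)
  }
  obj <- structure(
    list(parcels = parcels, adjacency = adjacency, cells = cells,
         cell_size_ha = cell_size_ha),
    class = "fs_landscape"
  )
  validate_landscape(obj)
}

validate_landscape <- function(x) {
  p <- x$parcels
  need <- c("parcel_id", "area_ha", "centroid_x", "centroid_y", "zone",
            "enterprise")
  miss <- setdiff(need, names(p))
  if (length(miss) > 0) {
    stop("parcel table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(p$parcel_id)) {
    stop("duplicate parcel_id(s)", call. = FALSE)
  }
  if (any(!is.finite(p$area_ha) | p$area_ha <= 0)) {
    stop("parcel area_ha must be finite and > 0 for parcel(s): ",
         paste(p$parcel_id[!is.finite(p$area_ha) | p$area_ha <= 0],
               collapse = ", "), call. = FALSE)
  }
  if (!all(p$zone %in% zones())) {
    stop("unknown zone label(s): ",
         paste(unique(p$zone[!p$zone %in% zones()]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(p$enterprise %in% enterprises())) {
    stop("unknown enterprise label(s): ",
         paste(unique(p$enterprise[!p$enterprise %in% enterprises()]),
               collapse = ", "), call. = FALSE)
  }
  if (any(p$forest_lock_steps < 0)) {
    stop("forest_lock_steps must be >= 0", call. = FALSE)
  }
  locked_nonforest <- p$forest_lock_steps > 0 &
    !(p$enterprise %in% forest_enterprises())
  if (any(locked_nonforest)) {
    stop("forest_lock_steps > 0 on non-forest parcel(s): ",
         paste(p$parcel_id[locked_nonforest], collapse = ", "),
         call. = FALSE)
  }
  adj <- x$adjacency
  if (!setequal(names(adj), p$parcel_id)) {
    stop("adjacency keys must match parcel_ids", call. = FALSE)
  }
  for (id in names(adj)) {
    if (id %in% adj[[id]]) stop("adjacency must be irreflexive", call. = FALSE)
    for (nb in adj[[id]]) {
      if (!(id %in% adj[[nb]])) {
        stop("adjacency must be symmetric (", id, " -> ", nb, ")",
             call. = FALSE)
      }
    }
  }
  x
}

#' @export
print.fs_landscape <- function(x, ...) {
  p <- x$parcels
  cat("<fs_landscape> ", nrow(p), " parcels, ",
      format(sum(p$area_ha), big.mark = ","), " ha total\n", sep = "")
  cat("  zones:       ",
      paste(sprintf("%s %d", names(table(p$zone)), table(p$zone)),
            collapse = ", "), "\n", sep = "")
  cat("  enterprises: ",
      paste(sprintf("%s %d", names(table(p$enterprise)),
                    table(p$enterprise)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load a parcel landscape from a file or data.frame
#'
#' Accepts three input shapes:
#' \describe{
#'   \item{parcel-level table}{CSV or data.frame with columns `parcel_id`,
#'     `landuse`, `area_ha`, `centroid_x`, `centroid_y`, one of
#'     `luc_class` or `zone`, and optionally `tenure`.}
#'   \item{cell-level table}{CSV or data.frame of raster cells with
#'     columns `cell_x`, `cell_y`, `parcel_id`, `landuse`, one of
#'     `luc_class` or `zone`, optionally `tenure`. Parcel area is cell
#'     count times `cell_size_ha`; the parcel's land use and zone are the
#'     predominant (majority-area) values, ties broken by the fixed label
#'     order (lowest wins).}
#'   \item{GeoJSON}{A FeatureCollection of Polygon features (planar
#'     coordinates in metres) with properties `parcel_id`, `landuse`, one
#'     of `luc_class`/`zone`, optionally `tenure`. Area and centroid are
#'     computed from the polygon; adjacency from shared boundary edges.}
#' }
#'
#' Parcels with Crown (or otherwise non-productive) `tenure` are removed:
#' no farmer agents are created on them. Unknown land-use labels are
#' mapped to `NonModelled` with a warning; such parcels are discarded by
#' [filter_parcels()].
#'
#' @param source File path (`.csv`, `.geojson`/`.json`) or a data.frame.
#' @param cell_size_ha Raster cell size in hectares (default 25).
#' @return An `fs_landscape`.
#' @export
load_landscape <- function(source, cell_size_ha = 25) {
  if (is.character(source)) {
    ext <- tolower(tools::file_ext(source))
    if (ext %in% c("geojson", "json")) {
      return(load_landscape_geojson(source))
    }
    source <- utils::read.csv(source, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(source)) {
    stop("source must be a file path or data.frame", call. = FALSE)
  }
  if (all(c("cell_x", "cell_y") %in% names(source))) {
    load_landscape_cells(source, cell_size_ha)
  } else {
    load_landscape_parcels(source, cell_size_ha)
  }
}

is_crown <- function(tenure) {
  !is.na(tenure) & tolower(trimws(tenure)) %in%
    c("crown", "crown-owned", "public", "conservation")
}

resolve_zone_col <- function(tab) {
  if ("zone" %in% names(tab)) {
    bad <- is.na(tab$zone) | !(tab$zone %in% zones())
    if (any(bad)) {
      stop("invalid zone for parcel(s): ",
           paste(unique(tab$parcel_id[bad]), collapse = ", "),
           call. = FALSE)
    }
    tab$zone
  } else if ("luc_class" %in% names(tab)) {
    assign_zone(tab$luc_class, tab$parcel_id)
  } else {
    stop("input must carry a `zone` or `luc_class` column", call. = FALSE)
  }
}

map_landuse <- function(landuse, parcel_id) {
  ent <- normalize_enterprise(landuse)
  unknown <- ent == "NonModelled" &
    tolower(gsub("[^a-z]", "", tolower(landuse))) != "nonmodelled"
  if (any(unknown)) {
    warning("unknown land-use label(s) mapped to NonModelled for parcel(s): ",
            paste(unique(parcel_id[unknown]), collapse = ", "),
            call. = FALSE)
  }
  ent
}

check_required <- function(tab, cols) {
  for (col in cols) {
    if (!(col %in% names(tab))) {
      stop("input missing required column: ", col, call. = FALSE)
    }
    bad <- is.na(tab[[col]])
    if (any(bad)) {
      stop("missing `", col, "` for parcel(s): ",
           paste(unique(tab$parcel_id[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
}

load_landscape_parcels <- function(tab, cell_size_ha) {
  check_required(tab, c("parcel_id", "landuse", "area_ha",
                        "centroid_x", "centroid_y"))
  if ("tenure" %in% names(tab)) tab <- tab[!is_crown(tab$tenure), ]
  if (nrow(tab) == 0) stop("no parcels left after tenure screen",
                           call. = FALSE)
  parcels <- data.frame(
    parcel_id = as.character(tab$parcel_id),
    area_ha = tab$area_ha,
    centroid_x = tab$centroid_x,
    centroid_y = tab$centroid_y,
    zone = resolve_zone_col(tab),
    enterprise = map_landuse(tab$landuse, tab$parcel_id),
    stringsAsFactors = FALSE
  )
  new_landscape(parcels, cell_size_ha = cell_size_ha)
}

# Majority-area predominant label; ties broken by the fixed order of
# `levels` (lowest wins).
predominant <- function(x, levels) {
  cnt <- table(factor(x, levels = levels))
  names(cnt)[which.max(cnt)]  # which.max takes the first maximum
}

load_landscape_cells <- function(tab, cell_size_ha) {
  check_required(tab, c("parcel_id", "landuse", "cell_x", "cell_y"))
  if ("tenure" %in% names(tab)) tab <- tab[!is_crown(tab$tenure), ]
  if (nrow(tab) == 0) stop("no parcels left after tenure screen",
                           call. = FALSE)
  tab$parcel_id <- as.character(tab$parcel_id)
  tab$zone_resolved <- resolve_zone_col(tab)
  tab$ent <- map_landuse(tab$landuse, tab$parcel_id)
  side <- sqrt(cell_size_ha * 1e4)
  ids <- sort(unique(tab$parcel_id))
  rows <- lapply(ids, function(id) {
    cc <- tab[tab$parcel_id == id, ]
    data.frame(
      parcel_id = id,
      area_ha = nrow(cc) * cell_size_ha,
      centroid_x = mean((cc$cell_x - 0.5) * side),
      centroid_y = mean((cc$cell_y - 0.5) * side),
      zone = predominant(cc$zone_resolved, zones()),
      enterprise = predominant(cc$ent, enterprises()),
      stringsAsFactors = FALSE
    )
  })
  parcels <- do.call(rbind, rows)
  cells <- data.frame(x = tab$cell_x, y = tab$cell_y,
                      parcel_id = tab$parcel_id,
                      stringsAsFactors = FALSE)
  ls <- new_landscape(parcels, cells = cells, cell_size_ha = cell_size_ha)
  build_adjacency(ls)
}

load_landscape_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats)) stop("GeoJSON must be a FeatureCollection",
                           call. = FALSE)
  props <- lapply(feats, function(f) f$properties)
  rings <- lapply(feats, function(f) {
    g <- f$geometry
    if (is.null(g) || !identical(g$type, "Polygon")) {
      stop("only Polygon geometries are supported", call. = FALSE)
    }
    ring <- g$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    # drop closing vertex if duplicated
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
  getp <- function(key) {
    vapply(props, function(p) {
      v <- p[[key]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  tab <- data.frame(
    parcel_id = getp("parcel_id"),
    landuse = getp("landuse"),
    stringsAsFactors = FALSE
  )
  luc <- getp("luc_class")
  zn <- getp("zone")
  if (any(!is.na(zn))) tab$zone <- zn else tab$luc_class <- as.integer(luc)
  ten <- getp("tenure")
  if (any(!is.na(ten))) tab$tenure <- ten
  geo <- t(vapply(rings, polygon_area_centroid, numeric(3)))
  tab$area_ha <- geo[, 1] / 1e4
  tab$centroid_x <- geo[, 2]
  tab$centroid_y <- geo[, 3]
  check_required(tab, c("parcel_id", "landuse", "area_ha",
                        "centroid_x", "centroid_y"))
  keep <- if ("tenure" %in% names(tab)) !is_crown(tab$tenure)
          else rep(TRUE, nrow(tab))
  tab2 <- tab[keep, ]
  if (nrow(tab2) == 0) stop("no parcels left after tenure screen",
                            call. = FALSE)
  parcels <- data.frame(
    parcel_id = as.character(tab2$parcel_id),
    area_ha = tab2$area_ha,
    centroid_x = tab2$centroid_x,
    centroid_y = tab2$centroid_y,
    zone = resolve_zone_col(tab2),
    enterprise = map_landuse(tab2$landuse, tab2$parcel_id),
    stringsAsFactors = FALSE
  )
  adjacency <- polygon_adjacency(rings[keep], parcels$parcel_id)
  new_landscape(parcels, adjacency = adjacency)
}

# Shoelace area (m^2) and centroid of a planar polygon ring.
polygon_area_centroid <- function(m) {
  x <- as.numeric(m[, 1]); y <- as.numeric(m[, 2])
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a2 <- sum(cross)
  if (abs(a2) < 1e-12) {
    return(c(0, mean(x), mean(y)))
  }
  cx <- sum((x + xn) * cross) / (3 * a2)
  cy <- sum((y + yn) * cross) / (3 * a2)
  c(abs(a2) / 2, cx, cy)
}

# Two polygons are adjacent iff they share at least one boundary edge
# (a full vertex-to-vertex segment); corner-only contact does not count.
polygon_adjacency <- function(rings, ids) {
  edge_keys <- lapply(rings, function(m) {
    nxt <- rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE])
    a <- paste(m[, 1], m[, 2], sep = ",")
    b <- paste(nxt[, 1], nxt[, 2], sep = ",")
    unique(ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|")))
  })
  owner <- data.frame(
    key = unlist(edge_keys),
    id = rep(ids, lengths(edge_keys)),
    stringsAsFactors = FALSE
  )
  adj <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  dup <- split(owner$id, owner$key)
  for (members in dup) {
    if (length(members) > 1) {
      for (i in members) {
        adj[[i]] <- union(adj[[i]], setdiff(members, i))
      }
    }
  }
  lapply(adj, sort)
}

#' Filter a landscape to modelled farms
#'
#' Retains parcels strictly larger than `min_area_ha` ("in excess of"
#' the threshold, so a parcel of exactly the threshold area is excluded)
#' whose predominant enterprise is one of Dairy, Sheep & Beef or
#' plantation Forestry; everything else is discarded and the removed
#' count reported via `message()`.
#'
#' @param landscape An `fs_landscape`.
#' @param min_area_ha Minimum farm size in hectares (default 100).
#' @return The filtered `fs_landscape`.
#' @export
filter_parcels <- function(landscape, min_area_ha = 100) {
  stopifnot(min_area_ha > 0)
  p <- landscape$parcels
  keep <- p$area_ha > min_area_ha &
    p$enterprise %in% c("Dairy", "SheepBeef", "Forestry")
  if (!any(keep)) {
    stop("no parcels remain after filtering: nothing to simulate",
         call. = FALSE)
  }
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(n_removed, " parcel(s) removed by the farm filter (area <= ",
            min_area_ha, " ha or non-modelled enterprise)")
  }
  kept_ids <- p$parcel_id[keep]
  adj <- lapply(landscape$adjacency[kept_ids],
                function(nb) intersect(nb, kept_ids))
  cells <- landscape$cells
  if (!is.null(cells)) cells <- cells[cells$parcel_id %in% kept_ids, ]
  structure(
    list(parcels = p[keep, , drop = FALSE], adjacency = adj, cells = cells,
         cell_size_ha = landscape$cell_size_ha),
    class = "fs_landscape"
  ) |> validate_landscape()
}

#' Derive the geographic adjacency relation of a landscape
#'
#' Two parcels are adjacent iff they share at least one raster cell edge
#' (rook contiguity); corner-only contact does not count. Requires cell
#' memberships (synthetic or cell-level loaded landscapes); GeoJSON
#' landscapes get their adjacency from shared polygon edges at load time.
#'
#' @param landscape An `fs_landscape` with a `cells` table.
#' @return The landscape with its `adjacency` replaced.
#' @export
build_adjacency <- function(landscape) {
  cells <- landscape$cells
  if (is.null(cells)) {
    stop("landscape carries no cell memberships; adjacency must be ",
         "supplied at construction", call. = FALSE)
  }
  ids <- landscape$parcels$parcel_id
  nx <- max(cells$x); ny <- max(cells$y)
  grid <- matrix(NA_integer_, nrow = nx, ncol = ny)
  grid[cbind(cells$x, cells$y)] <- match(cells$parcel_id, ids)
  pairs <- rbind(
    cbind(as.vector(grid[-nx, ]), as.vector(grid[-1, ])),
    cbind(as.vector(grid[, -ny]), as.vector(grid[, -1]))
  )
  pairs <- pairs[stats::complete.cases(pairs) & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  adj <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  if (nrow(pairs) > 0) {
    both <- rbind(pairs, pairs[, 2:1, drop = FALSE])
    key <- paste(both[, 1], both[, 2])
    both <- both[!duplicated(key), , drop = FALSE]
    sp <- split(ids[both[, 2]], both[, 1])
    for (k in names(sp)) adj[[ids[as.integer(k)]]] <- sort(sp[[k]])
  }
  landscape$adjacency <- adj
  validate_landscape(landscape)
}
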