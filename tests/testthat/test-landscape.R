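test_that("LUC classes partition exactly into the three zones", {
  expect_equal(assign_zone(1:8),
               c(rep("Plains", 4), rep("Foothills", 2), rep("Hills", 2)))
  expect_error(assign_zone(0), "out of range")
  expect_error(assign_zone(9, parcel_id = "P9"), "P9")
})

test_that("parcel-level tables load, screen tenure and map labels", {
  tab <- toy_parcel_table()
  ls <- load_landscape(tab)
  expect_s3_class(ls, "fs_landscape")
  expect_equal(nrow(ls$parcels), 5)
  expect_equal(ls$parcels$zone,
               c("Plains", "Foothills", "Hills", "Plains", "Foothills"))

  tab$tenure <- c(NA, NA, "Crown", NA, NA)
  ls2 <- load_landscape(tab)
  expect_false("T3" %in% ls2$parcels$parcel_id)

  tab2 <- toy_parcel_table()
  tab2$landuse[2] <- "Viticulture"
  expect_warning(ls3 <- load_landscape(tab2), "T2")
  expect_equal(ls3$parcels$enterprise[2], "NonModelled")

  tab3 <- toy_parcel_table()
  tab3$area_ha[c(1, 4)] <- NA
  expect_error(load_landscape(tab3), "T1, T4")
})

test_that("cell-level input resolves predominant land use and zone", {
  # parcel A: 3 SheepBeef + 2 Dairy cells -> SheepBeef by majority area
  cells <- data.frame(
    cell_x = c(1:5, 1:2),
    cell_y = c(rep(1, 5), rep(2, 2)),
    parcel_id = c(rep("A", 5), rep("B", 2)),
    landuse = c("SheepBeef", "SheepBeef", "SheepBeef", "Dairy", "Dairy",
                "Forestry", "Forestry"),
    luc_class = c(2, 2, 2, 5, 5, 7, 7)
  )
  ls <- load_landscape(cells)
  a <- ls$parcels[ls$parcels$parcel_id == "A", ]
  expect_equal(a$enterprise, "SheepBeef")
  expect_equal(a$zone, "Plains")   # 3 Plains vs 2 Foothills cells
  expect_equal(a$area_ha, 5 * 25)

  # exact tie broken by the fixed label order (Dairy before SheepBeef)
  cells2 <- cells
  cells2$landuse[1:5] <- c("Dairy", "Dairy", "SheepBeef", "SheepBeef",
                           "Forestry")  # 2-2 tie between Dairy and SheepBeef
  ls2 <- load_landscape(cells2)
  expect_equal(ls2$parcels$enterprise[ls2$parcels$parcel_id == "A"], "Dairy")
})

test_that("farm filter is strict on area and drops non-modelled uses", {
  p <- data.frame(
    parcel_id = c("a", "b", "c", "d"),
    area_ha = c(99, 101, 500, 300),
    centroid_x = 1:4, centroid_y = 0,
    zone = "Plains",
    enterprise = c("SheepBeef", "SheepBeef", "SheepBeef", "NonModelled")
  )
  ls <- new_landscape(p)
  expect_message(out <- filter_parcels(ls, 100), "2 parcel")
  expect_setequal(out$parcels$parcel_id, c("b", "c"))

  p$area_ha <- c(100, 100, 100, 100)  # exactly at threshold: excluded
  p$enterprise <- "SheepBeef"
  expect_error(suppressMessages(filter_parcels(new_landscape(p), 100)),
               "nothing to simulate")
})

test_that("adjacency is rook contiguity: shared edges, not corners", {
  cells <- data.frame(
    x = c(1, 2, 1, 2), y = c(1, 1, 2, 2),
    parcel_id = c("A", "D", "C", "B")
  )
  p <- data.frame(
    parcel_id = c("A", "B", "C", "D"),
    area_ha = 25, centroid_x = 1:4, centroid_y = 0,
    zone = "Plains", enterprise = "SheepBeef"
  )
  ls <- build_adjacency(new_landscape(p, cells = cells))
  expect_setequal(ls$adjacency[["A"]], c("C", "D"))  # edges only
  expect_false("B" %in% ls$adjacency[["A"]])         # corner contact
  expect_true("A" %in% ls$adjacency[["C"]])          # symmetric
  expect_true("A" %in% ls$adjacency[["D"]])

  # a parcel with no grid neighbours has an empty neighbour set
  cells_iso <- data.frame(x = c(1, 3), y = c(1, 1),
                          parcel_id = c("A", "B"))
  p_iso <- p[1:2, ]
  ls_iso <- build_adjacency(new_landscape(p_iso, cells = cells_iso))
  expect_length(ls_iso$adjacency[["B"]], 0)
})

test_that("synthetic generation is deterministic and respects config", {
  gc <- default_gen_config(nx = 15, ny = 12)
  a <- generate_synthetic_landscape(gc, seed = 7)
  b <- generate_synthetic_landscape(gc, seed = 7)
  expect_identical(a, b)
  expect_false(identical(
    a$parcels$enterprise,
    generate_synthetic_landscape(gc, seed = 8)$parcels$enterprise))

  gc1 <- default_gen_config(
    nx = 15, ny = 12,
    shares = list(Plains = c(SheepBeef = 1), Foothills = c(SheepBeef = 1),
                  Hills = c(SheepBeef = 1)))
  mono <- generate_synthetic_landscape(gc1, seed = 1)
  expect_true(all(mono$parcels$enterprise == "SheepBeef"))

  bad <- default_gen_config(nx = 15, ny = 12)
  bad$shares$Plains <- c(Dairy = 0.5, SheepBeef = 0.4)
  expect_error(generate_synthetic_landscape(bad, seed = 1), "sum to 1")
  expect_error(
    generate_synthetic_landscape(default_gen_config(min_cells = 2), 1),
    "100 ha")
})

test_that("generated landscapes satisfy the structural invariants", {
  for (s in 1:5) {
    gc <- default_gen_config(nx = 18, ny = 14)
    ls <- generate_synthetic_landscape(gc, seed = s)
    p <- ls$parcels
    # exact area partition of the grid
    expect_equal(sum(p$area_ha), gc$nx * gc$ny * gc$cell_size_ha)
    expect_true(all(p$area_ha >= gc$min_cells * gc$cell_size_ha))
    expect_true(all(p$zone %in% zones()))
    # adjacency symmetric and irreflexive
    for (id in p$parcel_id) {
      expect_false(id %in% ls$adjacency[[id]])
      for (nb in ls$adjacency[[id]]) {
        expect_true(id %in% ls$adjacency[[nb]])
      }
    }
  }
})

test_that("initial enterprise area shares track the zone targets", {
  # ~2,000-parcel catchment; ensemble mean within the binomial sampling
  # error of the target share
  gc <- default_gen_config(nx = 160, ny = 100)
  target <- local({
    zf <- gc$zone_fractions
    sum(vapply(zones(), function(z) {
      zf[[z]] * (gc$shares[[z]]["SheepBeef"] %||% 0)
    }, numeric(1)))
  })
  fr <- vapply(1:20, function(s) {
    ls <- generate_synthetic_landscape(gc, seed = s)
    p <- ls$parcels
    sum(p$area_ha[p$enterprise == "SheepBeef"]) / sum(p$area_ha)
  }, numeric(1))
  expect_lt(abs(mean(fr) - target), 0.03)
})

test_that("GeoJSON polygons load with computed area, centroid, adjacency", {
  # two 1000 m x 1000 m squares sharing an edge, one distant square
  sq <- function(x0, y0, s = 1000) {
    list(list(
      list(x0, y0), list(x0 + s, y0), list(x0 + s, y0 + s),
      list(x0, y0 + s), list(x0, y0)
    ))
  }
  feat <- function(id, lu, luc, x0, y0, tenure = NULL) {
    props <- list(parcel_id = id, landuse = lu, luc_class = luc)
    if (!is.null(tenure)) props$tenure <- tenure
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = sq(x0, y0)))
  }
  gj <- list(type = "FeatureCollection",
             features = list(
               feat("G1", "SheepBeef", 3, 0, 0),
               feat("G2", "Dairy", 2, 1000, 0),
               feat("G3", "Forestry", 7, 5000, 0),
               feat("G4", "SheepBeef", 5, 0, 5000, tenure = "Crown")))
  path <- file.path(tempdir(), "toy_landscape.geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  ls <- load_landscape(path)
  expect_setequal(ls$parcels$parcel_id, c("G1", "G2", "G3"))  # Crown gone
  expect_equal(ls$parcels$area_ha, rep(100, 3))               # 1 km^2
  g1 <- ls$parcels[ls$parcels$parcel_id == "G1", ]
  expect_equal(c(g1$centroid_x, g1$centroid_y), c(500, 500))
  expect_equal(ls$adjacency[["G1"]], "G2")                    # shared edge
  expect_length(ls$adjacency[["G3"]], 0)
})
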