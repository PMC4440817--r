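#' Enterprise and productivity-zone labels
#'
#' The model simulates conversion between four farm enterprises on three
#' productivity zones. `enterprises()` returns the five recognised
#' enterprise labels (including the `NonModelled` sink for land uses the
#' model does not simulate); `modelled_enterprises()` returns the four
#' enterprises a farm can convert to; `zones()` returns the three
#' productivity-zone labels in decreasing order of expected productivity.
#'
#' The fixed ordering of `modelled_enterprises()` is load-bearing: it is
#' the deterministic tie-break order used by [optimize_farm()] and by the
#' majority-area rule in [load_landscape()] (lowest position wins).
#'
#' @return A character vector of labels.
#' @export
#' @examples
#' enterprises()
#' zones()
enterprises <- function() {
  c("Dairy", "SheepBeef", "Forestry", "CarbonForestry", "NonModelled")
}

#' @rdname enterprises
#' @export
modelled_enterprises <- function() {
  c("Dairy", "SheepBeef", "Forestry", "CarbonForestry")
}

#' @rdname enterprises
#' @export
zones <- function() {
  c("Plains", "Foothills", "Hills")
}

# enterprises subject to the GHG emissions charge
livestock_enterprises <- function() c("Dairy", "SheepBeef")

# enterprises subject to the rotation lock-in after conversion
forest_enterprises <- function() c("Forestry", "CarbonForestry")

#' Map a Land Use Capability class to a productivity zone
#'
#' New Zealand's Land Use Capability (LUC) classification grades land from
#' 1 (most versatile) to 8 (least). Classes 1-4 map to `Plains`, 5-6 to
#' `Foothills`, and 7-8 to `Hills`.
#'
#' @param luc_class Integer vector of LUC classes in 1..8.
#' @param parcel_id Optional identifiers used in the error message when a
#'   class is out of range.
#' @return Character vector of zone labels, same length as `luc_class`.
#' @export
#' @examples
#' assign_zone(c(1, 4, 5, 6, 7, 8))
assign_zone <- function(luc_class, parcel_id = NULL) {
  luc <- as.integer(luc_class)
  bad <- is.na(luc) | luc < 1L | luc > 8L
  if (any(bad)) {
    ids <- if (is.null(parcel_id)) which(bad) else parcel_id[bad]
    stop("LUC class out of range 1-8 for parcel(s): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  ifelse(luc <= 4L, "Plains", ifelse(luc <= 6L, "Foothills", "Hills"))
}

# Normalise free-text land-use labels to enterprise labels; anything
# unrecognised becomes NonModelled (callers warn).
normalize_enterprise <- function(x) {
  key <- tolower(gsub("[^a-z]", "", tolower(x)))
  map <- c(
    dairy = "Dairy",
    sheepbeef = "SheepBeef", sheepandbeef = "SheepBeef",
    forestry = "Forestry", plantationforestry = "Forestry",
    pineplantation = "Forestry",
    carbonforestry = "CarbonForestry",
    nonmodelled = "NonModelled"
  )
  out <- unname(map[key])
  out[is.na(out)] <- "NonModelled"
  out
}
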