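#' Social information network: the k closest same-enterprise farmers
#'
#' A farmer's social network is the `k` farmers operating the same
#' enterprise whose farm centroids are nearest (Euclidean distance on the
#' planar coordinates), excluding the farmer themselves; if fewer than
#' `k` candidates exist, all of them. Distance ties are broken by lowest
#' parcel id. The network is recomputed every step because enterprises
#' change.
#'
#' @param farmer_id Identifier of the focal farmer.
#' @param population Population data.frame (see [init_population()]).
#' @param landscape An `fs_landscape`; farm centroids and current
#'   enterprises are read from its parcel table.
#' @param k Network size (default 10).
#' @return Character vector of farmer ids (possibly empty).
#' @export
social_network <- function(farmer_id, population, landscape, k = 10) {
  stopifnot(k >= 1)
  p <- landscape$parcels
  row_f <- match(farmer_id, population$farmer_id)
  if (is.na(row_f)) stop("unknown farmer_id: ", farmer_id, call. = FALSE)
  farm_f <- population$farm_id[row_f]
  i <- match(farm_f, p$parcel_id)
  cand <- which(p$enterprise == p$enterprise[i] & p$parcel_id != farm_f)
  cand <- cand[p$parcel_id[cand] %in% population$farm_id]
  if (length(cand) == 0) return(character(0))
  d <- sqrt((p$centroid_x[cand] - p$centroid_x[i])^2 +
            (p$centroid_y[cand] - p$centroid_y[i])^2)
  ord <- order(d, p$parcel_id[cand])
  sel <- cand[ord[seq_len(min(k, length(cand)))]]
  population$farmer_id[match(p$parcel_id[sel], population$farm_id)]
}

prof_of <- function(x) {
  if (is.numeric(x)) x else x$profitability_per_ha
}

#' Endorsement adjustment from the social network
#'
#' Compares the farmer's profitability per hectare with the equally
#' weighted mean over their social network: above the mean lowers the
#' conversion likelihood by 0.1, below raises it by 0.1; an exactly equal
#' comparison or an empty network leaves it unchanged.
#'
#' @param farmer Numeric profitability/ha, or a list/row with
#'   `profitability_per_ha`.
#' @param members Numeric vector of network members' profitability/ha
#'   (or a data.frame with that column).
#' @return One of -0.1, 0, +0.1.
#' @export
#' @examples
#' endorsement_adjustment(100, c(110, 130))  # below the mean: +0.1
endorsement_adjustment <- function(farmer, members) {
  own <- prof_of(farmer)
  vals <- if (is.data.frame(members)) members$profitability_per_ha
          else members
  if (length(vals) == 0) return(0)
  m <- mean(vals)
  if (own > m) -0.1 else if (own < m) 0.1 else 0
}

#' Geographic information network for a proposed enterprise
#'
#' The farms geographically adjacent to the farmer's own farm,
#' restricted to those currently operating the proposed enterprise.
#' Imitation only fires when a conversion is proposed, so the network is
#' conditional on the proposal.
#'
#' @inheritParams social_network
#' @param proposed Proposed enterprise label.
#' @return Character vector of farmer ids (possibly empty).
#' @export
geographic_network <- function(farmer_id, population, landscape, proposed) {
  p <- landscape$parcels
  row_f <- match(farmer_id, population$farmer_id)
  if (is.na(row_f)) stop("unknown farmer_id: ", farmer_id, call. = FALSE)
  farm_f <- population$farm_id[row_f]
  nb <- landscape$adjacency[[farm_f]]
  nb_ent <- p$enterprise[match(nb, p$parcel_id)]
  sel <- nb[nb_ent == proposed]
  sel <- sel[sel %in% population$farm_id]
  population$farmer_id[match(sel, population$farm_id)]
}

#' Imitation adjustment from adjacent farms
#'
#' Compares the farmer's profitability per hectare with the mean over
#' adjacent farms already operating the proposed enterprise: above the
#' mean lowers the conversion likelihood by 0.05, below raises it by
#' 0.05. The magnitude is deliberately half the endorsement effect:
#' imitation of neighbours carries less weight than endorsement within
#' the enterprise community.
#'
#' @inheritParams endorsement_adjustment
#' @return One of -0.05, 0, +0.05.
#' @export
imitation_adjustment <- function(farmer, members) {
  own <- prof_of(farmer)
  vals <- if (is.data.frame(members)) members$profitability_per_ha
          else members
  if (length(vals) == 0) return(0)
  m <- mean(vals)
  if (own > m) -0.05 else if (own < m) 0.05 else 0
}
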