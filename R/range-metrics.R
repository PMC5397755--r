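# Three range points per species and period.  Limits snap to occupied
# sites (the design observes a small set of discrete elevations); the
# abundance-weighted centre may fall between sites.

.absent_species <- function(species = NULL, period = NULL) {
  msg <- "species has no captures"
  if (!is.null(species)) msg <- paste0(msg, ": ", species)
  if (!is.null(period)) msg <- paste0(msg, " in period '", period, "'")
  stop(structure(class = c("elevshift_absent_species", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Elevational range limits of a species
#'
#' The lower and upper range limits are the minimum and maximum elevations of
#' the sites where the species was captured (count > 0).  Zero counts at
#' interior sites do not split the range.
#'
#' @param counts numeric vector of per-site counts, aligned with `elevations`.
#' @param elevations numeric vector of site elevations in metres.
#' @return Named numeric: `lower_m`, `upper_m`.
#' @export
range_limits <- function(counts, elevations) {
  stopifnot(length(counts) == length(elevations))
  occ <- elevations[counts > 0]
  if (!length(occ)) .absent_species()
  c(lower_m = min(occ), upper_m = max(occ))
}

#' Abundance-weighted range centre
#'
#' The mean of site elevations weighted by the proportion of the species'
#' individuals captured at each site: sum over sites of `E_i * p_i` where
#' `p_i = count_i / total`.  Always lies within the range limits.
#'
#' @inheritParams range_limits
#' @return Centre elevation in metres (scalar).
#' @examples
#' weighted_range_centre(c(1, 3), c(1000, 3000))  # 0.25*1000 + 0.75*3000
#' @export
weighted_range_centre <- function(counts, elevations) {
  stopifnot(length(counts) == length(elevations))
  total <- sum(counts)
  if (total <= 0) .absent_species()
  sum(elevations * counts) / total
}

#' All three range points of one species in one period
#'
#' @inheritParams range_limits
#' @return Named numeric: `lower_m`, `upper_m`, `centre_m`.
#' @export
range_points <- function(counts, elevations) {
  lim <- range_limits(counts, elevations)
  c(lim, centre_m = weighted_range_centre(counts, elevations))
}

#' Range points for a set of species in both periods
#'
#' @param dataset a [survey_dataset()].
#' @param species_list character vector of species; each must have at least
#'   one capture in each period.
#' @return Data frame with one row per (species, period): `species`,
#'   `period`, `lower_m`, `upper_m`, `centre_m`.
#' @export
range_points_table <- function(dataset, species_list) {
  stopifnot(inherits(dataset, "survey_dataset"), length(species_list) >= 1)
  elev <- dataset$sites$elevation_m
  rows <- vector("list", 2L * length(species_list))
  k <- 0L
  for (p in dataset$periods) {
    m <- species_site_matrix(dataset, p, species_list)
    for (sp in species_list) {
      if (sum(m[sp, ]) <= 0) .absent_species(sp, p)
      pts <- range_points(m[sp, ], elev)
      k <- k + 1L
      rows[[k]] <- data.frame(species = sp, period = p,
                              lower_m = pts[["lower_m"]],
                              upper_m = pts[["upper_m"]],
                              centre_m = pts[["centre_m"]])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$species, species_list),
                   match(out$period, dataset$periods)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
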