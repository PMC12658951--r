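#' Swedish coastal Baltic Sea case-study area figures
#'
#' Headline area figures for the method's motivating case study, the
#' coastal Swedish Baltic Sea: the study area (all sea within 15 km of the
#' Swedish baseline), the extent of the full marine protected area
#' network, and the extent of its strictly protected subset (IUCN
#' categories Ia, Ib, II). These feed the random-allocation expectations
#' of the network assessment: randomly placed MPAs of the same total
#' extent would on average cover the corresponding area fraction of any
#' biodiversity feature.
#'
#' @return List with areas in km^2 (`study_area_km2`, `mpa_km2`,
#'   `strict_mpa_km2`), the derived area fractions (`mpa_fraction`,
#'   `strict_fraction`), the grid resolution in metres, and the number of
#'   planning units at that resolution.
#' @export
baltic_case_study <- function() {
  study_area_km2 <- 49469
  mpa_km2 <- 5200
  strict_mpa_km2 <- 1373
  list(study_area_km2 = study_area_km2,
       mpa_km2 = mpa_km2,
       strict_mpa_km2 = strict_mpa_km2,
       mpa_fraction = mpa_km2 / study_area_km2,
       strict_fraction = strict_mpa_km2 / study_area_km2,
       resolution_m = 250,
       n_planning_units = 791511)
}
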