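#' Define a stroke center
#'
#' @param id Unique hospital label.
#' @param role One of `"PSC"` (primary stroke center, IVT only), `"CSC"`
#'   (comprehensive stroke center, IVT + EVT, home base of the mobile
#'   interventionalist), `"TSC"` (thrombectomy-capable stroke center, an
#'   upgraded PSC) or `"NSC"` (non-stroke center, carried but never routed to).
#' @param distance_to_csc Straight-line distance to the CSC in kilometres.
#' @param angio_transfer_minutes Minutes the mobile interventionalist needs
#'   from the hospital arrival point (e.g. helipad or entrance) to the
#'   angiography suite; 5 or 10 depending on the landing-area location.
#' @param x,y Optional planar coordinates in kilometres, used to derive
#'   inter-hospital travel times from per-modality speeds.
#' @return An object of class `hospital`.
#' @export
hospital <- function(id, role = c("PSC", "CSC", "TSC", "NSC"),
                     distance_to_csc = 0, angio_transfer_minutes = 10,
                     x = NULL, y = NULL) {
  role <- match.arg(role)
  assert_that(is.character(id) && length(id) == 1L && nzchar(id),
              "hospital: 'id' must be a non-empty string")
  assert_that(is_scalar_number(distance_to_csc) && distance_to_csc >= 0,
              "hospital '%s': distance_to_csc must be >= 0", id)
  assert_that(angio_transfer_minutes %in% c(5, 10),
              "hospital '%s': angio_transfer_minutes must be 5 or 10", id)
  if (role == "CSC")
    assert_that(distance_to_csc == 0,
                "hospital '%s': the CSC has distance_to_csc 0", id)
  structure(list(id = id, role = role, distance_to_csc = distance_to_csc,
                 angio_transfer_minutes = angio_transfer_minutes,
                 x = x, y = y),
            class = "hospital")
}

#' Assemble a region configuration
#'
#' A region bundles the stroke-center network, one travel-time model per
#' transport modality, the ground-EMS response-time distribution and the
#' scalar parameters of the mobile-interventionalist (MI) pathway.
#'
#' Each entry of `travel` is a list with either a `speed_kmh` (travel time is
#' then straight-line distance between hospital coordinates divided by speed)
#' or an explicit `matrix` of minutes with location labels as dimnames; a
#' matrix takes precedence where its labels cover the query.
#'
#' @param hospitals List of [hospital()] objects; exactly one CSC.
#' @param travel Named list with elements `car`, `gems`, `hems` as described
#'   above.
#' @param gems_response [dist_spec()] for the ground-EMS response time in
#'   minutes (ambulance dispatched from its station to pick up the MI).
#' @param hems_overhead_minutes Fixed helicopter overhead: fire-safety team on
#'   the helipad (20 min) plus MI pick-up (4 min).
#' @param hems_weather_failure_prob Probability that weather grounds the
#'   helicopter and the ground-EMS branch is used instead.
#' @param nearest_tsc_fraction Share of patients whose nearest facility is a
#'   thrombectomy-capable center; used by abstract-origin cohort generation.
#' @param telemedicine_prob Probability that the MI reviews the CT angiogram
#'   through telemedicine before leaving (preparation 10 min) rather than
#'   departing on the short briefing alone (5 min).
#' @return An object of class `region_config`.
#' @seealso [make_default_region()] for a ready-made synthetic region.
#' @export
region_config <- function(hospitals, travel, gems_response,
                          hems_overhead_minutes = 24,
                          hems_weather_failure_prob = 0.15,
                          nearest_tsc_fraction = 0.45,
                          telemedicine_prob = 1) {
  assert_that(length(hospitals) >= 1, "region_config: no hospitals")
  ids <- vapply(hospitals, `[[`, character(1), "id")
  assert_that(!anyDuplicated(ids), "region_config: duplicate hospital ids")
  roles <- vapply(hospitals, `[[`, character(1), "role")
  assert_that(sum(roles == "CSC") == 1,
              "region_config: exactly one CSC required (found %d)",
              sum(roles == "CSC"))
  assert_that(all(c("car", "gems", "hems") %in% names(travel)),
              "region_config: travel must define car, gems and hems")
  assert_that(inherits(gems_response, "dist_spec"),
              "region_config: gems_response must be a dist_spec")
  assert_that(hems_overhead_minutes >= 0,
              "region_config: hems_overhead_minutes must be >= 0")
  for (p in c(hems_weather_failure_prob, nearest_tsc_fraction,
              telemedicine_prob))
    assert_that(p >= 0 && p <= 1,
                "region_config: probabilities must lie in [0, 1]")
  names(hospitals) <- ids
  structure(list(hospitals = hospitals, travel = travel,
                 gems_response = gems_response,
                 hems_overhead_minutes = hems_overhead_minutes,
                 hems_weather_failure_prob = hems_weather_failure_prob,
                 nearest_tsc_fraction = nearest_tsc_fraction,
                 telemedicine_prob = telemedicine_prob),
            class = "region_config")
}

#' @export
print.region_config <- function(x, ...) {
  roles <- vapply(x$hospitals, `[[`, character(1), "role")
  cat(sprintf("<region_config> %d hospitals (%s)\n", length(x$hospitals),
              paste(sprintf("%d %s", table(roles), names(table(roles))),
                    collapse = ", ")))
  invisible(x)
}

hospital_ids <- function(region) names(region$hospitals)

hospital_roles <- function(region) {
  vapply(region$hospitals, `[[`, character(1), "role")
}

csc_id <- function(region) {
  hospital_ids(region)[hospital_roles(region) == "CSC"]
}

evt_roles <- function() c("TSC", "CSC")

#' Travel time between two locations
#'
#' `from` and `to` are hospital ids, labels present in the modality's explicit
#' travel matrix, or an abstract patient origin given as
#' `list(catchment = <hospital id>, leg_minutes = <minutes>)`, whose time to
#' any hospital is the on-scene-to-catchment leg plus the inter-hospital time
#' from the catchment.
#'
#' @param region A [region_config()].
#' @param modality `"car"`, `"gems"` or `"hems"`.
#' @param from,to Locations as described above.
#' @return Travel time in minutes.
#' @export
travel_time <- function(region, modality, from, to) {
  modality <- match.arg(modality, c("car", "gems", "hems"))
  if (is.list(from)) {
    assert_that(!is.null(from$catchment) && !is.null(from$leg_minutes),
                "travel_time: abstract origin needs catchment and leg_minutes")
    if (identical(from$catchment, to)) return(from$leg_minutes)
    return(from$leg_minutes +
             travel_time(region, modality, from$catchment, to))
  }
  if (identical(from, to)) return(0)
  tt <- region$travel[[modality]]
  m <- tt$matrix
  if (!is.null(m) && from %in% rownames(m) && to %in% colnames(m)) {
    val <- m[from, to]
    assert_that(is.finite(val),
                "travel_time: no %s entry from '%s' to '%s'", modality,
                from, to)
    return(val)
  }
  h1 <- region$hospitals[[from]]
  h2 <- region$hospitals[[to]]
  assert_that(!is.null(h1) && !is.null(h2) && !is.null(tt$speed_kmh) &&
                !is.null(h1$x) && !is.null(h2$x),
              "travel_time: no %s entry from '%s' to '%s'", modality, from, to)
  sqrt((h1$x - h2$x)^2 + (h1$y - h2$y)^2) / tt$speed_kmh * 60
}

#' Nearest hospital of an allowed role
#'
#' Scans every hospital whose role is in `candidates` and returns the one
#' minimizing travel time from `origin`.  Ties are broken by lexicographic
#' hospital id so results are deterministic under fixed seeds.
#'
#' @param origin A location accepted by [travel_time()].
#' @param candidates Character vector of allowed roles, e.g.
#'   `c("PSC", "TSC", "CSC")`.
#' @param region A [region_config()].
#' @param modality Transport modality for the travel-time lookup.
#' @return The nearest [hospital()].
#' @export
nearest_facility <- function(origin, candidates, region, modality = "gems") {
  keep <- hospital_roles(region) %in% candidates
  assert_that(any(keep), "nearest_facility: no hospital with role in {%s}",
              paste(candidates, collapse = ", "))
  hs <- region$hospitals[keep]
  hs <- hs[order(names(hs))]
  times <- vapply(hs, function(h) travel_time(region, modality, origin, h$id),
                  numeric(1))
  hs[[which.min(times)]]
}

#' Upgrade primary stroke centers to thrombectomy-capable centers
#'
#' Returns a modified copy of the region in which the named PSCs carry role
#' TSC; travel tables and all other hospitals are untouched.
#'
#' @param region A [region_config()].
#' @param psc_ids Character vector of PSC ids to upgrade (no duplicates).
#' @return A new `region_config`.
#' @export
upgrade_to_tsc <- function(region, psc_ids) {
  if (length(psc_ids) == 0) return(region)
  assert_that(!anyDuplicated(psc_ids),
              "upgrade_to_tsc: duplicated id in psc_ids")
  for (id in psc_ids) {
    h <- region$hospitals[[id]]
    assert_that(!is.null(h), "upgrade_to_tsc: no hospital '%s'", id)
    assert_that(h$role == "PSC",
                "upgrade_to_tsc: hospital '%s' has role %s, not PSC", id,
                h$role)
    region$hospitals[[id]]$role <- "TSC"
  }
  region
}

#' Route a patient from the stroke onset location
#'
#' Implements the two prehospital routing strategies:
#' \describe{
#'   \item{`nearest_ivt`}{current guidelines: transport to the nearest
#'     IVT-capable hospital (PSC, TSC or CSC).  If that hospital can also
#'     perform EVT the pathway class is `direct_to_tsc`, otherwise the patient
#'     follows the combined drip-and-ship / drive-the-doctor class `ds_dd`
#'     with a secondary transfer to the nearest TSC.}
#'   \item{`race`}{RACE-scale triage: patients whose nearest EVT-capable
#'     center is at least as near as any PSC go there irrespective of the
#'     scale; otherwise a positive RACE screen routes them to the nearest
#'     EVT-capable center and a (false) negative screen to the nearest PSC as
#'     `ds_dd`.}
#' }
#' For `ds_dd` the secondary destination is the nearest TSC from the first
#' hospital (never the CSC).
#'
#' @param case A patient case as produced by [generate_cohort()] /
#'   [cohort_case()]: needs `$origin` and `$race_negative`.
#' @param strategy `"nearest_ivt"` or `"race"`.
#' @param region A [region_config()] containing at least one EVT-capable
#'   hospital.
#' @return A list of class `routing_decision` with elements
#'   `first_destination`, `secondary` (TSC or `NULL`), `evt_center` and
#'   `pathway_class` (`"direct_to_tsc"` or `"ds_dd"`).
#' @export
route_patient <- function(case, strategy, region) {
  strategy <- match.arg(strategy, c("nearest_ivt", "race"))
  roles <- hospital_roles(region)
  assert_that(any(roles %in% evt_roles()),
              "route_patient: region has no EVT-capable hospital")
  assert_that(any(roles == "TSC"),
              "route_patient: region has no TSC; upgrade a PSC before routing")
  origin <- case$origin

  if (strategy == "nearest_ivt") {
    h <- nearest_facility(origin, c("PSC", "TSC", "CSC"), region)
    if (h$role %in% evt_roles()) {
      dec <- list(first_destination = h, secondary = NULL, evt_center = h,
                  pathway_class = "direct_to_tsc")
    } else {
      second <- nearest_facility(h$id, "TSC", region)
      dec <- list(first_destination = h, secondary = second,
                  evt_center = second, pathway_class = "ds_dd")
    }
  } else {
    e <- nearest_facility(origin, evt_roles(), region)
    has_psc <- any(roles == "PSC")
    t_e <- travel_time(region, "gems", origin, e$id)
    t_p <- if (has_psc) {
      p <- nearest_facility(origin, "PSC", region)
      travel_time(region, "gems", origin, p$id)
    } else Inf
    if (t_e <= t_p || !isTRUE(case$race_negative)) {
      dec <- list(first_destination = e, secondary = NULL, evt_center = e,
                  pathway_class = "direct_to_tsc")
    } else {
      second <- nearest_facility(p$id, "TSC", region)
      dec <- list(first_destination = p, secondary = second,
                  evt_center = second, pathway_class = "ds_dd")
    }
  }
  structure(dec, class = "routing_decision")
}
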