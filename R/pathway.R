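# Per-patient pathway assembly.  Event times are minutes since symptom
# onset.  Events not on a patient's realized path are simply absent from the
# timeline, never zero-filled.

.need_draws <- function(case, names) {
  missing <- setdiff(names, names(case$interval_draws))
  assert_that(length(missing) == 0, "pathway: missing interval draw(s): %s",
              paste(missing, collapse = ", "))
}

.timeline <- function(events, pathway_class, otg = NA_real_) {
  structure(list(events = events, pathway_class = pathway_class, otg = otg),
            class = "patient_timeline")
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat(sprintf("<patient_timeline> %s, OTG %s min\n", x$pathway_class,
              if (is.na(x$otg)) "pending" else sprintf("%.1f", x$otg)))
  print(round(x$events, 1))
  invisible(x)
}

#' Simulate the drip-and-ship baseline timeline
#'
#' Cumulative sum of the thirteen baseline interval draws: onset, 911 call,
#' EMS on scene, departure, PSC arrival, CT, IVT start, CTA, transfer call
#' (second 911 call), EMS back at the PSC, departure, CSC arrival,
#' angiography-suite arrival, groin puncture.
#'
#' @param case A `patient_case` (see [cohort_case()]) whose `interval_draws`
#'   contain every baseline interval.
#' @return A `patient_timeline` with `pathway_class = "ds_baseline"` and
#'   `otg` set.
#' @export
simulate_ds_baseline <- function(case) {
  nm <- baseline_interval_names()
  .need_draws(case, nm)
  t <- cumsum(case$interval_draws[nm])
  events <- stats::setNames(as.numeric(t), c(
    "call", "ems_on_scene", "scene_departure", "first_hospital_arrival",
    "ct", "ivt", "cta", "transfer_call", "ems_back_at_psc", "psc_departure",
    "evt_center_arrival", "angio_ready", "groin_puncture"))
  .timeline(events, "ds_baseline", otg = events[["groin_puncture"]])
}

#' Mobile-interventionalist notification moment
#'
#' `post_cta` notifies the MI at the CTA event (LVO confirmation).
#' `on_scene_race` notifies at the on-scene EMS assessment when the RACE
#' screen is positive; a RACE-negative LVO patient falls back to notification
#' after CTA confirmation.
#'
#' @param case A `patient_case`.
#' @param timeline The patient's `patient_timeline` so far (must contain the
#'   `cta` event for the fallback and `post_cta`).
#' @param moment `"post_cta"` or `"on_scene_race"`.
#' @return Notification time in minutes since onset.
#' @export
notify_mi <- function(case, timeline, moment = c("post_cta", "on_scene_race")) {
  moment <- match.arg(moment)
  ev <- timeline$events
  if (moment == "on_scene_race" && !isTRUE(case$race_negative)) {
    assert_that("ems_on_scene" %in% names(ev),
                "notify_mi: timeline lacks the on-scene event")
    return(ev[["ems_on_scene"]])
  }
  assert_that("cta" %in% names(ev), "notify_mi: timeline lacks the CTA event")
  ev[["cta"]]
}

#' Simulate the mobile interventionalist's path to the angiography suite
#'
#' The MI starts at the CSC.  Preparation to leave (5 min, or 10 min with a
#' telemedicine CTA review) runs in parallel with the transport response:
#' departure is at `notify + max(prep, response)`.  By car the response is
#' immediate; by ground EMS an ambulance responds from its station; by
#' helicopter a fixed overhead applies unless bad weather forces the
#' ground-EMS branch.  On arrival the transfer from the landing point to the
#' angiography suite takes the hospital's `angio_transfer_minutes`.
#'
#' @param notify Notification time in minutes since onset.
#' @param target_tsc Destination [hospital()] (or its id).
#' @param modality `"car"`, `"gems"` or `"hems"`.
#' @param region A [region_config()].
#' @param prep_minutes,response_draw,weather_u Optional explicit draws for
#'   common-random-number replay; when `NULL` they are drawn from the
#'   region's specs using the current RNG (`weather_u` is the uniform
#'   compared against `hems_weather_failure_prob`).
#' @return A list of class `mi_timeline` with `notify_time`, `prep_duration`,
#'   `response_duration`, `depart_time`, `travel_duration`, `tsc_arrival`,
#'   `angio_arrival` and `modality_used`.
#' @export
simulate_mi_path <- function(notify, target_tsc, modality, region,
                             prep_minutes = NULL, response_draw = NULL,
                             weather_u = NULL) {
  modality <- match.arg(modality, c("car", "gems", "hems"))
  target <- if (inherits(target_tsc, "hospital")) target_tsc
            else region$hospitals[[target_tsc]]
  assert_that(!is.null(target), "simulate_mi_path: unknown target hospital")
  if (is.null(prep_minutes)) {
    telemed <- stats::runif(1) < region$telemedicine_prob
    prep_minutes <- if (telemed) 10 else 5
  }
  used <- modality
  if (modality == "hems") {
    u <- weather_u %||% stats::runif(1)
    if (u < region$hems_weather_failure_prob) used <- "gems"
  }
  response <- switch(used,
    car = 0,
    gems = response_draw %||% spec_sample(region$gems_response, 1),
    hems = region$hems_overhead_minutes)
  travel <- travel_time(region, used, csc_id(region), target$id)
  depart <- notify + max(prep_minutes, response)
  arrival <- depart + travel
  structure(list(notify_time = notify, prep_duration = prep_minutes,
                 response_duration = response, depart_time = depart,
                 travel_duration = travel, tsc_arrival = arrival,
                 angio_arrival = arrival + target$angio_transfer_minutes,
                 modality_used = used),
            class = "mi_timeline")
}

#' Simulate the patient's drive-the-doctor timeline up to angio readiness
#'
#' For `direct_to_tsc` routing the onset-to-CTA chain runs as in the baseline
#' but at the EVT-capable first destination (the travel leg comes from the
#' region's travel model rather than the drawn PSC leg), followed by the
#' patient preparation interval `cta_to_angio_at_tsc` (scaled by
#' `prep_scale`).  For `ds_dd` the chain runs at the PSC, then the transfer
#' (second 911 call, EMS return, departure, PSC-to-TSC transport by ground
#' EMS) and preparation at the TSC.  `groin_puncture` is left unset; it is
#' filled by [synchronize()] against the interventionalist's arrival.
#'
#' @param case A `patient_case`.
#' @param routing A `routing_decision` from [route_patient()].
#' @param region A [region_config()].
#' @param prep_scale Multiplier on the preparation draw (sensitivity
#'   analyses use 0.75 and 1.25).
#' @return A `patient_timeline` with `otg = NA` and an `angio_ready` event.
#' @export
simulate_dd_patient <- function(case, routing, region, prep_scale = 1) {
  assert_that(inherits(routing, "routing_decision"),
              "simulate_dd_patient: 'routing' must come from route_patient()")
  assert_that(prep_scale > 0, "simulate_dd_patient: prep_scale must be > 0")
  d <- case$interval_draws
  .need_draws(case, c("onset_to_call", "call_to_scene", "on_scene",
                      "psc_arrival_to_ct", "ct_to_ivt", "ivt_to_cta",
                      "cta_to_angio_at_tsc"))
  first <- routing$first_destination
  leg <- travel_time(region, "gems", case$origin, first$id)
  t_call <- d[["onset_to_call"]]
  t_scene <- t_call + d[["call_to_scene"]]
  t_depart <- t_scene + d[["on_scene"]]
  t_arr <- t_depart + leg
  t_ct <- t_arr + d[["psc_arrival_to_ct"]]
  t_ivt <- t_ct + d[["ct_to_ivt"]]
  t_cta <- t_ivt + d[["ivt_to_cta"]]
  prep <- prep_scale * d[["cta_to_angio_at_tsc"]]

  if (routing$pathway_class == "direct_to_tsc") {
    events <- c(call = t_call, ems_on_scene = t_scene,
                scene_departure = t_depart, first_hospital_arrival = t_arr,
                ct = t_ct, ivt = t_ivt, cta = t_cta,
                angio_ready = t_cta + prep)
  } else {
    .need_draws(case, c("cta_to_transfer_call", "transfer_call_to_ems_at_psc",
                        "ems_at_psc_to_departure"))
    t_tc <- t_cta + d[["cta_to_transfer_call"]]
    t_ems <- t_tc + d[["transfer_call_to_ems_at_psc"]]
    t_dep2 <- t_ems + d[["ems_at_psc_to_departure"]]
    hop <- travel_time(region, "gems", first$id, routing$secondary$id)
    t_tsc <- t_dep2 + hop
    events <- c(call = t_call, ems_on_scene = t_scene,
                scene_departure = t_depart, first_hospital_arrival = t_arr,
                ct = t_ct, ivt = t_ivt, cta = t_cta, transfer_call = t_tc,
                ems_back_at_psc = t_ems, psc_departure = t_dep2,
                evt_center_arrival = t_tsc, angio_ready = t_tsc + prep)
  }
  .timeline(events, routing$pathway_class)
}

#' Synchronize patient and interventionalist at the angiography suite
#'
#' The procedure starts when both parties are present: the meeting time is
#' the later of the patient's `angio_ready` and the MI's `angio_arrival`;
#' whoever is earlier waits.  Groin puncture follows after the
#' angio-to-groin interval.
#'
#' @param patient A `patient_timeline` with an `angio_ready` event.
#' @param mi An `mi_timeline` from [simulate_mi_path()].
#' @param angio_to_groin A [dist_spec()] for the suite-arrival-to-puncture
#'   time, or ignored when `draw` is supplied.
#' @param draw Optional explicit angio-to-groin draw (common random numbers).
#' @return A list of class `sync_result` with `groin_time`, `mi_wait` and
#'   `patient_wait` (at most one of the waits is positive).
#' @export
synchronize <- function(patient, mi, angio_to_groin = NULL, draw = NULL) {
  ready <- patient$events[["angio_ready"]]
  arr <- mi$angio_arrival
  assert_that(is.finite(ready) && is.finite(arr),
              "synchronize: both angio_ready and angio_arrival must be set")
  a2g <- draw %||% spec_sample(angio_to_groin, 1)
  meeting <- max(ready, arr)
  structure(list(groin_time = meeting + a2g,
                 mi_wait = meeting - arr,
                 patient_wait = meeting - ready),
            class = "sync_result")
}
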