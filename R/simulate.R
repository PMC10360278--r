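# Vectorized cohort engine.  Scenario runs must be cheap enough to push
# 100,000 patients through 13 grid cells plus sensitivity re-runs, so the
# per-patient arithmetic of pathway.R is replicated here on whole columns.
# The test suite pins the two code paths together (vector output ==
# per-case output on the same cohort).

.interhospital_matrix <- function(region, modality) {
  ids <- sort(hospital_ids(region))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in ids) for (b in ids)
    m[a, b] <- travel_time(region, modality, a, b)
  m
}

# nearest hospital id (lexicographic tie-break) from each catchment, among a
# role subset; returns named character vector over all catchments present
.nearest_from <- function(m_gems, from_ids, to_ids) {
  sub <- m_gems[from_ids, sort(to_ids), drop = FALSE]
  picked <- colnames(sub)[max.col(-sub, ties.method = "first")]
  stats::setNames(picked, from_ids)
}

#' Simulate a full cohort through one scenario
#'
#' Vectorized engine behind [run_scenario()]: routes every patient, builds
#' the patient and mobile-interventionalist timelines, synchronizes them at
#' the angiography suite and returns per-patient results.  With
#' `routing = "baseline"` the drip-and-ship baseline chain is used and the
#' waiting columns are zero with `pathway_class = "ds_baseline"`.
#'
#' All stochastic inputs come from the cohort columns drawn by
#' [generate_cohort()], so two calls with the same cohort and scenario
#' settings are identical, and contrasts between scenarios on the same
#' cohort are common-random-number contrasts.
#'
#' @param cohort A `stroke_cohort`.
#' @param region A [region_config()] (already containing the scenario's TSC
#'   upgrades unless `routing = "baseline"`).
#' @param routing `"baseline"`, `"nearest_ivt"` or `"race"`.
#' @param notify `"post_cta"` or `"on_scene_race"`.
#' @param modality `"car"`, `"gems"` or `"hems"`.
#' @param prep_scale Multiplier on the `cta_to_angio_at_tsc` draw.
#' @return A `data.frame` with one row per patient: `otg`, `ppfo`-ready
#'   covariate echoes, `pathway_class`, destinations, the patient and MI
#'   component times, and `mi_wait` / `patient_wait`.
#' @export
simulate_cohort <- function(cohort, region, routing, notify = "post_cta",
                            modality = "car", prep_scale = 1) {
  routing <- match.arg(routing, c("baseline", "nearest_ivt", "race"))
  n <- nrow(cohort)
  iv <- function(nm) cohort[[paste0("iv_", nm)]]

  if (routing == "baseline") {
    parts <- vapply(baseline_interval_names(), iv, numeric(n))
    otg <- rowSums(parts)
    ready <- otg - iv("angio_to_groin")
    return(data.frame(id = cohort$id, pathway_class = "ds_baseline",
                      first_dest = csc_id(region), evt_center = csc_id(region),
                      cta_time = rowSums(parts[, 1:7, drop = FALSE]),
                      angio_ready = ready, mi_notify = NA_real_,
                      mi_angio_arrival = NA_real_, mi_wait = 0,
                      patient_wait = 0, otg = otg,
                      stringsAsFactors = FALSE))
  }

  notify <- match.arg(notify, c("post_cta", "on_scene_race"))
  modality <- match.arg(modality, c("car", "gems", "hems"))
  assert_that(prep_scale > 0, "simulate_cohort: prep_scale must be > 0")
  roles <- hospital_roles(region)
  assert_that(any(roles == "TSC"),
              "simulate_cohort: scenario region has no TSC")

  m_gems <- .interhospital_matrix(region, "gems")
  m_mi <- if (modality == "gems") m_gems
          else .interhospital_matrix(region, modality)
  csc <- csc_id(region)
  catchments <- sort(unique(cohort$catchment))
  assert_that(all(catchments %in% hospital_ids(region)),
              "simulate_cohort: cohort catchment not in region")

  tsc_ids <- names(roles)[roles == "TSC"]
  evt_ids <- names(roles)[roles %in% evt_roles()]
  near_tsc <- .nearest_from(m_gems, catchments, tsc_ids)
  near_evt <- .nearest_from(m_gems, catchments, evt_ids)
  catch_role <- roles[cohort$catchment]

  # routing: first destination, EVT center, pathway class ------------------
  if (routing == "nearest_ivt") {
    direct <- catch_role %in% evt_roles()
    first <- cohort$catchment
    evt <- ifelse(direct, cohort$catchment, near_tsc[cohort$catchment])
  } else {
    # catchment hospital is the nearest facility by construction, so the
    # nearest EVT center is at least as near as any PSC iff the catchment
    # itself is EVT-capable
    direct <- catch_role %in% evt_roles() | !cohort$race_negative
    first <- ifelse(direct, ifelse(catch_role %in% evt_roles(),
                                   cohort$catchment,
                                   near_evt[cohort$catchment]),
                    cohort$catchment)
    evt <- ifelse(direct, first, near_tsc[cohort$catchment])
  }
  cls <- ifelse(direct, "direct_to_tsc", "ds_dd")

  # patient timeline --------------------------------------------------------
  leg <- iv("scene_to_psc") +
    m_gems[cbind(cohort$catchment, first)]        # 0 when first == catchment
  t_scene <- iv("onset_to_call") + iv("call_to_scene")
  t_depart <- t_scene + iv("on_scene")
  t_arr <- t_depart + leg
  t_cta <- t_arr + iv("psc_arrival_to_ct") + iv("ct_to_ivt") + iv("ivt_to_cta")
  prep <- prep_scale * iv("cta_to_angio_at_tsc")

  transfer <- ifelse(direct, 0,
                     iv("cta_to_transfer_call") +
                       iv("transfer_call_to_ems_at_psc") +
                       iv("ems_at_psc_to_departure") +
                       m_gems[cbind(first, evt)])
  angio_ready <- t_cta + transfer + prep

  # mobile interventionalist -------------------------------------------------
  mi_notify <- if (notify == "post_cta") t_cta
               else ifelse(cohort$race_negative, t_cta, t_scene)
  mi_prep <- ifelse(cohort$mi_telemed_u < region$telemedicine_prob, 10, 5)
  if (modality == "car") {
    response <- rep(0, n)
    mi_travel <- m_mi[cbind(rep(csc, n), evt)]
  } else if (modality == "gems") {
    response <- cohort$mi_gems_response
    mi_travel <- m_gems[cbind(rep(csc, n), evt)]
  } else {
    grounded <- cohort$mi_weather_u < region$hems_weather_failure_prob
    response <- ifelse(grounded, cohort$mi_gems_response,
                       region$hems_overhead_minutes)
    mi_travel <- ifelse(grounded, m_gems[cbind(rep(csc, n), evt)],
                        m_mi[cbind(rep(csc, n), evt)])
  }
  angio_transfer <- vapply(region$hospitals, `[[`, numeric(1),
                           "angio_transfer_minutes")
  mi_arrival <- mi_notify + pmax(mi_prep, response) + mi_travel +
    angio_transfer[evt]

  # synchronization ----------------------------------------------------------
  meeting <- pmax(angio_ready, mi_arrival)
  data.frame(id = cohort$id, pathway_class = cls, first_dest = first,
             evt_center = evt, cta_time = t_cta, angio_ready = angio_ready,
             mi_notify = mi_notify, mi_angio_arrival = mi_arrival,
             mi_wait = meeting - mi_arrival,
             patient_wait = meeting - angio_ready,
             otg = meeting + iv("angio_to_groin"),
             stringsAsFactors = FALSE)
}
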