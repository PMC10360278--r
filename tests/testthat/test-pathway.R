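test_that("the drip-and-ship chain is an exact cumulative sum", {
  reg <- toy_region()
  ch <- toy_cohort(1, reg, pm_intervals(value = 10))
  case <- cohort_case(ch, 1)
  tl <- simulate_ds_baseline(case)
  expect_equal(tl$otg, 130)                       # 13 point-mass-10 steps
  expect_equal(unname(tl$events[["cta"]]), 70)
  expect_true(all(diff(tl$events) >= 0))

  ch0 <- toy_cohort(1, reg, pm_intervals(value = 0))
  expect_equal(simulate_ds_baseline(cohort_case(ch0, 1))$otg, 0)

  bad <- cohort_case(ch, 1)
  bad$interval_draws <- bad$interval_draws[-3]
  expect_error(simulate_ds_baseline(bad), "on_scene")
})

test_that("mean simulated baseline OTG matches linearity of expectation", {
  setup <- default_setup(n = 100000, seed = 13)
  sim <- simulate_cohort(setup$cohort, setup$region, "baseline")
  mu <- sum(sapply(strokesim:::baseline_interval_names(),
                   function(nm) spec_mean(setup$intervals[[nm]])))
  se <- sd(sim$otg) / sqrt(nrow(sim))
  expect_lt(abs(mean(sim$otg) - mu), 3 * se)
})

test_that("notification moment follows the RACE screen", {
  reg <- toy_region()
  ch <- toy_cohort(2, reg, pm_intervals(value = 10),
                   race_negative = c(FALSE, TRUE))
  tl <- simulate_ds_baseline(cohort_case(ch, 1))
  expect_equal(notify_mi(cohort_case(ch, 1), tl, "post_cta"),
               unname(tl$events[["cta"]]))
  expect_equal(notify_mi(cohort_case(ch, 1), tl, "on_scene_race"),
               unname(tl$events[["ems_on_scene"]]))
  # false-negative screen falls back to notification after CTA confirmation
  expect_equal(notify_mi(cohort_case(ch, 2), tl, "on_scene_race"),
               unname(tl$events[["cta"]]))
})

test_that("the interventionalist's path composes response, prep and travel", {
  reg <- toy_region()                              # gems 60 km/h: pscB 45 min
  # ground EMS: departure at notify + max(prep, response)
  mi <- simulate_mi_path(100, "pscB", "gems", reg, prep_minutes = 10,
                         response_draw = 9)
  expect_equal(mi$depart_time, 110)
  expect_equal(mi$tsc_arrival, 110 + 45)
  expect_equal(mi$angio_arrival, 110 + 45 + 10)

  # response can dominate prep
  mi2 <- simulate_mi_path(100, "pscB", "gems", reg, prep_minutes = 10,
                          response_draw = 30)
  expect_equal(mi2$depart_time, 130)

  # helicopter, good weather: fixed 24-min overhead then the flight
  mi3 <- simulate_mi_path(0, "pscC", "hems", reg, prep_minutes = 5,
                          weather_u = 0.99)
  expect_equal(mi3$modality_used, "hems")
  expect_equal(mi3$depart_time, 24)                # max(5, 24)
  expect_equal(mi3$angio_arrival, 24 + 75 / 180 * 60 + 10)

  # bad weather forces the ground-EMS branch
  mi4 <- simulate_mi_path(0, "pscC", "hems",
                          toy_region(weather_prob = 0.15),
                          prep_minutes = 5, response_draw = 9,
                          weather_u = 0.10)
  expect_equal(mi4$modality_used, "gems")
  expect_equal(mi4$tsc_arrival, 9 + 75)

  # car responds instantly and zero travel collapses to the prep time
  mi5 <- simulate_mi_path(50, "csc", "car", reg, prep_minutes = 10)
  expect_equal(mi5$tsc_arrival, 60)

  expect_error(simulate_mi_path(0, "pscB", "rocket", reg))
})

test_that("drive-the-doctor patient timelines match hand-computed chains", {
  reg <- upgrade_to_tsc(toy_region(), "pscC")
  ch <- toy_cohort(1, reg, pm_intervals(value = 10, prep = 45),
                   catchment = "pscC", race_negative = FALSE)
  case <- cohort_case(ch, 1)
  # co-locate the onset with the TSC: zero travel leg
  case$origin$leg_minutes <- 0
  case$interval_draws[["scene_to_psc"]] <- 0
  rt <- route_patient(case, "race", reg)
  expect_identical(rt$pathway_class, "direct_to_tsc")
  tl <- simulate_dd_patient(case, rt, reg)
  expect_equal(unname(tl$events[["angio_ready"]]), 6 * 10 + 45)
  expect_true(is.na(tl$otg))
  expect_false("transfer_call" %in% names(tl$events))

  # sensitivity multiplier scales only the preparation contribution
  iv60 <- pm_intervals(value = 10, prep = 60)
  ch60 <- toy_cohort(1, reg, iv60, catchment = "pscC", race_negative = FALSE)
  c60 <- cohort_case(ch60, 1)
  tl1 <- simulate_dd_patient(c60, rt, reg, prep_scale = 1)
  tl075 <- simulate_dd_patient(c60, rt, reg, prep_scale = 0.75)
  expect_equal(unname(tl1$events[["angio_ready"]] -
                        tl075$events[["angio_ready"]]), 15)

  # ds_dd with zero transfer intervals and zero hop equals the direct chain
  ivz <- pm_intervals(value = 10, prep = 45)
  for (nm in c("cta_to_transfer_call", "transfer_call_to_ems_at_psc",
               "ems_at_psc_to_departure"))
    ivz[[nm]] <- dist_spec("point_mass", value = 0)
  chz <- toy_cohort(1, reg, ivz, catchment = "pscC", race_negative = TRUE)
  cz <- cohort_case(chz, 1)
  rtz <- structure(list(first_destination = reg$hospitals[["pscC"]],
                        secondary = reg$hospitals[["pscC"]],
                        evt_center = reg$hospitals[["pscC"]],
                        pathway_class = "ds_dd"),
                   class = "routing_decision")
  tl_dd <- simulate_dd_patient(cz, rtz, reg)
  rt_direct <- structure(list(first_destination = reg$hospitals[["pscC"]],
                              secondary = NULL,
                              evt_center = reg$hospitals[["pscC"]],
                              pathway_class = "direct_to_tsc"),
                         class = "routing_decision")
  tl_direct <- simulate_dd_patient(cz, rt_direct, reg)
  expect_equal(unname(tl_dd$events[["angio_ready"]]),
               unname(tl_direct$events[["angio_ready"]]))
})

test_that("synchronization assigns one wait and is symmetric", {
  mk_pt <- function(ready) structure(list(events = c(angio_ready = ready)),
                                     class = "patient_timeline")
  mk_mi <- function(arr) structure(list(angio_arrival = arr),
                                   class = "mi_timeline")
  pm15 <- dist_spec("point_mass", value = 15)

  s <- synchronize(mk_pt(100), mk_mi(90), pm15)
  expect_equal(s$mi_wait, 10)
  expect_equal(s$patient_wait, 0)
  expect_equal(s$groin_time, 115)

  s2 <- synchronize(mk_pt(100), mk_mi(100), pm15)
  expect_equal(c(s2$mi_wait, s2$patient_wait), c(0, 0))

  s3 <- synchronize(mk_pt(90), mk_mi(100), pm15)
  expect_equal(c(s3$mi_wait, s3$patient_wait), c(s$patient_wait, s$mi_wait))
})

test_that("OTG conserves interval draws plus exactly one wait", {
  setup <- default_setup(n = 5000, seed = 14)
  reg <- upgrade_to_tsc(setup$region, default_tsc_ids(setup$region))
  m <- strokesim:::.interhospital_matrix(reg, "gems")
  ch <- setup$cohort
  for (routing in c("nearest_ivt", "race")) {
    sim <- simulate_cohort(ch, reg, routing, "post_cta", "gems")
    iv <- function(nm) ch[[paste0("iv_", nm)]]
    direct <- sim$pathway_class == "direct_to_tsc"
    patient_sum <- iv("onset_to_call") + iv("call_to_scene") + iv("on_scene") +
      iv("scene_to_psc") + m[cbind(ch$catchment, sim$first_dest)] +
      iv("psc_arrival_to_ct") + iv("ct_to_ivt") + iv("ivt_to_cta") +
      ifelse(direct, 0,
             iv("cta_to_transfer_call") + iv("transfer_call_to_ems_at_psc") +
               iv("ems_at_psc_to_departure") +
               m[cbind(sim$first_dest, sim$evt_center)]) +
      iv("cta_to_angio_at_tsc") + iv("angio_to_groin")
    resid <- sim$otg - (patient_sum + sim$patient_wait)
    expect_lt(max(abs(resid)), 1e-9)
    # never both waits positive
    expect_equal(sum(sim$mi_wait > 0 & sim$patient_wait > 0), 0)
  }
})

test_that("design levers are monotone under common random numbers", {
  setup <- default_setup(n = 5000, seed = 15)
  reg3 <- upgrade_to_tsc(setup$region, default_tsc_ids(setup$region))
  run <- function(region, ...) mean(simulate_cohort(setup$cohort, region,
                                                    ...)$otg)

  # earlier notification never increases mean OTG (per patient, in fact)
  a <- simulate_cohort(setup$cohort, reg3, "race", "post_cta", "gems")
  b <- simulate_cohort(setup$cohort, reg3, "race", "on_scene_race", "gems")
  expect_true(all(b$otg <= a$otg + 1e-9))

  # faster modality reduces the mean
  expect_lte(run(reg3, "race", "post_cta", "gems"),
             run(reg3, "race", "post_cta", "car"))
  expect_lte(run(reg3, "race", "post_cta", "hems"),
             run(reg3, "race", "post_cta", "gems"))

  # RACE routing reduces the mean relative to nearest-IVT routing
  expect_lte(run(reg3, "race", "post_cta", "car"),
             run(reg3, "nearest_ivt", "post_cta", "car"))

  # a larger upgrade set reduces the mean
  reg1 <- upgrade_to_tsc(setup$region, "psc8")
  expect_lte(run(reg3, "race", "post_cta", "car"),
             run(reg1, "race", "post_cta", "car"))

  # a uniformly faster travel table never increases the mean
  fast <- reg3
  for (mod in names(fast$travel))
    fast$travel[[mod]]$speed_kmh <- fast$travel[[mod]]$speed_kmh * 1.25
  expect_lte(run(fast, "race", "post_cta", "car"),
             run(reg3, "race", "post_cta", "car"))
})

test_that("an interventionalist already on site reduces to the patient path", {
  reg <- upgrade_to_tsc(toy_region(), "pscC")
  ch <- toy_cohort(1, reg, pm_intervals(value = 10, prep = 45),
                   catchment = "pscC", race_negative = FALSE)
  case <- cohort_case(ch, 1)
  rt <- route_patient(case, "race", reg)
  tl <- simulate_dd_patient(case, rt, reg)
  mi <- structure(list(angio_arrival = 0), class = "mi_timeline")
  s <- synchronize(tl, mi, draw = case$interval_draws[["angio_to_groin"]])
  expect_equal(s$groin_time,
               unname(tl$events[["angio_ready"]]) +
                 case$interval_draws[["angio_to_groin"]])
  expect_equal(s$patient_wait, 0)
})
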