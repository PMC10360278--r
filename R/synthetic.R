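# Synthetic stand-ins for the regional registry and EMS data: a 1-CSC /
# 8-PSC rural network, per-step interval distributions whose means sum to the
# drip-and-ship baseline level, and a covariate model for an EVT-treated LVO
# cohort.  These are declared fixtures emulating the statistical structure of
# the real region, not estimates of any patient records.

.default_psc_distances <- c(6, 13, 22, 31, 42, 54, 68, 84)
.default_psc_angles    <- c(10, 200, 100, 310, 160, 95, 160, 315)

#' Default synthetic region
#'
#' One comprehensive stroke center plus eight primary stroke centers at 6 to
#' 84 km, laid out deterministically on a plane so that inter-hospital travel
#' times follow straight-line distance at per-modality speeds (car 80 km/h,
#' ground EMS 90 km/h, helicopter 220 km/h).  The ground-EMS response spec
#' matches the published median (IQR) of 9 (7-12) minutes; helicopter
#' overhead is 24 minutes with a 15% weather fallback to ground EMS.
#'
#' @param seed Accepted for interface symmetry with the cohort generator; the
#'   layout itself is deterministic.
#' @return A [region_config()].
#' @export
make_default_region <- function(seed = 1L) {
  th <- .default_psc_angles * pi / 180
  hs <- c(
    list(hospital("csc", "CSC", 0, angio_transfer_minutes = 5, x = 0, y = 0)),
    lapply(seq_along(.default_psc_distances), function(i) {
      d <- .default_psc_distances[i]
      hospital(sprintf("psc%d", i), "PSC", d,
               angio_transfer_minutes = if (i %% 2 == 0) 10 else 5,
               x = d * cos(th[i]), y = d * sin(th[i]))
    }))
  region_config(
    hospitals = hs,
    travel = list(car = list(speed_kmh = 80),
                  gems = list(speed_kmh = 90),
                  hems = list(speed_kmh = 220)),
    gems_response = spec_from_median_iqr(9, 7, 12, "lognormal"),
    hems_overhead_minutes = 24,
    hems_weather_failure_prob = 0.15,
    nearest_tsc_fraction = 0.45)
}

#' Default thrombectomy-capable upgrade set
#'
#' The three PSCs most distant from the CSC.  Which three of the eight PSCs
#' to upgrade is a genuine regional design choice; distance from the CSC is
#' used here because remote PSCs gain most from avoiding the transfer.
#'
#' @param region A [region_config()].
#' @return Character vector of three PSC ids.
#' @export
default_tsc_ids <- function(region = make_default_region()) {
  ps <- Filter(function(h) h$role == "PSC", region$hospitals)
  d <- vapply(ps, `[[`, numeric(1), "distance_to_csc")
  names(sort(d, decreasing = TRUE))[1:3]
}

.lnorm_mean <- function(mean, sdlog) {
  dist_spec("lognormal", meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Default interval-time distributions
#'
#' Lognormal service-time specs for every pathway step, parameterized by mean
#' and log-scale spread.  The means are calibrated so the drip-and-ship chain
#' totals 241 minutes onset-to-groin, the level reported for comparable
#' drip-and-ship cohorts; individual step means are plausible round figures,
#' not fitted registry values.  The drive-the-doctor patient preparation step
#' (`cta_to_angio_at_tsc`) defaults to a 60-minute mean so that a 25% shorter
#' preparation equals 45 minutes.
#'
#' @return Named list of [dist_spec()] objects.
#' @export
default_intervals <- function() {
  list(
    onset_to_call             = .lnorm_mean(16, 0.80),
    call_to_scene             = .lnorm_mean(9,  0.40),
    on_scene                  = .lnorm_mean(18, 0.35),
    scene_to_psc              = .lnorm_mean(23, 0.45),
    psc_arrival_to_ct         = .lnorm_mean(14, 0.50),
    ct_to_ivt                 = .lnorm_mean(9,  0.50),
    ivt_to_cta                = .lnorm_mean(14, 0.55),
    psc_arrival_to_cta        = .lnorm_mean(37, 0.50),
    cta_to_transfer_call      = .lnorm_mean(22, 0.60),
    transfer_call_to_ems_at_psc = .lnorm_mean(20, 0.50),
    ems_at_psc_to_departure   = .lnorm_mean(11, 0.40),
    psc_to_csc                = .lnorm_mean(38, 0.35),
    csc_arrival_to_angio      = .lnorm_mean(25, 0.50),
    angio_to_groin            = .lnorm_mean(22, 0.45),
    cta_to_angio_at_tsc       = .lnorm_mean(60, 0.35),
    mi_prep                   = dist_spec("point_mass", value = 10))
}

# interval names drawn per patient, in fixed order (reproducibility contract)
baseline_interval_names <- function() {
  c("onset_to_call", "call_to_scene", "on_scene", "scene_to_psc",
    "psc_arrival_to_ct", "ct_to_ivt", "ivt_to_cta", "cta_to_transfer_call",
    "transfer_call_to_ems_at_psc", "ems_at_psc_to_departure", "psc_to_csc",
    "csc_arrival_to_angio", "angio_to_groin")
}

cohort_interval_names <- function() {
  c(baseline_interval_names(), "cta_to_angio_at_tsc")
}

#' Specify a synthetic cohort
#'
#' Covariate model for a cohort of LVO patients treated by EVT: age from a
#' truncated normal, NIHSS from a discretized gamma clamped to 0-42, a
#' 4-category CTA collateral grade, pre-stroke mRS capped at 2 (the inclusion
#' criterion) and a RACE screen that misses 5% of LVO patients.  Patient
#' origins are abstract: each case is assigned a catchment PSC with the given
#' weights and its on-scene-to-hospital leg reuses the `scene_to_psc` interval
#' draw.
#'
#' @param n Number of patients.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param age_mean,age_sd,age_range Truncated-normal age model in years.
#' @param nihss_shape,nihss_rate Gamma model for NIHSS before discretization.
#' @param collateral_probs Probabilities of collateral grades 0-3 (absent,
#'   <50%, >=50% but <100%, 100% filling); must sum to 1.
#' @param prestroke_probs Probabilities of pre-stroke mRS 0, 1, 2.
#' @param race_false_negative_prob Probability an LVO patient screens RACE
#'   negative (1 - negative predictive value complement; default 0.05).
#' @param catchment_weights Named probabilities over PSC ids, or `NULL` to
#'   derive them from the region: the default upgrade set's catchments share
#'   `nearest_tsc_fraction` equally and the remaining PSCs share the rest.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, seed = 1L, age_mean = 70, age_sd = 12,
                        age_range = c(18, 100), nihss_shape = 7.11,
                        nihss_rate = 0.444,
                        collateral_probs = c(0.05, 0.30, 0.40, 0.25),
                        prestroke_probs = c(0.75, 0.15, 0.10),
                        race_false_negative_prob = 0.05,
                        catchment_weights = NULL) {
  assert_that(n >= 1, "cohort_spec: n must be >= 1")
  assert_that(abs(sum(collateral_probs) - 1) < 1e-8 &&
                all(collateral_probs >= 0),
              "cohort_spec: collateral_probs must be probabilities summing to 1")
  assert_that(abs(sum(prestroke_probs) - 1) < 1e-8 && all(prestroke_probs >= 0),
              "cohort_spec: prestroke_probs must be probabilities summing to 1")
  assert_that(race_false_negative_prob >= 0 && race_false_negative_prob <= 1,
              "cohort_spec: race_false_negative_prob must lie in [0, 1]")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 nihss_shape = nihss_shape, nihss_rate = nihss_rate,
                 collateral_probs = collateral_probs,
                 prestroke_probs = prestroke_probs,
                 race_false_negative_prob = race_false_negative_prob,
                 catchment_weights = catchment_weights),
            class = "cohort_spec")
}

default_catchment_weights <- function(region) {
  psc <- names(Filter(function(h) h$role == "PSC", region$hospitals))
  tsc_like <- default_tsc_ids(region)
  w <- stats::setNames(rep(NA_real_, length(psc)), psc)
  f <- region$nearest_tsc_fraction
  w[tsc_like] <- f / length(tsc_like)
  rest <- setdiff(psc, tsc_like)
  w[rest] <- (1 - f) / length(rest)
  w
}

#' Generate a synthetic patient cohort
#'
#' Draws covariates, the catchment assignment, the RACE screen and every
#' stochastic quantity the pathway engine can need: one draw per baseline
#' interval, the drive-the-doctor preparation draw, the ground-EMS response
#' draw for the mobile interventionalist, and uniforms deciding helicopter
#' weather failure and telemedicine preparation.  Pre-drawing everything here
#' makes scenario runs deterministic functions of the cohort, which is what
#' gives the scenario grid its common-random-number contrasts.
#'
#' @param spec A [cohort_spec()].
#' @param region A [region_config()].
#' @param intervals Named list of [dist_spec()]s; defaults to
#'   [default_intervals()].
#' @return A `data.frame` of class `stroke_cohort`, one row per patient;
#'   interval draws are in columns prefixed `iv_`.
#' @export
generate_cohort <- function(spec, region, intervals = default_intervals()) {
  assert_that(inherits(spec, "cohort_spec"),
              "generate_cohort: 'spec' must be a cohort_spec")
  assert_that(inherits(region, "region_config"),
              "generate_cohort: 'region' must be a region_config")
  missing_iv <- setdiff(cohort_interval_names(), names(intervals))
  assert_that(length(missing_iv) == 0,
              "generate_cohort: missing interval spec(s): %s",
              paste(missing_iv, collapse = ", "))
  n <- spec$n
  set.seed(spec$seed)

  lo <- stats::pnorm(spec$age_range[1], spec$age_mean, spec$age_sd)
  hi <- stats::pnorm(spec$age_range[2], spec$age_mean, spec$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), spec$age_mean, spec$age_sd)
  nihss <- pmin(pmax(round(stats::rgamma(n, spec$nihss_shape,
                                         spec$nihss_rate)), 0L), 42L)
  collateral <- sample(0:3, n, replace = TRUE, prob = spec$collateral_probs)
  prestroke <- sample(0:2, n, replace = TRUE, prob = spec$prestroke_probs)

  w <- spec$catchment_weights %||% default_catchment_weights(region)
  assert_that(all(names(w) %in% hospital_ids(region)),
              "generate_cohort: catchment weight for unknown hospital")
  catchment <- sample(names(w), n, replace = TRUE, prob = w)
  race_negative <- stats::runif(n) < spec$race_false_negative_prob

  out <- data.frame(id = sprintf("pt%06d", seq_len(n)), age = age,
                    nihss = nihss, collateral = collateral,
                    prestroke_mrs = prestroke, catchment = catchment,
                    race_negative = race_negative,
                    stringsAsFactors = FALSE)
  for (nm in cohort_interval_names())
    out[[paste0("iv_", nm)]] <- spec_sample(intervals[[nm]], n)
  out$mi_gems_response <- spec_sample(region$gems_response, n)
  out$mi_weather_u <- stats::runif(n)
  out$mi_telemed_u <- stats::runif(n)
  class(out) <- c("stroke_cohort", "data.frame")
  attr(out, "seed") <- spec$seed
  out
}

#' Extract one patient as a standalone case
#'
#' Builds the per-patient structure consumed by the scalar pathway operations
#' ([simulate_ds_baseline()], [route_patient()], [simulate_dd_patient()]):
#' covariates, the abstract origin (catchment plus on-scene leg) and the named
#' interval draws.
#'
#' @param cohort A `stroke_cohort`.
#' @param i Row index.
#' @return A list of class `patient_case`.
#' @export
cohort_case <- function(cohort, i) {
  row <- cohort[i, , drop = FALSE]
  iv_cols <- grep("^iv_", names(cohort), value = TRUE)
  draws <- stats::setNames(as.numeric(row[1, iv_cols]),
                           sub("^iv_", "", iv_cols))
  structure(list(
    id = row$id, age = row$age, nihss = row$nihss,
    collateral_grade = row$collateral, prestroke_mrs = row$prestroke_mrs,
    origin = list(catchment = row$catchment,
                  leg_minutes = draws[["scene_to_psc"]]),
    race_negative = row$race_negative,
    interval_draws = draws,
    mi_gems_response = row$mi_gems_response,
    mi_weather_u = row$mi_weather_u,
    mi_telemed_u = row$mi_telemed_u), class = "patient_case")
}

#' Draw a synthetic "recorded" sample
#'
#' Convenience fixture generator for fitting and validation tests: `n`
#' reproducible draws from a spec, standing in for recorded interval times.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of minutes.
#' @export
make_observed_sample <- function(spec, n, seed = 1L) {
  assert_that(is_scalar_number(n) && n >= 1, "make_observed_sample: n must be >= 1")
  set.seed(seed)
  spec_sample(spec, n)
}

#' Write a complete synthetic study configuration
#'
#' Emits the region + intervals + outcome-coefficient config (YAML, see
#' [write_config()]) and a cohort CSV with one row per patient, providing a
#' self-contained fixture set for external tooling.
#'
#' @param dir Output directory (created if needed).
#' @param n Cohort size for the CSV.
#' @param seed Master seed.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir, n = 1000, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  region <- make_default_region(seed)
  intervals <- default_intervals()
  coeffs <- default_coefficients()
  cfg_path <- file.path(dir, "config.yaml")
  write_config(list(region = region, intervals = intervals,
                    coefficients = coeffs), cfg_path)
  cohort <- generate_cohort(cohort_spec(n, seed), region, intervals)
  csv_path <- file.path(dir, "cohort.csv")
  utils::write.csv(as.data.frame(cohort), csv_path, row.names = FALSE)
  invisible(c(config = cfg_path, cohort = csv_path))
}
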