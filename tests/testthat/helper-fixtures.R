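# Fixtures are built in code: no data files.

# every pathway interval a point mass (deterministic chains)
pm_intervals <- function(value = 10, prep = 45) {
  iv <- lapply(stats::setNames(nm = cohort_interval_names()),
               function(nm) dist_spec("point_mass", value = value))
  iv$cta_to_angio_at_tsc <- dist_spec("point_mass", value = prep)
  iv$psc_arrival_to_cta <- dist_spec("point_mass", value = value)
  iv$mi_prep <- dist_spec("point_mass", value = 10)
  iv
}

# small deterministic region: CSC at origin, three PSCs on a line east of it
toy_region <- function(gems_response = dist_spec("point_mass", value = 9),
                       weather_prob = 0, telemedicine_prob = 1) {
  region_config(
    hospitals = list(
      hospital("csc", "CSC", 0, 5, x = 0, y = 0),
      hospital("pscA", "PSC", 15, 5, x = 15, y = 0),
      hospital("pscB", "PSC", 45, 10, x = 45, y = 0),
      hospital("pscC", "PSC", 75, 10, x = 75, y = 0)),
    travel = list(car = list(speed_kmh = 60), gems = list(speed_kmh = 60),
                  hems = list(speed_kmh = 180)),
    gems_response = gems_response,
    hems_overhead_minutes = 24,
    hems_weather_failure_prob = weather_prob,
    nearest_tsc_fraction = 0.45,
    telemedicine_prob = telemedicine_prob)
}

# cohort with full control over the stochastic columns
toy_cohort <- function(n, region, intervals = pm_intervals(), seed = 1,
                       catchment = NULL, race_negative = NULL,
                       weather_u = NULL, telemed_u = NULL,
                       gems_response = NULL) {
  psc <- names(Filter(function(h) h$role == "PSC", region$hospitals))
  w <- stats::setNames(rep(1 / length(psc), length(psc)), psc)
  ch <- generate_cohort(cohort_spec(n, seed = seed, catchment_weights = w),
                        region, intervals)
  if (!is.null(catchment)) ch$catchment <- rep_len(catchment, n)
  if (!is.null(race_negative)) ch$race_negative <- rep_len(race_negative, n)
  if (!is.null(weather_u)) ch$mi_weather_u <- rep_len(weather_u, n)
  if (!is.null(telemed_u)) ch$mi_telemed_u <- rep_len(telemed_u, n)
  if (!is.null(gems_response)) ch$mi_gems_response <- rep_len(gems_response, n)
  ch
}

# random region whose travel times live in an explicit matrix, with labelled
# patient origins as extra rows: exercises the table-lookup path
random_matrix_region <- function(seed, n_hosp = 9, n_origin = 10) {
  set.seed(seed)
  hid <- sprintf("h%02d", seq_len(n_hosp))
  oid <- sprintf("o%02d", seq_len(n_origin))
  roles <- c("CSC", sample(c(rep("PSC", n_hosp - 4), rep("TSC", 3))))
  m <- matrix(stats::runif((n_hosp + n_origin) * n_hosp, 1, 120),
              n_hosp + n_origin, n_hosp,
              dimnames = list(c(hid, oid), hid))
  for (i in seq_len(n_hosp)) m[i, i] <- 0
  hs <- lapply(seq_len(n_hosp), function(i)
    hospital(hid[i], roles[i], if (roles[i] == "CSC") 0 else i * 7, 5))
  region_config(hs,
                travel = list(car = list(matrix = m),
                              gems = list(matrix = m),
                              hems = list(matrix = m)),
                gems_response = dist_spec("point_mass", value = 9))
}

# default full-model inputs shared across tests
default_setup <- function(n = 5000, seed = 42) {
  region <- make_default_region()
  intervals <- default_intervals()
  list(region = region, intervals = intervals,
       coeffs = default_coefficients(),
       cohort = generate_cohort(cohort_spec(n, seed = seed), region,
                                intervals))
}
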