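#' Define a scenario
#'
#' One cell of the drive-the-doctor design grid: which PSCs are upgraded,
#' how patients are routed, when the mobile interventionalist is notified,
#' how the MI travels, and an optional preparation-time multiplier for
#' sensitivity analysis.  A `baseline = TRUE` spec ignores the design levers
#' and runs the drip-and-ship chain.
#'
#' @param name Unique scenario label.
#' @param tsc_ids PSC ids to upgrade; defaults to [default_tsc_ids()].
#' @param routing `"nearest_ivt"` or `"race"`.
#' @param notify `"post_cta"` or `"on_scene_race"`.
#' @param modality `"car"`, `"gems"` or `"hems"`.
#' @param prep_scale Positive multiplier on the patient preparation draw.
#' @param n_patients Cohort size used when the runner must generate one.
#' @param seed Seed for cohort regeneration.
#' @param baseline Flag the drip-and-ship baseline cell.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, tsc_ids = NULL, routing = "race",
                          notify = "post_cta", modality = "car",
                          prep_scale = 1, n_patients = 100000L, seed = 1L,
                          baseline = FALSE) {
  assert_that(prep_scale > 0, "scenario_spec: prep_scale must be > 0")
  assert_that(n_patients >= 1, "scenario_spec: n_patients must be >= 1")
  if (!baseline) {
    routing <- match.arg(routing, c("nearest_ivt", "race"))
    notify <- match.arg(notify, c("post_cta", "on_scene_race"))
    modality <- match.arg(modality, c("car", "gems", "hems"))
  }
  structure(list(name = name, tsc_ids = tsc_ids, routing = routing,
                 notify = notify, modality = modality,
                 prep_scale = prep_scale, n_patients = as.integer(n_patients),
                 seed = as.integer(seed), baseline = baseline),
            class = "scenario_spec")
}

#' The 13-cell scenario grid
#'
#' The drip-and-ship baseline plus the full design grid of three upgraded
#' TSCs crossed with routing strategy (nearest IVT facility / RACE scale),
#' MI notification moment (after CTA / on scene by RACE) and transport
#' modality (car / ground EMS / helicopter EMS), in report order.
#'
#' @param n_patients,seed Passed to every [scenario_spec()].
#' @param tsc_ids Upgrade set shared by all cells.
#' @return List of 13 `scenario_spec`s, the first flagged baseline.
#' @export
default_scenario_grid <- function(n_patients = 100000L, seed = 1L,
                                  tsc_ids = NULL) {
  grid <- expand.grid(modality = c("car", "gems", "hems"),
                      notify = c("post_cta", "on_scene_race"),
                      routing = c("nearest_ivt", "race"),
                      stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    scenario_spec(sprintf("%s/%s/%s", g$routing, g$notify, g$modality),
                  tsc_ids = tsc_ids, routing = g$routing, notify = g$notify,
                  modality = g$modality, n_patients = n_patients, seed = seed)
  })
  c(list(scenario_spec("baseline", baseline = TRUE, n_patients = n_patients,
                       seed = seed)), specs)
}

.aggregate_run <- function(sim, ppfo_vec) {
  n <- nrow(sim)
  ci <- function(x) {
    m <- mean(x)
    hw <- 1.96 * stats::sd(x) / sqrt(n)
    c(mean = m, lo = m - hw, hi = m + hw)
  }
  otg <- ci(sim$otg)
  pf <- ci(100 * ppfo_vec)
  waits_known <- !all(is.na(sim$mi_angio_arrival))
  mi_w <- sim$mi_wait[sim$mi_wait > 0]
  pt_w <- sim$patient_wait[sim$patient_wait > 0]
  list(n = n,
       mean_otg = otg[["mean"]], otg_lo = otg[["lo"]], otg_hi = otg[["hi"]],
       mean_ppfo = pf[["mean"]], ppfo_lo = pf[["lo"]], ppfo_hi = pf[["hi"]],
       mi_wait_mean = if (waits_known && length(mi_w)) mean(mi_w) else NA_real_,
       mi_wait_pct = if (waits_known) 100 * mean(sim$mi_wait > 0) else NA_real_,
       patient_wait_mean = if (waits_known && length(pt_w)) mean(pt_w)
                           else NA_real_,
       patient_wait_pct = if (waits_known) 100 * mean(sim$patient_wait > 0)
                          else NA_real_,
       tie_pct = if (waits_known)
         100 * mean(sim$mi_wait == 0 & sim$patient_wait == 0) else NA_real_,
       frac_otg_over_390 = mean(sim$otg > 390))
}

#' Run one scenario over a cohort
#'
#' Routes every patient, assembles patient and MI timelines, synchronizes
#' them, evaluates the outcome model on the resulting onset-to-groin times
#' and aggregates: mean OTG and mean PPFO with normal-approximation 95%
#' confidence intervals of the Monte Carlo mean, conditional mean waiting
#' times with the percentage of cases in which each party waits (exact ties
#' count in neither percentage), and the fraction of simulated OTG above 390
#' minutes as a diagnostic (the 390-minute rule was an input-data exclusion,
#' so simulated times are never capped or resampled).
#'
#' @param spec A [scenario_spec()].
#' @param region Base [region_config()] (not yet upgraded).
#' @param intervals Named list of [dist_spec()]s.
#' @param coeffs An [outcome_coefficients()].
#' @param cohort Optional `stroke_cohort`; regenerated from
#'   `cohort_spec(spec$n_patients, spec$seed)` when `NULL`.  Only the first
#'   `spec$n_patients` rows are used.
#' @param keep_patients Attach the per-patient trace as `$patients`.
#' @return A list of class `scenario_result`.
#' @export
run_scenario <- function(spec, region, intervals, coeffs, cohort = NULL,
                         keep_patients = FALSE) {
  assert_that(inherits(spec, "scenario_spec"),
              "run_scenario: 'spec' must be a scenario_spec")
  if (is.null(cohort))
    cohort <- generate_cohort(cohort_spec(spec$n_patients, spec$seed),
                              region, intervals)
  assert_that(nrow(cohort) >= spec$n_patients,
              "run_scenario: cohort smaller than spec$n_patients")
  cohort <- cohort[seq_len(spec$n_patients), ]

  if (spec$baseline) {
    sim <- simulate_cohort(cohort, region, "baseline")
  } else {
    reg2 <- upgrade_to_tsc(region, spec$tsc_ids %||% default_tsc_ids(region))
    sim <- simulate_cohort(cohort, reg2, spec$routing, spec$notify,
                           spec$modality, spec$prep_scale)
  }
  pf <- ppfo(coeffs, sim$otg, cohort$age, cohort$nihss, cohort$collateral)
  out <- c(list(name = spec$name, spec = spec), .aggregate_run(sim, pf))
  if (keep_patients) out$patients <- cbind(sim, ppfo = pf)
  structure(out, class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: OTG %.1f (%.1f-%.1f), PPFO %.1f%% (%.1f-%.1f)\n",
              x$name, x$mean_otg, x$otg_lo, x$otg_hi, x$mean_ppfo, x$ppfo_lo,
              x$ppfo_hi))
  invisible(x)
}

#' Run the scenario grid with common random numbers
#'
#' Runs every spec on the *same* cohort so between-scenario contrasts reuse
#' identical patient draws, and reports each cell's change versus the
#' baseline cell in minutes of OTG and percentage points of PPFO.
#'
#' @param specs List of [scenario_spec()]s with unique names, exactly one
#'   flagged baseline.
#' @param region,intervals,coeffs,cohort As in [run_scenario()]; a `NULL`
#'   cohort is generated once from the first spec's size and seed.
#' @return A `data.frame` of class `scenario_table`, one row per scenario in
#'   input order, with columns for means, confidence bounds, waiting
#'   statistics and deltas versus baseline.
#' @export
run_scenario_grid <- function(specs, region, intervals, coeffs,
                              cohort = NULL) {
  assert_that(length(specs) >= 1, "run_scenario_grid: no scenarios")
  nms <- vapply(specs, `[[`, character(1), "name")
  assert_that(!anyDuplicated(nms),
              "run_scenario_grid: duplicate scenario name(s): %s",
              paste(nms[duplicated(nms)], collapse = ", "))
  is_base <- vapply(specs, `[[`, logical(1), "baseline")
  assert_that(sum(is_base) == 1,
              "run_scenario_grid: exactly one baseline spec required (found %d)",
              sum(is_base))
  if (is.null(cohort))
    cohort <- generate_cohort(cohort_spec(specs[[1]]$n_patients,
                                          specs[[1]]$seed), region, intervals)
  results <- lapply(specs, run_scenario, region = region,
                    intervals = intervals, coeffs = coeffs, cohort = cohort)
  base <- results[[which(is_base)]]
  rows <- lapply(results, function(r) {
    data.frame(scenario = r$name, routing = r$spec$routing,
               notify = r$spec$notify, modality = r$spec$modality,
               baseline = r$spec$baseline, n = r$n,
               mean_otg = r$mean_otg, otg_lo = r$otg_lo, otg_hi = r$otg_hi,
               mean_ppfo = r$mean_ppfo, ppfo_lo = r$ppfo_lo,
               ppfo_hi = r$ppfo_hi, mi_wait_mean = r$mi_wait_mean,
               mi_wait_pct = r$mi_wait_pct,
               patient_wait_mean = r$patient_wait_mean,
               patient_wait_pct = r$patient_wait_pct, tie_pct = r$tie_pct,
               delta_otg_vs_baseline = r$mean_otg - base$mean_otg,
               delta_ppfo_vs_baseline = r$mean_ppfo - base$mean_ppfo,
               frac_otg_over_390 = r$frac_otg_over_390,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_table", "data.frame")
  attr(out, "baseline") <- base$name
  out
}

#' Preparation-time sensitivity analysis
#'
#' Re-runs each drive-the-doctor scenario with the patient preparation draw
#' (`cta_to_angio_at_tsc`) scaled by each factor and reports the change in
#' mean OTG and mean PPFO versus the unscaled run of the same scenario, under
#' common random numbers.
#'
#' @param specs List of non-baseline [scenario_spec()]s.
#' @param region,intervals,coeffs,cohort As in [run_scenario()].
#' @param scales Multipliers; 0.75 and 1.25 probe preparation 25% shorter
#'   and longer.
#' @return A `data.frame`: scenario, scale, scaled and unscaled means, and
#'   the OTG / PPFO deltas.
#' @export
sensitivity_analysis <- function(specs, region, intervals, coeffs,
                                 cohort = NULL, scales = c(0.75, 1.25)) {
  assert_that(all(scales > 0), "sensitivity_analysis: scales must be > 0")
  specs <- Filter(function(s) !s$baseline, specs)
  assert_that(length(specs) >= 1,
              "sensitivity_analysis: no drive-the-doctor scenarios supplied")
  if (is.null(cohort))
    cohort <- generate_cohort(cohort_spec(specs[[1]]$n_patients,
                                          specs[[1]]$seed), region, intervals)
  rows <- list()
  for (s in specs) {
    ref <- run_scenario(s, region, intervals, coeffs, cohort)
    for (sc in scales) {
      s2 <- s
      s2$prep_scale <- s$prep_scale * sc
      r <- run_scenario(s2, region, intervals, coeffs, cohort)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = s$name, scale = sc, mean_otg = r$mean_otg,
        mean_otg_unscaled = ref$mean_otg, mean_ppfo = r$mean_ppfo,
        mean_ppfo_unscaled = ref$mean_ppfo,
        delta_otg = r$mean_otg - ref$mean_otg,
        delta_ppfo = r$mean_ppfo - ref$mean_ppfo, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Validate simulated times against recorded times
#'
#' Side-by-side mean / median / SD / minimum / maximum of simulated and
#' observed samples with absolute and relative differences — the numerical
#' validation used to accept a baseline model against registry data.
#'
#' @param simulated,observed Non-empty numeric vectors of minutes.
#' @return A 5-row `data.frame` with columns `statistic`, `simulated`,
#'   `observed`, `abs_diff`, `rel_diff`.
#' @export
validate_baseline <- function(simulated, observed) {
  s <- summary_stats(simulated)
  o <- summary_stats(observed)
  data.frame(statistic = names(s), simulated = as.numeric(s),
             observed = as.numeric(o), abs_diff = as.numeric(s - o),
             rel_diff = as.numeric(ifelse(o != 0, (s - o) / o, NA)),
             stringsAsFactors = FALSE)
}

#' Write scenario reports
#'
#' Writes `scenarios.csv` (report layout: times and percentages rounded to 1
#' decimal) and `scenarios.json` (full precision plus run metadata: package
#' version, baseline name, cohort size).  Re-running on the same table
#' reproduces identical files.
#'
#' @param results A `scenario_table` from [run_scenario_grid()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(results, dir) {
  assert_that(nrow(results) >= 1, "write_report: empty results table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, "scenarios.csv")
  json_path <- file.path(dir, "scenarios.json")
  rounded <- as.data.frame(results)
  num <- vapply(rounded, is.numeric, logical(1)) &
    !names(rounded) %in% c("n")
  rounded[num] <- lapply(rounded[num], round, digits = 1)
  utils::write.csv(rounded, csv_path, row.names = FALSE, na = "")
  payload <- list(
    metadata = list(package = "strokesim",
                    version = as.character(utils::packageVersion("strokesim")),
                    baseline = attr(results, "baseline"),
                    n_patients = results$n[1]),
    results = as.data.frame(results))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}
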