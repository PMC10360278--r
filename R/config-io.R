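# YAML configuration round-trip for region, interval set and outcome
# coefficients.  The reader validates field by field and reports the YAML
# path of the offending entry, so malformed files fail with a message that
# identifies the line to fix.

.spec_to_list <- function(spec) {
  out <- list(family = spec$family)
  out <- c(out, spec$params)
  if (spec$shift != 0) out$shift <- spec$shift
  if (!is.null(spec$truncation)) out$truncation <- as.numeric(spec$truncation)
  out
}

.spec_from_list <- function(x, where) {
  assert_that(is.list(x) && !is.null(x$family),
              "config %s: expected a distribution block with a 'family' field",
              where)
  fam <- x$family
  params <- x[setdiff(names(x), c("family", "shift", "truncation"))]
  tryCatch(
    do.call(dist_spec, c(list(family = fam), params,
                         list(shift = x$shift %||% 0,
                              truncation = x$truncation))),
    error = function(e) stop_config("config %s: %s", where,
                                    conditionMessage(e)))
}

#' Write a study configuration to YAML
#'
#' Serializes any subset of `region`, `intervals` and `coefficients` into a
#' single YAML file that [read_config()] can restore.  Travel models are
#' written as speeds and/or explicit matrices, distribution specs as
#' family + parameter blocks.
#'
#' @param config Named list with elements `region` ([region_config()]),
#'   `intervals` (named list of [dist_spec()]) and/or `coefficients`
#'   ([outcome_coefficients()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list()
  if (!is.null(config$region)) {
    r <- config$region
    out$region <- list(
      hospitals = lapply(unname(r$hospitals), function(h)
        Filter(Negate(is.null),
               list(id = h$id, role = h$role,
                    distance_to_csc = h$distance_to_csc,
                    angio_transfer_minutes = h$angio_transfer_minutes,
                    x = h$x, y = h$y))),
      travel = lapply(r$travel, function(tt) {
        Filter(Negate(is.null),
               list(speed_kmh = tt$speed_kmh,
                    matrix = if (!is.null(tt$matrix)) {
                      m <- tt$matrix
                      stats::setNames(lapply(rownames(m), function(a)
                        as.list(stats::setNames(m[a, ], colnames(m)))),
                        rownames(m))
                    }))
      }),
      gems_response = .spec_to_list(r$gems_response),
      hems_overhead_minutes = r$hems_overhead_minutes,
      hems_weather_failure_prob = r$hems_weather_failure_prob,
      nearest_tsc_fraction = r$nearest_tsc_fraction,
      telemedicine_prob = r$telemedicine_prob)
  }
  if (!is.null(config$intervals))
    out$intervals <- lapply(config$intervals, .spec_to_list)
  if (!is.null(config$coefficients)) {
    co <- config$coefficients
    out$coefficients <- list(cutpoints = co$cutpoints,
                             beta_otg = co$beta_otg, beta_age = co$beta_age,
                             beta_nihss = co$beta_nihss,
                             beta_collateral = co$beta_collateral,
                             otg_scale = co$otg_scale)
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' Restores the objects written by [write_config()], validating every block
#' and naming the offending YAML path on failure.
#'
#' @param path YAML file path.
#' @return Named list with any of `region`, `intervals`, `coefficients`.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "read_config: no such file '%s'", path)
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$region)) {
    r <- raw$region
    assert_that(is.list(r$hospitals) && length(r$hospitals) >= 1,
                "config region.hospitals: need a non-empty hospital list")
    hs <- lapply(seq_along(r$hospitals), function(i) {
      h <- r$hospitals[[i]]
      for (f in c("id", "role"))
        assert_that(!is.null(h[[f]]), "config region.hospitals[%d]: missing '%s'",
                    i, f)
      tryCatch(
        hospital(h$id, h$role, h$distance_to_csc %||% 0,
                 h$angio_transfer_minutes %||% 10, x = h$x, y = h$y),
        error = function(e) stop_config("config region.hospitals[%d]: %s", i,
                                        conditionMessage(e)))
    })
    travel <- lapply(r$travel, function(tt) {
      m <- NULL
      if (!is.null(tt$matrix)) {
        rows <- names(tt$matrix)
        cols <- unique(unlist(lapply(tt$matrix, names)))
        m <- matrix(NA_real_, length(rows), length(cols),
                    dimnames = list(rows, cols))
        for (a in rows) for (b in names(tt$matrix[[a]]))
          m[a, b] <- tt$matrix[[a]][[b]]
        assert_that(all(m[!is.na(m)] >= 0),
                    "config region.travel: negative travel time in matrix")
      }
      list(speed_kmh = tt$speed_kmh, matrix = m)
    })
    out$region <- tryCatch(
      region_config(hs, travel,
                    .spec_from_list(r$gems_response, "region.gems_response"),
                    hems_overhead_minutes = r$hems_overhead_minutes %||% 24,
                    hems_weather_failure_prob =
                      r$hems_weather_failure_prob %||% 0.15,
                    nearest_tsc_fraction = r$nearest_tsc_fraction %||% 0.45,
                    telemedicine_prob = r$telemedicine_prob %||% 1),
      error = function(e) stop_config("config region: %s",
                                      conditionMessage(e)))
  }
  if (!is.null(raw$intervals)) {
    out$intervals <- lapply(stats::setNames(names(raw$intervals),
                                            names(raw$intervals)),
                            function(nm) .spec_from_list(raw$intervals[[nm]],
                                                         paste0("intervals.",
                                                                nm)))
  }
  if (!is.null(raw$coefficients)) {
    co <- raw$coefficients
    out$coefficients <- tryCatch(
      outcome_coefficients(as.numeric(co$cutpoints), co$beta_otg, co$beta_age,
                           co$beta_nihss, as.numeric(co$beta_collateral),
                           otg_scale = co$otg_scale %||% 1),
      error = function(e) stop_config("config coefficients: %s",
                                      conditionMessage(e)))
  }
  out
}
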